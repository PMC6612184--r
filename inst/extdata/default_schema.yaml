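# Default trait-table schema: controlled vocabularies, alias map and
# substrate catalog for culture-derived bacterial trait databases.
binary_traits:
  - spore_formation
  - pigment_production
  - catalase
  - oxidase
  - urease
  - alkaline_phosphatase
  - acid_phosphatase
  - gelatinase
  - aesculin_hydrolysis
  - alpha_galactosidase
  - arylsulfatase
  - pyrazinamidase
  - tellurite_reductase
  - methane_production
  - h2s_production
  - indole_production
  - nitrate_reduction
categorical_traits:
  oxygen_use: [aerobic, facultative, anaerobic, microaerophilic]
  motility: [none, flagella, gliding, axial_filament, other]
  shape: [coccus, coccobacillus, bacillus, spirillum, other]
  gram_stain: [positive, negative, variable]
  aggregation: [singly, chains, clumps]
quantitative_traits:
  - gc_content
  - temperature_min
  - temperature_max
  - temperature_optimum
  - temperature_range
  - ph_min
  - ph_max
  - ph_optimum
  - ph_range
  - nacl_min
  - nacl_max
  - nacl_optimum
  - nacl_range
substrates:
  organic_acid:
    [acetate, citrate, formate, gluconate, malate, malonate, pyruvate,
     succinate, valerate, lactate, caprate, quinate, ketogluconate_2]
  amino_acid:
    [alanine, asparagine, aspartate, glutamate, glycine, leucine,
     proline, serine]
  monosaccharide: [glucose, fructose, xylose, rhamnose, glucosamine]
  oligo_polysaccharide: [cellobiose, maltose, starch]
  alcohol: [ethanol, butanol, xylitol]
  other: [urea, gelatin, thymidine]
alias_map:
  positive: ["+", "pos", "positive", "yes", "y", "1", "true"]
  negative: ["-", "neg", "negative", "no", "n", "0", "false"]
  unknown: ["", "nd", "n.d.", "na", "n/a", "?", "unknown"]
  variable: ["v", "var", "variable"]
multi_value_separator: ";"
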