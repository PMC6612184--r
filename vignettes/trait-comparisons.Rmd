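---
title: "Comparing bacterial trait databases: models, tests and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing bacterial trait databases: models, tests and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skintraits)
```

## The problem

Culture experiments have produced decades of phenotype data for bacterial
species: enzyme activities, oxygen requirements, cell shape, growth ranges
for temperature, pH and salt, and the carbon substrates a species can use.
`skintraits` turns such culture-derived trait tables into statistical
comparisons between communities — in the motivating application, between
the bacteria detected on human skin and bacteria described without habitat
bias ("the world"), and between skin microenvironments (dry, moist,
sebaceous). The package covers the full path: a schema-driven data model
with explicit unknowns, abundance-threshold screening of which species
count as community members, three families of tests matched to the three
trait classes, phylogenetically corrected regressions, and a synthetic-data
generator with known ground truth that calibrates every stage.

## Data model and unknowns

A trait database is one row per species. Binary traits (spore formation,
pigment production, eleven enzymes, gas production, nitrate reduction, and
per-substrate usage) take the states positive / negative / unknown.
Categorical traits carry a controlled vocabulary (oxygen use, motility,
shape, Gram stain, aggregation), and quantitative traits are GC content
plus min/optimum/max/range triples for temperature, pH and NaCl. The
schema — vocabularies, substrate catalog, and the alias map that
normalises raw tokens such as `+`, `-`, `ND`, `v` — lives in YAML, so new
trait classes need no code change.

Two semantics decisions shape everything downstream:

* **Known-only denominators.** Culture literature leaves many cells
  unknown. Every proportion and mean in the package is computed over known
  values only, and every result carries its `n`, so a prevalence of 0.75
  from 3 positives, 1 negative and 2 unknowns is reported as (k = 3,
  n = 4). With unknowns missing at random this estimates the same
  population quantity as a complete table, at reduced precision; under
  informative missingness (a trait assayed only in certain genera) it can
  be biased, which is why `n` is always attached.
* **Multi-valued categorical cells.** A species can aggregate both singly
  and in clumps. We record all levels and count the species once per level
  it exhibits, so level proportions need not sum to one. The alternative
  (first level wins) discards curated information and makes results depend
  on cell ordering.

A `v` token records strain variation: the value is treated as unknown but
the species/trait pair is flagged, and the flag survives a write/read
round trip. Missing `range` cells are derived as `max - min`; an explicit
conflicting range is kept and surfaced as a validation warning, because a
curated number should not be silently overwritten by an arithmetic rule.

## Screening community members

Species lists come from a read-classification summary: a species is "in"
the community when its relative abundance strictly exceeds 0.001% of reads
in at least one sample, and "abundant" above 0.1%. Comparisons are strict
(`>`) so a species exactly at a threshold is excluded; containment of the
abundant set in the all-taxa set is then automatic, and both thresholds
are recorded in the set's provenance. Site-specific sets apply the same
thresholds restricted to samples of one site class. Abundances are used
as reported, with no re-normalisation after dropping non-species rows:
screening is defined on read fractions, not on a renormalised composition.

## The three test families

**Binary traits.** Per group, the proportion positive with its binomial
standard error `sqrt(p(1-p)/n)`. The overall test is a Pearson chi-square
on the positive/negative by group table (no continuity correction);
pairwise contrasts use `z = (p1 - p2)/sqrt(se1^2 + se2^2)` with a
two-sided normal p-value. When both proportions sit on a common boundary
(both SEs zero), p = 1 by convention and the result is flagged. A pooled
variance option makes `z^2` equal the 2x2 chi-square exactly.

**Categorical traits.** A randomization test of equality of level
proportions: group labels are permuted (outcomes fixed), the per-level
statistic is the range of level proportions across groups, and the
per-level p-value is the add-one-corrected two-sided permutation p,
`(1 + #{|D*| >= |D|})/(B + 1)`, which is never below `1/(B+1)`. Because
level-wise over/under-representation is the scientific output of what is
nominally an overall test, an overall p from the maximum per-level
statistic under the same permutations is reported next to the level-wise
values. The fraction of resamples *less* extreme than the observation is
also reported, for readers who think of the permutation p in its
complementary form. The default is 1e5 resamples; an exact enumeration
mode exists for small groups. No multiple-testing correction is applied
across traits by default; a Benjamini-Hochberg switch exists but is off,
matching the analysis style the package reproduces.

**Quantitative traits.** The nonparametric relative effect
`p = P(X < Y) + 0.5 P(X = Y)` estimated from midranks of the pooled
sample; the implementation is algebraically the brute-force pair count
but runs in `n log n`. Inference is Brunner-Munzel: placement-based
variance, studentized statistic, Satterthwaite degrees of freedom —
robust to non-normality and unequal variances. For more than two groups,
all pairs are compared and the family-wise adjustment uses the
equicoordinate probability of a multivariate normal whose correlation is
estimated from the placement influence functions shared between
contrasts (the Tukey-type construction for rank statistics), evaluated
by seeded quasi-Monte-Carlo; a singular correlation estimate falls back
to a flagged Sidak bound. Degenerate all-tied inputs give flagged
conventional outputs (p = 1 at relative effect 1/2, else the minimum
attainable two-sided permutation p) rather than NaN.

## Phylogenetically corrected regressions

Trait differences between communities can reflect shared ancestry rather
than ecology: a few successful clades can carry their traits to high
prevalence. To probe this, group membership is regressed on each trait
individually, once naively (ordinary logistic regression, species
independent) and once with a phylogenetic correction, and each regression
is screened against its intercept-only null by a likelihood-ratio test
(chi-square, df = number of trait coefficients).

The corrected model is a logistic regression with a Gaussian random
effect on the log-odds scale built from independent increments on the
*internal* edges of the tree (scaled to unit height). An increment on an
edge is shared by exactly the species descending from it, so the random
effect encodes shared evolutionary history and nothing else; a star tree
has no internal edges, the random effect vanishes identically, and the
fit reduces — exactly, not approximately — to the naive regression.
Increment variances are damped by a mean-reversion rate `alpha`
(`integral of exp(-2 alpha (T - t))` along the edge): `alpha -> 0` gives
Brownian accumulation of shared history, large `alpha` forgets ancestry
quickly. The magnitude `s2` and `alpha` are estimated jointly with the
coefficients by maximising the Laplace-approximated marginal likelihood
(inner Newton over coefficients and random effect, outer box-constrained
quasi-Newton over `log s2`, `log alpha`, convergence tolerance 1e-8 on
the log-likelihood, up to 200 outer iterations, seeded random restarts
for the signal parameters). The reported log-likelihood is the Laplace
value, which is comparable between the full and intercept-only fits
because both carry the same random-effect structure; likelihood-ratio
statistics are clipped at zero and an apparent decrease beyond tolerance
is raised as an optimisation failure rather than reported. Complete
separation is flagged, not hidden.

This estimator is a deliberate design choice: it keeps a true
(approximated) likelihood for LRT screening, reduces exactly to the
naive fit when the tree carries no shared history, and in simulations is
conservative where naive regression is anti-conservative (both variables
phylogenetically clumped, no true effect). `ape::binaryPGLMM`, an
independent implementation of binary-trait PGLMM, is used in the test
suite as a cross-check of the fitted effect, never as the engine.
Categorical predictors are dummy-coded against a configurable reference
level; quantitative traits are not phylogenetically corrected, matching
the analysis the package reproduces. Species missing from the tree are
pruned and counted, and name matching is case-insensitive with
underscores equal to spaces.

## The synthetic-data generator

The generator is the package's ground truth, not a convenience fixture.
Its defaults are fixed at the study-like conditions the package targets:
200 "skin" species against 500 "world" species; an abundant-skin
spore-formation prevalence of 3% against 22.5% in the world; catalase,
oxidase and the phosphatases less common on skin; a facultative-heavy
oxygen profile against an aerobic-heavy one; pH optimum near 7.06 with a
range near 2.41 on skin against a wider 3.38 in the world; optimum
temperature about two degrees warmer on skin; GC content a few points
lower; 20% of cells unknown, injected completely at random (a
phylum-correlated missingness mode exists for robustness probing but is
off by default). Quantitative min/optimum/max/range quadruples are drawn
coherently — the optimum at a jittered interior point of the interval —
so range invariants hold by construction, and NaCl intervals are shifted
to stay nonnegative. Abundance profiles are log-normal, normalised per
sample to 90% of reads (the remainder emulating unclassified reads),
with the designated abundant taxa strictly exceeding 0.1% in at least
one sample and every other live taxon capped below it, so the screening
truth is exact by construction. Trees are pure-birth (rate 1, unit
height); conserved binary traits evolve as two-state Markov chains from
a stationary root draw.

What the generator does *not* emulate: taxonomic misclassification,
compositional coupling between taxa, informative missingness tied to
culture difficulty, and real phylogenies' non-ultrametric, imbalanced
shapes. Passing tests therefore demonstrate correctness of the
statistical machinery under the stated model, not robustness of the
biological conclusions to those data pathologies.

## Numerical choices and degenerate inputs

Permutation p-values are add-one corrected and exactly reproducible
given a seed; the package treats seeds as part of a configuration, and a
pipeline rerun with the same configuration writes byte-identical result
tables (numbers are formatted at 10 significant digits for that reason).
Randomization with two groups of identical composition returns p = 1.
Chi-square tests refuse degenerate margins and flag expected cells below
five. Logistic fits floor working weights at 1e-10; trees are rescaled
to unit height before fitting so `alpha` is comparable across inputs.
Problem sizes in the shipped tests — for example 200 sign-recovery
replicates on 200-tip trees, 120 clade-null replicates on 80-tip trees,
1000-replicate type-I calibrations — were chosen to keep Monte-Carlo
error well inside the asserted bounds while the full suite stays
comfortably runnable on a laptop.

## Known limitations

Species identity is an exact string key (after case/underscore
normalisation); no synonym resolution is attempted. The corrected
regression assumes the mean-reverting shared-history model described
above — it is one member of the family of phylogenetic logistic models,
fixed here as the reference behaviour with its settings recorded in
every fit. Abundant-versus-all contrasts compare a set with its superset
using tests that assume independent groups, as in the analysis style the
package reproduces; the resulting p-values are conservative in the usual
direction but are not a two-independent-sample inference. Quantitative
site contrasts with more than two groups are validated by simulation
only.
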