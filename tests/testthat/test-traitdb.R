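test_that("trait tables parse through the alias map with a parse report", {
  path <- write_toy_trait_tsv(tempfile(fileext = ".tsv"))
  db <- read_trait_table(path)
  d <- db$data
  expect_equal(d$catalase[d$species == "Staphylococcus epidermidis"],
               "positive")
  # "ND" becomes unknown and is listed in the parse report
  expect_true(is.na(d$oxidase[d$species == "Staphylococcus epidermidis"]))
  expect_true(any(db$parse_report$column == "oxidase" &
                    db$parse_report$action == "coerced to unknown"))
  # "v" records strain variation, value unknown
  expect_true(is.na(d$spore_formation[d$species == "Cutibacterium acnes"]))
  expect_equal(db$strain_variation$trait, "spore_formation")
  # missing range derived as max - min
  expect_equal(d$temperature_range[d$species == "Staphylococcus epidermidis"],
               25)
  # explicit range kept even where inconsistent (17 for a 17-degree span)
  expect_equal(d$temperature_range[d$species == "Cutibacterium acnes"], 17)
  # multi-valued categorical retains all levels
  expect_equal(d$aggregation[d$species == "Staphylococcus epidermidis"],
               "clumps;singly")
})

test_that("structural problems are errors with coordinates", {
  path <- write_toy_trait_tsv(tempfile(fileext = ".tsv"), extra_col = TRUE)
  expect_error(read_trait_table(path), "unknown column")
  db <- read_trait_table(path, ignore_extra = TRUE)
  expect_true(any(db$parse_report$column == "mystery"))

  dup <- tempfile(fileext = ".tsv")
  writeLines(c("species\tphylum\tcatalase",
               "A b\tFirmicutes\t+", "A b\tFirmicutes\t-"), dup)
  expect_error(read_trait_table(dup), "duplicate species")

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("species\tphylum\toxygen_use",
               "A b\tFirmicutes\tphotosynthetic"), bad)
  expect_error(read_trait_table(bad), "vocabulary.*oxygen_use|not in vocabulary")
})

test_that("read -> write -> read round-trips identically", {
  sim <- gen_trait_database(simulation_spec(n_taxa = c(40, 40), seed = 21))
  t1 <- tempfile(fileext = ".tsv"); t2 <- tempfile(fileext = ".tsv")
  write_trait_table(sim$db_a, t1)
  db1 <- read_trait_table(t1)
  write_trait_table(db1, t2)
  db2 <- read_trait_table(t2)
  expect_identical(db1$data, db2$data)
  expect_identical(db1$strain_variation, db2$strain_variation)
})

test_that("prevalence uses known-value denominators", {
  d <- data.frame(
    species = paste("sp", 1:6), phylum = "Firmicutes",
    catalase = c("positive", "positive", "positive", "negative", NA, NA),
    stringsAsFactors = FALSE)
  db <- trait_db(d)
  pv <- trait_prevalence(db, NULL, "catalase")
  expect_equal(pv$k, 3)
  expect_equal(pv$n, 4)
  expect_equal(pv$proportion, 0.75)
  expect_false(pv$flagged)

  pv0 <- trait_prevalence(db, NULL, "oxidase") # all unknown
  expect_true(pv0$flagged)
  expect_true(is.na(pv0$proportion))
  expect_error(trait_prevalence(db, NULL, "no_such_trait"), "unknown trait")
  # k <= n <= |set|
  expect_lte(pv$k, pv$n)
  expect_lte(pv$n, nrow(d))
})

test_that("single-valued categorical level proportions sum to one", {
  sim <- gen_trait_database(
    simulation_spec(n_taxa = c(80, 80), missingness = 0.3, seed = 5))
  db <- sim$db_a
  levs <- db$schema$categorical_traits$oxygen_use
  props <- vapply(levs, function(l)
    trait_prevalence(db, NULL, c("oxygen_use", l))$proportion, numeric(1))
  expect_equal(sum(props), 1, tolerance = 1e-12)
})

test_that("quantitative summaries ignore unknowns; range = max - min", {
  d <- data.frame(species = c("a b", "c d", "e f"), phylum = "x",
                  gc_content = c(30, 40, NA), stringsAsFactors = FALSE)
  db <- trait_db(d)
  sm <- summarize_quantitative(db, NULL, "gc_content")
  expect_equal(sm$mean, 35)
  expect_equal(sm$n, 2)
  expect_error(summarize_quantitative(db, NULL, "volume"), "unknown")

  sim <- gen_trait_database(simulation_spec(n_taxa = c(60, 60), seed = 8))
  dd <- sim$db_a$data
  both <- !is.na(dd$ph_min) & !is.na(dd$ph_max) & !is.na(dd$ph_range)
  expect_equal(dd$ph_range[both], (dd$ph_max - dd$ph_min)[both],
               tolerance = 1e-9)
})

test_that("validation reports bounds errors and range warnings", {
  d <- data.frame(species = c("a b", "c d"), phylum = "x",
                  gc_content = c(150, 50),
                  ph_min = c(5, 5), ph_max = c(8, 8),
                  ph_optimum = c(9, 7), ph_range = c(3, 3),
                  stringsAsFactors = FALSE)
  db <- trait_db(d)
  rep <- validate_trait_db(db)
  expect_s3_class(rep, "validation_report")
  sev <- rep$violations$severity[rep$violations$column == "gc_content"]
  expect_equal(sev, "error")
  expect_true(any(rep$violations$severity == "warning" &
                    rep$violations$column == "ph_optimum"))
  # fully clean record set yields no violations
  clean <- trait_db(data.frame(species = "a b", phylum = "x",
                               gc_content = 50, stringsAsFactors = FALSE))
  expect_equal(nrow(validate_trait_db(clean)$violations), 0)

  jl <- tempfile(fileext = ".jsonl")
  write_validation_report(rep, jl)
  lines <- readLines(jl)
  expect_equal(length(lines), nrow(rep$violations))
  expect_true(all(vapply(lines, jsonlite::validate, logical(1))))
})
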