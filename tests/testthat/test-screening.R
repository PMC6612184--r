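write_report <- function(path, wide = TRUE) {
  if (wide) {
    writeLines(c("taxon\trank\ts1\ts2",
                 "Staphylococcus epidermidis\tspecies\t12\t0.05",
                 "Staphylococcus\tgenus\t15\t1",
                 "Cutibacterium acnes\tS\t0.0005\t0.2"), path)
  } else {
    writeLines(c("taxon\tsample\tpercent\trank",
                 "Staphylococcus epidermidis\ts1\t12\tspecies",
                 "Staphylococcus epidermidis\ts2\t0.05\tspecies",
                 "Cutibacterium acnes\ts1\t0.0005\tspecies",
                 "Cutibacterium acnes\ts2\t0.2\tspecies",
                 "Staphylococcus\ts1\t15\tgenus"), path)
  }
  path
}

test_that("wide and long classification reports parse identically", {
  w <- read_classification_report(write_report(tempfile(), wide = TRUE))
  l <- read_classification_report(write_report(tempfile(), wide = FALSE))
  expect_equal(dim(w$values), c(2, 2))
  expect_equal(w$values[sort(rownames(w$values)), sort(colnames(w$values))],
               l$values[sort(rownames(l$values)), sort(colnames(l$values))])
  # genus rows skipped and counted
  expect_equal(attr(w, "skipped"), 1L)
  expect_equal(attr(l, "skipped"), 1L)
})

test_that("degenerate reports are rejected", {
  empty <- tempfile(); writeLines("taxon\trank\ts1", empty)
  expect_error(read_classification_report(empty), "no species rows")
  allgenus <- tempfile()
  writeLines(c("taxon\trank\ts1", "Staph\tgenus\t5"), allgenus)
  expect_error(read_classification_report(allgenus), "no species rows")
  neg <- tempfile()
  writeLines(c("taxon\ts1", "A b\t-1"), neg)
  expect_error(read_classification_report(neg), "negative")
})

test_that("metadata join labels unknown samples unclassified", {
  rp <- write_report(tempfile())
  md <- tempfile()
  writeLines(c("sample_id\tsite\tsite_class", "s1\tforearm\tdry"), md)
  expect_warning(tab <- read_classification_report(rp, md), "unclassified")
  expect_equal(unname(tab$site_class[c("s1", "s2")]),
               c("dry", "unclassified"))
})

test_that("threshold screening is strict and monotone", {
  m <- matrix(c(0.05, 0, 0.1, 0.05, 0.3, 0.2), nrow = 3, byrow = TRUE,
              dimnames = list(c("low sp", "edge sp", "high sp"),
                              c("s1", "s2")))
  tab <- abundance_table(m)
  all_set <- select_taxa(tab, 0.001)
  ab_set <- select_taxa(tab, 0.1)
  expect_true("low sp" %in% all_set$members)   # 0.05 > 0.001
  expect_false("low sp" %in% ab_set$members)   # 0.05 <= 0.1
  expect_false("edge sp" %in% ab_set$members)  # exactly 0.1 excluded
  expect_true("high sp" %in% ab_set$members)
  expect_setequal(select_taxa(tab, 0)$members, rownames(m))
  expect_true(all(ab_set$members %in% all_set$members))
})

test_that("screening is invariant to sample order and zero duplicates", {
  g <- gen_abundance_table(30, 8, seed = 3)
  tab <- g$table
  perm <- sample(ncol(tab$values))
  tab2 <- abundance_table(tab$values[, perm], tab$site_class[perm])
  expect_setequal(select_taxa(tab, 0.1)$members,
                  select_taxa(tab2, 0.1)$members)
  # monotonicity over random thresholds
  for (t2 in c(0.01, 0.05, 0.2)) {
    s_lo <- select_taxa(tab, 0.001)$members
    s_hi <- select_taxa(tab, t2)$members
    expect_true(all(s_hi %in% s_lo))
  }
  expect_error(select_taxa(tab, 0.1, restrict_to_sites = "nosuch"),
               "excludes all samples")
})

test_that("stratification partitions by phylum and reports strays", {
  d <- data.frame(species = paste("sp", 1:5),
                  phylum = c("Firmicutes", "Firmicutes", "Firmicutes",
                             "Proteobacteria", "Proteobacteria"),
                  stringsAsFactors = FALSE)
  db <- trait_db(d)
  st <- stratify(taxon_set("all", c(d$species, "ghost sp")), db)
  expect_equal(length(st$Firmicutes$members), 3)
  expect_equal(length(st$Proteobacteria$members), 2)
  expect_equal(attr(st, "unlabeled"), "ghost sp")
  empty <- stratify(taxon_set("none", character(0)), db)
  expect_equal(length(empty), 0)
})
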