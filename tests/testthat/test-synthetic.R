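test_that("pure-birth trees are reproducible, named and unit-height", {
  t2 <- gen_tree(2, seed = 4)
  expect_equal(length(t2$tip.label), 2)
  ta <- gen_tree(100, seed = 9)
  tb <- gen_tree(100, seed = 9)
  expect_identical(ape::write.tree(ta), ape::write.tree(tb))
  expect_false(identical(ape::write.tree(ta),
                         ape::write.tree(gen_tree(100, seed = 10))))
  depths <- ape::node.depth.edgelength(ta)[1:100]
  expect_equal(max(depths), 1, tolerance = 1e-12)
  expect_equal(mean(depths), 1, tolerance = 1e-9) # ultrametric
  expect_error(gen_tree(1), ">= 2")
})

test_that("two-state Markov traits respect rates and determinism", {
  tr <- gen_tree(800, seed = 21)
  # fast symmetric evolution: tip prevalence near the stationary 1/2
  v <- sim_binary_trait_on_tree(tr, 8, 8, seed = 3)
  expect_gt(mean(v), 0.40)
  expect_lt(mean(v), 0.60)
  # asymmetric rates pull prevalence toward rate01/(rate01+rate10)
  va <- sim_binary_trait_on_tree(tr, 9, 3, seed = 4)
  expect_gt(mean(va), 0.60)
  # near-zero rates: tips overwhelmingly share the root state
  tr2 <- gen_tree(300, seed = 22)
  vs <- sim_binary_trait_on_tree(tr2, 0.001, 0.001, seed = 5)
  expect_gte(max(mean(vs), 1 - mean(vs)), 0.99)
  expect_identical(sim_binary_trait_on_tree(tr2, 1, 1, seed = 6),
                   sim_binary_trait_on_tree(tr2, 1, 1, seed = 6))
  expect_error(sim_binary_trait_on_tree(tr2, 0, 1), "positive")
})

test_that("generated databases satisfy the schema invariants", {
  spec <- simulation_spec(n_taxa = c(60, 80), missingness = 0.25, seed = 31)
  sim <- gen_trait_database(spec)
  for (db in list(sim$db_a, sim$db_b)) {
    rep <- validate_trait_db(db)
    expect_equal(sum(rep$violations$severity == "error"), 0)
    expect_equal(sum(rep$violations$severity == "warning"), 0)
  }
  expect_equal(nrow(sim$db_a$data), 60)
  expect_equal(nrow(sim$db_b$data), 80)
  expect_identical(sim$truth$spec, spec)
  # missingness lands near its nominal rate across simulated binary traits
  sim_bin <- intersect(names(spec$binary), sim$db_a$schema$binary_traits)
  miss <- mean(is.na(as.matrix(sim$db_a$data[, sim_bin])))
  expect_gt(miss, 0.15); expect_lt(miss, 0.35)
  expect_error(simulation_spec(missingness = 1), "missingness")
})

test_that("abundance truth round-trips through threshold screening", {
  g <- gen_abundance_table(60, 12, abundant_fraction = 0.25, zero_taxa = 3,
                           seed = 41)
  ab <- select_taxa(g$table, 0.1)
  al <- select_taxa(g$table, 0.001)
  expect_setequal(ab$members, g$truth$abundant)
  expect_setequal(al$members, g$truth$all)
  # all-zero taxa fall outside even the permissive set
  zeros <- rownames(g$table$values)[rowSums(g$table$values) == 0]
  expect_equal(length(zeros), 3)
  expect_false(any(zeros %in% al$members))
  expect_true(all(ab$members %in% al$members))
  g2 <- gen_abundance_table(60, 12, abundant_fraction = 0.25, zero_taxa = 3,
                            seed = 41)
  expect_identical(g$table$values, g2$table$values)
})

test_that("null-spec binary data keeps the pairwise z calibrated", {
  set.seed(51)
  n_rep <- 500
  rej <- 0
  for (i in seq_len(n_rep)) {
    k1 <- rbinom(1, 300, 0.2); k2 <- rbinom(1, 300, 0.2)
    p <- pairwise_proportion_contrast(k1, 300, k2, 300)$p_value
    if (p < 0.05) rej <- rej + 1
  }
  expect_gt(rej / n_rep, 0.02)
  expect_lt(rej / n_rep, 0.08)
})

test_that("designed effect sizes are detectable at study scale", {
  set.seed(61)
  n_rep <- 300
  # spore-formation-like contrast: 3% vs 22.5%, n = 200 per group
  hits <- 0
  for (i in seq_len(n_rep)) {
    k1 <- rbinom(1, 200, 0.03); k2 <- rbinom(1, 200, 0.225)
    if (pairwise_proportion_contrast(k1, 200, k2, 200)$p_value < 0.05)
      hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.9)
  # pH-maximum-like shift: 7.97 vs 9.03, sd 1, n = 150 per group
  hits <- 0
  for (i in seq_len(n_rep)) {
    x <- rnorm(150, 7.97, 1); y <- rnorm(150, 9.03, 1)
    if (bm_contrast(x, y)$p_value < 0.05) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.95)
})
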