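test_that("tree pruning keeps the overlap and reports missing species", {
  tree <- gen_tree(5, seed = 1, tip_labels = paste("sp", 1:5))
  pr <- prune_to_overlap(tree, c("sp 1", "sp 3", "sp 5"))
  expect_equal(sort(pr$tree$tip.label), c("sp 1", "sp 3", "sp 5"))
  expect_equal(pr$dropped, character(0))
  pr2 <- prune_to_overlap(tree, c("sp 1", "ghost taxon"))
  expect_equal(pr2$dropped, "ghost taxon")
  # underscore / case normalisation
  pr3 <- prune_to_overlap(tree, c("SP_2", "sp 4"))
  expect_equal(sort(pr3$tree$tip.label), c("sp 2", "sp 4"))
  # idempotence
  pr4 <- prune_to_overlap(pr$tree, c("sp 1", "sp 3", "sp 5"))
  expect_equal(ape::write.tree(pr4$tree), ape::write.tree(pr$tree))
  expect_error(prune_to_overlap(tree, "nothing here"), "no overlap")
})

test_that("naive logistic regression recovers grouped-data closed forms", {
  # balanced, x-independent response
  y <- rep(c(0, 1), 20)
  x <- rep(c(0, 1), each = 20)
  f <- naive_logistic(y, x)
  expect_lt(abs(coef(f)[2]), 1e-8)
  expect_equal(f$loglik, 40 * log(0.5), tolerance = 1e-8)

  # 2x2 grouped data: beta1 = log odds ratio
  y2 <- c(rep(1, 8), rep(0, 2), rep(1, 2), rep(0, 8))
  x2 <- rep(c(1, 0), each = 10)
  f2 <- naive_logistic(y2, x2)
  expect_equal(unname(coef(f2)[2]), log(16), tolerance = 1e-6)
  # ML beats any grid point of the direct Bernoulli likelihood
  grid <- expand.grid(b0 = seq(-3, 3, 0.25), b1 = seq(-3, 3, 0.25))
  gl <- max(mapply(bernoulli_loglik, grid$b0, grid$b1,
                   MoreArgs = list(y = y2, x = x2)))
  expect_gte(f2$loglik, gl - 1e-8)

  # separation flagged, unknowns dropped and counted
  fs <- naive_logistic(c(0, 0, 0, 1, 1, 1), c(1, 2, 3, 10, 11, 12))
  expect_true(fs$separated)
  fd <- naive_logistic(c(0, 1, 0, 1), c(1, 2, NA, 4))
  expect_equal(fd$n_dropped, 1)
  expect_error(naive_logistic(rep(1, 5), rnorm(5)), "single class")
})

test_that("likelihood ratio test follows the chi-square reference", {
  mk <- function(ll, np) structure(list(loglik = ll, npar = np, n = 30,
                                        coefficients = rep(0, np)),
                                   class = "logistic_fit")
  eq <- lrt(mk(-10, 2), mk(-10, 1))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  crit <- lrt(mk(-10, 2), mk(-10 - 3.841459 / 2, 1))
  expect_equal(crit$p_value, 0.05, tolerance = 1e-4)
  z <- lrt(mk(-10, 3), mk(-10, 1))
  expect_equal(z$df, 2)
  expect_equal(z$p_value, 1)
  expect_error(lrt(mk(-12, 2), mk(-10, 1)), "optimization failure")
})

test_that("phylogenetic fit equals the naive fit on star trees", {
  for (s in 1:6) {
    set.seed(s)
    n <- sample(25:60, 1)
    star <- ape::stree(n, "star")
    star$edge.length <- rep(1, n)
    y <- stats::setNames(rbinom(n, 1, 0.5), star$tip.label)
    x <- stats::setNames(rbinom(n, 1, 0.4), star$tip.label)
    if (length(unique(y)) < 2 || length(unique(x)) < 2) next
    fp <- phylo_logistic(y, x, star)
    fn <- naive_logistic(y, x)
    expect_lt(max(abs(coef(fp) - coef(fn))), 1e-4)
    expect_lt(abs(fp$loglik - fn$loglik), 1e-4)
  }
})

test_that("corrected regression is more conservative under clade-structured nulls", {
  n_sim <- 120
  wins <- 0; used <- 0
  for (i in seq_len(n_sim)) {
    tr <- gen_tree(80, seed = 5000 + i)
    d <- sim_clade_null_data(tr, seed = 6000 + i)
    ps <- tryCatch({
      fn1 <- naive_logistic(d$y, d$x)
      fn0 <- naive_logistic(d$y, NULL)
      fp1 <- phylo_logistic(d$y, d$x, tr, n_starts = 1)
      fp0 <- phylo_logistic(d$y, NULL, tr, n_starts = 1)
      c(lrt(fn1, fn0)$p_value, lrt(fp1, fp0)$p_value)
    }, error = function(e) NULL)
    if (is.null(ps)) next
    used <- used + 1
    # tolerance absorbs floating-point noise when both p-values sit at 1
    if (ps[2] >= ps[1] - 1e-6) wins <- wins + 1
  }
  expect_gt(used, n_sim * 0.6)
  expect_gte(wins / used, 0.8)
})

test_that("corrected LRT p-values stay conservative under a phylogenetic null", {
  n_sim <- 100
  rej <- 0; used <- 0
  for (i in seq_len(n_sim)) {
    tr <- gen_tree(60, seed = 7000 + i)
    d <- sim_phylo_logistic_data(tr, beta0 = 0, beta1 = 0, signal_sd = 1,
                                 seed = 8000 + i)
    p <- tryCatch({
      f1 <- phylo_logistic(d$y, d$x, tr, n_starts = 1)
      f0 <- phylo_logistic(d$y, NULL, tr, n_starts = 1)
      lrt(f1, f0)$p_value
    }, error = function(e) NULL)
    if (is.null(p)) next
    used <- used + 1
    if (p < 0.05) rej <- rej + 1
  }
  expect_gt(used, 70)
  # stochastically >= uniform at the 0.05 level, within Monte-Carlo error
  expect_lte(rej / used, 0.05 + 2 * sqrt(0.05 * 0.95 / used))
})

test_that("phylogenetic fit agrees in sign with an independent PGLMM", {
  tr <- gen_tree(100, seed = 77)
  d <- sim_phylo_logistic_data(tr, beta0 = -0.5, beta1 = 1.8,
                               signal_sd = 1, seed = 78)
  f <- phylo_logistic(d$y, d$x, tr, n_starts = 2)
  ref <- ape::binaryPGLMM(y ~ x,
                          data = data.frame(y = d$y, x = d$x,
                                            row.names = names(d$y)),
                          phy = tr)
  expect_equal(sign(coef(f)[["x"]]), unname(sign(ref$B["x", 1])))
  expect_lt(abs(coef(f)[["x"]] - ref$B["x", 1]), 2)
})
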