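test_that("binomial proportion matches the closed form and boundaries", {
  expect_equal(binomial_proportion(0, 10), list(p_hat = 0, se = 0))
  expect_equal(binomial_proportion(10, 10), list(p_hat = 1, se = 0))
  b <- binomial_proportion(5, 10)
  expect_equal(b$p_hat, 0.5)
  expect_equal(b$se, sqrt(0.25 / 10))
  expect_error(binomial_proportion(1, 0), ">= 1")
  expect_error(binomial_proportion(11, 10), "\\[0, n\\]")
})

test_that("chi-square overall test agrees with the Pearson formula", {
  eq <- chi_square_overall(rbind(c(10, 10), c(10, 10)))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  ct <- chi_square_overall(rbind(c(20, 10), c(10, 20)))
  expect_equal(ct$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(ct$df, 1)
  expect_equal(ct$p_value, 0.00982, tolerance = 1e-3)
  sep <- chi_square_overall(rbind(c(5, 0), c(0, 5)))
  expect_equal(sep$statistic, 10)
  expect_true(sep$low_expected)
  expect_error(chi_square_overall(rbind(c(0, 0), c(5, 5))), "degenerate")

  # random tables against the hand formula
  set.seed(42)
  for (i in 1:25) {
    tab <- matrix(rpois(6, 20) + 1, nrow = 2)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(chi_square_overall(tab)$statistic, sum((tab - E)^2 / E),
                 tolerance = 1e-10)
    expect_equal(chi_square_overall(tab)$df, 2)
  }
})

test_that("pairwise z contrast uses binomial standard errors", {
  same <- pairwise_proportion_contrast(5, 10, 5, 10)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$direction, "none")
  z <- pairwise_proportion_contrast(9, 10, 1, 10)
  expect_equal(z$statistic, 0.8 / sqrt(2 * 0.009), tolerance = 1e-10)
  expect_equal(z$direction, "group1")
  bound <- pairwise_proportion_contrast(0, 10, 0, 20)
  expect_true(bound$flagged)
  expect_equal(bound$p_value, 1)
})

test_that("pooled z^2 equals the 2x2 chi-square statistic", {
  set.seed(7)
  for (i in 1:25) {
    n1 <- sample(5:40, 1); n2 <- sample(5:40, 1)
    k1 <- sample(1:(n1 - 1), 1); k2 <- sample(1:(n2 - 1), 1)
    z <- pairwise_proportion_contrast(k1, n1, k2, n2, pooled = TRUE)
    chi <- chi_square_overall(rbind(c(k1, k2), c(n1 - k1, n2 - k2)))
    expect_equal(z$statistic^2, chi$statistic, tolerance = 1e-10)
  }
})

test_that("randomization test handles degenerate and separated data", {
  # two identical all-clumps groups: no variation, p = 1
  rt <- randomization_test(rep(c("a", "b"), each = 6), rep("clumps", 12),
                           B = 99, seed = 1)
  expect_equal(unname(rt$statistic), 0)
  expect_equal(unname(rt$p_level[["clumps"]]), 1)
  expect_equal(rt$p_overall, 1)
  # complete separation attains the permutation minimum scale
  rt2 <- randomization_test(rep(c("a", "b"), each = 10),
                            c(rep("coccus", 10), rep("bacillus", 10)),
                            B = 2000, seed = 2)
  expect_lt(rt2$p_overall, 0.01)
  expect_gte(rt2$p_overall, 1 / 2001)
  expect_error(randomization_test(rep("a", 5), rep("x", 5)), "2 groups")
  expect_error(randomization_test(rep(c("a", "b"), 3), rep("x", 6), B = 0),
               "B must be")
})

test_that("randomization p is reproducible and order-invariant", {
  set.seed(10)
  lab <- rep(c("a", "b"), c(5, 7))
  out <- sample(c("coccus", "bacillus", "other"), 12, replace = TRUE)
  r1 <- randomization_test(lab, out, B = 500, seed = 99)
  r2 <- randomization_test(lab, out, B = 500, seed = 99)
  expect_identical(r1$p_level, r2$p_level)
  expect_gte(min(r1$p_level), 1 / 501)
  # permuting observations jointly leaves exact p unchanged
  perm <- sample(12)
  e1 <- randomization_test(lab, out, exact = TRUE)
  e2 <- randomization_test(lab[perm], out[perm], exact = TRUE)
  expect_equal(e1$p_level, e2$p_level)
  # less-extreme fraction complements the at-least-as-extreme count
  expect_equal(unname(e1$less_extreme + vapply(names(e1$p_level), function(l)
    e1$p_level[[l]], numeric(1))), rep(1, length(e1$p_level)))
})

test_that("exact enumeration matches the brute-force oracle on n <= 10", {
  set.seed(31)
  for (rep_i in 1:5) {
    n1 <- sample(3:5, 1); n2 <- sample(3:5, 1)
    lab <- rep(c("a", "b"), c(n1, n2))
    out <- sample(c("x", "y", "z"), n1 + n2, replace = TRUE)
    M <- sapply(sort(unique(out)), function(l) as.numeric(out == l))
    e <- randomization_test(lab, out, exact = TRUE)
    o <- exact_perm_oracle(lab, M)
    expect_equal(unname(e$p_level), o$p_level, tolerance = 1e-12)
    expect_equal(e$p_overall, o$p_overall, tolerance = 1e-12)
    # Monte-Carlo run converges to the exact value
    mc <- randomization_test(lab, out, B = 4000, seed = rep_i)
    expect_equal(unname(mc$p_level), o$p_level, tolerance = 0.05)
  }
})
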