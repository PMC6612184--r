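#' Binomial proportion with standard error
#'
#' Point estimate and standard error of a proportion under the standard
#' binomial model: p = k/n, se = sqrt(p(1-p)/n).
#'
#' @param k Number of positives (0 <= k <= n).
#' @param n Number of known observations (>= 1).
#' @return List with \code{p_hat} and \code{se}.
#' @export
binomial_proportion <- function(k, n) {
  if (length(k) != 1 || length(n) != 1 || is.na(k) || is.na(n))
    stop("k and n must be scalars")
  if (n < 1) stop("n must be >= 1")
  if (k < 0 || k > n) stop("k must be in [0, n]")
  p <- k / n
  list(p_hat = p, se = sqrt(p * (1 - p) / n))
}

#' Overall chi-square test on a positive/negative by group table
#'
#' Pearson chi-square test (no continuity correction) on a 2 x m
#' contingency table of trait state (positive / negative) by group, as an
#' overall test of equality of proportions. Degenerate margins (an empty
#' row or column) are an error; expected cells below 5 set the
#' \code{low_expected} flag.
#'
#' @param counts 2 x m matrix; rows positive/negative, columns groups.
#' @return List with \code{statistic}, \code{df}, \code{p_value},
#'   \code{low_expected}.
#' @export
chi_square_overall <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2) stop("counts must be a 2 x m table")
  if (any(counts < 0)) stop("negative cell count")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("degenerate margin: empty row or column")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value),
       low_expected = any(ct$expected < 5))
}

#' Pairwise comparison of two binomial proportions
#'
#' z test built from the standard errors of the binomial proportion:
#' z = (p1 - p2) / sqrt(se1^2 + se2^2), two-sided normal p-value. When
#' both proportions sit at a common boundary (both standard errors zero
#' and p1 = p2) the result is the conventional p = 1, flagged; zero
#' pooled standard error with p1 != p2 gives p = 0, flagged. With
#' \code{pooled = TRUE} the variance uses the pooled proportion, in which
#' case z^2 equals the 2 x 2 Pearson chi-square statistic.
#'
#' @param k1,n1 Positives and known count in group 1.
#' @param k2,n2 Positives and known count in group 2.
#' @param groups Length-2 labels.
#' @param trait Optional trait name carried into the result.
#' @param pooled Use the pooled-proportion variance? Default FALSE
#'   (unpooled, matching SE-bar comparisons).
#' @return A \code{trait_comparison} object.
#' @export
pairwise_proportion_contrast <- function(k1, n1, k2, n2,
                                         groups = c("group1", "group2"),
                                         trait = NA_character_,
                                         pooled = FALSE) {
  b1 <- binomial_proportion(k1, n1)
  b2 <- binomial_proportion(k2, n2)
  if (pooled) {
    pp <- (k1 + k2) / (n1 + n2)
    se2 <- pp * (1 - pp) * (1 / n1 + 1 / n2)
  } else {
    se2 <- b1$se^2 + b2$se^2
  }
  flagged <- FALSE
  if (se2 <= 0) {
    flagged <- TRUE
    if (b1$p_hat == b2$p_hat) { z <- 0; p <- 1 } else {
      z <- sign(b1$p_hat - b2$p_hat) * Inf; p <- 0
    }
  } else {
    z <- (b1$p_hat - b2$p_hat) / sqrt(se2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  new_trait_comparison(
    trait = trait, level = NA_character_, groups = groups,
    estimates = c(b1$p_hat, b2$p_hat), ses = c(b1$se, b2$se),
    statistic = z, p_value = p,
    direction = direction_of(c(b1$p_hat, b2$p_hat), groups),
    n_per_group = c(n1, n2),
    method = if (pooled) "binomial z (pooled SE)" else "binomial z",
    flagged = flagged)
}

#' Randomization test for categorical trait proportions
#'
#' Permutation test of the null of equality of level proportions between
#' groups: group labels are permuted B times while the observed outcomes
#' (possibly multi-level per observation) stay fixed. The per-level
#' statistic is the range of level proportions across groups (for two
#' groups, the absolute proportion difference). Per-level p-values are
#' the add-one-corrected two-sided permutation p,
#' p = (1 + #\{|D*| >= |D_obs|\}) / (B + 1); an overall p-value uses the
#' maximum per-level statistic under the same permutations. The fraction
#' of resamples strictly less extreme than the observation is reported
#' alongside. With \code{exact = TRUE} (two groups only) all label
#' assignments are enumerated and p-values are exact proportions without
#' the add-one correction.
#'
#' @param labels Group label per observation (>= 2 groups).
#' @param outcomes Category per observation: character vector, possibly
#'   several levels joined by \code{sep}; or a logical matrix
#'   (observations x levels).
#' @param B Number of resamples (>= 1). The study-scale default is 1e5.
#' @param seed Integer seed; results are exactly reproducible given it.
#' @param exact Enumerate all assignments instead of sampling.
#' @param sep Separator for multi-level outcome strings.
#' @return A \code{randomization_result}: per-level estimates, p-values,
#'   less-extreme fractions, and the overall max-statistic p-value.
#' @export
randomization_test <- function(labels, outcomes, B = 1e5, seed = NULL,
                               exact = FALSE, sep = ";") {
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  if (length(groups) < 2) stop("need >= 2 groups")
  if (!exact && B < 1) stop("B must be >= 1")

  if (is.matrix(outcomes)) {
    M <- outcomes * 1
    if (is.null(colnames(M))) colnames(M) <- paste0("level", seq_len(ncol(M)))
  } else {
    outcomes <- as.character(outcomes)
    lev <- sort(unique(unlist(strsplit(outcomes, sep, fixed = TRUE))))
    lev <- lev[nzchar(lev)]
    M <- sapply(lev, function(l)
      vapply(strsplit(outcomes, sep, fixed = TRUE),
             function(s) l %in% s, logical(1)) * 1)
    if (length(lev) == 1) M <- matrix(M, ncol = 1, dimnames = list(NULL, lev))
  }
  n <- nrow(M)
  if (length(labels) != n) stop("labels and outcomes disagree in length")
  gi <- match(labels, groups)
  ng <- tabulate(gi, length(groups))

  props <- function(g) rowsum(M, g) / ng
  stat_of <- function(pr) {
    hi <- pr[1, ]; lo <- pr[1, ]
    for (g in seq_len(nrow(pr))[-1]) {
      hi <- pmax(hi, pr[g, ]); lo <- pmin(lo, pr[g, ])
    }
    hi - lo
  }

  pr_obs <- props(gi)
  rownames(pr_obs) <- groups
  d_obs <- stat_of(pr_obs)
  overall_obs <- max(d_obs)

  if (exact) {
    if (length(groups) != 2)
      stop("exact enumeration supports two groups only")
    if (choose(n, ng[1]) > 2e5)
      stop("exact enumeration infeasible for ", n, " observations (",
           format(choose(n, ng[1]), big.mark = ","),
           " assignments); use Monte-Carlo resampling")
    idx_all <- utils::combn(n, ng[1])
    Bstar <- ncol(idx_all)
    d_star <- matrix(0, Bstar, ncol(M))
    for (b in seq_len(Bstar)) {
      g <- rep(2L, n); g[idx_all[, b]] <- 1L
      d_star[b, ] <- stat_of(props(g))
    }
    p_level <- vapply(seq_len(ncol(M)), function(j)
      mean(d_star[, j] >= d_obs[j] - 1e-12), numeric(1))
    less <- vapply(seq_len(ncol(M)), function(j)
      mean(d_star[, j] < d_obs[j] - 1e-12), numeric(1))
    p_overall <- mean(apply(d_star, 1, max) >= overall_obs - 1e-12)
    Bused <- Bstar
  } else {
    if (!is.null(seed)) set.seed(seed)
    B <- as.integer(B)
    d_star <- matrix(0, B, ncol(M))
    for (b in seq_len(B))
      d_star[b, ] <- stat_of(props(sample(gi)))
    p_level <- vapply(seq_len(ncol(M)), function(j)
      (1 + sum(d_star[, j] >= d_obs[j] - 1e-12)) / (B + 1), numeric(1))
    less <- vapply(seq_len(ncol(M)), function(j)
      mean(d_star[, j] < d_obs[j] - 1e-12), numeric(1))
    p_overall <- (1 + sum(apply(d_star, 1, max) >= overall_obs - 1e-12)) /
      (B + 1)
    Bused <- B
  }

  out <- list(
    levels = colnames(M), groups = groups,
    proportions = pr_obs, statistic = d_obs,
    p_level = stats::setNames(p_level, colnames(M)),
    less_extreme = stats::setNames(less, colnames(M)),
    overall_statistic = overall_obs, p_overall = p_overall,
    direction = apply(pr_obs, 2, function(col) groups[which.max(col)]),
    n_per_group = stats::setNames(ng, groups),
    B = Bused, seed = seed, exact = exact,
    method = if (exact) "exact permutation" else "randomization")
  class(out) <- "randomization_result"
  out
}

#' @export
print.randomization_result <- function(x, ...) {
  cat("<randomization_result> ", x$method, ", B = ", x$B, "\n", sep = "")
  df <- data.frame(level = x$levels,
                   t(x$proportions),
                   statistic = x$statistic,
                   p = x$p_level, higher_in = x$direction,
                   check.names = FALSE)
  print(df, row.names = FALSE, digits = 4)
  cat("overall (max-statistic) p = ", format(x$p_overall, digits = 4),
      "\n", sep = "")
  invisible(x)
}

# --- trait_comparison S3 -------------------------------------------------

new_trait_comparison <- function(trait, level, groups, estimates, ses,
                                 statistic, p_value, direction, n_per_group,
                                 method, flagged = FALSE, extra = list()) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12, all(ses >= 0))
  out <- c(list(trait = trait, level = level, groups = groups,
                estimates = stats::setNames(estimates, groups),
                ses = stats::setNames(ses, groups),
                statistic = statistic, p_value = min(p_value, 1),
                direction = direction,
                n_per_group = stats::setNames(n_per_group, groups),
                method = method, flagged = flagged), extra)
  class(out) <- "trait_comparison"
  out
}

direction_of <- function(estimates, groups) {
  if (isTRUE(all.equal(estimates[1], estimates[2]))) "none"
  else groups[which.max(estimates)]
}

#' @export
print.trait_comparison <- function(x, ...) {
  cat("<trait_comparison> ", x$method,
      if (!is.na(x$trait)) paste0(" [", x$trait,
        if (!is.na(x$level)) paste0(":", x$level), "]"), "\n", sep = "")
  est <- sprintf("%s: %.4g (se %.3g, n %d)", x$groups, x$estimates,
                 x$ses, x$n_per_group)
  cat(" ", paste(est, collapse = "  vs  "), "\n")
  cat("  statistic = ", format(x$statistic, digits = 4),
      ", p = ", format(x$p_value, digits = 4),
      ", higher in: ", x$direction,
      if (x$flagged) "  [flagged]", "\n", sep = "")
  invisible(x)
}
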