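# Independent oracles used across the suite. These deliberately use the
# naive O(n^2) / enumeration formulations, not the package's midrank or
# vectorised code paths.

# Relative effect by explicit pair counting.
brute_relative_effect <- function(x, y) {
  s <- 0
  for (xi in x) for (yj in y)
    s <- s + (xi < yj) + 0.5 * (xi == yj)
  s / (length(x) * length(y))
}

# Brunner-Munzel via explicit placements (no pooled ranks).
bm_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  lam <- vapply(x, function(xi) sum(y < xi) + 0.5 * sum(y == xi),
                numeric(1)) / ny
  kap <- vapply(y, function(yj) sum(x < yj) + 0.5 * sum(x == yj),
                numeric(1)) / nx
  p_hat <- mean(kap)
  S1 <- stats::var(lam); S2 <- stats::var(kap)
  V <- S1 / nx + S2 / ny
  stat <- (p_hat - 0.5) / sqrt(V)
  df <- (S1 / nx + S2 / ny)^2 /
    ((S1 / nx)^2 / (nx - 1) + (S2 / ny)^2 / (ny - 1))
  list(p_hat = p_hat, statistic = stat, df = df,
       p_value = 2 * stats::pt(-abs(stat), df))
}

# Exhaustive two-group permutation p for the per-level absolute
# proportion difference, by brute enumeration of group-1 index sets.
exact_perm_oracle <- function(labels, outcome_matrix) {
  groups <- sort(unique(labels))
  stopifnot(length(groups) == 2)
  n <- nrow(outcome_matrix)
  n1 <- sum(labels == groups[1])
  stat <- function(lab) {
    p1 <- colMeans(outcome_matrix[lab == groups[1], , drop = FALSE])
    p2 <- colMeans(outcome_matrix[lab == groups[2], , drop = FALSE])
    abs(p1 - p2)
  }
  d_obs <- stat(labels)
  sets <- utils::combn(n, n1)
  d_all <- matrix(0, ncol(sets), ncol(outcome_matrix))
  for (b in seq_len(ncol(sets))) {
    lab <- rep(groups[2], n); lab[sets[, b]] <- groups[1]
    d_all[b, ] <- stat(lab)
  }
  p_level <- vapply(seq_len(ncol(outcome_matrix)), function(j)
    mean(d_all[, j] >= d_obs[j] - 1e-12), numeric(1))
  p_overall <- mean(apply(d_all, 1, max) >= max(d_obs) - 1e-12)
  list(p_level = p_level, p_overall = p_overall)
}

# Bernoulli log-likelihood of a two-parameter logit model on a grid,
# for checking logistic ML fits without IRLS.
bernoulli_loglik <- function(beta0, beta1, y, x) {
  eta <- beta0 + beta1 * x
  sum(y * eta - log1p(exp(eta)))
}

# A tiny hand-written trait table as TSV text.
write_toy_trait_tsv <- function(path, extra_col = FALSE) {
  header <- c("species", "phylum", "catalase", "oxidase", "spore_formation",
              "oxygen_use", "aggregation", "gc_content",
              "temperature_min", "temperature_max", "temperature_optimum",
              "temperature_range", "use_glucose")
  if (extra_col) header <- c(header, "mystery")
  rows <- list(
    c("Staphylococcus epidermidis", "Firmicutes", "+", "ND", "-",
      "facultative", "clumps;singly", "32.1", "20", "45", "35", "", "+"),
    c("Cutibacterium acnes", "Actinobacteria", "+", "-", "v",
      "anaerobic", "singly", "60", "25", "42", "37", "17", "-"),
    c("Escherichia coli", "Proteobacteria", "-", "-", "-",
      "facultative", "chains", "50.8", "15", "45", "37", "30", "+"))
  if (extra_col) rows <- lapply(rows, function(r) c(r, "zzz"))
  writeLines(c(paste(header, collapse = "\t"),
               vapply(rows, paste, "", collapse = "\t")), path)
  path
}
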