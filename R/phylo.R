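#' Normalise species names for tree matching
#'
#' Case-insensitive, with underscores and spaces treated as equivalent.
#' @param x Character vector of names.
#' @return Normalised names.
#' @keywords internal
normalize_species_name <- function(x) tolower(gsub("_", " ", trimws(x)))

#' Prune a phylogeny to the overlap with a species list
#'
#' Restricts the tree to tips matching the species list (name matching is
#' case-insensitive with underscores equivalent to spaces); degree-2
#' internal nodes left by the pruning are collapsed with branch lengths
#' summed (as done by \pkg{ape}). Species absent from the tree are
#' returned in \code{dropped} and are simply ignored downstream, matching
#' the treatment of taxa missing from a reference ribosomal tree.
#'
#' @param tree An \pkg{ape} \code{phylo} object.
#' @param species Character vector of species names (nonempty).
#' @return List with \code{tree} (pruned) and \code{dropped} (species not
#'   found among the tips).
#' @export
prune_to_overlap <- function(tree, species) {
  stopifnot(inherits(tree, "phylo"), length(species) > 0)
  tipn <- normalize_species_name(tree$tip.label)
  spn <- normalize_species_name(species)
  keep <- tree$tip.label[tipn %in% spn]
  if (length(keep) == 0) stop("no overlap between tree tips and species list")
  dropped <- species[!spn %in% tipn]
  list(tree = ape::keep.tip(tree, keep), dropped = dropped)
}

#' Rescale a tree to unit height
#'
#' Divides all branch lengths by the maximum root-to-tip depth, making
#' fitted mean-reversion rates comparable across trees of different
#' absolute scale.
#' @param tree A \code{phylo} object with branch lengths.
#' @return The rescaled tree.
#' @export
scale_tree_height <- function(tree) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  h <- max(ape::node.depth.edgelength(tree))
  if (h <= 0) stop("tree has zero height")
  tree$edge.length <- tree$edge.length / h
  tree
}

# Build a model matrix for one predictor. x may be numeric, or
# character/factor (dummy coded against ref_level). Returns the matrix
# without intercept column.
predictor_matrix <- function(x, ref_level = NULL) {
  if (is.null(x)) return(NULL)
  if (is.numeric(x)) return(matrix(x, ncol = 1, dimnames = list(NULL, "x")))
  f <- factor(x)
  if (!is.null(ref_level)) {
    if (!ref_level %in% levels(f)) stop("ref_level not among levels of x")
    f <- stats::relevel(f, ref = ref_level)
  }
  if (nlevels(f) < 2) stop("categorical predictor has a single level")
  mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
  colnames(mm) <- paste0("x", levels(f)[-1])
  mm
}

new_logistic_fit <- function(coefficients, loglik, converged, n, n_dropped,
                             npar, method, alpha = NA_real_, s2 = NA_real_,
                             separated = FALSE, fitted = NULL, trace = NULL) {
  out <- list(coefficients = coefficients, loglik = loglik,
              converged = converged, separated = separated, n = n,
              n_dropped = n_dropped, npar = npar, method = method,
              alpha = alpha, s2 = s2, fitted = fitted, trace = trace)
  class(out) <- "logistic_fit"
  out
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic_fit> ", x$method, " (n = ", x$n,
      if (x$n_dropped > 0) paste0(", ", x$n_dropped, " dropped"),
      ")\n", sep = "")
  print(round(x$coefficients, 5))
  if (!is.na(x$alpha))
    cat(sprintf("  signal: alpha = %.4g, s2 = %.4g\n", x$alpha, x$s2))
  cat(sprintf("  logLik = %.5f, converged = %s%s\n", x$loglik,
              x$converged, if (x$separated) ", SEPARATION flagged" else ""))
  invisible(x)
}

#' @export
coef.logistic_fit <- function(object, ...) object$coefficients

#' @export
logLik.logistic_fit <- function(object, ...) {
  structure(object$loglik, df = object$npar, class = "logLik")
}

#' Naive logistic regression of group membership on one trait
#'
#' Ordinary maximum-likelihood logistic regression (iteratively
#' reweighted least squares via \code{stats::glm}) treating species as
#' independent observations. Observations with unknown predictor values
#' are dropped and counted; complete separation is detected and flagged
#' rather than silently returned.
#'
#' @param y Binary response per species (0/1 or logical), both classes
#'   present.
#' @param x Predictor per species: numeric, or character/factor (dummy
#'   coded); NULL fits the intercept-only null model.
#' @param ref_level Reference level for categorical predictors.
#' @return A \code{logistic_fit}.
#' @export
naive_logistic <- function(y, x = NULL, ref_level = NULL) {
  y <- as.numeric(y)
  keep <- !is.na(y)
  if (!is.null(x)) keep <- keep & !is.na(x)
  n_dropped <- sum(!keep)
  y <- y[keep]
  if (length(unique(y)) < 2) stop("response has a single class")
  X <- if (is.null(x)) matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
       else cbind("(Intercept)" = 1, predictor_matrix(x[keep], ref_level))
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial()))
  mu <- fit$fitted.values
  separated <- max(abs(fit$coefficients), na.rm = TRUE) > 12 ||
    all(abs(mu - y) < 1e-6)
  ll <- sum(y * log(pmax(mu, 1e-12)) + (1 - y) * log(pmax(1 - mu, 1e-12)))
  new_logistic_fit(
    coefficients = stats::setNames(fit$coefficients, colnames(X)),
    loglik = ll, converged = fit$converged, n = length(y),
    n_dropped = n_dropped, npar = ncol(X), method = "naive_glm",
    separated = separated, fitted = mu)
}

# Internal-edge random-effect design for a unit-height tree.
# Returns Z (tips x m incidence) and a function w(alpha) giving the
# per-edge variance weights of the OU-damped increments:
#   w_e = integral over the edge of exp(-2 alpha (T - t)) dt,  T = 1,
# i.e. old shared branches are discounted at rate 2*alpha. A star tree
# has no internal edges (m = 0), so the random effect vanishes exactly.
phylo_design <- function(tree) {
  ntip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  child <- tree$edge[, 2]
  internal <- which(child > ntip)
  m <- length(internal)
  Z <- matrix(0, ntip, m)
  if (m > 0) {
    # tips descended from each internal edge's child
    desc <- vector("list", max(tree$edge))
    ord <- rev(ape::postorder(tree))
    for (i in seq_len(ntip)) desc[[i]] <- i
    for (e in ape::postorder(tree)) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      desc[[p]] <- c(desc[[p]], desc[[ch]])
    }
    for (j in seq_len(m)) Z[desc[[child[internal[j]]]], j] <- 1
  }
  t1 <- depth[tree$edge[internal, 1]]
  t2 <- depth[child[internal]]
  w_of <- function(alpha) {
    if (m == 0) return(numeric(0))
    if (alpha < 1e-8) return(t2 - t1)
    (exp(-2 * alpha * (1 - t2)) - exp(-2 * alpha * (1 - t1))) / (2 * alpha)
  }
  list(Z = Z, w_of = w_of, m = m)
}

# Joint Newton maximisation of the Bernoulli loglik plus Gaussian prior
# on u; returns the mode, the penalised objective g and the Laplace
# correction term.
laplace_inner <- function(y, X, Z, wtilde, beta0 = NULL, u0 = NULL,
                          max_iter = 100, tol = 1e-10) {
  p <- ncol(X); m <- ncol(Z)
  beta <- if (is.null(beta0)) rep(0, p) else beta0
  u <- if (is.null(u0)) rep(0, m) else u0
  gfun <- function(beta, u) {
    eta <- drop(X %*% beta) + if (m > 0) drop(Z %*% u) else 0
    sum(y * eta - log1p(exp(eta))) -
      if (m > 0) 0.5 * sum(u^2 / wtilde) else 0
  }
  g <- gfun(beta, u)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + if (m > 0) drop(Z %*% u) else 0
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- c(crossprod(X, y - mu),
              if (m > 0) crossprod(Z, y - mu) - u / wtilde else NULL)
    XW <- X * w
    H11 <- crossprod(XW, X)
    if (m > 0) {
      H12 <- crossprod(XW, Z)
      H22 <- crossprod(Z * w, Z); diag(H22) <- diag(H22) + 1 / wtilde
      H <- rbind(cbind(H11, H12), cbind(t(H12), H22))
    } else H <- H11
    step <- tryCatch(solve(H + diag(1e-10, nrow(H)), grad),
                     error = function(e) grad * 0)
    fac <- 1
    repeat {
      beta_new <- beta + fac * step[1:p]
      u_new <- if (m > 0) u + fac * step[(p + 1):(p + m)] else u
      g_new <- gfun(beta_new, u_new)
      if (is.finite(g_new) && g_new >= g - 1e-12) break
      fac <- fac / 2
      if (fac < 1e-8) { beta_new <- beta; u_new <- u; g_new <- g; break }
    }
    delta <- g_new - g
    beta <- beta_new; u <- u_new; g <- g_new
    if (abs(delta) < tol) { converged <- TRUE; break }
  }
  # Laplace determinant term over u only
  logdet <- 0
  eta <- drop(X %*% beta) + if (m > 0) drop(Z %*% u) else 0
  mu <- stats::plogis(eta)
  if (m > 0) {
    w <- pmax(mu * (1 - mu), 1e-10)
    A <- crossprod(Z * w, Z) * outer(sqrt(wtilde), sqrt(wtilde))
    diag(A) <- diag(A) + 1
    ch <- tryCatch(chol(A), error = function(e) NULL)
    logdet <- if (is.null(ch)) determinant(A)$modulus else
      2 * sum(log(diag(ch)))
  }
  list(beta = beta, u = u, g = g, loglik = g - 0.5 * as.numeric(logdet),
       mu = mu, converged = converged)
}

#' Phylogenetically corrected logistic regression
#'
#' Logistic regression of a binary response on a single trait in which
#' species are not treated as independent: shared ancestry enters as a
#' Gaussian random effect on the latent (log-odds) scale, built from
#' independent increments on the internal edges of the unit-height tree.
#' Increment variances are discounted by a mean-reversion (signal decay)
#' rate alpha, so large alpha means ancestral history is forgotten
#' quickly (little phylogenetic correlation) and alpha near 0 approaches
#' Brownian accumulation of shared history. The signal magnitude s2 and
#' alpha are estimated jointly with the coefficients by maximising the
#' Laplace-approximated (penalised) likelihood, with seeded random
#' restarts for the signal parameters. On a star tree there are no
#' internal edges, the random effect vanishes identically, and the fit
#' coincides with \code{\link{naive_logistic}}.
#'
#' @param y Binary response named by species (both classes present).
#' @param x Predictor per species (same order as \code{y}); numeric or
#'   character/factor; NULL for the intercept-only null model.
#' @param tree A \code{phylo} object whose tips cover the observations
#'   (extra tips are pruned; observations missing from the tree are
#'   dropped and counted).
#' @param ref_level Reference level for categorical predictors.
#' @param n_starts Number of starts for (log s2, log alpha); the first is
#'   deterministic, the rest are seeded random jitters.
#' @param seed Seed for the random restarts.
#' @param reltol Convergence tolerance on the log-likelihood.
#' @param max_iter Maximum outer iterations.
#' @return A \code{logistic_fit} with \code{alpha} and \code{s2} filled.
#' @export
phylo_logistic <- function(y, x = NULL, tree, ref_level = NULL,
                           n_starts = 3, seed = 1L, reltol = 1e-8,
                           max_iter = 200) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(names(y))) stop("y must be named by species")
  species <- names(y)
  pr <- prune_to_overlap(tree, species)
  tipn <- normalize_species_name(pr$tree$tip.label)
  spn <- normalize_species_name(species)
  keep <- spn %in% tipn & !is.na(y)
  if (!is.null(x)) keep <- keep & !is.na(x)
  n_dropped <- sum(!keep)
  y2 <- as.numeric(y[keep])
  if (length(unique(y2)) < 2) stop("response has a single class")
  sp2 <- species[keep]
  tree2 <- ape::keep.tip(pr$tree,
                         pr$tree$tip.label[tipn %in% normalize_species_name(sp2)])
  tree2 <- scale_tree_height(tree2)
  ord <- match(normalize_species_name(tree2$tip.label),
               normalize_species_name(sp2))
  y2 <- y2[ord]; sp2 <- sp2[ord]
  X <- if (is.null(x))
    matrix(1, length(y2), 1, dimnames = list(NULL, "(Intercept)"))
  else cbind("(Intercept)" = 1,
             predictor_matrix(x[keep][ord], ref_level))

  des <- phylo_design(tree2)
  p <- ncol(X)

  if (des$m == 0) { # star tree: no shared internal history
    inner <- laplace_inner(y2, X, matrix(0, length(y2), 0), numeric(0))
    fit <- new_logistic_fit(
      coefficients = stats::setNames(inner$beta, colnames(X)),
      loglik = inner$loglik, converged = inner$converged, n = length(y2),
      n_dropped = n_dropped, npar = p + 2, method = "phylo_laplace",
      alpha = NA_real_, s2 = 0,
      separated = max(abs(inner$beta)) > 12, fitted = inner$mu)
    return(fit)
  }

  Z <- des$Z
  last <- new.env()
  nll <- function(theta) {
    s2 <- exp(theta[1]); alpha <- exp(theta[2])
    wt <- s2 * des$w_of(alpha)
    wt <- pmax(wt, 1e-12)
    inner <- laplace_inner(y2, X, Z, wt,
                           beta0 = last$beta, u0 = last$u)
    last$beta <- inner$beta; last$u <- inner$u
    -inner$loglik
  }

  starts <- list(c(log(0.5), log(1)))
  if (n_starts > 1) {
    set.seed(seed)
    for (s in seq_len(n_starts - 1))
      starts[[s + 1]] <- c(stats::runif(1, -4, 1), stats::runif(1, -2, 2.5))
  }
  best <- NULL
  trace <- list()
  for (st in starts) {
    last$beta <- NULL; last$u <- NULL
    opt <- tryCatch(
      stats::nlminb(st, nll,
                    lower = c(-12, log(1e-3)), upper = c(5, log(50)),
                    control = list(iter.max = max_iter, rel.tol = reltol)),
      error = function(e) NULL)
    if (is.null(opt)) next
    trace[[length(trace) + 1]] <- c(start = st, obj = opt$objective,
                                    conv = opt$convergence)
    if (is.null(best) || opt$objective < best$objective - 1e-10) best <- opt
  }
  if (is.null(best)) stop("phylogenetic logistic fit failed to start")

  s2 <- exp(best$par[1]); alpha <- exp(best$par[2])
  wt <- pmax(s2 * des$w_of(alpha), 1e-12)
  last$beta <- NULL; last$u <- NULL
  inner <- laplace_inner(y2, X, Z, wt)
  new_logistic_fit(
    coefficients = stats::setNames(inner$beta, colnames(X)),
    loglik = inner$loglik,
    converged = (best$convergence == 0) && inner$converged,
    n = length(y2), n_dropped = n_dropped, npar = p + 2,
    method = "phylo_laplace", alpha = alpha, s2 = s2,
    separated = max(abs(inner$beta)) > 12, fitted = inner$mu,
    trace = trace)
}

#' Likelihood-ratio test of nested logistic fits
#'
#' 2 * (logLik_full - logLik_null), clipped at zero, referred to a
#' chi-square with df equal to the difference in coefficient count. An
#' apparent decrease of the full model's likelihood beyond tolerance
#' signals an optimisation failure and is an error.
#'
#' @param fit_full,fit_null \code{logistic_fit} objects from the same
#'   observations, null nested in full.
#' @param tol Tolerance for negative statistics before erroring.
#' @return List with \code{statistic}, \code{df}, \code{p_value}.
#' @export
lrt <- function(fit_full, fit_null, tol = 1e-4) {
  stopifnot(inherits(fit_full, "logistic_fit"),
            inherits(fit_null, "logistic_fit"))
  if (fit_full$n != fit_null$n)
    stop("fits use different numbers of observations")
  stat <- 2 * (fit_full$loglik - fit_null$loglik)
  if (stat < -tol)
    stop(sprintf("full-model log-likelihood below null (%.6g): optimization failure",
                 stat / 2))
  stat <- max(stat, 0)
  df <- length(fit_full$coefficients) - length(fit_null$coefficients)
  if (df < 1) stop("null model is not nested in full model")
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}
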