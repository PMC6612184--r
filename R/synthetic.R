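#' Specify a two-group synthetic trait study
#'
#' Fixes the generating conditions for a pair of trait databases (group A
#' emulating abundant skin taxa, group B a habitat-unbiased "world"
#' reference). Defaults reproduce the statistical structure of the skin
#' study: an abundant-skin spore-formation prevalence near 3% against a
#' roughly 7.5-fold higher world prevalence, catalase and oxidase less
#' common on skin, a facultative-heavy oxygen-use profile, a pH maximum
#' near 7.97 on skin versus 9.03 in the world, optimum temperature about
#' two degrees warmer on skin, and lower skin GC content. Every default
#' can be overridden per trait.
#'
#' @param n_taxa Length-2 integer vector: species per group (A, B).
#' @param binary Named list; each element a length-2 numeric vector of
#'   positive prevalences (group A, group B) for one binary trait or
#'   substrate column (\code{use_*}).
#' @param categorical Named list; each element a list with numeric level
#'   probability vectors \code{a} and \code{b} (named by level, each
#'   summing to 1).
#' @param quantitative Named list keyed by variable family
#'   (\code{gc_content} or \code{<base>_optimum}); each element a list
#'   with \code{mean} (length 2), \code{sd} (length 2) and, for range
#'   families, \code{range_mean}/\code{range_sd}.
#' @param missingness Probability that any one trait value is replaced by
#'   unknown (completely at random), in [0, 1).
#' @param phylo_signal Mean-reversion rate used when binary traits are
#'   evolved on a tree (see \code{\link{sim_binary_trait_on_tree}}).
#' @param tree_birth Pure-birth speciation rate for generated trees.
#' @param seed Integer seed.
#' @return An object of class \code{simulation_spec}.
#' @export
simulation_spec <- function(n_taxa = c(200, 500),
                            binary = NULL, categorical = NULL,
                            quantitative = NULL,
                            missingness = 0.2,
                            phylo_signal = 2,
                            tree_birth = 1,
                            seed = 1L) {
  def_binary <- list(
    spore_formation = c(0.03, 0.225),
    pigment_production = c(0.52, 0.64),
    catalase = c(0.55, 0.665),
    oxidase = c(0.18, 0.34),
    acid_phosphatase = c(0.075, 0.34),
    alkaline_phosphatase = c(0.125, 0.19),
    urease = c(0.25, 0.30),
    nitrate_reduction = c(0.45, 0.40),
    h2s_production = c(0.10, 0.15),
    use_glucose = c(0.91, 0.60),
    use_glutamate = c(0.95, 0.70),
    use_gelatin = c(0.03, 0.20),
    use_urea = c(0.17, 0.30),
    use_xylose = c(0.25, 0.45),
    use_cellobiose = c(0.20, 0.40))
  def_categorical <- list(
    oxygen_use = list(
      a = c(aerobic = 0.25, facultative = 0.50, anaerobic = 0.20,
            microaerophilic = 0.05),
      b = c(aerobic = 0.50, facultative = 0.30, anaerobic = 0.17,
            microaerophilic = 0.03)),
    motility = list(
      a = c(none = 0.55, flagella = 0.40, gliding = 0.01,
            axial_filament = 0.001, other = 0.039),
      b = c(none = 0.44, flagella = 0.42, gliding = 0.08,
            axial_filament = 0.001, other = 0.059)),
    shape = list(
      a = c(coccus = 0.35, coccobacillus = 0.15, bacillus = 0.45,
            spirillum = 0.01, other = 0.04),
      b = c(coccus = 0.15, coccobacillus = 0.07, bacillus = 0.68,
            spirillum = 0.05, other = 0.05)),
    gram_stain = list(
      a = c(positive = 0.48, negative = 0.48, variable = 0.04),
      b = c(positive = 0.40, negative = 0.56, variable = 0.04)),
    aggregation = list(
      a = c(singly = 0.30, chains = 0.15, clumps = 0.55),
      b = c(singly = 0.35, chains = 0.30, clumps = 0.35)))
  def_quant <- list(
    gc_content = list(mean = c(51.7, 55.0), sd = c(11, 11)),
    temperature_optimum = list(mean = c(33.2, 31.2), sd = c(5, 5),
                               range_mean = c(25.3, 23), range_sd = c(6, 6)),
    ph_optimum = list(mean = c(7.06, 7.1), sd = c(0.6, 0.7),
                      range_mean = c(2.41, 3.38), range_sd = c(0.8, 0.9)),
    nacl_optimum = list(mean = c(1.23, 0.6), sd = c(0.8, 0.5),
                        range_mean = c(1.14, 1.5), range_sd = c(0.6, 0.8)))
  merge_named <- function(def, user) {
    if (is.null(user)) return(def)
    for (nm in names(user)) def[[nm]] <- user[[nm]]
    def
  }
  spec <- list(n_taxa = as.integer(n_taxa),
               binary = merge_named(def_binary, binary),
               categorical = merge_named(def_categorical, categorical),
               quantitative = merge_named(def_quant, quantitative),
               missingness = missingness, phylo_signal = phylo_signal,
               tree_birth = tree_birth, seed = as.integer(seed))
  stopifnot(length(spec$n_taxa) == 2, all(spec$n_taxa >= 1),
            missingness >= 0, missingness < 1)
  for (pv in spec$binary)
    stopifnot(length(pv) == 2, all(pv >= 0), all(pv <= 1))
  for (cv in spec$categorical) {
    stopifnot(abs(sum(cv$a) - 1) < 1e-6, abs(sum(cv$b) - 1) < 1e-6)
  }
  class(spec) <- "simulation_spec"
  spec
}

#' Simulate a pure-birth phylogeny
#'
#' Yule (pure-birth) tree with uniquely named tips and positive branch
#' lengths, reproducible by seed, rescaled to unit height.
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Integer seed.
#' @param birth Speciation rate.
#' @param tip_labels Optional tip names (length \code{n_tips}).
#' @return A \code{phylo} object of unit height.
#' @export
gen_tree <- function(n_tips, seed = 1L, birth = 1, tip_labels = NULL) {
  if (n_tips < 2) stop("n_tips must be >= 2")
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = birth, death = 0)
  tree$tip.label <- if (is.null(tip_labels))
    sprintf("sp_%04d", seq_len(n_tips)) else tip_labels
  scale_tree_height(tree)
}

#' Evolve a two-state trait along a tree
#'
#' Continuous-time two-state Markov evolution (rates 0->1 and 1->0) along
#' branches from a root state drawn from the stationary distribution.
#'
#' @param tree A \code{phylo} object with branch lengths.
#' @param rate01,rate10 Transition rates (> 0).
#' @param seed Integer seed.
#' @return Named 0/1 vector over the tips.
#' @export
sim_binary_trait_on_tree <- function(tree, rate01, rate10, seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  if (rate01 <= 0 || rate10 <= 0) stop("rates must be positive")
  set.seed(seed)
  Q <- matrix(c(-rate01, rate01, rate10, -rate10), 2, 2, byrow = TRUE,
              dimnames = list(c("0", "1"), c("0", "1")))
  pi0 <- rate10 / (rate01 + rate10)
  root <- sample(c("0", "1"), 1, prob = c(pi0, 1 - pi0))
  states <- ape::rTraitDisc(tree, model = Q, states = c("0", "1"),
                            root.value = match(root, c("0", "1")))
  stats::setNames(as.numeric(as.character(states)), tree$tip.label)
}

# Draw a coherent (min, optimum, max, range) quadruple: the optimum sits
# at a jittered interior point of the interval so min < optimum < max and
# range = max - min hold by construction.
draw_quant_family <- function(n, mean, sd, range_mean, range_sd) {
  opt <- stats::rnorm(n, mean, sd)
  r <- abs(stats::rnorm(n, range_mean, range_sd)) + 1e-3
  w <- stats::runif(n, 0.35, 0.65)
  mn <- opt - r * w
  mx <- mn + r
  list(min = mn, max = mx, optimum = opt, range = r)
}

#' Generate a two-group synthetic trait study
#'
#' Draws two trait databases conforming to the shared schema, one per
#' group, with independent per-species trait values at the spec's
#' prevalences / level probabilities / means, coherent quantitative
#' (min, optimum, max, range) quadruples, and unknowns injected
#' completely at random at the missingness rate. The truth record stores
#' every generating parameter.
#'
#' @param spec A \code{\link{simulation_spec}}.
#' @param schema A \code{trait_schema}.
#' @return List with \code{db_a}, \code{db_b} (both \code{trait_db}) and
#'   \code{truth}.
#' @export
gen_trait_database <- function(spec, schema = read_schema()) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  phyla <- c("Actinobacteria", "Firmicutes", "Proteobacteria",
             "Bacteroidetes")
  gen_group <- function(n, which, prefix) {
    d <- data.frame(
      species = sprintf("%s_sp_%04d", prefix, seq_len(n)),
      phylum = sample(phyla, n, replace = TRUE,
                      prob = c(0.3, 0.3, 0.3, 0.1)),
      stringsAsFactors = FALSE)
    idx <- if (which == "a") 1 else 2
    for (tr in names(spec$binary)) {
      pv <- spec$binary[[tr]][idx]
      d[[tr]] <- ifelse(stats::rbinom(n, 1, pv) == 1, "positive", "negative")
    }
    for (tr in names(spec$categorical)) {
      pr <- spec$categorical[[tr]][[which]]
      d[[tr]] <- sample(names(pr), n, replace = TRUE, prob = pr)
    }
    for (fam in names(spec$quantitative)) {
      qq <- spec$quantitative[[fam]]
      if (fam == "gc_content") {
        d$gc_content <- pmin(pmax(stats::rnorm(n, qq$mean[idx], qq$sd[idx]),
                                  1), 99)
      } else {
        base <- sub("_optimum$", "", fam)
        fr <- draw_quant_family(n, qq$mean[idx], qq$sd[idx],
                                qq$range_mean[idx], qq$range_sd[idx])
        if (base %in% c("nacl")) { # concentrations cannot be negative
          shift <- pmax(0, -fr$min)
          fr$min <- fr$min + shift; fr$max <- fr$max + shift
          fr$optimum <- fr$optimum + shift
        }
        d[[paste0(base, "_min")]] <- fr$min
        d[[paste0(base, "_max")]] <- fr$max
        d[[paste0(base, "_optimum")]] <- fr$optimum
        d[[paste0(base, "_range")]] <- fr$range
      }
    }
    # missingness completely at random, trait columns only
    if (spec$missingness > 0) {
      for (col in setdiff(names(d), c("species", "phylum"))) {
        hit <- stats::runif(n) < spec$missingness
        d[[col]][hit] <- NA
      }
    }
    trait_db(d, schema)
  }
  db_a <- gen_group(spec$n_taxa[1], "a", "skin")
  db_b <- gen_group(spec$n_taxa[2], "b", "world")
  list(db_a = db_a, db_b = db_b,
       truth = list(spec = spec, group_a = "skin", group_b = "world"))
}

#' Generate a synthetic abundance table
#'
#' Log-normal relative-abundance profiles normalised per sample to below
#' 100% of reads (a slack fraction emulates unclassified reads). A
#' designated fraction of taxa is made abundant by construction: each such
#' taxon strictly exceeds 0.1% in at least one sample while every other
#' nonzero taxon stays below it (but above 0.001% somewhere), so the
#' abundant truth list equals exactly what threshold screening recovers.
#'
#' @param n_taxa Number of taxa.
#' @param n_samples Number of samples.
#' @param site_labels Site classes to cycle over the samples.
#' @param abundant_fraction Fraction of taxa designated abundant.
#' @param zero_taxa Number of trailing all-zero taxa (default 0).
#' @param seed Integer seed.
#' @return List with \code{table} (an \code{abundance_table}) and
#'   \code{truth} (character vectors \code{abundant} and \code{all}).
#' @export
gen_abundance_table <- function(n_taxa, n_samples,
                                site_labels = c("dry", "moist", "sebaceous"),
                                abundant_fraction = 0.3,
                                zero_taxa = 0, seed = 1L) {
  stopifnot(n_taxa >= 1, n_samples >= 1,
            abundant_fraction >= 0, abundant_fraction <= 1)
  set.seed(seed)
  taxa <- sprintf("sp_%04d", seq_len(n_taxa))
  samples <- sprintf("s%03d", seq_len(n_samples))
  site <- rep(site_labels, length.out = n_samples)
  names(site) <- samples
  n_ab <- round(abundant_fraction * (n_taxa - zero_taxa))
  abundant <- taxa[seq_len(n_ab)]
  live <- n_taxa - zero_taxa

  m <- matrix(0, n_taxa, n_samples, dimnames = list(taxa, samples))
  if (live > 0) {
    meanlog <- stats::rnorm(live, -3, 1.5)
    for (s in seq_len(n_samples)) {
      raw <- stats::rlnorm(live, meanlog, 1)
      m[seq_len(live), s] <- 90 * raw / sum(raw)
    }
    # enforce the designed abundance classes
    for (i in seq_len(live)) {
      if (taxa[i] %in% abundant) {
        j <- which.max(m[i, ])
        m[i, j] <- max(m[i, j], stats::runif(1, 0.15, 0.6))
        m[i, -j] <- pmin(m[i, -j], 0.09)
      } else {
        m[i, ] <- pmin(m[i, ], 0.09)
        j <- which.max(m[i, ])
        m[i, j] <- max(m[i, j], stats::runif(1, 0.005, 0.05))
      }
    }
  }
  tab <- abundance_table(m, site)
  all_taxa <- taxa[apply(m, 1, function(v) any(v > 0.001))]
  list(table = tab, truth = list(abundant = abundant, all = all_taxa))
}

#' Simulate clade-structured binary data for regression checks
#'
#' Builds a dataset with no true effect in which both variables carry
#' strong phylogenetic clade structure: response and predictor evolve
#' independently of each other as slow two-state Markov traits on the
#' same tree. Their clade-level coincidences then masquerade as an
#' association when species are treated as independent, the classic
#' phylogenetic pseudo-replication scenario; a corrected fit should be
#' more conservative than the naive one.
#'
#' @param tree A \code{phylo} object.
#' @param response_rate Markov rate of the response trait (small =
#'   strongly clumped).
#' @param x_rate Markov rate of the (independent) predictor trait.
#' @param seed Integer seed.
#' @return List with named vectors \code{y} and \code{x}.
#' @export
sim_clade_null_data <- function(tree, response_rate = 0.15,
                                x_rate = 0.15, seed = 1L) {
  y <- sim_binary_trait_on_tree(tree, response_rate, response_rate,
                                seed = seed)
  x <- sim_binary_trait_on_tree(tree, x_rate, x_rate,
                                seed = seed + 77777L)
  list(y = y, x = x[names(y)])
}

#' Simulate a phylogenetic logistic dataset with a true effect
#'
#' The predictor evolves on the tree as a two-state Markov trait; the
#' response is Bernoulli with log-odds beta0 + beta1 x plus a latent
#' phylogenetic random effect built from internal-edge increments (the
#' same construction the corrected fit assumes).
#'
#' @param tree A \code{phylo} object.
#' @param beta0,beta1 Intercept and trait effect on the log-odds scale.
#' @param signal_sd Standard deviation scale of the latent phylogenetic
#'   effect.
#' @param alpha Mean-reversion rate of the latent effect.
#' @param x_rate Markov rate for the predictor trait.
#' @param seed Integer seed.
#' @return List with named vectors \code{y}, \code{x} and the latent
#'   effect \code{b}.
#' @export
sim_phylo_logistic_data <- function(tree, beta0 = 0, beta1 = 1.5,
                                    signal_sd = 1, alpha = 2,
                                    x_rate = 1, seed = 1L) {
  tree <- scale_tree_height(tree)
  x <- sim_binary_trait_on_tree(tree, x_rate, x_rate, seed = seed)
  set.seed(seed + 13579L)
  des <- phylo_design(tree)
  b <- if (des$m > 0) {
    u <- stats::rnorm(des$m, 0, sqrt(pmax(signal_sd^2 * des$w_of(alpha), 0)))
    drop(des$Z %*% u)
  } else rep(0, length(tree$tip.label))
  eta <- beta0 + beta1 * x[tree$tip.label] + b
  y <- stats::setNames(stats::rbinom(length(eta), 1, stats::plogis(eta)),
                       tree$tip.label)
  list(y = y, x = x[tree$tip.label], b = stats::setNames(b, tree$tip.label))
}
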