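#' Load and validate a pipeline run configuration
#'
#' A run configuration names the input files (two trait databases sharing
#' one schema, optionally a classification report with sample metadata
#' and a Newick tree), the screening thresholds (defaults: all taxa
#' 0.001% of reads, abundant taxa 0.1%), the contrasts to run and the
#' test settings (randomization resamples B, seed, alpha, optional
#' Benjamini-Hochberg switch, phylogenetic regressions on/off).
#'
#' @param config A YAML file path or an equivalent named list.
#' @return A validated list of class \code{run_config}.
#' @export
run_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  defaults <- list(
    thresholds = list(all = 0.001, abundant = 0.1),
    tests = list(B = 1e5, seed = 1L, alpha = 0.05, adjust = FALSE,
                 phylo = TRUE),
    contrasts = list("group_vs_group"))
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
    else for (k in names(defaults[[nm]]))
      if (is.list(defaults[[nm]]) && is.null(cfg[[nm]][[k]]))
        cfg[[nm]][[k]] <- defaults[[nm]][[k]]
  }
  if (is.null(cfg$paths)) stop("config needs a 'paths' block")
  for (p in unlist(cfg$paths))
    if (!file.exists(p)) stop("configured file does not exist: ", p)
  stopifnot(cfg$thresholds$all >= 0, cfg$thresholds$abundant >= 0,
            cfg$tests$alpha > 0, cfg$tests$alpha < 1, cfg$tests$B >= 1)
  cfg$tests$seed <- as.integer(cfg$tests$seed)
  class(cfg) <- "run_config"
  cfg
}

# One row of the results table.
result_row <- function(contrast, trait_class, trait, level, groups,
                       est, se, n, statistic, p_value, direction, method,
                       p_naive = NA_real_, p_phylo = NA_real_) {
  data.frame(contrast = contrast, trait_class = trait_class, trait = trait,
             level = level, group_1 = groups[1], group_2 = groups[2],
             estimate_1 = est[1], estimate_2 = est[2],
             se_1 = se[1], se_2 = se[2], n_1 = n[1], n_2 = n[2],
             statistic = statistic, p_value = p_value,
             direction = direction, method = method,
             p_naive = p_naive, p_phylo = p_phylo,
             stringsAsFactors = FALSE)
}

# Compare every trait between two database views.
# view: list(db = trait_db, taxa = character or NULL, label = chr)
compare_views <- function(view_a, view_b, contrast, tests, tree = NULL) {
  sch <- view_a$db$schema
  if (!identical(sch$binary_traits, view_b$db$schema$binary_traits) ||
      !identical(names(sch$categorical_traits),
                 names(view_b$db$schema$categorical_traits)))
    stop("schema mismatch between databases; unshared traits: ",
         paste(union(
           setdiff(sch$binary_traits, view_b$db$schema$binary_traits),
           setdiff(view_b$db$schema$binary_traits, sch$binary_traits)),
           collapse = ", "))
  groups <- c(view_a$label, view_b$label)
  rows <- list()
  seed_i <- tests$seed

  phylo_ps <- function(xa, xb) {
    # single-trait naive + corrected regressions of membership on trait
    if (is.null(tree)) return(c(NA_real_, NA_real_))
    y <- c(stats::setNames(rep(1, length(xa)), names(xa)),
           stats::setNames(rep(0, length(xb)), names(xb)))
    x <- c(xa, xb)
    ok <- !is.na(x)
    if (length(unique(y[ok])) < 2 || length(unique(x[ok])) < 2)
      return(c(NA_real_, NA_real_))
    p_n <- tryCatch({
      f1 <- naive_logistic(y, x)
      f0 <- naive_logistic(y[!is.na(x)], NULL)
      lrt(f1, f0)$p_value
    }, error = function(e) NA_real_)
    p_p <- tryCatch({
      f1 <- phylo_logistic(y, x, tree, seed = seed_i, n_starts = 2)
      f0 <- phylo_logistic(y[!is.na(x)], NULL, tree, seed = seed_i,
                           n_starts = 2)
      if (f1$n != f0$n) NA_real_ else lrt(f1, f0)$p_value
    }, error = function(e) NA_real_)
    c(p_n, p_p)
  }

  get_col <- function(view, col) {
    d <- view$db$data
    taxa <- if (is.null(view$taxa)) d$species else intersect(d$species, view$taxa)
    stats::setNames(d[[col]][match(taxa, d$species)], taxa)
  }

  # binary traits and substrates
  for (col in c(sch$binary_traits, substrate_columns(sch))) {
    va <- get_col(view_a, col); vb <- get_col(view_b, col)
    ka <- sum(va == "positive", na.rm = TRUE); na <- sum(!is.na(va))
    kb <- sum(vb == "positive", na.rm = TRUE); nb <- sum(!is.na(vb))
    if (na == 0 || nb == 0) next
    cls <- if (col %in% sch$binary_traits) "binary" else "substrate"
    chi <- tryCatch(
      chi_square_overall(rbind(c(ka, kb), c(na - ka, nb - kb))),
      error = function(e) NULL)
    pc <- pairwise_proportion_contrast(ka, na, kb, nb, groups = groups,
                                       trait = col)
    pp <- if (cls == "binary" || isTRUE(tests$phylo_substrates))
      phylo_ps(ifelse(va == "positive", 1, 0),
               ifelse(vb == "positive", 1, 0)) else c(NA_real_, NA_real_)
    rows[[length(rows) + 1]] <- result_row(
      contrast, cls, col, NA_character_, groups,
      est = pc$estimates, se = pc$ses, n = c(na, nb),
      statistic = if (is.null(chi)) pc$statistic else chi$statistic,
      p_value = if (is.null(chi)) pc$p_value else chi$p_value,
      direction = pc$direction,
      method = if (is.null(chi)) pc$method else "chi-square + binomial z",
      p_naive = pp[1], p_phylo = pp[2])
  }

  # categorical traits: randomization test
  sep <- sch$multi_value_separator
  for (col in names(sch$categorical_traits)) {
    va <- get_col(view_a, col); vb <- get_col(view_b, col)
    va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
    if (length(va) < 2 || length(vb) < 2) next
    labels <- c(rep(groups[1], length(va)), rep(groups[2], length(vb)))
    seed_i <- seed_i + 1L
    rt <- randomization_test(labels, c(va, vb), B = tests$B,
                             seed = seed_i, sep = sep)
    pp <- phylo_ps(
      stats::setNames(vapply(strsplit(va, sep, fixed = TRUE), `[`, "", 1),
                      names(va)),
      stats::setNames(vapply(strsplit(vb, sep, fixed = TRUE), `[`, "", 1),
                      names(vb)))
    for (lv in rt$levels) {
      pr <- rt$proportions[, lv]
      rows[[length(rows) + 1]] <- result_row(
        contrast, "categorical", col, lv, groups,
        est = pr[groups], se = c(NA_real_, NA_real_),
        n = rt$n_per_group[groups],
        statistic = rt$statistic[lv], p_value = rt$p_level[lv],
        direction = if (abs(diff(pr[groups])) < 1e-12) "none"
                    else groups[which.max(pr[groups])],
        method = "randomization", p_naive = pp[1], p_phylo = pp[2])
    }
    rows[[length(rows) + 1]] <- result_row(
      contrast, "categorical", col, "(overall)", groups,
      est = c(NA_real_, NA_real_), se = c(NA_real_, NA_real_),
      n = rt$n_per_group[groups],
      statistic = rt$overall_statistic, p_value = rt$p_overall,
      direction = "none", method = "randomization (max level)",
      p_naive = pp[1], p_phylo = pp[2])
  }

  # quantitative traits: relative effects
  for (col in sch$quantitative_traits) {
    xa <- get_col(view_a, col); xb <- get_col(view_b, col)
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    if (length(xa) < 2 || length(xb) < 2) next
    bm <- bm_contrast(as.numeric(xa), as.numeric(xb), groups = groups,
                      trait = col)
    rows[[length(rows) + 1]] <- result_row(
      contrast, "quantitative", col, NA_character_, groups,
      est = c(mean(as.numeric(xa)), mean(as.numeric(xb))),
      se = c(stats::sd(as.numeric(xa)) / sqrt(length(xa)),
             stats::sd(as.numeric(xb)) / sqrt(length(xb))),
      n = c(length(xa), length(xb)),
      statistic = bm$statistic, p_value = bm$p_value,
      direction = bm$direction, method = "Brunner-Munzel")
  }
  do.call(rbind, rows)
}

#' Run the full trait-comparison pipeline
#'
#' Loads the configured databases (and, when configured, the abundance
#' report, metadata and tree), builds the screening taxon sets, and runs
#' the appropriate test for every trait and contrast: binary and
#' substrate traits get an overall chi-square plus a binomial-z pairwise
#' contrast, categorical traits the seeded randomization test, and
#' quantitative traits the Brunner-Munzel relative-effect contrast.
#' When a tree is configured, naive and phylogenetically corrected
#' logistic regressions of group membership on each binary/categorical
#' trait are screened against null models by likelihood-ratio tests and
#' reported side by side. Results are deterministic given the configured
#' seed.
#'
#' @param config A \code{\link{run_config}}, path or list.
#' @return A \code{report_bundle}: list with \code{results} (one row per
#'   trait x contrast x level), \code{taxon_sets}, \code{provenance}.
#'   When \code{config$output_dir} is set, results and provenance are
#'   also written as TSV/JSON.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  schema <- if (!is.null(cfg$paths$schema)) read_schema(cfg$paths$schema)
            else read_schema()
  db_a <- read_trait_table(cfg$paths$db_a, schema)
  db_b <- if (!is.null(cfg$paths$db_b))
    read_trait_table(cfg$paths$db_b, schema) else NULL
  tree <- if (!is.null(cfg$paths$tree) && isTRUE(cfg$tests$phylo))
    ape::read.tree(cfg$paths$tree) else NULL

  tab <- NULL; sets <- list()
  if (!is.null(cfg$paths$abundance)) {
    tab <- read_classification_report(cfg$paths$abundance,
                                      cfg$paths$metadata)
    sets$all <- select_taxa(tab, cfg$thresholds$all, name = "all")
    sets$abundant <- select_taxa(tab, cfg$thresholds$abundant,
                                 name = "abundant")
    for (site in c("dry", "moist", "sebaceous"))
      if (site %in% tab$site_class)
        sets[[paste0("abundant_", site)]] <-
          select_taxa(tab, cfg$thresholds$abundant,
                      restrict_to_sites = site,
                      name = paste0("abundant_", site))
  }

  results <- list()
  for (ct in unlist(cfg$contrasts)) {
    if (ct == "group_vs_group") {
      if (is.null(db_b)) stop("contrast 'group_vs_group' needs paths$db_b")
      taxa_a <- if (!is.null(sets$abundant)) sets$abundant$members else NULL
      results[[ct]] <- compare_views(
        list(db = db_a, taxa = taxa_a, label = "group_a"),
        list(db = db_b, taxa = NULL, label = "group_b"),
        ct, cfg$tests, tree)
    } else if (ct == "abundant_vs_all") {
      if (is.null(tab)) stop("contrast 'abundant_vs_all' needs an abundance report")
      results[[ct]] <- compare_views(
        list(db = db_a, taxa = sets$abundant$members, label = "abundant"),
        list(db = db_a, taxa = sets$all$members, label = "all"),
        ct, cfg$tests, tree)
    } else if (ct == "site_pairs") {
      if (is.null(tab)) stop("contrast 'site_pairs' needs an abundance report")
      combos <- utils::combn(c("dry", "moist", "sebaceous"), 2)
      for (k in seq_len(ncol(combos))) {
        s1 <- combos[1, k]; s2 <- combos[2, k]
        n1 <- paste0("abundant_", s1); n2 <- paste0("abundant_", s2)
        if (is.null(sets[[n1]]) || is.null(sets[[n2]])) next
        results[[paste(s1, s2, sep = "_vs_")]] <- compare_views(
          list(db = db_a, taxa = sets[[n1]]$members, label = s1),
          list(db = db_a, taxa = sets[[n2]]$members, label = s2),
          paste(s1, s2, sep = "_vs_"), cfg$tests, tree)
      }
    } else if (ct == "per_phylum") {
      if (is.null(db_b)) stop("contrast 'per_phylum' needs paths$db_b")
      taxa_a <- if (!is.null(sets$abundant)) sets$abundant$members
                else db_a$data$species
      strata_a <- stratify(taxon_set("a", taxa_a), db_a)
      strata_b <- stratify(taxon_set("b", db_b$data$species), db_b)
      for (ph in intersect(names(strata_a), names(strata_b))) {
        results[[paste0("phylum_", ph)]] <- compare_views(
          list(db = db_a, taxa = strata_a[[ph]]$members,
               label = paste0("skin_", ph)),
          list(db = db_b, taxa = strata_b[[ph]]$members,
               label = paste0("world_", ph)),
          paste0("phylum_", ph), cfg$tests, tree)
      }
    } else stop("unknown contrast: ", ct)
  }
  res <- do.call(rbind, results)
  rownames(res) <- NULL
  if (isTRUE(cfg$tests$adjust))
    res$p_adjusted_bh <- stats::p.adjust(res$p_value, method = "BH")

  bundle <- list(
    results = res, taxon_sets = sets,
    provenance = list(
      package = "skintraits",
      version = as.character(utils::packageVersion("skintraits")),
      thresholds = cfg$thresholds, tests = cfg$tests,
      contrasts = unlist(cfg$contrasts),
      n_species = c(db_a = nrow(db_a$data),
                    db_b = if (is.null(db_b)) NA else nrow(db_b$data))))
  class(bundle) <- "report_bundle"

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_results_table(bundle, file.path(cfg$output_dir, "results.tsv"))
    jsonlite::write_json(bundle$provenance,
                         file.path(cfg$output_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  bundle
}

#' Write the results table of a run as TSV
#'
#' Deterministic formatting (fixed 10 significant digits) so identical
#' configurations and seeds produce byte-identical files.
#'
#' @param bundle A \code{report_bundle}.
#' @param path Output TSV path.
#' @export
write_results_table <- function(bundle, path) {
  res <- bundle$results
  num <- vapply(res, is.numeric, logical(1))
  for (cl in names(res)[num])
    res[[cl]] <- ifelse(is.na(res[[cl]]), "NA",
                        formatC(res[[cl]], digits = 10, format = "g"))
  utils::write.table(res, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle> ", nrow(x$results), " comparisons across ",
      length(unique(x$results$contrast)), " contrast(s)\n", sep = "")
  alpha <- x$provenance$tests$alpha
  cat("  p <", alpha, "in", sum(x$results$p_value < alpha, na.rm = TRUE),
      "rows\n")
  invisible(x)
}

#' Summary tables of prevalences and quantitative means
#'
#' Builds the descriptive companion tables of a run: per-trait prevalence
#' (binary traits, categorical levels and substrates, with known-value
#' denominators) and per-variable quantitative means, for each requested
#' taxon set of a database.
#'
#' @param db A \code{trait_db}.
#' @param sets Named list of taxon sets (NULL entry = all species).
#' @param output_dir Optional directory; writes
#'   \code{summary_prevalence.tsv} and \code{summary_quantitative.tsv}.
#' @return List with data frames \code{prevalence} and
#'   \code{quantitative}.
#' @export
summarize_tables <- function(db, sets = list(all = NULL),
                             output_dir = NULL) {
  sch <- db$schema
  prev_rows <- list()
  for (col in c(sch$binary_traits, substrate_columns(sch))) {
    row <- list(trait = col, level = NA_character_,
                class = if (col %in% sch$binary_traits) "binary"
                        else "substrate")
    for (sn in names(sets)) {
      pv <- trait_prevalence(db, sets[[sn]], col)
      row[[paste0("prop_", sn)]] <- pv$proportion
      row[[paste0("n_", sn)]] <- pv$n
    }
    prev_rows[[length(prev_rows) + 1]] <- as.data.frame(row)
  }
  for (tr in names(sch$categorical_traits))
    for (lv in sch$categorical_traits[[tr]]) {
      row <- list(trait = tr, level = lv, class = "categorical")
      for (sn in names(sets)) {
        pv <- trait_prevalence(db, sets[[sn]], c(tr, lv))
        row[[paste0("prop_", sn)]] <- pv$proportion
        row[[paste0("n_", sn)]] <- pv$n
      }
      prev_rows[[length(prev_rows) + 1]] <- as.data.frame(row)
    }
  prevalence <- do.call(rbind, prev_rows)

  quant_rows <- list()
  for (qv in sch$quantitative_traits) {
    row <- list(variable = qv)
    for (sn in names(sets)) {
      sm <- summarize_quantitative(db, sets[[sn]], qv)
      row[[paste0("mean_", sn)]] <- sm$mean
      row[[paste0("sd_", sn)]] <- sm$sd
      row[[paste0("n_", sn)]] <- sm$n
    }
    quant_rows[[length(quant_rows) + 1]] <- as.data.frame(row)
  }
  quantitative <- do.call(rbind, quant_rows)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(prevalence,
                       file.path(output_dir, "summary_prevalence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(quantitative,
                       file.path(output_dir, "summary_quantitative.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(prevalence = prevalence, quantitative = quantitative)
}
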