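#' Construct an abundance table
#'
#' Taxon-by-sample relative abundances in percent of reads, with a skin
#' site class (dry / moist / sebaceous / unclassified) attached to every
#' sample. Values must be nonnegative and each sample must sum to at most
#' 100 (small numerical slack allowed).
#'
#' @param values Numeric matrix, taxa in rows (rownames = species names),
#'   samples in columns (colnames = sample IDs).
#' @param site_class Character vector of site classes, one per sample
#'   (named by sample ID or in column order).
#' @return An object of class \code{abundance_table}.
#' @export
abundance_table <- function(values, site_class = NULL) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (any(values < 0)) stop("negative abundance value")
  cs <- colSums(values)
  if (any(cs > 100 + 1e-6))
    stop("per-sample abundances sum above 100%: ",
         paste(colnames(values)[cs > 100 + 1e-6], collapse = ", "))
  if (is.null(site_class))
    site_class <- rep("unclassified", ncol(values))
  if (!is.null(names(site_class)))
    site_class <- site_class[colnames(values)]
  site_class <- as.character(site_class)
  site_class[is.na(site_class)] <- "unclassified"
  ok <- c("dry", "moist", "sebaceous", "unclassified")
  if (!all(site_class %in% ok))
    stop("site_class must be one of: ", paste(ok, collapse = ", "))
  names(site_class) <- colnames(values)
  out <- list(values = values, site_class = site_class)
  class(out) <- "abundance_table"
  out
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("<abundance_table> ", nrow(x$values), " taxa x ", ncol(x$values),
      " samples\n", sep = "")
  cat("  site classes: ",
      paste(sprintf("%s=%d", names(table(x$site_class)),
                    table(x$site_class)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read a taxonomic classification report
#'
#' Parses the species-level summary of a read classifier (the style of a
#' Kraken report summarised per taxon) into an \code{abundance_table}.
#' Two TSV dialects are auto-detected: long (columns \code{taxon},
#' \code{sample}, \code{percent}, optional \code{rank}) and wide (column
#' \code{taxon}, optional \code{rank}, remaining columns one per sample).
#' Only species-rank rows are kept (\code{rank} of "species" or the
#' one-letter code "S"; when no rank column is present all rows are taken
#' as species). Skipped rows are counted in the \code{skipped} attribute.
#'
#' @param path Classification report TSV.
#' @param metadata_path Optional sample metadata TSV with columns
#'   \code{sample_id}, \code{site}, \code{site_class}; samples missing
#'   from it are labelled "unclassified" with a warning.
#' @return An \code{abundance_table}.
#' @export
read_classification_report <- function(path, metadata_path = NULL) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0) stop("no species rows in classification report")
  if (!"taxon" %in% names(raw))
    stop("classification report needs a 'taxon' column")

  skipped <- 0L
  if ("rank" %in% names(raw)) {
    is_sp <- tolower(raw$rank) %in% c("species", "s")
    skipped <- sum(!is_sp)
    raw <- raw[is_sp, , drop = FALSE]
  }
  if (nrow(raw) == 0) stop("no species rows in classification report")

  long <- all(c("sample", "percent") %in% names(raw))
  if (long) {
    raw$percent <- as.numeric(raw$percent)
    if (any(is.na(raw$percent))) stop("non-numeric abundance value")
    if (any(raw$percent < 0)) stop("negative abundance value")
    taxa <- sort(unique(raw$taxon))
    samples <- sort(unique(raw$sample))
    m <- matrix(0, length(taxa), length(samples),
                dimnames = list(taxa, samples))
    # duplicated (taxon, sample) rows collapse by sum so that duplicated
    # zero-abundance rows are harmless
    for (i in seq_len(nrow(raw)))
      m[raw$taxon[i], raw$sample[i]] <- m[raw$taxon[i], raw$sample[i]] +
        raw$percent[i]
  } else {
    samp_cols <- setdiff(names(raw), c("taxon", "rank"))
    if (length(samp_cols) == 0) stop("no sample columns in wide report")
    m <- as.matrix(raw[, samp_cols, drop = FALSE])
    mode(m) <- "numeric"
    if (any(is.na(m))) stop("non-numeric abundance value")
    if (any(m < 0)) stop("negative abundance value")
    rownames(m) <- raw$taxon
    if (anyDuplicated(rownames(m)) > 0)
      m <- rowsum(m, rownames(m))
  }

  site_class <- NULL
  if (!is.null(metadata_path)) {
    md <- utils::read.delim(metadata_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    if (!all(c("sample_id", "site_class") %in% names(md)))
      stop("sample metadata needs 'sample_id' and 'site_class' columns")
    site_class <- md$site_class[match(colnames(m), md$sample_id)]
    if (any(is.na(site_class))) {
      warning("sample(s) missing from metadata, labelled unclassified: ",
              paste(colnames(m)[is.na(site_class)], collapse = ", "))
      site_class[is.na(site_class)] <- "unclassified"
    }
    names(site_class) <- colnames(m)
  }
  out <- abundance_table(m, site_class)
  attr(out, "skipped") <- skipped
  out
}

#' Select taxa above an abundance threshold
#'
#' Members are the taxa whose relative abundance strictly exceeds the
#' threshold in at least one sample (optionally restricted to samples of
#' given site classes). The strict inequality follows the "> 0.001% of
#' reads" construction of the all-taxa list and the "> 0.1%" abundant
#' list, so a taxon exactly at the threshold is excluded.
#'
#' @param table An \code{abundance_table}.
#' @param threshold_percent Threshold in percent of reads (>= 0).
#' @param restrict_to_sites Optional character vector of site classes;
#'   only samples of those classes are screened.
#' @param name Label for the resulting set.
#' @return A \code{\link{taxon_set}} with provenance recording threshold
#'   and site restriction.
#' @export
select_taxa <- function(table, threshold_percent,
                        restrict_to_sites = NULL, name = NULL) {
  stopifnot(inherits(table, "abundance_table"), threshold_percent >= 0)
  m <- table$values
  if (!is.null(restrict_to_sites)) {
    keep <- table$site_class %in% restrict_to_sites
    if (!any(keep))
      stop("site restriction excludes all samples: ",
           paste(restrict_to_sites, collapse = ", "))
    m <- m[, keep, drop = FALSE]
  }
  hit <- apply(m, 1, function(v) any(v > threshold_percent))
  if (is.null(name))
    name <- sprintf("taxa > %g%%%s", threshold_percent,
                    if (is.null(restrict_to_sites)) "" else
                      paste0(" (", paste(restrict_to_sites, collapse = "+"), ")"))
  taxon_set(name, rownames(m)[hit],
            provenance = sprintf(
              "strictly > %g%% of reads in >= 1 of %d sample(s)%s",
              threshold_percent, ncol(m),
              if (is.null(restrict_to_sites)) "" else
                paste0("; sites: ", paste(restrict_to_sites, collapse = ","))))
}

#' Stratify a taxon set by phylum
#'
#' Partitions the members carrying a phylum label in the database into
#' per-phylum taxon sets; members absent from the database are returned
#' in the \code{unlabeled} attribute.
#'
#' @param taxon_set_obj A \code{taxon_set} or character vector.
#' @param db A \code{trait_db} supplying phylum labels.
#' @param by Stratification variable; only \code{"phylum"} is supported.
#' @return Named list of \code{taxon_set} objects, one per phylum.
#' @export
stratify <- function(taxon_set_obj, db, by = "phylum") {
  stopifnot(identical(by, "phylum"), inherits(db, "trait_db"))
  members <- if (inherits(taxon_set_obj, "taxon_set")) taxon_set_obj$members
             else as.character(taxon_set_obj)
  set_name <- if (inherits(taxon_set_obj, "taxon_set")) taxon_set_obj$name
              else "taxa"
  idx <- match(members, db$data$species)
  unlabeled <- members[is.na(idx)]
  labeled <- members[!is.na(idx)]
  phyla <- db$data$phylum[idx[!is.na(idx)]]
  out <- lapply(split(labeled, phyla), function(sp)
    taxon_set(paste0(set_name, " / ", db$data$phylum[match(sp[1], db$data$species)]),
              sp, provenance = paste0("phylum stratum of '", set_name, "'")))
  attr(out, "unlabeled") <- unlabeled
  out
}
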