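#' Read a culture-derived trait table
#'
#' Parses a UTF-8 tab-separated trait table (header row; first two columns
#' \code{species} and \code{phylum}; one row per species; empty cell =
#' unknown) into a \code{trait_db}. Cell tokens are normalised through the
#' schema's alias map: e.g. \code{"+"} becomes positive, \code{"-"}
#' negative, \code{"ND"} unknown, and \code{"v"} marks strain variation
#' (value stored as unknown and the trait recorded in the species'
#' strain-variation flags). Categorical cells may carry several levels
#' separated by the schema's separator (default \code{";"}); a species is
#' then counted once per level it exhibits. Missing quantitative ranges
#' are derived as \code{max - min} when both endpoints are known.
#'
#' @param path Path to the TSV file.
#' @param schema A \code{trait_schema} (default: the shipped schema).
#' @param ignore_extra Keep going when the file has columns not declared
#'   in the schema (they are dropped and listed in the parse report)?
#'   Default \code{FALSE}: unknown columns are an error.
#' @return An object of class \code{trait_db}: a list with elements
#'   \code{data} (one row per species), \code{schema},
#'   \code{strain_variation} (species/trait pairs flagged \code{"v"}), and
#'   \code{parse_report} (every coerced, derived or dropped cell).
#' @export
read_trait_table <- function(path, schema = read_schema(),
                             ignore_extra = FALSE) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, fileEncoding = "UTF-8")
  if (!all(c("species", "phylum") %in% names(raw)))
    stop("trait table must start with 'species' and 'phylum' columns")
  dup <- raw$species[duplicated(raw$species)]
  if (length(dup) > 0)
    stop("duplicate species in trait table: ",
         paste(unique(dup), collapse = ", "))
  if (any(!nzchar(trimws(raw$species))))
    stop("empty species name in trait table")

  known_cols <- c("species", "phylum", schema$binary_traits,
                  names(schema$categorical_traits),
                  schema$quantitative_traits, substrate_columns(schema))
  extra <- setdiff(names(raw), known_cols)
  report <- list()
  note <- function(row, column, original, action) {
    report[[length(report) + 1L]] <<-
      data.frame(row = row, column = column, original = original,
                 action = action, stringsAsFactors = FALSE)
  }
  if (length(extra) > 0) {
    if (!ignore_extra)
      stop("unknown column(s) in trait table: ",
           paste(extra, collapse = ", "),
           " (use ignore_extra = TRUE to drop them)")
    for (col in extra) note(NA_integer_, col, "", "column dropped")
    raw <- raw[, setdiff(names(raw), extra), drop = FALSE]
  }

  n <- nrow(raw)
  out <- data.frame(species = trimws(raw$species),
                    phylum = trimws(raw$phylum),
                    stringsAsFactors = FALSE)
  sv <- list() # strain-variation flags

  parse_binary_col <- function(col) {
    vals <- rep(NA_character_, n)
    if (!col %in% names(raw)) return(vals)
    for (i in seq_len(n)) {
      state <- normalize_token(raw[[col]][i], schema$alias_map)
      if (is.na(state))
        stop(sprintf("unrecognised token '%s' in column '%s', row %d",
                     raw[[col]][i], col, i))
      if (state == "variable") {
        sv[[length(sv) + 1L]] <<- data.frame(
          species = out$species[i], trait = col, stringsAsFactors = FALSE)
        note(i, col, raw[[col]][i], "strain variation -> unknown")
        state <- "unknown"
      }
      if (state == "unknown") {
        if (nzchar(trimws(raw[[col]][i])))
          note(i, col, raw[[col]][i], "coerced to unknown")
        vals[i] <- NA_character_
      } else {
        vals[i] <- state
      }
    }
    vals
  }

  for (tr in schema$binary_traits) out[[tr]] <- parse_binary_col(tr)
  for (sc in substrate_columns(schema)) out[[sc]] <- parse_binary_col(sc)

  for (tr in names(schema$categorical_traits)) {
    vocab <- schema$categorical_traits[[tr]]
    vals <- rep(NA_character_, n)
    if (tr %in% names(raw)) {
      for (i in seq_len(n)) {
        cell <- trimws(raw[[tr]][i])
        state <- normalize_token(cell, schema$alias_map)
        if (identical(state, "unknown")) {
          if (nzchar(cell)) note(i, tr, cell, "coerced to unknown")
          next
        }
        levels <- trimws(strsplit(cell, schema$multi_value_separator,
                                  fixed = TRUE)[[1]])
        levels <- levels[nzchar(levels)]
        bad <- setdiff(tolower(levels), tolower(vocab))
        if (length(bad) > 0)
          stop(sprintf(
            "level '%s' not in vocabulary of '%s' (row %d); allowed: %s",
            bad[1], tr, i, paste(vocab, collapse = "/")))
        levels <- vocab[match(tolower(levels), tolower(vocab))]
        vals[i] <- paste(unique(levels), collapse = schema$multi_value_separator)
      }
    }
    out[[tr]] <- vals
  }

  for (qv in schema$quantitative_traits) {
    vals <- rep(NA_real_, n)
    if (qv %in% names(raw)) {
      cell <- trimws(raw[[qv]])
      empty <- !nzchar(cell) |
        tolower(cell) %in% tolower(schema$alias_map$unknown)
      num <- suppressWarnings(as.numeric(cell))
      bad <- which(!empty & is.na(num))
      if (length(bad) > 0)
        stop(sprintf("non-numeric value '%s' in column '%s', row %d",
                     cell[bad[1]], qv, bad[1]))
      vals[!empty] <- num[!empty]
    }
    out[[qv]] <- vals
  }

  # Fill missing ranges from known endpoints (stored ranges win; any
  # conflict is surfaced later by validate()).
  for (base in c("temperature", "ph", "nacl")) {
    rg <- paste0(base, "_range")
    mn <- paste0(base, "_min"); mx <- paste0(base, "_max")
    fill <- is.na(out[[rg]]) & !is.na(out[[mn]]) & !is.na(out[[mx]])
    if (any(fill)) {
      out[[rg]][fill] <- out[[mx]][fill] - out[[mn]][fill]
      for (i in which(fill)) note(i, rg, "", "range derived as max - min")
    }
  }

  sv_df <- if (length(sv) > 0) unique(do.call(rbind, sv)) else
    data.frame(species = character(), trait = character(),
               stringsAsFactors = FALSE)
  rep_df <- if (length(report) > 0) do.call(rbind, report) else
    data.frame(row = integer(), column = character(), original = character(),
               action = character(), stringsAsFactors = FALSE)

  db <- list(data = out, schema = schema, strain_variation = sv_df,
             parse_report = rep_df)
  class(db) <- "trait_db"
  db
}

#' Build a trait database from an in-memory data frame
#'
#' Convenience constructor used mainly by the synthetic-data generator:
#' takes a data frame already in canonical form (binary cells
#' positive/negative/NA, categorical cells vocabulary levels joined by the
#' schema separator, numeric quantitative columns) and wraps it as a
#' \code{trait_db}. Missing schema columns are added as all-unknown.
#'
#' @param data Data frame with at least \code{species} and \code{phylum}.
#' @param schema A \code{trait_schema}.
#' @return A \code{trait_db}.
#' @export
trait_db <- function(data, schema = read_schema()) {
  stopifnot(is.data.frame(data), all(c("species", "phylum") %in% names(data)))
  if (anyDuplicated(data$species) > 0) stop("duplicate species")
  for (tr in c(schema$binary_traits, names(schema$categorical_traits),
               substrate_columns(schema)))
    if (!tr %in% names(data)) data[[tr]] <- NA_character_
  for (qv in schema$quantitative_traits)
    if (!qv %in% names(data)) data[[qv]] <- NA_real_
  keep <- c("species", "phylum", schema$binary_traits,
            names(schema$categorical_traits), schema$quantitative_traits,
            substrate_columns(schema))
  db <- list(data = data[, keep, drop = FALSE], schema = schema,
             strain_variation = data.frame(species = character(),
                                           trait = character(),
                                           stringsAsFactors = FALSE),
             parse_report = data.frame(row = integer(), column = character(),
                                       original = character(),
                                       action = character(),
                                       stringsAsFactors = FALSE))
  class(db) <- "trait_db"
  db
}

#' Write a trait database back to TSV
#'
#' Inverse of \code{\link{read_trait_table}}: positive/negative cells are
#' written as \code{"+"}/\code{"-"}, unknowns as empty cells, and traits
#' flagged for strain variation as \code{"v"}, so that read -> write ->
#' read round-trips to an identical database.
#'
#' @param db A \code{trait_db}.
#' @param path Output path.
#' @export
write_trait_table <- function(db, path) {
  stopifnot(inherits(db, "trait_db"))
  sch <- db$schema
  out <- db$data
  tok <- c(positive = "+", negative = "-")
  for (col in c(sch$binary_traits, substrate_columns(sch))) {
    v <- tok[out[[col]]]
    v[is.na(v)] <- ""
    flagged <- db$strain_variation$species[db$strain_variation$trait == col]
    v[out$species %in% flagged] <- "v"
    out[[col]] <- unname(v)
  }
  for (col in names(sch$categorical_traits)) {
    v <- out[[col]]; v[is.na(v)] <- ""; out[[col]] <- v
  }
  for (col in sch$quantitative_traits) {
    v <- out[[col]]
    out[[col]] <- ifelse(is.na(v), "", formatC(v, digits = 17, format = "g"))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.trait_db <- function(x, ...) {
  cat("<trait_db> ", nrow(x$data), " species\n", sep = "")
  cat("  phyla: ", paste(utils::head(sort(unique(x$data$phylum)), 6),
                         collapse = ", "), "\n", sep = "")
  sch <- x$schema
  cat("  traits: ", length(sch$binary_traits), " binary, ",
      length(sch$categorical_traits), " categorical, ",
      length(sch$quantitative_traits), " quantitative, ",
      length(substrate_columns(sch)), " substrates\n", sep = "")
  if (nrow(x$parse_report) > 0)
    cat("  parse report: ", nrow(x$parse_report), " entries\n", sep = "")
  invisible(x)
}

#' Validate a trait database
#'
#' Reports invariant violations without modifying the database: errors for
#' out-of-bounds GC content (outside [0, 100]) and empty species names;
#' warnings for quantitative triples with the optimum outside [min, max]
#' and for stored ranges that disagree with max - min. Also counts unknown
#' values per trait.
#'
#' @param db A \code{trait_db}.
#' @return A \code{validation_report}: list with \code{violations} (data
#'   frame of severity/species/column/message) and \code{unknown_counts}.
#' @export
validate_trait_db <- function(db) {
  stopifnot(inherits(db, "trait_db"))
  d <- db$data
  sch <- db$schema
  v <- list()
  flag <- function(severity, species, column, message) {
    v[[length(v) + 1L]] <<- data.frame(
      severity = severity, species = species, column = column,
      message = message, stringsAsFactors = FALSE)
  }
  bad_gc <- which(!is.na(d$gc_content) &
                    (d$gc_content < 0 | d$gc_content > 100))
  for (i in bad_gc)
    flag("error", d$species[i], "gc_content",
         sprintf("gc_content %g outside [0, 100]", d$gc_content[i]))
  for (i in which(!nzchar(trimws(d$species))))
    flag("error", d$species[i], "species", "empty species name")
  for (base in c("temperature", "ph", "nacl")) {
    mn <- d[[paste0(base, "_min")]]; mx <- d[[paste0(base, "_max")]]
    op <- d[[paste0(base, "_optimum")]]; rg <- d[[paste0(base, "_range")]]
    i_op <- which(!is.na(mn) & !is.na(mx) & !is.na(op) &
                    (op < mn - 1e-9 | op > mx + 1e-9))
    for (i in i_op)
      flag("warning", d$species[i], paste0(base, "_optimum"),
           sprintf("optimum %g outside [%g, %g]", op[i], mn[i], mx[i]))
    i_rg <- which(!is.na(mn) & !is.na(mx) & !is.na(rg) &
                    abs(rg - (mx - mn)) > 1e-9)
    for (i in i_rg)
      flag("warning", d$species[i], paste0(base, "_range"),
           sprintf("stored range %g != max - min = %g (stored value kept)",
                   rg[i], mx[i] - mn[i]))
    i_swap <- which(!is.na(mn) & !is.na(mx) & mx < mn - 1e-9)
    for (i in i_swap)
      flag("warning", d$species[i], paste0(base, "_min"),
           sprintf("min %g exceeds max %g", mn[i], mx[i]))
  }

  trait_cols <- c(sch$binary_traits, names(sch$categorical_traits),
                  sch$quantitative_traits, substrate_columns(sch))
  unknown_counts <- vapply(trait_cols, function(cl) sum(is.na(d[[cl]])),
                           integer(1))

  viol <- if (length(v) > 0) do.call(rbind, v) else
    data.frame(severity = character(), species = character(),
               column = character(), message = character(),
               stringsAsFactors = FALSE)
  rep <- list(violations = viol, unknown_counts = unknown_counts,
              n_species = nrow(d))
  class(rep) <- "validation_report"
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  ne <- sum(x$violations$severity == "error")
  nw <- sum(x$violations$severity == "warning")
  cat("<validation_report> ", x$n_species, " species: ", ne, " errors, ",
      nw, " warnings\n", sep = "")
  if (nrow(x$violations) > 0)
    print(utils::head(x$violations, 10), row.names = FALSE)
  invisible(x)
}

#' Write a validation report as JSON lines
#'
#' One violation per line, with species/column coordinates.
#'
#' @param report A \code{validation_report}.
#' @param path Output path.
#' @export
write_validation_report <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (nrow(report$violations) > 0)
    for (i in seq_len(nrow(report$violations)))
      writeLines(jsonlite::toJSON(as.list(report$violations[i, ]),
                                  auto_unbox = TRUE), con)
  invisible(path)
}

# Resolve a taxon set argument to species names present in the database;
# NULL means all species.
resolve_taxa <- function(db, taxon_set) {
  if (is.null(taxon_set)) return(db$data$species)
  members <- if (inherits(taxon_set, "taxon_set")) taxon_set$members
             else as.character(taxon_set)
  intersect(db$data$species, members)
}

#' Prevalence of a trait within a taxon set
#'
#' Computes k (species positive for the trait), n (species with a known
#' value) and the proportion k/n. Unknown values never enter the
#' denominator. The trait may be a binary trait name, a substrate name
#' (with or without the \code{use_} prefix), or a (categorical trait,
#' level) pair given as a length-2 character vector; for multi-valued
#' categorical cells a species counts as positive for every level it
#' exhibits, so level proportions need not sum to 1.
#'
#' @param db A \code{trait_db}.
#' @param taxon_set Species names, a \code{taxon_set}, or NULL for all.
#' @param trait Trait selector (see Details).
#' @return List with \code{k}, \code{n}, \code{proportion} (NA and
#'   \code{flagged = TRUE} when no known values), \code{trait},
#'   \code{level}.
#' @export
#' @examples
#' db <- gen_trait_database(simulation_spec(n_taxa = c(20, 20), seed = 1))$db_a
#' trait_prevalence(db, NULL, "catalase")
#' trait_prevalence(db, NULL, c("oxygen_use", "facultative"))
trait_prevalence <- function(db, taxon_set = NULL, trait) {
  stopifnot(inherits(db, "trait_db"))
  sch <- db$schema
  taxa <- resolve_taxa(db, taxon_set)
  d <- db$data[db$data$species %in% taxa, , drop = FALSE]
  level <- NA_character_

  if (length(trait) == 2) {
    tr <- trait[1]; level <- trait[2]
    if (!tr %in% names(sch$categorical_traits))
      stop("unknown categorical trait: ", tr)
    if (!level %in% sch$categorical_traits[[tr]])
      stop(sprintf("level '%s' not in vocabulary of '%s'", level, tr))
    vals <- d[[tr]]
    known <- !is.na(vals)
    sep <- sch$multi_value_separator
    pos <- vapply(vals[known],
                  function(v) level %in% strsplit(v, sep, fixed = TRUE)[[1]],
                  logical(1))
    k <- sum(pos); n <- sum(known)
  } else {
    tr <- as.character(trait)
    col <- if (tr %in% names(d)) tr
           else if (paste0("use_", tr) %in% names(d)) paste0("use_", tr)
           else stop("unknown trait: ", tr)
    if (!col %in% c(sch$binary_traits, substrate_columns(sch)))
      stop("trait '", tr, "' is not binary; pass c(trait, level) for ",
           "categorical traits")
    vals <- d[[col]]
    known <- !is.na(vals)
    k <- sum(vals[known] == "positive"); n <- sum(known)
    trait <- col
  }
  list(trait = trait[1], level = level, k = k, n = n,
       proportion = if (n > 0) k / n else NA_real_, flagged = (n == 0))
}

#' Mean of a quantitative trait within a taxon set
#'
#' Arithmetic mean over species with a known value (unknowns excluded
#' from the denominator), with the sample size and standard deviation.
#'
#' @param db A \code{trait_db}.
#' @param taxon_set Species names, a \code{taxon_set}, or NULL for all.
#' @param variable One of the schema's quantitative traits, e.g.
#'   \code{"gc_content"} or \code{"temperature_optimum"}.
#' @return List with \code{mean}, \code{sd}, \code{n}, \code{flagged}.
#' @export
summarize_quantitative <- function(db, taxon_set = NULL, variable) {
  stopifnot(inherits(db, "trait_db"))
  if (!variable %in% db$schema$quantitative_traits)
    stop("unknown quantitative variable: ", variable)
  taxa <- resolve_taxa(db, taxon_set)
  vals <- db$data[[variable]][db$data$species %in% taxa]
  vals <- vals[!is.na(vals)]
  list(variable = variable, n = length(vals),
       mean = if (length(vals) > 0) mean(vals) else NA_real_,
       sd = if (length(vals) > 1) stats::sd(vals) else NA_real_,
       flagged = (length(vals) == 0))
}

#' Construct a named taxon set
#'
#' @param name Label, e.g. "abundant skin".
#' @param members Character vector of species names.
#' @param provenance Free-text description of how the set was built
#'   (threshold, source).
#' @return An object of class \code{taxon_set}.
#' @export
taxon_set <- function(name, members, provenance = "") {
  out <- list(name = name, members = unique(as.character(members)),
              provenance = provenance)
  class(out) <- "taxon_set"
  out
}

#' @export
print.taxon_set <- function(x, ...) {
  cat("<taxon_set> '", x$name, "': ", length(x$members), " species\n",
      sep = "")
  if (nzchar(x$provenance)) cat("  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' @export
length.taxon_set <- function(x) length(x$members)
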