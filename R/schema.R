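#' Load a trait-table schema configuration
#'
#' A schema fixes the controlled vocabularies of a trait table: which
#' columns hold binary traits, the level vocabulary of each categorical
#' trait, the quantitative variables, the substrate catalog with its
#' category labels (organic acids, amino acids, monosaccharides,
#' oligo/polysaccharides, alcohols, other), and the alias map used to
#' normalise raw cell tokens ("+", "-", "v", "ND", ...) into positive /
#' negative / unknown / variable states. Schemas are plain YAML so new
#' trait classes need no code change.
#'
#' @param path Path to a YAML schema file. The default is the schema
#'   shipped with the package, whose vocabularies cover oxygen use,
#'   motility, shape, Gram stain and aggregation.
#' @return A list of class \code{trait_schema}.
#' @export
#' @examples
#' sch <- read_schema()
#' sch$categorical_traits$oxygen_use
read_schema <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_schema.yaml",
                        package = "skintraits", mustWork = TRUE)
  }
  sch <- yaml::read_yaml(path)
  required <- c("binary_traits", "categorical_traits", "quantitative_traits",
                "substrates", "alias_map")
  miss <- setdiff(required, names(sch))
  if (length(miss) > 0)
    stop("schema is missing fields: ", paste(miss, collapse = ", "))
  if (is.null(sch$multi_value_separator)) sch$multi_value_separator <- ";"
  sch$binary_traits <- as.character(sch$binary_traits)
  sch$quantitative_traits <- as.character(sch$quantitative_traits)
  class(sch) <- "trait_schema"
  sch
}

#' @export
print.trait_schema <- function(x, ...) {
  cat("<trait_schema>\n")
  cat("  binary traits:      ", length(x$binary_traits), "\n")
  cat("  categorical traits: ", paste(names(x$categorical_traits),
                                      collapse = ", "), "\n")
  cat("  quantitative traits:", length(x$quantitative_traits), "\n")
  cat("  substrates:         ", sum(lengths(x$substrates)), "in",
      length(x$substrates), "categories\n")
  invisible(x)
}

# All substrate names of a schema, as column names (use_<substrate>).
substrate_columns <- function(schema) {
  paste0("use_", unlist(schema$substrates, use.names = FALSE))
}

# Flat substrate -> category lookup.
substrate_catalog <- function(schema) {
  data.frame(
    substrate = unlist(schema$substrates, use.names = FALSE),
    category = rep(names(schema$substrates), lengths(schema$substrates)),
    stringsAsFactors = FALSE
  )
}

# Normalise one raw token against the alias map.
# Returns one of "positive", "negative", "unknown", "variable", or NA when
# the token matches no alias.
normalize_token <- function(token, alias_map) {
  tok <- tolower(trimws(token))
  for (state in names(alias_map)) {
    if (tok %in% tolower(alias_map[[state]])) return(state)
  }
  NA_character_
}
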