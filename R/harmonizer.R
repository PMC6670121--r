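#' Default fine-term to broad-category harmonization map
#'
#' Both splice terms collapse into "splicing", exonic_coding becomes
#' "exonic", every other term maps to its namesake. The map ships as an
#' editable TSV (`inst/extdata/harmonization_map.tsv`) so outputs of real
#' annotation tools with richer vocabularies can be harmonized without code
#' changes.
#'
#' @return Named character vector, fine term -> broad category.
#' @export
default_harmonization_map <- function() {
  c(exonic_coding = "exonic",
    splice_site = "splicing",
    splice_region = "splicing",
    ncRNA_exonic = "ncRNA_exonic",
    UTR5 = "UTR5",
    UTR3 = "UTR3",
    intronic = "intronic",
    upstream = "upstream",
    downstream = "downstream",
    intergenic = "intergenic")
}

#' Load a harmonization map from TSV
#'
#' @param path TSV with columns fine_term, broad_category.
#' @param require_terms Fine terms the map must cover (totality check);
#'   default the built-in vocabulary.
#' @return Named character vector, fine term -> broad category.
#' @export
load_harmonization_map <- function(path, require_terms = fine_terms()) {
  df <- read_tsv(path)
  if (!all(c("fine_term", "broad_category") %in% names(df)))
    stop("harmonization map needs columns fine_term, broad_category")
  if (anyDuplicated(df$fine_term) > 0L)
    stop("duplicate fine_term in harmonization map")
  map <- stats::setNames(df$broad_category, df$fine_term)
  missing <- setdiff(require_terms, names(map))
  if (length(missing))
    stop("harmonization map not total; missing: ",
         paste(missing, collapse = ", "))
  map
}

#' Map fine consequence terms to broad categories
#'
#' @param term Character vector of fine terms.
#' @param map Harmonization map (named character vector).
#' @return Character vector of broad categories.
#' @export
#' @examples
#' harmonize_terms(c("splice_region", "intronic"))
harmonize_terms <- function(term, map = default_harmonization_map()) {
  out <- unname(map[term])
  if (anyNA(out)) {
    bad <- unique(term[is.na(out)])
    stop("unknown fine term(s): ", paste(bad, collapse = ", "))
  }
  out
}

#' Broad category of one variant from its call list
#'
#' Collapses the calls to the most severe and harmonizes its term:
#' `harmonize_terms(collapse_most_severe(calls)$term)`.
#'
#' @param calls data.frame of calls for a single variant key.
#' @param map Harmonization map.
#' @return Single broad-category string.
#' @export
variant_category <- function(calls, map = default_harmonization_map()) {
  harmonize_terms(collapse_most_severe(calls)$term, map)
}

#' Per-variant broad-category assignment from a call table
#'
#' Applies precedence collapse and harmonization to every variant in a call
#' table, returning the named assignment vector the concordance module
#' consumes.
#'
#' @param calls data.frame as produced by [annotate_variants()] (any style).
#' @param map Harmonization map.
#' @return Named character vector: variant_key -> broad category.
#' @export
assignment_from_calls <- function(calls, map = default_harmonization_map()) {
  if (nrow(calls) == 0L)
    return(stats::setNames(character(0), character(0)))
  o <- order(calls$variant_key, calls$impact_rank, calls$transcript_id,
             method = "radix")
  first <- !duplicated(calls$variant_key[o])
  sel <- o[first]
  stats::setNames(harmonize_terms(calls$term[sel], map),
                  calls$variant_key[sel])
}
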