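#' Fine-grained consequence vocabulary and severity precedence
#'
#' The annotator classifies every (variant, transcript) pair into one of ten
#' fine-grained consequence terms. Severity is a strict total order over the
#' vocabulary; lower rank means more severe. The default order follows the
#' convention used by gene-based annotators that report a single most-severe
#' consequence: coding exonic effects outrank splice-site effects, which
#' outrank the near-boundary splice region, then non-coding exonic, UTRs,
#' intronic, flanking and intergenic.
#'
#' @return Character vector of the ten terms, most severe first.
#' @export
#' @examples
#' fine_terms()
fine_terms <- function() {
  c("exonic_coding", "splice_site", "splice_region", "ncRNA_exonic",
    "UTR5", "UTR3", "intronic", "upstream", "downstream", "intergenic")
}

#' Severity ranks for a precedence order
#'
#' @param precedence Character vector: a permutation of [fine_terms()],
#'   most severe first.
#' @return Named integer vector mapping each term to its rank (1 = most
#'   severe).
#' @export
fine_term_ranks <- function(precedence = fine_terms()) {
  if (!setequal(precedence, fine_terms()) ||
      anyDuplicated(precedence) > 0L) {
    stop("precedence must be a permutation of fine_terms()")
  }
  stats::setNames(seq_along(precedence), precedence)
}

#' Broad comparison categories
#'
#' The harmonized vocabulary in which two annotation strategies are compared:
#' both splice terms collapse into "splicing" and coding exonic becomes
#' "exonic"; all other fine terms keep their names.
#'
#' @return Character vector of the nine broad categories, ordered by the
#'   severity of their most severe fine term.
#' @export
broad_categories <- function() {
  c("exonic", "splicing", "ncRNA_exonic", "UTR5", "UTR3",
    "intronic", "upstream", "downstream", "intergenic")
}

# internal: "chrom:pos:ref:alt" identity string for normalized variants
make_variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Variant identity key
#'
#' Two variants are treated as "the same variant" for all matching and
#' concordance purposes iff their normalized (chrom, pos, ref, alt) keys are
#' equal. Keys are only meaningful on normalized, biallelic variants.
#'
#' @param variants A variant table (data.frame with columns chrom, pos, ref,
#'   alt) or a `variant_set`.
#' @return Character vector of keys, "chrom:pos:ref:alt".
#' @export
variant_key <- function(variants) {
  v <- if (inherits(variants, "variant_set")) variants$variants else variants
  make_variant_key(v$chrom, v$pos, v$ref, v$alt)
}

# internal: write a data.frame as a plain TSV (deterministic, no quoting)
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE, ...)
}
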