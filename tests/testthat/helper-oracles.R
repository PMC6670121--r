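# Independent brute-force oracles and tiny fixture builders. These
# deliberately re-derive results by the most naive route available (linear
# scans, per-base loops, nested loops) so they share no code path with the
# implementations they check.

# transcript spanning its exons exactly
make_tx <- function(id, chrom, strand, exons, cds = NULL,
                    biotype = if (is.null(cds)) "noncoding" else "coding") {
  exons <- matrix(exons, ncol = 2, byrow = TRUE)
  transcript_model(
    transcript_id = id, gene_id = paste0("g_", id), chrom = chrom,
    strand = strand, tx_start = min(exons[, 1]), tx_end = max(exons[, 2]),
    exons = exons,
    cds_start = if (is.null(cds)) NA_integer_ else cds[1],
    cds_end = if (is.null(cds)) NA_integer_ else cds[2],
    biotype = biotype)
}

# linear scan over all transcripts: ids overlapping [start, end]
linear_overlap_ids <- function(ts, chrom, start, end) {
  hits <- character(0)
  for (t in ts$transcripts) {
    if (t$chrom == chrom && t$tx_start <= end && t$tx_end >= start)
      hits <- c(hits, t$transcript_id)
  }
  sort(hits)
}

# per-base classification of position p against one transcript, written as
# plain scalar if/else logic
naive_base_label <- function(t, p, cfg) {
  w <- cfg$splice_window
  fl <- cfg$flank_window
  if (p < t$tx_start) {
    if (fl > 0 && t$tx_start - p <= fl)
      return(if (t$strand == "+") "upstream" else "downstream")
    return(NA_character_)
  }
  if (p > t$tx_end) {
    if (fl > 0 && p - t$tx_end <= fl)
      return(if (t$strand == "+") "downstream" else "upstream")
    return(NA_character_)
  }
  for (ei in seq_len(nrow(t$exons))) {
    if (p >= t$exons[ei, 1] && p <= t$exons[ei, 2]) {
      if (t$biotype == "noncoding") return("ncRNA_exonic")
      if (p >= t$cds_start && p <= t$cds_end) return("exonic_coding")
      if (p < t$cds_start)
        return(if (t$strand == "+") "UTR5" else "UTR3")
      return(if (t$strand == "+") "UTR3" else "UTR5")
    }
  }
  d <- Inf
  for (ei in seq_len(nrow(t$exons))) {
    if (p > t$exons[ei, 2]) d <- min(d, p - t$exons[ei, 2])
    if (p < t$exons[ei, 1]) d <- min(d, t$exons[ei, 1] - p)
  }
  if (d <= min(2, w)) return("splice_site")
  if (d <= w) return("splice_region")
  "intronic"
}

# most severe label over a REF interval, under the default precedence
naive_interval_label <- function(t, pos, ref, cfg) {
  ranks <- fine_term_ranks()
  best <- NA_integer_
  for (p in pos:(pos + nchar(ref) - 1L)) {
    lab <- naive_base_label(t, p, cfg)
    if (!is.na(lab) && (is.na(best) || ranks[[lab]] < best))
      best <- ranks[[lab]]
  }
  if (is.na(best)) NA_character_ else names(ranks)[best]
}

# independent suffix-then-prefix trimming of a single allele pair
naive_trim <- function(pos, ref, alt) {
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  while (length(r) > 1 && length(a) > 1 &&
         r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]; a <- a[-length(a)]
  }
  while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
    r <- r[-1]; a <- a[-1]; pos <- pos + 1
  }
  list(pos = pos, ref = paste(r, collapse = ""),
       alt = paste(a, collapse = ""))
}

# nested-loop per-category concordance tally
brute_concordance <- function(a, s, categories) {
  keys <- union(names(a), names(s))
  res <- list()
  for (cat in categories) {
    n_a <- 0L; n_s <- 0L; n_sh <- 0L
    for (k in keys) {
      ina <- !is.na(a[k]) && a[k] == cat
      ins <- !is.na(s[k]) && s[k] == cat
      if (ina) n_a <- n_a + 1L
      if (ins) n_s <- n_s + 1L
      if (ina && ins) n_sh <- n_sh + 1L
    }
    res[[cat]] <- c(n_A = n_a, n_S = n_s, n_shared = n_sh)
  }
  res
}

# write a VCF from raw body lines (header built for the given samples)
write_vcf_text <- function(body, samples = character(0),
                           path = tempfile(fileext = ".vcf")) {
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (length(samples)) cols <- c(cols, "FORMAT", samples)
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
               paste(cols, collapse = "\t"), body), path)
  path
}

# a small layout shared by several tests
small_layout <- function(seed = 11, n_transcripts = 12,
                         chrom_length = 3e5) {
  generate_layout(layout_config(chrom_length = chrom_length,
                                n_transcripts = n_transcripts,
                                seed = seed))
}

# random category assignment over n keys
random_assignment <- function(n, categories = broad_categories(),
                              prefix = "k") {
  stats::setNames(sample(categories, n, replace = TRUE),
                  paste0(prefix, seq_len(n)))
}
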