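#' Construct a transcript model
#'
#' A transcript model is the unit the annotator consults: one transcript with
#' its strand, exon structure, optional CDS bounds and biotype. All
#' coordinates are 1-based inclusive genomic positions, matching GFF3 and
#' VCF conventions.
#'
#' @param transcript_id,gene_id Identifier strings.
#' @param chrom Chromosome / contig name.
#' @param strand "+" or "-".
#' @param tx_start,tx_end Transcript span, 1-based inclusive.
#' @param exons Two-column matrix (start, end) of exons, 1-based inclusive;
#'   rows must be disjoint and sorted by start.
#' @param cds_start,cds_end Genomic CDS bounds (NA for non-coding).
#' @param biotype "coding" or "noncoding".
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand,
                             tx_start, tx_end, exons,
                             cds_start = NA_integer_, cds_end = NA_integer_,
                             biotype = c("coding", "noncoding")) {
  biotype <- match.arg(biotype)
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  t <- structure(list(
    transcript_id = as.character(transcript_id),
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    strand = strand,
    tx_start = as.integer(tx_start), tx_end = as.integer(tx_end),
    exons = exons,
    cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
    biotype = biotype), class = "transcript_model")
  validate_transcript_model(t)
  t
}

validate_transcript_model <- function(t) {
  id <- t$transcript_id
  if (!t$strand %in% c("+", "-"))
    stop("transcript ", id, ": strand must be '+' or '-'")
  if (t$tx_start > t$tx_end)
    stop("transcript ", id, ": tx_start > tx_end")
  ex <- t$exons
  if (nrow(ex) < 1L) stop("transcript ", id, ": no exons")
  if (any(ex[, 1] > ex[, 2]))
    stop("transcript ", id, ": exon start > end")
  if (any(ex[, 1] < t$tx_start) || any(ex[, 2] > t$tx_end))
    stop("transcript ", id, ": exon outside transcript span")
  if (nrow(ex) > 1L) {
    if (is.unsorted(ex[, 1], strictly = TRUE))
      stop("transcript ", id, ": exons not sorted by start")
    if (any(ex[-1L, 1] <= ex[-nrow(ex), 2]))
      stop("transcript ", id, ": overlapping exons")
  }
  if (t$biotype == "coding") {
    if (is.na(t$cds_start) || is.na(t$cds_end))
      stop("transcript ", id, ": coding transcript lacks CDS bounds")
    if (t$cds_start > t$cds_end)
      stop("transcript ", id, ": cds_start > cds_end")
    if (t$cds_start < min(ex[, 1]) || t$cds_end > max(ex[, 2]))
      stop("transcript ", id, ": CDS outside exon union span")
  } else if (!is.na(t$cds_start) || !is.na(t$cds_end)) {
    stop("transcript ", id, ": noncoding transcript carries CDS bounds")
  }
  invisible(t)
}

#' Construct a transcript set
#'
#' @param transcripts List of [transcript_model()] objects.
#' @param contig_lengths Named integer vector, chrom -> length (bp). Every
#'   transcript's chromosome must be present and contain its span.
#' @return An object of class `transcript_set`.
#' @export
transcript_set <- function(transcripts, contig_lengths) {
  ids <- vapply(transcripts, `[[`, "", "transcript_id")
  if (anyDuplicated(ids) > 0L)
    stop("duplicate transcript_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(transcripts) <- ids
  contig_lengths <- stats::setNames(as.numeric(contig_lengths),
                                    names(contig_lengths))
  for (t in transcripts) {
    len <- contig_lengths[t$chrom]
    if (is.na(len))
      stop("transcript ", t$transcript_id,
           ": no contig length for chromosome '", t$chrom, "'")
    if (t$tx_end > len)
      stop("transcript ", t$transcript_id, ": tx_end exceeds length of ",
           t$chrom)
  }
  structure(list(transcripts = transcripts,
                 contig_lengths = contig_lengths),
            class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat("transcript_set:", length(x$transcripts), "transcripts on",
      length(x$contig_lengths), "contigs\n")
  nc <- sum(vapply(x$transcripts, function(t) t$biotype == "coding", TRUE))
  cat("  coding:", nc, " noncoding:", length(x$transcripts) - nc, "\n")
  invisible(x)
}

#' @export
length.transcript_set <- function(x) length(x$transcripts)

# internal: read ##sequence-region pragmas (chrom, start, end) from a GFF3
gff3_sequence_regions <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  lens <- numeric(0)
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L || !startsWith(ln, "#")) break
    if (startsWith(ln, "##sequence-region")) {
      f <- strsplit(trimws(ln), "[ \t]+")[[1]]
      if (length(f) >= 4L) lens[f[2]] <- as.numeric(f[4])
    }
  }
  lens
}

#' Load transcript models from a GFF3 file
#'
#' Reads gene / mRNA (or transcript) / exon / CDS features linked by
#' ID/Parent attributes and assembles validated transcript models. A
#' transcript is coding iff it has at least one CDS feature; its CDS bounds
#' are the min/max over its CDS features. Contig lengths come from
#' `##sequence-region` pragmas or from a sidecar two-column TSV
#' (chrom, length).
#'
#' @param path GFF3 file path.
#' @param contig_lengths_path Optional TSV with columns chrom, length;
#'   overrides/extends the pragmas.
#' @return A [transcript_set()].
#' @export
load_gff3 <- function(path, contig_lengths_path = NULL) {
  check_gff3_lines(path)
  gr <- rtracklayer::import(path, format = "gff3")
  lens <- gff3_sequence_regions(path)
  if (!is.null(contig_lengths_path)) {
    sc <- utils::read.table(contig_lengths_path, sep = "\t", header = FALSE,
                            col.names = c("chrom", "length"),
                            stringsAsFactors = FALSE)
    lens[sc$chrom] <- sc$length
  }
  type <- as.character(gr$type)
  is_tx <- type %in% c("mRNA", "transcript")
  tx_gr <- gr[is_tx]
  parent1 <- function(g) {
    p <- g$Parent
    vapply(as.list(p), function(x) if (length(x)) x[[1]] else NA_character_, "")
  }
  child <- gr[type %in% c("exon", "CDS")]
  child_parent <- parent1(child)
  child_type <- as.character(child$type)
  tx_ids <- as.character(tx_gr$ID)
  tx_parent <- parent1(tx_gr)
  transcripts <- vector("list", length(tx_gr))
  for (i in seq_along(tx_gr)) {
    id <- tx_ids[i]
    sel <- !is.na(child_parent) & child_parent == id
    ex <- child[sel & child_type == "exon"]
    cds <- child[sel & child_type == "CDS"]
    if (length(ex) == 0L)
      stop("transcript ", id, ": no exon features")
    o <- order(GenomicRanges::start(ex))
    exons <- cbind(GenomicRanges::start(ex)[o], GenomicRanges::end(ex)[o])
    coding <- length(cds) > 0L
    transcripts[[i]] <- transcript_model(
      transcript_id = id,
      gene_id = if (is.na(tx_parent[i])) id else tx_parent[i],
      chrom = as.character(GenomicRanges::seqnames(tx_gr)[i]),
      strand = as.character(GenomicRanges::strand(tx_gr)[i]),
      tx_start = GenomicRanges::start(tx_gr)[i],
      tx_end = GenomicRanges::end(tx_gr)[i],
      exons = exons,
      cds_start = if (coding) min(GenomicRanges::start(cds)) else NA_integer_,
      cds_end = if (coding) max(GenomicRanges::end(cds)) else NA_integer_,
      biotype = if (coding) "coding" else "noncoding")
  }
  transcript_set(transcripts, lens)
}

# internal: cheap structural pre-check so malformed GFF3 lines are reported
# with their line number (the downstream parser's errors are file-level)
check_gff3_lines <- function(path) {
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- which(body)[nf != 9L]
  if (length(bad))
    stop("malformed GFF3 line ", bad[1], " in ", path,
         ": expected 9 tab-separated fields, found ", nf[match(bad[1], which(body))])
  invisible(TRUE)
}

#' Build an interval index over transcript spans
#'
#' @param ts A [transcript_set()].
#' @return An object of class `transcript_index` supporting
#'   [transcripts_overlapping()] and [flanking_transcripts()].
#' @export
build_index <- function(ts) {
  stopifnot(inherits(ts, "transcript_set"))
  n <- length(ts$transcripts)
  if (n == 0L) {
    gr <- GenomicRanges::GRanges()
  } else {
    chrom <- vapply(ts$transcripts, `[[`, "", "chrom")
    s <- vapply(ts$transcripts, `[[`, 0L, "tx_start")
    e <- vapply(ts$transcripts, `[[`, 0L, "tx_end")
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s, e))
    gr$transcript_id <- names(ts$transcripts)
  }
  structure(list(gr = gr, ts = ts), class = "transcript_index")
}

#' @export
print.transcript_index <- function(x, ...) {
  cat("transcript_index over", length(x$gr), "transcript spans\n")
  invisible(x)
}

#' Transcripts overlapping a genomic interval
#'
#' @param idx A [build_index()] result.
#' @param chrom Chromosome name; unknown chromosomes yield an empty result.
#' @param start,end 1-based inclusive query interval, start <= end.
#' @return List of `transcript_model`, ordered by transcript_id.
#' @export
transcripts_overlapping <- function(idx, chrom, start, end) {
  stopifnot(start <= end)
  if (length(idx$gr) == 0L) return(list())
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, idx$gr))
  ids <- sort(idx$gr$transcript_id[S4Vectors::subjectHits(hits)])
  unname(idx$ts$transcripts[ids])
}

#' Transcripts flanking (not overlapping) a position, strand-aware
#'
#' A transcript within `window` bp of `pos` but not overlapping it is an
#' upstream hit when `pos` lies 5' of the transcript (before tx_start on the
#' plus strand, after tx_end on the minus strand), and a downstream hit
#' otherwise. Distance is the positional offset: a transcript starting at
#' `pos + window` is still a hit, one at `pos + window + 1` is not.
#'
#' @param idx A [build_index()] result.
#' @param chrom Chromosome name.
#' @param pos 1-based position.
#' @param window Flank distance in bp, > 0.
#' @return List with elements `upstream` and `downstream`, each a list of
#'   `transcript_model` ordered by transcript_id.
#' @export
flanking_transcripts <- function(idx, chrom, pos, window) {
  stopifnot(window > 0)
  empty <- list(upstream = list(), downstream = list())
  if (length(idx$gr) == 0L) return(empty)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(q, idx$gr, maxgap = as.integer(window) - 1L))
  j <- S4Vectors::subjectHits(hits)
  s <- GenomicRanges::start(idx$gr)[j]
  e <- GenomicRanges::end(idx$gr)[j]
  keep <- pos < s | pos > e
  j <- j[keep]; s <- s[keep]; e <- e[keep]
  if (length(j) == 0L) return(empty)
  ids <- idx$gr$transcript_id[j]
  strand <- vapply(idx$ts$transcripts[ids], `[[`, "", "strand")
  # pos left of span: upstream for '+', downstream for '-'; right of span flips
  left <- pos < s
  up <- (left & strand == "+") | (!left & strand == "-")
  list(upstream = unname(idx$ts$transcripts[sort(ids[up])]),
       downstream = unname(idx$ts$transcripts[sort(ids[!up])]))
}
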