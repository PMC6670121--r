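#' Annotator configuration
#'
#' @param splice_window Intronic distance (bp) from an exon boundary within
#'   which a variant is called a splice-region variant; positions 1-2 into
#'   the intron are splice_site. Default 6, the broad splicing window used
#'   by gene-based annotators.
#' @param flank_window Distance (bp) beyond the transcript span within which
#'   a variant is upstream/downstream of the transcript. Default 1000.
#' @param style "precedence" reports the single most severe consequence per
#'   variant; "exhaustive" reports one call per affected transcript.
#' @param precedence Severity order (most severe first) over [fine_terms()].
#' @return An object of class `annotator_config`.
#' @export
annotator_config <- function(splice_window = 6L, flank_window = 1000L,
                             style = c("precedence", "exhaustive"),
                             precedence = fine_terms()) {
  style <- match.arg(style)
  stopifnot(splice_window >= 0, flank_window >= 0)
  structure(list(splice_window = as.integer(splice_window),
                 flank_window = as.integer(flank_window),
                 style = style,
                 ranks = fine_term_ranks(precedence)),
            class = "annotator_config")
}

#' @export
print.annotator_config <- function(x, ...) {
  cat("annotator_config: style =", x$style,
      " splice_window =", x$splice_window,
      " flank_window =", x$flank_window, "\n")
  invisible(x)
}

# internal: classify genomic positions relative to one transcript.
# Returns the severity rank at each position, or NA where the transcript
# implies no call (outside span and flank). Vectorized over positions.
label_positions_tx <- function(t, p, cfg) {
  ranks <- cfg$ranks
  out <- rep(NA_integer_, length(p))
  inside <- p >= t$tx_start & p <= t$tx_end
  left <- p < t$tx_start & (t$tx_start - p) <= cfg$flank_window
  right <- p > t$tx_end & (p - t$tx_end) <= cfg$flank_window
  if (cfg$flank_window > 0L) {
    if (t$strand == "+") {
      out[left] <- ranks[["upstream"]]
      out[right] <- ranks[["downstream"]]
    } else {
      out[left] <- ranks[["downstream"]]
      out[right] <- ranks[["upstream"]]
    }
  }
  if (any(inside)) {
    pi <- p[inside]
    starts <- t$exons[, 1]; ends <- t$exons[, 2]
    k <- findInterval(pi, starts)
    in_exon <- k >= 1L & pi <= ends[pmax(k, 1L)]
    r <- integer(length(pi))
    # exonic bases: CDS vs UTR (strand decides 5' vs 3') or ncRNA
    if (t$biotype == "coding") {
      in_cds <- in_exon & pi >= t$cds_start & pi <= t$cds_end
      before <- in_exon & pi < t$cds_start
      after <- in_exon & pi > t$cds_end
      r[in_cds] <- ranks[["exonic_coding"]]
      if (t$strand == "+") {
        r[before] <- ranks[["UTR5"]]; r[after] <- ranks[["UTR3"]]
      } else {
        r[before] <- ranks[["UTR3"]]; r[after] <- ranks[["UTR5"]]
      }
    } else {
      r[in_exon] <- ranks[["ncRNA_exonic"]]
    }
    # intronic bases: distance to the nearest exon boundary sets splice terms
    intr <- !in_exon
    if (any(intr)) {
      pin <- pi[intr]; kin <- k[intr]
      d_prev <- ifelse(kin >= 1L, pin - ends[pmax(kin, 1L)], Inf)
      d_next <- ifelse(kin < length(starts), starts[pmin(kin + 1L, length(starts))] - pin, Inf)
      d <- pmin(d_prev, d_next)
      ri <- rep(ranks[["intronic"]], length(pin))
      site_w <- min(2L, cfg$splice_window)
      ri[d <= cfg$splice_window] <- ranks[["splice_region"]]
      ri[d <= site_w] <- ranks[["splice_site"]]
      r[intr] <- ri
    }
    out[inside] <- r
  }
  out
}

# internal: terms from ranks under a config
rank_to_term <- function(rank, cfg) {
  names(cfg$ranks)[match(rank, cfg$ranks)]
}

#' Classify one variant against one transcript
#'
#' The affected interval is `[pos, pos + nchar(ref) - 1]` (an insertion sits
#' on its anchor base). Each base of the interval is classified relative to
#' the transcript -- coding exon, UTR (strand-aware), non-coding exon,
#' splice site (1-2 bp into an intron), splice region (within
#' `splice_window` bp of an exon boundary), intron, or strand-aware
#' upstream/downstream flank -- and the variant takes the most severe of the
#' touched regions.
#'
#' @param variant List or one-row data.frame with chrom, pos, ref, alt.
#' @param transcript A [transcript_model()].
#' @param cfg An [annotator_config()].
#' @return The fine consequence term, or NA_character_ when the transcript
#'   implies no call (wrong chromosome, or outside span and flank window).
#' @export
annotate_against_transcript <- function(variant, transcript,
                                        cfg = annotator_config()) {
  if (variant$chrom != transcript$chrom) return(NA_character_)
  p <- seq.int(variant$pos, variant$pos + nchar(variant$ref) - 1L)
  r <- label_positions_tx(transcript, p, cfg)
  if (all(is.na(r))) return(NA_character_)
  rank_to_term(min(r, na.rm = TRUE), cfg)
}

#' Annotate a set of variants against an indexed transcript set
#'
#' Produces the consequence-call table for every variant. In "exhaustive"
#' style each variant yields one call per transcript that classifies it
#' (including flanking transcripts), ordered by (impact rank,
#' transcript_id); a variant no transcript touches yields a single
#' intergenic call. In "precedence" style each variant yields exactly the
#' most severe of those calls, ties broken by transcript_id.
#'
#' @param variants A `variant_set` or a data.frame with chrom, pos, ref, alt.
#' @param idx A [build_index()] result.
#' @param cfg An [annotator_config()].
#' @return data.frame with columns variant_key, transcript_id (NA for
#'   intergenic), term, impact_rank.
#' @export
annotate_variants <- function(variants, idx, cfg = annotator_config()) {
  v <- if (inherits(variants, "variant_set")) variants$variants else variants
  n <- nrow(v)
  keys <- make_variant_key(v$chrom, v$pos, v$ref, v$alt)
  if (n == 0L) {
    return(data.frame(variant_key = character(0),
                      transcript_id = character(0),
                      term = character(0), impact_rank = integer(0),
                      stringsAsFactors = FALSE))
  }
  iv_end <- v$pos + nchar(v$ref) - 1L
  calls_i <- integer(0); calls_tx <- character(0); calls_r <- integer(0)
  if (length(idx$gr) > 0L) {
    q <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$pos, iv_end))
    maxgap <- if (cfg$flank_window > 0L) cfg$flank_window - 1L else -1L
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(q, idx$gr, maxgap = maxgap))
    qi <- S4Vectors::queryHits(hits); sj <- S4Vectors::subjectHits(hits)
    if (length(qi)) {
      by_tx <- split(qi, sj)
      for (jc in names(by_tx)) {
        j <- as.integer(jc)
        t <- idx$ts$transcripts[[idx$gr$transcript_id[j]]]
        vi <- by_tx[[jc]]
        w <- iv_end[vi] - v$pos[vi] + 1L
        p <- sequence(w, from = v$pos[vi])
        r <- label_positions_tx(t, p, cfg)
        grp <- rep(seq_along(vi), w)
        mins <- vapply(split(r, grp), function(z) {
          if (all(is.na(z))) NA_integer_ else min(z, na.rm = TRUE)
        }, 1L)
        ok <- !is.na(mins)
        calls_i <- c(calls_i, vi[ok])
        calls_tx <- c(calls_tx, rep(t$transcript_id, sum(ok)))
        calls_r <- c(calls_r, mins[ok])
      }
    }
  }
  # variants with no transcript-implied call are intergenic
  miss <- setdiff(seq_len(n), unique(calls_i))
  if (length(miss)) {
    calls_i <- c(calls_i, miss)
    calls_tx <- c(calls_tx, rep(NA_character_, length(miss)))
    calls_r <- c(calls_r, rep(cfg$ranks[["intergenic"]], length(miss)))
  }
  o <- order(calls_i, calls_r, calls_tx, method = "radix")
  out <- data.frame(variant_key = keys[calls_i[o]],
                    transcript_id = calls_tx[o],
                    term = rank_to_term(calls_r[o], cfg),
                    impact_rank = calls_r[o],
                    stringsAsFactors = FALSE)
  if (cfg$style == "precedence") {
    first <- !duplicated(calls_i[o])
    out <- out[first, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' All consequence calls for a single variant
#'
#' Convenience wrapper over [annotate_variants()] for one variant in
#' exhaustive style.
#'
#' @inheritParams annotate_against_transcript
#' @param idx A [build_index()] result.
#' @return data.frame of calls ordered by (impact_rank, transcript_id).
#' @export
annotate_exhaustive <- function(variant, idx, cfg = annotator_config()) {
  cfg$style <- "exhaustive"
  annotate_variants(as.data.frame(variant, stringsAsFactors = FALSE),
                    idx, cfg)
}

#' Collapse a call list to the single most severe call
#'
#' Keeps the call with minimal impact rank for one variant; ties are broken
#' by ascending transcript_id. All calls must belong to the same variant
#' key.
#'
#' @param calls data.frame as produced by [annotate_variants()] (columns
#'   variant_key, transcript_id, term, impact_rank), non-empty, one key.
#' @return One-row data.frame.
#' @export
collapse_most_severe <- function(calls) {
  stopifnot(nrow(calls) >= 1L)
  if (length(unique(calls$variant_key)) != 1L)
    stop("collapse_most_severe expects calls for a single variant_key")
  o <- order(calls$impact_rank, calls$transcript_id, method = "radix")
  out <- calls[o[1L], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-base consequence track over a whole genome
#'
#' Labels every base of every contig with the most severe fine consequence
#' any transcript implies there, by painting region intervals: flanks,
#' introns, splice regions/sites, UTR/CDS exon parts. This is a second,
#' independent route to the precedence-style classification -- the annotator
#' classifies positions, the track paints intervals -- and is used both as a
#' brute-force cross-check and by the synthetic-data generator to pre-compute
#' eligible placement intervals per category.
#'
#' @param ts A [transcript_set()].
#' @param cfg An [annotator_config()].
#' @return Named list, one integer vector of severity ranks per contig
#'   (length = contig length); intergenic bases carry the intergenic rank.
#' @export
label_genome <- function(ts, cfg = annotator_config()) {
  ranks <- cfg$ranks
  tracks <- lapply(ts$contig_lengths, function(len)
    rep(ranks[["intergenic"]], len))
  paint <- function(chrom, s, e, r) {
    s <- max(1L, s); e <- min(length(tracks[[chrom]]), e)
    if (s > e) return()
    seg <- s:e
    tracks[[chrom]][seg] <<- pmin(tracks[[chrom]][seg], r)
  }
  w <- cfg$splice_window
  w_site <- min(2L, w)
  fl <- cfg$flank_window
  for (t in ts$transcripts) {
    ch <- t$chrom
    if (fl > 0L) {
      r_left <- if (t$strand == "+") ranks[["upstream"]] else ranks[["downstream"]]
      r_right <- if (t$strand == "+") ranks[["downstream"]] else ranks[["upstream"]]
      paint(ch, t$tx_start - fl, t$tx_start - 1L, r_left)
      paint(ch, t$tx_end + 1L, t$tx_end + fl, r_right)
    }
    ex <- t$exons
    ne <- nrow(ex)
    # non-exon bases inside the span: introns between consecutive exons plus
    # any gap between the span edge and the terminal exons
    gaps <- rbind(
      if (t$tx_start < ex[1, 1]) c(t$tx_start, ex[1, 1] - 1L, NA, ex[1, 1]),
      if (ne > 1L) cbind(ex[-ne, 2] + 1L, ex[-1L, 1] - 1L,
                         ex[-ne, 2], ex[-1L, 1]),
      if (t$tx_end > ex[ne, 2]) c(ex[ne, 2] + 1L, t$tx_end, ex[ne, 2], NA))
    if (!is.null(gaps) && nrow(gaps)) for (gi in seq_len(nrow(gaps))) {
      gs <- gaps[gi, 1]; ge <- gaps[gi, 2]
      if (gs > ge) next
      paint(ch, gs, ge, ranks[["intronic"]])
      prev_end <- gaps[gi, 3]; next_start <- gaps[gi, 4]
      if (w > 0L) {
        if (!is.na(prev_end)) {
          paint(ch, gs, min(prev_end + w, ge), ranks[["splice_region"]])
          if (w_site > 0L)
            paint(ch, gs, min(prev_end + w_site, ge), ranks[["splice_site"]])
        }
        if (!is.na(next_start)) {
          paint(ch, max(next_start - w, gs), ge, ranks[["splice_region"]])
          if (w_site > 0L)
            paint(ch, max(next_start - w_site, gs), ge, ranks[["splice_site"]])
        }
      }
    }
    for (ei in seq_len(ne)) {
      es <- ex[ei, 1]; ee <- ex[ei, 2]
      if (t$biotype == "noncoding") {
        paint(ch, es, ee, ranks[["ncRNA_exonic"]])
      } else {
        r5 <- if (t$strand == "+") ranks[["UTR5"]] else ranks[["UTR3"]]
        r3 <- if (t$strand == "+") ranks[["UTR3"]] else ranks[["UTR5"]]
        if (es < t$cds_start) paint(ch, es, min(ee, t$cds_start - 1L), r5)
        if (ee > t$cds_end) paint(ch, max(es, t$cds_end + 1L), ee, r3)
        cs <- max(es, t$cds_start); ce <- min(ee, t$cds_end)
        if (cs <= ce) paint(ch, cs, ce, ranks[["exonic_coding"]])
      }
    }
  }
  tracks
}

#' Precedence-style classification of variants from a per-base track
#'
#' Looks up the most severe rank over each variant's REF interval in a
#' [label_genome()] track. Serves as the brute-force counterpart of
#' precedence-style [annotate_variants()].
#'
#' @param variants data.frame with chrom, pos, ref (or a `variant_set`).
#' @param tracks A [label_genome()] result.
#' @param cfg The [annotator_config()] the track was built with.
#' @return Character vector of fine terms.
#' @export
classify_from_track <- function(variants, tracks, cfg = annotator_config()) {
  v <- if (inherits(variants, "variant_set")) variants$variants else variants
  n <- nrow(v)
  out <- character(n)
  iv_end <- v$pos + nchar(v$ref) - 1L
  for (i in seq_len(n)) {
    tr <- tracks[[v$chrom[i]]]
    seg <- v$pos[i]:min(iv_end[i], length(tr))
    out[i] <- rank_to_term(min(tr[seg]), cfg)
  }
  out
}
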