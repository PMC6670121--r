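#' Subset a multi-sample VCF to a population
#'
#' Keeps only the requested sample columns and only the sites where at least
#' one retained genotype carries a non-missing ALT allele -- sites that are
#' all-REF (or all-missing) in the retained samples are dropped. AC, AN and
#' AF are recomputed over the retained samples (half-missing genotypes
#' contribute their observed allele); the INFO field is replaced with the
#' recomputed values and FORMAT is reduced to GT.
#'
#' @param x A `vcf_data` from [read_vcf()].
#' @param sample_ids Character vector of sample IDs to retain (non-empty,
#'   all present in the VCF header).
#' @return A `vcf_data` over the retained samples and kept sites, with
#'   attribute `n_sites_dropped`.
#' @export
subset_population <- function(x, sample_ids) {
  stopifnot(inherits(x, "vcf_data"))
  if (length(sample_ids) == 0L) stop("sample_ids must be non-empty")
  missing <- setdiff(sample_ids, x$samples)
  if (length(missing))
    stop("sample id(s) not in VCF header: ", paste(missing, collapse = ", "))
  gt <- x$gt[, sample_ids, drop = FALSE]
  gp <- parse_gt(gt)
  nalt <- lengths(strsplit(x$alt, ",", fixed = TRUE))
  has_alt <- function(m) !is.na(m) & m >= 1L
  keep <- rowSums(has_alt(gp$a)) + rowSums(has_alt(gp$b)) > 0
  keep[is.na(keep)] <- FALSE
  an <- rowSums(!is.na(gp$a)) + rowSums(!is.na(gp$b))
  # per-ALT allele counts, comma-joined in the original ALT order
  ac_str <- vapply(seq_along(x$pos), function(i) {
    if (!keep[i]) return(NA_character_)
    ks <- seq_len(nalt[i])
    ac <- vapply(ks, function(k)
      sum(gp$a[i, ] == k, na.rm = TRUE) + sum(gp$b[i, ] == k, na.rm = TRUE),
      0L)
    paste(ac, collapse = ",")
  }, "")
  af_str <- vapply(seq_along(x$pos), function(i) {
    if (!keep[i] || an[i] == 0) return(NA_character_)
    paste(signif(as.numeric(strsplit(ac_str[i], ",")[[1]]) / an[i], 6),
          collapse = ",")
  }, "")
  idx <- which(keep)
  gt_sub <- sub(":.*", "", gt[idx, , drop = FALSE])
  dim(gt_sub) <- c(length(idx), length(sample_ids))
  colnames(gt_sub) <- sample_ids
  structure(list(
    samples = sample_ids,
    chrom = x$chrom[idx], pos = x$pos[idx], id = x$id[idx],
    ref = x$ref[idx], alt = x$alt[idx], qual = x$qual[idx],
    filter = x$filter[idx],
    info = paste0("AC=", ac_str[idx], ";AN=", an[idx],
                  ifelse(is.na(af_str[idx]), "",
                         paste0(";AF=", af_str[idx]))),
    format = rep("GT", length(idx)),
    gt = gt_sub), class = "vcf_data",
    n_sites_dropped = sum(!keep))
}

#' Summary statistics over a normalized variant set
#'
#' Counts per-allele variants by type and the transition/transversion ratio
#' over SNVs. MNP and "other" alleles are counted but excluded from Ts/Tv.
#'
#' @param vs A normalized `variant_set` (or a data.frame with chrom, pos,
#'   ref, alt, vtype).
#' @return Object of class `variant_summary`: `n_sites` (distinct
#'   chrom:pos), `n_variants`, `n_snv`, `n_insertion`, `n_deletion`,
#'   `n_mnp`, `n_other`, `ts`, `tv`, `tstv` (NA when tv = 0).
#' @export
summarize_variants <- function(vs) {
  v <- if (inherits(vs, "variant_set")) vs$variants else vs
  snv <- v$vtype == "SNV"
  ts <- if (any(snv)) sum(is_transition(v$ref[snv], v$alt[snv])) else 0L
  tv <- sum(snv) - ts
  structure(list(
    n_sites = length(unique(paste(v$chrom, v$pos))),
    n_variants = nrow(v),
    n_snv = sum(snv),
    n_insertion = sum(v$vtype == "insertion"),
    n_deletion = sum(v$vtype == "deletion"),
    n_mnp = sum(v$vtype == "MNP"),
    n_other = sum(v$vtype == "other"),
    ts = ts, tv = tv,
    tstv = if (tv > 0) ts / tv else NA_real_),
    class = "variant_summary")
}

#' @export
print.variant_summary <- function(x, ...) {
  cat("sites:", x$n_sites, " variants:", x$n_variants, "\n")
  cat("SNV:", x$n_snv, " ins:", x$n_insertion, " del:", x$n_deletion,
      " MNP:", x$n_mnp, " other:", x$n_other, "\n")
  cat("Ts:", x$ts, " Tv:", x$tv, " Ts/Tv:",
      if (is.na(x$tstv)) "NA" else sprintf("%.4f", x$tstv), "\n")
  invisible(x)
}

#' @export
as.data.frame.variant_summary <- function(x, ...) {
  data.frame(statistic = names(unclass(x)),
             value = unlist(unclass(x), use.names = FALSE))
}

#' Variant density in fixed genomic bins
#'
#' Bin b (0-based index) covers positions `[b * bin_size + 1,
#' (b + 1) * bin_size]`. Empty bins are omitted from the result; reports can
#' render them as zero when contig lengths are known.
#'
#' @param vs A `variant_set` or data.frame with chrom, pos.
#' @param bin_size Bin width in bp (default 1 Mb).
#' @return data.frame of class `density_track` with columns chrom,
#'   bin_index, bin_start, bin_end, count; `bin_size` stored as an
#'   attribute.
#' @export
snp_density <- function(vs, bin_size = 1e6) {
  stopifnot(bin_size > 0)
  v <- if (inherits(vs, "variant_set")) vs$variants else vs
  bin <- (v$pos - 1) %/% bin_size
  agg <- stats::aggregate(list(count = rep(1L, nrow(v))),
                          by = list(chrom = v$chrom, bin_index = bin),
                          FUN = sum)
  agg <- agg[order(agg$chrom, agg$bin_index), , drop = FALSE]
  agg$bin_start <- agg$bin_index * bin_size + 1
  agg$bin_end <- (agg$bin_index + 1) * bin_size
  agg <- agg[, c("chrom", "bin_index", "bin_start", "bin_end", "count")]
  rownames(agg) <- NULL
  structure(agg, class = c("density_track", "data.frame"),
            bin_size = bin_size)
}

#' Render a density track with empty bins as zero
#'
#' @param track A [snp_density()] result.
#' @param contig_lengths Named vector of contig lengths; every bin up to the
#'   contig end is emitted.
#' @return data.frame with all bins, zeros included.
#' @export
density_report <- function(track, contig_lengths) {
  bin_size <- attr(track, "bin_size")
  out <- do.call(rbind, lapply(names(contig_lengths), function(ch) {
    nb <- ceiling(contig_lengths[[ch]] / bin_size)
    data.frame(chrom = ch, bin_index = seq_len(nb) - 1L,
               stringsAsFactors = FALSE)
  }))
  out$bin_start <- out$bin_index * bin_size + 1
  out$bin_end <- pmin((out$bin_index + 1) * bin_size,
                      contig_lengths[out$chrom])
  m <- match(paste(out$chrom, out$bin_index),
             paste(track$chrom, track$bin_index))
  out$count <- ifelse(is.na(m), 0L, track$count[m])
  out
}

#' Flag variants by membership in known-sites databases
#'
#' For each known-sites VCF, a variant is flagged iff its normalized
#' variant key (chrom:pos:ref:alt) occurs in that file -- matching is
#' allele-aware by default. Position-only matching (the convention of some
#' filter databases) is available via `allele_aware = FALSE`.
#'
#' @param vs A normalized `variant_set`.
#' @param known_paths Named character vector of known-sites VCF paths
#'   (names become flag columns; unnamed paths use the file name).
#' @param allele_aware Match on chrom:pos:ref:alt (default) or chrom:pos.
#' @return data.frame: variant_key plus one logical column per source.
#' @export
known_sites_annotate <- function(vs, known_paths, allele_aware = TRUE) {
  v <- if (inherits(vs, "variant_set")) vs$variants else vs
  nm <- names(known_paths)
  if (is.null(nm)) nm <- rep("", length(known_paths))
  nm[nm == ""] <- tools::file_path_sans_ext(basename(known_paths[nm == ""]))
  keys <- if (allele_aware) make_variant_key(v$chrom, v$pos, v$ref, v$alt)
          else paste(v$chrom, v$pos, sep = ":")
  out <- data.frame(variant_key = make_variant_key(v$chrom, v$pos,
                                                   v$ref, v$alt),
                    stringsAsFactors = FALSE)
  for (i in seq_along(known_paths)) {
    kv <- tryCatch(read_vcf(known_paths[[i]]),
                   error = function(e) stop("cannot read known-sites file ",
                                            known_paths[[i]], ": ",
                                            conditionMessage(e)))
    ks <- suppressWarnings(normalize_variants(split_multiallelic(kv)))
    kk <- if (allele_aware) variant_key(ks)
          else paste(ks$variants$chrom, ks$variants$pos, sep = ":")
    out[[nm[i]]] <- keys %in% kk
  }
  out
}
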