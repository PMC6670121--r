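#' Synthetic genome layout configuration
#'
#' Describes the small synthetic genome and transcript set the generator
#' emits. Defaults are the package's standard test-bed: 2 contigs of 5 Mb
#' carrying 50 transcripts, 70% of them coding, with a fraction of
#' transcript pairs deliberately overlapping so precedence collapse is
#' exercised.
#'
#' @param n_chroms Number of contigs.
#' @param chrom_length Length of each contig (bp).
#' @param n_transcripts Number of transcripts.
#' @param exons_per_transcript Integer range (min, max) of exons per
#'   transcript.
#' @param coding_fraction Proportion of transcripts given a CDS.
#' @param strand_prob Probability of the plus strand.
#' @param overlap_prob Probability a transcript is placed overlapping an
#'   earlier one on the same contig.
#' @param exon_length_range,intron_length_range Integer ranges (bp).
#' @param seed Integer seed; identical configs yield byte-identical output.
#' @return Object of class `layout_config`.
#' @export
layout_config <- function(n_chroms = 2L, chrom_length = 5e6,
                          n_transcripts = 50L,
                          exons_per_transcript = c(2L, 8L),
                          coding_fraction = 0.7, strand_prob = 0.5,
                          overlap_prob = 0.15,
                          exon_length_range = c(80L, 300L),
                          intron_length_range = c(50L, 2000L),
                          seed = 1L) {
  cfg <- list(n_chroms = as.integer(n_chroms),
              chrom_length = as.numeric(chrom_length),
              n_transcripts = as.integer(n_transcripts),
              exons_per_transcript = as.integer(exons_per_transcript),
              coding_fraction = coding_fraction,
              strand_prob = strand_prob, overlap_prob = overlap_prob,
              exon_length_range = as.integer(exon_length_range),
              intron_length_range = as.integer(intron_length_range),
              seed = as.integer(seed))
  stopifnot(cfg$n_chroms >= 1L, cfg$n_transcripts >= 1L,
            cfg$exons_per_transcript[1] >= 1L,
            diff(cfg$exons_per_transcript) >= 0L,
            cfg$coding_fraction >= 0, cfg$coding_fraction <= 1)
  max_span <- cfg$exons_per_transcript[2] * cfg$exon_length_range[2] +
    (cfg$exons_per_transcript[2] - 1L) * cfg$intron_length_range[2]
  if (cfg$chrom_length < max_span + 2L)
    stop("infeasible layout: chrom_length ", cfg$chrom_length,
         " cannot hold a transcript of up to ", max_span, " bp")
  structure(cfg, class = "layout_config")
}

#' Generate a synthetic transcript layout
#'
#' Draws transcripts with valid exon/CDS structure on the configured
#' contigs. Coding transcripts carry genomic CDS bounds strictly inside
#' their terminal exons, so UTR bases exist on both sides.
#'
#' @param cfg A [layout_config()].
#' @return A [transcript_set()].
#' @export
generate_layout <- function(cfg = layout_config()) {
  stopifnot(inherits(cfg, "layout_config"))
  set.seed(cfg$seed)
  chroms <- sprintf("chrS%d", seq_len(cfg$n_chroms))
  lens <- stats::setNames(rep(cfg$chrom_length, cfg$n_chroms), chroms)
  transcripts <- vector("list", cfg$n_transcripts)
  placed <- data.frame(chrom = character(0), tx_start = integer(0))
  for (i in seq_len(cfg$n_transcripts)) {
    n_ex <- sample(cfg$exons_per_transcript[1]:cfg$exons_per_transcript[2], 1L)
    ex_len <- sample(cfg$exon_length_range[1]:cfg$exon_length_range[2],
                     n_ex, replace = TRUE)
    in_len <- if (n_ex > 1L)
      sample(cfg$intron_length_range[1]:cfg$intron_length_range[2],
             n_ex - 1L, replace = TRUE) else integer(0)
    span <- sum(ex_len) + sum(in_len)
    same_chrom <- placed$chrom
    if (nrow(placed) > 0L && stats::runif(1) < cfg$overlap_prob) {
      anchor <- placed[sample(nrow(placed), 1L), ]
      chrom <- anchor$chrom
      start <- anchor$tx_start + sample(-2000:2000, 1L)
    } else {
      chrom <- sample(chroms, 1L)
      start <- sample.int(as.integer(cfg$chrom_length) - span - 1L, 1L)
    }
    start <- max(1L, min(start, as.integer(cfg$chrom_length) - span))
    offs <- cumsum(c(0L, as.integer(rbind(ex_len, c(in_len, 0L))[
      seq_len(2L * n_ex - 1L)])))
    ex_start <- start + offs[seq(1L, by = 2L, length.out = n_ex)]
    ex_end <- ex_start + ex_len - 1L
    coding <- stats::runif(1) < cfg$coding_fraction
    if (coding) {
      c1 <- ex_start[1] + sample.int(ex_len[1] - 2L, 1L)
      c2 <- ex_end[n_ex] - sample.int(ex_len[n_ex] - 2L, 1L)
      if (n_ex == 1L && c1 > c2) { tmp <- c1; c1 <- c2; c2 <- tmp }
      cds_start <- c1; cds_end <- c2
    } else {
      cds_start <- NA_integer_; cds_end <- NA_integer_
    }
    transcripts[[i]] <- transcript_model(
      transcript_id = sprintf("TX%04d", i),
      gene_id = sprintf("G%04d", i),
      chrom = chrom,
      strand = if (stats::runif(1) < cfg$strand_prob) "+" else "-",
      tx_start = start, tx_end = start + span - 1L,
      exons = cbind(ex_start, ex_end),
      cds_start = cds_start, cds_end = cds_end,
      biotype = if (coding) "coding" else "noncoding")
    placed <- rbind(placed,
                    data.frame(chrom = chrom, tx_start = start,
                               stringsAsFactors = FALSE))
  }
  transcript_set(transcripts, lens)
}

#' Write a transcript set as GFF3
#'
#' Emits `##sequence-region` pragmas and gene/mRNA/exon/CDS features linked
#' by ID/Parent, loadable by [load_gff3()]. Output is deterministic.
#'
#' @param ts A [transcript_set()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gff3 <- function(ts, path) {
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d",
                     names(ts$contig_lengths),
                     as.integer(ts$contig_lengths)))
  row <- function(chrom, type, s, e, strand, attrs)
    paste(chrom, "varconcord", type, s, e, ".", strand, ".", attrs,
          sep = "\t")
  for (t in ts$transcripts) {
    lines <- c(lines,
      row(t$chrom, "gene", t$tx_start, t$tx_end, t$strand,
          sprintf("ID=%s", t$gene_id)),
      row(t$chrom, "mRNA", t$tx_start, t$tx_end, t$strand,
          sprintf("ID=%s;Parent=%s", t$transcript_id, t$gene_id)))
    for (ei in seq_len(nrow(t$exons)))
      lines <- c(lines,
        row(t$chrom, "exon", t$exons[ei, 1], t$exons[ei, 2], t$strand,
            sprintf("ID=%s.e%d;Parent=%s", t$transcript_id, ei,
                    t$transcript_id)))
    if (t$biotype == "coding") {
      # CDS features: exon pieces intersected with the genomic CDS bounds
      for (ei in seq_len(nrow(t$exons))) {
        cs <- max(t$exons[ei, 1], t$cds_start)
        ce <- min(t$exons[ei, 2], t$cds_end)
        if (cs <= ce)
          lines <- c(lines,
            row(t$chrom, "CDS", cs, ce, t$strand,
                sprintf("ID=%s.c%d;Parent=%s", t$transcript_id, ei,
                        t$transcript_id)))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Synthetic variant-pool configuration
#'
#' Describes the variant pool drawn over a layout: how many variants, how
#' they distribute over broad annotation categories, the SNV fraction and
#' target Ts/Tv, the number of diploid samples, the allele-frequency
#' distribution and the fraction of variants planted in the known-sites
#' database. Defaults emulate a population-scale short-variant call set at
#' desk scale: 20,000 variants over 96 samples, 90% SNVs at Ts/Tv 2.0,
#' mostly intronic/intergenic with a small exonic/UTR/splice fraction, and
#' a low-frequency-skewed Beta allele-frequency spectrum.
#'
#' @param n_variants Number of (biallelic) variants.
#' @param category_mix Named proportions over [broad_categories()], sum 1.
#' @param snv_fraction Proportion of SNVs; the rest split evenly between
#'   insertions and deletions (lengths 1-4 bp).
#' @param target_tstv Expected transition/transversion ratio of SNVs.
#' @param n_samples Number of diploid samples.
#' @param af_dist Allele-frequency distribution: `list(kind = "beta",
#'   shape1, shape2)` or `list(kind = "uniform", min, max)`.
#' @param known_site_rate Probability a variant is planted in the
#'   known-sites set.
#' @param seed Integer seed.
#' @return Object of class `variant_config`.
#' @export
variant_config <- function(n_variants = 20000L,
                           category_mix = c(exonic = 0.05, splicing = 0.01,
                                            ncRNA_exonic = 0.02,
                                            UTR5 = 0.01, UTR3 = 0.02,
                                            intronic = 0.45,
                                            upstream = 0.06,
                                            downstream = 0.06,
                                            intergenic = 0.32),
                           snv_fraction = 0.9, target_tstv = 2.0,
                           n_samples = 96L,
                           af_dist = list(kind = "beta", shape1 = 0.3,
                                          shape2 = 3),
                           known_site_rate = 0.3, seed = 1L) {
  stopifnot(all(names(category_mix) %in% broad_categories()),
            all(category_mix >= 0), all(category_mix <= 1),
            abs(sum(category_mix) - 1) < 1e-9,
            snv_fraction >= 0, snv_fraction <= 1,
            target_tstv > 0, n_samples >= 0,
            known_site_rate >= 0, known_site_rate <= 1)
  structure(list(n_variants = as.integer(n_variants),
                 category_mix = category_mix,
                 snv_fraction = snv_fraction, target_tstv = target_tstv,
                 n_samples = as.integer(n_samples), af_dist = af_dist,
                 known_site_rate = known_site_rate,
                 seed = as.integer(seed)),
            class = "variant_config")
}

BASES <- c("A", "C", "G", "T")
TRANSITION_OF <- c(A = "G", G = "A", C = "T", T = "C")

draw_af <- function(n, d) {
  switch(d$kind,
         beta = stats::rbeta(n, d$shape1, d$shape2),
         uniform = stats::runif(n, d$min, d$max),
         stop("unknown af_dist kind: ", d$kind))
}

#' Generate a synthetic variant pool with planted ground truth
#'
#' Places variants by sampling positions from pre-computed per-category
#' eligible intervals (the per-base consequence track of the layout under
#' the default annotator configuration), so each variant's planted broad
#' category is guaranteed by construction rather than by post-hoc labeling.
#' Deletion REF intervals are constrained to lie within a single-category
#' run. SNV alternate alleles are drawn to hit the target Ts/Tv in
#' expectation; diploid genotypes are drawn per sample from the site's
#' allele frequency (every site is guaranteed at least one ALT allele, as
#' in a population call set that only reports segregating sites).
#'
#' @param layout A [transcript_set()] (typically from [generate_layout()]).
#' @param cfg A [variant_config()].
#' @param annot_cfg The [annotator_config()] defining the planted truth.
#' @return List: `vs` (a normalized `variant_set` with genotypes) and
#'   `truth` (data.frame: variant_key, planted_category, planted_known).
#' @export
generate_variants <- function(layout, cfg = variant_config(),
                              annot_cfg = annotator_config()) {
  stopifnot(inherits(layout, "transcript_set"),
            inherits(cfg, "variant_config"))
  set.seed(cfg$seed)
  map <- default_harmonization_map()
  rank_broad <- unname(map[names(annot_cfg$ranks)])  # rank -> broad
  tracks <- label_genome(layout, annot_cfg)
  broad_tracks <- lapply(tracks, function(tr) rank_broad[tr])
  chroms <- names(layout$contig_lengths)
  # integer category counts: floor plus largest-remainder distribution
  mix <- cfg$category_mix[cfg$category_mix > 0]
  raw <- mix * cfg$n_variants
  cnt <- floor(raw)
  rem <- cfg$n_variants - sum(cnt)
  if (rem > 0) {
    o <- order(raw - cnt, decreasing = TRUE)
    cnt[o[seq_len(rem)]] <- cnt[o[seq_len(rem)]] + 1
  }
  used <- lapply(layout$contig_lengths, function(len) logical(len))
  nv <- cfg$n_variants
  res_chrom <- character(nv); res_pos <- integer(nv)
  res_ref <- character(nv); res_alt <- character(nv)
  res_cat <- character(nv)
  out_i <- 0L
  ts_p <- cfg$target_tstv / (1 + cfg$target_tstv)
  for (cat in names(cnt)) {
    m <- as.integer(cnt[[cat]])
    if (m == 0L) next
    elig_pos <- lapply(broad_tracks, function(bt) which(bt == cat))
    n_elig <- sum(lengths(elig_pos))
    if (n_elig == 0L)
      stop("category '", cat, "' has proportion > 0 but no eligible ",
           "positions in the layout")
    if (n_elig < m)
      stop("category '", cat, "' has only ", n_elig,
           " eligible positions for ", m, " requested variants")
    elig_chrom <- rep(seq_along(chroms), lengths(elig_pos))
    elig_pos <- unlist(elig_pos, use.names = FALSE)
    pick <- sample.int(n_elig, m)
    kind <- ifelse(stats::runif(m) < cfg$snv_fraction, "SNV",
                   ifelse(stats::runif(m) < 0.5, "insertion", "deletion"))
    for (vi in seq_len(m)) {
      ci <- elig_chrom[pick[vi]]; p <- elig_pos[pick[vi]]
      del_len <- if (kind[vi] == "deletion") sample.int(4L, 1L) else 0L
      tries <- 0L
      repeat {
        bt <- broad_tracks[[ci]]
        ok <- !used[[chroms[ci]]][p] &&
          (del_len == 0L ||
             (p + del_len <= length(bt) &&
                all(bt[p:(p + del_len)] == cat) &&
                !any(used[[chroms[ci]]][p:(p + del_len)])))
        if (ok) break
        tries <- tries + 1L
        if (tries > 200L)
          stop("cannot place a ", kind[vi], " variant in category '",
               cat, "'")
        j <- sample.int(n_elig, 1L)
        ci <- elig_chrom[j]; p <- elig_pos[j]
      }
      span <- p:(p + del_len)
      used[[chroms[ci]]][span] <- TRUE
      if (kind[vi] == "SNV") {
        ref <- sample(BASES, 1L)
        alt <- if (stats::runif(1) < ts_p) TRANSITION_OF[[ref]]
               else sample(setdiff(BASES, c(ref, TRANSITION_OF[[ref]])), 1L)
      } else if (kind[vi] == "insertion") {
        ins_len <- sample.int(4L, 1L)
        ref <- sample(BASES, 1L)
        alt <- paste0(ref, paste(sample(BASES, ins_len, replace = TRUE),
                                 collapse = ""))
      } else {
        ref <- paste(sample(BASES, del_len + 1L, replace = TRUE),
                     collapse = "")
        alt <- substr(ref, 1L, 1L)
      }
      out_i <- out_i + 1L
      res_chrom[out_i] <- chroms[ci]; res_pos[out_i] <- p
      res_ref[out_i] <- ref; res_alt[out_i] <- alt
      res_cat[out_i] <- cat
    }
  }
  length(res_chrom) <- out_i; length(res_pos) <- out_i
  length(res_ref) <- out_i; length(res_alt) <- out_i
  length(res_cat) <- out_i
  o <- order(res_chrom, res_pos, method = "radix")
  n <- length(o)
  v <- data.frame(chrom = res_chrom[o], pos = res_pos[o],
                  ref = res_ref[o], alt = res_alt[o],
                  vtype = classify_type(res_ref[o], res_alt[o]),
                  src_site = seq_len(n), alt_index = 1L,
                  stringsAsFactors = FALSE)
  ns <- cfg$n_samples
  samples <- sprintf("S%03d", seq_len(ns))
  af <- draw_af(n, cfg$af_dist)
  gt_a <- matrix(stats::rbinom(n * ns, 1L, rep(af, ns)), nrow = n,
                 dimnames = list(NULL, samples))
  gt_b <- matrix(stats::rbinom(n * ns, 1L, rep(af, ns)), nrow = n,
                 dimnames = list(NULL, samples))
  if (ns > 0L) {
    mono <- which(rowSums(gt_a) + rowSums(gt_b) == 0L)
    if (length(mono))
      gt_a[cbind(mono, sample.int(ns, length(mono), replace = TRUE))] <- 1L
  }
  known <- stats::runif(n) < cfg$known_site_rate
  vs <- structure(list(variants = v,
                       gt_a = gt_a, gt_b = gt_b,
                       phased = matrix(FALSE, n, ns,
                                       dimnames = list(NULL, samples)),
                       samples = samples,
                       n_symbolic_skipped = 0L, n_source_sites = n),
                  class = "variant_set")
  truth <- data.frame(variant_key = variant_key(vs),
                      planted_category = res_cat[o],
                      planted_known = known,
                      stringsAsFactors = FALSE)
  list(vs = vs, truth = truth)
}

#' Write a complete synthetic fixture bundle
#'
#' Generates a layout and a variant pool and writes: `transcripts.gff3`,
#' `variants.vcf`, `truth.tsv`, `known_sites.vcf` (the variants planted as
#' known, sites-only), and `config.json` (the echoed configuration,
#' including seeds).
#'
#' @param dir Output directory (created if absent).
#' @param layout_cfg A [layout_config()].
#' @param var_cfg A [variant_config()].
#' @return Named character vector of the written paths, invisibly.
#' @export
generate_fixtures <- function(dir, layout_cfg = layout_config(),
                              var_cfg = variant_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ts <- generate_layout(layout_cfg)
  gen <- generate_variants(ts, var_cfg)
  paths <- c(gff3 = file.path(dir, "transcripts.gff3"),
             vcf = file.path(dir, "variants.vcf"),
             truth = file.path(dir, "truth.tsv"),
             known = file.path(dir, "known_sites.vcf"),
             config = file.path(dir, "config.json"))
  write_gff3(ts, paths[["gff3"]])
  write_vcf(gen$vs, paths[["vcf"]], contig_lengths = ts$contig_lengths)
  write_tsv(gen$truth, paths[["truth"]])
  kn <- which(gen$truth$planted_known)
  kvs <- gen$vs
  kvs$variants <- kvs$variants[kn, , drop = FALSE]
  kvs$gt_a <- kvs$gt_a[kn, , drop = FALSE]
  kvs$gt_b <- kvs$gt_b[kn, , drop = FALSE]
  kvs$phased <- kvs$phased[kn, , drop = FALSE]
  kvs$samples <- character(0)
  write_vcf(kvs, paths[["known"]])
  jsonlite::write_json(list(layout = unclass(layout_cfg),
                            variants = unclass(var_cfg)),
                       paths[["config"]], auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Independently perturb a truth assignment into two noisy copies
#'
#' Each key's category is re-drawn uniformly over the vocabulary with
#' probability `rate_a` (copy A) and `rate_b` (copy B), independently. With
#' both rates 1 the expected agreement between the copies is 1/K over K
#' categories.
#'
#' @param truth Named character vector: key -> category.
#' @param rate_a,rate_b Re-draw probabilities in [0, 1].
#' @param seed Integer seed.
#' @param categories Vocabulary to re-draw from.
#' @return List of two named character vectors, `a` and `b`.
#' @export
perturb_assignments <- function(truth, rate_a, rate_b, seed,
                                categories = broad_categories()) {
  stopifnot(rate_a >= 0, rate_a <= 1, rate_b >= 0, rate_b <= 1)
  set.seed(seed)
  redraw <- function(x, rate) {
    hit <- stats::runif(length(x)) < rate
    x[hit] <- sample(categories, sum(hit), replace = TRUE)
    x
  }
  list(a = redraw(truth, rate_a), b = redraw(truth, rate_b))
}
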