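# one coding plus-strand transcript: exons 1000-2000, 3000-5000; CDS 1500-4500
fixture_tx <- function(strand = "+") {
  make_tx("t1", "chr1", strand, c(1000, 2000, 3000, 5000), cds = c(1500, 4500))
}

snv <- function(pos, chrom = "chr1", ref = "A", alt = "G") {
  list(chrom = chrom, pos = pos, ref = ref, alt = alt)
}

test_that("intronic positions near exon boundaries get splice terms", {
  t1 <- fixture_tx()
  cfg <- annotator_config(splice_window = 6)
  # intron is 2001..2999; distances from the donor boundary (exon end 2000)
  expect_equal(annotate_against_transcript(snv(2001), t1, cfg), "splice_site")
  expect_equal(annotate_against_transcript(snv(2002), t1, cfg), "splice_site")
  expect_equal(annotate_against_transcript(snv(2003), t1, cfg), "splice_region")
  expect_equal(annotate_against_transcript(snv(2006), t1, cfg), "splice_region")
  expect_equal(annotate_against_transcript(snv(2007), t1, cfg), "intronic")
  # acceptor side (next exon starts at 3000)
  expect_equal(annotate_against_transcript(snv(2994), t1, cfg), "splice_region")
  expect_equal(annotate_against_transcript(snv(2998), t1, cfg), "splice_site")
  # exonic bases near the boundary stay exonic
  expect_equal(annotate_against_transcript(snv(2000), t1, cfg), "exonic_coding")
})

test_that("UTR assignment is strand-aware", {
  cfg <- annotator_config()
  tp <- fixture_tx("+"); tm <- fixture_tx("-")
  expect_equal(annotate_against_transcript(snv(1200), tp, cfg), "UTR5")
  expect_equal(annotate_against_transcript(snv(4800), tp, cfg), "UTR3")
  expect_equal(annotate_against_transcript(snv(1200), tm, cfg), "UTR3")
  expect_equal(annotate_against_transcript(snv(4800), tm, cfg), "UTR5")
})

test_that("flanks are strand-aware and chromosome mismatches yield no call", {
  cfg <- annotator_config(flank_window = 1000)
  tp <- fixture_tx("+")
  expect_equal(annotate_against_transcript(snv(500), tp, cfg), "upstream")
  expect_equal(annotate_against_transcript(snv(5500), tp, cfg), "downstream")
  expect_equal(annotate_against_transcript(snv(500), fixture_tx("-"), cfg),
               "downstream")
  expect_true(is.na(annotate_against_transcript(snv(500, chrom = "chr2"),
                                                tp, cfg)))
  expect_true(is.na(annotate_against_transcript(snv(6500), tp, cfg)))
})

test_that("a REF interval straddling a boundary takes the most severe region", {
  cfg <- annotator_config()
  t1 <- fixture_tx()
  # deletion spanning exon end 2000 into the intron
  del <- list(chrom = "chr1", pos = 1998, ref = "AAAAA", alt = "A")
  expect_equal(annotate_against_transcript(del, t1, cfg), "exonic_coding")
  # deletion fully inside the intron but touching the splice region
  del2 <- list(chrom = "chr1", pos = 2005, ref = "AAA", alt = "A")
  expect_equal(annotate_against_transcript(del2, t1, cfg), "splice_region")
})

test_that("per-pair classification matches the naive per-base oracle", {
  set.seed(19)
  ts <- small_layout(seed = 21, n_transcripts = 15)
  cfg <- annotator_config()
  txs <- ts$transcripts
  for (i in seq_len(2000)) {
    t <- txs[[sample(length(txs), 1)]]
    # concentrate positions around the transcript so all regions are hit
    pos <- t$tx_start + sample((-1500):(t$tx_end - t$tx_start + 1500), 1)
    if (pos < 1) next
    reflen <- sample(c(1, 1, 1, 2, 4), 1)
    v <- list(chrom = t$chrom, pos = pos,
              ref = strrep("A", reflen), alt = "A")
    if (reflen == 1) v$alt <- "G"
    expect_identical(annotate_against_transcript(v, t, cfg),
                     naive_interval_label(t, pos, v$ref, cfg),
                     info = sprintf("%s pos %d len %d", t$transcript_id,
                                    pos, reflen))
  }
})

test_that("exhaustive style lists all calls in severity order", {
  t1 <- make_tx("tA", "chr1", "+", c(1000, 2000), cds = c(1200, 1800))
  t2 <- make_tx("tB", "chr1", "+", c(500, 600, 1900, 3000), cds = c(550, 2500))
  idx <- build_index(transcript_set(list(t1, t2), c(chr1 = 1e5)))
  # 1500: coding exonic in tA, intronic in tB
  calls <- annotate_exhaustive(snv(1500), idx)
  expect_equal(calls$term, c("exonic_coding", "intronic"))
  expect_equal(calls$transcript_id, c("tA", "tB"))
  # far from everything: single intergenic call with no transcript
  calls2 <- annotate_exhaustive(snv(90000), idx)
  expect_equal(calls2$term, "intergenic")
  expect_true(is.na(calls2$transcript_id))
  # coding in tB and within tA's downstream flank: severity orders the calls
  calls3 <- annotate_exhaustive(snv(2400), idx)
  expect_equal(calls3$term, c("exonic_coding", "downstream"))
  expect_equal(calls3$transcript_id, c("tB", "tA"))
})

test_that("collapse keeps the most severe call, ties broken by transcript", {
  calls <- data.frame(
    variant_key = "chr1:1500:A:G",
    transcript_id = c("tB", "tA"),
    term = c("intronic", "exonic_coding"),
    impact_rank = unname(fine_term_ranks()[c("intronic", "exonic_coding")]),
    stringsAsFactors = FALSE)
  expect_equal(collapse_most_severe(calls)$term, "exonic_coding")
  expect_equal(collapse_most_severe(calls[1, ])$term, "intronic")
  tie <- calls; tie$term <- "intronic"; tie$impact_rank <- tie$impact_rank[1]
  expect_equal(collapse_most_severe(tie)$transcript_id, "tA")
  mixed <- calls; mixed$variant_key <- c("k1", "k2")
  expect_error(collapse_most_severe(mixed), "single variant_key")
})

test_that("collapse is invariant to call order", {
  set.seed(4)
  ranks <- fine_term_ranks()
  for (i in seq_len(200)) {
    n <- sample(1:6, 1)
    terms <- sample(names(ranks), n, replace = TRUE)
    calls <- data.frame(variant_key = "k",
                        transcript_id = paste0("t", sample(100, n)),
                        term = terms,
                        impact_rank = unname(ranks[terms]),
                        stringsAsFactors = FALSE)
    ref <- collapse_most_severe(calls)
    perm <- collapse_most_severe(calls[sample(n), , drop = FALSE])
    expect_identical(perm, ref)
    # the collapsed term equals the minimum by rank (sort oracle)
    expect_equal(ref$term, terms[order(ranks[terms])][1])
  }
})

test_that("annotation is total: >=1 exhaustive call, exactly 1 precedence call", {
  ts <- small_layout(seed = 13)
  idx <- build_index(ts)
  gen <- generate_variants(ts, variant_config(n_variants = 500,
                                              n_samples = 0, seed = 14))
  keys <- variant_key(gen$vs)
  ex <- annotate_variants(gen$vs, idx, annotator_config(style = "exhaustive"))
  expect_true(all(keys %in% ex$variant_key))
  pr <- annotate_variants(gen$vs, idx, annotator_config(style = "precedence"))
  expect_equal(sort(pr$variant_key), sort(keys))
  expect_equal(anyDuplicated(pr$variant_key), 0L)
})
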