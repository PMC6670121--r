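test_that("sites that are all-REF or all-missing in the subset are dropped", {
  body <- c(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t./.\t1/1",
    "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t0/1\t0/0\t0/0",
    "chr1\t300\t.\tG\tA\t.\tPASS\t.\tGT\t0/0\t0/0\t1/1")
  x <- read_vcf(write_vcf_text(body, samples = c("s1", "s2", "s3")))
  sub <- subset_population(x, c("s1", "s2"))
  # site 100: retained genotypes 0/0 and ./. -> dropped; site 300 all REF
  expect_equal(sub$pos, 200L)
  expect_equal(attr(sub, "n_sites_dropped"), 2L)
  expect_match(sub$info[1], "AC=1;AN=4")
  expect_error(subset_population(x, c("s1", "nope", "zz")), "nope")
})

test_that("half-missing genotypes contribute their observed allele", {
  body <- "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t./1\t0/."
  x <- read_vcf(write_vcf_text(body, samples = c("s1", "s2")))
  sub <- subset_population(x, c("s1", "s2"))
  expect_equal(sub$pos, 100L)
  expect_match(sub$info[1], "AC=1;AN=2")
})

test_that("subsetting matches a brute-force genotype scan on a 500-site VCF", {
  ts <- small_layout(seed = 51)
  gen <- generate_variants(ts, variant_config(n_variants = 500,
                                              n_samples = 20, seed = 52))
  p <- tempfile(fileext = ".vcf")
  write_vcf(gen$vs, p)
  x <- read_vcf(p)
  keep_ids <- x$samples[1:5]
  sub <- subset_population(x, keep_ids)
  # brute force: a site is kept iff any retained GT string contains a "1"
  kept_brute <- integer(0)
  ac_brute <- integer(0); an_brute <- integer(0)
  for (i in seq_along(x$pos)) {
    alleles <- unlist(strsplit(sub(":.*", "", x$gt[i, keep_ids]), "[/|]"))
    if (any(alleles == "1")) {
      kept_brute <- c(kept_brute, x$pos[i])
      ac_brute <- c(ac_brute, sum(alleles == "1"))
      an_brute <- c(an_brute, sum(alleles != "."))
    }
  }
  expect_equal(sub$pos, kept_brute)
  expect_equal(as.integer(sub("AC=([0-9]+);.*", "\\1", sub$info)), ac_brute)
  expect_equal(as.integer(sub(".*AN=([0-9]+).*", "\\1", sub$info)), an_brute)
})

test_that("subsetting is idempotent and monotone in the sample set", {
  ts <- small_layout(seed = 53)
  gen <- generate_variants(ts, variant_config(n_variants = 400,
                                              n_samples = 12, seed = 54))
  p <- tempfile(fileext = ".vcf")
  write_vcf(gen$vs, p)
  x <- read_vcf(p)
  small <- x$samples[1:3]
  big <- x$samples[1:8]
  s1 <- subset_population(x, small)
  s2 <- subset_population(s1, small)
  expect_equal(s2$pos, s1$pos)
  expect_equal(s2$info, s1$info)
  expect_equal(s2$gt, s1$gt)
  sb <- subset_population(x, big)
  expect_true(all(paste(s1$chrom, s1$pos) %in% paste(sb$chrom, sb$pos)))
})

test_that("summary statistics match hand counts", {
  v <- data.frame(chrom = "c", pos = 1:3,
                  ref = c("A", "C", "C"), alt = c("G", "T", "A"),
                  vtype = "SNV", stringsAsFactors = FALSE)
  sm <- summarize_variants(v)
  expect_equal(sm$ts, 2L)
  expect_equal(sm$tv, 1L)
  expect_equal(sm$tstv, 2.0)
  empty <- v[0, ]
  sm0 <- summarize_variants(empty)
  expect_equal(sm0$n_variants, 0L)
  expect_true(is.na(sm0$tstv))
})

test_that("generated SNVs recover the planted Ts/Tv", {
  ts <- small_layout(seed = 55)
  gen <- generate_variants(ts, variant_config(n_variants = 10000,
                                              snv_fraction = 1,
                                              target_tstv = 2.0,
                                              n_samples = 0, seed = 56))
  sm <- summarize_variants(gen$vs)
  p_hat <- sm$ts / sm$n_snv
  sigma <- sqrt((2 / 3) * (1 / 3) / sm$n_snv)
  expect_lt(abs(p_hat - 2 / 3), 3 * sigma)
})

test_that("density bins are position-anchored and conserve counts", {
  v <- data.frame(chrom = "c1", pos = c(1, 999999, 1000001),
                  ref = "A", alt = "G", vtype = "SNV",
                  stringsAsFactors = FALSE)
  d <- snp_density(v, bin_size = 1e6)
  expect_equal(d$bin_index, c(0, 1))
  expect_equal(d$count, c(2L, 1L))
  expect_equal(d$bin_start, c(1, 1e6 + 1))
  set.seed(57)
  v2 <- data.frame(chrom = sample(c("c1", "c2"), 5000, replace = TRUE),
                   pos = sample.int(1e7, 5000, replace = TRUE),
                   ref = "A", alt = "G", vtype = "SNV",
                   stringsAsFactors = FALSE)
  d2 <- snp_density(v2)
  expect_equal(sum(d2$count), 5000L)
  rep2 <- density_report(d2, c(c1 = 1e7, c2 = 1e7))
  expect_equal(nrow(rep2), 20L)
  expect_equal(sum(rep2$count), 5000L)
})

test_that("uniform positions fill bins consistently with a multinomial", {
  set.seed(58)
  v <- data.frame(chrom = "c1", pos = sample.int(1e7, 10000, replace = TRUE),
                  ref = "A", alt = "G", vtype = "SNV",
                  stringsAsFactors = FALSE)
  counts <- density_report(snp_density(v), c(c1 = 1e7))$count
  cs <- suppressWarnings(chisq.test(counts, p = rep(0.1, 10)))
  expect_gt(cs$p.value, 1e-4)
})

test_that("known-sites membership is allele-aware", {
  known <- write_vcf_text(c("chr1\t100\t.\tA\tG\t.\tPASS\t.",
                            "chr1\t200\t.\tC\tT\t.\tPASS\t."))
  q <- read_vcf(write_vcf_text(c("chr1\t100\t.\tA\tG\t.\tPASS\t.",
                                 "chr1\t200\t.\tC\tA\t.\tPASS\t.",
                                 "chr1\t300\t.\tG\tA\t.\tPASS\t.")))
  vs <- normalize_variants(split_multiallelic(q))
  flags <- known_sites_annotate(vs, c(db = known))
  expect_equal(flags$db, c(TRUE, FALSE, FALSE))
  # position-only mode flags the same-position different-allele variant
  flags2 <- known_sites_annotate(vs, c(db = known), allele_aware = FALSE)
  expect_equal(flags2$db, c(TRUE, TRUE, FALSE))
  expect_error(known_sites_annotate(vs, c(db = "/nonexistent.vcf")),
               "nonexistent")
})

test_that("planted known-site membership is recovered at its rate", {
  d <- tempfile()
  paths <- generate_fixtures(
    d, layout_config(chrom_length = 3e5, n_transcripts = 12, seed = 61),
    variant_config(n_variants = 2000, n_samples = 4,
                   known_site_rate = 0.3, seed = 62))
  vs <- normalize_variants(split_multiallelic(read_vcf(paths[["vcf"]])))
  flags <- known_sites_annotate(vs, c(known = unname(paths[["known"]])))
  truth <- read.table(paths[["truth"]], sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  expect_equal(flags$known,
               truth$planted_known[match(flags$variant_key,
                                         truth$variant_key)])
  rate <- mean(flags$known)
  sigma <- sqrt(0.3 * 0.7 / nrow(flags))
  expect_lt(abs(rate - 0.3), 3 * sigma)
})
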