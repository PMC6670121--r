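test_that("VCF records are read in order with genotypes parsed", {
  p <- write_vcf_text(c(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1",
    "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t./.",
    "chr2\t50\t.\tG\tA\t.\tPASS\t.\tGT\t1|1"), samples = "s1")
  x <- read_vcf(p)
  expect_equal(x$pos, c(100L, 200L, 50L))
  expect_equal(x$samples, "s1")
  vs <- split_multiallelic(x)
  expect_equal(unname(vs$gt_a[, 1]), c(0L, NA, 1L))
  expect_equal(unname(vs$gt_b[, 1]), c(1L, NA, 1L))
  expect_equal(unname(vs$phased[, 1]), c(FALSE, FALSE, TRUE))
})

test_that("a record with the wrong field count is reported by line number", {
  p <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
               "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t0/0",
               "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t0/1"), p)
  expect_error(read_vcf(p), "line 4")
})

test_that("multiallelic splitting recodes genotypes per ALT", {
  p <- write_vcf_text("chr1\t100\t.\tA\tG,T\t.\tPASS\t.\tGT\t1/2",
                      samples = "s1")
  vs <- split_multiallelic(read_vcf(p))
  expect_equal(nrow(vs$variants), 2L)
  expect_equal(vs$variants$alt, c("G", "T"))
  expect_equal(unname(vs$gt_a[, 1]), c(1L, NA))
  expect_equal(unname(vs$gt_b[, 1]), c(NA, 1L))
})

test_that("symbolic ALTs are skipped and counted", {
  p <- write_vcf_text("chr1\t100\t.\tA\t<DEL>\t.\tPASS\t.\tGT\t0/1",
                      samples = "s1")
  expect_warning(vs <- split_multiallelic(read_vcf(p)), "symbolic")
  expect_equal(nrow(vs$variants), 0L)
  expect_equal(vs$n_symbolic_skipped, 1L)
})

test_that("splitting conserves the non-REF allele count of the source record", {
  set.seed(31)
  for (i in seq_len(30)) {
    nalt <- sample(1:3, 1)
    alts <- sample(c("C", "G", "T", "AT", "CCG"), nalt)
    gts <- replicate(6, paste(sample(c(0:nalt, "."), 2, replace = TRUE),
                              collapse = "/"))
    body <- paste0("chr1\t", 100 + i, "\t.\tA\t",
                   paste(alts, collapse = ","),
                   "\t.\tPASS\t.\tGT\t", paste(gts, collapse = "\t"))
    vs <- split_multiallelic(read_vcf(write_vcf_text(
      body, samples = paste0("s", 1:6))))
    alleles <- unlist(strsplit(gts, "/"))
    n_nonref <- sum(alleles != "0" & alleles != ".")
    n_split <- sum(vs$gt_a == 1L, na.rm = TRUE) +
      sum(vs$gt_b == 1L, na.rm = TRUE)
    expect_equal(n_split, n_nonref)
  }
})

test_that("normalization trims suffix first, keeps the indel anchor", {
  n <- normalize_alleles(100, "CTT", "CT")
  expect_equal(n$pos, 100L)
  expect_equal(n$ref, "CT")
  expect_equal(n$alt, "C")
  expect_equal(n$vtype, "deletion")
  expect_identical(normalize_alleles(100, "A", "G")[c("pos", "ref", "alt")],
                   list(pos = 100L, ref = "A", alt = "G"))
  # shared prefix with room on both sides advances the position
  n2 <- normalize_alleles(100, "TA", "TG")
  expect_equal(n2$pos, 101L)
  expect_equal(n2$ref, "A")
  expect_equal(n2$alt, "G")
  expect_error(normalize_alleles(100, "ACA", "ACA"), "not a variant")
})

test_that("normalization matches a naive trimmer and is idempotent", {
  set.seed(17)
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(2000)) {
    ref <- paste(sample(bases, sample.int(5, 1), replace = TRUE),
                 collapse = "")
    alt <- paste(sample(bases, sample.int(5, 1), replace = TRUE),
                 collapse = "")
    if (ref == alt) next
    nv <- naive_trim(100, ref, alt)
    if (nv$ref == nv$alt) next
    got <- normalize_alleles(100, ref, alt)
    expect_equal(got[c("pos", "ref", "alt")],
                 list(pos = as.integer(nv$pos), ref = nv$ref, alt = nv$alt))
    again <- normalize_alleles(got$pos, got$ref, got$alt)
    expect_identical(again[c("pos", "ref", "alt")],
                     got[c("pos", "ref", "alt")])
  }
})

test_that("every normalized allele pair gets exactly one variant type", {
  expect_equal(classify_type("A", "G"), "SNV")
  expect_equal(classify_type("CT", "C"), "deletion")
  expect_equal(classify_type("C", "CT"), "insertion")
  expect_equal(classify_type("AT", "GC"), "MNP")
  expect_equal(classify_type("N", "A"), "other")
  set.seed(23)
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(500)) {
    ref <- paste(sample(bases, sample.int(4, 1), replace = TRUE), collapse = "")
    alt <- paste(sample(bases, sample.int(4, 1), replace = TRUE), collapse = "")
    if (ref == alt) next
    nv <- naive_trim(1, ref, alt)
    if (nv$ref == nv$alt) next
    vt <- classify_type(nv$ref, nv$alt)
    expect_true(vt %in% c("SNV", "insertion", "deletion", "MNP"))
    expect_equal(vt == "SNV",
                 nchar(nv$ref) == 1 && nchar(nv$alt) == 1)
  }
})

test_that("exactly 4 of the 12 ordered substitutions are transitions", {
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  tr <- is_transition(pairs$ref, pairs$alt)
  expect_equal(sum(tr), 4L)
  expect_equal(sum(!tr), 8L)
  expect_true(is_transition("A", "G"))
  expect_false(is_transition("C", "A"))
  expect_error(is_transition("AT", "A"), "SNV")
})

test_that("written VCFs read back identically, with consistent AC/AN", {
  ts <- small_layout(seed = 3)
  gen <- generate_variants(ts, variant_config(n_variants = 800,
                                              n_samples = 10, seed = 8))
  p <- tempfile(fileext = ".vcf")
  write_vcf(gen$vs, p, contig_lengths = ts$contig_lengths)
  back <- normalize_variants(split_multiallelic(read_vcf(p)))
  expect_equal(variant_key(back), variant_key(gen$vs))
  expect_equal(unname(back$gt_a), unname(gen$vs$gt_a))
  expect_equal(unname(back$gt_b), unname(gen$vs$gt_b))
  # AC/AN in INFO match an independent recount of the genotype matrix
  raw <- read_vcf(p)
  ac <- as.integer(sub(".*AC=([0-9]+);.*", "\\1", raw$info))
  an <- as.integer(sub(".*AN=([0-9]+).*", "\\1", raw$info))
  for (i in sample(length(ac), 50)) {
    alleles <- unlist(strsplit(sub(":.*", "", raw$gt[i, ]), "[/|]"))
    expect_equal(ac[i], sum(alleles == "1"))
    expect_equal(an[i], sum(alleles != "."))
  }
})

test_that("an empty variant set writes a header-only VCF", {
  empty <- structure(list(
    variants = data.frame(chrom = character(0), pos = integer(0),
                          ref = character(0), alt = character(0),
                          vtype = character(0), src_site = integer(0),
                          alt_index = integer(0)),
    gt_a = matrix(integer(0), 0, 0), gt_b = matrix(integer(0), 0, 0),
    phased = matrix(logical(0), 0, 0), samples = character(0),
    n_symbolic_skipped = 0L, n_source_sites = 0L), class = "variant_set")
  p <- tempfile(fileext = ".vcf")
  write_vcf(empty, p)
  x <- read_vcf(p)
  expect_length(x$pos, 0L)
})
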