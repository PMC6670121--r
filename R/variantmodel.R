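#' Read a VCF 4.2 file
#'
#' Wraps the vcfR parser and returns a light record container: site fields
#' plus the raw per-sample strings. Both plain and bgzip/gzip files are
#' accepted. A structural pre-check reports the first line whose field count
#' disagrees with the sample header, by line number.
#'
#' @param path VCF file path (.vcf or .vcf.gz).
#' @return An object of class `vcf_data` with elements `samples`, `chrom`,
#'   `pos`, `id`, `ref`, `alt` (comma-joined ALT string), `qual`, `filter`,
#'   `info`, `format`, and `gt` (character matrix, one column per sample,
#'   NA for missing).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("cannot open VCF file: ", path)
  check_vcf_lines(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE, checkFile = FALSE)
  fix <- v@fix
  has_gt <- ncol(v@gt) > 0L
  samples <- if (has_gt) colnames(v@gt)[-1L] else character(0)
  gt <- if (has_gt && length(samples)) {
    m <- v@gt[, -1L, drop = FALSE]
    if (is.null(dim(m))) m <- matrix(m, ncol = length(samples))
    colnames(m) <- samples
    m
  } else {
    matrix(character(0), nrow = nrow(fix), ncol = 0)
  }
  structure(list(
    samples = samples,
    chrom = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    id = as.character(fix[, "ID"]),
    ref = as.character(fix[, "REF"]),
    alt = as.character(fix[, "ALT"]),
    qual = as.character(fix[, "QUAL"]),
    filter = as.character(fix[, "FILTER"]),
    info = as.character(fix[, "INFO"]),
    format = if (has_gt) as.character(v@gt[, 1L]) else
      rep(NA_character_, nrow(fix)),
    gt = gt), class = "vcf_data")
}

# internal: per-line field-count check with line numbers
check_vcf_lines <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  lines <- readLines(con)
  hdr <- which(startsWith(lines, "#CHROM"))
  if (length(hdr) != 1L)
    stop("not a VCF: expected exactly one #CHROM header line in ", path)
  nexp <- length(strsplit(lines[hdr], "\t", fixed = TRUE)[[1]])
  body <- seq_along(lines) > hdr & nzchar(lines)
  if (!any(body)) return(invisible(TRUE))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- which(body)[nf != nexp]
  if (length(bad))
    stop("VCF parse error at line ", bad[1], " of ", path, ": expected ",
         nexp, " fields, found ", nf[match(bad[1], which(body))])
  invisible(TRUE)
}

#' @export
print.vcf_data <- function(x, ...) {
  cat("vcf_data:", length(x$pos), "records,", length(x$samples), "samples\n")
  invisible(x)
}

# internal: parse GT subfield strings into integer allele matrices.
# Returns list(a, b, phased); "." and absent alleles are NA. Haploid calls
# fill allele a only.
parse_gt <- function(gt) {
  d <- dim(gt)
  g <- sub(":.*", "", as.character(gt))
  g[is.na(g) | g == "." | g == "./." | g == ".|."] <- NA
  phased <- !is.na(g) & grepl("|", g, fixed = TRUE)
  a_chr <- sub("^([^/|]*)[/|].*$", "\\1", g)
  b_chr <- ifelse(grepl("[/|]", g), sub("^[^/|]*[/|]", "", g), NA)
  to_int <- function(x) {
    x[!is.na(x) & x == "."] <- NA
    suppressWarnings(as.integer(x))
  }
  a <- to_int(a_chr); b <- to_int(b_chr)
  dim(a) <- d; dim(b) <- d; dim(phased) <- d
  list(a = a, b = b, phased = phased)
}

#' Split multi-allelic VCF records into biallelic variants
#'
#' Each ALT allele of each record becomes one variant. Genotypes are recoded
#' per ALT: an allele equal to the ALT's index becomes 1, the REF allele 0,
#' any other non-REF allele missing. Symbolic ALTs (`<...>`, breakends, `*`)
#' are skipped with a warning and counted.
#'
#' @param x A `vcf_data` from [read_vcf()].
#' @return An object of class `variant_set`: `variants` (data.frame with
#'   chrom, pos, ref, alt, vtype, src_site, alt_index), genotype matrices
#'   `gt_a`, `gt_b` (0/1/NA), `phased`, `samples`, and counters
#'   `n_symbolic_skipped`, `n_source_sites`.
#' @export
split_multiallelic <- function(x) {
  stopifnot(inherits(x, "vcf_data"))
  n <- length(x$pos)
  alts <- strsplit(x$alt, ",", fixed = TRUE)
  nalt <- lengths(alts)
  site <- rep(seq_len(n), nalt)
  alt_index <- sequence(nalt)
  alt <- unlist(alts, use.names = FALSE)
  if (length(alt) == 0L) alt <- character(0)
  symbolic <- grepl("[][<>*]", alt)
  n_sym <- sum(symbolic)
  if (n_sym > 0L)
    warning("skipped ", n_sym, " symbolic ALT allele(s)")
  keep <- !symbolic
  site <- site[keep]; alt_index <- alt_index[keep]; alt <- alt[keep]
  gp <- parse_gt(x$gt)
  ns <- length(x$samples)
  recode <- function(m) {
    if (ns == 0L || length(site) == 0L)
      return(matrix(integer(0), nrow = length(site), ncol = ns,
                    dimnames = list(NULL, x$samples)))
    mm <- m[site, , drop = FALSE]
    k <- matrix(alt_index, nrow = length(site), ncol = ns)
    out <- matrix(NA_integer_, nrow = length(site), ncol = ns,
                  dimnames = list(NULL, x$samples))
    out[!is.na(mm) & mm == 0L] <- 0L
    out[!is.na(mm) & mm == k] <- 1L
    out
  }
  structure(list(
    variants = data.frame(chrom = x$chrom[site], pos = x$pos[site],
                          ref = x$ref[site], alt = alt,
                          vtype = rep(NA_character_, length(site)),
                          src_site = site, alt_index = alt_index,
                          stringsAsFactors = FALSE),
    gt_a = recode(gp$a), gt_b = recode(gp$b),
    phased = if (ns && length(site)) gp$phased[site, , drop = FALSE] else
      matrix(logical(0), nrow = length(site), ncol = ns),
    samples = x$samples,
    n_symbolic_skipped = n_sym,
    n_source_sites = n), class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat("variant_set:", nrow(x$variants), "variants (from", x$n_source_sites,
      "sites),", length(x$samples), "samples\n")
  if (!all(is.na(x$variants$vtype))) {
    print(table(x$variants$vtype))
  }
  invisible(x)
}

# internal: vectorized parsimony trimming of allele pairs.
# Suffix first, then prefix (advancing pos), each only while both alleles
# keep >= 1 base, so indels retain their left anchor.
trim_alleles <- function(pos, ref, alt) {
  pos <- as.integer(pos)
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    can <- nr > 1L & na > 1L &
      substr(ref, nr, nr) == substr(alt, na, na)
    if (!any(can)) break
    ref[can] <- substr(ref[can], 1L, nr[can] - 1L)
    alt[can] <- substr(alt[can], 1L, na[can] - 1L)
  }
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    can <- nr > 1L & na > 1L &
      substr(ref, 1L, 1L) == substr(alt, 1L, 1L)
    if (!any(can)) break
    ref[can] <- substr(ref[can], 2L, nr[can])
    alt[can] <- substr(alt[can], 2L, na[can])
    pos[can] <- pos[can] + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Normalize one allele substitution
#'
#' Trims the common suffix, then the common prefix (advancing the position),
#' each only while both alleles retain at least one base, so that insertions
#' and deletions keep a left anchor base as in the VCF convention. The
#' operation is idempotent. An allele pair that is identical after trimming
#' is not a variant and is rejected.
#'
#' @param pos 1-based position of the first REF base.
#' @param ref,alt Allele strings.
#' @return List with elements `pos`, `ref`, `alt`, `vtype`.
#' @export
#' @examples
#' normalize_alleles(100, "CTT", "CT")  # suffix trimmed: CT/C deletion at 100
normalize_alleles <- function(pos, ref, alt) {
  tr <- trim_alleles(pos, ref, alt)
  if (any(tr$ref == tr$alt))
    stop("ref equals alt after trimming: not a variant")
  c(tr, list(vtype = classify_type(tr$ref, tr$alt)))
}

#' Normalize all variants in a variant set
#'
#' Applies [normalize_alleles()] trimming to every variant, drops
#' non-variants (REF == ALT after trimming, counted in attribute
#' `n_nonvariant_dropped`), and fills the `vtype` column.
#'
#' @param vs A `variant_set`.
#' @return The normalized `variant_set`.
#' @export
normalize_variants <- function(vs) {
  stopifnot(inherits(vs, "variant_set"))
  v <- vs$variants
  tr <- trim_alleles(v$pos, v$ref, v$alt)
  drop <- tr$ref == tr$alt
  keep <- which(!drop)
  v <- v[keep, , drop = FALSE]
  v$pos <- tr$pos[keep]; v$ref <- tr$ref[keep]; v$alt <- tr$alt[keep]
  v$vtype <- classify_type(v$ref, v$alt)
  rownames(v) <- NULL
  vs$variants <- v
  vs$gt_a <- vs$gt_a[keep, , drop = FALSE]
  vs$gt_b <- vs$gt_b[keep, , drop = FALSE]
  vs$phased <- vs$phased[keep, , drop = FALSE]
  attr(vs, "n_nonvariant_dropped") <- sum(drop)
  vs
}

#' Classify variant type from normalized alleles
#'
#' @param ref,alt Normalized allele strings (vectorized).
#' @return Character vector over \{SNV, insertion, deletion, MNP, other\}.
#'   Alleles containing characters outside A/C/G/T are "other".
#' @export
classify_type <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  out <- rep("other", length(ref))
  ok <- grepl("^[ACGT]+$", ref) & grepl("^[ACGT]+$", alt)
  out[ok & nr == 1L & na == 1L] <- "SNV"
  out[ok & na > nr] <- "insertion"
  out[ok & nr > na] <- "deletion"
  out[ok & nr == na & nr > 1L] <- "MNP"
  out
}

#' Is a single-base substitution a transition?
#'
#' Transitions are the purine-purine and pyrimidine-pyrimidine exchanges
#' A<->G and C<->T; the remaining eight ordered substitutions are
#' transversions.
#'
#' @param ref,alt Single bases (vectorized); must describe SNVs.
#' @return Logical vector.
#' @export
is_transition <- function(ref, alt) {
  if (any(classify_type(ref, alt) != "SNV"))
    stop("is_transition is defined for SNVs only")
  (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
    (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
}

#' Write VCF 4.2
#'
#' @param x A `variant_set` (one biallelic record per variant, with AC/AN/AF
#'   recomputed from the genotype matrices) or a `vcf_data` (records written
#'   as stored).
#' @param path Output path; a ".gz" suffix gzips the output.
#' @param contig_lengths Optional named vector emitted as contig header
#'   lines.
#' @param ... Unused.
#' @return The path, invisibly.
#' @export
write_vcf <- function(x, path, ...) UseMethod("write_vcf")

vcf_open <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
}

vcf_header <- function(samples, contig_lengths = NULL, extra = character(0)) {
  h <- c("##fileformat=VCFv4.2",
         "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Alternate allele count in called genotypes\">",
         "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Number of called alleles\">",
         "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Alternate allele frequency\">",
         "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  if (!is.null(contig_lengths))
    h <- c(h, sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                      as.integer(contig_lengths)))
  h <- c(h, extra)
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (length(samples)) cols <- c(cols, "FORMAT", samples)
  c(h, paste(cols, collapse = "\t"))
}

#' @rdname write_vcf
#' @export
write_vcf.variant_set <- function(x, path, contig_lengths = NULL, ...) {
  v <- x$variants
  ns <- length(x$samples)
  if (ns > 0L && nrow(v) > 0L) {
    ac <- rowSums(x$gt_a == 1L, na.rm = TRUE) +
      rowSums(x$gt_b == 1L, na.rm = TRUE)
    an <- rowSums(!is.na(x$gt_a)) + rowSums(!is.na(x$gt_b))
    af <- ifelse(an > 0, signif(ac / an, 6), NA)
    info <- paste0("AC=", ac, ";AN=", an,
                   ifelse(is.na(af), "", paste0(";AF=", af)))
    sep <- ifelse(x$phased, "|", "/")
    achr <- ifelse(is.na(x$gt_a), ".", as.character(x$gt_a))
    bchr <- ifelse(is.na(x$gt_b), ".", as.character(x$gt_b))
    gt <- matrix(paste0(achr, sep, bchr), nrow = nrow(v))
    body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", info, "GT",
                  apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  } else if (nrow(v) > 0L) {
    body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", ".",
                  sep = "\t")
  } else {
    body <- character(0)
  }
  con <- vcf_open(path)
  on.exit(close(con))
  writeLines(c(vcf_header(x$samples, contig_lengths), body), con)
  invisible(path)
}

#' @rdname write_vcf
#' @export
write_vcf.vcf_data <- function(x, path, contig_lengths = NULL, ...) {
  dot <- function(z) ifelse(is.na(z), ".", z)
  n <- length(x$pos)
  if (n > 0L) {
    body <- paste(x$chrom, x$pos, dot(x$id), x$ref, x$alt, dot(x$qual),
                  dot(x$filter), dot(x$info), sep = "\t")
    if (length(x$samples)) {
      gt <- apply(x$gt, 1L, function(r) paste(dot(r), collapse = "\t"))
      body <- paste(body, dot(x$format), gt, sep = "\t")
    }
  } else {
    body <- character(0)
  }
  con <- vcf_open(path)
  on.exit(close(con))
  writeLines(c(vcf_header(x$samples, contig_lengths), body), con)
  invisible(path)
}
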