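#' Pipeline run configuration
#'
#' Bundles the inputs and the two annotation strategies of an end-to-end
#' comparison run: a multi-sample VCF, transcript models, an optional
#' population subset, two annotator configurations ("tool A" and "tool B"),
#' a harmonization map, and optional known-sites databases.
#'
#' @param input_vcf,gff3 Input paths (must exist).
#' @param out_dir Output directory (created if absent).
#' @param samples_file Optional plain-text file, one sample ID per line;
#'   when given, the pipeline subsets the VCF to these samples first.
#' @param config_a,config_b The two [annotator_config()]s being compared.
#' @param map_path Optional harmonization map TSV (default: the built-in
#'   map).
#' @param known_sites Optional named vector of known-sites VCF paths.
#' @param bin_size Density bin width in bp.
#' @return Object of class `run_config`.
#' @export
run_config <- function(input_vcf, gff3, out_dir,
                       samples_file = NULL,
                       config_a = annotator_config(style = "precedence"),
                       config_b = annotator_config(style = "exhaustive"),
                       map_path = NULL, known_sites = NULL,
                       bin_size = 1e6) {
  for (p in c(input_vcf, gff3, samples_file, map_path,
              unname(known_sites)))
    if (!file.exists(p)) stop("input path does not exist: ", p)
  structure(list(input_vcf = input_vcf, gff3 = gff3, out_dir = out_dir,
                 samples_file = samples_file,
                 config_a = config_a, config_b = config_b,
                 map_path = map_path, known_sites = known_sites,
                 bin_size = bin_size),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full annotation-comparison pipeline
#'
#' Executes subset (optional) -> summarize -> density -> annotate under
#' both configurations -> harmonize -> compare, writing every intermediate
#' as a re-loadable file plus a manifest with per-stage counters and
#' checksums. Reruns on identical inputs produce byte-identical outputs:
#' no stage uses randomness and the manifest carries no timestamps.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`summary`,
#'   `concordance`, `assignments`, `counters`) and the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  counters <- list()
  paths <- c()
  vcf <- stage("read_vcf", read_vcf(config$input_vcf))
  counters$records_read <- length(vcf$pos)
  ts <- stage("load_gff3", load_gff3(config$gff3))
  idx <- build_index(ts)
  if (!is.null(config$samples_file)) {
    ids <- readLines(config$samples_file)
    ids <- ids[nzchar(ids)]
    vcf <- stage("subset_population", subset_population(vcf, ids))
    counters$sites_dropped_by_subset <- attr(vcf, "n_sites_dropped")
    p <- file.path(out, "subset.vcf")
    write_vcf(vcf, p, contig_lengths = ts$contig_lengths)
    paths["subset"] <- p
  }
  vs <- stage("split_normalize", {
    withCallingHandlers(
      normalize_variants(split_multiallelic(vcf)),
      warning = function(w) invokeRestart("muffleWarning"))
  })
  counters$symbolic_alt_skipped <- vs$n_symbolic_skipped
  counters$nonvariant_dropped <- attr(vs, "n_nonvariant_dropped")
  counters$variants_after_split <- nrow(vs$variants)
  sm <- stage("summarize", summarize_variants(vs))
  paths["summary"] <- file.path(out, "summary_stats.tsv")
  write_tsv(as.data.frame(sm), paths[["summary"]])
  dens <- stage("density", snp_density(vs, config$bin_size))
  paths["density"] <- file.path(out, "density.tsv")
  write_tsv(density_report(dens, ts$contig_lengths), paths[["density"]])
  map <- if (is.null(config$map_path)) default_harmonization_map()
         else load_harmonization_map(config$map_path)
  assignments <- list()
  for (side in c("a", "b")) {
    cfg <- config[[paste0("config_", side)]]
    calls <- stage(paste0("annotate_", side),
                   annotate_variants(vs, idx, cfg))
    assignments[[side]] <- assignment_from_calls(calls, map)
    p <- file.path(out, sprintf("categories_%s.tsv", toupper(side)))
    write_tsv(data.frame(variant_key = names(assignments[[side]]),
                         category = unname(assignments[[side]])), p)
    paths[paste0("categories_", side)] <- p
  }
  conc <- stage("compare",
                compare_assignments(assignments$a, assignments$b))
  rp <- write_concordance_report(conc, file.path(out, "concordance"))
  paths["concordance_tsv"] <- rp[["tsv"]]
  paths["concordance_json"] <- rp[["json"]]
  if (!is.null(config$known_sites)) {
    ks <- stage("known_sites",
                known_sites_annotate(vs, config$known_sites))
    paths["known_sites"] <- file.path(out, "known_sites.tsv")
    write_tsv(ks, paths[["known_sites"]])
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("varconcord")),
    config = list(input_vcf = config$input_vcf, gff3 = config$gff3,
                  samples_file = config$samples_file,
                  bin_size = config$bin_size,
                  config_a = unclass(config$config_a),
                  config_b = unclass(config$config_b)),
    input_checksums = as.list(tools::md5sum(
      c(config$input_vcf, config$gff3))),
    counters = counters,
    outputs = {
      md5 <- tools::md5sum(unname(paths))
      stats::setNames(as.list(unname(md5)), basename(names(md5)))
    })
  paths["manifest"] <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(summary = sm, concordance = conc,
                 assignments = assignments, counters = counters,
                 paths = paths))
}
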