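# Run manifests, results I/O, printed-table validation and the R-level
# command entry points behind the `aaxscan` command-line script.

#' Run manifest
#'
#' Captures what determines a run: the configuration echo, input-file
#' checksums, the seed, the package version and the stage counts, so a run
#' is reproducible from the manifest plus its inputs.
#'
#' @param command which subcommand produced the run.
#' @param config configuration list to echo.
#' @param inputs named character vector of input file paths (md5-summed).
#' @param seed integer seed used, or `NULL`.
#' @param counts named list/vector of stage counts (SNPs loaded, SNPs after
#'   QC, pairs enumerated/tested/significant, ...).
#' @return a `run_manifest` list.
#' @export
run_manifest <- function(command, config = list(), inputs = character(0),
                         seed = NULL, counts = list()) {
  checksums <- if (length(inputs)) {
    as.list(tools::md5sum(unlist(inputs)))
  } else {
    list()
  }
  structure(
    list(command = command,
         version = as.character(utils::packageVersion("aaxscan")),
         seed = seed, config = config, input_md5 = checksums,
         counts = counts),
    class = "run_manifest"
  )
}

#' @rdname run_manifest
#' @param manifest a `run_manifest`.
#' @param path output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write / read scan results as TSV
#'
#' The results table mirrors the layout of the study's report tables
#' (`SNP`, chromosome and position for both loci, `effect`, `log10_inv_p`,
#' `rank`) plus `se`, `t`, `pattern`, `status` and `significant`.
#'
#' @param results an `epistasis_scan` data frame.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_results <- function(results, path) {
  data.table::fwrite(as.data.frame(results), path, sep = "\t", na = "NA")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  out <- data.table::fread(path, data.table = FALSE,
                           colClasses = list(character = "pattern"))
  class(out) <- c("epistasis_scan", "data.frame")
  out
}

#' Packaged reference-table fixtures
#'
#' Paths to the plain-text copies of the published worked values from the
#' million-cow Holstein fat-percentage A-by-A study that this package
#' re-implements the analysis of: the allelic-combination A-by-A values
#' (AC1..AC4 with their aa values) for example Chr14a x SGN and Chr14b
#' pairs, and the corresponding published effect tables.
#'
#' @param which fixture name.
#' @return file path within the installed package.
#' @export
aa_fixture_path <- function(which = c("aa_chr14a_sgn", "aa_chr14b",
                                      "effects_pfct_sgn", "effects_casd_sgn",
                                      "effects_chr14b1", "effects_chr14b2")) {
  which <- match.arg(which)
  system.file("extdata", paste0("holstein_fpc_", which, ".tsv"),
              package = "aaxscan", mustWork = TRUE)
}

#' Reconstruct published effects from published A-by-A values
#'
#' Joins the packaged A-by-A value tables with the published effect tables
#' on the SNP pair, rebuilds the 2x2 aa matrix from the AC labels, applies
#' the contrast of [compute_aa_effect()] and compares with the printed
#' effect.  Because the published aa values are rounded to 4 decimals, a
#' reconstruction can differ from the printed effect by up to 2e-4 (four
#' values at half-a-unit each); `match` records agreement within that
#' bound.  The AC1/AC4 pattern class of every row is recomputed as well.
#'
#' @param tolerance allowed absolute difference for `match`.
#' @return data frame with one row per joined pair: SNP ids, printed and
#'   reconstructed effect, their difference, `match`, and `pattern`.
#' @export
validate_printed_tables <- function(tolerance = 2e-4) {
  aa_files <- c("aa_chr14a_sgn", "aa_chr14b")
  eff_files <- c("effects_pfct_sgn", "effects_casd_sgn",
                 "effects_chr14b1", "effects_chr14b2")
  aa <- do.call(rbind, lapply(aa_files, function(f) {
    data.table::fread(aa_fixture_path(f), data.table = FALSE)
  }))
  eff <- do.call(rbind, lapply(eff_files, function(f) {
    d <- data.table::fread(aa_fixture_path(f), data.table = FALSE)
    d[, c("snp1", "snp2", "effect")]
  }))
  eff <- eff[!duplicated(paste(eff$snp1, eff$snp2)), , drop = FALSE]
  merged <- merge(aa, eff, by = c("snp1", "snp2"))
  recon <- numeric(nrow(merged))
  pattern <- character(nrow(merged))
  for (r in seq_len(nrow(merged))) {
    m <- aa_matrix_from_labels(
      labels = unlist(merged[r, c("ac1", "ac2", "ac3", "ac4")]),
      values = unlist(merged[r, c("aa1", "aa2", "aa3", "aa4")]))
    recon[r] <- compute_aa_effect(m)$alpha_alpha
    rk <- structure(list(ranking = unlist(merged[r, c("ac1", "ac2", "ac3",
                                                      "ac4")]),
                         tied = FALSE), class = "aa_table")
    pattern[r] <- classify_pattern(rk, chr14_locus = 1L)
  }
  out <- data.frame(
    snp1 = merged$snp1, snp2 = merged$snp2,
    effect_printed = merged$effect, effect_reconstructed = recon,
    diff = recon - merged$effect,
    match = abs(recon - merged$effect) <= tolerance,
    pattern = pattern, stringsAsFactors = FALSE
  )
  out[order(out$snp1, out$snp2), , drop = FALSE]
}

#' Rebuild the 2x2 aa matrix from AC labels and values
#'
#' @param labels character vector of combination labels (`"1_2"` style).
#' @param values aa values in the same order.
#' @return 2x2 numeric matrix indexed by allele at locus 1 (rows) and
#'   locus 2 (columns).
#' @export
aa_matrix_from_labels <- function(labels, values) {
  m <- matrix(NA_real_, 2L, 2L,
              dimnames = list(locus1 = c("1", "2"), locus2 = c("1", "2")))
  for (q in seq_along(labels)) {
    al <- strsplit(labels[q], "_", fixed = TRUE)[[1L]]
    m[al[1L], al[2L]] <- values[q]
  }
  if (anyNA(m)) stop("labels do not cover the four allelic combinations")
  m
}

# ---------------------------------------------------------------------------
# command entry points (thin wrappers used by inst/cli/aaxscan.R)

#' Simulate a population from a YAML configuration
#'
#' Reads a YAML simulation configuration, draws the population, writes the
#' canonical TSV trio, a ground-truth JSON and a run manifest.  The YAML
#' mirrors [sim_config()]; SNPs may be given explicitly (`snps: {table:
#' [...]}` with one map row per entry) or compactly (`snps: {n: 50,
#' chromosomes: 5, maf_range: [0.1, 0.5]}`).  SNPs named in
#' `epistatic_pairs` get their MAFs overridden to the pattern defaults of
#' [build_effect_table()] unless the pair carries explicit `maf_i`/`maf_j`.
#'
#' @param config_path YAML file path.
#' @param out_prefix output path prefix.
#' @param seed optional integer overriding the configured seed.
#' @return invisibly, the [simulate_population()] output.
#' @export
cli_simulate <- function(config_path, out_prefix, seed = NULL) {
  if (!file.exists(config_path)) stop("config file not found: ", config_path)
  raw <- yaml::read_yaml(config_path)
  spec <- if (!is.null(raw$snps$table)) {
    do.call(rbind, lapply(raw$snps$table, as.data.frame))
  } else {
    snp_grid(raw$snps$n, raw$snps$chromosomes %||% 5L,
             unlist(raw$snps$maf_range %||% c(0.1, 0.5)))
  }
  pairs <- lapply(raw$epistatic_pairs %||% list(), function(pp) {
    i <- .resolve_snp(pp$snp_i, spec); j <- .resolve_snp(pp$snp_j, spec)
    pat <- pp$pattern %||% 1L
    spec$maf[i] <<- pp$maf_i %||% (if (pat == 1L) 0.2 else 0.4)
    spec$maf[j] <<- pp$maf_j %||% (if (pat == 1L) 0.4 else 0.2)
    planted_pair(i, j, pp$aa_magnitude, pat)
  })
  cfg <- sim_config(
    n_individuals = raw$n_individuals,
    snp_spec = spec,
    mu = raw$mu %||% 0,
    sigma_a2 = raw$sigma_a2 %||% 0.35,
    sigma_e2 = raw$sigma_e2 %||% 0.60,
    pta_reliability = raw$pta_reliability %||% 0.7,
    additive_effects = unlist(raw$additive_effects %||% NULL),
    epistatic_pairs = pairs,
    family_size = raw$family_size %||% 1L,
    seed = seed %||% raw$seed
  )
  sim <- simulate_population(cfg)
  paths <- write_cohort(sim$panel, sim$cohort, out_prefix)
  truth_path <- paste0(out_prefix, "_truth.json")
  jsonlite::write_json(
    list(a = sim$truth$a, mu = sim$truth$mu,
         pair_tables = lapply(sim$truth$pair_tables, function(m) {
           unclass(as.data.frame(unclass(m)))
         }),
         family = sim$truth$family),
    truth_path, auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- run_manifest(
    "simulate",
    config = raw, inputs = c(config = config_path), seed = cfg$seed,
    counts = list(n_individuals = cfg$n_individuals, n_snps = nrow(spec),
                  n_planted_pairs = length(pairs)))
  write_manifest(manifest, paste0(out_prefix, "_manifest.json"))
  message("simulate: wrote ", paste(basename(c(paths, truth_path)),
                                    collapse = ", "))
  invisible(sim)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a scan from files
#'
#' Loads the panel and cohort, applies the MAF filter, runs [run_scan()]
#' and writes the ranked results TSV plus a manifest with the stage counts.
#'
#' @param genotype_path,phenotype_path,map_path input files
#'   (see [load_cohort()]).
#' @param out_path results TSV path.
#' @param threshold significance threshold on log10(1/p).
#' @param top_k retained best pairs.
#' @param maf_threshold QC minor-allele-frequency floor.
#' @param focal_chromosome focal chromosome for pattern classification.
#' @param format input dialect (`"tsv"` or `"plink"`).
#' @param gene_map_path optional gene map for annotation.
#' @param min_cell_count per-cell count floor for testability.
#' @return invisibly, the scan results.
#' @export
cli_scan <- function(genotype_path, phenotype_path, map_path, out_path,
                     threshold = 32, top_k = 50000L, maf_threshold = 0.05,
                     focal_chromosome = 14L, format = "tsv",
                     gene_map_path = NULL, min_cell_count = 0L) {
  loaded <- load_cohort(genotype_path, phenotype_path, map_path, format)
  n_loaded <- nrow(loaded$panel)
  qc <- filter_maf(loaded$panel, loaded$cohort, maf_threshold)
  message("scan: ", n_loaded, " SNPs loaded, ", nrow(qc$panel),
          " after MAF >= ", maf_threshold)
  gm <- if (!is.null(gene_map_path)) load_gene_map(gene_map_path)
  cfg <- scan_config(significance_log10p = threshold, top_k = top_k,
                     min_cell_count = min_cell_count,
                     focal_chromosome = focal_chromosome)
  res <- run_scan(qc$panel, qc$cohort, cfg, gene_map = gm)
  write_results(res, out_path)
  manifest <- run_manifest(
    "scan",
    config = list(threshold = threshold, top_k = top_k,
                  maf_threshold = maf_threshold,
                  focal_chromosome = focal_chromosome, format = format,
                  min_cell_count = min_cell_count),
    inputs = c(genotypes = genotype_path, phenotypes = phenotype_path,
               map = map_path),
    counts = list(snps_loaded = n_loaded, snps_after_maf = nrow(qc$panel),
                  pairs_enumerated = attr(res, "n_pairs"),
                  pairs_tested = attr(res, "n_tested"),
                  pairs_significant = attr(res, "n_significant")))
  write_manifest(manifest, paste0(out_path, ".manifest.json"))
  message("scan: ", attr(res, "n_tested"), " pairs tested, ",
          attr(res, "n_significant"), " significant; results in ", out_path)
  invisible(res)
}

#' Region report from a results file
#'
#' @param results_path results TSV written by [cli_scan()].
#' @param out_prefix output path prefix for the report TSV/JSON and the
#'   plot-data exports.
#' @param focal_chromosome focal chromosome.
#' @param threshold significance threshold on log10(1/p).
#' @param scheme_path optional YAML region scheme (list of `region`,
#'   `start`, `end` entries); default is [chr14_region_scheme()].
#' @return invisibly, the [summarize_regions()] report.
#' @export
cli_report <- function(results_path, out_prefix, focal_chromosome = 14L,
                       threshold = 32, scheme_path = NULL) {
  if (!file.exists(results_path)) {
    stop("results file not found: ", results_path)
  }
  res <- read_results(results_path)
  scheme <- if (!is.null(scheme_path)) {
    region_scheme(do.call(rbind, lapply(yaml::read_yaml(scheme_path),
                                        as.data.frame)))
  } else {
    chr14_region_scheme()
  }
  rep <- summarize_regions(res, scheme, focal_chromosome, threshold)
  data.table::fwrite(rep$by_region, paste0(out_prefix, "_regions.tsv"),
                     sep = "\t")
  jsonlite::write_json(
    list(focal_chromosome = rep$focal_chromosome, threshold = rep$threshold,
         total = rep$total, by_region = rep$by_region),
    paste0(out_prefix, "_regions.json"), auto_unbox = TRUE, digits = NA)
  data.table::fwrite(manhattan_data(res, scheme, focal_chromosome),
                     paste0(out_prefix, "_manhattan.tsv"), sep = "\t")
  data.table::fwrite(link_data(res),
                     paste0(out_prefix, "_links.tsv"), sep = "\t")
  manifest <- run_manifest(
    "report",
    config = list(focal_chromosome = focal_chromosome,
                  threshold = threshold),
    inputs = c(results = results_path),
    counts = list(significant_focal_pairs = rep$total))
  write_manifest(manifest, paste0(out_prefix, "_manifest.json"))
  message("report: ", rep$total, " significant pairs on chromosome ",
          focal_chromosome)
  invisible(rep)
}
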