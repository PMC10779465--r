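# Synthetic populations with the statistical structure the scan assumes:
# Hardy-Weinberg genotypes at specified MAFs, a polygenic component with a
# PTA-like prediction of stated reliability, residual noise, and planted
# additive and two-locus A x A effects.

#' Evenly spaced SNP specification
#'
#' Convenience builder for a simulation SNP map: `n_snps` SNPs spread over
#' `n_chromosomes` chromosomes (codes 1, 2, ...), 1 Mb apart within a
#' chromosome, with minor allele frequencies evenly spaced over `maf_range`
#' (deterministic, so the map is part of the configuration rather than of
#' the random draw).
#'
#' @param n_snps number of SNPs.
#' @param n_chromosomes number of chromosomes to spread them over.
#' @param maf_range length-2 numeric range of MAFs.
#' @return data frame with columns `snp_id`, `chromosome`, `position_bp`,
#'   `maf`.
#' @export
snp_grid <- function(n_snps, n_chromosomes = 5L, maf_range = c(0.1, 0.5)) {
  chrom <- rep(seq_len(n_chromosomes), length.out = n_snps)
  chrom <- sort(chrom)
  within <- stats::ave(seq_len(n_snps), chrom, FUN = seq_along)
  data.frame(
    snp_id = sprintf("snp%04d", seq_len(n_snps)),
    chromosome = chrom,
    position_bp = 1000000L * within,
    maf = seq(maf_range[1L], maf_range[2L], length.out = n_snps),
    stringsAsFactors = FALSE
  )
}

#' Planted two-locus epistatic pair
#'
#' @param snp_i,snp_j SNP ids or panel indices; must lie on different
#'   chromosomes (only inter-chromosome pairs are scanned).
#' @param aa_magnitude target A-by-A contrast effect in phenotype units.
#' @param pattern 1 or 2: whether AC1/AC4 share an allele of locus i
#'   (pattern 1) or of locus j (pattern 2); see [classify_pattern()].
#' @return a `planted_pair` list.
#' @export
planted_pair <- function(snp_i, snp_j, aa_magnitude, pattern = 1L) {
  stopifnot(pattern %in% c(1L, 2L))
  structure(list(snp_i = snp_i, snp_j = snp_j,
                 aa_magnitude = aa_magnitude, pattern = as.integer(pattern)),
            class = "planted_pair")
}

#' Simulation configuration
#'
#' Collects everything that determines a synthetic population.  Defaults
#' emulate a high-heritability dairy component trait on the phenotypic
#' standard-deviation scale: polygenic variance 0.35, residual variance
#' 0.60 and a PTA reliability (squared correlation between the polygenic
#' prediction and the true polygenic value) of 0.7.  These are illustrative
#' round values for a yield-deviation analysis, not estimates from any
#' particular cattle population.
#'
#' @param n_individuals cohort size.
#' @param snp_spec data frame with `snp_id`, `chromosome`, `position_bp`,
#'   `maf` (see [snp_grid()]); `maf` is the frequency of allele 1, the
#'   minor allele.
#' @param mu common mean of the phenotype.
#' @param sigma_a2 polygenic additive variance.
#' @param sigma_e2 residual variance.
#' @param pta_reliability squared correlation between `a_tilde` and the true
#'   polygenic value, in `[0, 1]`.
#' @param additive_effects optional per-SNP allele-substitution effects
#'   (phenotype change per copy of allele 1); default all zero.
#' @param epistatic_pairs list of [planted_pair()] objects.
#' @param family_size 1 for unrelated individuals (additive relationship
#'   matrix = identity); larger values create half-sib family blocks with
#'   additive relationship 0.25 within a family.
#' @param seed integer seed making the draw reproducible.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_individuals, snp_spec, mu = 0,
                       sigma_a2 = 0.35, sigma_e2 = 0.60,
                       pta_reliability = 0.7,
                       additive_effects = NULL,
                       epistatic_pairs = list(),
                       family_size = 1L, seed = NULL) {
  stopifnot(n_individuals >= 1, nrow(snp_spec) >= 1)
  if (sigma_a2 < 0 || sigma_e2 < 0) stop("variances must be non-negative")
  if (pta_reliability < 0 || pta_reliability > 1) {
    stop("`pta_reliability` must lie in [0, 1]")
  }
  if (any(snp_spec$maf <= 0 | snp_spec$maf >= 1)) {
    stop("snp_spec$maf must lie strictly inside (0, 1)")
  }
  if (is.null(additive_effects)) additive_effects <- numeric(nrow(snp_spec))
  if (length(additive_effects) != nrow(snp_spec)) {
    stop("`additive_effects` must have one entry per SNP")
  }
  for (pp in epistatic_pairs) {
    i <- .resolve_snp(pp$snp_i, snp_spec)
    j <- .resolve_snp(pp$snp_j, snp_spec)
    if (snp_spec$chromosome[i] == snp_spec$chromosome[j]) {
      stop("planted pair ", snp_spec$snp_id[i], " x ", snp_spec$snp_id[j],
           " must lie on different chromosomes")
    }
  }
  structure(
    list(n_individuals = as.integer(n_individuals), snp_spec = snp_spec,
         mu = mu, sigma_a2 = sigma_a2, sigma_e2 = sigma_e2,
         pta_reliability = pta_reliability,
         additive_effects = additive_effects,
         epistatic_pairs = epistatic_pairs,
         family_size = as.integer(family_size), seed = seed),
    class = "sim_config"
  )
}

.resolve_snp <- function(x, snp_spec) {
  if (is.character(x)) {
    i <- match(x, snp_spec$snp_id)
    if (is.na(i)) stop("unknown SNP id in planted pair: ", x)
    i
  } else {
    i <- as.integer(x)
    if (i < 1L || i > nrow(snp_spec)) stop("SNP index out of range: ", x)
    i
  }
}

#' Two-locus genotypic-value table with a planted A-by-A effect
#'
#' Builds the 3x3 table of genotypic values
#' `g[j, l] = additive_i * j + additive_j * l +
#'   aa_magnitude * (j - 2 f1) * (l - 2 f2)`
#' whose A-by-A contrast ([compute_aa_effect()]) equals `aa_magnitude`
#' exactly under Hardy-Weinberg, linkage-equilibrium genotype frequencies
#' at allele-1 frequencies `f1`, `f2`, and whose additive margins carry no
#' interaction when `aa_magnitude = 0`.  Under this parameterization the
#' aa values factorize as `aa_ik = aa_magnitude * u_i * v_k` with
#' `u = (1 - f1, -f1)`, `v = (1 - f2, -f2)`, so AC1 and AC4 share the
#' allele of whichever locus has the more extreme frequency: the anchor
#' locus of the requested pattern must be the one with the smaller minor
#' allele frequency.  Defaults pick frequencies accordingly (0.2 for the
#' anchor, 0.4 for the partner).
#'
#' @param additive_i,additive_j allele-substitution effects of the two loci.
#' @param aa_magnitude target A-by-A contrast effect.
#' @param pattern 1 (anchor = locus i) or 2 (anchor = locus j).
#' @param freq1,freq2 allele-1 frequencies; defaults chosen to realize the
#'   requested pattern.
#' @return 3x3 matrix `g[dosage_i + 1, dosage_j + 1]` with attributes
#'   `freq1`, `freq2`, `aa_magnitude`, `pattern`.
#' @export
build_effect_table <- function(additive_i = 0, additive_j = 0,
                               aa_magnitude = 0, pattern = 1L,
                               freq1 = NULL, freq2 = NULL) {
  stopifnot(pattern %in% c(1L, 2L))
  if (is.null(freq1)) freq1 <- if (pattern == 1L) 0.2 else 0.4
  if (is.null(freq2)) freq2 <- if (pattern == 1L) 0.4 else 0.2
  if (freq1 <= 0 || freq1 >= 1 || freq2 <= 0 || freq2 >= 1) {
    stop("allele frequencies must lie strictly inside (0, 1): ",
         "a monomorphic locus has no defined A x A value")
  }
  j <- 0:2
  g <- outer(additive_i * j, additive_j * j, `+`) +
    aa_magnitude * outer(j - 2 * freq1, j - 2 * freq2)
  dimnames(g) <- list(locus1 = 0:2, locus2 = 0:2)
  if (aa_magnitude != 0) {
    got <- classify_pattern(
      compute_aa_values(.hwe_le_cells(freq1, freq2, g)),
      chr14_locus = pattern)
    if (got != "1") {
      warning("frequencies (", freq1, ", ", freq2, ") do not realize ",
              "pattern ", pattern,
              ": the anchor locus must have the smaller minor allele frequency")
    }
  }
  structure(g, freq1 = freq1, freq2 = freq2,
            aa_magnitude = aa_magnitude, pattern = as.integer(pattern))
}

# expected HWE x LE cell "counts" (unit total) for a genotypic-value table
.hwe_le_cells <- function(freq1, freq2, g) {
  hw <- function(f) c((1 - f)^2, 2 * f * (1 - f), f^2)
  two_locus_cells(counts = outer(hw(freq1), hw(freq2)), means = g,
                  v2 = NA_real_, n_total = 1)
}

#' Simulate a cohort under the scan's statistical model
#'
#' Draws genotypes per SNP as Binomial(2, maf) (Hardy-Weinberg, linkage
#' equilibrium across SNPs), a polygenic component `a` with variance
#' `sigma_a2` (optionally in half-sib family blocks), a PTA-like prediction
#' `a_tilde = r a + sqrt(r (1 - r)) sigma_a z` with squared correlation
#' `r = pta_reliability` to the true `a`, residual noise with variance
#' `sigma_e2`, and phenotype
#' `y = mu + sum(additive effects) + sum(planted A x A effects) + a + e`.
#' The identical configuration (including `seed`) reproduces the output
#' bitwise.
#'
#' @param config a [sim_config()].
#' @return a `sim_output` list with `panel` ([snp_panel()]), `cohort`
#'   ([cohort_data()]) and `truth` (the true polygenic vector, residuals,
#'   per-component phenotype parts, planted-pair genotypic-value tables and
#'   family blocks) for recovery tests.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_individuals
  spec <- config$snp_spec
  m <- nrow(spec)
  dosage <- matrix(rbinom(n * m, 2L, rep(spec$maf, each = n)), n, m)
  colnames(dosage) <- spec$snp_id
  ids <- sprintf("ind%05d", seq_len(n))
  additive <- drop(dosage %*% config$additive_effects)
  epistatic <- numeric(n)
  pair_tables <- list()
  for (pp in config$epistatic_pairs) {
    i <- .resolve_snp(pp$snp_i, spec)
    j <- .resolve_snp(pp$snp_j, spec)
    tab <- build_effect_table(0, 0, pp$aa_magnitude, pp$pattern,
                              freq1 = spec$maf[i], freq2 = spec$maf[j])
    epistatic <- epistatic + tab[cbind(dosage[, i] + 1L, dosage[, j] + 1L)]
    pair_tables[[paste(spec$snp_id[i], spec$snp_id[j], sep = ":")]] <- tab
  }
  sa <- sqrt(config$sigma_a2)
  if (config$family_size > 1L) {
    fam <- rep(seq_len(ceiling(n / config$family_size)),
               each = config$family_size)[seq_len(n)]
    a <- sa * (sqrt(0.25) * rnorm(max(fam))[fam] + sqrt(0.75) * rnorm(n))
  } else {
    fam <- NULL
    a <- rnorm(n, 0, sa)
  }
  r <- config$pta_reliability
  a_tilde <- r * a + sqrt(r * (1 - r)) * sa * rnorm(n)
  e <- rnorm(n, 0, sqrt(config$sigma_e2))
  y <- config$mu + additive + epistatic + a + e
  panel <- snp_panel(spec$snp_id, spec$chromosome, spec$position_bp,
                     maf = pmin(spec$maf, 1 - spec$maf))
  cohort <- cohort_data(ids, dosage, y, a_tilde)
  structure(
    list(panel = panel, cohort = cohort,
         truth = list(a = a, e = e, mu = config$mu, additive = additive,
                      epistatic = epistatic, pair_tables = pair_tables,
                      family = fam, config = config)),
    class = "sim_output"
  )
}

#' @export
print.sim_output <- function(x, ...) {
  cat("Simulated population:", length(x$cohort$individual_id),
      "individuals x", ncol(x$cohort$dosage), "SNPs;",
      length(x$truth$pair_tables), "planted A x A pair(s)\n")
  invisible(x)
}
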