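# Statistical core: AGLS phenotype adjustment, two-locus genotype-class
# means, allelic-combination A x A values, the A x A contrast and its t-test.

#' Subtract polygenic adjustments from yield deviations
#'
#' Computes the AGLS-adjusted phenotype `y* = y - a_tilde`, where `a_tilde`
#' is the polygenic prediction (2 x PTA) for each individual and `y` is the
#' yield deviation (phenotype with fixed non-genetic effects pre-removed).
#' One record per individual, so the polygenic design matrix is the identity.
#'
#' @param y numeric vector of yield deviations.
#' @param a_tilde numeric vector of polygenic adjustments, same length.
#' @return numeric vector `y - a_tilde`.
#' @export
#' @examples
#' adjust_phenotypes(c(1, 2, 3), c(0.5, 0.5, 0.5))
adjust_phenotypes <- function(y, a_tilde) {
  if (length(y) != length(a_tilde)) {
    stop("`y` (", length(y), ") and `a_tilde` (", length(a_tilde),
         ") must have the same length")
  }
  as.numeric(y) - as.numeric(a_tilde)
}

#' Two-locus genotype-class summary
#'
#' Container for the nine two-locus genotype classes of a SNP pair: cell
#' counts, estimated genotypic values (cell means of the adjusted
#' phenotype), the residual variance estimate and the rank of the
#' cell-means design.  Cells are indexed by the allele-1 dosage at each
#' locus (0, 1, 2), locus 1 in rows.
#'
#' @param counts 3x3 numeric matrix of cell counts (row = dosage at locus 1).
#' @param means 3x3 numeric matrix of genotypic-value estimates; `NA` where
#'   the cell is empty.  Entries at empty cells are ignored.
#' @param v2 residual variance estimate (`NA` if not available).
#' @param n_total total number of individuals; defaults to `sum(counts)`.
#' @return an object of class `two_locus_cells`.
#' @seealso [fit_two_locus_means()] which estimates all components from data.
#' @export
two_locus_cells <- function(counts, means, v2 = NA_real_,
                            n_total = sum(counts)) {
  counts <- matrix(as.numeric(counts), 3L, 3L,
                   dimnames = list(locus1 = 0:2, locus2 = 0:2))
  means <- matrix(as.numeric(means), 3L, 3L,
                  dimnames = list(locus1 = 0:2, locus2 = 0:2))
  if (any(counts < 0)) stop("cell counts must be non-negative")
  means[counts == 0] <- NA_real_
  if (any(counts > 0 & is.na(means))) {
    stop("genotypic values must be defined for all non-empty cells")
  }
  k <- sum(counts > 0)
  structure(
    list(counts = counts, means = means, n_total = n_total,
         k_rank = k, df = n_total - k, v2 = v2),
    class = "two_locus_cells"
  )
}

#' @export
print.two_locus_cells <- function(x, ...) {
  cat("Two-locus genotype classes: n =", x$n_total,
      "| non-empty cells =", x$k_rank, "| v2 =", format(x$v2), "\n")
  cat("counts:\n"); print(x$counts)
  cat("genotypic values:\n"); print(round(x$means, 4))
  invisible(x)
}

#' Estimate the nine two-locus genotypic values by least squares
#'
#' Fits the cell-means model for one SNP pair to the AGLS-adjusted
#' phenotypes: the estimate for each of the nine genotype classes is the
#' within-cell mean of `y_star` (the closed form of the least-squares fit
#' with a generalized inverse), and the residual variance is
#' `v2 = RSS / (n - k)` with `k` the number of non-empty cells (the
#' cell-means parameterization absorbs the overall mean).
#'
#' @param y_star numeric vector of adjusted phenotypes (see
#'   [adjust_phenotypes()]).
#' @param dosage_i,dosage_j integer vectors of allele-1 dosages (0/1/2) at
#'   the two loci, aligned with `y_star`.
#' @return a [two_locus_cells()] object.
#' @export
fit_two_locus_means <- function(y_star, dosage_i, dosage_j) {
  n <- length(y_star)
  if (n == 0L) stop("no observations")
  if (length(dosage_i) != n || length(dosage_j) != n) {
    stop("dosage vectors must match the length of `y_star`")
  }
  .check_dosage(dosage_i, "dosage_i")
  .check_dosage(dosage_j, "dosage_j")
  cell <- 3L * as.integer(dosage_i) + as.integer(dosage_j) + 1L
  counts <- tabulate(cell, nbins = 9L)
  sums <- numeric(9L)
  rs <- rowsum(y_star, cell)
  sums[as.integer(rownames(rs))] <- rs[, 1L]
  means <- rep(NA_real_, 9L)
  nz <- counts > 0L
  means[nz] <- sums[nz] / counts[nz]
  k <- sum(nz)
  tss <- sum(y_star^2)
  rss <- max(tss - sum(sums[nz]^2 / counts[nz]), 0)
  if (rss < 1e-12 * tss) rss <- 0  # exact fit up to floating-point noise
  v2 <- if (n > k) rss / (n - k) else NA_real_
  two_locus_cells(
    counts = matrix(counts, 3L, 3L, byrow = TRUE),
    means = matrix(means, 3L, 3L, byrow = TRUE),
    v2 = v2, n_total = n
  )
}

.check_dosage <- function(d, what) {
  bad <- which(!(d %in% c(0L, 1L, 2L)))
  if (length(bad)) {
    stop("`", what, "` contains non-{0,1,2} value ", d[bad[1L]],
         " at position ", bad[1L])
  }
  invisible(TRUE)
}

# allele-copy weights: row i = copies of allele i carried at dosage 0,1,2
.allele_copies <- rbind(`1` = c(0, 1, 2), `2` = c(2, 1, 0))

.combination_weights <- function(counts) {
  C <- .allele_copies
  W <- C %*% counts %*% t(C)
  dimnames(W) <- list(locus1 = c("1", "2"), locus2 = c("1", "2"))
  W
}

.stop_inestimable <- function(msg) {
  stop(structure(
    class = c("aaxscan_inestimable", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Allelic-combination A-by-A values of a SNP pair
#'
#' Computes, from the nine genotype-class means, the four
#' allelic-combination means, the two pairs of allele means, the population
#' mean, the additive allele values and the four A-by-A values
#' `aa_ik = mu_ik - mu - a_i - a_k`.  All means are dosage-weighted means of
#' cell means: a cell with dosages (j, k) and count n_jk contributes weight
#' `n_jk * j * k` to the allele-1/allele-1 combination, and a heterozygote
#' contributes one copy to each allele class.  The four combinations are
#' ranked AC1..AC4 from the most positive to the most negative A-by-A value;
#' ties are broken by the lexicographic combination label and flagged.
#'
#' @param cells a [two_locus_cells()] object.
#' @return an object of class `aa_table`: a list with `values` (2x2 matrix of
#'   aa values, allele 1 first), `table` (one row per combination with label,
#'   weight fraction and aa value), `ranking` (labels of AC1..AC4), `mu`,
#'   `allele_means`, `additive_values`, `freq` (combination weight
#'   fractions), and `tied` (logical tie flag).
#' @export
compute_aa_values <- function(cells) {
  N <- cells$counts
  G <- cells$means
  G0 <- ifelse(is.na(G), 0, G)
  C <- .allele_copies
  W <- .combination_weights(N)
  if (any(W <= 0)) {
    .stop_inestimable(
      "a locus is monomorphic in this pair's data: undefined allele mean")
  }
  S <- C %*% (N * G0) %*% t(C)
  mu_ik <- S / W
  mu_i <- rowSums(S) / rowSums(W)
  mu_k <- colSums(S) / colSums(W)
  mu <- sum(S) / sum(W)
  a_i <- mu_i - mu
  a_k <- mu_k - mu
  aa <- mu_ik - mu - outer(a_i, a_k, `+`)
  labs <- outer(c("1", "2"), c("1", "2"), paste, sep = "_")
  ord <- order(-as.vector(aa), as.vector(labs))
  tab <- data.frame(
    label = c("1_1", "1_2", "2_1", "2_2"),
    allele_locus1 = c(1L, 1L, 2L, 2L),
    allele_locus2 = c(1L, 2L, 1L, 2L),
    freq = c(W[1, 1], W[1, 2], W[2, 1], W[2, 2]) / sum(W),
    aa = c(aa[1, 1], aa[1, 2], aa[2, 1], aa[2, 2]),
    stringsAsFactors = FALSE
  )
  structure(
    list(values = aa, table = tab,
         ranking = as.vector(labs)[ord],
         mu = mu,
         allele_means = list(locus1 = mu_i, locus2 = mu_k),
         additive_values = list(locus1 = a_i, locus2 = a_k),
         combination_means = mu_ik,
         freq = W / sum(W),
         tied = anyDuplicated(as.vector(aa)) > 0L),
    class = "aa_table"
  )
}

#' @export
print.aa_table <- function(x, ...) {
  cat("A x A values (allelic combinations, allele 1 first):\n")
  print(round(x$values, 6))
  cat("ranking AC1..AC4:", paste(x$ranking, collapse = " > "))
  if (x$tied) cat("  [tied, lexicographic tie-break]")
  cat("\n")
  invisible(x)
}

#' A-by-A contrast effect from the four A-by-A values
#'
#' The epistasis effect of a SNP pair is the contrast
#' `alpha_alpha = [aa_11 - aa_12] - [aa_21 - aa_22]` of the four
#' allelic-combination A-by-A values, with allele 1 (the first allele of the
#' SNP map) ordered first at both loci.  The same quantity equals the double
#' difference of the four allelic-combination means, and the contrast
#' `s %*% g_hat` over the nine genotypic values (see [build_contrast()]).
#'
#' @param aa an `aa_table` from [compute_aa_values()], or a bare 2x2 matrix
#'   of aa values (allele 1 first on both margins).
#' @return an object of class `aa_effect` carrying `alpha_alpha`; the
#'   test-statistic fields are `NA` until [t_test_aa()] fills them.
#' @export
compute_aa_effect <- function(aa) {
  v <- if (inherits(aa, "aa_table")) aa$values else as.matrix(aa)
  if (!all(dim(v) == c(2L, 2L))) stop("need the four A x A values")
  alpha <- (v[1, 1] - v[1, 2]) - (v[2, 1] - v[2, 2])
  structure(
    list(alpha_alpha = alpha, se = NA_real_, t = NA_real_, df = NA_real_,
         log10_inv_p = NA_real_, contrast = NULL, status = "effect_only"),
    class = "aa_effect"
  )
}

#' @export
print.aa_effect <- function(x, ...) {
  cat("A x A effect:", format(x$alpha_alpha, digits = 6))
  if (!is.na(x$t)) {
    cat("  se =", format(x$se, digits = 4),
        " t =", format(x$t, digits = 5),
        " log10(1/p) =", format(x$log10_inv_p, digits = 6))
  }
  cat("  [", x$status, "]\n", sep = "")
  invisible(x)
}

#' A-by-A contrast coefficients over the nine genotype classes
#'
#' Derives the row vector of contrast coefficients `s` such that
#' `sum(s * g_hat)` equals the A-by-A effect of [compute_aa_effect()] under
#' the same dosage weighting: the coefficient of cell (j, k) with count
#' n_jk is `n_jk * sum_{i,l} sign_il * c_i(j) * c_l(k) / W_il`, where
#' `c_i(j)` counts copies of allele i at dosage j, `W_il` are the
#' combination weights and the signs follow the (+,-,-,+) pattern of the
#' contrast.  With equal counts in all nine cells the coefficients reduce to
#' the Kronecker product of the additive contrasts (corner pattern
#' +1/0/-1).  Coefficients sum to zero.
#'
#' @param cells a [two_locus_cells()] object.
#' @return 3x3 numeric matrix of coefficients (zero at empty cells).
#' @export
build_contrast <- function(cells) {
  N <- cells$counts
  C <- .allele_copies
  W <- .combination_weights(N)
  if (any(W <= 0)) {
    .stop_inestimable("contrast is not estimable: empty marginal allele class")
  }
  sgn <- matrix(c(1, -1, -1, 1), 2L, 2L, byrow = TRUE)
  s <- matrix(0, 3L, 3L)
  for (i in 1:2) {
    for (l in 1:2) {
      s <- s + sgn[i, l] * outer(C[i, ], C[l, ]) / W[i, l]
    }
  }
  s <- s * N
  dimnames(s) <- dimnames(N)
  s
}

#' t-test of the A-by-A contrast
#'
#' Computes `t = |L| / se` with `L = sum(s * g_hat)` and
#' `se = sqrt(v2 * sum(s^2 / n))` (the cell-means design makes `X'X` the
#' diagonal matrix of cell counts), and the two-sided significance as
#' log10(1/p) from the t distribution with `n - k` degrees of freedom.  The
#' tail probability is evaluated in log space, so values such as
#' log10(1/p) = 70 are returned accurately instead of underflowing to
#' `p = 0`.
#'
#' @param cells a [two_locus_cells()] object with `v2` estimated.
#' @param contrast coefficient matrix from [build_contrast()].
#' @return an `aa_effect` object with `status` one of `"tested"` (regular
#'   case), `"degenerate"` (`v2 = 0` with a non-zero contrast: infinite t,
#'   flagged rather than silently dropped).
#' @export
t_test_aa <- function(cells, contrast) {
  G0 <- ifelse(is.na(cells$means), 0, cells$means)
  L <- sum(contrast * G0)
  nz <- cells$counts > 0
  q <- sum(contrast[nz]^2 / cells$counts[nz])
  v2 <- cells$v2
  df <- cells$df
  if (!is.na(v2) && v2 > 0 && df > 0) {
    se <- sqrt(v2 * q)
    tstat <- abs(L) / se
    l10 <- log10_inv_p(tstat, df)
    status <- "tested"
  } else if (L == 0) {
    se <- 0; tstat <- 0; l10 <- 0
    status <- "tested"
  } else {
    se <- 0; tstat <- Inf; l10 <- Inf
    status <- "degenerate"
  }
  structure(
    list(alpha_alpha = L, se = se, t = tstat, df = df,
         log10_inv_p = l10, contrast = contrast, status = status),
    class = "aa_effect"
  )
}

#' Extreme-tail log10(1/p) for a two-sided t-test
#'
#' `-log10` of the two-sided tail probability of the t distribution,
#' computed entirely in log space (`pt(..., log.p = TRUE)`), valid far
#' beyond the double-precision underflow limit of `2 * pt(-t, df)`.
#'
#' @param t absolute t statistic (vectorized).
#' @param df degrees of freedom.
#' @return numeric vector of log10(1/p) values, floored at 0.
#' @export
#' @examples
#' log10_inv_p(18, 1e6)   # about 71.7
log10_inv_p <- function(t, df) {
  lp <- pt(-abs(t), df = df, log.p = TRUE) + log(2)
  pmax(0, -lp / log(10))
}

#' Classify the AC1/AC4 allele-sharing pattern of a SNP pair
#'
#' For significant pairs involving the focal (Chr14) region, the two
#' extreme allelic combinations AC1 and AC4 share an allele at one locus:
#' pattern 1 when they share the focal-locus allele (one Chr14 allele
#' interacting with both alleles of the partner SNP), pattern 2 when they
#' share the partner-locus allele.  `"other"` marks the never-observed case
#' of completely different alleles.
#'
#' @param aa an `aa_table` from [compute_aa_values()].
#' @param chr14_locus which locus of the pair (1 or 2) lies on the focal
#'   chromosome.
#' @return `"1"`, `"2"` or `"other"`; if the aa ranking was tied the result
#'   carries attribute `tied = TRUE` (the class then depends on the
#'   deterministic lexicographic tie-break).
#' @export
classify_pattern <- function(aa, chr14_locus = 1L) {
  stopifnot(chr14_locus %in% c(1L, 2L))
  ac1 <- strsplit(aa$ranking[1L], "_", fixed = TRUE)[[1L]]
  ac4 <- strsplit(aa$ranking[4L], "_", fixed = TRUE)[[1L]]
  shared <- c(ac1[1L] == ac4[1L], ac1[2L] == ac4[2L])
  out <- if (xor(shared[1L], shared[2L])) {
    anchor <- which(shared)
    if (anchor == chr14_locus) "1" else "2"
  } else {
    "other"
  }
  if (isTRUE(aa$tied)) attr(out, "tied") <- TRUE
  out
}

#' Full A-by-A test of one SNP pair
#'
#' Convenience wrapper running [fit_two_locus_means()],
#' [compute_aa_values()], [build_contrast()] and [t_test_aa()] for a single
#' pair of dosage vectors.
#'
#' @inheritParams fit_two_locus_means
#' @param min_cell_count optional floor on non-empty cell counts; pairs with
#'   an occupied cell below the floor are rejected as inestimable
#'   (default 0: estimability of the contrast is the only requirement).
#' @return a list of class `aa_test` with elements `cells`, `aa` and
#'   `effect`.  Signals a condition of class `aaxscan_inestimable` when the
#'   contrast cannot be estimated.
#' @export
test_pair <- function(y_star, dosage_i, dosage_j, min_cell_count = 0L) {
  cells <- fit_two_locus_means(y_star, dosage_i, dosage_j)
  if (min_cell_count > 0 &&
      any(cells$counts > 0 & cells$counts < min_cell_count)) {
    .stop_inestimable(
      paste0("occupied cell below the minimum count of ", min_cell_count))
  }
  s <- build_contrast(cells)
  eff <- t_test_aa(cells, s)
  aa <- compute_aa_values(cells)
  structure(list(cells = cells, aa = aa, effect = eff), class = "aa_test")
}

#' @export
print.aa_test <- function(x, ...) {
  print(x$effect)
  invisible(x)
}
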