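# The statistical core: cell means, A x A values, contrast, t-test,
# pattern classification, and their algebraic invariants.

test_that("phenotype adjustment is elementwise subtraction", {
  y <- rnorm(100); a <- rnorm(100)
  expect_equal(adjust_phenotypes(y, a), y - a)
  expect_equal(adjust_phenotypes(y, numeric(100)), y)
  expect_equal(adjust_phenotypes(y, y), numeric(100))
  expect_error(adjust_phenotypes(y, a[-1]), "length")
})

test_that("cell means equal an independent split-apply oracle", {
  set.seed(1)
  n <- 200L
  d1 <- rbinom(n, 2, 0.4); d2 <- rbinom(n, 2, 0.3)
  y <- rnorm(n)
  cells <- fit_two_locus_means(y, d1, d2)
  for (j in 0:2) for (l in 0:2) {
    sel <- d1 == j & d2 == l
    if (any(sel)) {
      expect_equal(cells$means[j + 1, l + 1], mean(y[sel]), tolerance = 1e-12)
      expect_equal(cells$counts[j + 1, l + 1], sum(sel))
    } else {
      expect_true(is.na(cells$means[j + 1, l + 1]))
    }
  }
  # residual variance against the lm() cell-means fit
  fit <- lm(y ~ 0 + factor(3 * d1 + d2))
  expect_equal(cells$v2, summary(fit)$sigma^2, tolerance = 1e-12)
  expect_equal(cells$df, fit$df.residual)
})

test_that("degenerate inputs give the closed-form corner cases", {
  cells <- fit_two_locus_means(rep(2.5, 30), rep(2L, 30), rep(2L, 30))
  expect_equal(cells$means[3, 3], 2.5)
  expect_equal(cells$k_rank, 1L)
  expect_equal(cells$v2, 0)
  expect_true(all(is.na(cells$means[-9])))

  z <- fit_two_locus_means(numeric(40), rbinom(40, 2, .5), rbinom(40, 2, .5))
  expect_equal(z$v2, 0)
  expect_true(all(z$means[z$counts > 0] == 0))

  expect_error(fit_two_locus_means(c(1, 2), c(0L, 3L), c(1L, 1L)),
               "non-\\{0,1,2\\}.*position 2")
})

test_that("aa values match the brute-force allele-copy oracle", {
  # the worked single-cell table: g_22 = 1, all other cells 0, HWE p = q = 0.5
  counts <- 16 * outer(c(1, 2, 1) / 4, c(1, 2, 1) / 4)
  means <- matrix(0, 3, 3); means[3, 3] <- 1
  cells <- two_locus_cells(counts, means, v2 = 1)
  aa <- compute_aa_values(cells)
  expect_equal(aa$values, brute_aa(counts, means),
               ignore_attr = TRUE, tolerance = 1e-12)

  # and on arbitrary random tables
  set.seed(2)
  for (r in 1:25) {
    cl <- random_cells()
    expect_equal(compute_aa_values(cl)$values, brute_aa(cl$counts, cl$means),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("a purely additive table has zero aa values at any frequencies", {
  set.seed(3)
  for (r in 1:20) {
    f1 <- runif(1, 0.05, 0.95); f2 <- runif(1, 0.05, 0.95)
    g <- outer(runif(1, -1, 1) * (0:2) + runif(1), runif(1, -1, 1) * (0:2),
               `+`)
    aa <- compute_aa_values(hwe_cells(f1, f2, g))
    expect_lt(max(abs(aa$values)), 1e-12)
  }
})

test_that("weighted marginal sums of aa values vanish", {
  set.seed(4)
  # row/column-wise under factorized (linkage-equilibrium) counts
  for (r in 1:20) {
    f1 <- runif(1, 0.1, 0.9); f2 <- runif(1, 0.1, 0.9)
    aa <- compute_aa_values(hwe_cells(f1, f2, matrix(rnorm(9), 3, 3)))
    p1 <- rowSums(aa$freq); p2 <- colSums(aa$freq)
    expect_lt(max(abs(aa$values %*% p2)), 1e-10)
    expect_lt(max(abs(p1 %*% aa$values)), 1e-10)
  }
  # overall, for arbitrary joint counts
  for (r in 1:20) {
    aa <- compute_aa_values(random_cells())
    expect_lt(abs(sum(aa$freq * aa$values)), 1e-10)
  }
})

test_that("all algebraic forms of the contrast agree on random tables", {
  set.seed(5)
  for (r in 1:100) {
    cl <- random_cells()
    aa <- compute_aa_values(cl)
    v <- aa$values; m <- aa$combination_means
    f1 <- (v[1, 1] - v[1, 2]) - (v[2, 1] - v[2, 2])
    f2 <- (v[1, 1] - v[2, 1]) - (v[1, 2] - v[2, 2])
    f3 <- (m[1, 1] - m[1, 2]) - (m[2, 1] - m[2, 2])
    f4 <- (m[1, 1] - m[2, 1]) - (m[1, 2] - m[2, 2])
    f5 <- sum(build_contrast(cl) * cl$means)
    expect_equal(compute_aa_effect(aa)$alpha_alpha, f1, tolerance = 1e-12)
    expect_equal(f2, f1, tolerance = 1e-12)
    expect_equal(f3, f1, tolerance = 1e-12)
    expect_equal(f4, f1, tolerance = 1e-12)
    expect_equal(f5, f1, tolerance = 1e-12)
  }
})

test_that("equal cell counts reduce the contrast to the Kronecker form", {
  cl <- two_locus_cells(matrix(7, 3, 3), matrix(rnorm(9), 3, 3), v2 = 1)
  s <- build_contrast(cl)
  kron <- outer(c(-1, 0, 1), c(-1, 0, 1))
  expect_equal(s / s[3, 3], kron / kron[3, 3], ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("contrast coefficients always sum to zero", {
  set.seed(6)
  for (r in 1:25) {
    expect_lt(abs(sum(build_contrast(random_cells()))), 1e-12)
  }
})

test_that("the contrast is rejected as inestimable for a monomorphic locus", {
  counts <- matrix(0, 3, 3); counts[3, ] <- c(5, 10, 5)  # locus 1 all dosage 2
  cl <- two_locus_cells(counts, matrix(1, 3, 3), v2 = 1)
  expect_error(build_contrast(cl), class = "aaxscan_inestimable")
  expect_error(compute_aa_values(cl), class = "aaxscan_inestimable")
})

test_that("the t statistic matches an independent least-squares oracle", {
  set.seed(7)
  n <- 60L
  d1 <- rbinom(n, 2, 0.5); d2 <- rbinom(n, 2, 0.5)
  y <- rnorm(n) + 0.3 * d1 * d2
  fit <- test_pair(y, d1, d2)
  t_oracle <- oracle_contrast_t(y, d1, d2, fit$effect$contrast)
  expect_equal(fit$effect$t, t_oracle, tolerance = 1e-10)

  # and again on a larger draw with unequal frequencies
  n <- 500L
  d1 <- rbinom(n, 2, 0.2); d2 <- rbinom(n, 2, 0.35)
  y <- rnorm(n)
  fit <- test_pair(y, d1, d2)
  expect_equal(fit$effect$t, oracle_contrast_t(y, d1, d2, fit$effect$contrast),
               tolerance = 1e-10)
})

test_that("a null contrast gives t = 0 and log10(1/p) = 0", {
  cl <- two_locus_cells(matrix(4, 3, 3), matrix(1.7, 3, 3), v2 = 0.5)
  eff <- t_test_aa(cl, build_contrast(cl))
  expect_equal(eff$alpha_alpha, 0)
  expect_equal(eff$t, 0)
  expect_equal(eff$log10_inv_p, 0)
})

test_that("zero residual variance with a non-null contrast is flagged", {
  g <- matrix(rnorm(9), 3, 3)
  d1 <- rep(0:2, each = 60); d2 <- rep(rep(0:2, each = 20), 3)
  y <- g[cbind(d1 + 1, d2 + 1)]  # exact cell means, zero residual
  fit <- test_pair(y, d1, d2)
  expect_equal(fit$effect$status, "degenerate")
  expect_true(is.infinite(fit$effect$t))
})

test_that("extreme tails are computed without underflow", {
  expect_equal(log10_inv_p(0, 1000), 0)
  # p far below the double-precision underflow limit of 2*pt(-t, df)
  expect_gt(log10_inv_p(60, 1e6), 700)
  expect_true(is.finite(log10_inv_p(60, 1e6)))
})

test_that("relabeling alleles flips the effect sign but not significance", {
  set.seed(8)
  for (r in 1:10) {
    n <- 300L
    d1 <- rbinom(n, 2, runif(1, 0.2, 0.8))
    d2 <- rbinom(n, 2, runif(1, 0.2, 0.8))
    y <- rnorm(n) + 0.2 * (d1 - 1) * (d2 - 1)
    a <- test_pair(y, d1, d2)$effect
    b <- test_pair(y, 2L - d1, d2)$effect
    expect_equal(b$alpha_alpha, -a$alpha_alpha, tolerance = 1e-12)
    expect_equal(b$t, a$t, tolerance = 1e-12)
    expect_equal(b$log10_inv_p, a$log10_inv_p, tolerance = 1e-12)
  }
})

test_that("swapping the locus order leaves effect, t and pattern intact", {
  set.seed(9)
  for (r in 1:10) {
    n <- 300L
    d1 <- rbinom(n, 2, 0.25); d2 <- rbinom(n, 2, 0.45)
    y <- rnorm(n) + 0.3 * (d1 - 0.5) * (d2 - 0.8)
    a <- test_pair(y, d1, d2)
    b <- test_pair(y, d2, d1)
    expect_equal(b$effect$alpha_alpha, a$effect$alpha_alpha,
                 tolerance = 1e-12)
    expect_equal(b$effect$t, a$effect$t, tolerance = 1e-12)
    pa <- classify_pattern(a$aa, chr14_locus = 1L)
    pb <- classify_pattern(b$aa, chr14_locus = 2L)
    expect_equal(as.character(pa), as.character(pb))
  }
})

test_that("AGLS with the exact BLUP equals explicit V-inverse GLS", {
  set.seed(10)
  n <- 200L
  s2a <- 0.4; s2e <- 0.6
  spec <- snp_grid(2, 2); spec$maf <- c(0.4, 0.5)
  sim <- simulate_population(sim_config(
    n, spec, sigma_a2 = s2a, sigma_e2 = s2e, family_size = 5L, seed = 10,
    epistatic_pairs = list(planted_pair(1, 2, 0.4, 1))))
  d1 <- sim$cohort$dosage[, 1]; d2 <- sim$cohort$dosage[, 2]
  y <- sim$cohort$y
  fam <- sim$truth$family
  A <- outer(fam, fam, `==`) * 0.25 + diag(0.75, n)
  V <- s2a * A + s2e * diag(n)
  cell <- factor(3 * d1 + d2, levels = 0:8)
  X <- model.matrix(~ 0 + cell)
  X <- X[, colSums(X) > 0, drop = FALSE]
  Vi <- solve(V)
  b_gls <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  a_blup <- s2a * A %*% Vi %*% (y - X %*% b_gls)
  cells <- fit_two_locus_means(drop(y - a_blup), d1, d2)
  b_agls <- t(cells$means)[t(cells$counts) > 0]  # row-major = cell code order
  expect_equal(unname(b_agls), unname(drop(b_gls)), tolerance = 1e-8)
})

test_that("pattern classification follows the AC1/AC4 shared allele", {
  mk <- function(ranking) {
    structure(list(ranking = ranking, tied = FALSE), class = "aa_table")
  }
  # shared locus-1 allele, locus 1 focal -> pattern 1
  expect_equal(classify_pattern(mk(c("1_1", "2_1", "2_2", "1_2")), 1L), "1")
  # shared locus-2 allele, locus 1 focal -> pattern 2
  expect_equal(classify_pattern(mk(c("1_1", "2_2", "1_2", "2_1")), 1L), "2")
  # same rankings seen from the other locus
  expect_equal(classify_pattern(mk(c("1_1", "2_1", "2_2", "1_2")), 2L), "2")
  # completely different alleles
  expect_equal(classify_pattern(mk(c("1_1", "1_2", "2_1", "2_2")), 1L),
               "other")
})

test_that("published example pairs classify to their reported patterns", {
  t7 <- read.delim(aa_fixture_path("aa_chr14a_sgn"))
  t8 <- read.delim(aa_fixture_path("aa_chr14b"))
  mk <- function(row) {
    structure(list(ranking = unlist(row[c("ac1", "ac2", "ac3", "ac4")]),
                   tied = FALSE), class = "aa_table")
  }
  r7 <- t7[t7$snp1 == "rs109146371" & t7$snp2 == "rs42766480", ]
  expect_equal(classify_pattern(mk(r7), 1L), "1")
  r8 <- t8[t8$snp1 == "rs134537992" & t8$snp2 == "rs42368654", ]
  expect_equal(classify_pattern(mk(r8), 1L), "2")
  # every Chr14a x SGN example row shares the Chr14 allele (pattern 1)
  expect_true(all(vapply(seq_len(nrow(t7)), function(r) {
    classify_pattern(mk(t7[r, ]), 1L)
  }, character(1)) == "1"))
})

test_that("tied aa rankings are flagged and broken lexicographically", {
  # perfectly symmetric table: aa values +c, -c, -c, +c
  cl <- hwe_cells(0.5, 0.5, outer(0:2 - 1, 0:2 - 1) * 0.4)
  aa <- compute_aa_values(cl)
  expect_true(aa$tied)
  expect_equal(aa$ranking[1], "1_1")  # lexicographic among the tied pair
  expect_true(isTRUE(attr(classify_pattern(aa, 1L), "tied")))
})
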