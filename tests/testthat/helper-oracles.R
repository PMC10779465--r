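# Independent oracles and small fixture builders used across the suite.
# Each oracle deliberately takes a different code path from the package
# implementation it checks.

# Brute-force evaluation of the allelic-combination decomposition by
# explicit loops over cells and allele copies (no matrix algebra).
brute_aa <- function(counts, means) {
  copies <- function(allele, dosage) if (allele == 1L) dosage else 2L - dosage
  Wc <- matrix(0, 2, 2); Sc <- matrix(0, 2, 2)
  Wi <- numeric(2); Si <- numeric(2)
  Wk <- numeric(2); Sk <- numeric(2)
  Wt <- 0; St <- 0
  for (j in 0:2) for (l in 0:2) {
    n <- counts[j + 1, l + 1]
    if (n == 0) next
    g <- means[j + 1, l + 1]
    for (i in 1:2) for (k in 1:2) {
      w <- copies(i, j) * copies(k, l) * n
      Wc[i, k] <- Wc[i, k] + w
      Sc[i, k] <- Sc[i, k] + w * g
    }
    for (i in 1:2) {
      w <- copies(i, j) * 2 * n  # each individual carries 2 copies at locus 2
      Wi[i] <- Wi[i] + w; Si[i] <- Si[i] + w * g
    }
    for (k in 1:2) {
      w <- copies(k, l) * 2 * n
      Wk[k] <- Wk[k] + w; Sk[k] <- Sk[k] + w * g
    }
    Wt <- Wt + 4 * n; St <- St + 4 * n * g
  }
  mu <- St / Wt
  mu_i <- Si / Wi; mu_k <- Sk / Wk
  aa <- matrix(NA_real_, 2, 2)
  for (i in 1:2) for (k in 1:2) {
    aa[i, k] <- Sc[i, k] / Wc[i, k] - mu - (mu_i[i] - mu) - (mu_k[k] - mu)
  }
  aa
}

# t statistic of a cell-mean contrast from an ordinary lm() fit.
oracle_contrast_t <- function(y, d1, d2, s) {
  code <- 3L * d1 + d2 + 1L
  cell <- factor(code)
  fit <- lm(y ~ 0 + cell)
  svec <- as.vector(t(s))           # svec[code] = s[d1+1, d2+1]
  w <- svec[as.integer(levels(cell))]
  est <- sum(w * coef(fit))
  se <- sqrt(drop(t(w) %*% vcov(fit) %*% w))
  abs(est) / se
}

# expected two-locus cell table under Hardy-Weinberg + linkage equilibrium
hwe_cells <- function(freq1, freq2, g, n = 1) {
  hw <- function(f) c((1 - f)^2, 2 * f * (1 - f), f^2)
  two_locus_cells(counts = n * outer(hw(freq1), hw(freq2)), means = g,
                  v2 = NA_real_, n_total = n)
}

random_cells <- function(min_count = 5L, max_count = 60L) {
  two_locus_cells(
    counts = matrix(sample(min_count:max_count, 9L, replace = TRUE), 3L, 3L),
    means = matrix(rnorm(9), 3L, 3L),
    v2 = NA_real_
  )
}

# tiny 3-cow, 2-SNP on-disk fixture in the canonical TSV dialect
write_tiny_fixture <- function(dir, bad_dosage = FALSE) {
  gpath <- file.path(dir, "geno.tsv")
  ppath <- file.path(dir, "pheno.tsv")
  mpath <- file.path(dir, "map.tsv")
  d <- if (bad_dosage) "3" else "2"
  writeLines(c("individual_id\tsnpA\tsnpB",
               "cow1\t0\t1",
               paste0("cow2\t1\t", d),
               "cow3\t2\t0"), gpath)
  writeLines(c("individual_id\ty\ta_tilde",
               "cow1\t1.5\t0.2",
               "cow2\t-0.3\t-0.1",
               "cow3\t0.8\t0.0"), ppath)
  writeLines(c("snp_id\tchromosome\tposition_bp\tallele1\tallele2",
               "snpA\t1\t1000\tA\tG",
               "snpB\t2\t2000\tC\tT"), mpath)
  list(genotypes = gpath, phenotypes = ppath, map = mpath)
}
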