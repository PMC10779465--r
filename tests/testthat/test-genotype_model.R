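# Panel/cohort containers, TSV and PLINK I/O, MAF filtering.

test_that("the TSV trio round-trips through write_cohort/load_cohort", {
  dir <- withr::local_tempdir()
  f <- write_tiny_fixture(dir)
  loaded <- load_cohort(f$genotypes, f$phenotypes, f$map)
  expect_s3_class(loaded$panel, "snp_panel")
  expect_equal(nrow(loaded$panel), 2L)
  expect_equal(dim(loaded$cohort$dosage), c(3L, 2L))
  expect_equal(loaded$cohort$y, c(1.5, -0.3, 0.8))

  write_cohort(loaded$panel, loaded$cohort, file.path(dir, "rt"))
  again <- load_cohort(file.path(dir, "rt_genotypes.tsv"),
                       file.path(dir, "rt_phenotypes.tsv"),
                       file.path(dir, "rt_map.tsv"))
  expect_equal(as.data.frame(again$panel), as.data.frame(loaded$panel))
  expect_equal(again$cohort$dosage, loaded$cohort$dosage)
  expect_equal(again$cohort$y, loaded$cohort$y)
  expect_equal(again$cohort$a_tilde, loaded$cohort$a_tilde)
})

test_that("invalid dosages are rejected with cell context", {
  dir <- withr::local_tempdir()
  f <- write_tiny_fixture(dir, bad_dosage = TRUE)
  expect_error(load_cohort(f$genotypes, f$phenotypes, f$map),
               "3.*cow2.*snpB")
})

test_that("SNP id disagreement between genotypes and map is rejected", {
  dir <- withr::local_tempdir()
  f <- write_tiny_fixture(dir)
  m <- readLines(f$map)
  writeLines(sub("snpB", "snpZ", m), f$map)
  expect_error(load_cohort(f$genotypes, f$phenotypes, f$map), "snp")
})

test_that("PLINK .raw/.bim dialect loads and orients to the map allele", {
  dir <- withr::local_tempdir()
  bim <- file.path(dir, "g.bim")
  raw <- file.path(dir, "g.raw")
  phe <- file.path(dir, "p.tsv")
  writeLines(c("1\tsnpA\t0\t1000\tA\tG",
               "2\tsnpB\t0\t2000\tC\tT"), bim)
  # snpA counts the bim allele1 (A); snpB counts the OTHER allele (T)
  writeLines(c("FID IID PAT MAT SEX PHENOTYPE snpA_A snpB_T",
               "f1 cow1 0 0 2 -9 0 1",
               "f1 cow2 0 0 2 -9 1 0",
               "f1 cow3 0 0 2 -9 2 2"), raw)
  writeLines(c("individual_id\ty\ta_tilde",
               "cow1\t1\t0", "cow2\t2\t0", "cow3\t3\t0"), phe)
  loaded <- load_cohort(raw, phe, bim, format = "plink")
  expect_equal(unname(loaded$cohort$dosage[, "snpA"]), c(0L, 1L, 2L))
  # snpB dosages flipped so they count allele1 = C
  expect_equal(unname(loaded$cohort$dosage[, "snpB"]), c(1L, 2L, 0L))
})

test_that("MAF filter agrees with an independent per-SNP counting oracle", {
  set.seed(11)
  n <- 400L
  m <- 1000L
  true_maf <- runif(m, 0.005, 0.5)
  dosage <- matrix(rbinom(n * m, 2L, rep(true_maf, each = n)), n, m)
  colnames(dosage) <- sprintf("s%04d", seq_len(m))
  panel <- snp_panel(colnames(dosage), rep(1L, m), seq_len(m))
  cohort <- cohort_data(sprintf("i%03d", 1:n), dosage, rnorm(n), rnorm(n))

  flt <- filter_maf(panel, cohort, 0.05)

  # oracle: tabulate genotype classes per SNP and count alleles directly
  keep_oracle <- vapply(seq_len(m), function(j) {
    tab <- table(factor(dosage[, j], levels = 0:2))
    n1 <- tab[["1"]] + 2L * tab[["2"]]
    min(n1, 2L * n - n1) / (2 * n) >= 0.05
  }, logical(1L))
  expect_setequal(flt$panel$snp_id, colnames(dosage)[keep_oracle])
  expect_true(all(flt$panel$maf >= 0.05))
})

test_that("MAF filter is idempotent and monotone in the threshold", {
  set.seed(12)
  n <- 120L; m <- 60L
  dosage <- matrix(rbinom(n * m, 2L, rep(runif(m, 0.01, 0.5), each = n)),
                   n, m, dimnames = list(NULL, sprintf("s%02d", 1:m)))
  panel <- snp_panel(colnames(dosage), rep_len(1:3, m), seq_len(m))
  cohort <- cohort_data(sprintf("i%03d", 1:n), dosage, rnorm(n), rnorm(n))

  once <- filter_maf(panel, cohort, 0.05)
  twice <- filter_maf(once$panel, once$cohort, 0.05)
  expect_equal(twice$panel$snp_id, once$panel$snp_id)

  kept <- vapply(c(0, 0.05, 0.2, 0.4), function(th) {
    nrow(filter_maf(panel, cohort, th)$panel)
  }, numeric(1L))
  expect_equal(kept[1L], m)  # threshold 0 keeps everything
  expect_true(all(diff(kept) <= 0))
})

test_that("swapping allele labels maps dosage to 2 - d and keeps the MAF", {
  set.seed(13)
  d <- matrix(rbinom(300, 2, 0.3), 100, 3)
  expect_equal(empirical_maf(2L - d), empirical_maf(d))
})

test_that("a monomorphic SNP is excluded at any positive threshold", {
  dosage <- cbind(mono = rep(0L, 50), poly = rbinom(50, 2, 0.5))
  panel <- snp_panel(c("mono", "poly"), c(1L, 2L), c(1L, 2L))
  cohort <- cohort_data(sprintf("i%02d", 1:50), dosage, rnorm(50), rnorm(50))
  flt <- filter_maf(panel, cohort, 0.05)
  expect_equal(flt$panel$snp_id, "poly")
})

test_that("gene annotation follows the inside/flanking/up-downstream rules", {
  gm <- data.frame(chrom = c(14L, 14L, 14L), start = c(100, 500, 900),
                   end = c(200, 600, 950), gene = c("G1", "G2", "G3"))
  expect_equal(annotate_position(14L, 150, gm), "G1")
  expect_equal(annotate_position(14L, 300, gm), "G1-G2")
  expect_equal(annotate_position(14L, 50, gm), "G1 (u)")
  expect_equal(annotate_position(14L, 1000, gm), "G3 (d)")
  expect_equal(annotate_position(3L, 1000, gm), "")
})
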