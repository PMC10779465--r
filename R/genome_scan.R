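# Pair enumeration, the genome-wide A x A scan, thresholds and ranking.

#' Scan configuration
#'
#' @param significance_log10p log10(1/p) threshold declaring a pair
#'   significant (default 32, the strict criterion used at million-cow
#'   scale; far beyond any Bonferroni bound).
#' @param bonferroni_alpha genome-wide error rate for the reference
#'   Bonferroni threshold (default 0.05).
#' @param top_k number of best-ranked pairs retained in the scan output
#'   regardless of the threshold (default 50000).
#' @param include_intra include same-chromosome pairs (default `FALSE`;
#'   the scan is inter-chromosome by design, the flag is an extension).
#' @param min_cell_count per-cell count floor passed to [test_pair()]
#'   (default 0: estimability only).
#' @param focal_chromosome chromosome used for AC1/AC4 pattern
#'   classification of pairs touching it (default 14).
#' @return a `scan_config` list.
#' @export
scan_config <- function(significance_log10p = 32, bonferroni_alpha = 0.05,
                        top_k = 50000L, include_intra = FALSE,
                        min_cell_count = 0L, focal_chromosome = 14L) {
  stopifnot(significance_log10p >= 0, top_k >= 1)
  if (bonferroni_alpha <= 0 || bonferroni_alpha >= 1) {
    stop("`bonferroni_alpha` must lie in (0, 1)")
  }
  structure(
    list(significance_log10p = significance_log10p,
         bonferroni_alpha = bonferroni_alpha, top_k = as.integer(top_k),
         include_intra = isTRUE(include_intra),
         min_cell_count = as.integer(min_cell_count),
         focal_chromosome = as.integer(focal_chromosome)),
    class = "scan_config"
  )
}

#' Enumerate the SNP pairs of a scan
#'
#' Yields every unordered pair of panel SNPs on different chromosomes
#' exactly once, in a deterministic order: SNPs are put in canonical
#' (chromosome, position, id) order and pairs are emitted in nested-loop
#' order over that ranking, so the output does not depend on the input row
#' order of the panel.
#'
#' @param panel a [snp_panel()].
#' @param config a [scan_config()]; `include_intra = TRUE` adds
#'   same-chromosome pairs.
#' @return 2-column integer matrix of row indices into `panel`.
#' @export
enumerate_pairs <- function(panel, config = scan_config()) {
  m <- nrow(panel)
  if (m < 2L) return(matrix(integer(0), 0L, 2L))
  ord <- order(panel$chromosome, panel$position_bp, panel$snp_id)
  idx <- which(upper.tri(diag(m)), arr.ind = TRUE) # col-major: j varies slower
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  a <- ord[idx[, 1L]]
  b <- ord[idx[, 2L]]
  if (!config$include_intra) {
    keep <- panel$chromosome[a] != panel$chromosome[b]
    a <- a[keep]; b <- b[keep]
  }
  cbind(i = a, j = b)
}

#' Reference Bonferroni threshold on the log10(1/p) scale
#'
#' @param n_tests number of tests performed.
#' @param alpha genome-wide false-positive rate.
#' @return `-log10(alpha / n_tests)`.
#' @export
#' @examples
#' bonferroni_threshold(20, 0.05)  # about 2.602
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (n_tests < 1) stop("`n_tests` must be at least 1")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
  log10(n_tests) - log10(alpha)
}

#' Run the inter-chromosome A-by-A scan
#'
#' Adjusts phenotypes by the polygenic predictions, tests every enumerated
#' pair with [test_pair()], classifies the AC1/AC4 pattern of pairs
#' touching the focal chromosome, and ranks tested pairs by descending
#' log10(1/p) (ties broken by absolute effect, then by SNP ids).  Per-pair
#' failures (inestimable contrasts, degenerate residual variance) are
#' recorded as status codes and never abort the scan.
#'
#' @param panel a [snp_panel()] (after QC; see [filter_maf()]).
#' @param cohort the matching [cohort_data()].
#' @param config a [scan_config()].
#' @param gene_map optional gene map ([load_gene_map()]) for annotation.
#' @return a data frame of class `epistasis_scan`, one row per enumerated
#'   pair, with SNP/chromosome/position columns for both loci, `effect`
#'   (alpha-alpha), `se`, `t`, `log10_inv_p`, `rank` (1 = most significant;
#'   `NA` for untested pairs), `significant`, `pattern` and `status`
#'   (`tested` / `inestimable` / `degenerate`).  Rows are ordered by rank,
#'   untested pairs last.  If more than `top_k` pairs were tested, only the
#'   `top_k` best plus all significant pairs are kept (the counts are
#'   preserved in the attributes).
#' @export
run_scan <- function(panel, cohort, config = scan_config(),
                     gene_map = NULL) {
  y_star <- adjust_phenotypes(cohort$y, cohort$a_tilde)
  pairs <- enumerate_pairs(panel, config)
  np <- nrow(pairs)
  effect <- se <- tstat <- l10 <- rep(NA_real_, np)
  status <- rep("tested", np)
  pattern <- rep(NA_character_, np)
  dos <- cohort$dosage
  col_of <- match(panel$snp_id, colnames(dos))
  for (p in seq_len(np)) {
    i <- pairs[p, 1L]; j <- pairs[p, 2L]
    res <- tryCatch(
      test_pair(y_star, dos[, col_of[i]], dos[, col_of[j]],
                min_cell_count = config$min_cell_count),
      aaxscan_inestimable = function(e) NULL
    )
    if (is.null(res)) {
      status[p] <- "inestimable"
      next
    }
    eff <- res$effect
    effect[p] <- eff$alpha_alpha
    se[p] <- eff$se
    tstat[p] <- eff$t
    l10[p] <- eff$log10_inv_p
    if (eff$status == "degenerate") status[p] <- "degenerate"
    anchor <- if (panel$chromosome[i] == config$focal_chromosome) 1L
      else if (panel$chromosome[j] == config$focal_chromosome) 2L
      else NA_integer_
    if (!is.na(anchor)) {
      pattern[p] <- as.character(classify_pattern(res$aa, anchor))
    }
  }
  out <- data.frame(
    snp_i = panel$snp_id[pairs[, 1L]],
    chr_i = panel$chromosome[pairs[, 1L]],
    pos_i = panel$position_bp[pairs[, 1L]],
    snp_j = panel$snp_id[pairs[, 2L]],
    chr_j = panel$chromosome[pairs[, 2L]],
    pos_j = panel$position_bp[pairs[, 2L]],
    effect = effect, se = se, t = tstat, log10_inv_p = l10,
    rank = NA_integer_, pattern = pattern, status = status,
    stringsAsFactors = FALSE
  )
  if (!is.null(gene_map)) {
    out$gene_i <- annotate_position(out$chr_i, out$pos_i, gene_map)
    out$gene_j <- annotate_position(out$chr_j, out$pos_j, gene_map)
  }
  tested <- which(out$status == "tested")
  if (length(tested)) {
    o <- tested[order(-out$log10_inv_p[tested], -abs(out$effect[tested]),
                      out$snp_i[tested], out$snp_j[tested])]
    out$rank[o] <- seq_along(o)
  }
  out$significant <- out$status == "tested" &
    !is.na(out$log10_inv_p) &
    out$log10_inv_p > config$significance_log10p
  n_tested <- length(tested)
  n_significant <- sum(out$significant)
  keep <- is.na(out$rank) | out$rank <= config$top_k | out$significant
  out <- out[keep, , drop = FALSE]
  out <- out[order(is.na(out$rank), out$rank, out$snp_i, out$snp_j), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "config") <- config
  attr(out, "n_pairs") <- np
  attr(out, "n_tested") <- n_tested
  attr(out, "n_significant") <- n_significant
  class(out) <- c("epistasis_scan", "data.frame")
  out
}

#' @export
print.epistasis_scan <- function(x, n = 10L, ...) {
  cat("A x A scan:", attr(x, "n_pairs"), "pairs enumerated,",
      attr(x, "n_tested"), "tested,",
      attr(x, "n_significant"), "significant at log10(1/p) >",
      attr(x, "config")$significance_log10p, "\n")
  print(utils::head(as.data.frame(x), n))
  invisible(x)
}
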