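# Region bookkeeping of significant pairs on a focal chromosome.

#' Region scheme
#'
#' Named closed base-pair intervals on a focal chromosome.  Intervals may
#' be nested; [assign_region()] returns the finest (narrowest) enclosing
#' one.  A label may span several disjoint intervals (rows sharing the
#' name).
#'
#' @param regions data frame with columns `region`, `start`, `end` (bp,
#'   closed intervals).
#' @return a `region_scheme` data frame.
#' @export
region_scheme <- function(regions) {
  stopifnot(all(c("region", "start", "end") %in% names(regions)))
  if (any(regions$start > regions$end)) stop("malformed interval: start > end")
  regions <- regions[, c("region", "start", "end")]
  regions$start <- as.numeric(regions$start)
  regions$end <- as.numeric(regions$end)
  class(regions) <- c("region_scheme", "data.frame")
  regions
}

#' Default Chr14 region scheme
#'
#' The sub-structure of the 0.14-9.52 Mb Chr14 segment carrying the
#' inter-chromosome A-by-A effects of fat percentage: `Chr14a`
#' (0.14-0.88 Mb), the `gap` (0.9-2.2 Mb, no significant inter-chromosome
#' effects), and `Chr14b` (2.21-9.52 Mb) split into `Chr14b1` and
#' `Chr14b2`.  The Chr14b1 boundaries are the SNP-derived ones
#' (2,282,659-2,421,119 bp, i.e. the 138.46 Kb cluster), since rounding
#' the quoted 2.28-2.42 Mb to plain bp would exclude the cluster's own
#' boundary SNP; Chr14b2 is the remainder of Chr14b on either side.
#' Positions between interval edges map to `"outside"`.
#'
#' @return a [region_scheme()].
#' @export
chr14_region_scheme <- function() {
  region_scheme(data.frame(
    region = c("Chr14a", "gap", "Chr14b2", "Chr14b1", "Chr14b2"),
    start = c(140000, 900000, 2210000, 2282659, 2421120),
    end = c(880000, 2200000, 2282658, 2421119, 9520000),
    stringsAsFactors = FALSE
  ))
}

#' Assign positions to regions
#'
#' @param position_bp numeric vector of positions.
#' @param scheme a [region_scheme()].
#' @return character vector: label of the narrowest enclosing interval, or
#'   `"outside"`.
#' @export
assign_region <- function(position_bp, scheme = chr14_region_scheme()) {
  width <- scheme$end - scheme$start
  vapply(position_bp, function(p) {
    hit <- which(scheme$start <= p & p <= scheme$end)
    if (!length(hit)) return("outside")
    scheme$region[hit[which.min(width[hit])]]
  }, character(1L))
}

#' Integer percentage with round-half-up
#'
#' @param count,total non-negative counts.
#' @return `100 * count / total` rounded half-up to an integer (so
#'   2148/2761 gives 78).
#' @export
region_percentage <- function(count, total) {
  if (total == 0) return(0L)
  as.integer(floor(100 * count / total + 0.5))
}

#' Summarize significant pairs by focal-chromosome region
#'
#' Counts, for each region of the scheme, the significant pairs whose
#' focal-chromosome SNP falls in that region, with integer percentages of
#' the focal total (round-half-up), the set of partner chromosomes and the
#' best-ranked pairs.  The counts always partition the focal total and the
#' summary does not depend on the input row order.
#'
#' @param results an `epistasis_scan` data frame (or compatible data frame
#'   with `chr_i`, `pos_i`, `chr_j`, `pos_j`, `log10_inv_p`, `rank`,
#'   `status` columns).
#' @param scheme a [region_scheme()].
#' @param focal_chromosome chromosome whose regions are summarized.
#' @param threshold significance threshold on log10(1/p); `NULL` uses the
#'   `significant` column / scan attribute if present, else 32.
#' @param top_n how many top pairs to keep per region.
#' @return a `region_report` list with elements `by_region` (data frame:
#'   region, n_pairs, pct, partner_chromosomes), `total` (focal significant
#'   pairs), `top_pairs` (named list of data frames) and `threshold`.
#' @export
summarize_regions <- function(results, scheme = chr14_region_scheme(),
                              focal_chromosome = 14L, threshold = NULL,
                              top_n = 20L) {
  if (is.null(threshold)) {
    cfg <- attr(results, "config")
    threshold <- if (!is.null(cfg)) cfg$significance_log10p else 32
  }
  sig <- results[results$status == "tested" &
                   !is.na(results$log10_inv_p) &
                   results$log10_inv_p > threshold, , drop = FALSE]
  focal_i <- sig$chr_i == focal_chromosome
  focal_j <- sig$chr_j == focal_chromosome
  focal <- sig[xor(focal_i, focal_j), , drop = FALSE]
  fpos <- ifelse(focal$chr_i == focal_chromosome, focal$pos_i, focal$pos_j)
  ppos <- ifelse(focal$chr_i == focal_chromosome, focal$chr_j, focal$chr_i)
  region <- assign_region(fpos, scheme)
  total <- nrow(focal)
  labels <- unique(c(unique(scheme$region), "outside"))
  by_region <- do.call(rbind, lapply(labels, function(r) {
    inr <- region == r
    data.frame(
      region = r,
      n_pairs = sum(inr),
      pct = region_percentage(sum(inr), total),
      partner_chromosomes = paste(sort(unique(ppos[inr])), collapse = ","),
      stringsAsFactors = FALSE
    )
  }))
  rownames(by_region) <- NULL
  top_pairs <- lapply(stats::setNames(labels, labels), function(r) {
    sub <- focal[region == r, , drop = FALSE]
    sub <- sub[order(sub$rank), , drop = FALSE]
    utils::head(sub, top_n)
  })
  structure(
    list(by_region = by_region, total = total, top_pairs = top_pairs,
         threshold = threshold, focal_chromosome = focal_chromosome),
    class = "region_report"
  )
}

#' @export
print.region_report <- function(x, ...) {
  cat("Significant pairs touching chromosome", x$focal_chromosome, ":",
      x$total, "(log10(1/p) >", x$threshold, ")\n")
  print(x$by_region)
  invisible(x)
}

#' Manhattan-plot data export
#'
#' One row per focal-chromosome SNP occurrence in the results: position,
#' log10(1/p) and region label, ready for plotting.
#'
#' @inheritParams summarize_regions
#' @return data frame with `snp_id`, `position_bp`, `log10_inv_p`,
#'   `region`.
#' @export
manhattan_data <- function(results, scheme = chr14_region_scheme(),
                           focal_chromosome = 14L) {
  tested <- results[results$status == "tested", , drop = FALSE]
  rows <- list()
  for (side in c("i", "j")) {
    chr <- tested[[paste0("chr_", side)]]
    sel <- chr == focal_chromosome
    if (any(sel)) {
      rows[[side]] <- data.frame(
        snp_id = tested[[paste0("snp_", side)]][sel],
        position_bp = tested[[paste0("pos_", side)]][sel],
        log10_inv_p = tested$log10_inv_p[sel],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(snp_id = character(0), position_bp = numeric(0),
                      log10_inv_p = numeric(0), region = character(0)))
  }
  out$region <- assign_region(out$position_bp, scheme)
  rownames(out) <- NULL
  out[order(out$position_bp), , drop = FALSE]
}

#' Circular-plot link data export
#'
#' @param results an `epistasis_scan` data frame.
#' @param significant_only keep only significant pairs (default `TRUE`).
#' @return data frame `chr_i, pos_i, chr_j, pos_j, weight` with
#'   `weight = log10_inv_p`.
#' @export
link_data <- function(results, significant_only = TRUE) {
  sub <- if (significant_only && "significant" %in% names(results)) {
    results[results$significant, , drop = FALSE]
  } else {
    results[results$status == "tested", , drop = FALSE]
  }
  data.frame(chr_i = sub$chr_i, pos_i = sub$pos_i,
             chr_j = sub$chr_j, pos_j = sub$pos_j,
             weight = sub$log10_inv_p, stringsAsFactors = FALSE)
}
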