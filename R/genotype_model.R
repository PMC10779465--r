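# SNP panel / cohort containers, file I/O and QC filters.

#' SNP panel
#'
#' A data frame describing the SNP map: identifier, chromosome code,
#' base-pair position (1-based), allele labels and minor allele frequency.
#' Chromosome codes are 1-29 plus 31 for the nonrecombining region of ChrX,
#' the convention of the bovine genotyping panels this package targets.
#'
#' @param snp_id character vector of unique SNP identifiers.
#' @param chromosome integer chromosome codes in `{1..29, 31}`.
#' @param position_bp integer positions (bp, 1-based), non-negative.
#' @param allele1,allele2 allele labels; dosages count copies of `allele1`.
#' @param maf minor allele frequencies in `[0, 0.5]` (`NA` allowed until
#'   computed from data).
#' @return a `snp_panel` data frame.
#' @export
snp_panel <- function(snp_id, chromosome, position_bp,
                      allele1 = "A1", allele2 = "A2", maf = NA_real_) {
  p <- data.frame(
    snp_id = as.character(snp_id),
    chromosome = as.integer(chromosome),
    position_bp = as.integer(position_bp),
    allele1 = as.character(allele1),
    allele2 = as.character(allele2),
    maf = as.numeric(maf),
    stringsAsFactors = FALSE
  )
  class(p) <- c("snp_panel", "data.frame")
  validate_snp_panel(p)
}

#' @rdname snp_panel
#' @param panel object to validate.
#' @export
validate_snp_panel <- function(panel) {
  if (anyDuplicated(panel$snp_id)) {
    stop("duplicated snp_id: ", panel$snp_id[duplicated(panel$snp_id)][1L])
  }
  if (any(panel$position_bp < 0)) stop("positions must be non-negative")
  ok_chr <- panel$chromosome %in% c(1:29, 31L)
  if (!all(ok_chr)) {
    stop("chromosome codes must be in {1..29, 31}; offending code: ",
         panel$chromosome[!ok_chr][1L])
  }
  bad <- !is.na(panel$maf) & (panel$maf < 0 | panel$maf > 0.5)
  if (any(bad)) stop("maf must lie in [0, 0.5]")
  panel
}

#' Cohort genotypes and phenotypes
#'
#' Bundles the dosage matrix (individuals x SNPs, counting copies of
#' allele 1), yield deviations `y` and polygenic adjustments `a_tilde`
#' (2 x PTA).  Missing dosages are rejected: imputation is an upstream
#' concern and the statistical core assumes complete data.
#'
#' @param individual_id character vector of individual identifiers.
#' @param dosage integer matrix of allele-1 dosages in `{0, 1, 2}`, one row
#'   per individual, SNP ids as column names.
#' @param y numeric yield deviations.
#' @param a_tilde numeric polygenic adjustments.
#' @return a `cohort_data` object.
#' @export
cohort_data <- function(individual_id, dosage, y, a_tilde) {
  n <- length(individual_id)
  if (nrow(dosage) != n || length(y) != n || length(a_tilde) != n) {
    stop("individual_id, dosage rows, y and a_tilde must all have length ", n)
  }
  .check_dosage_matrix(dosage)
  storage.mode(dosage) <- "integer"
  rownames(dosage) <- individual_id
  structure(
    list(individual_id = as.character(individual_id), dosage = dosage,
         y = as.numeric(y), a_tilde = as.numeric(a_tilde)),
    class = "cohort_data"
  )
}

.check_dosage_matrix <- function(dosage) {
  bad <- which(is.na(dosage) | !(dosage %in% c(0L, 1L, 2L)))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(dosage)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(dosage)) + 1L
    rn <- rownames(dosage)[i]; cn <- colnames(dosage)[j]
    stop("invalid dosage value ", dosage[bad[1L]], " at individual ",
         if (is.null(rn)) i else rn, ", SNP ",
         if (is.null(cn)) j else cn, " (dosages must be 0, 1 or 2)")
  }
  invisible(TRUE)
}

#' @export
print.cohort_data <- function(x, ...) {
  cat("Cohort:", length(x$individual_id), "individuals x",
      ncol(x$dosage), "SNPs\n")
  invisible(x)
}

#' Empirical minor allele frequencies
#'
#' @param dosage dosage matrix (allele-1 copies per individual x SNP).
#' @return numeric vector of per-SNP minor allele frequencies.
#' @export
empirical_maf <- function(dosage) {
  f1 <- colMeans(dosage) / 2
  pmin(f1, 1 - f1)
}

#' Load a SNP panel and cohort from files
#'
#' Two dialects are supported.  `"tsv"` is the canonical plain-text trio:
#' a genotype table with header `individual_id` followed by one column per
#' SNP id; a phenotype table `individual_id, y, a_tilde`; and a map table
#' `snp_id, chromosome, position_bp, allele1, allele2[, maf]`.  `"plink"`
#' reads an additive-coded `.raw` export plus the 6-column `.bim` map;
#' dosages are re-oriented so that they always count copies of the map's
#' first allele, whatever allele the `.raw` file counted.
#'
#' @param genotype_path genotype table (`.tsv`) or PLINK `.raw` file.
#' @param phenotype_path phenotype table (`individual_id, y, a_tilde`).
#' @param map_path SNP map (`.tsv`) or PLINK `.bim` file.
#' @param format `"tsv"` or `"plink"`.
#' @return a list with elements `panel` ([snp_panel()]) and `cohort`
#'   ([cohort_data()]); SNP columns follow the map order, individuals the
#'   genotype-file order.
#' @export
load_cohort <- function(genotype_path, phenotype_path, map_path,
                        format = c("tsv", "plink")) {
  format <- match.arg(format)
  for (p in c(genotype_path, phenotype_path, map_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  gm <- switch(format,
    tsv = .read_tsv_genotypes(genotype_path, map_path),
    plink = .read_plink_genotypes(genotype_path, map_path)
  )
  phen <- data.table::fread(phenotype_path, data.table = FALSE)
  need <- c("individual_id", "y", "a_tilde")
  if (!all(need %in% names(phen))) {
    stop("phenotype file must have columns: ", paste(need, collapse = ", "))
  }
  phen$individual_id <- as.character(phen$individual_id)
  idx <- match(rownames(gm$dosage), phen$individual_id)
  if (anyNA(idx)) {
    stop("individuals missing from phenotype file, e.g.: ",
         rownames(gm$dosage)[which(is.na(idx))[1L]])
  }
  phen <- phen[idx, , drop = FALSE]
  cohort <- cohort_data(rownames(gm$dosage), gm$dosage, phen$y, phen$a_tilde)
  list(panel = gm$panel, cohort = cohort)
}

.read_tsv_genotypes <- function(genotype_path, map_path) {
  map <- data.table::fread(map_path, data.table = FALSE)
  need <- c("snp_id", "chromosome", "position_bp", "allele1", "allele2")
  if (!all(need %in% names(map))) {
    stop("map file must have columns: ", paste(need, collapse = ", "))
  }
  g <- data.table::fread(genotype_path, data.table = FALSE)
  if (names(g)[1L] != "individual_id") {
    stop("genotype file must start with an `individual_id` column")
  }
  ids <- as.character(g$individual_id)
  snps <- names(g)[-1L]
  if (!setequal(snps, map$snp_id)) {
    only_g <- setdiff(snps, map$snp_id)
    only_m <- setdiff(map$snp_id, snps)
    stop("SNP ids disagree between genotype and map files",
         if (length(only_g)) paste0("; only in genotypes: ", only_g[1L]),
         if (length(only_m)) paste0("; only in map: ", only_m[1L]))
  }
  dosage <- as.matrix(g[, map$snp_id, drop = FALSE])
  rownames(dosage) <- ids
  .check_dosage_matrix(dosage)
  storage.mode(dosage) <- "integer"
  maf <- if ("maf" %in% names(map)) map$maf else empirical_maf(dosage)
  panel <- snp_panel(map$snp_id, map$chromosome, map$position_bp,
                     map$allele1, map$allele2, maf)
  list(panel = panel, dosage = dosage)
}

.read_plink_genotypes <- function(raw_path, bim_path) {
  bim <- data.table::fread(bim_path, data.table = FALSE, header = FALSE)
  if (ncol(bim) != 6L) stop(".bim file must have 6 columns")
  names(bim) <- c("chromosome", "snp_id", "cm", "position_bp",
                  "allele1", "allele2")
  raw <- data.table::fread(raw_path, data.table = FALSE)
  meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(meta %in% names(raw))) {
    stop(".raw file must carry the standard PLINK header columns")
  }
  gcols <- setdiff(names(raw), meta)
  counted <- sub("^(.*)_([^_]+)$", "\\2", gcols)
  snp <- sub("^(.*)_([^_]+)$", "\\1", gcols)
  idx <- match(bim$snp_id, snp)
  if (anyNA(idx)) {
    stop("SNP ids disagree between .raw and .bim, e.g.: ",
         bim$snp_id[which(is.na(idx))[1L]])
  }
  dosage <- as.matrix(raw[, gcols[idx], drop = FALSE])
  colnames(dosage) <- bim$snp_id
  rownames(dosage) <- as.character(raw$IID)
  # orient to the map's first allele
  flip <- counted[idx] != bim$allele1
  if (any(flip)) dosage[, flip] <- 2L - dosage[, flip]
  .check_dosage_matrix(dosage)
  storage.mode(dosage) <- "integer"
  panel <- snp_panel(bim$snp_id, bim$chromosome, bim$position_bp,
                     bim$allele1, bim$allele2, empirical_maf(dosage))
  list(panel = panel, dosage = dosage)
}

#' Write a panel/cohort pair as the canonical TSV trio
#'
#' Writes `<prefix>_genotypes.tsv`, `<prefix>_phenotypes.tsv` and
#' `<prefix>_map.tsv` in the dialect read back by [load_cohort()].
#'
#' @param panel a [snp_panel()].
#' @param cohort a [cohort_data()].
#' @param prefix output path prefix.
#' @return invisibly, the three file paths.
#' @export
write_cohort <- function(panel, cohort, prefix) {
  paths <- paste0(prefix, c("_genotypes.tsv", "_phenotypes.tsv", "_map.tsv"))
  g <- data.frame(individual_id = cohort$individual_id,
                  cohort$dosage, check.names = FALSE,
                  stringsAsFactors = FALSE)
  data.table::fwrite(g, paths[1L], sep = "\t")
  data.table::fwrite(
    data.frame(individual_id = cohort$individual_id, y = cohort$y,
               a_tilde = cohort$a_tilde, stringsAsFactors = FALSE),
    paths[2L], sep = "\t")
  data.table::fwrite(as.data.frame(panel), paths[3L], sep = "\t")
  invisible(paths)
}

#' Minor-allele-frequency filter
#'
#' Retains exactly the SNPs whose empirical MAF, computed from the cohort's
#' dosages, is at least `threshold`; the panel's `maf` column is updated to
#' the empirical values.  The filter is idempotent and the retained set is
#' non-increasing in the threshold.
#'
#' @param panel a [snp_panel()].
#' @param cohort the matching [cohort_data()].
#' @param threshold frequency threshold in `[0, 0.5]` (default 0.05, the
#'   usual panel QC requirement).
#' @return list with the filtered `panel` and `cohort`.
#' @export
filter_maf <- function(panel, cohort, threshold = 0.05) {
  if (threshold < 0 || threshold > 0.5) {
    stop("`threshold` must lie in [0, 0.5]")
  }
  maf <- empirical_maf(cohort$dosage)
  keep <- maf >= threshold
  if (!any(keep)) warning("no SNP passes the MAF threshold of ", threshold)
  panel <- panel[keep, , drop = FALSE]
  panel$maf <- maf[keep]
  class(panel) <- c("snp_panel", "data.frame")
  cohort$dosage <- cohort$dosage[, keep, drop = FALSE]
  list(panel = panel, cohort = cohort)
}

#' Load a BED-like gene map
#'
#' Reads a tab-separated gene map with columns `chrom, start, end, gene`
#' (header optional), used only to annotate scan results.
#'
#' @param path file path.
#' @return data frame with columns `chrom`, `start`, `end`, `gene`.
#' @export
load_gene_map <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("chrom", strsplit(first, "\t")[[1L]][1L], fixed = TRUE)
  gm <- data.table::fread(path, data.table = FALSE, header = has_header)
  if (!has_header) names(gm) <- c("chrom", "start", "end", "gene")[seq_len(ncol(gm))]
  gm$chrom <- as.integer(gm$chrom)
  if (any(gm$start > gm$end)) stop("gene map has start > end")
  gm
}

#' Annotate positions against a gene map
#'
#' Labels each position in the style of the study tables: the gene name
#' when the position falls inside a gene, `"g1-g2"` when it lies between
#' two genes, and `"g (u)"` / `"g (d)"` upstream/downstream of the first or
#' last gene of the chromosome.
#'
#' @param chromosome,position_bp vectors of positions to annotate.
#' @param gene_map data frame from [load_gene_map()].
#' @return character vector of labels (`""` when no gene is on the
#'   chromosome).
#' @export
annotate_position <- function(chromosome, position_bp, gene_map) {
  mapply(function(chr, pos) {
    g <- gene_map[gene_map$chrom == chr, , drop = FALSE]
    if (!nrow(g)) return("")
    g <- g[order(g$start), , drop = FALSE]
    inside <- g$start <= pos & pos <= g$end
    if (any(inside)) return(g$gene[which(inside)[1L]])
    before <- g$end < pos    # genes upstream of the position
    after <- g$start > pos
    if (any(before) && any(after)) {
      paste0(g$gene[max(which(before))], "-", g$gene[min(which(after))])
    } else if (any(before)) {
      paste0(g$gene[max(which(before))], " (d)")
    } else {
      paste0(g$gene[min(which(after))], " (u)")
    }
  }, chromosome, position_bp, USE.NAMES = FALSE)
}
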