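#' Minor allele frequency of one SNP
#'
#' Frequency of the less common allele among non-missing genotypes, computed
#' from dosage codes (variant-allele frequency folded at 0.5).
#'
#' @param ds a \code{\link{genotype_dataset}}.
#' @param snp SNP column name.
#' @param subset optional logical subject filter (e.g. controls only).
#' @return frequency in [0, 0.5].
#' @export
snp_maf <- function(ds, snp, subset = NULL) {
  g <- ds$genotypes[, snp]
  if (!is.null(subset)) g <- g[subset]
  g <- g[!is.na(g)]
  if (!length(g)) stop_undefined(sprintf("no genotypes for %s", snp))
  p <- sum(g) / (2 * length(g))
  min(p, 1 - p)
}

#' Composite linkage disequilibrium r-squared between two SNPs
#'
#' Squared Pearson correlation of the 0/1/2 dosage codes over subjects with
#' both genotypes observed (the composite-LD convention, which needs no
#' phase information).
#'
#' @param ds a \code{\link{genotype_dataset}}.
#' @param snpA,snpB SNP column names.
#' @return r-squared in [0, 1]. A monomorphic (zero-variance) SNP makes the
#'   statistic undefined and raises a condition of class
#'   \code{snpmdr_undefined_error}.
#' @export
ld_r2 <- function(ds, snpA, snpB) {
  a <- ds$genotypes[, snpA]; b <- ds$genotypes[, snpB]
  keep <- !is.na(a) & !is.na(b)
  if (sum(keep) < 2) stop_undefined("fewer than 2 complete genotype pairs")
  a <- a[keep]; b <- b[keep]
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 || vb == 0)
    stop_undefined(sprintf("r2 undefined: %s is monomorphic in complete pairs",
                           if (va == 0) snpA else snpB))
  stats::cor(a, b)^2
}

#' Quality-control filter: MAF, Hardy-Weinberg, LD pruning
#'
#' Standard pre-analysis SNP filtering for case-control panels: drops SNPs
#' with minor allele frequency below \code{maf_min}, SNPs out of
#' Hardy-Weinberg equilibrium in controls at \code{hwe_alpha} (exact test),
#' and for every remaining pair with composite LD \eqn{r^2} above
#' \code{ld_r2_max} drops the later SNP in panel order (deterministic
#' pruning).
#'
#' @param ds a \code{\link{genotype_dataset}}.
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param hwe_alpha HWE significance threshold, tested in controls
#'   (default 0.05).
#' @param ld_r2_max maximum tolerated pairwise r-squared (default 0.1).
#' @param hwe_method \code{"exact"} (default) or \code{"chi2"};
#'   see \code{\link{hwe_test}}.
#' @return list with \code{dataset} (the filtered
#'   \code{\link{genotype_dataset}}) and \code{report}, a data.frame with one
#'   row per input SNP: \code{snp}, \code{maf}, \code{hwe_p}, \code{max_r2},
#'   \code{kept}, \code{reason}.
#' @export
qc_filter <- function(ds, maf_min = 0.01, hwe_alpha = 0.05, ld_r2_max = 0.1,
                      hwe_method = c("exact", "chi2")) {
  stopifnot(inherits(ds, "genotype_dataset"))
  hwe_method <- match.arg(hwe_method)
  snps <- colnames(ds$genotypes)
  ctrl <- ds$status == "control"
  maf <- hwe_p <- rep(NA_real_, length(snps))
  reason <- rep("", length(snps))
  for (i in seq_along(snps)) {
    maf[i] <- tryCatch(snp_maf(ds, snps[i]), snpmdr_undefined_error =
                         function(e) NA_real_)
    tab <- marginal_counts(ds, snps[i])$counts["control", ]
    hwe_p[i] <- hwe_test(tab[1], tab[2], tab[3], method = hwe_method)$p
    if (is.na(maf[i]) || maf[i] < maf_min) reason[i] <- "MAF"
    else if (hwe_p[i] < hwe_alpha) reason[i] <- "HWE"
  }
  kept <- reason == ""
  # LD pruning among survivors, panel order; first SNP of a high-LD pair wins
  max_r2 <- rep(NA_real_, length(snps))
  surv <- which(kept)
  for (jj in seq_along(surv)) {
    j <- surv[jj]
    if (!kept[j]) next
    for (ii in seq_len(jj - 1L)) {
      i <- surv[ii]
      if (!kept[i]) next
      r2 <- tryCatch(ld_r2(ds, snps[i], snps[j]),
                     snpmdr_undefined_error = function(e) NA_real_)
      if (!is.na(r2)) {
        max_r2[j] <- max(max_r2[j], r2, na.rm = TRUE)
        max_r2[i] <- max(max_r2[i], r2, na.rm = TRUE)
        if (r2 > ld_r2_max) { kept[j] <- FALSE; reason[j] <- "LD"; break }
      }
    }
  }
  report <- data.frame(snp = snps, maf = maf, hwe_p = hwe_p,
                       max_r2 = max_r2, kept = kept,
                       reason = ifelse(kept, "", reason),
                       stringsAsFactors = FALSE)
  out <- genotype_dataset(ds$genotypes[, kept, drop = FALSE], ds$status,
                          covariates = ds$covariates, panel = ds$panel)
  list(dataset = out, report = report)
}

#' Write a QC report as TSV
#' @param report the \code{report} element of \code{\link{qc_filter}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_qc_report <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
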