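#' Construct a case-control genotype dataset
#'
#' The core container for individual-level data: a subjects-by-SNPs matrix of
#' minor-allele dosage codes (0 = homozygous common allele, 1 = heterozygous,
#' 2 = homozygous variant allele, \code{NA} = missing), a binary disease
#' status per subject, and optional covariate columns.
#'
#' @param genotypes integer matrix or data.frame, subjects in rows and SNPs in
#'   columns; values must be 0, 1, 2 or \code{NA}. Column names are the SNP
#'   identifiers (required); row names are subject identifiers (generated as
#'   \code{S1..Sn} when absent).
#' @param status vector of length \code{nrow(genotypes)}; accepted encodings
#'   are \code{0/1}, \code{"control"/"case"}, logical (TRUE = case) or a
#'   two-level factor with levels \code{control}, \code{case}.
#' @param covariates optional data.frame of per-subject covariates
#'   (equal-length with subjects).
#' @param panel optional SNP metadata data.frame as returned by
#'   \code{\link{load_snp_panel}}.
#' @return an object of class \code{genotype_dataset}: a list with elements
#'   \code{genotypes} (integer matrix), \code{status} (factor with levels
#'   \code{control}, \code{case}), \code{subjects}, \code{covariates},
#'   \code{panel}.
#' @examples
#' g <- matrix(c(0, 1, 2, 0, 1, 1), nrow = 3,
#'             dimnames = list(NULL, c("rs1", "rs2")))
#' ds <- genotype_dataset(g, status = c(0, 1, 1))
#' dim(ds$genotypes)
#' @export
genotype_dataset <- function(genotypes, status, covariates = NULL,
                             panel = NULL) {
  if (is.data.frame(genotypes)) genotypes <- as.matrix(genotypes)
  if (!is.matrix(genotypes))
    stop_validation("`genotypes` must be a matrix or data.frame")
  if (is.null(colnames(genotypes)))
    stop_validation("`genotypes` must have SNP column names")
  mode(genotypes) <- "integer"
  bad <- !(genotypes %in% c(0L, 1L, 2L, NA))
  if (any(bad))
    stop_validation(sprintf(
      "genotype codes must be 0/1/2/NA; %d offending cell(s), first at row %d",
      sum(bad), (which(bad)[1] - 1L) %% nrow(genotypes) + 1L))
  status <- coerce_status(status)
  if (length(status) != nrow(genotypes))
    stop_validation("`status` must have one entry per subject")
  if (anyNA(status))
    stop_validation("`status` must be defined (non-missing) for every subject")
  if (is.null(rownames(genotypes)))
    rownames(genotypes) <- paste0("S", seq_len(nrow(genotypes)))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != nrow(genotypes))
      stop_validation("`covariates` must be equal-length with subjects")
  }
  structure(list(genotypes = genotypes, status = status,
                 subjects = rownames(genotypes),
                 covariates = covariates, panel = panel),
            class = "genotype_dataset")
}

coerce_status <- function(status) {
  lv <- c("control", "case")
  if (is.factor(status)) status <- as.character(status)
  if (is.logical(status)) return(factor(ifelse(status, "case", "control"), lv))
  if (is.numeric(status)) {
    if (!all(status %in% c(0, 1, NA)))
      stop_validation("numeric status must be 0 (control) / 1 (case)")
    return(factor(ifelse(status == 1, "case", "control"), lv))
  }
  s <- tolower(trimws(as.character(status)))
  map <- c("0" = "control", "1" = "case", "control" = "control",
           "case" = "case")
  out <- map[s]
  if (any(is.na(out) & !is.na(s)))
    stop_validation(sprintf("status value '%s' is not binary (0/1 or control/case)",
                            s[which(is.na(out) & !is.na(s))[1]]))
  factor(unname(out), lv)
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("<genotype_dataset> %d subjects (%d cases / %d controls), %d SNPs\n",
              length(x$subjects), sum(x$status == "case"),
              sum(x$status == "control"), ncol(x$genotypes)))
  cat("SNPs:", paste(colnames(x$genotypes), collapse = ", "), "\n")
  if (!is.null(x$covariates))
    cat("covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$genotypes)

#' Subset a genotype dataset by subjects
#' @param ds a \code{\link{genotype_dataset}}.
#' @param i subject index (logical or integer).
#' @return a \code{genotype_dataset} restricted to the selected subjects.
#' @keywords internal
subset_subjects <- function(ds, i) {
  genotype_dataset(ds$genotypes[i, , drop = FALSE], ds$status[i],
                   covariates = if (!is.null(ds$covariates))
                     ds$covariates[i, , drop = FALSE],
                   panel = ds$panel)
}

#' Per-SNP class-by-genotype count table
#'
#' A 2 x 3 table of genotype counts (rows: control, case; columns: genotype
#' codes 0, 1, 2) -- the unit of analysis for single-SNP association.
#'
#' @param snp SNP identifier (rsID string).
#' @param counts 2 x 3 non-negative integer matrix, rows control/case,
#'   columns genotype 0/1/2. A named list with \code{control} and \code{case}
#'   length-3 vectors is also accepted.
#' @return object of class \code{genotype_count_table}.
#' @examples
#' genotype_count_table("rs1800629",
#'   rbind(control = c(634, 72, 4), case = c(154, 21, 46)))
#' @export
genotype_count_table <- function(snp, counts) {
  if (is.list(counts) && !is.matrix(counts))
    counts <- rbind(control = counts$control, case = counts$case)
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 3)))
    stop_validation("`counts` must be a 2 x 3 matrix (control/case x genotype 0/1/2)")
  if (!is_wholenumber(counts) || any(counts < 0))
    stop_validation("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(class = c("control", "case"),
                           genotype = c("0", "1", "2"))
  structure(list(snp = snp, counts = counts), class = "genotype_count_table")
}

#' @export
print.genotype_count_table <- function(x, ...) {
  cat(sprintf("<genotype_count_table> %s (n = %d controls / %d cases)\n",
              x$snp, sum(x$counts["control", ]), sum(x$counts["case", ])))
  print(x$counts)
  invisible(x)
}

#' Marginal genotype counts for one SNP
#'
#' Tallies the 2 x 3 class-by-genotype table for a single SNP, excluding
#' subjects with a missing genotype at that SNP.
#'
#' @param ds a \code{\link{genotype_dataset}}.
#' @param snp SNP column name.
#' @return a \code{\link{genotype_count_table}}.
#' @export
marginal_counts <- function(ds, snp) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (!snp %in% colnames(ds$genotypes))
    stop_validation(sprintf("SNP '%s' not in panel", snp))
  g <- ds$genotypes[, snp]
  keep <- !is.na(g)
  m <- matrix(0L, 2, 3)
  for (cls in 1:2) {
    sel <- keep & (ds$status == c("control", "case")[cls])
    m[cls, ] <- tabulate(g[sel] + 1L, nbins = 3L)
  }
  genotype_count_table(snp, m)
}

#' Load the packaged cytokine SNP panel metadata
#'
#' Metadata for the five cytokine-gene SNPs the package ships as a worked
#' panel: IL1A rs1800587, IL6 rs1800796, TNFA rs361525, TNFA rs1800629 and
#' IFNG rs2069705 -- rsID, gene, common/variant allele, genomic location
#' (stored verbatim as a \code{chrom:position} label; no genome-build
#' arithmetic is done) and a functional annotation.
#'
#' @return data.frame with columns \code{rsid}, \code{gene},
#'   \code{ref_allele}, \code{alt_allele}, \code{genomic_location},
#'   \code{annotation}.
#' @export
load_snp_panel <- function() {
  p <- system.file("extdata", "cytokine_panel_snps.tsv", package = "snpmdr",
                   mustWork = TRUE)
  df <- read.delim(p, stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(df$rsid), all(df$ref_allele != df$alt_allele))
  df
}

#' Load the packaged case-control genotype counts for the cytokine panel
#'
#' Per-SNP marginal genotype counts from a dementia case-control study of
#' 221 cases and 710 controls genotyped at the five cytokine SNPs of
#' \code{\link{load_snp_panel}}. These marginal tables are the only
#' individual-level information available for that cohort;
#' \code{\link{resample_from_marginals}} turns them into subject-level data
#' under a conditional-independence assumption.
#'
#' @return named list of \code{\link{genotype_count_table}}, one per SNP, in
#'   panel order.
#' @examples
#' tabs <- load_panel_counts()
#' tabs[["rs1800629"]]$counts["case", ]
#' @export
load_panel_counts <- function() {
  p <- system.file("extdata", "cytokine_panel_counts.tsv", package = "snpmdr",
                   mustWork = TRUE)
  df <- read.delim(p, stringsAsFactors = FALSE)
  snps <- unique(df$rsid)
  out <- lapply(snps, function(s) {
    d <- df[df$rsid == s, ]
    m <- rbind(control = unlist(d[d$class == "control", c("n0", "n1", "n2")]),
               case    = unlist(d[d$class == "case",    c("n0", "n1", "n2")]))
    genotype_count_table(s, m)
  })
  names(out) <- snps
  out
}
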