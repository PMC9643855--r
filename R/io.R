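#' Read a case-control genotype file
#'
#' Reads individual-level genotype data in one of three text dialects:
#' \describe{
#'   \item{\code{tabular}}{tab- or comma-delimited with a header; one column of
#'     subject identifiers, a \code{status} column (\code{0/1} or
#'     \code{control/case}), SNP columns coded 0/1/2, and any remaining
#'     columns kept as covariates.}
#'   \item{\code{ped_map}}{PLINK text PED with its companion MAP file. Allele
#'     pairs are recoded to dosage of the variant allele against the panel's
#'     declared common allele (never against file-observed frequency), so the
#'     coding is deterministic across files. \code{0} alleles are missing.}
#'   \item{\code{mdr_flat}}{the tab-delimited flat format used by MDR-style
#'     software: attribute columns coded 0/1/2 followed by a final
#'     \code{Class} column (0 = control, 1 = case).}
#' }
#' Recognised missing-genotype tokens are \code{NA}, \code{.} and the empty
#' string; any other uninterpretable token is an error (never silently
#' coerced).
#'
#' @param path input file path.
#' @param dialect one of \code{"tabular"}, \code{"ped_map"}, \code{"mdr_flat"}.
#' @param map for \code{ped_map}: path to the MAP file (default: \code{path}
#'   with extension replaced by \code{.map}).
#' @param panel for \code{ped_map}: SNP metadata data.frame with columns
#'   \code{rsid}, \code{ref_allele} (common) and \code{alt_allele} (variant);
#'   defaults to \code{\link{load_snp_panel}} restricted to the MAP's SNPs.
#' @param snp_cols for \code{tabular}: character vector naming the SNP
#'   columns. Default: every non-id, non-status column whose non-missing
#'   values are all 0/1/2.
#' @param id_col,status_col for \code{tabular}: column names (defaults
#'   \code{"subject_id"}, \code{"status"}; falls back to the first column for
#'   ids).
#' @return a \code{\link{genotype_dataset}}.
#' @export
read_genotype_table <- function(path,
                                dialect = c("tabular", "ped_map", "mdr_flat"),
                                map = NULL, panel = NULL, snp_cols = NULL,
                                id_col = "subject_id", status_col = "status") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_validation(sprintf("file not found: %s", path))
  switch(dialect,
         tabular  = read_tabular(path, snp_cols, id_col, status_col),
         ped_map  = read_ped_map(path, map, panel),
         mdr_flat = read_mdr_flat(path))
}

MISSING_TOKENS <- c("NA", ".", "")

parse_geno_column <- function(x, col, lines) {
  s <- trimws(as.character(x))
  miss <- is.na(x) | s %in% MISSING_TOKENS
  bad <- !miss & !s %in% c("0", "1", "2")
  if (any(bad))
    stop_validation(sprintf(
      "malformed genotype '%s' in column %s at line %d",
      s[which(bad)[1]], col, lines[which(bad)[1]]))
  out <- suppressWarnings(as.integer(s))
  out[miss] <- NA_integer_
  out
}

read_delim_auto <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  read.delim(path, sep = sep, stringsAsFactors = FALSE,
             colClasses = "character", check.names = FALSE)
}

read_tabular <- function(path, snp_cols, id_col, status_col) {
  df <- read_delim_auto(path)
  if (!status_col %in% names(df))
    stop_validation(sprintf("no '%s' column in %s", status_col, path))
  if (!id_col %in% names(df)) id_col <- names(df)[1]
  other <- setdiff(names(df), c(id_col, status_col))
  if (is.null(snp_cols)) {
    looks_geno <- vapply(other, function(cl) {
      s <- trimws(df[[cl]])
      all(is.na(s) | s %in% c("0", "1", "2", MISSING_TOKENS))
    }, logical(1))
    snp_cols <- other[looks_geno]
  }
  if (!length(snp_cols)) stop_validation("no genotype columns identified")
  lines <- seq_len(nrow(df)) + 1L  # header is line 1
  g <- vapply(snp_cols, function(cl) parse_geno_column(df[[cl]], cl, lines),
              integer(nrow(df)))
  g <- matrix(g, nrow = nrow(df), dimnames = list(df[[id_col]], snp_cols))
  cov_cols <- setdiff(other, snp_cols)
  covs <- NULL
  if (length(cov_cols)) {
    covs <- df[cov_cols]
    covs[] <- lapply(covs, function(x) {
      y <- suppressWarnings(as.numeric(x))
      if (all(is.na(y) == (is.na(x) | x %in% MISSING_TOKENS))) y else x
    })
  }
  genotype_dataset(g, df[[status_col]], covariates = covs)
}

read_ped_map <- function(path, map, panel) {
  map_path <- map %||% sub("\\.ped$", ".map", path)
  if (!file.exists(map_path))
    stop_validation(sprintf("MAP file not found: %s", map_path))
  mp <- read.table(map_path, stringsAsFactors = FALSE)
  rsids <- mp[[2]]
  if (is.null(panel)) {
    panel <- load_snp_panel()
  }
  panel <- panel[match(rsids, panel$rsid), , drop = FALSE]
  if (anyNA(panel$rsid))
    stop_validation(sprintf("SNP '%s' absent from the panel metadata; a common allele must be declared",
                            rsids[which(is.na(panel$rsid))[1]]))
  pd <- read.table(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- 6L + 2L * length(rsids)
  if (ncol(pd) != need)
    stop_validation(sprintf("PED has %d columns; expected %d for %d SNPs",
                            ncol(pd), need, length(rsids)))
  n <- nrow(pd)
  g <- matrix(NA_integer_, n, length(rsids),
              dimnames = list(pd[[2]], rsids))
  for (j in seq_along(rsids)) {
    a1 <- toupper(pd[[6L + 2L * j - 1L]]); a2 <- toupper(pd[[6L + 2L * j]])
    common <- toupper(panel$ref_allele[j]); variant <- toupper(panel$alt_allele[j])
    miss <- a1 == "0" | a2 == "0"
    ok <- a1 %in% c(common, variant) & a2 %in% c(common, variant)
    if (any(!ok & !miss))
      stop_validation(sprintf(
        "uninterpretable allele '%s/%s' for %s at line %d (expected %s/%s)",
        a1[!ok & !miss][1], a2[!ok & !miss][1], rsids[j],
        which(!ok & !miss)[1], common, variant))
    dose <- (a1 == variant) + (a2 == variant)
    dose[miss] <- NA_integer_
    g[, j] <- dose
  }
  pheno <- pd[[6]]
  if (!all(pheno %in% c("1", "2")))
    stop_validation("PED phenotype column must be 1 (control) / 2 (case)")
  genotype_dataset(g, ifelse(pheno == "2", "case", "control"),
                   panel = panel)
}

read_mdr_flat <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                   check.names = FALSE)
  cls_col <- names(df)[ncol(df)]
  if (tolower(cls_col) != "class")
    stop_validation("MDR flat file must end with a 'Class' column")
  lines <- seq_len(nrow(df)) + 1L
  snps <- names(df)[-ncol(df)]
  g <- vapply(snps, function(cl) parse_geno_column(df[[cl]], cl, lines),
              integer(nrow(df)))
  g <- matrix(g, nrow = nrow(df), dimnames = list(NULL, snps))
  genotype_dataset(g, df[[cls_col]])
}

#' Write a dataset in the MDR flat-file format
#'
#' Tab-delimited text with one attribute column per SNP (codes 0/1/2,
#' missing as \code{NA}) and a final \code{Class} column (0 = control,
#' 1 = case). Covariates are not part of this format and are dropped.
#' \code{read_genotype_table(path, "mdr_flat")} inverts it.
#'
#' @param ds a \code{\link{genotype_dataset}} with no missing status.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_mdr_flatfile <- function(ds, path) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (anyNA(ds$status)) stop_validation("status must be complete")
  out <- as.data.frame(ds$genotypes)
  out$Class <- as.integer(ds$status == "case")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a dataset as a tabular genotype file
#'
#' Tab-delimited with header: \code{subject_id}, \code{status}
#' (control/case), one column per SNP and one per covariate. Inverse of
#' \code{read_genotype_table(path, "tabular")}.
#'
#' @param ds a \code{\link{genotype_dataset}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_genotype_table <- function(ds, path) {
  stopifnot(inherits(ds, "genotype_dataset"))
  out <- data.frame(subject_id = ds$subjects,
                    status = as.character(ds$status),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(ds$genotypes))
  if (!is.null(ds$covariates)) out <- cbind(out, ds$covariates)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
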