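INHERITANCE_MODELS <- c("codominant_het", "codominant_hom", "dominant",
                        "recessive", "overdominant", "additive")

#' Per-class allele counts and frequencies
#'
#' Collapses a genotype count table to allele counts: common allele
#' \eqn{2 n_0 + n_1}, variant allele \eqn{2 n_2 + n_1} per class, with
#' percentages of the \eqn{2N} alleles in that class.
#'
#' @param tab a \code{\link{genotype_count_table}}.
#' @return data.frame with columns \code{class}, \code{allele}
#'   (\code{common}/\code{variant}), \code{count}, \code{pct}.
#' @export
allele_frequencies <- function(tab) {
  stopifnot(inherits(tab, "genotype_count_table"))
  out <- do.call(rbind, lapply(c("control", "case"), function(cls) {
    n <- tab$counts[cls, ]
    tot <- 2 * sum(n)
    if (tot == 0)
      stop_undefined(sprintf("empty %s class: allele percentages undefined", cls))
    data.frame(class = cls, allele = c("common", "variant"),
               count = c(2 * n[1] + n[2], 2 * n[3] + n[2]),
               pct = 100 * c(2 * n[1] + n[2], 2 * n[3] + n[2]) / tot,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  out
}

#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' Tests whether observed genotype counts are compatible with
#' Hardy-Weinberg proportions \eqn{p^2, 2pq, q^2}.
#' \describe{
#'   \item{\code{chi2}}{Pearson statistic against HWE-expected counts from
#'     the observed allele frequency, 1 degree of freedom.}
#'   \item{\code{exact}}{conditional exact test: enumerates every possible
#'     heterozygote count given the observed allele counts and sums the
#'     probabilities of configurations no more probable than the observed one
#'     (no mid-p adjustment).}
#' }
#'
#' @param n0,n1,n2 genotype counts (common hom, het, variant hom).
#' @param method \code{"chi2"} or \code{"exact"}.
#' @return list with \code{statistic} (chi-squared statistic; \code{NA} for
#'   the exact test) and \code{p}. A monomorphic sample returns \code{p = 1}
#'   by convention.
#' @examples
#' hwe_test(25, 50, 25)$p          # exact HWE proportions -> p = 1
#' hwe_test(50, 0, 50)$statistic   # complete heterozygote deficit
#' @export
hwe_test <- function(n0, n1, n2, method = c("chi2", "exact")) {
  method <- match.arg(method)
  n <- n0 + n1 + n2
  if (n == 0) stop_validation("empty genotype counts")
  na <- 2 * n2 + n1                     # variant allele count
  if (na == 0 || na == 2 * n)           # monomorphic
    return(list(statistic = if (method == "chi2") 0 else NA_real_, p = 1))
  if (method == "chi2") {
    q <- na / (2 * n)
    e <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
    stat <- sum((c(n0, n1, n2) - e)^2 / e)
    list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
  } else {
    list(statistic = NA_real_, p = hwe_exact_p(n, na, n1))
  }
}

# Conditional exact HWE p-value: heterozygote count h given 2n alleles of
# which `na` are the variant; h runs over values with the parity of `na`.
hwe_exact_p <- function(n, na, h_obs) {
  na <- min(na, 2 * n - na)
  h <- seq.int(na %% 2, na, by = 2)
  n2 <- (na - h) / 2
  n0 <- n - h - n2
  logp <- lgamma(n + 1) - lgamma(n0 + 1) - lgamma(h + 1) - lgamma(n2 + 1) +
    h * log(2) - (lgamma(2 * n + 1) - lgamma(na + 1) - lgamma(2 * n - na + 1))
  p <- exp(logp)
  p <- p / sum(p)
  obs <- p[match(h_obs, h)]
  if (is.na(obs)) stop_validation("heterozygote count inconsistent with allele counts")
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

#' Odds ratio with Wald confidence interval for a 2 x 2 table
#'
#' \eqn{OR = ad / bc} with the 95\% Wald interval
#' \eqn{\exp(\ln OR \pm z_{0.975} \sqrt{1/a + 1/b + 1/c + 1/d})}, where
#' a = exposed cases, b = unexposed cases, c = exposed controls,
#' d = unexposed controls. When any cell is zero and \code{haldane} is set,
#' the Haldane-Anscombe correction adds 0.5 to all four cells before the OR
#' and interval are computed. The p-value is the two-sided Fisher exact test
#' on the uncorrected integer table.
#'
#' @param a,b,c,d non-negative counts.
#' @param haldane apply the 0.5 correction on zero cells (default TRUE).
#' @param conf_level confidence level (default 0.95).
#' @return list: \code{or}, \code{ci_low}, \code{ci_high}, \code{p},
#'   \code{haldane_applied}. If both \eqn{ad} and \eqn{bc} are zero the OR is
#'   undefined and a \code{snpmdr_undefined_error} is raised.
#' @examples
#' odds_ratio_2x2(97, 124, 195, 515)  # OR 2.066 (1.51 - 2.82)
#' @export
odds_ratio_2x2 <- function(a, b, c, d, haldane = TRUE, conf_level = 0.95) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop_validation("counts must be non-negative")
  if (sum(cells) == 0) stop_validation("empty table")
  if (a * d == 0 && b * c == 0)
    stop_undefined("odds ratio undefined: both diagonal products are zero")
  p <- fisher.test(matrix(round(cells), 2, 2, byrow = TRUE))$p.value
  corrected <- haldane && any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(or = or, ci_low = exp(log(or) - z * se), ci_high = exp(log(or) + z * se),
       p = p, haldane_applied = corrected)
}

#' Collapse a genotype count table under an inheritance model
#'
#' Builds the 2 x 2 exposure table(s) for one inheritance model. The exposure
#' group (the "a/c" column) is fixed per model:
#' \describe{
#'   \item{codominant}{two tables -- heterozygote vs common homozygote, and
#'     variant homozygote vs common homozygote;}
#'   \item{dominant}{common homozygote vs carriers of the variant allele;}
#'   \item{recessive}{variant homozygote vs the rest;}
#'   \item{overdominant}{heterozygote vs both homozygotes;}
#'   \item{additive}{allele-count table, alleles as units (variant vs
#'     common).}
#' }
#' Published tables sometimes print the reciprocal orientation for some rows;
#' with a fixed convention those values correspond to \eqn{1/OR}.
#'
#' @param tab a \code{\link{genotype_count_table}}.
#' @param model one of \code{"codominant"} (both tables),
#'   \code{"codominant_het"}, \code{"codominant_hom"}, \code{"dominant"},
#'   \code{"recessive"}, \code{"overdominant"}, \code{"additive"}.
#' @return named list of 2 x 2 tables, each a list \code{(a, b, c, d,
#'   exposure)} with a = exposed cases, b = unexposed cases, c = exposed
#'   controls, d = unexposed controls.
#' @export
inheritance_tables <- function(tab, model) {
  stopifnot(inherits(tab, "genotype_count_table"))
  ca <- tab$counts["case", ]; co <- tab$counts["control", ]
  two <- function(a, b, c, d, exposure)
    list(a = unname(a), b = unname(b), c = unname(c), d = unname(d),
         exposure = exposure)
  tabs <- list(
    codominant_het = two(ca[2], ca[1], co[2], co[1],
                         "heterozygote vs common homozygote"),
    codominant_hom = two(ca[3], ca[1], co[3], co[1],
                         "variant homozygote vs common homozygote"),
    dominant = two(ca[1], ca[2] + ca[3], co[1], co[2] + co[3],
                   "common homozygote vs variant carrier"),
    recessive = two(ca[3], ca[1] + ca[2], co[3], co[1] + co[2],
                    "variant homozygote vs rest"),
    overdominant = two(ca[2], ca[1] + ca[3], co[2], co[1] + co[3],
                       "heterozygote vs homozygotes"),
    additive = two(2 * ca[3] + ca[2], 2 * ca[1] + ca[2],
                   2 * co[3] + co[2], 2 * co[1] + co[2],
                   "variant allele vs common allele (allele count)"))
  if (identical(model, "codominant")) return(tabs[c("codominant_het",
                                                    "codominant_hom")])
  if (!model %in% names(tabs))
    stop_validation(sprintf("unknown inheritance model '%s'", model))
  tabs[model]
}

#' Crude odds-ratio scan over all inheritance models
#'
#' Applies \code{\link{inheritance_tables}} and \code{\link{odds_ratio_2x2}}
#' for every inheritance model of one SNP's count table: the crude
#' (unadjusted) association profile of that SNP.
#'
#' @param tab a \code{\link{genotype_count_table}}.
#' @param haldane passed to \code{\link{odds_ratio_2x2}}.
#' @return data.frame with one row per model: \code{snp}, \code{model},
#'   \code{exposure}, \code{a}, \code{b}, \code{c}, \code{d}, \code{or},
#'   \code{ci_low}, \code{ci_high}, \code{p}, \code{n_used}.
#' @examples
#' tabs <- load_panel_counts()
#' scan <- crude_model_scan(tabs[["rs1800796"]])
#' scan[scan$model == "dominant", c("or", "ci_low", "ci_high")]
#' @export
crude_model_scan <- function(tab, haldane = TRUE) {
  rows <- lapply(INHERITANCE_MODELS, function(m) {
    t2 <- inheritance_tables(tab, m)[[1]]
    res <- tryCatch(odds_ratio_2x2(t2$a, t2$b, t2$c, t2$d, haldane = haldane),
                    snpmdr_undefined_error = function(e)
                      list(or = NA_real_, ci_low = NA_real_,
                           ci_high = NA_real_, p = NA_real_))
    data.frame(snp = tab$snp, model = m, exposure = t2$exposure,
               a = t2$a, b = t2$b, c = t2$c, d = t2$d,
               or = res$or, ci_low = res$ci_low, ci_high = res$ci_high,
               p = res$p, n_used = t2$a + t2$b + t2$c + t2$d,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Genotype term for model-coded logistic regression. Returns a vector or,
# for the full codominant factor fit, a factor.
genotype_term <- function(g, model) {
  switch(model,
         codominant     = factor(g, levels = 0:2),
         codominant_het = as.integer(g == 1),
         codominant_hom = as.integer(g == 2),
         dominant       = as.integer(g == 0),  # exposure = common homozygote
         recessive      = as.integer(g == 2),
         overdominant   = as.integer(g == 1),
         additive       = as.numeric(g),
         stop_validation(sprintf("unknown inheritance model '%s'", model)))
}

#' Covariate-adjusted odds ratio under an inheritance model
#'
#' Logistic regression of case status on the model-coded genotype term plus
#' covariates. The genotype coding follows the same exposure conventions as
#' \code{\link{inheritance_tables}}; \code{codominant_het} and
#' \code{codominant_hom} are contrasts of a single 3-level factor fit.
#'
#' @param ds a \code{\link{genotype_dataset}} with covariates.
#' @param snp SNP column name.
#' @param model inheritance model name (see \code{\link{inheritance_tables}};
#'   also accepts \code{"codominant_het"} / \code{"codominant_hom"}).
#' @param covariates character vector of covariate column names (may be
#'   empty for a crude logistic fit).
#' @return list: \code{snp}, \code{model}, \code{or}, \code{ci_low},
#'   \code{ci_high}, \code{p}, \code{aic}, \code{n_used}, \code{adjusted},
#'   \code{covariates}, \code{separation} (TRUE when quasi-complete
#'   separation leaves the Wald interval undefined; no silent fallback).
#' @export
adjusted_model_or <- function(ds, snp, model, covariates = character()) {
  stopifnot(inherits(ds, "genotype_dataset"))
  g <- ds$genotypes[, snp]
  covs <- if (length(covariates)) ds$covariates[covariates] else NULL
  keep <- !is.na(g)
  if (!is.null(covs)) keep <- keep & complete.cases(covs)
  g <- g[keep]
  fit_model <- if (model %in% c("codominant_het", "codominant_hom"))
    "codominant" else model
  term <- genotype_term(g, fit_model)
  if (length(unique(g)) < 2)
    stop_undefined(sprintf("genotype of %s is constant in complete cases", snp))
  df <- data.frame(.y = as.integer(ds$status[keep] == "case"), .g = term)
  if (!is.null(covs)) df <- cbind(df, covs[keep, , drop = FALSE])
  n_par <- ncol(df)
  if (nrow(df) < 10 * n_par)
    warning(sprintf("only %d complete cases for %d parameters", nrow(df), n_par))
  form <- stats::as.formula(paste(".y ~", paste(setdiff(names(df), ".y"),
                                                collapse = " + ")))
  warned_sep <- FALSE
  fit <- withCallingHandlers(
    glm(form, family = binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        warned_sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  coef_name <- switch(model,
                      codominant_het = ".g1",
                      codominant_hom = ".g2",
                      if (fit_model == "codominant") ".g1" else ".g")
  if (!coef_name %in% rownames(sm))
    stop_undefined(sprintf("coefficient for %s (%s) not estimable", snp, model))
  est <- sm[coef_name, "Estimate"]; se <- sm[coef_name, "Std. Error"]
  separation <- warned_sep || se > 100 || abs(est) > 15
  z <- qnorm(0.975)
  list(snp = snp, model = model,
       or = exp(est),
       ci_low = if (separation) NA_real_ else exp(est - z * se),
       ci_high = if (separation) NA_real_ else exp(est + z * se),
       p = if (separation) NA_real_ else sm[coef_name, "Pr(>|z|)"],
       aic = AIC(fit), n_used = nrow(df), adjusted = length(covariates) > 0,
       covariates = covariates, separation = separation)
}

#' Select the best-fitting inheritance model by AIC
#'
#' Fits logistic models (optionally covariate-adjusted) under the five
#' inheritance codings -- codominant (3-level factor), dominant, recessive,
#' overdominant, additive -- and returns the one with minimum AIC. Ties are
#' broken by that fixed model order, so selection is deterministic given the
#' data.
#'
#' @inheritParams adjusted_model_or
#' @return the selected model name; the per-model AIC vector is attached as
#'   attribute \code{"aic"}.
#' @export
select_best_model_aic <- function(ds, snp, covariates = character()) {
  models <- c("codominant", "dominant", "recessive", "overdominant", "additive")
  aic <- vapply(models, function(m) {
    tryCatch(adjusted_model_or(ds, snp, m, covariates)$aic,
             error = function(e) NA_real_)
  }, numeric(1))
  if (sum(!is.na(aic)) < 2)
    stop_undefined("fewer than two inheritance models could be fitted")
  best <- models[which.min(aic)]  # which.min skips NA, returns first minimum
  structure(best, aic = aic)
}

#' Fisher exact test on the 2 x 3 genotype table
#'
#' Two-sided exact test comparing the full genotype distribution between
#' cases and controls (network enumeration over all tables with the observed
#' margins).
#'
#' @param tab a \code{\link{genotype_count_table}}.
#' @return the exact p-value.
#' @export
fisher_genotype_test <- function(tab) {
  stopifnot(inherits(tab, "genotype_count_table"))
  m <- tab$counts[, colSums(tab$counts) > 0, drop = FALSE]
  if (ncol(m) < 2) return(1)
  fisher.test(m, workspace = 2e7)$p.value
}

#' Bonferroni multiple-testing adjustment
#'
#' \eqn{\min(1, m p)} for each of \eqn{m} p-values.
#'
#' @param pvals numeric vector of p-values.
#' @return adjusted p-values.
#' @export
bonferroni <- function(pvals) p.adjust(pvals, method = "bonferroni")

#' Full association report for a panel of count tables
#'
#' Runs \code{\link{crude_model_scan}} on each SNP, adds the exact genotype
#' test, exact HWE p-value in controls, allele frequencies, and a Bonferroni
#' column over the per-SNP genotype-test p-values.
#'
#' @param tables named list of \code{\link{genotype_count_table}}.
#' @return data.frame of scan rows for all SNPs, with columns
#'   \code{hwe_p_controls}, \code{fisher_genotype_p} and
#'   \code{fisher_genotype_p_bonferroni} repeated within SNP.
#' @export
association_report <- function(tables) {
  fisher_p <- vapply(tables, fisher_genotype_test, numeric(1))
  bonf <- bonferroni(fisher_p)
  rows <- lapply(seq_along(tables), function(i) {
    tab <- tables[[i]]
    sc <- crude_model_scan(tab)
    co <- tab$counts["control", ]
    sc$hwe_p_controls <- hwe_test(co[1], co[2], co[3], method = "exact")$p
    sc$fisher_genotype_p <- fisher_p[i]
    sc$fisher_genotype_p_bonferroni <- bonf[i]
    sc
  })
  do.call(rbind, rows)
}
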