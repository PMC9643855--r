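# Multifactor dimensionality reduction (MDR).
#
# A k-locus genotype combination defines 3^k cells. Each cell is pooled into
# a "high-risk" or "low-risk" class by comparing its case:control ratio
# (normalised by class totals) against a threshold T, reducing the
# k-dimensional genotype space to one binary attribute that is then scored
# by balanced accuracy under stratified cross-validation.

# Encode each subject's k-locus genotype as a cell index in 1..3^k.
# Subjects missing any of the k genotypes get NA and are excluded by keep.
cell_codes <- function(genotypes, snps) {
  g <- genotypes[, snps, drop = FALSE]
  code <- rep(1L, nrow(g))
  for (j in seq_along(snps)) code <- code + g[, j] * 3L^(j - 1L)
  list(code = code, keep = !is.na(code), n_cells = 3L^length(snps))
}

# Core cell fit: counts, case:control ratio, high/low/empty status.
# Ratio R = (n_cases/total_cases) / (n_controls/total_controls), with the
# totals taken over the (training) subset; cells with cases but no controls
# are high (R = Inf); cells with neither are empty and classify low.
fit_cells <- function(code, case, n_cells, threshold) {
  t_ca <- sum(case); t_co <- sum(!case)
  nca <- tabulate(code[case], nbins = n_cells)
  nco <- tabulate(code[!case], nbins = n_cells)
  ratio <- (nca * t_co) / (nco * t_ca)    # Inf when nco=0, nca>0; NaN if empty
  empty <- nca == 0L & nco == 0L
  high <- !empty & ratio > threshold
  list(high = high, empty = empty, nca = nca, nco = nco, ratio = ratio,
       t_ca = t_ca, t_co = t_co)
}

# Balanced accuracy of the high/low rule on a subset.
eval_rule <- function(high, code, case) {
  t_ca <- sum(case); t_co <- sum(!case)
  pred_high <- high[code]
  sens <- sum(pred_high & case) / t_ca
  spec <- sum(!pred_high & !case) / t_co
  c(ba = (sens + spec) / 2, sens = sens, spec = spec)
}

#' Stratified cross-validation folds
#'
#' Assigns subjects to folds by seeded shuffling within each class followed
#' by cyclic allocation (fold = position mod \code{n_folds}), giving exact
#' stratification and full determinism given the seed.
#'
#' @param status factor of control/case.
#' @param n_folds number of folds (default 10).
#' @param seed optional RNG seed.
#' @return integer fold index per subject.
#' @export
make_folds <- function(status, n_folds = 10, seed = NULL) {
  if (min(table(status)) < n_folds)
    stop_validation(sprintf(
      "smallest class has %d subjects; cannot stratify %d folds",
      min(table(status)), n_folds))
  with_seed(seed, {
    folds <- integer(length(status))
    for (cls in levels(status)) {
      i <- which(status == cls)
      perm <- if (length(i) > 1) sample(i) else i
      folds[perm] <- (seq_along(perm) - 1L) %% n_folds + 1L
    }
    folds
  })
}

#' Label the genotype cells of a k-SNP combination
#'
#' Computes, for every combination of genotype codes at the given SNPs, the
#' case and control counts, the normalised case:control ratio
#' \eqn{R = (n_{ca}/N_{ca}) / (n_{co}/N_{co})}, and the risk label:
#' \code{high} iff \eqn{R > T} (cells with cases but no controls are high),
#' \code{low} otherwise, \code{empty} when the cell holds no subjects.
#'
#' @param ds a \code{\link{genotype_dataset}}; subjects missing any of the
#'   SNPs are excluded.
#' @param snps character vector of k SNP names.
#' @param threshold the ratio threshold T (default 1.05; classic MDR uses 1).
#' @return data.frame with one row per cell: one genotype column per SNP,
#'   \code{n_cases}, \code{n_controls}, \code{ratio}, \code{label}.
#' @examples
#' ds <- resample_from_marginals(load_panel_counts(), seed = 1)
#' label_cells(ds, "rs1800629")
#' @export
label_cells <- function(ds, snps, threshold = 1.05) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (threshold <= 0) stop_validation("threshold must be positive")
  cc <- cell_codes(ds$genotypes, snps)
  case <- ds$status == "case"
  if (!sum(case[cc$keep]) || !sum(!case[cc$keep]))
    stop_validation("both classes must be present")
  fit <- fit_cells(cc$code[cc$keep], case[cc$keep], cc$n_cells, threshold)
  combos <- expand.grid(rep(list(0:2), length(snps)))
  names(combos) <- snps
  out <- cbind(combos,
               data.frame(n_cases = fit$nca, n_controls = fit$nco,
                          ratio = fit$ratio,
                          label = ifelse(fit$empty, "empty",
                                         ifelse(fit$high, "high", "low"))))
  rownames(out) <- NULL
  out
}

new_mdr_model <- function(snps, threshold, fit, n_folds) {
  cells <- expand.grid(rep(list(0:2), length(snps)))
  names(cells) <- snps
  cells$n_cases <- fit$nca; cells$n_controls <- fit$nco
  cells$ratio <- fit$ratio
  cells$label <- ifelse(fit$empty, "empty", ifelse(fit$high, "high", "low"))
  structure(list(snps = snps, threshold = threshold, cells = cells,
                 high = fit$high, n_folds = n_folds,
                 train_ba = NA_real_, test_ba = NA_real_,
                 sensitivity = NA_real_, specificity = NA_real_,
                 cv_consistency = NA_integer_, classifier_or = NULL,
                 p_perm = NA_real_),
            class = "mdr_model")
}

#' @export
print.mdr_model <- function(x, ...) {
  cat(sprintf("<mdr_model> %d-locus: %s (T = %g)\n", length(x$snps),
              paste(x$snps, collapse = " + "), x$threshold))
  cat(sprintf("  train BA %.4f | test BA %.4f | sens %.4f | spec %.4f | CVC %s/%d\n",
              x$train_ba, x$test_ba, x$sensitivity, x$specificity,
              x$cv_consistency, x$n_folds))
  if (!is.null(x$classifier_or))
    cat(sprintf("  classifier OR %.2f (%.2f-%.2f)\n", x$classifier_or$or,
                x$classifier_or$ci_low, x$classifier_or$ci_high))
  invisible(x)
}

#' Classify subjects with a fitted MDR model
#'
#' Assigns each subject the risk label of its genotype cell; cells that were
#' empty in training classify as low (conservative convention).
#'
#' @param model a fitted \code{mdr_model}.
#' @param genotypes a \code{\link{genotype_dataset}}, or a matrix/data.frame
#'   with the model's SNP columns. Missing genotypes among the model SNPs are
#'   an error -- exclude those subjects upstream.
#' @return character vector of \code{"high"} / \code{"low"}.
#' @export
classify <- function(model, genotypes) {
  stopifnot(inherits(model, "mdr_model"))
  g <- if (inherits(genotypes, "genotype_dataset")) genotypes$genotypes
       else as.matrix(genotypes)
  cc <- cell_codes(g, model$snps)
  if (any(!cc$keep))
    stop_validation("missing genotypes among model SNPs; exclude those subjects upstream")
  ifelse(model$high[cc$code], "high", "low")
}

#' Confusion metrics of an MDR model on a dataset
#'
#' @param model a fitted \code{mdr_model}.
#' @param ds a \code{\link{genotype_dataset}}; subjects missing model SNPs
#'   are excluded.
#' @return list: \code{balanced_accuracy}, \code{sensitivity} (high-labelled
#'   cases / cases), \code{specificity} (low-labelled controls / controls).
#' @export
confusion_metrics <- function(model, ds) {
  cc <- cell_codes(ds$genotypes, model$snps)
  case <- (ds$status == "case")[cc$keep]
  if (!sum(case) || !sum(!case)) stop_validation("both classes must be present")
  m <- eval_rule(model$high, cc$code[cc$keep], case)
  list(balanced_accuracy = unname(m["ba"]), sensitivity = unname(m["sens"]),
       specificity = unname(m["spec"]))
}

#' Odds ratio of the pooled high/low MDR attribute
#'
#' The 2 x 2 odds ratio of the model's high/low classification against
#' case/control status (Haldane-Anscombe corrected on zero cells).
#'
#' @param model a fitted \code{mdr_model}.
#' @param ds a \code{\link{genotype_dataset}}.
#' @return \code{\link{odds_ratio_2x2}} result list.
#' @export
classifier_or <- function(model, ds) {
  cc <- cell_codes(ds$genotypes, model$snps)
  case <- (ds$status == "case")[cc$keep]
  pred_high <- model$high[cc$code[cc$keep]]
  odds_ratio_2x2(sum(pred_high & case), sum(!pred_high & case),
                 sum(pred_high & !case), sum(!pred_high & !case))
}

#' Cross-validate one SNP combination
#'
#' Stratified n-fold cross-validation of the MDR rule for a fixed SNP set:
#' cells are labelled on each training split and the pooled attribute is
#' evaluated on the held-out fold.
#'
#' @param ds a \code{\link{genotype_dataset}}.
#' @param snps SNP names of the combination.
#' @param threshold ratio threshold T (default 1.05).
#' @param n_folds folds (default 10).
#' @param seed RNG seed for the fold split.
#' @param folds optional precomputed fold assignment (overrides \code{seed}).
#' @return list: \code{test_ba}, \code{test_sens}, \code{test_spec} (means
#'   over folds), \code{per_fold} data.frame, \code{folds}.
#' @export
cross_validate <- function(ds, snps, threshold = 1.05, n_folds = 10,
                           seed = NULL, folds = NULL) {
  stopifnot(inherits(ds, "genotype_dataset"))
  case <- ds$status == "case"
  if (is.null(folds)) folds <- make_folds(ds$status, n_folds, seed)
  cc <- cell_codes(ds$genotypes, snps)
  per <- t(vapply(seq_len(n_folds), function(f) {
    tr <- cc$keep & folds != f
    te <- cc$keep & folds == f
    fit <- fit_cells(cc$code[tr], case[tr], cc$n_cells, threshold)
    c(train = eval_rule(fit$high, cc$code[tr], case[tr]),
      test = eval_rule(fit$high, cc$code[te], case[te]))
  }, numeric(6)))
  per <- as.data.frame(per)
  names(per) <- c("train_ba", "train_sens", "train_spec",
                  "test_ba", "test_sens", "test_spec")
  per$fold <- seq_len(n_folds)
  list(test_ba = mean(per$test_ba), test_sens = mean(per$test_sens),
       test_spec = mean(per$test_spec), per_fold = per, folds = folds)
}

#' Exhaustive MDR model search with cross-validation
#'
#' Evaluates every k-SNP combination for each k in \code{k_min..k_max} under
#' stratified n-fold cross-validation. Within each fold the winning
#' combination is the one with minimal training classification error
#' (1 - training balanced accuracy; ties broken by combination order). The
#' reported model per k is the modal fold winner, refit on all data, with
#' testing metrics averaged over folds; its cross-validation consistency
#' (CVC) is the number of folds that chose it. The overall best model
#' maximises testing balanced accuracy, with ties resolved towards higher
#' CVC and then smaller k.
#'
#' @param ds a \code{\link{genotype_dataset}}.
#' @param k_min,k_max combination sizes to search (defaults 1 and the panel
#'   size).
#' @param threshold ratio threshold T (default 1.05).
#' @param n_folds folds (default 10).
#' @param seed RNG seed for the fold split.
#' @return object of class \code{mdr_search}: list with \code{models} (one
#'   fitted \code{mdr_model} per k), \code{summary} (data.frame: k, snps,
#'   train_ba, test_ba, sensitivity, specificity, cv_consistency, or,
#'   ci_low, ci_high), \code{best} (the winning \code{mdr_model}),
#'   \code{folds}.
#' @examples
#' ds <- resample_from_marginals(load_panel_counts(), seed = 1)
#' res <- search_best_models(ds, k_min = 1, k_max = 2, seed = 1)
#' res$summary
#' @export
search_best_models <- function(ds, k_min = 1,
                               k_max = ncol(ds$genotypes),
                               threshold = 1.05, n_folds = 10, seed = NULL) {
  stopifnot(inherits(ds, "genotype_dataset"))
  snps <- colnames(ds$genotypes)
  if (k_max > length(snps)) stop_validation("k_max exceeds the number of SNPs")
  case <- ds$status == "case"
  folds <- make_folds(ds$status, n_folds, seed)
  models <- list(); summ <- list()
  for (k in k_min:k_max) {
    combos <- combn(snps, k, simplify = FALSE)
    train_err <- matrix(NA_real_, length(combos), n_folds)
    test_ba <- test_sens <- test_spec <- train_err
    for (ci in seq_along(combos)) {
      cc <- cell_codes(ds$genotypes, combos[[ci]])
      for (f in seq_len(n_folds)) {
        tr <- cc$keep & folds != f
        te <- cc$keep & folds == f
        fit <- fit_cells(cc$code[tr], case[tr], cc$n_cells, threshold)
        train_err[ci, f] <- 1 - eval_rule(fit$high, cc$code[tr], case[tr])["ba"]
        m <- eval_rule(fit$high, cc$code[te], case[te])
        test_ba[ci, f] <- m["ba"]; test_sens[ci, f] <- m["sens"]
        test_spec[ci, f] <- m["spec"]
      }
    }
    winners <- apply(train_err, 2, which.min)      # first index on ties
    counts <- tabulate(winners, nbins = length(combos))
    modal <- which.max(counts)                     # first (smallest) on ties
    cvc <- counts[modal]
    best_snps <- combos[[modal]]
    cc <- cell_codes(ds$genotypes, best_snps)
    fit <- fit_cells(cc$code[cc$keep], case[cc$keep], cc$n_cells, threshold)
    mod <- new_mdr_model(best_snps, threshold, fit, n_folds)
    full <- eval_rule(fit$high, cc$code[cc$keep], case[cc$keep])
    mod$train_ba <- unname(full["ba"])
    mod$test_ba <- mean(test_ba[modal, ])
    mod$sensitivity <- mean(test_sens[modal, ])
    mod$specificity <- mean(test_spec[modal, ])
    mod$cv_consistency <- cvc
    mod$classifier_or <- tryCatch(classifier_or(mod, ds),
                                  snpmdr_undefined_error = function(e) NULL)
    models[[as.character(k)]] <- mod
    summ[[as.character(k)]] <- data.frame(
      k = k, snps = paste(best_snps, collapse = "+"),
      train_ba = mod$train_ba, test_ba = mod$test_ba,
      sensitivity = mod$sensitivity, specificity = mod$specificity,
      cv_consistency = cvc,
      or = mod$classifier_or$or %||% NA_real_,
      ci_low = mod$classifier_or$ci_low %||% NA_real_,
      ci_high = mod$classifier_or$ci_high %||% NA_real_,
      stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, summ)
  rownames(summary) <- NULL
  # best: max test BA, then higher consistency, then smaller k
  ord <- order(-summary$test_ba, -summary$cv_consistency, summary$k)
  structure(list(models = models, summary = summary,
                 best = models[[as.character(summary$k[ord[1]])]],
                 folds = folds, threshold = threshold),
            class = "mdr_search")
}

#' @export
print.mdr_search <- function(x, ...) {
  cat("<mdr_search>\n")
  print(x$summary, digits = 4)
  cat("best model:\n"); print(x$best)
  invisible(x)
}

#' Permutation test for an MDR combination
#'
#' Permutes case/control labels \code{n_perm} times, recomputing the mean
#' testing balanced accuracy (with freshly stratified folds per permutation),
#' and reports \eqn{p = (r + 1) / (n_{perm} + 1)} where \eqn{r} counts
#' permutations with accuracy at least the observed -- never exactly zero.
#'
#' @param ds a \code{\link{genotype_dataset}}.
#' @param snps SNP combination to test.
#' @param threshold ratio threshold T (default 1.05).
#' @param n_folds folds (default 10).
#' @param n_perm number of permutations (at least 1).
#' @param seed RNG seed.
#' @return list: \code{p}, \code{observed_ba}, \code{perm_ba} (vector).
#' @export
permutation_test <- function(ds, snps, threshold = 1.05, n_folds = 10,
                             n_perm = 1000, seed = NULL) {
  if (n_perm < 1) stop_validation("n_perm must be at least 1")
  case <- ds$status == "case"
  cc <- cell_codes(ds$genotypes, snps)
  with_seed(seed, {
    obs <- cv_mean_ba(cc, case, make_folds_raw(case, n_folds), n_folds,
                      threshold)
    perm <- vapply(seq_len(n_perm), function(i) {
      pc <- sample(case)
      cv_mean_ba(cc, pc, make_folds_raw(pc, n_folds), n_folds, threshold)
    }, numeric(1))
    list(p = (sum(perm >= obs) + 1) / (n_perm + 1),
         observed_ba = obs, perm_ba = perm)
  })
}

# Fold assignment from a logical case vector using the current RNG stream.
make_folds_raw <- function(case, n_folds) {
  folds <- integer(length(case))
  for (is_case in c(FALSE, TRUE)) {
    i <- which(case == is_case)
    perm <- if (length(i) > 1) sample(i) else i
    folds[perm] <- (seq_along(perm) - 1L) %% n_folds + 1L
  }
  folds
}

# Mean test balanced accuracy over folds (fast path, no bookkeeping).
cv_mean_ba <- function(cc, case, folds, n_folds, threshold) {
  ba <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    tr <- cc$keep & folds != f
    te <- cc$keep & folds == f
    fit <- fit_cells(cc$code[tr], case[tr], cc$n_cells, threshold)
    ba[f] <- eval_rule(fit$high, cc$code[te], case[te])["ba"]
  }
  mean(ba)
}

#' List the risk genotype combinations of a fitted model
#'
#' All non-empty cells of the model sorted by decreasing case:control ratio,
#' with their counts and labels -- the machine-readable analogue of a
#' high/low-risk genotype bar chart. The number of empty cells is attached
#' as attribute \code{"empty_cells"}.
#'
#' @param model a fitted \code{mdr_model}.
#' @return data.frame of non-empty cells (genotype columns, \code{n_cases},
#'   \code{n_controls}, \code{ratio}, \code{label}).
#' @export
list_risk_combinations <- function(model) {
  stopifnot(inherits(model, "mdr_model"))
  cells <- model$cells[model$cells$label != "empty", , drop = FALSE]
  cells <- cells[order(-cells$ratio), , drop = FALSE]
  rownames(cells) <- NULL
  structure(cells, empty_cells = sum(model$cells$label == "empty"))
}
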