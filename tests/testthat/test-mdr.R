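panel_ds <- resample_from_marginals(load_panel_counts(), seed = 1)

test_that("cell labelling reproduces the single-locus ratios from the marginals", {
  cells <- label_cells(panel_ds, "rs1800629", threshold = 1.05)
  # ratios derived directly from the published counts
  expect_equal(cells$ratio,
               c((154 / 221) / (634 / 710), (21 / 221) / (72 / 710),
                 (46 / 221) / (4 / 710)), tolerance = 1e-12)
  expect_equal(cells$label, c("low", "low", "high"))

  even <- genotype_dataset(matrix(c(rep(0L, 20)), ncol = 1,
                                  dimnames = list(NULL, "s")),
                           rep(c(0, 1), 10))
  expect_equal(label_cells(even, "s")$label[1], "low")   # R = 1 is low
  expect_equal(label_cells(even, "s", threshold = 1e-9)$label[1], "high")
})

test_that("classification and confusion metrics match count bookkeeping", {
  fit <- search_best_models(panel_ds, 1, 1, seed = 1)
  mod <- fit$models[["1"]]
  expect_identical(mod$snps, "rs1800629")
  lab <- classify(mod, panel_ds)
  case <- panel_ds$status == "case"
  expect_equal(sum(lab == "high" & case), 46)
  expect_equal(sum(lab == "high" & !case), 4)
  cm <- confusion_metrics(mod, panel_ds)
  expect_equal(cm$sensitivity, 46 / 221, tolerance = 1e-12)
  expect_equal(cm$specificity, 706 / 710, tolerance = 1e-12)
  expect_equal(cm$balanced_accuracy, (46 / 221 + 706 / 710) / 2,
               tolerance = 1e-12)
  r <- classifier_or(mod, panel_ds)
  expect_equal(r$or, (46 * 706) / (175 * 4), tolerance = 1e-12)

  # subjects in cells unseen at training classify low
  toy <- genotype_dataset(matrix(c(0L, 0L, 1L, 1L), ncol = 1,
                                 dimnames = list(NULL, "s")), c(0, 0, 1, 1))
  m <- search_best_models(toy, 1, 1, n_folds = 2, seed = 1)$models[["1"]]
  unseen <- matrix(2L, 1, 1, dimnames = list(NULL, "s"))
  expect_equal(classify(m, unseen), "low")
})

test_that("all-low classifiers give an undefined odds ratio", {
  g <- matrix(rep(0L, 40), ncol = 1, dimnames = list(NULL, "s"))
  ds <- genotype_dataset(g, rep(c(0, 1), 20))
  m <- search_best_models(ds, 1, 1, n_folds = 2, seed = 1)$models[["1"]]
  expect_error(classifier_or(m, ds), class = "snpmdr_undefined_error")
})

test_that("cross-validation is deterministic, perfect on a determining SNP, and null-calibrated", {
  det <- genotype_dataset(
    matrix(rep(c(0L, 2L), each = 50), ncol = 1, dimnames = list(NULL, "s")),
    rep(c(0, 1), each = 50))
  cv <- cross_validate(det, "s", n_folds = 10, seed = 5)
  expect_equal(cv$test_ba, 1)

  a <- cross_validate(panel_ds, c("rs1800587", "rs2069705"), seed = 7)
  b <- cross_validate(panel_ds, c("rs1800587", "rs2069705"), seed = 7)
  expect_identical(a$per_fold, b$per_fold)
  expect_identical(a$folds, b$folds)

  hits <- vapply(1:20, function(s) {
    ds <- random_dataset(500, 500, 1, mafs = 0.3, seed = 400 + s)
    ba <- cross_validate(ds, "rs1", seed = s)$test_ba
    ba >= 0.45 && ba <= 0.55
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("the exhaustive search enumerates C(m,k) combinations per k", {
  res <- search_best_models(panel_ds, 1, 5, seed = 2)
  expect_equal(nrow(res$summary), 5)
  # combination counts 5, 10, 10, 5, 1 are implied by exhaustive search;
  # spot-check via a fold-winner recount at k = 2
  expect_true(all(res$summary$cv_consistency <= 10))
  single <- genotype_dataset(panel_ds$genotypes[, "rs1800629", drop = FALSE],
                             panel_ds$status)
  one <- search_best_models(single, 1, 1, seed = 3)
  expect_equal(one$models[["1"]]$cv_consistency, 10)
})

test_that("best training accuracy is monotone in k at T = 1 on a fixed split", {
  # at the classic threshold T = 1 refining the cell partition can never
  # lose training balanced accuracy, so the per-k best is non-decreasing
  for (s in 1:5) {
    ds <- random_dataset(60, 60, 4, seed = 500 + s)
    case <- ds$status == "case"
    rows <- seq_along(ds$subjects)
    best_tr <- vapply(1:4, function(k) {
      combos <- combn(colnames(ds$genotypes), k, simplify = FALSE)
      max(vapply(combos, function(cmb) {
        cells <- label_cells(ds, cmb, threshold = 1)
        hi <- cells$label == "high"
        sens <- sum(cells$n_cases[hi]) / sum(case)
        spec <- sum(cells$n_controls[!hi]) / sum(!case)
        (sens + spec) / 2
      }, numeric(1)))
    }, numeric(1))
    expect_true(all(diff(best_tr) >= -1e-12),
                label = sprintf("seed %d best train BA %s", s,
                                paste(round(best_tr, 4), collapse = " ")))
  }
})

test_that("swapping classes and inverting the threshold flips cell labels", {
  set.seed(14)
  for (i in 1:10) {
    ds <- random_dataset(40, 60, 2, seed = 600 + i)
    t <- 1.05
    orig <- label_cells(ds, c("rs1", "rs2"), threshold = t)
    swapped <- genotype_dataset(ds$genotypes,
                                ifelse(ds$status == "case", 0, 1))
    flip <- label_cells(swapped, c("rs1", "rs2"), threshold = 1 / t)
    both <- orig$n_cases > 0 & orig$n_controls > 0 &
      abs(orig$ratio - t) > 1e-9 & abs(orig$ratio - 1 / t) > 1e-9
    expect_equal(flip$label[both] == "high", orig$label[both] == "low")
  }
})

test_that("search results equal the naive brute-force reference", {
  for (s in 1:6) {
    n_ca <- sample(30:90, 1); n_co <- sample(30:90, 1)
    ds <- random_dataset(n_ca, n_co, 4, seed = 700 + s)
    folds <- make_folds(ds$status, 5, seed = s)
    res <- search_best_models(ds, 1, 2, n_folds = 5, seed = s)
    for (k in 1:2) {
      ref <- naive_mdr_search_k(ds, k, folds, 1.05)
      mod <- res$models[[as.character(k)]]
      expect_identical(mod$snps, ref$modal_snps)
      expect_equal(mod$cv_consistency, ref$consistency)
      expect_equal(mod$test_ba, ref$test_ba, tolerance = 1e-12)
    }
  }
})

test_that("permutation p respects the +1 rule and rejects n_perm = 0", {
  det <- genotype_dataset(
    matrix(rep(c(0L, 2L), each = 50), ncol = 1, dimnames = list(NULL, "s")),
    rep(c(0, 1), each = 50))
  r <- permutation_test(det, "s", n_perm = 19, seed = 15)
  expect_equal(r$p, 1 / 20)            # observed BA = 1 beats all permutations
  expect_gt(r$p, 0)
  expect_error(permutation_test(det, "s", n_perm = 0),
               class = "snpmdr_validation_error")
})

test_that("risk-combination listing sorts by ratio and reports empty cells", {
  fit <- search_best_models(panel_ds, 1, 1, seed = 1)
  lst <- list_risk_combinations(fit$models[["1"]])
  expect_equal(nrow(lst), 3)
  expect_equal(lst$rs1800629[1], 2)    # top row is the variant homozygote
  expect_true(all(diff(lst$ratio) <= 0))
  expect_equal(attr(lst, "empty_cells"), 0)

  sparse <- genotype_dataset(
    matrix(c(0L, 0L, 1L, 1L), ncol = 1, dimnames = list(NULL, "s")),
    c(0, 1, 0, 1))
  m <- search_best_models(sparse, 1, 1, n_folds = 2, seed = 1)$models[["1"]]
  l2 <- list_risk_combinations(m)
  expect_equal(nrow(l2), 2)
  expect_equal(attr(l2, "empty_cells"), 1)
})
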