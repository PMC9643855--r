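tabs <- load_panel_counts()

test_that("allele counts and percentages match the published table rows", {
  af <- allele_frequencies(tabs[["rs1800587"]])
  ctrl_common <- af[af$class == "control" & af$allele == "common", ]
  case_var <- af[af$class == "case" & af$allele == "variant", ]
  expect_equal(ctrl_common$count, 1173)
  expect_equal(round(ctrl_common$pct, 1), 82.6)
  expect_equal(case_var$count, 110)
  expect_equal(round(case_var$pct, 1), 24.9)

  empty <- genotype_count_table("x", rbind(c(0, 0, 0), c(1, 2, 3)))
  expect_error(allele_frequencies(empty), class = "snpmdr_undefined_error")
})

test_that("chi-squared HWE statistic matches hand computation", {
  # perfect HWE proportions -> statistic 0, p 1
  h <- hwe_test(25, 50, 25)
  expect_equal(h$statistic, 0)
  expect_equal(h$p, 1)
  # complete heterozygote deficit at p = q = 0.5: expected (25, 50, 25),
  # Pearson statistic = 25 + 50 + 25 = 100
  expect_equal(hwe_test(50, 0, 50)$statistic, 100)
  # monomorphic -> p = 1 by convention
  expect_equal(hwe_test(30, 0, 0)$p, 1)
  expect_equal(hwe_test(30, 0, 0, method = "exact")$p, 1)
})

test_that("exact HWE p equals brute-force enumeration on random tables", {
  set.seed(6)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    g <- rbinom(n, 2, runif(1, 0.05, 0.5))
    n0 <- sum(g == 0); n1 <- sum(g == 1); n2 <- sum(g == 2)
    if (n1 + n2 == 0) next
    expect_equal(hwe_test(n0, n1, n2, method = "exact")$p,
                 oracle_hwe_exact(n0, n1, n2), tolerance = 1e-10,
                 label = sprintf("(%d,%d,%d)", n0, n1, n2))
  }
})

test_that("odds_ratio_2x2 reproduces published values and obeys symmetry", {
  r <- odds_ratio_2x2(97, 124, 195, 515)
  expect_equal(r$or, 2.066, tolerance = 5e-4)
  expect_equal(r$ci_low, 1.51, tolerance = 5e-3)
  expect_equal(r$ci_high, 2.82, tolerance = 5e-3)

  r2 <- odds_ratio_2x2(16, 127, 23, 486)
  expect_equal(r2$or, 2.66, tolerance = 5e-3)
  expect_equal(r2$ci_low, 1.36, tolerance = 5e-3)
  expect_equal(r2$ci_high, 5.18, tolerance = 5e-3)

  expect_equal(odds_ratio_2x2(10, 10, 10, 10)$or, 1)

  # properties over random tables: reciprocal under exposure swap, CI covers
  # OR, Fisher p invariant under swaps
  set.seed(7)
  for (i in 1:20) {
    t <- sample(1:50, 4)
    a <- odds_ratio_2x2(t[1], t[2], t[3], t[4])
    b <- odds_ratio_2x2(t[2], t[1], t[4], t[3])
    expect_equal(a$or, 1 / b$or, tolerance = 1e-12)
    expect_true(a$ci_low <= a$or && a$or <= a$ci_high)
    expect_equal(a$p, b$p, tolerance = 1e-12)
  }
})

test_that("Haldane correction handles zero cells; double-zero diagonal is undefined", {
  r <- odds_ratio_2x2(10, 0, 0, 10)
  expect_true(r$haldane_applied)
  expect_equal(r$or, (10.5 * 10.5) / (0.5 * 0.5))
  expect_error(odds_ratio_2x2(5, 0, 3, 0), class = "snpmdr_undefined_error")
})

test_that("inheritance tables give the published codominant and recessive ORs", {
  t629 <- inheritance_tables(tabs[["rs1800629"]], "codominant_het")[[1]]
  expect_equal(unlist(t629[c("a", "b", "c", "d")]),
               c(a = 21, b = 154, c = 72, d = 634))
  expect_equal(odds_ratio_2x2(t629$a, t629$b, t629$c, t629$d)$or, 1.20,
               tolerance = 5e-3)
  tif <- inheritance_tables(tabs[["rs2069705"]], "recessive")[[1]]
  expect_equal(odds_ratio_2x2(tif$a, tif$b, tif$c, tif$d)$or, 1.35,
               tolerance = 5e-3)
})

test_that("crude scan reproduces published rows and is 1 on a null SNP", {
  il6 <- crude_model_scan(tabs[["rs1800796"]])
  expect_equal(il6$or[il6$model == "dominant"], 2.066, tolerance = 5e-4)
  expect_equal(il6$or[il6$model == "recessive"], 0.451, tolerance = 5e-4)
  il1a <- crude_model_scan(tabs[["rs1800587"]])
  expect_equal(il1a$or[il1a$model == "overdominant"], 1.3813, tolerance = 5e-5)

  null_tab <- genotype_count_table("null", rbind(c(50, 30, 20), c(50, 30, 20)))
  sc <- crude_model_scan(null_tab)
  expect_true(all(abs(sc$or - 1) < 1e-12))
})

test_that("adjusted OR converges to the crude OR when covariates are null", {
  set.seed(8)
  ds <- random_dataset(2500, 2500, 1, mafs = 0.3)
  ds$covariates <- data.frame(noise = rnorm(5000))
  crude <- adjusted_model_or(ds, "rs1", "additive", character())
  adj <- adjusted_model_or(ds, "rs1", "additive", "noise")
  expect_lt(abs(log(adj$or) - log(crude$or)), 0.05)
  expect_true(adj$adjusted)
  expect_false(crude$adjusted)
  expect_true(is.finite(adj$aic))
})

test_that("separation and constant genotype terms are flagged, not silent", {
  set.seed(9)
  ds <- random_dataset(100, 100, 1, mafs = 0.3)
  ds$covariates <- data.frame(leak = as.numeric(ds$status == "case"))
  res <- suppressWarnings(adjusted_model_or(ds, "rs1", "additive", "leak"))
  expect_true(res$separation)
  expect_true(is.na(res$ci_low))

  mono <- genotype_dataset(matrix(rep(0L, 40), ncol = 1,
                                  dimnames = list(NULL, "rs1")),
                           rep(c(0, 1), 20))
  expect_error(adjusted_model_or(mono, "rs1", "additive"),
               "constant", class = "snpmdr_undefined_error")
})

test_that("AIC selects the generating inheritance model in most seeds", {
  pick <- function(seed, probs, n) {
    spec <- cohort_spec(n, n, c(rs1 = 0.4), seed = seed)
    ds <- simulate_cohort(spec, penetrance_model("rs1", probs))
    as.character(suppressWarnings(select_best_model_aic(ds, "rs1")))
  }
  rec <- vapply(1:30, function(s) pick(s, c(0.2, 0.2, 0.7), 1000), "")
  expect_gte(mean(rec == "recessive"), 0.9)
  # per-allele log-odds mechanism -> additive coding wins most seeds
  padd <- plogis(qlogis(0.25) + log(1.8) * (0:2))
  add <- vapply(1:20, function(s) pick(s + 100, padd, 2500), "")
  expect_gte(mean(add == "additive"), 0.8)
  # determinism on a fixed dataset
  ds <- random_dataset(100, 100, 1, seed = 10)
  expect_identical(as.character(select_best_model_aic(ds, "rs1")),
                   as.character(select_best_model_aic(ds, "rs1")))
})

test_that("2x3 Fisher test equals enumeration and approximates chi-squared", {
  same <- genotype_count_table("s", rbind(c(10, 20, 5), c(10, 20, 5)))
  expect_equal(fisher_genotype_test(same), 1)

  extreme <- genotype_count_table("e", rbind(c(5, 0, 0), c(0, 0, 5)))
  expect_equal(fisher_genotype_test(extreme),
               oracle_fisher_2x3(rbind(c(5, 0, 0), c(0, 0, 5))),
               tolerance = 1e-9)

  set.seed(11)
  for (i in 1:5) {
    m <- matrix(rpois(6, 8) + 1, 2, 3)
    expect_equal(fisher_genotype_test(genotype_count_table("r", m)),
                 oracle_fisher_2x3(m), tolerance = 1e-7)
  }
  big <- matrix(c(150, 160, 120, 110, 40, 55), 2, 3)
  chi <- suppressWarnings(chisq.test(big))$p.value
  expect_lt(abs(fisher_genotype_test(genotype_count_table("b", big)) - chi),
            0.05)
})

test_that("bonferroni caps at 1 and scales by the number of tests", {
  expect_equal(bonferroni(0.01), 0.01)
  expect_equal(bonferroni(c(0.01, 0.04)), c(0.02, 0.08))
  expect_equal(bonferroni(rep(0.5, 3)), rep(1, 3))
})
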