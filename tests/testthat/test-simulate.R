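test_that("HWE genotype sampling matches the binomial model", {
  expect_true(all(sample_genotypes_hwe(0, 100, seed = 1) == 0))
  g <- sample_genotypes_hwe(0.5, 1e5, seed = 2)
  freqs <- tabulate(g + 1, 3) / 1e5
  se <- sqrt(c(0.25, 0.5, 0.25) * c(0.75, 0.5, 0.75) / 1e5)
  expect_true(all(abs(freqs - c(0.25, 0.5, 0.25)) < 3 * se))
  expect_identical(sample_genotypes_hwe(0.3, 50, seed = 9),
                   sample_genotypes_hwe(0.3, 50, seed = 9))
  expect_error(sample_genotypes_hwe(0.7, 10), class = "snpmdr_validation_error")
})

test_that("XOR penetrance encodes the exactly-one-heterozygote rule", {
  m <- xor_penetrance("a", "b", 0.6, 0.1)
  cell <- function(ga, gb) m$probs[1 + ga + 3 * gb]
  expect_equal(cell(1, 1), 0.1)          # double het is low
  expect_equal(cell(1, 0), 0.6)
  expect_equal(cell(0, 1), 0.6)
  expect_equal(cell(2, 1), 0.6)
  expect_equal(cell(0, 0), 0.1)
  u <- xor_penetrance("a", "b", 0.3, 0.3)
  expect_true(all(u$probs == 0.3))
  # closed-form prevalence at mafs 0.5: sum over the 9 cells with HWE weights
  w <- c(0.25, 0.5, 0.25)
  prev <- sum(outer(w, w) * matrix(m$probs, 3, 3))
  expect_equal(prev, 0.1 + 0.5 * (0.6 - 0.1))
  # and equal marginal penetrance per genotype of each locus
  marg <- sapply(0:2, function(ga) sum(w * matrix(m$probs, 3, 3)[ga + 1, ]))
  expect_true(all(abs(marg - prev) < 1e-12))
})

test_that("a uniform-penetrance cohort shows null per-SNP association", {
  spec <- cohort_spec(200, 200, c(rs1 = 0.3, rs2 = 0.5), seed = 21)
  ds <- simulate_cohort(spec, uniform_penetrance("rs1", 0.5))
  for (s in c("rs1", "rs2")) {
    t2 <- inheritance_tables(marginal_counts(ds, s), "additive")[[1]]
    r <- odds_ratio_2x2(t2$a, t2$b, t2$c, t2$d)
    se <- sqrt(1 / t2$a + 1 / t2$b + 1 / t2$c + 1 / t2$d)
    expect_lt(abs(log(r$or)), 3 * se)
  }
})

test_that("control-sample MAFs recover the generating frequencies", {
  mafs <- c(rs1 = 0.12, rs2 = 0.35, rs3 = 0.5)
  spec <- cohort_spec(50, 4000, mafs, seed = 22)
  ds <- simulate_cohort(spec, NULL)
  ctrl <- ds$status == "control"
  for (s in names(mafs)) {
    est <- snp_maf(ds, s, subset = ctrl)
    se <- sqrt(mafs[[s]] * (1 - mafs[[s]]) / (2 * 4000))
    expect_lt(abs(est - mafs[[s]]), 3 * se)
  }
})

test_that("degenerate quotas and impossible ascertainment behave as specified", {
  spec <- cohort_spec(0, 10, c(rs1 = 0.3), seed = 23)
  ds <- simulate_cohort(spec, uniform_penetrance("rs1", 0))
  expect_equal(sum(ds$status == "control"), 10)
  expect_equal(nrow(ds$genotypes), 10)

  spec2 <- cohort_spec(5, 5, c(rs1 = 0.3), seed = 24)
  expect_error(simulate_cohort(spec2, uniform_penetrance("rs1", 0),
                               max_attempts = 5000),
               "ascertainment", class = "snpmdr_validation_error")
})

test_that("marginal resampling is exact, seeded, and joint rows vary by seed", {
  tabs <- load_panel_counts()
  d1 <- resample_from_marginals(tabs, seed = 1)
  d2 <- resample_from_marginals(tabs, seed = 1)
  d3 <- resample_from_marginals(tabs, seed = 2)
  expect_identical(d1$genotypes, d2$genotypes)
  expect_false(identical(d1$genotypes, d3$genotypes))
  for (s in names(tabs))
    expect_identical(marginal_counts(d3, s)$counts, tabs[[s]]$counts)

  one <- list(genotype_count_table("z", rbind(c(2, 0, 0), c(0, 0, 2))))
  dz <- resample_from_marginals(one, seed = 3)
  expect_equal(unname(dz$genotypes[dz$status == "control", "z"]), c(0L, 0L))
  expect_equal(unname(dz$genotypes[dz$status == "case", "z"]), c(2L, 2L))

  bad <- list(tabs[[1]], genotype_count_table("w", rbind(c(1, 0, 0), c(1, 0, 0))))
  expect_error(resample_from_marginals(bad), class = "snpmdr_validation_error")
})

test_that("cohort specs round-trip through JSON and YAML config files", {
  pj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(n_cases = 30, n_controls = 60,
                            mafs = list(rs1 = 0.2, rs2 = 0.4), seed = 5),
                       pj, auto_unbox = TRUE)
  sp <- read_cohort_spec(pj)
  expect_equal(sp$n_cases, 30L)
  expect_equal(sp$mafs, c(rs1 = 0.2, rs2 = 0.4))
  expect_equal(sp$seed, 5)

  py <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_cases: 10", "n_controls: 20", "mafs:", "  rsX: 0.35",
               "seed: 2"), py)
  spy <- read_cohort_spec(py)
  expect_equal(spy$mafs, c(rsX = 0.35))
  ds <- simulate_cohort(spy, NULL)
  expect_equal(unname(table(ds$status)), c(20L, 10L), ignore_attr = TRUE)
})

test_that("normal covariates match their class means and SDs", {
  params <- list(age = list(type = "normal",
                            control = c(mean = 71.5, sd = 7.8),
                            case = c(mean = 76.9, sd = 7.9)),
                 fixed = list(type = "normal",
                              control = c(mean = 5, sd = 0),
                              case = c(mean = 5, sd = 0)))
  status <- factor(rep(c("control", "case"), c(1e5, 1e4)),
                   c("control", "case"))
  cov <- simulate_covariates(params, status, seed = 31)
  expect_lt(abs(mean(cov$age[status == "control"]) - 71.5), 0.1)
  expect_lt(abs(mean(cov$age[status == "case"]) - 76.9), 0.3)
  expect_true(all(cov$fixed == 5))
})

test_that("skewed covariates hit the specified median and quartiles", {
  params <- list(glucose = list(type = "skewed",
                                control = c(median = 98, q1 = 90, q3 = 109),
                                case = c(median = 110, q1 = 95, q3 = 148)))
  status <- factor(rep("control", 1e5), c("control", "case"))
  cov <- simulate_covariates(params, status, seed = 32)
  q <- quantile(cov$glucose, c(0.25, 0.5, 0.75))
  expect_true(all(abs(q - c(90, 98, 109)) < 1))

  bad <- list(g = list(type = "skewed",
                       control = c(median = 98, q1 = 109, q3 = 90),
                       case = c(median = 98, q1 = 109, q3 = 90)))
  expect_error(simulate_covariates(bad, status, seed = 1),
               "inverted", class = "snpmdr_validation_error")
})

test_that("LDL equations and BMI classes follow their definitions", {
  expect_equal(ldl_friedewald(200, 50, 100), 130)
  expect_equal(ldl_friedewald(200, 50, 100, variant = "delong"), 134)
  expect_equal(ldl_friedewald(180, 45, 0), 135)
  expect_equal(ldl_friedewald(180, 45, 0, variant = "delong"), 135)
  expect_warning(ldl_friedewald(300, 50, 450), "unreliable")
  expect_error(ldl_friedewald(-1, 50, 100), class = "snpmdr_validation_error")

  expect_equal(as.character(bmi_class(c(24.9, 25.0, 29.9, 30.0, 41))),
               c("normal", "overweight", "overweight", "obese", "obese"))
  expect_error(bmi_class(0), class = "snpmdr_validation_error")
})
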