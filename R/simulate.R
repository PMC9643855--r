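#' Penetrance model over a set of SNPs
#'
#' Maps every k-locus genotype combination (codes 0/1/2 per SNP) to a disease
#' probability -- the generative device for simulating case-control data with
#' known architecture, including pure epistasis.
#'
#' @param snps character vector of k SNP names.
#' @param probs numeric vector of length \eqn{3^k} of disease probabilities,
#'   ordered with the first SNP varying fastest (cell index
#'   \eqn{1 + \sum_j g_j 3^{j-1}}), or a k-dimensional array with dimensions
#'   \code{c(3, 3, ...)}.
#' @return object of class \code{penetrance_model}.
#' @seealso \code{\link{xor_penetrance}}, \code{\link{uniform_penetrance}}
#' @export
penetrance_model <- function(snps, probs) {
  k <- length(snps)
  probs <- as.numeric(probs)
  if (length(probs) != 3^k)
    stop_validation(sprintf("need 3^%d = %d probabilities, got %d",
                            k, 3^k, length(probs)))
  if (any(probs < 0 | probs > 1))
    stop_validation("penetrance values must lie in [0, 1]")
  structure(list(snps = snps, probs = probs), class = "penetrance_model")
}

#' @export
print.penetrance_model <- function(x, ...) {
  cat(sprintf("<penetrance_model> %d locus/loci: %s\n", length(x$snps),
              paste(x$snps, collapse = ", ")))
  cat(sprintf("penetrance range [%.3g, %.3g]\n", min(x$probs), max(x$probs)))
  invisible(x)
}

#' Uniform (null) penetrance model
#' @param snps SNP names (the model spans them but confers no effect).
#' @param p constant disease probability (default 0.5).
#' @return a \code{\link{penetrance_model}}.
#' @export
uniform_penetrance <- function(snps, p = 0.5)
  penetrance_model(snps, rep(p, 3^length(snps)))

#' XOR (pure epistasis) two-locus penetrance model
#'
#' Disease probability \code{p_high} when exactly one of the two loci is
#' heterozygous, \code{p_low} otherwise (including the double heterozygote).
#' At allele frequencies 0.5 under Hardy-Weinberg each locus has identical
#' marginal penetrance across its three genotypes, so the model carries
#' interaction with no single-locus main effect -- the canonical hard case an
#' MDR search should still detect. Expected population prevalence at mafs 0.5
#' is \eqn{p_{low} + (p_{high} - p_{low})/2}.
#'
#' @param snpA,snpB locus names.
#' @param p_high,p_low penetrances, \eqn{0 \le p_{low} < p_{high} \le 1}
#'   (equality gives the uniform model).
#' @return a \code{\link{penetrance_model}} over \code{c(snpA, snpB)}.
#' @export
xor_penetrance <- function(snpA, snpB, p_high = 0.6, p_low = 0.1) {
  if (p_low > p_high) stop_validation("p_low must not exceed p_high")
  g <- expand.grid(a = 0:2, b = 0:2)   # a varies fastest = snpA
  probs <- ifelse((g$a == 1) + (g$b == 1) == 1, p_high, p_low)
  penetrance_model(c(snpA, snpB), probs)
}

penetrance_lookup <- function(model, genotypes) {
  # genotypes: matrix with columns >= model$snps
  idx <- rep(1L, nrow(genotypes))
  for (j in seq_along(model$snps))
    idx <- idx + genotypes[, model$snps[j]] * 3L^(j - 1L)
  model$probs[idx]
}

#' Sample genotypes under Hardy-Weinberg equilibrium
#'
#' i.i.d. dosage draws with \eqn{P(2) = m^2}, \eqn{P(1) = 2m(1-m)},
#' \eqn{P(0) = (1-m)^2} for minor allele frequency \eqn{m} -- equivalently a
#' Binomial(2, m) count of variant alleles.
#'
#' @param maf minor allele frequency in [0, 0.5].
#' @param n number of subjects.
#' @param seed optional RNG seed (the global stream is used when NULL, and
#'   restored otherwise).
#' @return integer vector of genotype codes.
#' @export
sample_genotypes_hwe <- function(maf, n, seed = NULL) {
  if (maf < 0 || maf > 0.5) stop_validation("maf must lie in [0, 0.5]")
  with_seed(seed, rbinom(n, 2L, maf))
}

#' Specification of a synthetic case-control cohort
#'
#' @param n_cases,n_controls class quotas (positive integers).
#' @param mafs named numeric vector of per-SNP minor allele frequencies in
#'   (0, 0.5]; the names define the simulated panel.
#' @param covariate_params per-variable distribution parameters for both
#'   classes (see \code{\link{table2_covariate_params}} for the packaged
#'   defaults and the expected structure), or NULL for no covariates.
#' @param seed RNG seed used by \code{\link{simulate_cohort}}.
#' @return object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_cases, n_controls, mafs, covariate_params = NULL,
                        seed = NULL) {
  if (n_cases < 0 || n_controls < 0 || n_cases + n_controls == 0)
    stop_validation("class quotas must be non-negative and not both zero")
  if (is.null(names(mafs)) || any(!nzchar(names(mafs))))
    stop_validation("`mafs` must be a named vector (names are SNP ids)")
  if (any(mafs <= 0 | mafs > 0.5))
    stop_validation("mafs must lie in (0, 0.5]")
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 mafs = mafs, covariate_params = covariate_params,
                 seed = seed),
            class = "cohort_spec")
}

#' Read a cohort specification from a JSON or YAML config file
#'
#' The file carries the \code{\link{cohort_spec}} fields as key-value pairs:
#' \code{n_cases}, \code{n_controls}, \code{mafs} (a named mapping),
#' optional \code{covariate_params} and \code{seed}.
#'
#' @param path config file; format chosen by extension (\code{.json} or
#'   \code{.yaml}/\code{.yml}; YAML requires the \pkg{yaml} package).
#' @return a \code{\link{cohort_spec}}.
#' @export
read_cohort_spec <- function(path) {
  if (!file.exists(path)) stop_validation(sprintf("file not found: %s", path))
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_validation("reading YAML specs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  cohort_spec(n_cases = raw$n_cases, n_controls = raw$n_controls,
              mafs = unlist(raw$mafs),
              covariate_params = raw$covariate_params,
              seed = raw$seed)
}

#' Default covariate distribution parameters
#'
#' The parameter set the packaged examples use to emulate an elderly
#' case-control dementia cohort: age, education, BMI, total cholesterol and
#' HDL as normal mean/SD per class; glucose, LDL and triglycerides as
#' right-skewed median/quartile specifications; sex as a per-class male
#' frequency.
#'
#' @return named list; each element is a list with \code{type}
#'   (\code{"normal"}, \code{"skewed"} or \code{"binary"}) and per-class
#'   parameters (\code{control}, \code{case}): \code{c(mean, sd)} for
#'   normal, \code{c(median, q1, q3)} for skewed, a male-probability scalar
#'   for binary.
#' @export
table2_covariate_params <- function() {
  nrm <- function(co, ca) list(type = "normal", control = co, case = ca)
  skw <- function(co, ca) list(type = "skewed", control = co, case = ca)
  list(
    sex = list(type = "binary", control = 270 / 710, case = 76 / 221),
    age = nrm(c(mean = 71.5, sd = 7.8), c(mean = 76.9, sd = 7.9)),
    education = nrm(c(mean = 6.9, sd = 5.2), c(mean = 5.7, sd = 5.5)),
    bmi = nrm(c(mean = 27.4, sd = 5.0), c(mean = 26.4, sd = 5.4)),
    glucose = skw(c(median = 98, q1 = 90, q3 = 109),
                  c(median = 110, q1 = 95, q3 = 148)),
    cholesterol = nrm(c(mean = 202.6, sd = 41.2), c(mean = 247.0, sd = 31.6)),
    hdl = nrm(c(mean = 52.8, sd = 14.0), c(mean = 48.0, sd = 9.8)),
    ldl = skw(c(median = 117, q1 = 95, q3 = 140),
              c(median = 121, q1 = 101, q3 = 150.5)),
    triglycerides = skw(c(median = 146, q1 = 111, q3 = 196),
                        c(median = 167, q1 = 132, q3 = 240)))
}

# Draw from a three-parameter (shifted) log-normal matched exactly to the
# median and both quartiles. Falls back to a normal when the quartiles are
# symmetric about the median (the shift diverges there). Left-skewed specs
# (q1 + q3 < 2 median) are handled by reflection.
r_quantile_lognormal <- function(n, m, q1, q3) {
  if (!(q1 < m && m < q3))
    stop_validation(sprintf(
      "inverted quantile spec: need q1 < median < q3, got (%g, %g, %g)",
      q1, m, q3))
  denom <- q1 + q3 - 2 * m
  if (abs(denom) < 1e-9 * max(abs(m), 1))
    return(rnorm(n, m, (q3 - q1) / (2 * qnorm(0.75))))
  if (denom < 0) return(-r_quantile_lognormal(n, -m, -q3, -q1))
  gamma <- (q1 * q3 - m^2) / denom
  mu <- log(m - gamma)
  sigma <- log((q3 - gamma) / (m - gamma)) / qnorm(0.75)
  gamma + rlnorm(n, mu, sigma)
}

#' Simulate covariates for a given status vector
#'
#' Normal variables are drawn from the per-class mean/SD; skewed variables
#' from a shifted log-normal matched to the per-class median and quartiles;
#' binary (sex) from the per-class male frequency. An SD of zero yields a
#' constant column.
#'
#' @param params covariate parameter list (structure of
#'   \code{\link{table2_covariate_params}}).
#' @param status factor of \code{control}/\code{case} per subject.
#' @param seed optional RNG seed.
#' @return data.frame of covariates, one row per subject.
#' @export
simulate_covariates <- function(params, status, seed = NULL) {
  n <- length(status)
  with_seed(seed, {
    out <- lapply(names(params), function(v) {
      p <- params[[v]]
      x <- if (identical(p$type, "binary")) character(n) else numeric(n)
      for (cls in c("control", "case")) {
        i <- which(status == cls)
        if (!length(i)) next
        par <- p[[cls]]
        x[i] <- switch(p$type,
          normal = rnorm(length(i), par[["mean"]], par[["sd"]]),
          skewed = r_quantile_lognormal(length(i), par[["median"]],
                                        par[["q1"]], par[["q3"]]),
          binary = ifelse(runif(length(i)) < par, "male", "female"),
          stop_validation(sprintf("unknown covariate type '%s'", p$type)))
      }
      x
    })
    names(out) <- names(params)
    as.data.frame(out, stringsAsFactors = FALSE)
  })
}

#' Simulate a case-control cohort from a penetrance model
#'
#' Repeatedly draws individuals -- independent SNPs under Hardy-Weinberg at
#' the spec's allele frequencies, disease status from the penetrance table --
#' and keeps them until both class quotas are filled (case-control
#' ascertainment by rejection sampling, capped at \code{max_attempts}
#' draws). SNPs outside the model, and any extra background SNPs, have no
#' effect on disease. Covariates are then attached per class when the spec
#' carries covariate parameters.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param model a \code{\link{penetrance_model}} whose SNPs are a subset of
#'   the spec panel, or NULL for a null cohort (uniform penetrance 0.5).
#' @param background_snps number of additional effect-free SNPs to append,
#'   named \code{null1, null2, ...}.
#' @param background_maf their minor allele frequency (default 0.3).
#' @param max_attempts rejection-sampling cap (default 1e7); exceeded quotas
#'   raise an ascertainment error of class \code{snpmdr_validation_error}.
#' @param seed RNG seed; defaults to \code{spec$seed}.
#' @return a \code{\link{genotype_dataset}} (controls first, then cases).
#' @examples
#' spec <- cohort_spec(50, 50, c(rsA = 0.5, rsB = 0.5), seed = 1)
#' ds <- simulate_cohort(spec, xor_penetrance("rsA", "rsB", 0.6, 0.1))
#' table(ds$status)
#' @export
simulate_cohort <- function(spec, model = NULL, background_snps = 0,
                            background_maf = 0.3, max_attempts = 1e7,
                            seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  mafs <- spec$mafs
  if (background_snps > 0) {
    bg <- setNames(rep(background_maf, background_snps),
                   paste0("null", seq_len(background_snps)))
    mafs <- c(mafs, bg)
  }
  if (is.null(model)) model <- uniform_penetrance(names(mafs)[1])
  if (!all(model$snps %in% names(mafs)))
    stop_validation("penetrance model SNPs must be in the spec panel")
  snps <- names(mafs)
  with_seed(seed, {
    need_ca <- spec$n_cases; need_co <- spec$n_controls
    acc_ca <- acc_co <- vector("list", 0L)
    drawn <- 0
    while ((need_ca > 0 || need_co > 0) && drawn < max_attempts) {
      b <- min(max(1000L, 2L * (need_ca + need_co)), max_attempts - drawn)
      drawn <- drawn + b
      g <- vapply(snps, function(s) rbinom(b, 2L, mafs[[s]]), integer(b))
      g <- matrix(g, nrow = b, dimnames = list(NULL, snps))
      case <- runif(b) < penetrance_lookup(model, g)
      if (need_ca > 0 && any(case)) {
        take <- utils::head(which(case), need_ca)
        acc_ca[[length(acc_ca) + 1L]] <- g[take, , drop = FALSE]
        need_ca <- need_ca - length(take)
      }
      if (need_co > 0 && any(!case)) {
        take <- utils::head(which(!case), need_co)
        acc_co[[length(acc_co) + 1L]] <- g[take, , drop = FALSE]
        need_co <- need_co - length(take)
      }
    }
    if (need_ca > 0 || need_co > 0)
      stop_validation(sprintf(
        "ascertainment failed: %d case(s) and %d control(s) still missing after %g draws",
        need_ca, need_co, drawn))
    g <- rbind(do.call(rbind, acc_co), do.call(rbind, acc_ca))
    status <- factor(rep(c("control", "case"),
                         c(spec$n_controls, spec$n_cases)),
                     levels = c("control", "case"))
    covs <- if (!is.null(spec$covariate_params))
      simulate_covariates(spec$covariate_params, status)
    genotype_dataset(g, status, covariates = covs)
  })
}

#' Resample subject-level data from marginal genotype counts
#'
#' For each class and SNP independently, emits a random permutation of the
#' exact genotype multiset given by the counts, so the per-SNP class
#' marginals of the result reproduce the input tables integer-for-integer
#' under any seed. The joint genotype distribution across SNPs is
#' independent conditional on class -- an emulation assumption, since count
#' tables carry no joint information.
#'
#' @param tables list of \code{\link{genotype_count_table}} sharing class
#'   sizes.
#' @param seed optional RNG seed.
#' @return a \code{\link{genotype_dataset}} (controls first, then cases).
#' @examples
#' ds <- resample_from_marginals(load_panel_counts(), seed = 7)
#' identical(marginal_counts(ds, "rs1800629")$counts,
#'           load_panel_counts()[["rs1800629"]]$counts)
#' @export
resample_from_marginals <- function(tables, seed = NULL) {
  stopifnot(length(tables) >= 1)
  sizes <- vapply(tables, function(t) rowSums(t$counts), numeric(2))
  if (any(sizes[1, ] != sizes[1, 1]) || any(sizes[2, ] != sizes[2, 1]))
    stop_validation("all tables must share the same class sizes")
  n_co <- sizes["control", 1]; n_ca <- sizes["case", 1]
  with_seed(seed, {
    g <- vapply(tables, function(t) {
      co <- rep(0:2, t$counts["control", ])
      ca <- rep(0:2, t$counts["case", ])
      c(if (n_co > 1) sample(co) else co, if (n_ca > 1) sample(ca) else ca)
    }, integer(n_co + n_ca))
    g <- matrix(g, nrow = n_co + n_ca,
                dimnames = list(NULL, unname(vapply(tables, `[[`, "", "snp"))))
    status <- factor(rep(c("control", "case"), c(n_co, n_ca)),
                     levels = c("control", "case"))
    genotype_dataset(g, status)
  })
}

#' LDL cholesterol from the Friedewald equation or the DeLong modification
#'
#' \code{friedewald}: \eqn{LDL = TC - HDL - TG/5};
#' \code{delong}: \eqn{LDL = TC - HDL - 0.16 TG} (all mg/dL). The Friedewald
#' estimate is unreliable at triglycerides \eqn{\ge} 400 mg/dL (a warning is
#' raised).
#'
#' @param total_chol,hdl,trig total cholesterol, HDL and triglycerides in
#'   mg/dL (vectorised; non-negative).
#' @param variant \code{"friedewald"} (default) or \code{"delong"}.
#' @return LDL cholesterol in mg/dL.
#' @examples
#' ldl_friedewald(200, 50, 100)                      # 130
#' ldl_friedewald(200, 50, 100, variant = "delong")  # 134
#' @export
ldl_friedewald <- function(total_chol, hdl, trig,
                           variant = c("friedewald", "delong")) {
  variant <- match.arg(variant)
  if (any(total_chol < 0 | hdl < 0 | trig < 0, na.rm = TRUE))
    stop_validation("lipid inputs must be non-negative")
  if (variant == "friedewald" && any(trig >= 400, na.rm = TRUE))
    warning("Friedewald equation is unreliable at triglycerides >= 400 mg/dL")
  total_chol - hdl - trig * switch(variant, friedewald = 0.2, delong = 0.16)
}

#' Classify body mass index
#'
#' Half-open classes: normal \eqn{< 25}, overweight \eqn{[25, 30)}, obese
#' \eqn{\ge 30} kg/m2 (the boundary 30.0 is assigned obese so the classes
#' partition the whole range).
#'
#' @param bmi BMI in kg/m2 (vectorised, positive).
#' @return factor with levels \code{normal}, \code{overweight}, \code{obese}.
#' @export
bmi_class <- function(bmi) {
  if (any(bmi <= 0, na.rm = TRUE)) stop_validation("BMI must be positive")
  cut(bmi, breaks = c(0, 25, 30, Inf), right = FALSE,
      labels = c("normal", "overweight", "obese"))
}
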