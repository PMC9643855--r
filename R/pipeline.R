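#' Configuration for an end-to-end analysis run
#'
#' @param input path to a genotype file readable by
#'   \code{\link{read_genotype_table}}, or NULL to simulate/resample.
#' @param dialect input dialect (see \code{\link{read_genotype_table}}).
#' @param cohort a \code{\link{cohort_spec}} for the \code{simulate} stage,
#'   or the string \code{"panel_marginals"} to resample the packaged
#'   cytokine-panel count tables.
#' @param stages subset of \code{c("simulate", "qc", "assoc", "mdr",
#'   "network")}, run in that order.
#' @param k_min,k_max,threshold,n_folds,n_perm MDR parameters.
#' @param seed RNG seed; mandatory when any stochastic stage
#'   (\code{simulate}, \code{mdr} with permutations, fold splitting) runs.
#' @param out_dir output directory (created if absent).
#' @return object of class \code{run_config}.
#' @export
run_config <- function(input = NULL, dialect = "tabular", cohort = NULL,
                       stages = c("simulate", "qc", "assoc", "mdr", "network"),
                       k_min = 1, k_max = NULL, threshold = 1.05,
                       n_folds = 10, n_perm = 0, seed = NULL,
                       out_dir = tempfile("snpmdr_run_")) {
  stages <- match.arg(stages, several.ok = TRUE)
  stochastic <- "simulate" %in% stages || "mdr" %in% stages
  if (stochastic && is.null(seed))
    stop_validation("`seed` is mandatory when a stochastic stage runs")
  structure(list(input = input, dialect = dialect, cohort = cohort,
                 stages = stages, k_min = k_min, k_max = k_max,
                 threshold = threshold, n_folds = n_folds, n_perm = n_perm,
                 seed = seed, out_dir = out_dir),
            class = "run_config")
}

run_stage <- function(name, code) {
  tryCatch(force(code), error = function(e) {
    stop(structure(class = c("snpmdr_stage_error", "error", "condition"),
                   list(message = sprintf("stage '%s' failed: %s", name,
                                          conditionMessage(e)),
                        call = NULL, stage = name)))
  })
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order -- cohort simulation (or input
#' reading), QC filtering, single-SNP association, the MDR search, and the
#' interaction network -- writing each stage's tables to the output
#' directory together with a JSON manifest recording package version, seed
#' and parameters. Outputs are deterministic given the configuration seed.
#'
#' Files written (per stage): \code{cohort.tsv}, \code{descriptive.tsv},
#' \code{qc_report.tsv}, \code{association.tsv}, \code{mdr_summary.tsv},
#' \code{risk_combinations.tsv}, \code{network_nodes.tsv},
#' \code{network_edges.tsv}, \code{dendrogram.nwk}, \code{manifest.json}.
#'
#' @param config a \code{\link{run_config}}.
#' @param quiet suppress per-stage messages.
#' @return invisibly, a list with the in-memory results (\code{dataset},
#'   \code{qc}, \code{association}, \code{mdr}, \code{network},
#'   \code{files}).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  files <- character()
  out <- list()
  emit <- function(df, fname) {
    p <- file.path(config$out_dir, fname)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    files[[fname]] <<- p
  }

  ds <- NULL
  if ("simulate" %in% config$stages) {
    ds <- run_stage("simulate", {
      if (identical(config$cohort, "panel_marginals") || is.null(config$cohort))
        resample_from_marginals(load_panel_counts(), seed = config$seed)
      else simulate_cohort(config$cohort, seed = config$seed)
    })
    say("simulate: %d subjects, %d SNPs", nrow(ds$genotypes),
        ncol(ds$genotypes))
    p <- file.path(config$out_dir, "cohort.tsv")
    write_genotype_table(ds, p); files[["cohort.tsv"]] <- p
  } else if (!is.null(config$input)) {
    ds <- run_stage("read", read_genotype_table(config$input, config$dialect))
    say("read: %d subjects, %d SNPs", nrow(ds$genotypes), ncol(ds$genotypes))
  } else stop_validation("either an input file or the simulate stage is required")
  out$dataset <- ds

  if (!is.null(ds$covariates)) {
    desc <- run_stage("descriptive", descriptive_table(ds))
    emit(desc, "descriptive.tsv")
  }

  if ("qc" %in% config$stages) {
    qc <- run_stage("qc", qc_filter(ds))
    say("qc: %d of %d SNPs kept", sum(qc$report$kept), nrow(qc$report))
    emit(qc$report, "qc_report.tsv")
    ds <- qc$dataset
    out$qc <- qc$report
  }

  if ("assoc" %in% config$stages) {
    assoc <- run_stage("assoc", {
      tabs <- lapply(colnames(ds$genotypes), function(s) marginal_counts(ds, s))
      names(tabs) <- colnames(ds$genotypes)
      association_report(tabs)
    })
    say("assoc: %d model rows", nrow(assoc))
    emit(assoc, "association.tsv")
    pj <- file.path(config$out_dir, "association.json")
    jsonlite::write_json(assoc, pj, auto_unbox = TRUE, digits = NA)
    files[["association.json"]] <- pj
    out$association <- assoc
  }

  if ("mdr" %in% config$stages) {
    mdr <- run_stage("mdr", {
      res <- search_best_models(ds, k_min = config$k_min,
                                k_max = config$k_max %||% ncol(ds$genotypes),
                                threshold = config$threshold,
                                n_folds = config$n_folds, seed = config$seed)
      if (config$n_perm > 0)
        res$best$p_perm <- permutation_test(
          ds, res$best$snps, threshold = config$threshold,
          n_folds = config$n_folds, n_perm = config$n_perm,
          seed = config$seed)$p
      res
    })
    say("mdr: best model %s (test BA %.3f)",
        paste(mdr$best$snps, collapse = "+"), mdr$best$test_ba)
    emit(mdr$summary, "mdr_summary.tsv")
    emit(list_risk_combinations(mdr$best), "risk_combinations.tsv")
    pj <- file.path(config$out_dir, "mdr_model.json")
    best <- mdr$best
    jsonlite::write_json(
      list(snps = best$snps, threshold = best$threshold,
           cells = best$cells, train_ba = best$train_ba,
           test_ba = best$test_ba, sensitivity = best$sensitivity,
           specificity = best$specificity,
           cv_consistency = best$cv_consistency,
           classifier_or = best$classifier_or[c("or", "ci_low", "ci_high")],
           p_perm = best$p_perm),
      pj, auto_unbox = TRUE, digits = NA, null = "null")
    files[["mdr_model.json"]] <- pj
    out$mdr <- mdr
  }

  if ("network" %in% config$stages) {
    net <- run_stage("network", build_network(ds))
    emit(net$nodes, "network_nodes.tsv")
    emit(net$edges, "network_edges.tsv")
    dend <- run_stage("network", interaction_dendrogram(net))
    p <- file.path(config$out_dir, "dendrogram.nwk")
    writeLines(dend$newick, p); files[["dendrogram.nwk"]] <- p
    say("network: %d edges, dendrogram written", nrow(net$edges))
    out$network <- net
    out$dendrogram <- dend
  }

  manifest <- list(
    package = "snpmdr",
    version = as.character(utils::packageVersion("snpmdr")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed, stages = config$stages,
    parameters = list(k_min = config$k_min, k_max = config$k_max,
                      threshold = config$threshold, n_folds = config$n_folds,
                      n_perm = config$n_perm),
    outputs = as.list(files))
  mp <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  files[["manifest.json"]] <- mp
  out$files <- files
  invisible(out)
}

#' Class-comparison table of covariates
#'
#' Summarises each covariate per class and tests the case-control
#' difference: approximately normal variables as mean (SD) with a two-sample
#' t-test; skewed variables as median (IQR) with a Wilcoxon rank-sum test;
#' categorical variables as n (\%) with a chi-squared test. A covariate
#' constant in both groups gets p = 1 by convention and a note.
#'
#' @param ds a \code{\link{genotype_dataset}} with covariates.
#' @param skewed names of covariates to summarise as median (IQR)
#'   (default: glucose, LDL, triglycerides -- the typical right-skewed
#'   biochemistry panels).
#' @return data.frame: \code{variable}, \code{control}, \code{case},
#'   \code{test}, \code{p}, \code{note}.
#' @export
descriptive_table <- function(ds,
                              skewed = c("glucose", "ldl", "triglycerides")) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (is.null(ds$covariates)) stop_validation("dataset has no covariates")
  case <- ds$status == "case"
  rows <- lapply(names(ds$covariates), function(v) {
    x <- ds$covariates[[v]]
    if (all(is.na(x))) stop_validation(sprintf("covariate '%s' is all-missing", v))
    note <- ""
    if (is.numeric(x)) {
      if (length(unique(stats::na.omit(x))) == 1) {
        p <- 1; test <- "none"; note <- "constant"
        fmt <- sprintf("%.1f (constant)", unique(stats::na.omit(x)))
        co <- ca <- fmt
      } else if (v %in% skewed) {
        q <- function(z) sprintf("%.1f (%.1f-%.1f)", median(z, na.rm = TRUE),
                                 quantile(z, .25, na.rm = TRUE),
                                 quantile(z, .75, na.rm = TRUE))
        co <- q(x[!case]); ca <- q(x[case])
        p <- wilcox.test(x[case], x[!case])$p.value
        test <- "wilcoxon"
      } else {
        s <- function(z) sprintf("%.1f +/- %.1f", mean(z, na.rm = TRUE),
                                 sd(z, na.rm = TRUE))
        co <- s(x[!case]); ca <- s(x[case])
        p <- t.test(x[case], x[!case])$p.value
        test <- "t"
      }
    } else {
      x <- factor(x)
      tab <- table(x, case)
      n <- function(cl) paste(sprintf("%s %d (%.1f%%)", rownames(tab),
                                      tab[, cl],
                                      100 * tab[, cl] / sum(tab[, cl])),
                              collapse = ", ")
      co <- n("FALSE"); ca <- n("TRUE")
      if (nlevels(x) < 2) { p <- 1; test <- "none"; note <- "constant" }
      else { p <- chisq.test(tab)$p.value; test <- "chi-squared" }
    }
    data.frame(variable = v, control = co, case = ca, test = test, p = p,
               note = note, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
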