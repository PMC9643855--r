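# Shared fixtures and independent brute-force oracles for the test suite.
# Oracles deliberately use different code paths (data.frame grouping, string
# keys, explicit loops) from the package internals they check.

# Small random dataset with given class sizes and SNP count.
random_dataset <- function(n_cases, n_controls, n_snps, mafs = NULL,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mafs <- mafs %||% runif(n_snps, 0.1, 0.5)
  n <- n_cases + n_controls
  g <- vapply(seq_len(n_snps), function(j) rbinom(n, 2, mafs[j]), integer(n))
  g <- matrix(g, nrow = n, dimnames = list(NULL, paste0("rs", seq_len(n_snps))))
  genotype_dataset(g, rep(c(0, 1), c(n_controls, n_cases)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# --- exact HWE oracle: direct factorial enumeration -------------------------
# Conditional probability of each heterozygote count given allele counts,
# computed from first principles with exact rational-ish arithmetic in logs.
oracle_hwe_exact <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  na <- 2 * n2 + n1                  # variant allele count
  na <- min(na, 2 * n - na)
  hs <- seq(na %% 2, na, by = 2)
  probs <- sapply(hs, function(h) {
    v <- (na - h) / 2                # variant homs
    c0 <- n - h - v
    exp(lfactorial(n) - lfactorial(c0) - lfactorial(h) - lfactorial(v) +
          h * log(2) + lfactorial(na) + lfactorial(2 * n - na) -
          lfactorial(2 * n))
  })
  probs <- probs / sum(probs)
  obs <- probs[hs == n1]
  sum(probs[probs <= obs * (1 + 1e-12)])
}

# --- 2x3 Fisher oracle: enumerate all tables with fixed margins -------------
oracle_fisher_2x3 <- function(m) {
  r <- rowSums(m); cs <- colSums(m)
  logp <- function(t) sum(lfactorial(r)) + sum(lfactorial(cs)) -
    lfactorial(sum(t)) - sum(lfactorial(t))
  p_obs <- logp(m)
  total <- 0
  for (a in 0:min(r[1], cs[1])) for (b in 0:min(r[1] - a, cs[2])) {
    cc <- r[1] - a - b
    if (cc > cs[3]) next
    t <- rbind(c(a, b, cc), cs - c(a, b, cc))
    if (any(t < 0)) next
    lp <- logp(t)
    if (lp <= p_obs + 1e-9) total <- total + exp(lp)
  }
  min(1, total)
}

# --- entropy oracles: explicit probability-table loops ----------------------
oracle_entropy_bits <- function(x) {
  h <- 0
  for (v in unique(x)) {
    p <- mean(x == v)
    h <- h - p * log2(p)
  }
  h
}

oracle_mi_pct <- function(a, cls) {
  i <- 0
  for (va in unique(a)) for (vc in unique(cls)) {
    pj <- mean(a == va & cls == vc)
    if (pj > 0) i <- i + pj * log2(pj / (mean(a == va) * mean(cls == vc)))
  }
  100 * i / oracle_entropy_bits(cls)
}

oracle_ig_pct <- function(a, b, cls) {
  oracle_mi_pct(paste(a, b), cls) - oracle_mi_pct(a, cls) -
    oracle_mi_pct(b, cls)
}

# --- naive MDR reference ----------------------------------------------------
# Fits one combination on a subject subset using string keys and table();
# returns the high-risk key set and classification metrics, independent of
# the package's tabulate()-based internals.
naive_mdr_rule <- function(geno, case, rows, threshold) {
  key <- apply(geno[rows, , drop = FALSE], 1, paste, collapse = "/")
  tca <- sum(case[rows]); tco <- sum(!case[rows])
  keys <- unique(key)
  ratio <- sapply(keys, function(k) {
    (sum(case[rows][key == k]) / tca) / (sum(!case[rows][key == k]) / tco)
  })
  names(ratio) <- keys
  keys[!is.na(ratio) & ratio > threshold]
}

naive_mdr_eval <- function(geno, case, rows, high_keys) {
  key <- apply(geno[rows, , drop = FALSE], 1, paste, collapse = "/")
  pred <- key %in% high_keys          # unseen keys -> low
  sens <- sum(pred & case[rows]) / sum(case[rows])
  spec <- sum(!pred & !case[rows]) / sum(!case[rows])
  (sens + spec) / 2
}

# Full naive search for one k: per-fold winners by training error, modal
# winner, consistency, and the modal combination's mean test BA.
naive_mdr_search_k <- function(ds, k, folds, threshold) {
  geno <- ds$genotypes
  case <- ds$status == "case"
  combos <- combn(colnames(geno), k, simplify = FALSE)
  n_folds <- max(folds)
  train_err <- matrix(NA_real_, length(combos), n_folds)
  test_ba <- train_err
  for (ci in seq_along(combos)) {
    sub <- geno[, combos[[ci]], drop = FALSE]
    ok <- !apply(sub, 1, anyNA)
    for (f in seq_len(n_folds)) {
      tr <- which(ok & folds != f); te <- which(ok & folds == f)
      hk <- naive_mdr_rule(sub, case, tr, threshold)
      train_err[ci, f] <- 1 - naive_mdr_eval(sub, case, tr, hk)
      test_ba[ci, f] <- naive_mdr_eval(sub, case, te, hk)
    }
  }
  winners <- apply(train_err, 2, which.min)
  modal <- which.max(tabulate(winners, length(combos)))
  list(winners = winners, modal_snps = combos[[modal]],
       consistency = sum(winners == modal),
       test_ba = mean(test_ba[modal, ]),
       per_combo_test_ba = rowMeans(test_ba))
}

# --- naive average-linkage clustering oracle --------------------------------
# Returns the cophenetic distance matrix implied by repeated merging of the
# two clusters with minimal average inter-cluster dissimilarity.
oracle_average_linkage_cophenetic <- function(d) {
  labs <- rownames(d)
  clusters <- as.list(labs)
  coph <- matrix(NA_real_, nrow(d), ncol(d), dimnames = dimnames(d))
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      dij <- mean(d[clusters[[i]], clusters[[j]]])
      if (dij < best_d) { best_d <- dij; best <- c(j, i) }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    coph[a, b] <- best_d; coph[b, a] <- best_d
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  diag(coph) <- 0
  coph
}
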