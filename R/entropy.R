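# Information-theoretic interaction scoring.
#
# Main effects are measured as the mutual information I(A;C) between an
# attribute and case/control status; pairwise effects as the interaction
# information IG(A;B;C) = I(AB;C) - I(A;C) - I(B;C). Both are reported as a
# percentage of the status entropy H(C), so the logarithm base cancels.
# Positive IG means synergy (the pair carries class information beyond its
# parts), negative means redundancy. Entropies are empirical plug-in
# estimates with no bias correction, matching the MDR software lineage.

#' Shannon entropy of a discrete distribution
#'
#' \eqn{H = -\sum p \log_2 p} in bits, with \eqn{0 \log 0 = 0}.
#'
#' @param p vector of probabilities (non-negative, summing to 1 within 1e-9).
#' @return entropy in bits.
#' @examples
#' entropy(c(0.5, 0.5))  # 1 bit
#' @export
entropy <- function(p) {
  if (any(p < 0)) stop_validation("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-9) stop_validation("probabilities must sum to 1")
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Empirical entropy of an integer-coded sample (counts -> plug-in H).
sample_entropy <- function(x) {
  n <- length(x)
  entropy(table(x) / n)
}

# Complete cases, joint attribute code, and case indicator for a SNP subset.
attr_and_class <- function(ds, snps) {
  cc <- cell_codes(ds$genotypes, snps)
  keep <- cc$keep
  list(attr = cc$code[keep], case = (ds$status == "case")[keep])
}

#' Mutual information between attribute(s) and status, as a percentage
#'
#' Empirical \eqn{I(A;C) = H(A) + H(C) - H(A,C)} for the (joint) genotype
#' attribute of one or more SNPs against case/control status, reported as
#' \eqn{100 \cdot I / H(C)}. Joint attributes live on the product genotype
#' space. Complete cases only.
#'
#' @param ds a \code{\link{genotype_dataset}}.
#' @param snps one or more SNP names (joint attribute).
#' @return percentage of the status entropy explained.
#' @export
mutual_information_pct <- function(ds, snps) {
  z <- attr_and_class(ds, snps)
  hc <- sample_entropy(z$case)
  if (hc == 0) stop_undefined("single-class data: H(C) = 0")
  ha <- sample_entropy(z$attr)
  hac <- sample_entropy(paste(z$attr, z$case))
  100 * (ha + hc - hac) / hc
}

#' Interaction information of a SNP pair with status, as a percentage
#'
#' \eqn{IG(A;B;C) = I(AB;C) - I(A;C) - I(B;C)} as a percentage of
#' \eqn{H(C)}; positive values indicate synergy, negative redundancy. All
#' three terms are computed on the subjects complete for both SNPs, so the
#' decomposition is internally consistent.
#'
#' @param ds a \code{\link{genotype_dataset}}.
#' @param snpA,snpB SNP names.
#' @return interaction information as a percentage of H(C).
#' @export
interaction_information_pct <- function(ds, snpA, snpB) {
  cc <- cell_codes(ds$genotypes, c(snpA, snpB))
  sub <- subset_subjects(ds, cc$keep)
  mutual_information_pct(sub, c(snpA, snpB)) -
    mutual_information_pct(sub, snpA) -
    mutual_information_pct(sub, snpB)
}

#' Build the SNP interaction network
#'
#' Node scores are per-SNP main effects \eqn{I(A;C)} and edge scores are
#' pairwise interaction information \eqn{IG(A;B;C)}, both as percentages of
#' \eqn{H(C)}. Each edge is categorised by sign: synergy (> 0), redundancy
#' (< 0) or neutral (= 0).
#'
#' @param ds a \code{\link{genotype_dataset}}.
#' @param snps SNPs to include (default: the whole panel; at least 2).
#' @return object of class \code{interaction_network}: list with
#'   \code{nodes} (data.frame \code{snp}, \code{node_pct}) and \code{edges}
#'   (data.frame \code{snpA}, \code{snpB}, \code{edge_pct},
#'   \code{category}).
#' @examples
#' ds <- resample_from_marginals(load_panel_counts(), seed = 1)
#' net <- build_network(ds)
#' head(net$edges)
#' @export
build_network <- function(ds, snps = colnames(ds$genotypes)) {
  if (length(snps) < 2) stop_validation("need at least 2 SNPs")
  nodes <- data.frame(
    snp = snps,
    node_pct = vapply(snps, function(s) mutual_information_pct(ds, s),
                      numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  pairs <- combn(snps, 2, simplify = FALSE)
  edges <- do.call(rbind, lapply(pairs, function(p) {
    ig <- interaction_information_pct(ds, p[1], p[2])
    data.frame(snpA = p[1], snpB = p[2], edge_pct = ig,
               category = if (ig > 0) "synergy"
                          else if (ig < 0) "redundancy" else "neutral",
               stringsAsFactors = FALSE)
  }))
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  print(x$nodes, digits = 4); print(x$edges, digits = 4)
  invisible(x)
}

#' Interaction dendrogram
#'
#' Agglomerative clustering of the SNPs with average linkage on the
#' dissimilarity \eqn{d(A,B) = S_{max} - S(A,B)}, where \eqn{S} is the edge
#' (interaction-information) score and \eqn{S_{max}} its maximum over edges
#' -- so the strongest synergy merges first and the merge heights are
#' non-negative shifts below it. The tree is exported in Newick format with
#' branch heights.
#'
#' @param network an \code{\link{interaction_network}}.
#' @return list of class \code{interaction_dendrogram}: \code{hclust} (the
#'   merge tree), \code{phylo} (ape tree) and \code{newick} (string).
#' @export
interaction_dendrogram <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  snps <- network$nodes$snp
  if (length(snps) < 2) stop_validation("need at least 2 nodes")
  s_max <- max(network$edges$edge_pct)
  d <- matrix(0, length(snps), length(snps), dimnames = list(snps, snps))
  for (i in seq_len(nrow(network$edges))) {
    e <- network$edges[i, ]
    d[e$snpA, e$snpB] <- d[e$snpB, e$snpA] <- s_max - e$edge_pct
  }
  hc <- hclust(as.dist(d), method = "average")
  ph <- ape::as.phylo(hc)
  structure(list(hclust = hc, phylo = ph,
                 newick = ape::write.tree(ph)),
            class = "interaction_dendrogram")
}

#' @export
print.interaction_dendrogram <- function(x, ...) {
  cat("<interaction_dendrogram>\n", x$newick, "\n")
  invisible(x)
}

#' Write network node and edge tables as TSV
#' @param network an \code{\link{interaction_network}}.
#' @param node_path,edge_path output paths.
#' @return invisibly, c(node_path, edge_path).
#' @export
write_network_tsv <- function(network, node_path, edge_path) {
  write.table(network$nodes, node_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(network$edges, edge_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(node_path, edge_path))
}
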