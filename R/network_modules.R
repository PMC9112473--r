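# Interaction-network module construction: thresholded weighted adjacency
# from a STRING-style edge list, topological overlap measure (TOM), and
# average-linkage hierarchical clustering of 1 - TOM into mutually exclusive
# gene modules.

#' Build a weighted adjacency matrix over a gene set
#'
#' An edge exists when both endpoints are in `genes` and the combined score
#' is at least `threshold` (0.4 by default, STRING medium confidence). The
#' score is retained as the edge weight unless `binarize = TRUE`.
#'
#' @param edges data.frame from [load_interactions()].
#' @param genes Character vector of gene ids spanning the matrix.
#' @param threshold Minimum combined score in (0, 1].
#' @param binarize Replace qualifying scores by 1.
#' @return Symmetric genes x genes matrix with zero diagonal.
#' @export
build_adjacency <- function(edges, genes, threshold = 0.4, binarize = FALSE) {
  cn_assert(length(genes) >= 1, "empty gene set")
  cn_assert(threshold > 0 && threshold <= 1, "threshold must be in (0, 1]",
            "corgnet_parameter_error")
  genes <- unique(genes)
  a <- matrix(0, length(genes), length(genes),
              dimnames = list(genes, genes))
  keep <- edges$gene_a %in% genes & edges$gene_b %in% genes &
    edges$combined_score >= threshold
  if (any(keep)) {
    e <- edges[keep, , drop = FALSE]
    w <- if (binarize) rep(1, nrow(e)) else e$combined_score
    a[cbind(e$gene_a, e$gene_b)] <- w
    a[cbind(e$gene_b, e$gene_a)] <- w
  }
  a
}

#' Topological overlap measure of a weighted adjacency matrix
#'
#' For i != j, `omega_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` and node connectivity `k_i = sum_u a_iu`; the
#' diagonal is 1. Pairs of isolated nodes get overlap 0 (denominator 1).
#' Dissimilarity for clustering is `1 - omega`.
#'
#' @param adj Symmetric adjacency matrix with zero diagonal, entries in
#'   \[0, 1\].
#' @return Symmetric TOM matrix `omega` with unit diagonal.
#' @export
topological_overlap <- function(adj) {
  cn_assert(is.matrix(adj) && nrow(adj) == ncol(adj),
            "adjacency must be square")
  cn_assert(max(abs(adj - t(adj))) < 1e-12, "adjacency must be symmetric")
  cn_assert(all(diag(adj) == 0), "adjacency diagonal must be zero")
  cn_assert(all(adj >= 0 & adj <= 1), "adjacency entries must be in [0, 1]")
  k <- colSums(adj)
  l <- adj %*% adj          # zero diagonal makes this exactly sum_{u != i,j}
  kmin <- outer(k, k, pmin)
  omega <- (l + adj) / (kmin + 1 - adj)
  diag(omega) <- 1
  dimnames(omega) <- dimnames(adj)
  omega
}

#' Partition genes into mutually exclusive network modules
#'
#' Agglomerative clustering of `1 - omega`; the tree is cut at a fixed
#' dissimilarity height or into a fixed number of clusters. Clusters smaller
#' than `min_module_size` are pooled into module 0 (the unassigned pool —
#' genes without interactions land there since their dissimilarity to
#' everything is 1); remaining modules are relabeled 1..M by decreasing size
#' (ties by first gene id).
#'
#' @param tom TOM matrix from [topological_overlap()].
#' @param linkage `"average"` (default) or `"complete"`.
#' @param cut `"height"` (cut at dissimilarity `cut_value`) or
#'   `"n_clusters"`.
#' @param cut_value Height in \[0, 1\] or integer number of clusters.
#' @param min_module_size Minimum retained module size.
#' @return data.frame `gene_id`, `module_id` (0 = unassigned pool), plus a
#'   `sizes` attribute (named module sizes).
#' @export
cluster_modules <- function(tom, linkage = c("average", "complete"),
                            cut = c("height", "n_clusters"), cut_value = 0.95,
                            min_module_size = 5) {
  linkage <- match.arg(linkage)
  cut <- match.arg(cut)
  n <- nrow(tom)
  cn_assert(n >= 2, "module clustering needs at least 2 genes")
  diss <- 1 - tom
  diag(diss) <- 0
  hc <- hclust(as.dist(diss), method = linkage)
  if (cut == "height") {
    cn_assert(cut_value >= 0 && cut_value <= 1,
              "height cut must be in [0, 1]", "corgnet_parameter_error")
    cl <- cutree(hc, h = cut_value)
  } else {
    cn_assert(cut_value >= 1 && cut_value <= n,
              "n_clusters must be in [1, n genes]", "corgnet_parameter_error")
    cl <- cutree(hc, k = as.integer(cut_value))
  }
  genes <- rownames(tom)
  sizes <- table(cl)
  small <- as.integer(names(sizes)[sizes < min_module_size])
  module <- ifelse(cl %in% small, 0L, cl)
  kept <- setdiff(unique(module), 0L)
  if (length(kept)) {
    first_gene <- vapply(kept, function(m) min(genes[module == m]),
                         character(1))
    ord <- kept[order(-as.vector(table(factor(module, levels = kept))),
                      first_gene)]
    module <- ifelse(module == 0L, 0L, match(module, ord))
  }
  out <- data.frame(gene_id = genes, module_id = as.integer(module),
                    stringsAsFactors = FALSE)
  attr(out, "sizes") <- table(out$module_id)
  out
}

#' Summarize a module partition (degree and intra-module overlap per gene)
#' @param partition data.frame from [cluster_modules()].
#' @param adj Adjacency matrix used for clustering.
#' @param tom Matching TOM matrix.
#' @return data.frame `gene_id`, `module_id`, `module_size`, `degree`,
#'   `mean_intra_omega`.
#' @export
module_table <- function(partition, adj, tom) {
  sizes <- table(partition$module_id)
  data.frame(
    gene_id = partition$gene_id,
    module_id = partition$module_id,
    module_size = as.integer(sizes[as.character(partition$module_id)]),
    degree = colSums(adj)[partition$gene_id],
    mean_intra_omega = vapply(seq_len(nrow(partition)), function(i) {
      g <- partition$gene_id[i]
      others <- partition$gene_id[partition$module_id ==
                                    partition$module_id[i] &
                                    partition$gene_id != g]
      if (length(others) == 0) return(NA_real_)
      mean(tom[g, others])
    }, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}
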