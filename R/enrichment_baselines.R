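# Module annotation by one-sided hypergeometric gene-set enrichment with
# Holm step-down correction, plus the comparator analyses: a per-gene Welch
# t-test screen, drug-variability ranking by mean absolute deviation of the
# AUC, and drug-drug response correlation.

#' Hypergeometric gene-set enrichment with Holm correction
#'
#' For each term, `p_raw = P(X >= overlap)` with X hypergeometric
#' (population = universe size, successes = term size within the universe,
#' draws = query size); `p_holm` is the Holm step-down adjustment across all
#' tested terms. Terms are intersected with the universe first and dropped
#' below `min_term` genes.
#'
#' @param query Character vector of genes of interest (must lie in
#'   `universe`; genes outside it are dropped with a message).
#' @param universe Character vector: the gene background.
#' @param terms Named list of gene sets ([load_gmt()]).
#' @param min_term Minimum term size (after universe intersection).
#' @return data.frame `term_id`, `term_size`, `overlap`, `p_raw`, `p_holm`,
#'   ordered by `p_raw`.
#' @export
enrich <- function(query, universe, terms, min_term = 2) {
  universe <- unique(universe)
  query0 <- unique(query)
  query <- intersect(query0, universe)
  if (length(query) < length(query0))
    message(sprintf("enrich: %d query genes outside the universe dropped",
                    length(query0) - length(query)))
  cn_assert(length(query) >= 1, "empty query after universe intersection")
  tsets <- lapply(terms, intersect, universe)
  keep <- vapply(tsets, length, integer(1)) >= min_term
  tsets <- tsets[keep]
  if (length(tsets) == 0)
    return(data.frame(term_id = character(), term_size = integer(),
                      overlap = integer(), p_raw = numeric(),
                      p_holm = numeric(), stringsAsFactors = FALSE))
  N <- length(universe)
  n <- length(query)
  K <- vapply(tsets, length, integer(1))
  ov <- vapply(tsets, function(s) length(intersect(s, query)), integer(1))
  p_raw <- phyper(ov - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term_id = names(tsets), term_size = K, overlap = ov,
                    p_raw = p_raw, p_holm = p.adjust(p_raw, method = "holm"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p_raw, out$term_id), , drop = FALSE]
}

#' Per-gene differential-expression screen (Welch t + Holm)
#'
#' The comparator analysis: a two-sided Welch t-test per gene between
#' resistant and sensitive samples, Holm-corrected across all genes; a gene
#' is significant when `p_holm < alpha_holm` (default 0.1).
#'
#' @param z genes x samples matrix.
#' @param labels data.frame from [label_by_auc()].
#' @param alpha_holm Family-wise significance threshold.
#' @param var_equal Use the pooled-variance t.
#' @return data.frame `gene_id`, `t`, `p_raw`, `p_holm`, `significant`.
#' @export
ttest_screen <- function(z, labels, alpha_holm = 0.1, var_equal = FALSE) {
  is_res <- align_labels(z, labels)
  cn_assert(sum(is_res) >= 2 && sum(!is_res) >= 2,
            "each class needs at least 2 samples")
  w <- welch_rows(z, is_res, var_equal)
  ok <- is.finite(w$t)
  out <- data.frame(gene_id = rownames(z)[ok], t = w$t[ok], p_raw = w$p[ok],
                    stringsAsFactors = FALSE)
  out$p_holm <- p.adjust(out$p_raw, method = "holm")
  out$significant <- out$p_holm < alpha_holm
  out
}

#' Rank drugs by response variability (mean absolute deviation of the AUC)
#'
#' @param auc_by_drug Either a named list of numeric AUC vectors or a long
#'   data.frame with columns `drug` and `auc`.
#' @return data.frame `drug`, `n`, `mad_auc`, sorted descending; drugs with
#'   fewer than 2 samples are excluded with a message.
#' @export
drug_variability <- function(auc_by_drug) {
  if (is.data.frame(auc_by_drug)) {
    cn_assert(all(c("drug", "auc") %in% names(auc_by_drug)),
              "long table needs columns drug and auc")
    auc_by_drug <- split(auc_by_drug$auc, auc_by_drug$drug)
  }
  n <- vapply(auc_by_drug, length, integer(1))
  if (any(n < 2))
    message(sprintf("drug_variability: excluded %d drugs with < 2 samples",
                    sum(n < 2)))
  keep <- names(auc_by_drug)[n >= 2]
  mad_auc <- vapply(auc_by_drug[keep],
                    function(x) mean(abs(x - mean(x))), numeric(1))
  out <- data.frame(drug = keep, n = n[keep], mad_auc = mad_auc,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$mad_auc, out$drug), , drop = FALSE]
}

#' Pearson correlation between two drugs' responses on shared samples
#'
#' @param auc_a,auc_b Numeric AUC vectors named by sample id.
#' @return Pearson r over the intersection of sample names (>= 3 required).
#' @export
response_correlation <- function(auc_a, auc_b) {
  cn_assert(!is.null(names(auc_a)) && !is.null(names(auc_b)),
            "AUC vectors must be named by sample id")
  shared <- intersect(names(auc_a), names(auc_b))
  cn_assert(length(shared) >= 3,
            "need at least 3 shared samples for a correlation")
  cor(auc_a[shared], auc_b[shared], method = "pearson")
}
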