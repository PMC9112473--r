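# Condition-responsive-gene (CORG) pathway activity scoring. For a pathway p
# and sample j the activity over k selected genes is a_pj = sum_i z_ij /
# sqrt(k); the pathway score is the two-sample t statistic of the activity
# between resistant and sensitive samples, and k is chosen greedily as the
# smallest prefix of t-ranked member genes attaining the maximal |t|.

#' Label samples sensitive/resistant from drug-response AUC
#'
#' Fixed mode: sensitive iff `auc < cutoff` (a sample exactly at the cutoff is
#' resistant, the cutoff belonging to the upper mode of a bimodal AUC
#' distribution). Percentile mode: sensitive iff `auc` is at or below the
#' `cutoff`-th nearest-rank percentile of the observed AUCs.
#'
#' @param responses data.frame with columns `sample_id`, `auc`.
#' @param mode `"fixed"` or `"percentile"`.
#' @param cutoff AUC value (fixed) or percentile in (0, 100) (percentile).
#' @return data.frame `sample_id`, `label` (factor sensitive/resistant).
#' @export
label_by_auc <- function(responses, mode = c("fixed", "percentile"), cutoff) {
  mode <- match.arg(mode)
  cn_assert(is.data.frame(responses) &&
              all(c("sample_id", "auc") %in% names(responses)),
            "responses must have columns sample_id and auc")
  auc <- responses$auc
  if (mode == "fixed") {
    if (cutoff < min(auc) || cutoff > max(auc))
      warning(sprintf("cutoff %g lies outside the observed AUC range [%g, %g]",
                      cutoff, min(auc), max(auc)))
    sens <- auc < cutoff
  } else {
    cn_assert(cutoff > 0 && cutoff < 100,
              "percentile cutoff must be in (0, 100)",
              "corgnet_parameter_error")
    sens <- auc <= nearest_rank(auc, cutoff)
  }
  n_s <- sum(sens); n_r <- sum(!sens)
  if (n_s == 0 || n_r == 0)
    cn_stop(sprintf(
      "labeling produced an empty class (sensitive = %d, resistant = %d)",
      n_s, n_r), "corgnet_labeling_error")
  data.frame(sample_id = responses$sample_id,
             label = factor(ifelse(sens, "sensitive", "resistant"),
                            levels = c("sensitive", "resistant")),
             stringsAsFactors = FALSE)
}

#' Z-normalize each gene row (mean 0, sd 1 with n-1 denominator)
#'
#' Constant rows cannot be normalized and are dropped with a message.
#'
#' @param expr genes x samples numeric matrix.
#' @return The row-standardized matrix.
#' @export
zscore_rows <- function(expr) {
  cn_assert(ncol(expr) >= 2, "z-scoring needs at least 2 samples")
  mu <- rowMeans(expr)
  sd <- sqrt(rowSums((expr - mu)^2) / (ncol(expr) - 1))
  const <- sd == 0 | !is.finite(sd)
  if (all(const))
    cn_stop("all expression rows are constant; nothing to normalize",
            "corgnet_validation_error")
  if (any(const))
    message(sprintf("zscore_rows: dropped %d constant gene rows", sum(const)))
  (expr[!const, , drop = FALSE] - mu[!const]) / sd[!const]
}

# Vectorized Welch (or pooled) two-sample t for each row of `m`, oriented
# resistant - sensitive. Returns t, df and two-sided p for finite rows.
welch_rows <- function(m, is_res, var_equal = FALSE) {
  n1 <- sum(is_res); n2 <- sum(!is_res)
  x1 <- m[, is_res, drop = FALSE]; x2 <- m[, !is_res, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, nrow(m))
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m1 - m2) / sqrt(se2)
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# labels -> logical is_resistant aligned to the columns of `z`
align_labels <- function(z, labels) {
  cn_assert(is.data.frame(labels) &&
              all(c("sample_id", "label") %in% names(labels)),
            "labels must have columns sample_id and label")
  idx <- match(colnames(z), labels$sample_id)
  cn_assert(!anyNA(idx), "every expression sample needs a label")
  labels$label[idx] == "resistant"
}

#' Per-gene Welch t statistics (resistant minus sensitive)
#'
#' Genes with zero variance in both classes have no defined t and are
#' excluded (recorded in the `excluded` attribute).
#'
#' @param z genes x samples matrix (typically the z-scored form).
#' @param labels data.frame from [label_by_auc()].
#' @param var_equal Use the pooled-variance t instead of Welch.
#' @return data.frame `gene_id`, `t` (attribute `excluded`: dropped genes).
#' @export
gene_tscores <- function(z, labels, var_equal = FALSE) {
  is_res <- align_labels(z, labels)
  cn_assert(sum(is_res) >= 2 && sum(!is_res) >= 2,
            "each class needs at least 2 samples for a t statistic")
  w <- welch_rows(z, is_res, var_equal)
  bad <- !is.finite(w$t)
  out <- data.frame(gene_id = rownames(z)[!bad], t = w$t[!bad],
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- rownames(z)[bad]
  out
}

# t statistics of activity prefixes: given ordered gene rows, prefix m has
# activity colCumsum(z)[m, ] / sqrt(m). Returns the per-prefix t vector.
prefix_tscores <- function(z_ord, is_res, var_equal = FALSE) {
  cs <- apply(z_ord, 2, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1)
  act <- cs / sqrt(seq_len(nrow(z_ord)))
  welch_rows(act, is_res, var_equal)$t
}

#' Greedy condition-responsive-gene activity for one pathway
#'
#' Member genes present in `z` are ranked by their t statistic — descending
#' for the up-in-resistant direction, ascending for down-in-resistant. For
#' each prefix length m the t statistic of the aggregated activity
#' `colSums(z[1:m, ]) / sqrt(m)` is computed; k is the smallest prefix length
#' attaining the maximal |t|. Both directions are searched and the stronger
#' one kept, so the score can never fall below the best single member gene's
#' |t|; when both directions tie, the sign of the members' mean t decides, as
#' in the original CORG formulation.
#'
#' @param pathway_genes Character vector of member gene ids.
#' @param z z-scored genes x samples matrix.
#' @param labels data.frame from [label_by_auc()].
#' @param pathway_id Optional id stored in the result.
#' @param var_equal Use pooled-variance t statistics.
#' @return List with `pathway_id`, `member_genes_ranked`, `k`,
#'   `selected_genes`, `activity` (named per-sample vector), `score` (signed
#'   t, resistant minus sensitive), `direction`, `n_genes_present`.
#' @export
greedy_pathway_activity <- function(pathway_genes, z, labels,
                                    pathway_id = NULL, var_equal = FALSE) {
  present <- intersect(pathway_genes, rownames(z))
  if (length(present) == 0)
    cn_stop(sprintf("pathway %s has no member genes in the expression matrix",
                    pathway_id %||% "<unnamed>"), "corgnet_pathway_skip")
  n_dropped <- length(unique(pathway_genes)) - length(present)
  if (n_dropped > 0)
    message(sprintf("pathway %s: %d member genes absent from matrix",
                    pathway_id %||% "<unnamed>", n_dropped))
  is_res <- align_labels(z, labels)
  cn_assert(sum(is_res) >= 2 && sum(!is_res) >= 2,
            "each class needs at least 2 samples")

  zt <- gene_tscores(z[present, , drop = FALSE], labels, var_equal)
  present <- zt$gene_id  # zero-variance members cannot contribute
  if (length(present) == 0)
    cn_stop(sprintf("pathway %s has no members with a defined t statistic",
                    pathway_id %||% "<unnamed>"), "corgnet_pathway_skip")
  tg <- zt$t

  # deterministic orderings: ties on t broken by gene id
  eval_dir <- function(ord) {
    ids <- present[ord]
    tv <- prefix_tscores(z[ids, , drop = FALSE], is_res, var_equal)
    tv[!is.finite(tv)] <- 0
    k <- unname(which.max(abs(tv)))  # first index at the max = smallest k
    list(absmax = abs(unname(tv[k])), k = k, score = unname(tv[k]),
         ids = ids)
  }
  up <- eval_dir(order(-tg, present))  # up_in_resistant candidates first
  dn <- eval_dir(order(tg, present))
  if (abs(up$absmax - dn$absmax) <= 1e-12) {
    # tie: direction given by the sign of the members' mean t (CORG rule)
    best <- if (mean(tg) >= 0) up else dn
  } else {
    best <- if (up$absmax > dn$absmax) up else dn
  }

  sel <- best$ids[seq_len(best$k)]
  activity <- colSums(z[sel, , drop = FALSE]) / sqrt(best$k)
  list(pathway_id = pathway_id, member_genes_ranked = best$ids, k = best$k,
       selected_genes = sel, activity = activity, score = best$score,
       direction = if (best$score >= 0) "up_in_resistant"
                   else "down_in_resistant",
       n_genes_present = length(present))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score every pathway in a collection
#'
#' Pathways with no member genes present are skipped and recorded in the
#' `skipped` attribute; result order follows collection order.
#'
#' @inheritParams greedy_pathway_activity
#' @param collection Named list of gene-id character vectors ([load_gmt()]).
#' @return List of [greedy_pathway_activity()] results, attribute `skipped`.
#' @export
score_all_pathways <- function(collection, z, labels, var_equal = FALSE) {
  cn_assert(length(collection) >= 1, "empty pathway collection")
  skipped <- character()
  out <- list()
  for (id in names(collection)) {
    res <- tryCatch(
      greedy_pathway_activity(collection[[id]], z, labels, pathway_id = id,
                              var_equal = var_equal),
      corgnet_pathway_skip = function(e) NULL)
    if (is.null(res)) skipped <- c(skipped, id) else out[[id]] <- res
  }
  attr(out, "skipped") <- skipped
  out
}

pathway_score_table <- function(results) {
  data.frame(
    pathway_id = vapply(results, `[[`, character(1), "pathway_id"),
    n_genes_present = vapply(results, `[[`, numeric(1), "n_genes_present"),
    k = vapply(results, `[[`, numeric(1), "k"),
    score = vapply(results, `[[`, numeric(1), "score"),
    direction = vapply(results, `[[`, character(1), "direction"),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Retain pathways in the extreme tails of the score distribution
#'
#' A pathway is retained when its score lies within the bottom `tail_pct`
#' percent or the top `tail_pct` percent of scores (symmetric nearest-rank:
#' with n distinct scores exactly `ceiling(tail_pct/100 * n)` per tail, i.e.
#' 10 percent per tail returns 20 percent of the input).
#'
#' @param results Output of [score_all_pathways()].
#' @param tail_pct Per-tail percentage in (0, 50].
#' @return data.frame `pathway_id`, `score`, `retained`, `p_empirical` (NA).
#' @export
filter_percentile <- function(results, tail_pct) {
  cn_assert(tail_pct > 0 && tail_pct <= 50, "tail_pct must be in (0, 50]",
            "corgnet_parameter_error")
  tab <- pathway_score_table(results)
  n <- nrow(tab)
  if (n < 5) {
    warning("fewer than 5 pathways; retaining all")
    retained <- rep(TRUE, n)
  } else {
    r <- ceiling(tail_pct / 100 * n)
    s <- sort(tab$score)
    retained <- tab$score <= s[r] | tab$score >= s[n - r + 1]
  }
  cbind(tab[c("pathway_id", "score")],
        data.frame(retained = retained, p_empirical = NA_real_))
}

#' Retain pathways against a label-permutation null
#'
#' For each of `n_perm` permutations of the sample labels the full greedy
#' search is re-run; the empirical p-value uses the add-one estimator
#' `p = (1 + #permuted |score| >= observed |score|) / (1 + n_perm)`, so
#' p >= 1/(1 + n_perm) always.
#'
#' @inheritParams score_all_pathways
#' @param n_perm Number of label permutations (>= 100).
#' @param alpha Retention threshold on the empirical p-value.
#' @param seed Optional integer seed for the permutation stream.
#' @return data.frame `pathway_id`, `score`, `retained`, `p_empirical`.
#' @export
filter_permutation <- function(collection, z, labels, n_perm = 1000,
                               alpha = 0.05, seed = NULL, var_equal = FALSE) {
  cn_assert(n_perm >= 100, "n_perm must be at least 100",
            "corgnet_parameter_error")
  obs <- score_all_pathways(collection, z, labels, var_equal)
  tab <- pathway_score_table(obs)
  ge <- numeric(nrow(tab))
  with_seed_(seed, {
    for (b in seq_len(n_perm)) {
      pl <- labels
      pl$label <- sample(pl$label)  # preserves class counts: never degenerate
      pr <- score_all_pathways(collection, z, pl, var_equal)
      ps <- vapply(tab$pathway_id, function(id) {
        if (is.null(pr[[id]])) NA_real_ else abs(pr[[id]]$score)
      }, numeric(1))
      ge <- ge + as.numeric(!is.na(ps) & ps >= abs(tab$score))
    }
  })
  p <- (1 + ge) / (1 + n_perm)
  cbind(tab[c("pathway_id", "score")],
        data.frame(retained = p <= alpha, p_empirical = p))
}
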