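# Two-stage feature ranking. Stage one runs shadow-feature (Boruta-style)
# all-relevant selection per network module on a random-forest importance
# engine; stage two ranks the pooled Confirmed genes with linear SVM
# recursive feature elimination, averaging within-fold integer ranks across
# stratified cross-validation folds. Module importance is the minimum
# averaged rank over the module's confirmed members.

#' Random-forest mean-decrease-in-impurity importance
#'
#' Classification forest over a binary outcome; importances are averaged
#' Gini decreases weighted by node size. Randomness (bootstraps, feature
#' subsampling) is drawn from R's RNG, so wrap in `set.seed()` for
#' reproducibility.
#'
#' @param x samples x features numeric matrix.
#' @param y Binary vector (0/1, logical, or 2-level factor).
#' @param ntree Number of trees.
#' @param mtry Features tried per split; default `floor(sqrt(p))`.
#' @param min_node Minimum node size to attempt a split.
#' @return Named numeric importance vector (one entry per column of `x`).
#' @export
rf_importance <- function(x, y, ntree = 500, mtry = NULL, min_node = 2) {
  x <- as.matrix(x)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  cn_assert(all(y %in% c(0L, 1L)), "y must be binary")
  cn_assert(length(y) == nrow(x), "x and y dimensions disagree")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  imp <- .rf_importance_cpp(x, y, as.integer(ntree), as.integer(mtry),
                            as.integer(min_node))
  names(imp) <- colnames(x)
  imp
}

#' Shadow-feature (Boruta-style) all-relevant selection for one module
#'
#' Each run appends a shuffled shadow copy of every undecided-or-confirmed
#' feature (padded to at least 5 shadows), fits a random forest, and counts a
#' hit for every real feature whose importance exceeds the maximum shadow
#' importance. After each run, one-sided binomial tests against hit
#' probability 0.5 — Bonferroni-corrected across the module's features — mark
#' features Confirmed or Rejected; rejected features leave the model.
#' Features still undecided after `max_runs` stay Tentative. Only Confirmed
#' features advance in the pipeline.
#'
#' @param z_module genes x samples matrix restricted to one module.
#' @param labels data.frame from [label_by_auc()].
#' @param max_runs Maximum forest runs.
#' @param p_value Per-test significance level before Bonferroni adjustment.
#' @param seed Optional integer seed.
#' @param ntree Trees per forest run.
#' @return data.frame `gene_id`, `decision` (Confirmed/Rejected/Tentative),
#'   `n_hits`, `n_runs`.
#' @export
boruta_select <- function(z_module, labels, max_runs = 100, p_value = 0.01,
                          seed = NULL, ntree = 500) {
  is_res <- align_labels(z_module, labels)
  cn_assert(sum(is_res) >= 5 && sum(!is_res) >= 5,
            "shadow-feature selection needs >= 5 samples per class")
  genes <- rownames(z_module)
  if (length(genes) < 2) {
    warning("single-gene module: shadow comparison degenerate, gene left Tentative")
    return(data.frame(gene_id = genes, decision = "Tentative",
                      n_hits = 0L, n_runs = 0L, stringsAsFactors = FALSE))
  }
  X <- t(z_module)
  y <- as.integer(is_res)
  p <- length(genes)
  decision <- setNames(rep("Tentative", p), genes)
  hits <- setNames(rep(0L, p), genes)
  runs <- 0L

  with_seed_(seed, {
    while (any(decision == "Tentative") && runs < max_runs) {
      active <- genes[decision != "Rejected"]
      Xa <- X[, active, drop = FALSE]
      n_sh <- max(5L, length(active))
      sh_src <- active[((seq_len(n_sh) - 1L) %% length(active)) + 1L]
      Xsh <- apply(X[, sh_src, drop = FALSE], 2, sample)
      imp <- rf_importance(cbind(Xa, Xsh), y, ntree = ntree)
      sh_max <- max(imp[(length(active) + 1):(length(active) + n_sh)])
      hit <- imp[seq_along(active)] > sh_max
      hits[active] <- hits[active] + as.integer(hit)
      runs <- runs + 1L

      und <- genes[decision == "Tentative"]
      p_conf <- pbinom(hits[und] - 1L, runs, 0.5, lower.tail = FALSE)
      p_rej <- pbinom(hits[und], runs, 0.5)
      thr <- p_value / p  # Bonferroni across the module's features
      decision[und[p_conf < thr]] <- "Confirmed"
      decision[und[p_rej < thr]] <- "Rejected"
    }
  })
  data.frame(gene_id = genes, decision = unname(decision),
             n_hits = unname(hits), n_runs = runs, stringsAsFactors = FALSE)
}

# ---- linear soft-margin SVM via the quadprog dual ---------------------------

# y in {-1, +1}; returns weight vector w, intercept b, duals alpha.
svm_fit <- function(X, y, C = 1) {
  n <- nrow(X)
  K <- tcrossprod(X)
  Q <- (y %o% y) * K
  ridge <- 1e-8 * max(1, mean(diag(K)))
  sol <- NULL
  for (i in 1:6) {
    sol <- tryCatch(
      quadprog::solve.QP(
        Dmat = Q + diag(ridge, n), dvec = rep(1, n),
        Amat = cbind(y, diag(n), -diag(n)),
        bvec = c(0, rep(0, n), rep(-C, n)), meq = 1),
      error = function(e) NULL)
    if (!is.null(sol)) break
    ridge <- ridge * 100
  }
  if (is.null(sol)) cn_stop("SVM dual QP failed to solve", "corgnet_error")
  alpha <- pmin(pmax(sol$solution, 0), C)
  w <- drop(crossprod(X, alpha * y))
  tol <- 1e-6 * C
  margin <- alpha > tol & alpha < C - tol
  sv <- if (any(margin)) margin else alpha > tol
  b <- if (any(sv)) mean(y[sv] - X[sv, , drop = FALSE] %*% w) else 0
  list(w = w, b = b, alpha = alpha)
}

svm_predict <- function(fit, X) {
  ifelse(drop(X %*% fit$w) + fit$b >= 0, 1, -1)
}

# Stratified fold assignment: within each class, fold ids 1..k are dealt in
# shuffled order so every fold keeps both classes whenever counts allow.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  if (any(vapply(seq_len(k), function(f)
    length(unique(y[fold != f])) < 2, logical(1))))
    cn_stop("cannot form folds with both classes in every training split",
            "corgnet_validation_error")
  fold
}

#' SVM recursive feature elimination with cross-validation averaged ranks
#'
#' Per fold: features are standardized with training-split statistics, a
#' linear soft-margin SVM (C = `C`) is fit, and the feature with the smallest
#' squared weight is removed; iterating until none remain gives within-fold
#' integer ranks (last survivor = rank 1). `avg_rank` is the mean across
#' folds. The error curve refits the SVM per fold on the top-m features of
#' that fold's ranking and reports pooled held-out misclassification error
#' next to the no-information rate error (1 - majority class frequency).
#'
#' Features constant across all samples carry no class information and are
#' dropped up front with a message.
#'
#' @param z_confirmed genes x samples matrix of the features to rank.
#' @param labels data.frame from [label_by_auc()].
#' @param cv `"kfold"` (stratified, `k` folds) or `"loocv"`.
#' @param k Folds for `cv = "kfold"`.
#' @param C Soft-margin cost.
#' @param seed Optional integer seed (fold assignment).
#' @return List: `ranks` (data.frame `gene_id`, `avg_rank`, plus a
#'   `per_fold` matrix attribute, genes x folds) and `curve` (data.frame
#'   `n_features`, `cv_error`, `nir_error`).
#' @export
svm_rfe_rank <- function(z_confirmed, labels, cv = c("kfold", "loocv"),
                         k = 10, C = 1, seed = NULL) {
  cv <- match.arg(cv)
  is_res <- align_labels(z_confirmed, labels)
  sdv <- apply(z_confirmed, 1, stats::sd)
  if (any(sdv == 0)) {
    message(sprintf("svm_rfe_rank: dropped %d constant features", sum(sdv == 0)))
    z_confirmed <- z_confirmed[sdv > 0, , drop = FALSE]
  }
  genes <- rownames(z_confirmed)
  nf <- length(genes)
  cn_assert(nf >= 2, "SVM-RFE needs at least 2 non-constant features")
  X_all <- t(z_confirmed)
  y <- ifelse(is_res, 1, -1)
  n <- length(y)

  fold <- with_seed_(seed, {
    if (cv == "loocv") seq_len(n) else stratified_folds(y, k)
  })
  n_folds <- max(fold)

  per_fold <- matrix(NA_real_, nf, n_folds, dimnames = list(genes, NULL))
  err_by_m <- matrix(0, nf, 2)  # errors, trials per feature count
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2)
      cn_stop("training fold lost a class", "corgnet_validation_error")
    mu <- colMeans(X_all[tr, , drop = FALSE])
    sg <- apply(X_all[tr, , drop = FALSE], 2, stats::sd)
    sg[sg == 0] <- 1  # constant-in-fold features scale to all-zero, weight 0
    Xtr <- sweep(sweep(X_all[tr, , drop = FALSE], 2, mu), 2, sg, "/")
    Xte <- sweep(sweep(X_all[!tr, , drop = FALSE], 2, mu), 2, sg, "/")

    remaining <- seq_len(nf)
    rank_f <- integer(nf)
    for (iter in seq_len(nf)) {
      if (length(remaining) == 1) {
        worst <- 1
      } else {
        fit <- svm_fit(Xtr[, remaining, drop = FALSE], y[tr], C)
        worst <- which.min(fit$w^2)
      }
      rank_f[remaining[worst]] <- nf - iter + 1L
      remaining <- remaining[-worst]
    }
    per_fold[, f] <- rank_f

    for (m in seq_len(nf)) {
      top <- which(rank_f <= m)
      fit <- svm_fit(Xtr[, top, drop = FALSE], y[tr], C)
      pred <- svm_predict(fit, Xte[, top, drop = FALSE])
      err_by_m[m, 1] <- err_by_m[m, 1] + sum(pred != y[!tr])
      err_by_m[m, 2] <- err_by_m[m, 2] + sum(!tr)
    }
  }

  ranks <- data.frame(gene_id = genes, avg_rank = rowMeans(per_fold),
                      stringsAsFactors = FALSE)
  attr(ranks, "per_fold") <- per_fold
  curve <- data.frame(
    n_features = seq_len(nf),
    cv_error = err_by_m[, 1] / err_by_m[, 2],
    nir_error = 1 - max(table(y)) / n)
  list(ranks = ranks, curve = curve)
}

#' Rank modules by their best-ranked confirmed member gene
#'
#' A module's importance is the minimum `avg_rank` over its members present
#' in the rank table; modules are ordered ascending, ties broken by more
#' confirmed members, then by module id. Modules with no ranked member are
#' excluded with a message.
#'
#' @param ranks `ranks` data.frame from [svm_rfe_rank()].
#' @param partition data.frame from [cluster_modules()].
#' @return data.frame `module_id`, `position`, `min_member_rank`,
#'   `n_confirmed`.
#' @export
rank_modules <- function(ranks, partition) {
  idx <- match(ranks$gene_id, partition$gene_id)
  cn_assert(!anyNA(idx), "every ranked gene needs a module assignment")
  mod <- partition$module_id[idx]
  all_mods <- sort(unique(partition$module_id))
  missing <- setdiff(all_mods, unique(mod))
  if (length(missing))
    message(sprintf("rank_modules: %d modules have no confirmed genes",
                    length(missing)))
  agg <- do.call(rbind, lapply(split(seq_along(mod), mod), function(i) {
    data.frame(module_id = mod[i][1], min_member_rank = min(ranks$avg_rank[i]),
               n_confirmed = length(i))
  }))
  agg <- agg[order(agg$min_member_rank, -agg$n_confirmed, agg$module_id), ,
             drop = FALSE]
  agg$position <- seq_len(nrow(agg))
  rownames(agg) <- NULL
  agg[c("module_id", "position", "min_member_rank", "n_confirmed")]
}
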