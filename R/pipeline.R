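# End-to-end orchestration: label -> z-normalize -> pathway scoring ->
# filter -> pooled gene union -> adjacency/TOM/modules -> per-module shadow
# selection -> pooled SVM-RFE -> module ranking -> per-top-module enrichment.
# One global seed fans out into fixed per-stage substreams so any stage can
# be reproduced independently.

#' Assemble and validate a pipeline run configuration
#'
#' Input arguments may be file paths (loaded through the data_io readers) or
#' the corresponding in-memory objects.
#'
#' @param expression Path to an expression TSV or a genes x samples matrix.
#' @param response Path to a response table or a data.frame
#'   (`sample_id`, `auc`).
#' @param pathways Path to a GMT or a named list of gene sets.
#' @param interactions Path to an interaction TSV or an edge data.frame.
#' @param enrichment_terms Optional GMT path / named list for module
#'   annotation.
#' @param label_mode,label_cutoff Passed to [label_by_auc()].
#' @param filter_mode `"percentile"` or `"permutation"`.
#' @param tail_pct,n_perm,alpha Filter parameters.
#' @param interaction_threshold Minimum combined score (default 0.4).
#' @param score_scale Interaction score scale (see [load_interactions()]).
#' @param linkage,cut,cut_value,min_module_size Passed to
#'   [cluster_modules()].
#' @param boruta_max_runs,boruta_p_value,ntree Passed to [boruta_select()].
#' @param cv,cv_k,svm_C Passed to [svm_rfe_rank()].
#' @param top_modules Number of leading modules to annotate by enrichment.
#' @param min_term Minimum enrichment term size.
#' @param seed Global integer seed.
#' @param out_dir Optional output directory for [write_results()].
#' @return A classed `run_config` list.
#' @export
run_config <- function(expression, response, pathways, interactions,
                       enrichment_terms = NULL,
                       label_mode = "fixed", label_cutoff = 9,
                       filter_mode = c("percentile", "permutation"),
                       tail_pct = 10, n_perm = 1000, alpha = 0.05,
                       interaction_threshold = 0.4,
                       score_scale = "unit",
                       linkage = "average", cut = "height", cut_value = 0.95,
                       min_module_size = 5,
                       boruta_max_runs = 100, boruta_p_value = 0.01,
                       ntree = 500,
                       cv = c("kfold", "loocv"), cv_k = 10, svm_C = 1,
                       top_modules = 5, min_term = 2,
                       seed = 1, out_dir = NULL) {
  cfg <- list(expression = expression, response = response,
              pathways = pathways, interactions = interactions,
              enrichment_terms = enrichment_terms,
              label_mode = match.arg(label_mode, c("fixed", "percentile")),
              label_cutoff = label_cutoff,
              filter_mode = match.arg(filter_mode),
              tail_pct = tail_pct, n_perm = n_perm, alpha = alpha,
              interaction_threshold = interaction_threshold,
              score_scale = match.arg(score_scale,
                                      c("unit", "string_milli")),
              linkage = match.arg(linkage, c("average", "complete")),
              cut = match.arg(cut, c("height", "n_clusters")),
              cut_value = cut_value, min_module_size = min_module_size,
              boruta_max_runs = boruta_max_runs,
              boruta_p_value = boruta_p_value, ntree = ntree,
              cv = match.arg(cv), cv_k = cv_k, svm_C = svm_C,
              top_modules = top_modules, min_term = min_term,
              seed = as.integer(seed), out_dir = out_dir)
  for (f in c("expression", "response", "pathways", "interactions",
              "enrichment_terms")) {
    v <- cfg[[f]]
    if (is.character(v) && length(v) == 1 && !file.exists(v))
      cn_stop(sprintf("config field '%s': file not found: %s", f, v),
              "corgnet_validation_error")
  }
  structure(cfg, class = "run_config")
}

#' Read a YAML pipeline configuration
#' @param path Path to a YAML file whose keys match [run_config()] arguments.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  cn_assert(file.exists(path), sprintf("config file not found: %s", path),
            "corgnet_io_error")
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(run_config)))
  cn_assert(length(unknown) == 0,
            sprintf("unknown config fields: %s",
                    paste(unknown, collapse = ", ")))
  do.call(run_config, vals)
}

resolve_input <- function(x, loader, ...) {
  if (is.character(x) && length(x) == 1) loader(x, ...) else x
}

#' Run the full pipeline from a configuration
#'
#' Stages: label samples from AUC, z-normalize expression over the labeled
#' samples, score all pathways by greedy CORG activity, filter pathways
#' (percentile tails or label-permutation null), pool all genes of retained
#' pathways, build the thresholded interaction adjacency and its topological
#' overlap, cluster into mutually exclusive modules, run shadow-feature
#' selection per module, rank the pooled Confirmed genes with SVM-RFE,
#' derive module importance by minimum member rank, and annotate the top
#' modules by hypergeometric enrichment. Identical config plus seed gives
#' identical outputs.
#'
#' @param config A [run_config()].
#' @return List of result tables (`pathway_scores`, `modules`, `boruta`,
#'   `feature_ranks`, `cv_curve`, `module_ranking`, `enrichment`) plus
#'   `labels`, `partition` and the `manifest` (stage counts, parameters).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- "load_inputs"
  res <- tryCatch({
    expr <- resolve_input(config$expression, load_expression)
    resp <- resolve_input(config$response, load_response)
    paths <- resolve_input(config$pathways, load_gmt)
    edges <- resolve_input(config$interactions, load_interactions,
                           score_scale = config$score_scale)
    terms <- if (is.null(config$enrichment_terms)) NULL else
      resolve_input(config$enrichment_terms, load_gmt)

    stage <- "label"
    shared <- intersect(colnames(expr), resp$sample_id)
    cn_assert(length(shared) >= 4,
              "fewer than 4 samples shared between expression and response")
    labels <- label_by_auc(resp[match(shared, resp$sample_id), , drop = FALSE],
                           config$label_mode, config$label_cutoff)

    stage <- "zscore"
    z <- zscore_rows(expr[, shared, drop = FALSE])

    stage <- "pathway_scores"
    scored <- score_all_pathways(paths, z, labels)
    cn_assert(length(scored) >= 1, "no pathway could be scored")
    filt <- if (config$filter_mode == "percentile") {
      filter_percentile(scored, config$tail_pct)
    } else {
      filter_permutation(paths[names(scored)], z, labels,
                         n_perm = config$n_perm, alpha = config$alpha,
                         seed = sub_seed(config$seed, "filter"))
    }
    pathway_scores <- merge(
      pathway_score_table(scored), filt[c("pathway_id", "retained",
                                          "p_empirical")],
      by = "pathway_id", sort = FALSE)

    stage <- "pool_genes"
    retained_ids <- filt$pathway_id[filt$retained]
    cn_assert(length(retained_ids) >= 1, "no pathway retained by the filter")
    pooled <- sort(unique(unlist(lapply(paths[retained_ids],
                                        intersect, rownames(z)))))
    cn_assert(length(pooled) >= 2, "fewer than 2 pooled genes")

    stage <- "modules"
    adj <- build_adjacency(edges, pooled, config$interaction_threshold)
    tom <- topological_overlap(adj)
    partition <- cluster_modules(tom, config$linkage, config$cut,
                                 config$cut_value, config$min_module_size)
    modules <- module_table(partition, adj, tom)

    stage <- "boruta"
    decisions <- list()
    for (m in sort(unique(partition$module_id))) {
      mg <- partition$gene_id[partition$module_id == m]
      d <- if (length(mg) < 2) {
        data.frame(gene_id = mg, decision = "Tentative", n_hits = 0L,
                   n_runs = 0L, stringsAsFactors = FALSE)
      } else {
        boruta_select(z[mg, , drop = FALSE], labels,
                      max_runs = config$boruta_max_runs,
                      p_value = config$boruta_p_value,
                      seed = sub_seed(config$seed, "boruta") + m,
                      ntree = config$ntree)
      }
      d$module_id <- m
      decisions[[as.character(m)]] <- d
    }
    boruta <- do.call(rbind, decisions)
    rownames(boruta) <- NULL
    boruta <- boruta[c("gene_id", "module_id", "decision", "n_hits", "n_runs")]
    confirmed <- boruta$gene_id[boruta$decision == "Confirmed"]
    cn_assert(length(confirmed) >= 2,
              "fewer than 2 genes confirmed by shadow-feature selection")

    stage <- "svm_rfe"
    rfe <- svm_rfe_rank(z[confirmed, , drop = FALSE], labels,
                        cv = config$cv, k = config$cv_k, C = config$svm_C,
                        seed = sub_seed(config$seed, "rfe"))
    feature_ranks <- merge(rfe$ranks,
                           boruta[c("gene_id", "module_id", "decision")],
                           by = "gene_id", sort = FALSE)
    pf <- attr(rfe$ranks, "per_fold")
    feature_ranks$fold_ranks <- apply(
      pf[feature_ranks$gene_id, , drop = FALSE], 1, paste, collapse = ",")

    stage <- "module_ranking"
    module_ranking <- rank_modules(rfe$ranks, partition)

    stage <- "enrichment"
    enrichment <- NULL
    if (!is.null(terms)) {
      universe <- intersect(rownames(z), unique(unlist(terms)))
      top <- module_ranking$module_id[
        seq_len(min(config$top_modules, nrow(module_ranking)))]
      etabs <- lapply(top, function(m) {
        q <- intersect(confirmed,
                       partition$gene_id[partition$module_id == m])
        q <- intersect(q, universe)
        if (length(q) == 0) return(NULL)
        cbind(module_id = m, enrich(q, universe, terms,
                                    min_term = config$min_term))
      })
      enrichment <- do.call(rbind, Filter(Negate(is.null), etabs))
    }

    manifest_counts <- list(
      n_samples = length(shared),
      n_sensitive = sum(labels$label == "sensitive"),
      n_resistant = sum(labels$label == "resistant"),
      n_genes_z = nrow(z),
      n_pathways_scored = length(scored),
      n_pathways_skipped = length(attr(scored, "skipped")),
      n_pathways_retained = length(retained_ids),
      n_pooled_genes = length(pooled),
      n_modules = length(setdiff(unique(partition$module_id), 0L)),
      n_confirmed = length(confirmed))

    out <- list(pathway_scores = pathway_scores, modules = modules,
                boruta = boruta, feature_ranks = feature_ranks,
                cv_curve = rfe$curve, module_ranking = module_ranking,
                enrichment = enrichment, labels = labels,
                partition = partition,
                manifest = list(params = config[setdiff(names(config),
                  c("expression", "response", "pathways", "interactions",
                    "enrichment_terms"))],
                  seed = config$seed, counts = manifest_counts))
    if (!is.null(config$out_dir)) {
      tabs <- out[c("pathway_scores", "modules", "boruta", "feature_ranks",
                    "cv_curve", "module_ranking")]
      if (!is.null(enrichment)) tabs$enrichment <- enrichment
      inputs <- lapply(config[c("expression", "response", "pathways",
                                "interactions", "enrichment_terms")],
                       function(x) if (is.character(x)) x else "<in-memory>")
      write_results(tabs, config$out_dir, inputs = inputs,
                    params = out$manifest$params, seed = config$seed)
    }
    out
  }, corgnet_error = function(e) {
    cn_stop(sprintf("pipeline failed at stage '%s': %s", stage,
                    conditionMessage(e)), "corgnet_pipeline_error")
  })
  res
}
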