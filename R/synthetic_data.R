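# Synthetic pharmacogenomic fixtures with recorded ground truth. The
# generator emulates the structure the pipeline assumes: a two-class
# expression matrix with planted differentially-active driver pathways, an
# interaction network whose stochastic-block-model blocks align with
# co-expressed gene groups (pathways are drawn within blocks), and a bimodal
# AUC vector driven by the planted class.

#' Specification of a synthetic dataset
#'
#' Defaults state the benchmark world used throughout the test-suite: 100
#' samples, 1000 genes in 20 blocks of 50, 20 pathways (one per block, 15-25
#' genes), one driver pathway with a 1.5-sd mean shift in resistant samples,
#' block-model edge probabilities 0.3 (within) / 0.01 (between) with
#' within-block combined scores uniform on \[0.4, 1\] and between-block
#' scores below the 0.4 threshold, half the samples resistant, and AUC =
#' 6 + 2 x resistant + N(0, 0.5).
#'
#' @param n_samples,n_genes,n_pathways Sizes.
#' @param pathway_size_range Length-2 integer range of member counts.
#' @param n_driver_pathways Number of planted driver pathways.
#' @param effect_delta Mean shift (in within-class sd units) added to driver
#'   genes in resistant samples.
#' @param block_p_in,block_p_out Within/between-block edge probabilities.
#' @param score_range Combined-score interval for within-block edges; its
#'   lower bound doubles as the network threshold the between-block scores
#'   stay below.
#' @param label_fraction_resistant Fraction of samples labeled resistant.
#' @param auc_noise_sd Gaussian noise sd of the AUC model.
#' @param block_sd Sd of the shared per-block factor inducing co-expression.
#' @param seed Integer seed; the whole dataset is a pure function of the spec.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_samples = 100, n_genes = 1000, n_pathways = 20,
                           pathway_size_range = c(15, 25),
                           n_driver_pathways = 1, effect_delta = 1.5,
                           block_p_in = 0.3, block_p_out = 0.01,
                           score_range = c(0.4, 1),
                           label_fraction_resistant = 0.5,
                           auc_noise_sd = 0.5, block_sd = 0.5, seed = 1) {
  spec <- list(n_samples = n_samples, n_genes = n_genes,
               n_pathways = n_pathways,
               pathway_size_range = as.integer(pathway_size_range),
               n_driver_pathways = n_driver_pathways,
               effect_delta = effect_delta, block_p_in = block_p_in,
               block_p_out = block_p_out, score_range = score_range,
               label_fraction_resistant = label_fraction_resistant,
               auc_noise_sd = auc_noise_sd, block_sd = block_sd,
               seed = as.integer(seed))
  with(spec, {
    cn_assert(n_samples >= 4 && n_genes >= n_pathways && n_pathways >= 1,
              "infeasible sizes", "corgnet_parameter_error")
    cn_assert(all(c(block_p_in, block_p_out,
                    label_fraction_resistant) >= 0) &&
                all(c(block_p_in, block_p_out,
                      label_fraction_resistant) <= 1),
              "probabilities must lie in [0, 1]", "corgnet_parameter_error")
    cn_assert(effect_delta >= 0 && auc_noise_sd >= 0,
              "effect_delta and auc_noise_sd must be non-negative",
              "corgnet_parameter_error")
    cn_assert(length(pathway_size_range) == 2 &&
                pathway_size_range[1] >= 1 &&
                pathway_size_range[2] <= floor(n_genes / n_pathways),
              "pathway sizes must fit inside one block",
              "corgnet_parameter_error")
    cn_assert(n_driver_pathways >= 0 && n_driver_pathways <= n_pathways,
              "n_driver_pathways out of range", "corgnet_parameter_error")
  })
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic dataset with recorded ground truth
#'
#' Gene i in sample j is `delta_i * 1[resistant_j] + f_{b(i), j} + eps_ij`
#' with `eps ~ N(0, 1)` and a shared block factor `f ~ N(0, block_sd^2)`;
#' `delta_i = effect_delta` for driver-pathway genes, 0 otherwise. Pathway p
#' is drawn inside block p so planted pathways align with network blocks;
#' decoy pathways never contain driver genes. Interaction edges follow a
#' stochastic block model with within-block scores uniform on `score_range`
#' and between-block scores uniform below its lower bound. AUC is
#' `6 + 2 * 1[resistant] + N(0, auc_noise_sd)`. The enrichment collection
#' holds one term per block (the block's full gene content).
#'
#' @param spec A [synthetic_spec()].
#' @return List: `expression` (genes x samples matrix), `response`
#'   (data.frame `sample_id`, `auc`), `pathways` and `enrichment_terms` (GMT
#'   style named lists), `interactions` (edge data.frame), `truth` (list:
#'   `driver_pathway_ids`, `driver_gene_ids`, `planted_module_of_gene`,
#'   `true_effect_per_gene`, `planted_labels`, `driver_blocks`), `spec`.
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed_(spec$seed, {
    n <- spec$n_samples; g <- spec$n_genes; np <- spec$n_pathways
    genes <- sprintf("g%04d", seq_len(g))
    samples <- sprintf("s%03d", seq_len(n))
    base_size <- g %/% np
    block <- rep(seq_len(np), times = c(rep(base_size, np - 1),
                                        g - base_size * (np - 1)))
    names(block) <- genes

    n_res <- round(n * spec$label_fraction_resistant)
    cn_assert(n_res >= 2 && n - n_res >= 2,
              "label fraction leaves a class with < 2 samples",
              "corgnet_parameter_error")
    is_res <- sample(rep(c(TRUE, FALSE), c(n_res, n - n_res)))
    names(is_res) <- samples

    driver_blocks <- sort(sample(np, spec$n_driver_pathways))
    pathways <- list()
    size_pool <- seq(spec$pathway_size_range[1], spec$pathway_size_range[2])
    sizes <- size_pool[sample.int(length(size_pool), np, replace = TRUE)]
    for (p in seq_len(np)) {
      pathways[[sprintf("P%02d", p)]] <-
        sort(sample(genes[block == p], sizes[p]))
    }
    driver_ids <- sprintf("P%02d", driver_blocks)
    driver_genes <- sort(unique(unlist(pathways[driver_ids])))

    delta <- setNames(numeric(g), genes)
    delta[driver_genes] <- spec$effect_delta

    f_block <- matrix(rnorm(np * n, 0, spec$block_sd), np, n)
    expr <- matrix(rnorm(g * n), g, n, dimnames = list(genes, samples)) +
      f_block[block, ] + delta %o% as.numeric(is_res)

    # stochastic block model over all gene pairs
    i <- rep(seq_len(g - 1), times = (g - 1):1)
    j <- sequence((g - 1):1, from = 2:g)
    same <- block[i] == block[j]
    p_edge <- ifelse(same, spec$block_p_in, spec$block_p_out)
    on <- runif(length(i)) < p_edge
    lo <- spec$score_range[1]
    sc <- ifelse(same[on],
                 runif(sum(on), lo, spec$score_range[2]),
                 runif(sum(on), 0.05, lo - 0.01))
    interactions <- data.frame(gene_a = genes[i[on]], gene_b = genes[j[on]],
                               combined_score = round(sc, 3),
                               stringsAsFactors = FALSE)

    auc <- 6 + 2 * as.numeric(is_res) + rnorm(n, 0, spec$auc_noise_sd)
    response <- data.frame(sample_id = samples, auc = auc,
                           stringsAsFactors = FALSE)

    terms <- lapply(seq_len(np), function(b) genes[block == b])
    names(terms) <- sprintf("BLOCK%02d", seq_len(np))

    list(expression = expr, response = response, pathways = pathways,
         enrichment_terms = terms, interactions = interactions,
         truth = list(driver_pathway_ids = driver_ids,
                      driver_gene_ids = driver_genes,
                      planted_module_of_gene = block,
                      true_effect_per_gene = delta,
                      planted_labels = ifelse(is_res, "resistant",
                                              "sensitive"),
                      driver_blocks = driver_blocks),
         spec = spec)
  })
}

#' Write a synthetic dataset bundle to disk in the pipeline's input formats
#'
#' Emits `expression.tsv`, `response.csv`, `pathways.gmt`,
#' `enrichment_terms.gmt`, `interactions.tsv` and `ground_truth.json`, all
#' loadable unchanged by the data_io readers.
#'
#' @param bundle Output of [generate_dataset()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_fixture <- function(bundle, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok) cn_stop(sprintf("cannot create %s", out_dir), "corgnet_io_error")
  paths <- c(
    expression = file.path(out_dir, "expression.tsv"),
    response = file.path(out_dir, "response.csv"),
    pathways = file.path(out_dir, "pathways.gmt"),
    enrichment_terms = file.path(out_dir, "enrichment_terms.gmt"),
    interactions = file.path(out_dir, "interactions.tsv"),
    truth = file.path(out_dir, "ground_truth.json"))
  write_expression(bundle$expression, paths["expression"])
  write.table(bundle$response, paths["response"], sep = ",", quote = FALSE,
              row.names = FALSE)
  write_gmt(bundle$pathways, paths["pathways"])
  write_gmt(bundle$enrichment_terms, paths["enrichment_terms"])
  write.table(bundle$interactions, paths["interactions"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- bundle$truth
  truth$planted_module_of_gene <- as.list(truth$planted_module_of_gene)
  truth$true_effect_per_gene <- as.list(truth$true_effect_per_gene)
  truth$planted_labels <- as.list(truth$planted_labels)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
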