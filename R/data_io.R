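# Readers and writers for the pipeline's external formats: expression TSV
# (genes in rows, header = sample ids), GMT gene-set collections, 3-column
# interaction edge lists, 2-column response tables, and TSV/JSON result
# bundles. All gene/sample matching downstream is by exact string identity.

#' Load a gene x sample expression matrix from TSV
#'
#' The file must have a header row of sample identifiers and gene identifiers
#' in the first column. Values are assumed pre-normalized (e.g. log2 RMA
#' scale). Duplicate gene rows are collapsed by their mean; rows containing
#' missing values are dropped (and counted in a message) when
#' `drop_incomplete = TRUE`, otherwise they are an error.
#'
#' @param path Path to a tab-separated file.
#' @param drop_incomplete Drop rows with any missing value instead of failing.
#' @return A numeric matrix with gene ids as rownames and sample ids as
#'   colnames.
#' @export
load_expression <- function(path, drop_incomplete = TRUE) {
  cn_assert(file.exists(path), sprintf("expression file not found: %s", path),
            "corgnet_io_error")
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    cn_stop("malformed expression header: need gene id column plus >= 1 sample",
            "corgnet_format_error")
  gene <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples))
    cn_stop("duplicate sample identifiers in expression header",
            "corgnet_validation_error")

  incomplete <- rowSums(is.na(vals)) > 0
  if (any(incomplete)) {
    if (!drop_incomplete)
      cn_stop(sprintf("%d expression rows contain missing values",
                      sum(incomplete)), "corgnet_validation_error")
    message(sprintf("load_expression: dropped %d incomplete gene rows",
                    sum(incomplete)))
    vals <- vals[!incomplete, , drop = FALSE]
    gene <- gene[!incomplete]
  }
  if (anyDuplicated(gene)) {
    n_dup <- length(gene) - length(unique(gene))
    message(sprintf("load_expression: collapsed %d duplicate gene rows by mean",
                    n_dup))
    vals <- rowsum(vals, group = gene, reorder = FALSE) /
      as.vector(table(factor(gene, levels = unique(gene))))
    gene <- rownames(vals)
  }
  rownames(vals) <- gene
  colnames(vals) <- samples
  cn_assert(ncol(vals) >= 2, "expression matrix needs at least 2 samples")
  cn_assert(nrow(vals) >= 1, "expression matrix has no usable gene rows")
  vals
}

#' Write an expression matrix as TSV (gene ids in the first column)
#' @param mat Numeric matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a drug-response table (sample_id, auc)
#'
#' Comma-separated for `.csv` paths, tab-separated otherwise. Higher AUC
#' means more resistant.
#'
#' @param path Path to a 2-column table with header.
#' @return A data.frame with columns `sample_id` and `auc`.
#' @export
load_response <- function(path) {
  cn_assert(file.exists(path), sprintf("response file not found: %s", path),
            "corgnet_io_error")
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    cn_stop("response table needs columns sample_id and auc",
            "corgnet_format_error")
  out <- data.frame(sample_id = as.character(df[[1]]),
                    auc = as.numeric(df[[2]]),
                    stringsAsFactors = FALSE)
  cn_assert(!anyDuplicated(out$sample_id),
            "duplicate sample identifiers in response table")
  cn_assert(all(is.finite(out$auc)), "non-finite AUC values in response table")
  out
}

#' Load a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Empty lines are skipped;
#' repeated genes within a set are stored once.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors with a `description` attribute
#'   (named character vector).
#' @export
load_gmt <- function(path) {
  cn_assert(file.exists(path), sprintf("GMT file not found: %s", path),
            "corgnet_io_error")
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  sets <- list()
  desc <- character()
  for (i in keep) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      cn_stop(sprintf("GMT line %d has fewer than 3 fields", i),
              "corgnet_format_error")
    id <- f[1]
    if (id %in% names(sets))
      cn_stop(sprintf("duplicate gene-set id '%s' (line %d)", id, i),
              "corgnet_validation_error")
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    cn_assert(length(genes) >= 1, sprintf("gene set '%s' is empty", id))
    sets[[id]] <- genes
    desc[id] <- f[2]
  }
  attr(sets, "description") <- desc
  sets
}

#' Write a gene-set collection to GMT
#' @param sets Named list of character vectors (optional `description` attr).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, desc[[id]], sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Load a protein-protein interaction edge list
#'
#' Expects three columns: gene_a, gene_b, combined_score. STRING-style raw
#' files carry integer scores 0-1000; pass `score_scale = "string_milli"` to
#' divide by 1000 so that the conventional 0.4 medium-confidence threshold
#' applies on the unit scale. Self edges are dropped; duplicate undirected
#' edges are collapsed keeping the maximum score.
#'
#' @param path Path to a whitespace/tab-separated 3-column file (a header
#'   line is detected and skipped when the third field is not numeric).
#' @param score_scale `"unit"` (scores already in \[0,1\]) or
#'   `"string_milli"` (raw 0-1000 scores, divided by 1000).
#' @return A data.frame `gene_a`, `gene_b`, `combined_score` with
#'   `gene_a < gene_b` and rows sorted, so ingestion order never matters.
#' @export
load_interactions <- function(path, score_scale = c("unit", "string_milli")) {
  score_scale <- match.arg(score_scale)
  cn_assert(file.exists(path), sprintf("interaction file not found: %s", path),
            "corgnet_io_error")
  first <- readLines(path, n = 1L)
  f1 <- strsplit(trimws(first), "[\t ]+")[[1]]
  has_header <- length(f1) >= 3 && is.na(suppressWarnings(as.numeric(f1[3])))
  df <- read.table(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(df) < 3)
    cn_stop("interaction file needs 3 columns: gene_a, gene_b, combined_score",
            "corgnet_format_error")
  a <- as.character(df[[1]]); b <- as.character(df[[2]])
  s <- as.numeric(df[[3]])
  hi <- if (score_scale == "string_milli") 1000 else 1
  cn_assert(all(is.finite(s)) && all(s >= 0) && all(s <= hi),
            sprintf("combined scores outside declared %s range [0, %g]",
                    score_scale, hi))
  if (score_scale == "string_milli") s <- s / 1000

  self <- a == b
  if (any(self))
    message(sprintf("load_interactions: dropped %d self edges", sum(self)))
  a2 <- pmin(a[!self], b[!self])
  b2 <- pmax(a[!self], b[!self])
  s2 <- s[!self]
  key <- paste(a2, b2, sep = "\r")
  smax <- tapply(s2, key, max)
  parts <- do.call(rbind, strsplit(names(smax), "\r", fixed = TRUE))
  out <- data.frame(gene_a = parts[, 1], gene_b = parts[, 2],
                    combined_score = as.numeric(smax),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write result tables plus a JSON run manifest
#'
#' Each element of `tables` is written as `<name>.tsv` with a header. The
#' manifest records input paths, parameters, the seed, the package version
#' and per-table row counts; reruns with identical inputs produce
#' byte-identical files.
#'
#' @param tables Named list of data.frames.
#' @param out_dir Output directory (created if needed).
#' @param inputs Named list/character of input paths for the manifest.
#' @param params Named list of parameters for the manifest.
#' @param seed Integer seed recorded in the manifest (or NULL).
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
write_results <- function(tables, out_dir, inputs = list(), params = list(),
                          seed = NULL) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0)
    cn_stop(sprintf("output directory not writable: %s", out_dir),
            "corgnet_io_error")
  stopifnot(is.list(tables), !is.null(names(tables)))
  counts <- list()
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    write.table(tab, file.path(out_dir, paste0(nm, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
    counts[[nm]] <- nrow(tab)
  }
  manifest <- list(
    package = "corgnet",
    version = as.character(packageVersion("corgnet")),
    inputs = inputs, params = params, seed = seed,
    row_counts = counts
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}

#' Read a run manifest written by [write_results()]
#' @param path Path to `manifest.json`.
#' @return The manifest list.
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}
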