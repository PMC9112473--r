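# Fixture builders shared across the suite. Everything is generated in code;
# files go to tempdir().

# genes x samples matrix of standard normals with optional class shift on the
# first `n_shift` genes (added to resistant samples).
mk_z <- function(n_genes, n_samples, delta = 0, n_shift = 0, seed = NULL) {
  build <- function() {
    z <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("s%03d", seq_len(n_samples))))
    if (n_shift > 0 && delta != 0) {
      res <- seq_len(n_samples) > n_samples / 2
      z[seq_len(n_shift), res] <- z[seq_len(n_shift), res] + delta
    }
    z
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

# half sensitive / half resistant labels for the columns of z
mk_labels <- function(z) {
  n <- ncol(z)
  data.frame(sample_id = colnames(z),
             label = factor(rep(c("sensitive", "resistant"),
                                c(floor(n / 2), ceiling(n / 2))),
                            levels = c("sensitive", "resistant")),
             stringsAsFactors = FALSE)
}

write_tsv_fixture <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# independent oracle for the greedy CORG search: exhaustive prefix scan over
# both t-orderings, each prefix scored with stats::t.test
oracle_corg <- function(genes, z, labels, var_equal = FALSE) {
  is_res <- labels$label[match(colnames(z), labels$sample_id)] == "resistant"
  zz <- z[intersect(genes, rownames(z)), , drop = FALSE]
  tg <- apply(zz, 1, function(r)
    t.test(r[is_res], r[!is_res], var.equal = var_equal)$statistic)
  best <- -Inf
  for (ord in list(order(-tg, rownames(zz)), order(tg, rownames(zz)))) {
    ids <- rownames(zz)[ord]
    for (m in seq_along(ids)) {
      a <- colSums(zz[ids[seq_len(m)], , drop = FALSE]) / sqrt(m)
      tt <- t.test(a[is_res], a[!is_res], var.equal = var_equal)$statistic
      best <- max(best, abs(tt))
    }
  }
  list(absmax = best, max_single = max(abs(tg)))
}

# brute-force topological overlap via explicit triple loop
oracle_tom <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  om <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    om[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(om) <- dimnames(a)
  om
}

# Holm step-down by definition: sort ascending, multiply by (m - i + 1),
# running maximum, cap at 1, unsort.
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(cummax(p[o] * (m - seq_len(m) + 1)), 1)
  adj[order(o)]
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  n2 <- ch2(sum(tab))
  exp_ <- si * sj / n2
  (sij - exp_) / ((si + sj) / 2 - exp_)
}
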