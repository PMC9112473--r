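# Labeling, z-normalization, Welch t, greedy CORG search, pathway filters

test_that("label_by_auc applies fixed and percentile cutoffs with the stated boundary", {
  resp <- data.frame(sample_id = sprintf("c%02d", 1:4),
                     auc = c(8.5, 9.5, 9, 3))
  lab <- label_by_auc(resp, "fixed", cutoff = 9)
  expect_identical(as.character(lab$label), c("sensitive", "resistant",
                                              "resistant", "sensitive"))

  # percentile mode, nearest rank: 5th percentile of 1..100 labels exactly 5
  resp2 <- data.frame(sample_id = sprintf("c%03d", 1:100), auc = 1:100)
  lab2 <- label_by_auc(resp2, "percentile", cutoff = 5)
  expect_identical(sum(lab2$label == "sensitive"), 5L)

  expect_error(suppressWarnings(label_by_auc(resp, "fixed", cutoff = 100)),
               class = "corgnet_labeling_error")
  # an out-of-range cutoff warns before the (inevitable) empty-class error
  expect_warning(
    tryCatch(label_by_auc(resp, "fixed", cutoff = 20),
             corgnet_labeling_error = function(e) NULL),
    "outside the observed AUC range")
})

test_that("zscore_rows standardizes rows and drops constants", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5), d = c(2, 4, 6))
  colnames(m) <- c("s1", "s2", "s3")
  z <- suppressMessages(zscore_rows(m))
  expect_equal(unname(z["a", ]), c(-1, 0, 1))
  expect_false("b" %in% rownames(z))
  expect_error(zscore_rows(rbind(x = c(1, 1, 1))),
               class = "corgnet_validation_error")

  zr <- mk_z(50, 12, seed = 3)
  zs <- zscore_rows(zr)
  expect_lt(max(abs(rowMeans(zs))), 1e-12)
  expect_lt(max(abs(apply(zs, 1, sd) - 1)), 1e-12)
})

test_that("gene_tscores matches the Welch formula, t.test, and is antisymmetric", {
  z <- rbind(g1 = c(1, 2, 3, 4, 5, 6))
  colnames(z) <- sprintf("s%d", 1:6)
  lab <- mk_labels(z)  # first 3 sensitive, last 3 resistant
  t1 <- gene_tscores(z, lab)$t
  expect_equal(t1, 3.6742, tolerance = 1e-4)  # (5-2)/sqrt(2/3), by hand

  zz <- mk_z(30, 14, seed = 8)
  ll <- mk_labels(zz)
  got <- gene_tscores(zz, ll)
  is_res <- ll$label == "resistant"
  ora <- apply(zz, 1, function(r) t.test(r[is_res], r[!is_res])$statistic)
  expect_equal(got$t, unname(ora[got$gene_id]), tolerance = 1e-10)

  flipped <- ll
  flipped$label <- factor(ifelse(ll$label == "resistant", "sensitive",
                                 "resistant"),
                          levels = c("sensitive", "resistant"))
  expect_equal(gene_tscores(zz, flipped)$t, -got$t, tolerance = 1e-12)

  expect_error(gene_tscores(zz[, 1:3],
                            ll[1:3, ]), class = "corgnet_validation_error")
})

test_that("greedy CORG activity obeys its formula and edge cases", {
  z <- mk_z(12, 20, seed = 21)
  lab <- mk_labels(z)

  # single-gene pathway: k = 1, score = that gene's t, activity = its z row
  r1 <- greedy_pathway_activity("g001", z, lab)
  expect_identical(r1$k, 1L)
  expect_equal(unname(r1$activity), unname(z["g001", ]), tolerance = 1e-12)
  expect_equal(r1$score, gene_tscores(z["g001", , drop = FALSE], lab)$t,
               tolerance = 1e-12)

  # activity = sum z / sqrt(k): sample with unit z on all selected genes -> 2
  z2 <- z
  z2[, "s001"] <- 1
  r2 <- greedy_pathway_activity(rownames(z2), z2, lab)
  expect_equal(unname(r2$activity["s001"]), unname(r2$k / sqrt(r2$k)),
               tolerance = 1e-12)
  expect_equal(unname(r2$activity),
               unname(colSums(z2[r2$selected_genes, , drop = FALSE]) /
                        sqrt(r2$k)), tolerance = 1e-12)

  # absent members dropped; fully absent pathway raises the skip condition
  expect_message(greedy_pathway_activity(c("g001", "nope"), z, lab, "P"),
                 "absent")
  expect_error(greedy_pathway_activity(c("x", "y"), z, lab),
               class = "corgnet_pathway_skip")
})

test_that("greedy search equals the exhaustive prefix oracle on random pathways", {
  withr::with_seed(100, {
    z <- mk_z(60, 24)
    lab <- mk_labels(z)
    for (i in 1:25) {
      genes <- sample(rownames(z), sample(1:15, 1))
      got <- suppressMessages(greedy_pathway_activity(genes, z, lab))
      ora <- oracle_corg(genes, z, lab)
      expect_equal(abs(got$score), ora$absmax, tolerance = 1e-8)
      expect_gte(abs(got$score), ora$max_single - 1e-8)
      # stored activity consistent with the selected prefix
      expect_equal(unname(got$activity),
                   unname(colSums(z[got$selected_genes, , drop = FALSE]) /
                            sqrt(got$k)), tolerance = 1e-12)
    }
  })
})

test_that("score_all_pathways keeps input order, records skips, is deterministic", {
  z <- mk_z(40, 16, seed = 31)
  lab <- mk_labels(z)
  coll <- list(A = rownames(z)[1:5], GONE = c("q1", "q2"),
               B = rownames(z)[6:20])
  res <- suppressMessages(score_all_pathways(coll, z, lab))
  expect_identical(names(res), c("A", "B"))
  expect_identical(attr(res, "skipped"), "GONE")
  res2 <- suppressMessages(score_all_pathways(coll, z, lab))
  expect_identical(vapply(res, `[[`, numeric(1), "score"),
                   vapply(res2, `[[`, numeric(1), "score"))
})

mk_fake_results <- function(scores) {
  out <- lapply(seq_along(scores), function(i)
    list(pathway_id = sprintf("P%03d", i), n_genes_present = 5, k = 2,
         score = scores[i], direction = "up_in_resistant"))
  names(out) <- sprintf("P%03d", seq_along(scores))
  out
}

test_that("percentile filter keeps symmetric nearest-rank tails", {
  filt <- filter_percentile(mk_fake_results(seq(-5, 5, length.out = 20)), 10)
  expect_identical(sum(filt$retained), 4L)  # 2 per tail

  expect_identical(sum(filter_percentile(
    mk_fake_results(rnorm(11)), 50)$retained), 11L)

  # two-tailed symmetry: negating scores keeps the same retained set
  withr::with_seed(17, {
    for (i in 1:10) {
      sc <- rnorm(sample(20:80, 1))
      a <- filter_percentile(mk_fake_results(sc), 15)
      b <- filter_percentile(mk_fake_results(-sc), 15)
      expect_identical(a$retained, b$retained)
    }
  })
  expect_warning(filter_percentile(mk_fake_results(1:3), 10), "fewer than 5")
  expect_error(filter_percentile(mk_fake_results(1:10), 60),
               class = "corgnet_parameter_error")
})

test_that("permutation filter detects a planted pathway and bounds p from below", {
  withr::with_seed(55, {
    z <- mk_z(40, 60, delta = 1.5, n_shift = 12)
    lab <- mk_labels(z)
    coll <- list(driver = rownames(z)[1:12], noise = rownames(z)[21:32])
    filt <- filter_permutation(coll, zscore_rows(z), lab, n_perm = 199,
                               alpha = 0.05, seed = 2)
    expect_true(all(filt$p_empirical >= 1 / 200))
    expect_lte(filt$p_empirical[filt$pathway_id == "driver"], 0.05)
    expect_true(filt$retained[filt$pathway_id == "driver"])
    expect_gt(filt$p_empirical[filt$pathway_id == "noise"], 0.05)
  })
  expect_error(filter_permutation(list(a = "g001"), mk_z(5, 10, seed = 1),
                                  mk_labels(mk_z(5, 10, seed = 1)),
                                  n_perm = 10),
               class = "corgnet_parameter_error")
})
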