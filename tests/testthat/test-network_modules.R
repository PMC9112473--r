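# Adjacency construction, topological overlap, module clustering

test_that("build_adjacency thresholds at >= 0.4 and stays symmetric", {
  edges <- data.frame(gene_a = c("A", "B", "C"), gene_b = c("B", "C", "D"),
                      combined_score = c(0.39, 0.40, 0.9))
  a <- build_adjacency(edges, c("A", "B", "C", "D"), threshold = 0.4)
  expect_equal(a["A", "B"], 0)       # 0.39 < 0.4 drops the edge
  expect_equal(a["B", "C"], 0.40)    # boundary kept, weight = score
  expect_equal(a["C", "D"], 0.9)
  expect_identical(a, t(a))
  expect_true(all(a["A", ] == 0))    # no qualifying edge -> zero row
  b <- build_adjacency(edges, c("A", "B", "C", "D"), 0.4, binarize = TRUE)
  expect_equal(unname(b["C", "D"]), 1)
})

test_that("topological overlap reproduces hand values", {
  g3 <- c("A", "B", "C")
  tri <- matrix(1, 3, 3, dimnames = list(g3, g3)); diag(tri) <- 0
  expect_true(all(abs(topological_overlap(tri) - 1) < 1e-12))

  path <- matrix(0, 3, 3, dimnames = list(g3, g3))
  path["A", "B"] <- path["B", "A"] <- 1
  path["B", "C"] <- path["C", "B"] <- 1
  om <- topological_overlap(path)
  expect_equal(om["A", "B"], 1)      # (0 + 1)/(1 + 1 - 1)
  expect_equal(om["A", "C"], 0.5)    # (1 + 0)/(1 + 1 - 0)

  iso <- matrix(0, 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(topological_overlap(iso)["x", "y"], 0)
})

test_that("topological overlap matches the triple-loop oracle on random graphs", {
  withr::with_seed(7, {
    for (i in 1:8) {
      n <- sample(5:20, 1)
      a <- matrix(0, n, n)
      on <- upper.tri(a) & matrix(runif(n * n) < 0.3, n, n)
      a[on] <- runif(sum(on))
      a <- a + t(a)
      dimnames(a) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
      expect_lt(max(abs(topological_overlap(a) - oracle_tom(a))), 1e-12)
    }
  })
})

test_that("unit-weight twins with a connecting edge get overlap 1", {
  # nodes 1 and 2 connected and sharing the same other neighbors
  n <- 6
  a <- matrix(0, n, n)
  a[1, 2] <- a[2, 1] <- 1
  for (u in 3:5) { a[1, u] <- a[u, 1] <- 1; a[2, u] <- a[u, 2] <- 1 }
  dimnames(a) <- list(letters[1:n], letters[1:n])
  expect_equal(topological_overlap(a)["a", "b"], 1)
})

test_that("clustering separates cliques and forms a true partition", {
  g <- sprintf("g%02d", 1:20)
  a <- matrix(0, 20, 20, dimnames = list(g, g))
  a[1:10, 1:10] <- 1
  a[11:20, 11:20] <- 1
  diag(a) <- 0
  part <- cluster_modules(topological_overlap(a), cut_value = 0.5)
  expect_identical(sort(unique(part$module_id)), c(1L, 2L))
  expect_true(all(table(part$module_id) == 10))
  # same genes, shuffled input order -> identical partition as sets
  perm <- sample(20)
  part2 <- cluster_modules(topological_overlap(a[perm, perm]),
                           cut_value = 0.5)
  split1 <- lapply(split(part$gene_id, part$module_id), sort)
  split2 <- lapply(split(part2$gene_id, part2$module_id), sort)
  expect_identical(split1, split2)

  expect_error(cluster_modules(matrix(1, 1, 1,
                                      dimnames = list("x", "x"))),
               class = "corgnet_validation_error")
  expect_error(cluster_modules(topological_overlap(a), cut_value = 2),
               class = "corgnet_parameter_error")
})

test_that("small clusters pool into module 0 and sizes always sum to n", {
  withr::with_seed(12, {
    for (i in 1:5) {
      n <- sample(12:40, 1)
      a <- matrix(0, n, n)
      on <- upper.tri(a) & matrix(runif(n * n) < 0.25, n, n)
      a[on] <- runif(sum(on), 0.4, 1)
      a <- a + t(a)
      dimnames(a) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
      part <- cluster_modules(topological_overlap(a), cut_value = 0.9,
                              min_module_size = 4)
      expect_identical(nrow(part), n)
      expect_identical(sum(table(part$module_id)), n)
      sizes <- table(part$module_id[part$module_id > 0])
      if (length(sizes)) expect_true(all(sizes >= 4))
      # modules relabeled by decreasing size
      if (length(sizes) > 1)
        expect_true(all(diff(as.integer(sizes)) <= 0))
    }
  })
})

test_that("planted stochastic-block-model graphs are recovered", {
  hits <- 0
  for (s in 1:5) {
    withr::with_seed(400 + s, {
      blocks <- rep(1:5, each = 30)
      n <- length(blocks)
      a <- matrix(0, n, n)
      pin <- outer(blocks, blocks, "==")
      pr <- ifelse(pin, 0.3, 0.01)
      on <- upper.tri(a) & matrix(runif(n * n), n, n) < pr
      a[on] <- runif(sum(on), 0.4, 1)
      a <- a + t(a)
      dimnames(a) <- list(sprintf("g%03d", 1:n), sprintf("g%03d", 1:n))
      part <- cluster_modules(topological_overlap(a), cut_value = 0.95,
                              min_module_size = 5)
      ari <- adjusted_rand(part$module_id, blocks)
      if (ari >= 0.8) hits <- hits + 1
    })
  }
  expect_gte(hits, 4)
})
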