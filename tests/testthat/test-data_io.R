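# Readers/writers: expression TSV, GMT, interaction edge lists, result bundles

test_that("load_expression validates shape, collapses duplicates, drops incomplete rows", {
  p <- write_tsv_fixture(c("gene_id\ts1\ts2\ts3\ts4",
                           "g1\t1\t2\t3\t4",
                           "g2\t5\t6\t7\t8",
                           "g3\t0\t0\t1\t1"))
  m <- load_expression(p)
  expect_identical(dim(m), c(3L, 4L))
  expect_identical(rownames(m), c("g1", "g2", "g3"))
  expect_identical(colnames(m), c("s1", "s2", "s3", "s4"))

  # duplicated gene row (1,2) and (3,4) collapses to the mean (2,3)
  p2 <- write_tsv_fixture(c("gene_id\ta\tb", "g1\t1\t2", "g1\t3\t4",
                            "g2\t0\t1"))
  m2 <- suppressMessages(load_expression(p2))
  expect_equal(unname(m2["g1", ]), c(2, 3))

  # missing cell: row dropped when drop_incomplete, error otherwise
  p3 <- write_tsv_fixture(c("gene_id\ta\tb", "g1\t1\t", "g2\t0\t1"))
  m3 <- suppressMessages(load_expression(p3, drop_incomplete = TRUE))
  expect_false("g1" %in% rownames(m3))
  expect_error(load_expression(p3, drop_incomplete = FALSE),
               class = "corgnet_validation_error")

  # malformed header / too few samples
  p4 <- write_tsv_fixture(c("gene_id", "g1"))
  expect_error(load_expression(p4), class = "corgnet_format_error")
  p5 <- write_tsv_fixture(c("gene_id\ts1", "g1\t1", "g2\t2"))
  expect_error(load_expression(p5), class = "corgnet_validation_error")
})

test_that("expression write/load round-trip preserves values and order", {
  z <- mk_z(25, 6, seed = 11)
  path <- tempfile(fileext = ".tsv")
  write_expression(z, path)
  back <- load_expression(path)
  expect_identical(rownames(back), rownames(z))
  expect_identical(colnames(back), colnames(z))
  expect_lt(max(abs(back - z)), 1e-12)
})

test_that("load_gmt parses sets, enforces uniqueness, and round-trips", {
  p <- write_tsv_fixture(c("P1\tdesc\tA\tB\tC", "", "P2\tx\tB\tB\tD"),
                         ext = ".gmt")
  sets <- load_gmt(p)
  expect_identical(sets$P1, c("A", "B", "C"))
  expect_identical(sets$P2, c("B", "D"))  # repeated gene stored once

  bad <- write_tsv_fixture(c("P1\tdesc\tA", "P1\tdesc\tB"), ext = ".gmt")
  expect_error(load_gmt(bad), class = "corgnet_validation_error")
  short <- write_tsv_fixture(c("P1\tdesc\tA", "P2\tonlydesc"), ext = ".gmt")
  expect_error(load_gmt(short), "line 2", class = "corgnet_format_error")

  # property: random collections (sizes 1 .. 10000) survive a round-trip
  withr::with_seed(5, {
    pool <- sprintf("G%05d", 1:12000)
    coll <- lapply(setNames(c(1, 7, 500, 10000), paste0("S", 1:4)),
                   function(k) sample(pool, k))
    f <- tempfile(fileext = ".gmt")
    write_gmt(coll, f)
    expect_identical(load_gmt(f)[names(coll)], coll)
  })
})

test_that("load_interactions scales, deduplicates and drops self-edges", {
  p <- write_tsv_fixture(c("protein1\tprotein2\tcombined_score",
                           "A\tB\t400", "B\tA\t700", "A\tA\t900",
                           "C\tB\t950"))
  e <- suppressMessages(load_interactions(p, score_scale = "string_milli"))
  expect_identical(nrow(e), 2L)
  expect_equal(e$combined_score[e$gene_a == "A" & e$gene_b == "B"], 0.7)
  expect_equal(e$combined_score[e$gene_a == "B" & e$gene_b == "C"], 0.95)
  expect_false(any(e$gene_a == e$gene_b))

  # raw 400 on the milli scale is 0.400 on the unit scale
  p1 <- write_tsv_fixture(c("A\tB\t400"))
  expect_equal(load_interactions(p1, "string_milli")$combined_score, 0.4)

  # scores outside the declared scale are rejected
  p2 <- write_tsv_fixture(c("A\tB\t1.4"))
  expect_error(load_interactions(p2, "unit"),
               class = "corgnet_validation_error")

  # order independence: shuffled lines give the identical edge list
  withr::with_seed(9, {
    lines <- sprintf("N%d\tN%d\t%0.3f", sample(50), sample(50, 50),
                     runif(50))
    lines <- lines[!vapply(strsplit(lines, "\t"), function(f)
      f[1] == f[2], logical(1))]
    e1 <- load_interactions(write_tsv_fixture(lines), "unit")
    e2 <- load_interactions(write_tsv_fixture(sample(lines)), "unit")
    expect_identical(e1, e2)
  })
})

test_that("write_results emits headers, manifests round-trip, reruns are byte-identical", {
  d1 <- file.path(tempdir(), "res1"); d2 <- file.path(tempdir(), "res2")
  tabs <- list(
    module_ranking = data.frame(module_id = integer(), position = integer(),
                                min_member_rank = numeric()),
    scores = data.frame(pathway_id = c("a", "b"), score = c(1.5, -2)))
  man <- write_results(tabs, d1, inputs = list(expr = "x.tsv"),
                       params = list(tail_pct = 10), seed = 7L)
  lines <- readLines(file.path(d1, "module_ranking.tsv"))
  expect_identical(lines, "module_id\tposition\tmin_member_rank")
  back <- read_manifest(file.path(d1, "manifest.json"))
  expect_identical(back$params$tail_pct, 10L)
  expect_identical(back$seed, 7L)
  expect_identical(back$row_counts$scores, 2L)

  write_results(tabs, d2, inputs = list(expr = "x.tsv"),
                params = list(tail_pct = 10), seed = 7L)
  for (f in c("module_ranking.tsv", "scores.tsv", "manifest.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})
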