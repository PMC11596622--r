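test_that("de-duplication keeps the lexicographically smallest id per group", {
  m <- Matrix::sparseMatrix(i = c(1, 2, 3), j = c(1, 2, 1), x = c(1, 2, 1),
                            dims = c(3, 2),
                            dimnames = list(c("C2", "C1", "C3"), NULL))
  # C2 (row 1) and C3 (row 3) share a vector; C1 differs
  dd <- deduplicate_entities(m)
  expect_setequal(dd$kept, c("C2", "C1"))
  expect_equal(dd$removed$removed_id, "C3")
  expect_equal(dd$removed$kept_id, "C2")

  # idempotent: rerunning on the kept rows removes nothing
  dd2 <- deduplicate_entities(m[dd$kept, , drop = FALSE])
  expect_equal(nrow(dd2$removed), 0L)

  # all distinct: nothing removed
  m2 <- Matrix::sparseMatrix(i = 1:3, j = 1:3, x = 1:3, dims = c(3, 3),
                             dimnames = list(c("a", "b", "c"), NULL))
  expect_equal(nrow(deduplicate_entities(m2)$removed), 0L)

  # all-zero rows form one duplicate group too
  m3 <- Matrix::sparseMatrix(i = 1, j = 1, x = 1, dims = c(3, 2),
                             dimnames = list(c("z", "y", "x"), NULL))
  dd3 <- deduplicate_entities(m3)
  expect_setequal(dd3$kept, c("z", "x"))
  expect_equal(dd3$removed$removed_id, "y")
})

test_that("cross-join produces n_c x n_p entries labeled from annotations", {
  ds <- tiny_pair_dataset(n_c = 3, n_p = 2, positives = cbind(1, 1))
  expect_equal(n_entries(ds), 6)
  expect_equal(sum(ds$labels), 1)
  expect_equal(entry_labels(ds), c(1, 0, 0, 0, 0, 0))

  ds1 <- tiny_pair_dataset(n_c = 1, n_p = 1)
  expect_equal(n_entries(ds1), 1)

  h <- toy_hierarchy()
  cm <- Matrix::sparseMatrix(i = 1, j = 1, x = 1, dims = c(1, 1),
                             dimnames = list("c1", "f1"))
  pm0 <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(0, 1), dimnames = list(NULL, "g1"))
  expect_error(cross_join(cm, pm0, list(), h, c(c1 = 1), numeric(0)),
               "at least one")
})

test_that("entry index arithmetic is a bijection", {
  ds <- tiny_pair_dataset(n_c = 4, n_p = 3)
  ip <- entry_pairs(ds, 1:12)
  expect_equal(nrow(unique(as.data.frame(ip))), 12L)
  expect_equal(range(ip[, "i_c"]), c(1, 4))
  expect_equal(range(ip[, "i_p"]), c(1, 3))
  expect_error(entry_pairs(ds, 13), "out of range")
})

test_that("size filters shrink the dataset monotonically", {
  sd <- generate_dataset(synth_config(n_compounds = 30L, seed = 9L))
  ds <- build_pair_dataset(sd$molecules, sd$hierarchy, sd$annotations,
                           max_depth = 0)
  expect_identical(
    n_entries(filter_compounds_by_size(ds, 1)), n_entries(ds))

  counts <- vapply(1:15, function(thr)
    n_entries(filter_compounds_by_size(ds, thr)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  for (thr in c(1, 8, 15)) {
    f <- filter_compounds_by_size(ds, thr)
    expect_true(all(f$compound_sizes >= thr))
    expect_equal(n_entries(f),
                 length(f$compound_ids) * length(f$pathway_ids))
  }

  pcounts <- vapply(pathway_filter_grid()[1:10], function(thr)
    n_entries(filter_pathways_by_size(ds, thr)), numeric(1))
  expect_true(all(diff(pcounts) <= 0))

  expect_error(filter_compounds_by_size(ds, 10000), "every compound")
})

test_that("a dataset with sizes {1,3,7} keeps one compound at threshold 4", {
  ds <- tiny_pair_dataset(n_c = 3, n_p = 2)
  ds$compound_sizes <- stats::setNames(c(1, 3, 7), ds$compound_ids)
  f <- filter_compounds_by_size(ds, 4)
  expect_equal(length(f$compound_ids), 1L)
  expect_equal(unname(f$compound_sizes), 7)
})

test_that("the pathway filter grid is the documented 20-threshold sequence", {
  g <- pathway_filter_grid()
  expect_length(g, 20L)
  expect_equal(g[1], 5L)
  expect_equal(g[20], 200L)
  expect_true(all(diff(g) > 0))
  expect_equal(g, c(5L, 10L, 15L, 20L, 25L, 30L, 35L, 40L, 45L, 50L,
                    60L, 70L, 80L, 90L, 100L, 120L, 140L, 160L, 180L, 200L))
})

test_that("level filtering drops pathways but never compounds", {
  sd <- generate_dataset(synth_config(n_compounds = 25L, seed = 10L))
  ds <- build_pair_dataset(sd$molecules, sd$hierarchy, sd$annotations,
                           max_depth = 0)
  same <- filter_by_levels(ds, c("L1", "L2", "L3"))
  expect_equal(n_entries(same), n_entries(ds))
  l3 <- filter_by_levels(ds, "L3")
  expect_true(all(l3$level_of == "L3"))
  expect_equal(length(l3$compound_ids), length(ds$compound_ids))
  l23 <- filter_by_levels(ds, c("L2", "L3"))
  expect_equal(length(l23$pathway_ids),
               sum(ds$level_of %in% c("L2", "L3")))
})

test_that("stratified splits preserve the positive fraction exactly per stratum", {
  # 100 entries, 10 positives, test fraction 0.2 -> exactly 2 test positives
  ds <- tiny_pair_dataset(n_c = 20, n_p = 5,
                          positives = cbind(1:10, rep(1:5, 2)))
  expect_equal(n_entries(ds), 100)
  expect_equal(sum(ds$labels), 10)
  plan <- stratified_split(ds, 0.2, seed = 3)
  expect_equal(sum(entry_labels(ds, plan$test)), 2)
  expect_length(plan$test, 20L)
  # disjoint and covering
  expect_length(intersect(plan$train, plan$test), 0L)
  expect_setequal(c(plan$train, plan$test), 1:100)
  # deterministic given the seed, different across seeds
  plan2 <- stratified_split(ds, 0.2, seed = 3)
  expect_identical(plan$test, plan2$test)
  plan3 <- stratified_split(ds, 0.2, seed = 4)
  expect_false(identical(plan$test, plan3$test))
})

test_that("positive fraction is preserved within 0.5% across many seeds", {
  set.seed(99)
  pos <- cbind(sample(100, 60, replace = TRUE), sample(100, 60, replace = TRUE))
  ds <- tiny_pair_dataset(n_c = 100, n_p = 100, positives = pos)
  global <- sum(ds$labels) / n_entries(ds)
  for (s in 1:50) {
    plan <- stratified_split(ds, 0.1, seed = s)
    test_frac <- mean(entry_labels(ds, plan$test))
    expect_lt(abs(test_frac - global), 0.005)
  }
})

test_that("the dataset container round-trips through the directory format", {
  sd <- generate_dataset(synth_config(n_compounds = 20L, seed = 21L))
  ds <- build_pair_dataset(sd$molecules, sd$hierarchy, sd$annotations,
                           max_depth = 1)
  dir <- tempfile()
  write_pair_dataset(ds, dir)
  expect_true(all(file.exists(file.path(dir,
    c("compound_matrix.mtx", "pathway_matrix.mtx", "labels.tsv",
      "compounds.tsv", "pathways.tsv", "hierarchy.tsv", "manifest.json")))))
  back <- read_pair_dataset(dir)
  expect_equal(back$compound_ids, ds$compound_ids)
  expect_equal(back$pathway_ids, ds$pathway_ids)
  expect_equal(as.matrix(back$compound_matrix), as.matrix(ds$compound_matrix))
  expect_equal(as.matrix(back$pathway_matrix), as.matrix(ds$pathway_matrix))
  expect_equal(as.matrix(back$labels), as.matrix(ds$labels))
  expect_equal(back$level_of, ds$level_of)
  expect_equal(unname(back$pathway_sizes), unname(ds$pathway_sizes))
})

test_that("after de-duplication no two entries share features with different labels", {
  sd <- generate_dataset(synth_config(n_compounds = 40L, seed = 31L))
  ds <- build_pair_dataset(sd$molecules, sd$hierarchy, sd$annotations,
                           max_depth = 0)
  # all compound rows distinct and all pathway rows distinct implies all
  # concatenated entry vectors are distinct
  expect_equal(nrow(deduplicate_entities(ds$compound_matrix)$removed), 0L)
  expect_equal(nrow(deduplicate_entities(ds$pathway_matrix)$removed), 0L)
})
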