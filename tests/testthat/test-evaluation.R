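test_that("confusion tallies the 2x2 table and matches a naive recount", {
  cc <- confusion(c(1, 0, 1, 0), c(1, 0, 0, 1))
  expect_equal(unclass(cc), c(tp = 1, tn = 1, fp = 1, fn = 1))

  perfect <- confusion(c(1, 1, 0), c(1, 1, 0))
  expect_equal(perfect[["fp"]], 0)
  expect_equal(perfect[["fn"]], 0)

  set.seed(8)
  truth <- rbinom(1000, 1, 0.3)
  pred <- rbinom(1000, 1, 0.3)
  got <- confusion(truth, pred)
  naive <- c(tp = 0, tn = 0, fp = 0, fn = 0)
  for (i in seq_along(truth)) {
    cellkey <- if (truth[i] && pred[i]) "tp" else if (!truth[i] && !pred[i])
      "tn" else if (pred[i]) "fp" else "fn"
    naive[cellkey] <- naive[cellkey] + 1
  }
  expect_equal(unclass(got), naive)
  expect_error(confusion(c(1, 0), 1), "same length")
})

test_that("mcc reproduces hand-checkable values and handles zero marginals", {
  expect_equal(mcc(10, 10, 0, 0), 1)
  expect_equal(mcc(confusion_counts(10, 10, 0, 0)), 1)
  # undefined when a marginal is zero
  expect_true(is.na(mcc(0, 10, 0, 0)))
  expect_true(is.na(mcc(confusion(c(0, 0), c(0, 0)))))
  # balanced random-like counts give 0
  expect_equal(mcc(5, 5, 5, 5), 0)
  # large counts: log-space denominator stays exact to printed precision
  expect_equal(round(mcc(145888, 747972, 8497, 4188), 3), 0.950)
  expect_equal(round(mcc(85204, 14085671, 34729, 28996), 3), 0.726)
})

test_that("mcc symmetry: class swap preserves it, prediction negation negates it", {
  set.seed(21)
  for (i in 1:25) {
    cts <- as.numeric(sample(0:500, 4, replace = TRUE))
    m <- mcc(cts[1], cts[2], cts[3], cts[4])
    swapped <- mcc(cts[2], cts[1], cts[4], cts[3])
    negated <- mcc(cts[3], cts[4], cts[1], cts[2])  # flip all predictions
    if (is.na(m)) {
      expect_true(is.na(swapped))
    } else {
      expect_equal(swapped, m)
      expect_equal(negated, -m)
    }
  }
})

test_that("derived metrics match standard definitions and propagate NA", {
  m <- derived_metrics(confusion_counts(1, 1, 1, 1))
  expect_equal(m$accuracy, 0.5)
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 0.5)
  expect_equal(m$f1, 0.5)
  expect_equal(m$specificity, 0.5)

  no_pos_pred <- derived_metrics(confusion_counts(0, 5, 0, 2))
  expect_true(is.na(no_pos_pred$precision))
  expect_false(is.na(no_pos_pred$specificity))
})

# build a pathway_cv object directly from counts (no training involved)
fake_cv <- function(per_iteration, per_pathway, per_compound, h) {
  structure(list(per_iteration = per_iteration,
                 per_pathway = per_pathway, per_compound = per_compound,
                 level_of = stats::setNames(h$level, h$pathway_id),
                 pathway_sizes = stats::setNames(rep(10, nrow(h)), h$pathway_id),
                 compound_sizes = stats::setNames(rep(5, nrow(per_compound)),
                                                  rownames(per_compound)),
                 hierarchy = h, config = mlp_config(),
                 test_fraction = 0.1, base_seed = 1L),
            class = "pathway_cv")
}

test_that("aggregate_overall returns mean/median/sd of per-iteration metrics", {
  h <- toy_hierarchy()
  pp <- matrix(1, nrow(h), 4, dimnames = list(h$pathway_id,
                                              c("tp", "tn", "fp", "fn")))
  pc <- matrix(1, 2, 4, dimnames = list(c("c1", "c2"),
                                        c("tp", "tn", "fp", "fn")))
  # three iterations engineered to yield accuracies 0.7, 0.8, 0.9
  pi <- data.frame(iteration = 1:3, seed = 1:3,
                   tp = c(70, 80, 90), tn = c(0, 0, 0),
                   fp = c(30, 20, 10), fn = c(0, 0, 0))
  cv <- fake_cv(pi, pp, pc, h)
  agg <- aggregate_overall(cv, "accuracy")
  expect_equal(unname(agg["mean"]), 0.8)
  expect_equal(unname(agg["median"]), 0.8)
  expect_equal(unname(agg["sd"]), stats::sd(c(0.7, 0.8, 0.9)))

  # identical iterations: zero spread
  pi2 <- pi; pi2$tp <- 80; pi2$fp <- 20
  expect_equal(unname(aggregate_overall(fake_cv(pi2, pp, pc, h),
                                        "accuracy")["sd"]), 0)
})

test_that("group aggregation sums counts before deriving metrics", {
  h <- toy_hierarchy()
  set.seed(12)
  pp <- matrix(sample(0:50, nrow(h) * 4, replace = TRUE), nrow(h), 4,
               dimnames = list(h$pathway_id, c("tp", "tn", "fp", "fn")))
  pc <- matrix(sample(0:50, 8, replace = TRUE), 2, 4,
               dimnames = list(c("c1", "c2"), c("tp", "tn", "fp", "fn")))
  pi <- data.frame(iteration = 1, seed = 1, tp = sum(pp[, "tp"]),
                   tn = sum(pp[, "tn"]), fp = sum(pp[, "fp"]),
                   fn = sum(pp[, "fn"]))
  cv <- fake_cv(pi, pp, pc, h)

  # level grouping equals a brute-force regroup-and-sum oracle
  by_level <- aggregate_by_group(cv, "level")
  for (lev in c("L1", "L2", "L3")) {
    sel <- h$pathway_id[h$level == lev]
    oracle <- colSums(pp[sel, , drop = FALSE])
    row <- by_level[by_level$group == lev, ]
    expect_equal(c(row$tp, row$tn, row$fp, row$fn), unname(oracle))
    expect_equal(row$mcc, unname(mcc(oracle["tp"], oracle["tn"],
                                     oracle["fp"], oracle["fn"])))
  }

  # subtree grouping: every pathway maps to its L1 ancestor, L1s included
  by_sub <- aggregate_by_group(cv, "l1_subtree")
  expect_setequal(by_sub$group, c("r1", "r2"))
  r1_members <- c("r1", "q1", "q2", "p1", "p2", "p3", "p4")
  oracle_r1 <- colSums(pp[r1_members, ])
  expect_equal(unname(unlist(by_sub[by_sub$group == "r1",
                                    c("tp", "tn", "fp", "fn")])),
               unname(oracle_r1))

  # a singleton group equals the pathway's own metrics
  by_path <- aggregate_by_group(cv, "pathway")
  p3 <- by_path[by_path$group == "p3", ]
  expect_equal(p3$mcc, mcc(pp["p3", "tp"], pp["p3", "tn"],
                           pp["p3", "fp"], pp["p3", "fn"]))

  by_comp <- aggregate_by_group(cv, "compound")
  expect_setequal(by_comp$group, c("c1", "c2"))
})

test_that("published subtree and per-pathway rows reproduce from their counts", {
  # aggregated subtree counts -> MCC, and a full per-pathway metric row
  expect_equal(round(mcc(2775, 1034201, 585, 280), 3), 0.866)
  metab <- derived_metrics(confusion_counts(121569, 4494, 3074, 657))
  expect_equal(round(metab$mcc, 3), 0.706)
  expect_equal(round(metab$f1, 3), 0.985)
  expect_equal(round(metab$specificity, 3), 0.594)
})

test_that("size-MCC correlation matches the closed-form Pearson value", {
  # hand computation for (1,0.2), (2,0.4), (3,0.5):
  # Sxy = 0.3, Sxx = 2, Syy = 0.0466667 -> r = 0.3/sqrt(2*0.0466667)
  r_hand <- 0.3 / sqrt(2 * (0.027778 + 0.001111 + 0.017778))
  got <- size_mcc_correlation(c(a = 1, b = 2, c = 3),
                              c(a = 0.2, b = 0.4, c = 0.5))
  expect_equal(got$r, r_hand, tolerance = 1e-4)
  t_stat <- got$r * sqrt((3 - 2) / (1 - got$r^2))
  expect_equal(got$p_value, 2 * stats::pt(-abs(t_stat), df = 1),
               tolerance = 1e-10)

  perfect <- size_mcc_correlation(c(a = 1, b = 2, c = 3),
                                  c(a = 0.1, b = 0.2, c = 0.3))
  expect_equal(perfect$r, 1)

  expect_error(size_mcc_correlation(c(a = 2, b = 2, c = 2),
                                    c(a = 0.1, b = 0.2, c = 0.3)),
               "zero variance")
  # NA MCCs are excluded
  out <- size_mcc_correlation(c(a = 1, b = 2, c = 3, d = 4),
                              c(a = 0.2, b = 0.4, c = 0.5, d = NA))
  expect_equal(out$n, 3)
})

test_that("run_cv accumulates per-entity counts consistently and reproducibly", {
  sd <- generate_dataset(synth_config(n_compounds = 40L, seed = 61L))
  ds <- build_pair_dataset(sd$molecules, sd$hierarchy, sd$annotations,
                           max_depth = 0)
  cfg <- mlp_config(hidden_sizes = c(16L, 8L), max_epochs = 15L,
                    patience = 5L, seed = 5L)
  cv <- run_cv(ds, cfg, n_iterations = 2L, base_seed = 7L)
  expect_equal(nrow(cv$per_iteration), 2L)

  # conservation: per-pathway and per-compound sums equal the summed
  # per-iteration overall counts
  overall <- colSums(cv$per_iteration[, c("tp", "tn", "fp", "fn")])
  expect_equal(unname(colSums(cv$per_pathway)), unname(overall))
  expect_equal(unname(colSums(cv$per_compound)), unname(overall))

  # each iteration's counts total the test-set size
  n_test <- length(stratified_split(ds, 0.1, seed = 8L)$test)
  expect_true(all(rowSums(cv$per_iteration[, c("tp", "tn", "fp", "fn")]) ==
                    n_test))

  # determinism: identical inputs give identical results
  cv2 <- run_cv(ds, cfg, n_iterations = 2L, base_seed = 7L)
  expect_identical(cv$per_iteration, cv2$per_iteration)
  expect_identical(cv$per_pathway, cv2$per_pathway)
})

test_that("cv reports are written as parseable TSV and JSON", {
  sd <- generate_dataset(synth_config(n_compounds = 30L, seed = 71L))
  ds <- build_pair_dataset(sd$molecules, sd$hierarchy, sd$annotations,
                           max_depth = 0)
  cfg <- mlp_config(hidden_sizes = c(16L, 8L), max_epochs = 10L,
                    patience = 5L, seed = 2L)
  cv <- run_cv(ds, cfg, n_iterations = 1L, base_seed = 3L)
  dir <- tempfile()
  write_cv_reports(cv, dir)
  for (f in c("per_iteration.tsv", "per_compound_counts.tsv",
              "per_pathway_counts.tsv", "metrics_by_level.tsv",
              "metrics_by_l1_subtree.tsv", "metrics_by_pathway.tsv")) {
    expect_true(file.exists(file.path(dir, f)))
    expect_gt(nrow(utils::read.delim(file.path(dir, f))), 0)
  }
  js <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_true("overall_mcc" %in% names(js))
})
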