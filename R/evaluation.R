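#' Confusion counts
#'
#' Standard 2x2 tally of binary predictions against ground truth. Counts are
#' stored as doubles: at KEGG scale the summed true-negative counts exceed
#' the 32-bit integer range.
#'
#' @param truth,predicted Equal-length 0/1 (or logical) vectors.
#' @return Object of class `confusion_counts`: named numeric vector with
#'   elements `tp`, `tn`, `fp`, `fn`.
#' @export
confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("'truth' and 'predicted' must have the same length")
  t1 <- as.logical(truth); p1 <- as.logical(predicted)
  confusion_counts(tp = sum(t1 & p1), tn = sum(!t1 & !p1),
                   fp = sum(!t1 & p1), fn = sum(t1 & !p1))
}

#' @rdname confusion
#' @param tp,tn,fp,fn Non-negative counts.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  x <- c(tp = as.numeric(tp), tn = as.numeric(tn),
         fp = as.numeric(fp), fn = as.numeric(fn))
  if (any(x < 0)) stop("confusion counts must be non-negative")
  structure(x, class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion: TP %s  TN %s  FP %s  FN %s>\n",
              format(x[["tp"]], big.mark = ","),
              format(x[["tn"]], big.mark = ","),
              format(x[["fp"]], big.mark = ","),
              format(x[["fn"]], big.mark = ",")))
  invisible(x)
}

#' Matthews correlation coefficient
#'
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)). The four
#' marginal products can overflow naive 64-bit arithmetic at KEGG scale
#' (true negatives reach tens of millions), so the denominator is evaluated
#' in log space; the numerator's two products stay below 2^53 at these
#' scales and are exact in double precision. When any marginal is zero the
#' MCC is undefined and `NA` is returned -- an expected outcome for rarely
#' predicted pathways, reported as null rather than zero.
#'
#' @param tp A `confusion_counts` object, or the TP count.
#' @param tn,fp,fn Remaining counts when `tp` is numeric.
#' @return MCC in [-1, 1], or `NA` when undefined.
#' @export
mcc <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (inherits(tp, "confusion_counts")) {
    c_ <- tp
    tp <- c_[["tp"]]; tn <- c_[["tn"]]; fp <- c_[["fp"]]; fn <- c_[["fn"]]
  }
  tp <- unname(tp); tn <- unname(tn); fp <- unname(fp); fn <- unname(fn)
  marg <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  if (any(marg == 0)) return(NA_real_)
  num <- tp * tn - fp * fn
  if (num == 0) return(0)
  num / exp(0.5 * sum(log(marg)))
}

#' The six derived metrics
#'
#' MCC, accuracy, precision, recall, F1 and specificity from one confusion
#' matrix. A metric whose defining denominator is zero is `NA` (undefined),
#' never coerced to 0.
#'
#' @param counts A `confusion_counts` object.
#' @return Named list of class `metric_set`.
#' @export
derived_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts[["tp"]]; tn <- counts[["tn"]]
  fp <- counts[["fp"]]; fn <- counts[["fn"]]
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  structure(list(
    mcc = mcc(counts),
    accuracy = safe_div(tp + tn, tp + tn + fp + fn),
    precision = precision,
    recall = recall,
    f1 = f1,
    specificity = safe_div(tn, tn + fp)
  ), class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  vals <- vapply(x, function(v) if (is.na(v)) "NA" else sprintf("%.3f", v),
                 character(1))
  cat(paste(names(x), vals, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

.sum_counts <- function(mat) {
  # mat: n x 4 matrix with columns tp,tn,fp,fn
  confusion_counts(sum(mat[, "tp"]), sum(mat[, "tn"]),
                   sum(mat[, "fp"]), sum(mat[, "fn"]))
}

#' Repeated stratified cross-validation of the pair classifier
#'
#' Runs `n_iterations` train/test cycles. Iteration `i` draws its stratified
#' split with seed `base_seed + i`, trains a fresh MLP (the training seed is
#' also offset per iteration), and scores the held-out entries. Overall
#' confusion counts are recorded per iteration; per-compound and per-pathway
#' counts are accumulated across iterations, which keeps their metrics
#' defined even when a single iteration's test slice contains few entries for
#' an entity. Identical inputs reproduce an identical result.
#'
#' @param ds A `pair_dataset`.
#' @param cfg An [mlp_config()].
#' @param n_iterations Number of CV iterations (>= 1).
#' @param test_fraction Held-out fraction per iteration.
#' @param base_seed Integer; iteration `i` uses `base_seed + i`.
#' @param verbose Report per-iteration progress.
#' @return Object of class `pathway_cv`: `per_iteration` (data.frame with
#'   iteration, seed, tp, tn, fp, fn), `per_compound` and `per_pathway`
#'   (count matrices accumulated across iterations, rows named by id),
#'   `level_of`, `pathway_sizes`, `compound_sizes`, `hierarchy`, `config`.
#' @export
run_cv <- function(ds, cfg = mlp_config(), n_iterations = 5L,
                   test_fraction = 0.1, base_seed = 1L, verbose = FALSE) {
  stopifnot(inherits(ds, "pair_dataset"), n_iterations >= 1L)
  n_c <- length(ds$compound_ids)
  n_p <- length(ds$pathway_ids)
  per_compound <- matrix(0, n_c, 4L,
                         dimnames = list(ds$compound_ids,
                                         c("tp", "tn", "fp", "fn")))
  per_pathway <- matrix(0, n_p, 4L,
                        dimnames = list(ds$pathway_ids,
                                        c("tp", "tn", "fp", "fn")))
  per_iteration <- data.frame(iteration = integer(0), seed = integer(0),
                              tp = numeric(0), tn = numeric(0),
                              fp = numeric(0), fn = numeric(0))
  for (i in seq_len(n_iterations)) {
    seed_i <- base_seed + i
    plan <- stratified_split(ds, test_fraction, seed = seed_i, iteration = i)
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i
    model <- tryCatch(mlp_fit(ds, plan, cfg_i),
                      error = function(e)
                        stop(sprintf("CV iteration %d failed: %s", i,
                                     conditionMessage(e))))
    pred <- predict(model, ds, plan$test)
    truth <- entry_labels(ds, plan$test)
    cell <- ifelse(truth == 1,
                   ifelse(pred$labels == 1, "tp", "fn"),
                   ifelse(pred$labels == 1, "fp", "tn"))
    ip <- entry_pairs(ds, plan$test)
    for (cl in c("tp", "tn", "fp", "fn")) {
      sel <- cell == cl
      if (any(sel)) {
        tc <- tabulate(ip[sel, "i_c"], nbins = n_c)
        tpw <- tabulate(ip[sel, "i_p"], nbins = n_p)
        per_compound[, cl] <- per_compound[, cl] + tc
        per_pathway[, cl] <- per_pathway[, cl] + tpw
      }
    }
    cc <- confusion(truth, pred$labels)
    per_iteration <- rbind(per_iteration,
                           data.frame(iteration = i, seed = seed_i,
                                      tp = cc[["tp"]], tn = cc[["tn"]],
                                      fp = cc[["fp"]], fn = cc[["fn"]]))
    if (verbose)
      message(sprintf("iteration %d/%d: test MCC %.3f", i, n_iterations,
                      mcc(cc)))
  }
  structure(list(per_iteration = per_iteration,
                 per_compound = per_compound, per_pathway = per_pathway,
                 level_of = ds$level_of, pathway_sizes = ds$pathway_sizes,
                 compound_sizes = ds$compound_sizes,
                 hierarchy = ds$hierarchy, config = cfg,
                 test_fraction = test_fraction, base_seed = base_seed),
            class = "pathway_cv")
}

#' @export
print.pathway_cv <- function(x, ...) {
  m <- vapply(seq_len(nrow(x$per_iteration)), function(i)
    mcc(confusion_counts(x$per_iteration$tp[i], x$per_iteration$tn[i],
                         x$per_iteration$fp[i], x$per_iteration$fn[i])),
    numeric(1))
  cat(sprintf("<cross-validation: %d iteration(s); per-iteration MCC mean %.3f, median %.3f, sd %.4f>\n",
              nrow(x$per_iteration), mean(m, na.rm = TRUE),
              stats::median(m, na.rm = TRUE), stats::sd(m)))
  invisible(x)
}

#' @export
summary.pathway_cv <- function(object, ...) {
  lev <- aggregate_by_group(object, "level")
  cat("Per-iteration overall MCC:\n")
  print(aggregate_overall(object, "mcc"))
  cat("\nBy hierarchy level (counts summed across iterations):\n")
  print(lev, digits = 3)
  invisible(object)
}

# per-iteration metric values from the stored overall counts
.iteration_metric <- function(cv, metric) {
  vapply(seq_len(nrow(cv$per_iteration)), function(i) {
    cc <- confusion_counts(cv$per_iteration$tp[i], cv$per_iteration$tn[i],
                           cv$per_iteration$fp[i], cv$per_iteration$fn[i])
    derived_metrics(cc)[[metric]]
  }, numeric(1))
}

#' Aggregate a metric across CV iterations
#'
#' Computes the chosen metric per CV iteration from that iteration's overall
#' confusion counts and returns its mean, median, and standard deviation
#' across iterations.
#'
#' @param cv A `pathway_cv`.
#' @param metric One of `"mcc"`, `"accuracy"`, `"precision"`, `"recall"`,
#'   `"f1"`, `"specificity"`.
#' @return Named numeric vector `c(mean, median, sd)`.
#' @export
aggregate_overall <- function(cv, metric = "mcc") {
  stopifnot(inherits(cv, "pathway_cv"))
  metric <- match.arg(metric, c("mcc", "accuracy", "precision", "recall",
                                "f1", "specificity"))
  vals <- .iteration_metric(cv, metric)
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L)
    stop(sprintf("metric '%s' is undefined in every iteration", metric))
  c(mean = mean(vals), median = stats::median(vals),
    sd = if (length(vals) > 1L) stats::sd(vals) else 0)
}

#' Group-wise metrics from accumulated confusion counts
#'
#' Sums the per-entity confusion counts (accumulated across all CV
#' iterations) within each group and derives the metrics from the summed
#' counts. Groupings: `"level"` pools pathways by hierarchy level;
#' `"l1_subtree"` pools every pathway under each L1 top category, the L1
#' pathway itself included; `"pathway"` and `"compound"` return per-entity
#' rows. Metrics with a zero denominator are `NA`.
#'
#' @param cv A `pathway_cv`.
#' @param grouping One of `"level"`, `"l1_subtree"`, `"pathway"`,
#'   `"compound"`.
#' @return Data frame with one row per group: the group id, the four summed
#'   counts, and the six metrics.
#' @export
aggregate_by_group <- function(cv, grouping = c("level", "l1_subtree",
                                                "pathway", "compound")) {
  stopifnot(inherits(cv, "pathway_cv"))
  grouping <- match.arg(grouping)
  if (grouping == "compound") {
    mat <- cv$per_compound
    group <- rownames(mat)
  } else {
    mat <- cv$per_pathway
    group <- switch(grouping,
      pathway = rownames(mat),
      level = unname(cv$level_of[rownames(mat)]),
      l1_subtree = {
        h <- cv$hierarchy
        parent <- stats::setNames(h$parent_id, h$pathway_id)
        level <- stats::setNames(h$level, h$pathway_id)
        vapply(rownames(mat), function(p) {
          while (!is.na(parent[[p]])) p <- parent[[p]]
          if (level[[p]] != "L1") NA_character_ else p
        }, character(1))
      })
    if (anyNA(group)) stop("pathway with no L1 ancestor in hierarchy")
  }
  groups <- sort(unique(group), method = "radix")
  rows <- lapply(groups, function(g) {
    cc <- .sum_counts(mat[group == g, , drop = FALSE])
    m <- derived_metrics(cc)
    data.frame(group = g, tp = cc[["tp"]], tn = cc[["tn"]], fp = cc[["fp"]],
               fn = cc[["fn"]], mcc = m$mcc, accuracy = m$accuracy,
               precision = m$precision, recall = m$recall, f1 = m$f1,
               specificity = m$specificity)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson correlation between entity size and MCC
#'
#' Relates compound or pathway sizes to the per-entity MCCs accumulated over
#' CV. Entities with undefined MCC are excluded; at least three paired values
#' with nonzero variance on both sides are required. The p-value comes from
#' the two-sided t-test of the Pearson correlation.
#'
#' @param sizes Named numeric vector of entity sizes.
#' @param mccs Named numeric vector of per-entity MCCs (NA allowed).
#' @return List with `r`, `p_value`, and `n` (pairs used).
#' @export
size_mcc_correlation <- function(sizes, mccs) {
  ids <- intersect(names(sizes), names(mccs))
  x <- as.numeric(sizes[ids]); y <- as.numeric(mccs[ids])
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L)
    stop("need at least 3 paired, defined values")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Write CV reports as TSV and JSON
#'
#' Emits the per-iteration overall counts, the per-entity counts (id, tp, tn,
#' fp, fn), and the level / L1-subtree / per-L1-pathway metric tables. TSV
#' values are rounded to 3 decimal places like the published tables; the
#' JSON carries full precision.
#'
#' @param cv A `pathway_cv`.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_cv_reports <- function(cv, dir) {
  stopifnot(inherits(cv, "pathway_cv"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    num <- vapply(df, is.numeric, logical(1)) &
      !(names(df) %in% c("tp", "tn", "fp", "fn", "iteration", "seed"))
    df[num] <- lapply(df[num], round, digits = 3L)
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  w(cv$per_iteration, "per_iteration.tsv")
  w(data.frame(id = rownames(cv$per_compound), cv$per_compound),
    "per_compound_counts.tsv")
  w(data.frame(id = rownames(cv$per_pathway), cv$per_pathway),
    "per_pathway_counts.tsv")
  by_level <- aggregate_by_group(cv, "level")
  by_subtree <- aggregate_by_group(cv, "l1_subtree")
  per_pathway <- aggregate_by_group(cv, "pathway")
  w(by_level, "metrics_by_level.tsv")
  w(by_subtree, "metrics_by_l1_subtree.tsv")
  w(per_pathway, "metrics_by_pathway.tsv")
  overall_mcc <- tryCatch(as.list(aggregate_overall(cv, "mcc")),
                          error = function(e)
                            list(mean = NA, median = NA, sd = NA))
  jsonlite::write_json(
    list(overall_mcc = overall_mcc,
         by_level = by_level, by_l1_subtree = by_subtree),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
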