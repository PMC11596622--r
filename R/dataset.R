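#' De-duplicate entities by exact feature-vector equality
#'
#' Among each group of rows with exactly equal feature vectors, the
#' lexicographically smallest id is kept. Duplicate compound or pathway
#' vectors would otherwise leak between training and test sets of the
#' cross-join, because a pair seen in training would reappear in the test set
#' under another id. Idempotent.
#'
#' @param features Sparse or dense matrix with entity ids as row names.
#' @return List with `kept` (ids in original row order) and `removed`
#'   (data.frame of `removed_id`, `kept_id` pairs; zero rows if all vectors
#'   are distinct).
#' @export
deduplicate_entities <- function(features) {
  ids <- rownames(features)
  if (is.null(ids)) stop("'features' must have row names (entity ids)")
  tm <- methods::as(methods::as(features, "CsparseMatrix"), "TsparseMatrix")
  key <- rep("", nrow(features))
  if (length(tm@i)) {
    ord <- order(tm@i, tm@j)
    parts <- split(paste0(tm@j[ord], ":", tm@x[ord]), tm@i[ord])
    key[as.integer(names(parts)) + 1L] <-
      vapply(parts, paste, character(1), collapse = ";")
  }
  groups <- split(ids, key)
  removed <- data.frame(removed_id = character(0), kept_id = character(0))
  drop <- character(0)
  for (g in groups) {
    if (length(g) > 1L) {
      g_sorted <- sort(g, method = "radix")
      keep_id <- g_sorted[1L]
      removed <- rbind(removed, data.frame(removed_id = g_sorted[-1L],
                                           kept_id = keep_id))
    }
  }
  if (nrow(removed)) {
    removed <- removed[order(removed$removed_id, method = "radix"), ,
                       drop = FALSE]
    rownames(removed) <- NULL
    drop <- removed$removed_id
  }
  list(kept = ids[!(ids %in% drop)], removed = removed)
}

#' Cross-join compounds and pathways into a pair dataset
#'
#' Every compound is paired with every pathway; the binary label of a pair is
#' 1 exactly when the pathway is in the compound's expanded annotation set.
#' The dataset never materializes the concatenated feature table: it stores
#' the two count matrices separately plus a sparse label matrix, and entry
#' `k` (1-based, row-major over pathways) maps to compound
#' `(k-1) %/% n_p + 1` and pathway `(k-1) %% n_p + 1`.
#'
#' @param compound_features Sparse compound-by-color matrix (row names = ids),
#'   already de-duplicated.
#' @param pathway_features Sparse pathway-by-color matrix (row names = ids),
#'   already de-duplicated.
#' @param expanded Expanded annotation map ([propagate_annotations()]).
#' @param h A [pathway_hierarchy] covering the pathway ids.
#' @param compound_sizes Named vector of compound sizes.
#' @param pathway_sizes Named vector of pathway sizes.
#' @return A `pair_dataset`: list with `compound_matrix`, `pathway_matrix`,
#'   `compound_ids`, `pathway_ids`, `labels` (sparse n_c x n_p 0/1 matrix),
#'   `level_of` (named character), `compound_sizes`, `pathway_sizes`,
#'   `hierarchy`.
#' @export
cross_join <- function(compound_features, pathway_features, expanded, h,
                       compound_sizes, pathway_sizes) {
  stopifnot(inherits(h, "pathway_hierarchy"))
  cids <- rownames(compound_features)
  pids <- rownames(pathway_features)
  if (length(cids) == 0L || length(pids) == 0L)
    stop("cross-join requires at least one compound and one pathway")
  expanded <- expanded[names(expanded) %in% cids]
  pos_c <- rep(names(expanded), lengths(expanded))
  pos_p <- unlist(expanded, use.names = FALSE)
  in_ds <- pos_p %in% pids
  labels <- Matrix::sparseMatrix(
    i = match(pos_c[in_ds], cids),
    j = match(pos_p[in_ds], pids),
    x = 1,
    dims = c(length(cids), length(pids)),
    dimnames = list(cids, pids)
  )
  labels@x[] <- 1  # duplicate (compound, pathway) annotations collapse to 1
  level_of <- stats::setNames(h$level, h$pathway_id)[pids]
  structure(
    list(
      compound_matrix = methods::as(compound_features, "CsparseMatrix"),
      pathway_matrix = methods::as(pathway_features, "CsparseMatrix"),
      compound_ids = cids,
      pathway_ids = pids,
      labels = labels,
      level_of = level_of,
      compound_sizes = compound_sizes[cids],
      pathway_sizes = pathway_sizes[pids],
      hierarchy = h
    ),
    class = "pair_dataset"
  )
}

#' @export
print.pair_dataset <- function(x, ...) {
  cat(sprintf(
    "<pair dataset: %d compounds x %d pathways = %s entries (%s positive, %.2f%%)>\n",
    length(x$compound_ids), length(x$pathway_ids),
    format(n_entries(x), big.mark = ","),
    format(sum(x$labels), big.mark = ","),
    100 * sum(x$labels) / n_entries(x)))
  cat(sprintf("  feature dims: %d compound + %d pathway\n",
              ncol(x$compound_matrix), ncol(x$pathway_matrix)))
  invisible(x)
}

#' Number of conceptual entries in a pair dataset
#'
#' @param ds A `pair_dataset`.
#' @return `n_compounds * n_pathways` as a double (can exceed .Machine
#'   integer range at KEGG scale).
#' @export
n_entries <- function(ds) {
  as.numeric(length(ds$compound_ids)) * length(ds$pathway_ids)
}

#' Map entry indices to (compound, pathway) index pairs
#'
#' @param ds A `pair_dataset`.
#' @param k Vector of 1-based entry indices.
#' @return Two-column integer matrix with columns `i_c`, `i_p`.
#' @export
entry_pairs <- function(ds, k) {
  n_p <- length(ds$pathway_ids)
  if (any(k < 1 | k > n_entries(ds))) stop("entry index out of range")
  cbind(i_c = as.integer((k - 1) %/% n_p + 1),
        i_p = as.integer((k - 1) %% n_p + 1))
}

#' Labels of entries
#'
#' @param ds A `pair_dataset`.
#' @param k Vector of 1-based entry indices; default all entries.
#' @return Numeric 0/1 vector.
#' @export
entry_labels <- function(ds, k = seq_len(n_entries(ds))) {
  ip <- entry_pairs(ds, k)
  as.numeric(ds$labels[ip])
}

.subset_pair_dataset <- function(ds, keep_c = NULL, keep_p = NULL) {
  if (is.null(keep_c)) keep_c <- seq_along(ds$compound_ids)
  if (is.null(keep_p)) keep_p <- seq_along(ds$pathway_ids)
  ds$compound_matrix <- ds$compound_matrix[keep_c, , drop = FALSE]
  ds$pathway_matrix <- ds$pathway_matrix[keep_p, , drop = FALSE]
  ds$compound_ids <- ds$compound_ids[keep_c]
  ds$pathway_ids <- ds$pathway_ids[keep_p]
  ds$labels <- ds$labels[keep_c, keep_p, drop = FALSE]
  ds$level_of <- ds$level_of[keep_p]
  ds$compound_sizes <- ds$compound_sizes[keep_c]
  ds$pathway_sizes <- ds$pathway_sizes[keep_p]
  ds
}

#' Filter compounds by size
#'
#' Removes compounds whose number of non-hydrogen atoms is below the
#' threshold; the entry count shrinks to `n_c' * n_p`.
#'
#' @param ds A `pair_dataset`.
#' @param threshold Minimum compound size (>= 1) to keep.
#' @return Filtered `pair_dataset`.
#' @export
filter_compounds_by_size <- function(ds, threshold) {
  stopifnot(inherits(ds, "pair_dataset"), threshold >= 1)
  keep <- which(ds$compound_sizes >= threshold)
  if (length(keep) == 0L)
    stop(sprintf("compound size filter %d removes every compound", threshold))
  .subset_pair_dataset(ds, keep_c = keep)
}

#' Filter pathways by size
#'
#' Removes pathways whose size (summed member compound sizes) is below the
#' threshold.
#'
#' @inheritParams filter_compounds_by_size
#' @return Filtered `pair_dataset`.
#' @export
filter_pathways_by_size <- function(ds, threshold) {
  stopifnot(inherits(ds, "pair_dataset"), threshold >= 1)
  keep <- which(ds$pathway_sizes >= threshold)
  if (length(keep) == 0L)
    stop(sprintf("pathway size filter %d removes every pathway", threshold))
  .subset_pair_dataset(ds, keep_p = keep)
}

#' The pathway size filter grid
#'
#' Thresholds run from 5 to 50 by multiples of 5, 50 to 100 by multiples of
#' 10, and 100 to 200 by multiples of 20: twenty filters in total.
#'
#' @return Integer vector of length 20.
#' @export
pathway_filter_grid <- function() {
  as.integer(c(seq(5L, 50L, by = 5L), seq(60L, 100L, by = 10L),
               seq(120L, 200L, by = 20L)))
}

#' Restrict a pair dataset to hierarchy levels
#'
#' Keeps only pathways whose level is in `levels`; compounds are untouched.
#'
#' @param ds A `pair_dataset`.
#' @param levels Non-empty subset of `c("L1", "L2", "L3")`.
#' @return Filtered `pair_dataset`.
#' @export
filter_by_levels <- function(ds, levels) {
  stopifnot(inherits(ds, "pair_dataset"))
  levels <- match.arg(levels, c("L1", "L2", "L3"), several.ok = TRUE)
  keep <- which(ds$level_of %in% levels)
  if (length(keep) == 0L)
    stop("level filter removes every pathway")
  .subset_pair_dataset(ds, keep_p = keep)
}

#' Stratified train/test split of pair-dataset entries
#'
#' Splits the entry indices into disjoint train and test sets preserving the
#' positive/negative label proportion (stratification on the binary label
#' only). The split is at entry level, as in the cross-join evaluation
#' protocol: the same compound can occur in both sides, paired with
#' different pathways.
#'
#' @param ds A `pair_dataset`.
#' @param test_fraction Fraction of entries assigned to the test set, in
#'   (0, 1). Default 0.1.
#' @param seed Integer seed; the plan is deterministic given the seed.
#' @param iteration Optional iteration number carried along in the plan.
#' @return A `split_plan`: list with `iteration`, `seed`, `train`, `test`
#'   (1-based entry indices).
#' @export
stratified_split <- function(ds, test_fraction = 0.1, seed = 1L,
                             iteration = NA_integer_) {
  stopifnot(inherits(ds, "pair_dataset"),
            test_fraction > 0, test_fraction < 1)
  n <- n_entries(ds)
  lab <- entry_labels(ds)
  pos <- which(lab == 1)
  neg <- which(lab == 0)
  if (length(pos) == 0L || length(neg) == 0L)
    stop("stratified split needs at least one positive and one negative entry")
  n_test_pos <- round(test_fraction * length(pos))
  n_test_neg <- round(test_fraction * length(neg))
  if (n_test_pos + n_test_neg == 0L || n_test_pos + n_test_neg >= n)
    stop("test_fraction yields an empty train or test side")
  test <- local_seed(seed, {
    c(sample(pos, n_test_pos), sample(neg, n_test_neg))
  })
  test <- sort(test)
  structure(list(iteration = iteration, seed = as.integer(seed),
                 train = setdiff(seq_len(n), test), test = test),
            class = "split_plan")
}

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Write / read a pair dataset as a plain-text directory container
#'
#' The container holds the two sparse count matrices in MatrixMarket format
#' (`compound_matrix.mtx`, `pathway_matrix.mtx`), the positive pairs as a
#' two-column 0-based index TSV (`labels.tsv`), id and level tables, the
#' hierarchy, sizes, and a JSON manifest.
#'
#' @param ds A `pair_dataset`.
#' @param dir Directory to create/fill.
#' @return `read_pair_dataset()` returns a `pair_dataset` equal to the one
#'   written.
#' @export
write_pair_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "pair_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(ds$compound_matrix, file.path(dir, "compound_matrix.mtx"))
  Matrix::writeMM(ds$pathway_matrix, file.path(dir, "pathway_matrix.mtx"))
  pos <- Matrix::which(ds$labels != 0, arr.ind = TRUE)
  utils::write.table(
    data.frame(compound_index = pos[, 1] - 1L, pathway_index = pos[, 2] - 1L),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(compound_id = ds$compound_ids, size = ds$compound_sizes),
    file.path(dir, "compounds.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(pathway_id = ds$pathway_ids, level = ds$level_of,
               size = ds$pathway_sizes),
    file.path(dir, "pathways.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_hierarchy(ds$hierarchy, file.path(dir, "hierarchy.tsv"))
  writeLines(colnames(ds$compound_matrix), file.path(dir, "compound_features.txt"))
  writeLines(colnames(ds$pathway_matrix), file.path(dir, "pathway_features.txt"))
  jsonlite::write_json(
    list(n_compounds = length(ds$compound_ids),
         n_pathways = length(ds$pathway_ids),
         n_entries = n_entries(ds),
         d_compound = ncol(ds$compound_matrix),
         d_pathway = ncol(ds$pathway_matrix)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_pair_dataset
#' @export
read_pair_dataset <- function(dir) {
  cm <- methods::as(Matrix::readMM(file.path(dir, "compound_matrix.mtx")),
                    "CsparseMatrix")
  pm <- methods::as(Matrix::readMM(file.path(dir, "pathway_matrix.mtx")),
                    "CsparseMatrix")
  comp <- utils::read.delim(file.path(dir, "compounds.tsv"),
                            colClasses = c("character", "numeric"))
  path <- utils::read.delim(file.path(dir, "pathways.tsv"),
                            colClasses = c("character", "character", "numeric"))
  dimnames(cm) <- list(comp$compound_id,
                       readLines(file.path(dir, "compound_features.txt")))
  dimnames(pm) <- list(path$pathway_id,
                       readLines(file.path(dir, "pathway_features.txt")))
  lab <- utils::read.delim(file.path(dir, "labels.tsv"))
  labels <- Matrix::sparseMatrix(i = lab$compound_index + 1L,
                                 j = lab$pathway_index + 1L, x = 1,
                                 dims = c(nrow(cm), nrow(pm)),
                                 dimnames = list(comp$compound_id,
                                                 path$pathway_id))
  h <- read_hierarchy(file.path(dir, "hierarchy.tsv"))
  structure(
    list(compound_matrix = cm, pathway_matrix = pm,
         compound_ids = comp$compound_id, pathway_ids = path$pathway_id,
         labels = labels,
         level_of = stats::setNames(path$level, path$pathway_id),
         compound_sizes = stats::setNames(comp$size, comp$compound_id),
         pathway_sizes = stats::setNames(path$size, path$pathway_id),
         hierarchy = h),
    class = "pair_dataset")
}

#' Build a pair dataset from molecules, hierarchy and annotations
#'
#' End-to-end dataset construction: featurize compounds, remove duplicate
#' compound vectors, propagate annotations upward, build pathway features,
#' remove duplicate pathway vectors, cross-join, then apply size and level
#' filters (in that order).
#'
#' @param mols List of [molecule] objects (hydrogens are stripped here).
#' @param h A [pathway_hierarchy].
#' @param annotations Data frame with `compound_id`, `pathway_id` columns, or
#'   a named list as from [read_annotations()].
#' @param max_depth Coloring depth for [color_atoms()].
#' @param compound_threshold,pathway_threshold Minimum entity sizes (1 = no
#'   filtering).
#' @param levels Hierarchy levels to retain.
#' @return A `pair_dataset`, with attribute `"dedup"` holding the two
#'   de-duplication reports.
#' @export
build_pair_dataset <- function(mols, h, annotations, max_depth = "auto",
                               compound_threshold = 1L, pathway_threshold = 1L,
                               levels = c("L1", "L2", "L3")) {
  direct <- if (is.data.frame(annotations)) annotations_to_map(annotations)
            else annotations
  mols <- lapply(mols, strip_hydrogens)
  feats <- featurize_compounds(mols, max_depth = max_depth)
  dd_c <- deduplicate_entities(feats$features)
  cf <- feats$features[dd_c$kept, , drop = FALSE]
  expanded <- propagate_annotations(direct, h)
  pf <- build_pathway_features(cf, expanded, h)
  dd_p <- deduplicate_entities(pf$features)
  pm <- pf$features[dd_p$kept, , drop = FALSE]
  psize <- pathway_size(pf$members[dd_p$kept], feats$sizes)
  ds <- cross_join(cf, pm, expanded, h, feats$sizes, psize)
  if (compound_threshold > 1L)
    ds <- filter_compounds_by_size(ds, compound_threshold)
  if (pathway_threshold > 1L)
    ds <- filter_pathways_by_size(ds, pathway_threshold)
  if (!setequal(levels, c("L1", "L2", "L3")))
    ds <- filter_by_levels(ds, levels)
  attr(ds, "dedup") <- list(compounds = dd_c$removed, pathways = dd_p$removed)
  ds
}
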