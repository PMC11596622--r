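#' Three-level pathway hierarchies
#'
#' Pathways are organized on three levels: top categories (L1), subcategories
#' (L2), and individual pathways (L3). L1 nodes have no parent, every L2's
#' parent is an L1, and every L3's parent is an L2; this rules out cycles by
#' construction.
#'
#' @param nodes Data frame with columns `pathway_id`, `name`, `level` (one of
#'   `"L1"`, `"L2"`, `"L3"`), and `parent_id` (`NA` or `""` for L1 nodes).
#' @return The validated data frame with class `pathway_hierarchy`.
#' @export
pathway_hierarchy <- function(nodes) {
  nodes <- as.data.frame(nodes)
  req <- c("pathway_id", "name", "level", "parent_id")
  if (!all(req %in% names(nodes)))
    stop("hierarchy needs columns: ", paste(req, collapse = ", "))
  nodes$pathway_id <- as.character(nodes$pathway_id)
  nodes$name <- as.character(nodes$name)
  nodes$level <- as.character(nodes$level)
  nodes$parent_id <- as.character(nodes$parent_id)
  nodes$parent_id[is.na(nodes$parent_id) | nodes$parent_id == ""] <- NA_character_
  if (anyDuplicated(nodes$pathway_id))
    stop("duplicate pathway ids in hierarchy")
  if (!all(nodes$level %in% c("L1", "L2", "L3")))
    stop("hierarchy levels must be L1, L2 or L3")
  lev <- stats::setNames(nodes$level, nodes$pathway_id)
  l1 <- nodes$level == "L1"
  if (any(!is.na(nodes$parent_id[l1])))
    stop("L1 pathways must not have a parent")
  l2 <- nodes[nodes$level == "L2", ]
  if (nrow(l2) && (anyNA(l2$parent_id) || any(lev[l2$parent_id] != "L1")))
    stop("every L2 pathway must have an L1 parent")
  l3 <- nodes[nodes$level == "L3", ]
  if (nrow(l3) && (anyNA(l3$parent_id) || any(lev[l3$parent_id] != "L2")))
    stop("every L3 pathway must have an L2 parent")
  class(nodes) <- c("pathway_hierarchy", "data.frame")
  nodes
}

#' @export
print.pathway_hierarchy <- function(x, ...) {
  cat(sprintf("<pathway hierarchy: %d L1 / %d L2 / %d L3>\n",
              sum(x$level == "L1"), sum(x$level == "L2"),
              sum(x$level == "L3")))
  invisible(x)
}

#' Read / write a pathway hierarchy as TSV
#'
#' Columns: `pathway_id`, `name`, `level`, `parent_id` (empty for L1).
#'
#' @param path TSV file path.
#' @param h A `pathway_hierarchy`.
#' @return `read_hierarchy()` returns a `pathway_hierarchy`.
#' @export
read_hierarchy <- function(path) {
  pathway_hierarchy(utils::read.delim(path, colClasses = "character"))
}

#' @rdname read_hierarchy
#' @export
write_hierarchy <- function(h, path) {
  out <- as.data.frame(h)
  out$parent_id[is.na(out$parent_id)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read direct compound-pathway annotations from TSV
#'
#' Columns: `compound_id`, `pathway_id`. Returns the direct annotation map as
#' a named list of pathway-id sets.
#'
#' @param path TSV file path.
#' @return Named list: compound id -> character vector of pathway ids.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  annotations_to_map(df)
}

#' @rdname read_annotations
#' @param df Data frame with columns `compound_id` and `pathway_id`.
#' @export
annotations_to_map <- function(df) {
  lapply(split(df$pathway_id, df$compound_id), unique)
}

# parent lookup vector for a hierarchy
.parent_of <- function(h) stats::setNames(h$parent_id, h$pathway_id)

#' Propagate annotations up the hierarchy
#'
#' Compounds are usually annotated to individual (L3, sometimes L2) pathways,
#' but association holds at every ancestor level: a compound in a glycolysis
#' pathway is also associated with its carbohydrate-metabolism subcategory
#' and with the metabolism top category. This upward closure turns the direct
#' map into the expanded map used to label compound-pathway pairs.
#'
#' @param direct Named list: compound id -> character vector of directly
#'   annotated pathway ids.
#' @param h A [pathway_hierarchy].
#' @return Named list: compound id -> set of pathway ids including all
#'   hierarchy ancestors (no duplicates).
#' @export
propagate_annotations <- function(direct, h) {
  stopifnot(inherits(h, "pathway_hierarchy"))
  parent <- .parent_of(h)
  unknown <- setdiff(unique(unlist(direct, use.names = FALSE)), names(parent))
  if (length(unknown))
    stop("annotations reference unknown pathway ids: ",
         paste(unknown, collapse = ", "))
  # ancestor chain per pathway (at most 2 hops in a 3-level hierarchy)
  anc1 <- parent
  anc2 <- unname(parent[anc1]); names(anc2) <- names(parent)
  closure <- lapply(stats::setNames(names(parent), names(parent)), function(p) {
    out <- c(p, anc1[[p]], anc2[[p]])
    out[!is.na(out)]
  })
  lapply(direct, function(ps) {
    sort(unique(unlist(closure[ps], use.names = FALSE)), method = "radix")
  })
}

#' Build pathway feature vectors
#'
#' A pathway's feature vector is the element-wise sum of the count vectors of
#' the compounds associated with it (after upward propagation). The pathway
#' feature vocabulary is the compound vocabulary restricted to colors that
#' are positive in at least one pathway, which is why the pathway feature
#' dimension can be smaller than the compound feature dimension. Pathways
#' with zero member compounds are excluded with a warning.
#'
#' @param compound_features Sparse compound-by-color count matrix with
#'   compound ids as row names.
#' @param expanded Expanded annotation map from [propagate_annotations()].
#' @param h A [pathway_hierarchy].
#' @return List with `features` (sparse pathway-by-color matrix over the
#'   restricted vocabulary), `members` (named list: pathway id -> member
#'   compound ids), and `dropped` (pathway ids excluded for having no
#'   members).
#' @export
build_pathway_features <- function(compound_features, expanded, h) {
  stopifnot(inherits(h, "pathway_hierarchy"))
  cids <- rownames(compound_features)
  expanded <- expanded[names(expanded) %in% cids]
  pairs <- data.frame(
    compound = rep(names(expanded), lengths(expanded)),
    pathway = unlist(expanded, use.names = FALSE)
  )
  members <- lapply(split(pairs$compound, pairs$pathway), unique)
  dropped <- setdiff(h$pathway_id, names(members))
  if (length(dropped))
    warning(sprintf("excluding %d pathway(s) with zero member compounds: %s",
                    length(dropped),
                    paste(utils::head(dropped, 5L), collapse = ", ")))
  pids <- h$pathway_id[h$pathway_id %in% names(members)]
  members <- members[pids]
  membership <- Matrix::sparseMatrix(
    i = rep(seq_along(members), lengths(members)),
    j = match(unlist(members, use.names = FALSE), cids),
    x = 1,
    dims = c(length(members), length(cids)),
    dimnames = list(pids, cids)
  )
  feats <- membership %*% compound_features
  keep <- Matrix::colSums(feats) > 0
  feats <- methods::as(feats[, keep, drop = FALSE], "CsparseMatrix")
  list(features = feats, members = members, dropped = dropped)
}

#' Pathway size
#'
#' The size of a pathway is the total number of non-hydrogen atoms across all
#' compounds associated with it (after propagation).
#'
#' @param members Named list: pathway id -> member compound ids.
#' @param compound_sizes Named integer vector of compound sizes.
#' @return Named numeric vector of pathway sizes.
#' @export
pathway_size <- function(members, compound_sizes) {
  vapply(members, function(cs) sum(compound_sizes[cs]), numeric(1))
}
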