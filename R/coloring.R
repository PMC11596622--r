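#' Atom-coloring count features
#'
#' Atom colors are canonical strings describing an atom's element (with a
#' formal-charge suffix when nonzero) and its bonded neighborhood up to a
#' depth, in the spirit of Morgan-style iterative neighborhood refinement.
#' The depth-0 color of an atom is its element symbol (e.g. `"C"`, `"N+1"`);
#' the depth-d color is its depth-(d-1) color followed by the
#' lexicographically sorted list of `order:neighborcolor` pairs in
#' parentheses. Two atoms with isomorphic rooted neighborhoods receive
#' identical colors, so the color multiset of a molecule is invariant under
#' atom relabeling.
#'
#' `color_atoms()` returns the multiset (a character vector with repeats) of
#' every atom's color at every depth `0..D`; an atom contributes a deeper
#' color only while its color string is still changing, so a molecule whose
#' refinement has stabilized (e.g. a single atom) contributes each stable
#' color once. With `max_depth = "auto"` the depth `D` is the first depth at
#' which the partition of atoms into color classes stops refining.
#'
#' @param mol A hydrogen-stripped, non-empty [molecule].
#' @param max_depth Non-negative integer depth, or `"auto"` (default) for the
#'   partition-refinement fixpoint.
# per-atom color strings at exactly depth d (internal; used by color_atoms
# and by partition-equivalence tests)
.atom_colors <- function(mol, d) {
  n <- nrow(mol$atoms)
  ch <- mol$atoms$charge
  col <- paste0(mol$atoms$element,
                ifelse(ch > 0L, paste0("+", ch),
                       ifelse(ch < 0L, paste0("-", abs(ch)), "")))
  nbr <- vector("list", n)
  ord <- vector("list", n)
  if (nrow(mol$bonds) > 0L) {
    for (k in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$a[k]; b <- mol$bonds$b[k]; o <- mol$bonds$order[k]
      nbr[[a]] <- c(nbr[[a]], b); ord[[a]] <- c(ord[[a]], o)
      nbr[[b]] <- c(nbr[[b]], a); ord[[b]] <- c(ord[[b]], o)
    }
  }
  for (dd in seq_len(d)) {
    col <- vapply(seq_len(n), function(i) {
      if (length(nbr[[i]]) == 0L) return(col[i])
      pairs <- paste0(ord[[i]], ":", col[nbr[[i]]])
      paste0(col[i], "(", paste(sort(pairs, method = "radix"),
                                collapse = ","), ")")
    }, character(1))
  }
  col
}

#' @return Character vector: the multiset of atom colors over depths 0..D.
#' @export
color_atoms <- function(mol, max_depth = "auto") {
  stopifnot(inherits(mol, "molecule"))
  n <- nrow(mol$atoms)
  if (n == 0L) stop("empty molecule: cannot color")
  if (any(mol$atoms$element == "H"))
    stop("molecule must be hydrogen-stripped before coloring (see strip_hydrogens)")
  auto <- identical(max_depth, "auto")
  if (!auto) {
    max_depth <- as.integer(max_depth)
    if (is.na(max_depth) || max_depth < 0L)
      stop("'max_depth' must be a non-negative integer or \"auto\"")
  }
  ch <- mol$atoms$charge
  col <- paste0(mol$atoms$element,
                ifelse(ch > 0L, paste0("+", ch),
                       ifelse(ch < 0L, paste0("-", abs(ch)), "")))
  nbr <- vector("list", n)
  ord <- vector("list", n)
  if (nrow(mol$bonds) > 0L) {
    for (k in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$a[k]; b <- mol$bonds$b[k]; o <- mol$bonds$order[k]
      nbr[[a]] <- c(nbr[[a]], b); ord[[a]] <- c(ord[[a]], o)
      nbr[[b]] <- c(nbr[[b]], a); ord[[b]] <- c(ord[[b]], o)
    }
  }
  out <- col
  n_classes <- length(unique(col))
  d <- 0L
  repeat {
    if (!auto && d >= max_depth) break
    nxt <- vapply(seq_len(n), function(i) {
      if (length(nbr[[i]]) == 0L) return(col[i])
      pairs <- paste0(ord[[i]], ":", col[nbr[[i]]])
      paste0(col[i], "(", paste(sort(pairs, method = "radix"),
                                collapse = ","), ")")
    }, character(1))
    k <- length(unique(nxt))
    if (auto && k == n_classes) break   # partition stopped refining
    changed <- nxt != col
    out <- c(out, nxt[changed])
    col <- nxt
    n_classes <- k
    d <- d + 1L
  }
  out
}

#' Build the shared color vocabulary
#'
#' The vocabulary is the lexicographically sorted union of all colors seen
#' across compounds. Sorting uses byte (radix) order, so the result is
#' deterministic, locale-independent, and stable under permutation of the
#' compound order.
#'
#' @param color_multisets A list of character vectors as returned by
#'   [color_atoms()], one per compound.
#' @return Character vector of unique colors in sorted order, of class
#'   `color_vocabulary`; `match()` against it gives 1-based feature indices.
#' @export
build_vocabulary <- function(color_multisets) {
  if (length(color_multisets) == 0L)
    stop("cannot build a vocabulary from zero compounds")
  colors <- sort(unique(unlist(color_multisets, use.names = FALSE)),
                 method = "radix")
  structure(colors, class = "color_vocabulary")
}

#' @export
print.color_vocabulary <- function(x, ...) {
  cat(sprintf("<color vocabulary: %d colors>\n", length(x)))
  utils::head(unclass(x)) |> print()
  invisible(x)
}

#' Write / read a color vocabulary
#'
#' Plain-text serialization: one color per line; the line number is the
#' 1-based feature index.
#'
#' @param vocab A `color_vocabulary`.
#' @param path File path.
#' @return `read_vocabulary()` returns a `color_vocabulary`.
#' @export
write_vocabulary <- function(vocab, path) {
  writeLines(as.character(vocab), path)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  structure(readLines(path, warn = FALSE), class = "color_vocabulary")
}

#' Count colors against a vocabulary
#'
#' Converts one compound's color multiset into a sparse count vector of
#' dimension `length(vocab)`. Colors absent from the vocabulary (novel
#' compounds at inference time) are dropped with a warning.
#'
#' @param colors Character vector from [color_atoms()].
#' @param vocab A `color_vocabulary`.
#' @return A sparse numeric vector ([Matrix::sparseVector]) of counts.
#' @export
featurize <- function(colors, vocab) {
  idx <- match(colors, vocab)
  if (anyNA(idx)) {
    novel <- unique(colors[is.na(idx)])
    warning(sprintf("%d color(s) not in vocabulary were dropped: %s",
                    length(novel),
                    paste(utils::head(novel, 3L), collapse = ", ")))
    idx <- idx[!is.na(idx)]
  }
  tab <- table(idx)
  Matrix::sparseVector(x = as.numeric(tab),
                       i = as.integer(names(tab)),
                       length = length(vocab))
}

#' Featurize a set of molecules
#'
#' Colors every molecule, builds the shared vocabulary from all of them, and
#' assembles the sparse compound-by-color count matrix. Row order follows the
#' input order; the vocabulary itself does not depend on it.
#'
#' @param mols List of hydrogen-stripped [molecule] objects.
#' @param max_depth Coloring depth passed to [color_atoms()].
#' @return List with `features` (a `dgCMatrix`, rows named by compound id,
#'   columns by color), `vocabulary`, and `sizes` (named integer vector of
#'   compound sizes).
#' @export
featurize_compounds <- function(mols, max_depth = "auto") {
  if (length(mols) == 0L) stop("no molecules to featurize")
  ids <- unname(vapply(mols, function(m) m$compound_id, character(1)))
  if (anyDuplicated(ids))
    stop("duplicate compound ids among input molecules")
  multisets <- lapply(mols, color_atoms, max_depth = max_depth)
  vocab <- build_vocabulary(multisets)
  triplets <- lapply(seq_along(multisets), function(i) {
    tab <- table(match(multisets[[i]], vocab))
    list(i = rep.int(i, length(tab)),
         j = as.integer(names(tab)),
         x = as.numeric(tab))
  })
  features <- Matrix::sparseMatrix(
    i = unlist(lapply(triplets, `[[`, "i")),
    j = unlist(lapply(triplets, `[[`, "j")),
    x = unlist(lapply(triplets, `[[`, "x")),
    dims = c(length(mols), length(vocab)),
    dimnames = list(ids, as.character(vocab))
  )
  sizes <- vapply(mols, function(m) m$size, integer(1))
  names(sizes) <- ids
  list(features = features, vocabulary = vocab, sizes = sizes)
}

#' Featurize every molfile in a directory
#'
#' Reads `*.mol` files (filename stem = compound id), strips hydrogens, and
#' calls [featurize_compounds()]. Unreadable files are skipped with a
#' warning; it is an error if nothing can be read.
#'
#' @param dir Directory containing `.mol` files.
#' @param max_depth Coloring depth.
#' @return As [featurize_compounds()].
#' @export
featurize_directory <- function(dir, max_depth = "auto") {
  paths <- sort(list.files(dir, pattern = "\\.mol$", full.names = TRUE))
  if (length(paths) == 0L)
    stop(sprintf("no .mol files found in %s", dir))
  mols <- list()
  for (p in paths) {
    m <- tryCatch(strip_hydrogens(read_molfile(p)), error = function(e) {
      warning(sprintf("skipping %s: %s", basename(p), conditionMessage(e)))
      NULL
    })
    if (!is.null(m)) mols[[length(mols) + 1L]] <- m
  }
  if (length(mols) == 0L)
    stop("all molfiles failed to parse")
  featurize_compounds(mols, max_depth = max_depth)
}
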