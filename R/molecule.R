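#' Heavy-atom molecular graphs from CTAB V2000 molfiles
#'
#' A `molecule` is a light-weight chemical graph: an ordered atom list
#' (element symbol plus formal charge) and an undirected bond list with
#' integer bond orders (1, 2, 3, or 4 for aromatic bonds as written in the
#' molfile). The compound size used throughout the package is the number of
#' non-hydrogen atoms.
#'
#' @param compound_id Character scalar identifying the compound.
#' @param elements Character vector of element symbols, one per atom.
#' @param charges Integer vector of formal charges (same length as
#'   `elements`). Defaults to all zero.
#' @param bonds A three-column matrix or data.frame with 1-based atom indices
#'   `a`, `b` and integer bond `order`. May have zero rows.
#' @return An object of class `molecule` with fields `compound_id`, `atoms`
#'   (data.frame of `element`, `charge`), `bonds` (data.frame of `a`, `b`,
#'   `order`) and `size` (number of non-hydrogen atoms).
#' @export
molecule <- function(compound_id, elements, charges = NULL, bonds = NULL) {
  if (!is.character(compound_id) || length(compound_id) != 1L)
    stop("'compound_id' must be a single string")
  n <- length(elements)
  if (n == 0L)
    stop("empty molecule: a molecule must contain at least one atom")
  if (is.null(charges)) charges <- integer(n)
  if (length(charges) != n)
    stop("'charges' must have one entry per atom")
  if (is.null(bonds) || NROW(bonds) == 0L) {
    bonds <- data.frame(a = integer(0), b = integer(0), order = integer(0))
  } else {
    bonds <- as.data.frame(bonds)
    names(bonds) <- c("a", "b", "order")
    bonds$a <- as.integer(bonds$a)
    bonds$b <- as.integer(bonds$b)
    bonds$order <- as.integer(bonds$order)
  }
  if (nrow(bonds) > 0L) {
    if (any(bonds$a < 1L | bonds$a > n | bonds$b < 1L | bonds$b > n))
      stop("structural error: bond references an out-of-range atom index")
    if (any(bonds$a == bonds$b))
      stop("structural error: self-bond")
    key <- paste(pmin(bonds$a, bonds$b), pmax(bonds$a, bonds$b))
    if (anyDuplicated(key))
      stop("structural error: duplicate undirected bond")
  }
  structure(
    list(
      compound_id = compound_id,
      atoms = data.frame(element = as.character(elements),
                         charge = as.integer(charges),
                         stringsAsFactors = FALSE),
      bonds = bonds,
      size = sum(elements != "H")
    ),
    class = "molecule"
  )
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule %s: %d atoms (%d heavy), %d bonds>\n",
              x$compound_id, nrow(x$atoms), x$size, nrow(x$bonds)))
  invisible(x)
}

# Element symbol on a V2000 atom line sits in columns 32-34; fall back to the
# fourth whitespace token for writers that pad differently.
.molfile_atom_element <- function(line) {
  el <- trimws(substr(line, 32L, 34L))
  if (el == "" || !grepl("^[A-Za-z*][A-Za-z]?$", el)) {
    tok <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    el <- if (length(tok) >= 4L) tok[4L] else ""
  }
  el
}

#' Parse a CTAB V2000 molfile
#'
#' Reads one compound from molfile text into a [molecule]. Only the V2000
#' connection-table dialect is accepted; V3000 files are rejected. Formal
#' charges are taken from `M  CHG` property lines (the legacy atom-block
#' charge column is ignored, following modern molfile convention). Hydrogens
#' are kept; use [strip_hydrogens()] to obtain the heavy-atom graph.
#' Coordinates are parsed but discarded. Disconnected components (e.g.
#' salts) are retained.
#'
#' @param text Molfile content: a single string or a character vector of
#'   lines.
#' @param compound_id Identifier for the compound; defaults to the first
#'   header line (or "unnamed" if blank).
#' @return A [molecule] with hydrogens not yet removed.
#' @export
parse_molfile <- function(text, compound_id = NULL) {
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    strsplit(text, "\n", fixed = TRUE)[[1]] else as.character(text)
  if (length(lines) < 4L)
    stop("parse error: molfile has fewer than 4 lines (no counts line)")
  counts <- lines[4L]
  if (grepl("V3000", counts, fixed = TRUE))
    stop("unsupported molfile dialect: V3000 (only V2000 is accepted)")
  if (!grepl("V2000", counts, fixed = TRUE))
    stop(sprintf("parse error on counts line (line 4): 'V2000' tag missing in %s",
                 dQuote(counts)))
  natoms <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(natoms) || is.na(nbonds))
    stop(sprintf("parse error on counts line (line 4): cannot read atom/bond counts from %s",
                 dQuote(counts)))
  if (natoms == 0L)
    stop("empty molecule: counts line declares zero atoms")
  if (length(lines) < 4L + natoms + nbonds)
    stop(sprintf("parse error: counts line declares %d atoms and %d bonds but the file has only %d further lines",
                 natoms, nbonds, length(lines) - 4L))
  atom_lines <- lines[5L:(4L + natoms)]
  elements <- vapply(atom_lines, .molfile_atom_element, character(1),
                     USE.NAMES = FALSE)
  bad <- which(!grepl("^[A-Za-z*][A-Za-z]?$", elements))
  if (length(bad))
    stop(sprintf("parse error: atom block line %d (file line %d) has no element symbol; counts line may overstate the atom count",
                 bad[1L], 4L + bad[1L]))
  bonds <- NULL
  if (nbonds > 0L) {
    bond_lines <- lines[(5L + natoms):(4L + natoms + nbonds)]
    a <- suppressWarnings(as.integer(substr(bond_lines, 1L, 3L)))
    b <- suppressWarnings(as.integer(substr(bond_lines, 4L, 6L)))
    o <- suppressWarnings(as.integer(substr(bond_lines, 7L, 9L)))
    if (anyNA(a) || anyNA(b) || anyNA(o))
      stop("parse error: malformed bond block line")
    if (any(a < 1L | a > natoms | b < 1L | b > natoms))
      stop("structural error: bond references an atom index outside the atom block")
    bonds <- data.frame(a = a, b = b, order = o)
  }
  charges <- integer(natoms)
  rest <- lines[-seq_len(4L + natoms + nbonds)]
  for (ln in rest) {
    if (startsWith(ln, "M  END")) break
    if (startsWith(ln, "M  CHG")) {
      tok <- strsplit(trimws(substr(ln, 7L, nchar(ln))), "[[:space:]]+")[[1]]
      tok <- suppressWarnings(as.integer(tok))
      npairs <- tok[1L]
      if (is.na(npairs) || length(tok) < 1L + 2L * npairs)
        stop("parse error: malformed 'M  CHG' property line")
      idx <- tok[seq(2L, by = 2L, length.out = npairs)]
      val <- tok[seq(3L, by = 2L, length.out = npairs)]
      if (any(idx < 1L | idx > natoms))
        stop("structural error: 'M  CHG' references an out-of-range atom")
      charges[idx] <- val
    }
  }
  if (is.null(compound_id)) {
    compound_id <- trimws(lines[1L])
    if (compound_id == "") compound_id <- "unnamed"
  }
  molecule(compound_id, elements, charges, bonds)
}

#' Read a molfile from disk
#'
#' The filename stem (without the `.mol` extension) is used as the compound
#' identifier.
#'
#' @param path Path to a `.mol` file.
#' @return A [molecule].
#' @export
read_molfile <- function(path) {
  id <- sub("\\.mol$", "", basename(path))
  parse_molfile(readLines(path, warn = FALSE), compound_id = id)
}

#' Serialize a molecule as V2000 molfile text
#'
#' Writes a canonical re-serialization of the graph (all coordinates zero).
#' Round-trips through [parse_molfile()].
#'
#' @param mol A [molecule].
#' @return A single string of molfile text.
#' @export
write_molfile <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  n <- nrow(mol$atoms)
  m <- nrow(mol$bonds)
  header <- c(mol$compound_id, "  pathpred", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m)
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   0, 0, 0, mol$atoms$element)
  bonds <- if (m > 0L)
    sprintf("%3d%3d%3d  0", mol$bonds$a, mol$bonds$b, mol$bonds$order)
  else character(0)
  chg <- which(mol$atoms$charge != 0L)
  props <- character(0)
  while (length(chg) > 0L) {
    take <- chg[seq_len(min(8L, length(chg)))]
    props <- c(props, paste0(
      sprintf("M  CHG%3d", length(take)),
      paste0(sprintf("%4d%4d", take, mol$atoms$charge[take]), collapse = "")
    ))
    chg <- chg[-seq_len(min(8L, length(chg)))]
  }
  paste(c(header, counts, atoms, bonds, props, "M  END"), collapse = "\n")
}

#' Remove hydrogens from a molecule
#'
#' Deletes every hydrogen atom and all bonds incident to one, preserving the
#' order of the surviving atoms and remapping bond indices. Idempotent. The
#' result's `size` equals its atom count.
#'
#' @param mol A [molecule].
#' @return A hydrogen-free [molecule].
#' @export
strip_hydrogens <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  keep <- which(mol$atoms$element != "H")
  if (length(keep) == 0L)
    stop("empty molecule: all atoms are hydrogens")
  remap <- rep(NA_integer_, nrow(mol$atoms))
  remap[keep] <- seq_along(keep)
  b <- mol$bonds
  if (nrow(b) > 0L) {
    b <- b[!is.na(remap[b$a]) & !is.na(remap[b$b]), , drop = FALSE]
    b$a <- remap[b$a]
    b$b <- remap[b$b]
    rownames(b) <- NULL
  }
  molecule(mol$compound_id, mol$atoms$element[keep], mol$atoms$charge[keep], b)
}
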