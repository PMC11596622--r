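# Small hand-built molecules and hierarchies used across tests.

methane_molfile <- function() {
  paste(c(
    "methane", "  test", "",
    "  5  4  0  0  0  0  0  0  0  0999 V2000",
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            0, 0, 0, c("C", "H", "H", "H", "H")),
    "  1  2  1  0", "  1  3  1  0", "  1  4  1  0", "  1  5  1  0",
    "M  END"), collapse = "\n")
}

ethanol_heavy <- function() {
  # heavy-atom graph C1-C2-O3, explicit hydrogens absent
  molecule("ethanol", c("C", "C", "O"),
           bonds = data.frame(a = c(1, 2), b = c(2, 3), order = c(1, 1)))
}

water_molecule <- function() {
  molecule("water", c("O", "H", "H"),
           bonds = data.frame(a = c(1, 1), b = c(2, 3), order = c(1, 1)))
}

benzene_heavy <- function() {
  molecule("benzene", rep("C", 6),
           bonds = data.frame(a = 1:6, b = c(2:6, 1), order = rep(4L, 6)))
}

co2_molecule <- function() {
  molecule("co2", c("O", "C", "O"),
           bonds = data.frame(a = c(1, 2), b = c(2, 3), order = c(2, 2)))
}

toy_hierarchy <- function() {
  # 2 L1 / 3 L2 / 6 L3
  pathway_hierarchy(data.frame(
    pathway_id = c("r1", "r2", "q1", "q2", "q3", paste0("p", 1:6)),
    name = c("top 1", "top 2", "mid 1", "mid 2", "mid 3",
             paste("leaf", 1:6)),
    level = c("L1", "L1", "L2", "L2", "L2", rep("L3", 6)),
    parent_id = c(NA, NA, "r1", "r1", "r2", "q1", "q1", "q2", "q2", "q3", "q3")
  ))
}

# serialize a molecule graph for equality checks that ignore irrelevant
# representation details (bond direction, bond row order)
graph_signature <- function(mol) {
  b <- mol$bonds
  key <- paste(pmin(b$a, b$b), pmax(b$a, b$b), b$order)
  list(atoms = paste(mol$atoms$element, mol$atoms$charge),
       bonds = sort(key))
}

# small pair dataset built directly from matrices (no molecules involved)
tiny_pair_dataset <- function(n_c = 3, n_p = 2, positives = cbind(1, 1)) {
  n_leaf <- max(0, n_p - 2)
  leaves <- if (n_leaf > 0) paste0("p", seq_len(n_leaf)) else character(0)
  h <- pathway_hierarchy(data.frame(
    pathway_id = c("r1", "q1", leaves),
    name = "x",
    level = c("L1", "L2", rep("L3", n_leaf)),
    parent_id = c(NA, "r1", rep("q1", n_leaf))
  )[seq_len(n_p), , drop = FALSE])
  cids <- paste0("C", seq_len(n_c))
  pids <- h$pathway_id
  cm <- Matrix::sparseMatrix(i = seq_len(n_c), j = seq_len(n_c), x = seq_len(n_c),
                             dims = c(n_c, n_c),
                             dimnames = list(cids, paste0("f", seq_len(n_c))))
  pm <- Matrix::sparseMatrix(i = seq_len(n_p), j = seq_len(n_p), x = 1,
                             dims = c(n_p, n_p),
                             dimnames = list(pids, paste0("g", seq_len(n_p))))
  expanded <- list()
  for (r in seq_len(nrow(positives))) {
    cid <- cids[positives[r, 1]]
    expanded[[cid]] <- union(expanded[[cid]], pids[positives[r, 2]])
  }
  cross_join(cm, pm, expanded, h,
             stats::setNames(rep(5, n_c), cids),
             stats::setNames(rep(10, n_p), pids))
}
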