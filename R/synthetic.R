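#' Configuration for the synthetic KEGG-like generator
#'
#' The generator emulates the inputs of the real pipeline without any
#' download: random heavy-atom molecular graphs written as valid V2000
#' molfiles, a three-level pathway hierarchy, and direct compound-pathway
#' annotations carrying a planted, tunable signal. Compounds belong to
#' latent classes; each terminal (L3) pathway prefers one class, and a
#' compound's annotations follow its class with a strength set by
#' `class_purity`. The class signal is planted in element composition (not
#' topology), so even depth-0 atom colors separate the classes and the
#' planted signal is robust to the coloring-depth choice.
#'
#' `class_purity` is calibrated so that 0.5 means no signal at all (labels
#' independent of composition) and 1.0 means a noise-free planted signal:
#' internally a compound keeps its own class with probability
#' `2 * (class_purity - 0.5)` and otherwise draws an effective class
#' uniformly from all classes.
#'
#' @param n_compounds Number of compounds.
#' @param n_l1,n_l2,n_l3 Pathway counts per hierarchy level.
#' @param size_range Length-2 integer vector: min/max heavy atoms per
#'   molecule (sizes are sampled uniformly).
#' @param elements Element alphabet.
#' @param n_classes Number of latent compound classes; defaults to `n_l3`
#'   (one class per terminal pathway, which makes the planted labels a
#'   deterministic function of the effective class).
#' @param class_purity Signal strength in [0.5, 1].
#' @param annotation_rate Mean direct annotations per compound (>= 1). Rates
#'   above 1 add random extra annotations that are intentionally not
#'   predictable from the features, emulating multi-pathway compounds.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n_compounds = 200L, n_l1 = 4L, n_l2 = 6L,
                         n_l3 = 12L, size_range = c(4L, 25L),
                         elements = c("C", "N", "O", "S", "P"),
                         n_classes = NULL, class_purity = 1.0,
                         annotation_rate = 1, seed = 1L) {
  if (is.null(n_classes)) n_classes <- n_l3
  stopifnot(n_compounds >= 1L, n_l1 >= 1L, n_l2 >= 1L, n_l3 >= 1L,
            length(size_range) == 2L, size_range[1] >= 1L,
            size_range[2] >= size_range[1], length(elements) >= 2L,
            n_classes >= 1L, class_purity >= 0.5, class_purity <= 1,
            annotation_rate >= 1)
  if (n_classes > length(elements) * (length(elements) - 1L))
    stop("too many classes for the element alphabet: need n_classes <= ",
         length(elements) * (length(elements) - 1L))
  structure(list(n_compounds = as.integer(n_compounds),
                 n_l1 = as.integer(n_l1), n_l2 = as.integer(n_l2),
                 n_l3 = as.integer(n_l3),
                 size_range = as.integer(size_range), elements = elements,
                 n_classes = as.integer(n_classes),
                 class_purity = class_purity,
                 annotation_rate = annotation_rate, seed = as.integer(seed)),
            class = "synth_config")
}

# class k's signature element pair: a distinct (main, secondary) ordered pair
.class_pair <- function(cfg, class_id) {
  ne <- length(cfg$elements)
  pairs <- expand.grid(main = seq_len(ne), sec = seq_len(ne))
  pairs <- pairs[pairs$main != pairs$sec, , drop = FALSE]
  pairs <- pairs[order(pairs$main, pairs$sec), , drop = FALSE]
  unlist(pairs[((class_id - 1L) %% nrow(pairs)) + 1L, ])
}

# exact class composition for a molecule of k atoms: ~60% main element,
# ~30% secondary, remainder round-robin over the others; distinct across
# classes at every size >= 2, so classes are separable from depth-0 colors
.class_composition <- function(cfg, class_id, k) {
  pick <- .class_pair(cfg, class_id)
  ne <- length(cfg$elements)
  n_main <- min(ceiling(0.6 * k), k)
  n_sec <- min(ceiling(0.3 * k), k - n_main)
  counts <- integer(ne)
  counts[pick["main"]] <- n_main
  counts[pick["sec"]] <- n_sec
  rest <- k - n_main - n_sec
  if (rest > 0L) {
    others <- setdiff(seq_len(ne), pick)
    counts[others] <- counts[others] +
      tabulate(rep_len(others, rest), nbins = ne)[others]
  }
  counts
}

#' Generate one random molecule
#'
#' Draws a connected random tree over `k ~ Uniform(size_range)` heavy atoms,
#' adds up to two extra ring-closing edges, and fills in elements with the
#' latent class's exact composition (~60% signature main element, ~30%
#' signature secondary, remainder spread over the rest; atom order random),
#' so classes are separable in color space at every molecule size. Bond
#' orders are sampled from {1, 2}. Returns the graph and its V2000 molfile text; the
#' text round-trips through [parse_molfile()].
#'
#' @param cfg A [synth_config()].
#' @param class_id Latent class of the compound.
#' @param compound_id Identifier written into the molfile header.
#' @param seed Integer seed.
#' @return List with `molecule` and `molfile` (single string).
#' @export
generate_molecule <- function(cfg, class_id, compound_id = "synthetic",
                              seed = cfg$seed) {
  stopifnot(inherits(cfg, "synth_config"))
  local_seed(seed, {
    k <- sample(cfg$size_range[1]:cfg$size_range[2], 1L)
    counts <- .class_composition(cfg, class_id, k)
    elements <- sample(rep(cfg$elements, counts))  # exact composition, random order
    bonds <- NULL
    if (k > 1L) {
      parent <- vapply(2:k, function(i) sample.int(i - 1L, 1L), integer(1))
      order <- sample(c(1L, 2L), k - 1L, replace = TRUE, prob = c(0.85, 0.15))
      bonds <- data.frame(a = parent, b = 2:k, order = order)
      n_extra <- sample(0:2, 1L)
      if (n_extra > 0L && k > 3L) {
        have <- paste(pmin(bonds$a, bonds$b), pmax(bonds$a, bonds$b))
        for (tries in seq_len(10L * n_extra)) {
          if (n_extra == 0L) break
          ab <- sort(sample.int(k, 2L))
          key <- paste(ab[1], ab[2])
          if (!(key %in% have)) {
            bonds <- rbind(bonds,
                           data.frame(a = ab[1], b = ab[2], order = 1L))
            have <- c(have, key)
            n_extra <- n_extra - 1L
          }
        }
      }
    }
    mol <- molecule(compound_id, elements, bonds = bonds)
    list(molecule = mol, molfile = write_molfile(mol))
  })
}

#' Generate a random three-level pathway hierarchy
#'
#' The first `n_l1` L2 nodes are spread over distinct L1 parents (so every
#' top category has at least one child when `n_l2 >= n_l1`), the rest draw a
#' random parent; L3 nodes are attached to L2 parents the same way.
#'
#' @param cfg A [synth_config()].
#' @param seed Integer seed.
#' @return A [pathway_hierarchy].
#' @export
generate_hierarchy <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synth_config"))
  local_seed(seed, {
    l1 <- sprintf("L1_%03d", seq_len(cfg$n_l1))
    l2 <- sprintf("L2_%03d", seq_len(cfg$n_l2))
    l3 <- sprintf("L3_%03d", seq_len(cfg$n_l3))
    p2 <- c(l1[seq_len(min(cfg$n_l1, cfg$n_l2))],
            sample(l1, max(0L, cfg$n_l2 - cfg$n_l1), replace = TRUE))
    p3 <- c(l2[seq_len(min(cfg$n_l2, cfg$n_l3))],
            sample(l2, max(0L, cfg$n_l3 - cfg$n_l2), replace = TRUE))
    pathway_hierarchy(data.frame(
      pathway_id = c(l1, l2, l3),
      name = c(paste("Top category", seq_along(l1)),
               paste("Subcategory", seq_along(l2)),
               paste("Pathway", seq_along(l3))),
      level = c(rep("L1", cfg$n_l1), rep("L2", cfg$n_l2),
                rep("L3", cfg$n_l3)),
      parent_id = c(rep(NA_character_, cfg$n_l1), p2[seq_len(cfg$n_l2)],
                    p3[seq_len(cfg$n_l3)])
    ))
  })
}

#' Generate direct annotations with a planted class signal
#'
#' Each L3 pathway prefers one latent class (round robin). Every compound
#' draws an effective class -- its own with probability
#' `2 * (class_purity - 0.5)`, otherwise uniform over all classes -- and is
#' annotated to the L3 pathway(s) preferring that effective class. With one
#' class per L3 (the default), the resulting labels are a deterministic
#' function of the effective class. With probability 0.1 the parent L2 is
#' also annotated directly (redundant after propagation, but it exercises the
#' direct-L2 code path found in real annotation tables). When
#' `annotation_rate > 1`, additional `Poisson(annotation_rate - 1)` random L3
#' annotations are planted per compound; these are noise by construction.
#'
#' @param cfg A [synth_config()].
#' @param h A [pathway_hierarchy] from [generate_hierarchy()].
#' @param classes Integer vector of true class per compound, named by
#'   compound id.
#' @param seed Integer seed.
#' @return Data frame with columns `compound_id`, `pathway_id` (direct
#'   annotations).
#' @export
generate_annotations <- function(cfg, h, classes, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synth_config"), inherits(h, "pathway_hierarchy"))
  l3 <- h$pathway_id[h$level == "L3"]
  parent <- stats::setNames(h$parent_id, h$pathway_id)
  pref_class <- rep_len(seq_len(cfg$n_classes), length(l3))  # pathway -> class
  s <- 2 * (cfg$class_purity - 0.5)
  local_seed(seed, {
    rows <- lapply(names(classes), function(cid) {
      eff <- if (stats::runif(1) < s) classes[[cid]]
             else sample.int(cfg$n_classes, 1L)
      ps <- l3[pref_class == eff]
      if (length(ps) == 0L) ps <- sample(l3, 1L)
      extra <- integer(0)
      if (cfg$annotation_rate > 1) {
        m <- stats::rpois(1L, cfg$annotation_rate - 1)
        if (m > 0L) extra <- sample(seq_along(l3), min(m, length(l3)))
      }
      ann <- unique(c(ps, l3[extra]))
      if (stats::runif(1) < 0.1) ann <- c(ann, parent[[ps[1L]]])
      data.frame(compound_id = cid, pathway_id = ann)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate a complete synthetic dataset
#'
#' Produces molecules (with molfile text), a hierarchy, latent classes, and
#' direct annotations, optionally writing them to a directory in the layout
#' the pipeline reads: `molfiles/*.mol`, `hierarchy.tsv`, `annotations.tsv`,
#' and `manifest.json` echoing the configuration and seed.
#'
#' @param cfg A [synth_config()].
#' @param dir Optional output directory.
#' @return List with `molecules`, `molfiles` (named character), `hierarchy`,
#'   `annotations`, `classes`, `config`.
#' @export
generate_dataset <- function(cfg = synth_config(), dir = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  ids <- sprintf("C%05d", seq_len(cfg$n_compounds))
  classes <- stats::setNames(rep_len(seq_len(cfg$n_classes), cfg$n_compounds),
                             ids)
  mols <- vector("list", cfg$n_compounds)
  molfiles <- character(cfg$n_compounds)
  for (i in seq_len(cfg$n_compounds)) {
    seed_i <- as.integer((as.numeric(cfg$seed) * 1009 + i) %%
                           .Machine$integer.max)
    g <- generate_molecule(cfg, classes[[i]], compound_id = ids[i],
                           seed = seed_i)
    mols[[i]] <- g$molecule
    molfiles[i] <- g$molfile
  }
  names(mols) <- ids
  names(molfiles) <- ids
  h <- generate_hierarchy(cfg, seed = cfg$seed)
  ann <- generate_annotations(cfg, h, classes, seed = cfg$seed + 1L)
  if (!is.null(dir)) {
    dir.create(file.path(dir, "molfiles"), showWarnings = FALSE,
               recursive = TRUE)
    for (i in seq_along(ids))
      writeLines(molfiles[i], file.path(dir, "molfiles",
                                        paste0(ids[i], ".mol")))
    write_hierarchy(h, file.path(dir, "hierarchy.tsv"))
    utils::write.table(ann, file.path(dir, "annotations.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(unclass(cfg), file.path(dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  list(molecules = mols, molfiles = molfiles, hierarchy = h,
       annotations = ann, classes = classes, config = cfg)
}
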