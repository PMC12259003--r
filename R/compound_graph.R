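# Compound hop-graph construction: heavy-atom nodes featurised by element and
# attached-hydrogen count, edges between all atom pairs within 3 covalent
# bonds, labelled by hop distance.

#' Element vocabulary for atom featurisation
#'
#' Fixed ordered vocabulary of atomic species used to one-hot encode nodes.
#' Species outside the list map to `"other"` (with a warning at graph build
#' time).
#'
#' @return Character vector of species codes.
#' @export
element_vocabulary <- function() {
  c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B", "other")
}

#' @noRd
H_COUNT_MAX <- 4L

element_index <- function(elements, warn_unknown = TRUE) {
  vocab <- element_vocabulary()
  idx <- match(elements, vocab)
  unknown <- is.na(idx)
  if (any(unknown)) {
    if (warn_unknown) {
      warning(sprintf(
        "element(s) outside vocabulary mapped to 'other': %s (vocabulary: %s)",
        paste(unique(elements[unknown]), collapse = ", "),
        paste(vocab, collapse = ", ")), call. = FALSE)
    }
    idx[unknown] <- match("other", vocab)
  }
  idx
}

#' One-hot node feature matrix for a molecule or pocket graph
#'
#' Concatenates a one-hot over the element vocabulary with (for compound
#' graphs) a one-hot over the attached-hydrogen count, clamped at 4.
#'
#' @param elements character vector of species codes.
#' @param h_counts optional integer vector of attached-hydrogen counts.
#' @return numeric matrix, one row per atom.
#' @export
node_features <- function(elements, h_counts = NULL) {
  vocab <- element_vocabulary()
  n <- length(elements)
  fe <- matrix(0, n, length(vocab))
  fe[cbind(seq_len(n), element_index(elements, warn_unknown = FALSE))] <- 1
  if (is.null(h_counts)) return(fe)
  h <- pmin(pmax(as.integer(h_counts), 0L), H_COUNT_MAX)
  fh <- matrix(0, n, H_COUNT_MAX + 1L)
  fh[cbind(seq_len(n), h + 1L)] <- 1
  cbind(fe, fh)
}

#' Exact bond-hop distance between two atoms (BFS oracle)
#'
#' Breadth-first search over the covalent (1-hop) bond graph. Serves as the
#' independent oracle for `hop_class` labels.
#'
#' @param bonds two-column matrix of covalent bonds (node index pairs).
#' @param i,j node indices (i != j).
#' @param n_nodes total number of nodes; inferred from `bonds` if missing.
#' @return integer hop distance, or `Inf` if i and j are disconnected.
#' @export
bond_hop_oracle <- function(bonds, i, j, n_nodes = max(bonds)) {
  i <- as.integer(i); j <- as.integer(j)
  if (i == j) stop("bond_hop_oracle: i and j must differ")
  if (i < 1L || j < 1L || i > n_nodes || j > n_nodes) {
    stop(sprintf("bond_hop_oracle: index out of range (n_nodes = %d)", n_nodes))
  }
  adj <- vector("list", n_nodes)
  if (nrow(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      a <- bonds[r, 1L]; b <- bonds[r, 2L]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  dist <- rep(NA_integer_, n_nodes)
  dist[i] <- 0L
  frontier <- i
  while (length(frontier)) {
    nxt <- integer(0)
    for (u in frontier) {
      for (v in adj[[u]]) {
        if (is.na(dist[v])) {
          dist[v] <- dist[u] + 1L
          nxt <- c(nxt, v)
        }
      }
    }
    if (!is.na(dist[j])) return(dist[j])
    frontier <- nxt
  }
  Inf
}

# All unordered pairs within max_hops bonds, with their hop distance.
# Vectorised multi-source BFS via boolean adjacency powers.
hop_edges <- function(bonds, n_nodes, max_hops = 3L) {
  if (n_nodes < 2L || nrow(bonds) == 0L) {
    return(data.frame(i = integer(0), j = integer(0), hop = integer(0)))
  }
  A <- matrix(FALSE, n_nodes, n_nodes)
  A[as.matrix(bonds)] <- TRUE
  A[as.matrix(bonds)[, 2:1, drop = FALSE]] <- TRUE
  reach <- A
  hop <- matrix(NA_integer_, n_nodes, n_nodes)
  hop[A] <- 1L
  cur <- A
  for (h in seq_len(max_hops - 1L) + 1L) {
    cur <- (cur %*% A) > 0
    new <- cur & !reach & !diag(TRUE, n_nodes)
    hop[new] <- h
    reach <- reach | cur
  }
  idx <- which(!is.na(hop) & upper.tri(hop), arr.ind = TRUE)
  o <- order(idx[, 1L], idx[, 2L])
  data.frame(i = idx[o, 1L], j = idx[o, 2L], hop = hop[idx][o])
}

new_molecule_graph <- function(mol_id, elements, h_counts, bonds,
                               coords = NULL) {
  n <- length(elements)
  eh <- hop_edges(bonds, n)
  g <- list(
    mol_id = mol_id,
    elements = elements,
    h_counts = as.integer(h_counts),
    edges = cbind(i = eh$i, j = eh$j),
    hop_class = as.integer(eh$hop),
    bonds = as.matrix(bonds),
    coords = coords,
    n_nodes = n
  )
  class(g) <- "MoleculeGraph"
  g
}

#' @export
print.MoleculeGraph <- function(x, ...) {
  cat(sprintf("MoleculeGraph '%s': %d heavy atoms, %d hop edges (%s)%s\n",
              x$mol_id, x$n_nodes, nrow(x$edges),
              paste(sprintf("%d-hop: %d", 1:3,
                            tabulate(x$hop_class, 3L)), collapse = ", "),
              if (is.null(x$coords)) "" else ", with 3D coords"))
  invisible(x)
}

# Parse a V2000 molblock (possibly with explicit hydrogens) into heavy-atom
# elements, H counts, heavy-heavy bonds and coordinates.
parse_molblock <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  counts <- lines[4L]
  n_atoms <- as.integer(substr(counts, 1L, 3L))
  n_bonds <- as.integer(substr(counts, 4L, 6L))
  if (is.na(n_atoms) || is.na(n_bonds)) stop("malformed molblock counts line")
  at <- lines[4L + seq_len(n_atoms)]
  xyz <- cbind(as.numeric(substr(at, 1L, 10L)),
               as.numeric(substr(at, 11L, 20L)),
               as.numeric(substr(at, 21L, 30L)))
  elem <- trimws(substr(at, 31L, 33L))
  bd <- lines[4L + n_atoms + seq_len(n_bonds)]
  bonds <- cbind(as.integer(substr(bd, 1L, 3L)),
                 as.integer(substr(bd, 4L, 6L)))
  heavy <- elem != "H"
  hidx <- which(!heavy)
  h_counts <- integer(sum(heavy))
  remap <- cumsum(heavy)
  keep <- heavy[bonds[, 1L]] & heavy[bonds[, 2L]]
  if (length(hidx) && nrow(bonds)) {
    hb <- bonds[xor(heavy[bonds[, 1L]], heavy[bonds[, 2L]]), , drop = FALSE]
    if (nrow(hb)) {
      heavy_end <- ifelse(heavy[hb[, 1L]], hb[, 1L], hb[, 2L])
      tab <- table(remap[heavy_end])
      h_counts[as.integer(names(tab))] <- as.integer(tab)
    }
  }
  list(elements = elem[heavy],
       h_counts = h_counts,
       bonds = matrix(remap[bonds[keep, , drop = FALSE]], ncol = 2L),
       coords = xyz[heavy, , drop = FALSE])
}

#' Build the hop graph of a small molecule from a SMILES string
#'
#' Heavy atoms become nodes with (element, attached-H count) one-hot features;
#' edges connect every atom pair within 3 covalent bonds, labelled 1-, 2- or
#' 3-hop. Bond order and aromaticity are deliberately ignored for hop
#' counting. Node order follows the parser's canonical atom order and the
#' construction is deterministic.
#'
#' @param smiles a single SMILES string.
#' @param mol_id identifier stored on the graph.
#' @return a `MoleculeGraph`.
#' @examples
#' \donttest{
#' g <- build_compound_graph("CCO", "ethanol")
#' g$h_counts   # 3 2 1
#' }
#' @export
build_compound_graph <- function(smiles, mol_id = smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  mol <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(
      "SMI", "SDF", paste0(smiles, " ", mol_id, "\n"),
      options = data.frame(names = "h", args = ""))),
    error = function(e) NULL)
  if (is.null(mol) || !nzchar(mol) || !grepl("V2000", mol, fixed = TRUE)) {
    stop(sprintf("could not parse SMILES: '%s'", smiles), call. = FALSE)
  }
  p <- parse_molblock(mol)
  if (length(p$elements) < 1L) {
    stop(sprintf("could not parse SMILES: '%s' (no heavy atoms)", smiles),
         call. = FALSE)
  }
  unk <- setdiff(unique(p$elements), element_vocabulary())
  if (length(unk)) {
    warning(sprintf(
      "'%s': element(s) %s outside vocabulary (%s); mapped to 'other'",
      mol_id, paste(unk, collapse = ", "),
      paste(element_vocabulary(), collapse = ", ")), call. = FALSE)
  }
  new_molecule_graph(mol_id, p$elements, p$h_counts, p$bonds, coords = NULL)
}

#' Validate the structural invariants of a MoleculeGraph
#'
#' Checks hop labels against the BFS oracle, symmetry-by-construction (each
#' unordered pair stored once, i < j), absence of self-edges, and that no
#' pair within 3 bonds is missing.
#'
#' @param g a `MoleculeGraph`.
#' @return `TRUE` invisibly; stops on violation.
#' @export
validate_molecule_graph <- function(g) {
  stopifnot(inherits(g, "MoleculeGraph"))
  if (nrow(g$edges)) {
    stopifnot(all(g$edges[, 1L] < g$edges[, 2L]))
    oracle <- mapply(function(i, j) bond_hop_oracle(g$bonds, i, j, g$n_nodes),
                     g$edges[, 1L], g$edges[, 2L])
    stopifnot(all(oracle == g$hop_class))
  }
  if (g$n_nodes >= 2L) {
    for (i in seq_len(g$n_nodes - 1L)) {
      for (j in seq.int(i + 1L, g$n_nodes)) {
        d <- bond_hop_oracle(g$bonds, i, j, g$n_nodes)
        present <- any(g$edges[, 1L] == i & g$edges[, 2L] == j)
        stopifnot((is.finite(d) && d <= 3L) == present)
      }
    }
  }
  invisible(TRUE)
}
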