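# Pocket graph construction. Given a protein heavy-atom point cloud and a
# pocket specification (bound ligand or centroid), select the pocket surface
# atoms S and assemble the three-tier neighbourhood graph:
#   E1: each surface atom to its x nearest surface atoms,
#   E2: each surface atom to its y nearest protein atoms (any atom),
#   E3: each tier-2 neighbour to its z nearest protein atoms.
# The final graph is the union E1 u E2 u E3; its node set is every atom
# touched by an edge. Inter-atomic distances are the sole geometric feature
# passed on to the encoder.

cross_dist <- function(a, b) {
  # pairwise Euclidean distances, rows of a vs rows of b
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Select pocket surface atoms near a bound ligand
#'
#' A protein atom belongs to the pocket surface S when its distance to the
#' nearest ligand atom is at most `cutoff` (closed threshold).
#'
#' @param protein n x 3 matrix of protein heavy-atom coordinates (Angstrom).
#' @param ligand m x 3 matrix of ligand heavy-atom coordinates.
#' @param cutoff interaction distance in Angstrom (default 4).
#' @return sorted integer vector of protein atom indices.
#' @export
select_surface_atoms <- function(protein, ligand, cutoff = 4.0) {
  stopifnot(nrow(protein) > 0, nrow(ligand) > 0, cutoff > 0)
  dmin <- apply(cross_dist(as.matrix(protein), as.matrix(ligand)), 1L, min)
  S <- which(dmin <= cutoff)
  if (!length(S)) {
    stop("no pocket surface found: no protein atom within ",
         cutoff, " Angstrom of the ligand (check pocket specification)",
         call. = FALSE)
  }
  S
}

#' Select pocket surface atoms around a 3D centroid
#'
#' @param protein n x 3 coordinate matrix.
#' @param center length-3 centroid.
#' @param shell shell radius in Angstrom.
#' @return sorted integer vector of protein atom indices.
#' @export
select_surface_by_center <- function(protein, center, shell = 8.0) {
  stopifnot(length(center) == 3L, shell > 0)
  d <- sqrt(colSums((t(as.matrix(protein)) - as.numeric(center))^2))
  S <- which(d <= shell)
  if (!length(S)) {
    stop("no pocket surface found: no protein atom within ", shell,
         " Angstrom of the given centre", call. = FALSE)
  }
  S
}

#' Randomised pocket centering from a known bound ligand
#'
#' Perturbs the ligand's geometric centre by a uniform random offset inside a
#' ball of the given radius, then selects surface atoms within a shell of the
#' perturbed centroid. Used during training to avoid over-dependence on exact
#' pocket-centre knowledge.
#'
#' @param protein n x 3 coordinate matrix.
#' @param known_ligand m x 3 coordinate matrix of the reference ligand.
#' @param radius maximal centroid offset in Angstrom.
#' @param seed integer seed; the same seed reproduces the same centroid.
#' @param shell surface-shell radius in Angstrom (default 8).
#' @return list with `center` (length-3) and `surface` (index vector).
#' @export
random_center_pocket <- function(protein, known_ligand, radius, seed,
                                 shell = 8.0) {
  stopifnot(radius >= 0)
  centroid <- colMeans(as.matrix(known_ligand))
  offset <- c(0, 0, 0)
  if (radius > 0) {
    rng <- local_rng(seed)
    repeat {
      offset <- rng$runif(3L, -radius, radius)
      if (sum(offset^2) <= radius^2) break
    }
  }
  center <- centroid + offset
  list(center = as.numeric(center),
       surface = select_surface_by_center(protein, center, shell))
}

# k nearest rows of 'pool' (coordinates) to each row of 'query'; the query
# atom itself (same index in the protein cloud) is excluded. Ties broken by
# ascending atom index.
knn_indices <- function(query_idx, pool_idx, coords, k) {
  D <- cross_dist(coords[query_idx, , drop = FALSE],
                  coords[pool_idx, , drop = FALSE])
  out <- vector("list", length(query_idx))
  for (r in seq_along(query_idx)) {
    d <- D[r, ]
    d[pool_idx == query_idx[r]] <- Inf
    ord <- order(d, pool_idx)
    out[[r]] <- pool_idx[ord[seq_len(min(k, sum(is.finite(d))))]]
  }
  out
}

#' Build the three-tier pocket graph
#'
#' @param protein n x 3 coordinate matrix of protein heavy atoms.
#' @param elements character vector of atomic species, length n.
#' @param S integer vector of surface atom indices.
#' @param x,y,z neighbourhood sizes for tiers E1 (surface-surface),
#'   E2 (surface-any) and E3 (tier-2 fan-out). Defaults 8, 4, 4.
#' @param pocket_id identifier stored on the graph.
#' @return a `PocketGraph` with fields `coords`, `elements`, `surface_mask`,
#'   `edges` (two-column, node indices local to the graph), `edge_tier`
#'   (1, 2, 3; the lowest tier that produced the edge), `edge_dist`
#'   (Angstrom) and `atom_index` (original protein atom indices).
#' @export
build_pocket_graph <- function(protein, elements, S, x = 8L, y = 4L, z = 4L,
                               pocket_id = "pocket") {
  protein <- as.matrix(protein)
  S <- sort(unique(as.integer(S)))
  stopifnot(x >= 1L, y >= 1L, z >= 1L)
  if (length(S) <= x) {
    stop(sprintf(
      "pocket surface has %d atoms but x = %d nearest surface neighbours were requested; reduce x or enlarge the pocket",
      length(S), x), call. = FALSE)
  }
  all_idx <- seq_len(nrow(protein))

  e1n <- knn_indices(S, S, protein, x)
  E1 <- cbind(rep(S, lengths(e1n)), unlist(e1n))

  e2n <- knn_indices(S, all_idx, protein, y)
  E2 <- cbind(rep(S, lengths(e2n)), unlist(e2n))

  t2 <- sort(unique(unlist(e2n)))
  e3n <- knn_indices(t2, all_idx, protein, z)
  E3 <- cbind(rep(t2, lengths(e3n)), unlist(e3n))

  # collapse to unordered pairs, tier = lowest tier producing the edge
  tier_of <- function(E, t) {
    if (!nrow(E)) return(NULL)
    key <- paste(pmin(E[, 1L], E[, 2L]), pmax(E[, 1L], E[, 2L]))
    data.frame(a = pmin(E[, 1L], E[, 2L]), b = pmax(E[, 1L], E[, 2L]),
               tier = t, key = key)
  }
  ed <- rbind(tier_of(E1, 1L), tier_of(E2, 2L), tier_of(E3, 3L))
  ed <- ed[order(ed$key, ed$tier), ]
  ed <- ed[!duplicated(ed$key), ]
  ed <- ed[order(ed$a, ed$b), ]

  nodes <- sort(unique(c(ed$a, ed$b)))
  local <- match(seq_len(nrow(protein)), nodes)
  edges <- cbind(i = local[ed$a], j = local[ed$b])
  dist <- sqrt(rowSums((protein[ed$a, , drop = FALSE] -
                          protein[ed$b, , drop = FALSE])^2))
  g <- list(
    pocket_id = pocket_id,
    atom_index = nodes,
    elements = elements[nodes],
    coords = protein[nodes, , drop = FALSE],
    surface_mask = nodes %in% S,
    edges = edges,
    edge_tier = as.integer(ed$tier),
    edge_dist = dist,
    n_nodes = length(nodes),
    knn = list(x = as.integer(x), y = as.integer(y), z = as.integer(z))
  )
  class(g) <- "PocketGraph"
  g
}

#' @export
print.PocketGraph <- function(x, ...) {
  cat(sprintf(
    "PocketGraph '%s': %d atoms (%d surface), %d edges (E1 %d, E2 %d, E3 %d)\n",
    x$pocket_id, x$n_nodes, sum(x$surface_mask), nrow(x$edges),
    sum(x$edge_tier == 1L), sum(x$edge_tier == 2L), sum(x$edge_tier == 3L)))
  invisible(x)
}

#' Validate the structural invariants of a PocketGraph
#'
#' Every node is touched by at least one edge, no self-edges, and stored edge
#' distances agree with distances recomputed from coordinates to 1e-6 A.
#'
#' @param g a `PocketGraph`.
#' @return `TRUE` invisibly; stops on violation.
#' @export
validate_pocket_graph <- function(g) {
  stopifnot(inherits(g, "PocketGraph"))
  stopifnot(all(seq_len(g$n_nodes) %in% c(g$edges[, 1L], g$edges[, 2L])))
  stopifnot(all(g$edges[, 1L] != g$edges[, 2L]))
  d <- sqrt(rowSums((g$coords[g$edges[, 1L], , drop = FALSE] -
                       g$coords[g$edges[, 2L], , drop = FALSE])^2))
  stopifnot(max(abs(d - g$edge_dist)) < 1e-6)
  invisible(TRUE)
}
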