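# Synthetic protein-ligand complexes with planted atomic complementarity.
#
# A SyntheticWorld fixes T latent atom types and a compatibility permutation
# on them: a ligand atom of latent type tau "binds" pocket atoms of type
# compatibility(tau). Each complex restricts its ligand to a subset of the
# types; every ligand atom is placed within contact distance (2.5-4 A) of a
# pocket partner atom of the compatible type, with filler pocket atoms on a
# hemispherical shell kept > 4 A away. Latent types surface through the
# element vocabulary (type tau -> a designated element), corrupted with
# probability feature_noise, so the real featurisers and encoders are
# exercised unmodified. Screening libraries pair "actives" (compounds drawn
# from a pocket's compatible type subset) with "decoys" (shuffled type
# compositions); a trained model should rank actives above decoys, a random
# model should not (EF ~ 1).

#' Define a synthetic world of latent atom types
#'
#' @param n_types number of latent types T (>= 2); each maps to one element
#'   of the vocabulary.
#' @param feature_noise probability that an atom's observed element is
#'   random instead of its type's designated element (in [0, 0.5)).
#' @param seed seed fixing the compatibility permutation.
#' @param shell_radius pocket-shell radius in Angstrom.
#' @param contact_range planted pocket-ligand contact distance range (A).
#' @param types_per_pocket how many ligand types a single complex uses.
#' @param lib_atom_range heavy-atom count range for library compounds.
#' @return a `SyntheticWorld`.
#' @export
synthetic_world <- function(n_types = 4L, feature_noise = 0.1, seed = 1L,
                            shell_radius = 6.0, contact_range = c(2.5, 4.0),
                            types_per_pocket = max(1L, n_types %/% 2L),
                            lib_atom_range = c(8L, 14L)) {
  stopifnot(n_types >= 2L, feature_noise >= 0, feature_noise < 0.5,
            n_types <= 10L, types_per_pocket >= 1L,
            types_per_pocket <= n_types, lib_atom_range[1L] >= 4L)
  compat <- with_seed(seed, sample.int(n_types))
  w <- list(n_types = as.integer(n_types),
            compatibility = as.integer(compat),
            feature_noise = feature_noise,
            seed = as.integer(seed),
            shell_radius = shell_radius,
            contact_range = contact_range,
            types_per_pocket = as.integer(types_per_pocket),
            lib_atom_range = as.integer(lib_atom_range),
            type_elements = element_vocabulary()[seq_len(n_types)])
  class(w) <- "SyntheticWorld"
  w
}

#' @export
print.SyntheticWorld <- function(x, ...) {
  cat(sprintf(
    "SyntheticWorld: %d types (%s), compatibility %s, noise %.2f\n",
    x$n_types, paste(x$type_elements, collapse = ","),
    paste(x$compatibility, collapse = ","), x$feature_noise))
  invisible(x)
}

observe_elements <- function(world, types) {
  n <- length(types)
  flip <- stats::runif(n) < world$feature_noise
  el <- world$type_elements[types]
  el[flip] <- world$type_elements[sample.int(world$n_types, sum(flip),
                                             replace = TRUE)]
  el
}

random_unit <- function(n = 1L) {
  v <- matrix(stats::rnorm(3L * n), n, 3L)
  v / sqrt(rowSums(v^2))
}

# Random connected molecule: a spanning tree plus (sometimes) one extra
# cycle-closing edge, grown in 3D with ~1.5 A bond lengths.
random_molecule_geometry <- function(n_atoms) {
  coords <- matrix(0, n_atoms, 3L)
  bonds <- matrix(integer(0), 0L, 2L)
  for (i in seq_len(n_atoms)[-1L]) {
    parent <- sample.int(i - 1L, 1L)
    repeat {
      pos <- coords[parent, ] + 1.5 * as.numeric(random_unit())
      if (sqrt(sum(pos^2)) <= 3.5) break
    }
    coords[i, ] <- pos
    bonds <- rbind(bonds, c(parent, i))
  }
  if (n_atoms >= 4L && stats::runif(1L) < 0.5) {
    nonadj <- which(outer(seq_len(n_atoms), seq_len(n_atoms), "<"),
                    arr.ind = TRUE)
    have <- paste(bonds[, 1L], bonds[, 2L])
    cand <- nonadj[!(paste(nonadj[, 1L], nonadj[, 2L]) %in% have), ,
                   drop = FALSE]
    if (nrow(cand)) {
      pick <- cand[sample.int(nrow(cand), 1L), ]
      bonds <- rbind(bonds, pick)
    }
  }
  coords <- sweep(coords, 2L, colMeans(coords))
  list(coords = coords, bonds = bonds)
}

#' Generate one synthetic protein-ligand complex
#'
#' @param world a [synthetic_world()].
#' @param n_pocket_atoms total protein atoms (planted partners + shell
#'   filler), default 40.
#' @param n_ligand_atoms ligand heavy atoms (>= 4), default 12.
#' @param seed complex seed; the same seed reproduces the complex exactly.
#' @param complex_id identifier; default derived from the seed.
#' @param x,y,z pocket-graph neighbourhood sizes (see
#'   [build_pocket_graph()]).
#' @return list with `complex_id`, `pocket` (`PocketGraph`), `ligand`
#'   (`MoleculeGraph` with coords), `pairs` (ground-truth interacting
#'   pairs), `protein` (full cloud: `coords`, `elements`), `surface`
#'   (indices), `ligand_types`, `pocket_types`, `type_subset`.
#' @export
generate_complex <- function(world, n_pocket_atoms = 40L,
                             n_ligand_atoms = 12L, seed = 1L,
                             complex_id = sprintf("cx%04d", seed),
                             x = 8L, y = 4L, z = 4L) {
  stopifnot(inherits(world, "SyntheticWorld"), n_ligand_atoms >= 4L,
            n_pocket_atoms > n_ligand_atoms)
  with_seed(seed, {
    type_subset <- sort(sample.int(world$n_types, world$types_per_pocket))
    lig_types <- sample(type_subset, n_ligand_atoms, replace = TRUE)
    geom <- random_molecule_geometry(n_ligand_atoms)

    # planted partners: one pocket atom of the compatible type per ligand atom
    partner_types <- world$compatibility[lig_types]
    pdir <- geom$coords + 1e-8
    pdir <- pdir / sqrt(rowSums(pdir^2))
    contact <- stats::runif(n_ligand_atoms, world$contact_range[1L],
                            world$contact_range[2L])
    partner_coords <- geom$coords + pdir * contact

    n_fill <- n_pocket_atoms - n_ligand_atoms
    fill_coords <- matrix(NA_real_, n_fill, 3L)
    for (i in seq_len(n_fill)) {
      placed <- FALSE
      for (try in seq_len(200L)) {
        u <- as.numeric(random_unit())
        r <- stats::runif(1L, world$shell_radius, world$shell_radius + 3)
        pos <- u * r
        if (min(sqrt(colSums((t(geom$coords) - pos)^2))) > 4.0) {
          fill_coords[i, ] <- pos
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("infeasible geometry: could not place shell atoms > 4 A from the ligand",
             call. = FALSE)
      }
    }
    fill_types <- sample(world$compatibility[type_subset], n_fill,
                         replace = TRUE)

    protein_coords <- rbind(partner_coords, fill_coords)
    pocket_types <- c(partner_types, fill_types)
    protein_elements <- observe_elements(world, pocket_types)
    lig_elements <- observe_elements(world, lig_types)

    surface <- select_surface_atoms(protein_coords, geom$coords, 4.0)
    # small pockets cannot honour a large E1 neighbourhood; clamp x
    pocket <- build_pocket_graph(protein_coords, protein_elements, surface,
                                 x = min(x, length(surface) - 1L),
                                 y = y, z = z,
                                 pocket_id = complex_id)
    deg <- tabulate(c(geom$bonds), n_ligand_atoms)
    ligand <- new_molecule_graph(complex_id, lig_elements,
                                 pmax(0L, 3L - deg), geom$bonds,
                                 coords = geom$coords)
    pairs <- extract_interacting_pairs(pocket, ligand, 4.0)
    list(complex_id = complex_id, pocket = pocket, ligand = ligand,
         pairs = pairs,
         protein = list(coords = protein_coords,
                        elements = protein_elements),
         surface = surface, ligand_types = lig_types,
         pocket_types = pocket_types, type_subset = type_subset)
  })
}

#' Generate a set of synthetic training complexes
#'
#' @inheritParams generate_complex
#' @param n_complexes number of complexes.
#' @param seed base seed; complex i uses `seed * 1000 + i`.
#' @return list of complexes as from [generate_complex()].
#' @export
generate_training_set <- function(world, n_complexes, seed = 1L,
                                  n_pocket_atoms = 40L,
                                  n_ligand_atoms = 12L, ...) {
  lapply(seq_len(n_complexes), function(i)
    generate_complex(world, n_pocket_atoms, n_ligand_atoms,
                     seed = seed * 1000L + i,
                     complex_id = sprintf("cx%d_%03d", seed, i), ...))
}

#' Generate a labelled screening library for one synthetic pocket
#'
#' Actives draw their latent types from the pocket's compatible type subset;
#' decoys draw from all types uniformly (shuffled composition). Library
#' compounds carry no coordinates, as in real inference.
#'
#' @param world a [synthetic_world()].
#' @param complex a [generate_complex()] result defining the pocket.
#' @param n_actives,n_decoys compound counts (each >= 1).
#' @param seed library seed.
#' @return list with `compounds` (list of `MoleculeGraph`) and `labels`
#'   (data.frame `compound_id`, `active`).
#' @export
generate_screen_library <- function(world, complex, n_actives, n_decoys,
                                    seed = 1L) {
  stopifnot(n_actives >= 1L, n_decoys >= 1L)
  with_seed(seed, {
    make_cmpd <- function(id, active) {
      na <- sample(seq.int(world$lib_atom_range[1L],
                           world$lib_atom_range[2L]), 1L)
      types <- if (active) sample(complex$type_subset, na, replace = TRUE)
               else sample.int(world$n_types, na, replace = TRUE)
      geom <- random_molecule_geometry(na)
      deg <- tabulate(c(geom$bonds), na)
      new_molecule_graph(id, observe_elements(world, types),
                         pmax(0L, 3L - deg), geom$bonds, coords = NULL)
    }
    # ids are assigned by a random permutation so lexicographic tie-breaks
    # in downstream ranking are independent of the active/decoy label
    n_total <- n_actives + n_decoys
    perm <- sample.int(n_total)
    is_active <- rep(c(TRUE, FALSE), c(n_actives, n_decoys))
    compounds <- lapply(seq_len(n_total), function(i)
      make_cmpd(sprintf("cmpd_%04d", perm[i]), is_active[i]))
    labels <- data.frame(
      compound_id = vapply(compounds, `[[`, character(1), "mol_id"),
      active = is_active,
      stringsAsFactors = FALSE)
    list(compounds = compounds, labels = labels)
  })
}
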