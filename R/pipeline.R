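# Pipeline helpers shared by the command-line surface, the tests and the
# reproduction script: cross-activity for synthetic worlds, calibration-pair
# sampling, and the embed -> calibrate -> index -> score -> EF chain.

#' Cross-activity map of a synthetic training set
#'
#' In a synthetic world a compound binds any pocket whose compatible type
#' set covers the compound's types, so two complexes with overlapping latent
#' type subsets are mutually active. Hard-negative sampling must know this:
#' a hard negative may not come from a compound active against the anchor
#' pocket.
#'
#' @param complexes list of complexes from [generate_training_set()].
#' @return data.frame with columns `pocket_complex`, `ligand_complex`.
#' @export
synthetic_active_map <- function(complexes) {
  ids <- vapply(complexes, `[[`, character(1), "complex_id")
  subs <- lapply(complexes, `[[`, "type_subset")
  rows <- list()
  for (i in seq_along(complexes)) {
    for (j in seq_along(complexes)) {
      if (i != j && length(intersect(subs[[i]], subs[[j]]))) {
        rows[[length(rows) + 1L]] <- data.frame(
          pocket_complex = ids[i], ligand_complex = ids[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(pocket_complex = character(0),
                      ligand_complex = character(0)))
  }
  do.call(rbind, rows)
}

#' Embed training complexes and sample non-interacting pairs for calibration
#'
#' Draws random (pocket surface atom, ligand atom) combinations across
#' different complexes of the training set -- guaranteed not to be within
#' the interaction cutoff of any single complex -- and returns their
#' embedding distances.
#'
#' @param complexes training complexes.
#' @param model trained model (as returned in `$model` by
#'   [train_encoders()]).
#' @param n_pairs sample size (>= 100).
#' @param seed RNG seed.
#' @return numeric vector of embedding distances, suitable for
#'   [calibrate()].
#' @export
sample_noninteracting_distances <- function(complexes, model,
                                            n_pairs = 20000L, seed = 1L) {
  stopifnot(length(complexes) >= 2L, n_pairs >= 100L)
  cfg <- model$config
  P <- lapply(complexes, function(cx)
    embed_pocket(cx$pocket, cfg, model$pocket_weights))
  L <- lapply(complexes, function(cx)
    embed_compound(cx$ligand, cfg, model$compound_weights))
  np <- vapply(P, nrow, integer(1))
  nl <- vapply(L, nrow, integer(1))
  Pm <- do.call(rbind, P); Lm <- do.call(rbind, L)
  pcx <- rep(seq_along(P), np); lcx <- rep(seq_along(L), nl)
  with_seed(seed, {
    i <- sample.int(nrow(Pm), n_pairs, replace = TRUE)
    j <- sample.int(nrow(Lm), n_pairs, replace = TRUE)
    keep <- pcx[i] != lcx[j]
    sqrt(rowSums((Pm[i[keep], , drop = FALSE] -
                    Lm[j[keep], , drop = FALSE])^2))
  })
}

#' Screen a compound library against one pocket
#'
#' Embeds the library, builds the (optionally sharded) index, accumulates
#' nearest-neighbour similarity scores and returns the ranked result.
#'
#' @param pocket a `PocketGraph`.
#' @param compounds list of `MoleculeGraph`.
#' @param model trained model list (`config`, weights, `checkpoint_id`).
#' @param cal a [calibrate()] result.
#' @param k neighbours per pocket atom per shard; default exhaustive.
#' @param shard_capacity atoms per shard; default one shard.
#' @return a `ScreenResult` data.frame.
#' @export
screen_library <- function(pocket, compounds, model, cal, k = NULL,
                           shard_capacity = NULL) {
  cfg <- model$config
  Zp <- embed_pocket(pocket, cfg, model$pocket_weights)
  embs <- lapply(compounds, embed_compound, config = cfg,
                 weights = model$compound_weights)
  E <- do.call(rbind, embs)
  cid <- rep(vapply(compounds, `[[`, character(1), "mol_id"),
             vapply(embs, nrow, integer(1)))
  aidx <- unlist(lapply(embs, function(e) seq_len(nrow(e))))
  idx <- build_index(E, cid, aidx,
                     shard_capacity = shard_capacity %||% nrow(E),
                     checkpoint_id = model$checkpoint_id)
  score_compounds(Zp, idx, k = k %||% nrow(E), cal)
}
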