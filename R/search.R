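# Similarity calibration and nearest-neighbour score accumulation.
#
# Calibration: from a large sample of non-interacting (pocket atom, ligand
# atom) embedding pairs, D_max is the maximum pairwise L2 distance; raw
# similarities are s' = D_max - dist, and the noise threshold t is the
# percentile (default 99th) of the non-interacting s' distribution, so that
# 99% of random atom matches fall below it. The final similarity is
# s = max(0, s' - t).
#
# Screening: compound-atom embeddings live in a sharded exact-search index;
# each pocket atom retrieves its k nearest ligand atoms per shard, each
# retrieved distance is converted to a similarity, and the score of compound
# Cn is the sum of similarities over retrieved pairs whose ligand atom
# belongs to Cn.

#' Calibrate the distance-to-similarity transform
#'
#' @param pocket_embs,ligand_embs equal-length row-aligned matrices: row i of
#'   each forms one non-interacting pair. Alternatively `pocket_embs` may be
#'   a numeric vector of precomputed pair distances (`ligand_embs = NULL`).
#' @param percentile quantile of the non-interacting similarity distribution
#'   used as noise threshold (default 0.99).
#' @param checkpoint_id optional id tying the calibration to a model.
#' @return a `SimilarityCalibration` with `D_max`, `t`, `sample_size`,
#'   `percentile`.
#' @export
calibrate <- function(pocket_embs, ligand_embs = NULL, percentile = 0.99,
                      checkpoint_id = NULL) {
  if (is.null(ligand_embs)) {
    dists <- as.numeric(pocket_embs)
  } else {
    stopifnot(nrow(pocket_embs) == nrow(ligand_embs))
    dists <- sqrt(rowSums((pocket_embs - ligand_embs)^2))
  }
  if (length(dists) < 100L) {
    stop("calibration needs a sample of at least 100 non-interacting pairs",
         call. = FALSE)
  }
  D_max <- max(dists)
  if (D_max <= 0) {
    stop("degenerate calibration sample: all embedding pairs identical",
         call. = FALSE)
  }
  s_prime <- D_max - dists
  t <- stats::quantile(s_prime, percentile, names = FALSE)
  structure(list(D_max = D_max, t = t, sample_size = length(dists),
                 percentile = percentile, checkpoint_id = checkpoint_id),
            class = "SimilarityCalibration")
}

#' @export
print.SimilarityCalibration <- function(x, ...) {
  cat(sprintf(
    "SimilarityCalibration: D_max = %.4f, t = %.4f (%.0f%% of %d pairs)\n",
    x$D_max, x$t, 100 * x$percentile, x$sample_size))
  invisible(x)
}

#' Convert embedding distances to clamped similarities
#'
#' `s = max(0, (D_max - dist) - t)`: monotone non-increasing in the distance,
#' 0 at and beyond `D_max - t`.
#'
#' @param dist nonnegative embedding L2 distance(s).
#' @param cal a [calibrate()] result.
#' @return similarity value(s) >= 0.
#' @export
pair_similarity <- function(dist, cal) {
  stopifnot(inherits(cal, "SimilarityCalibration"), all(dist >= 0))
  pmax(0, (cal$D_max - dist) - cal$t)
}

#' Build a sharded exact nearest-neighbour index of compound-atom embeddings
#'
#' Embeddings are split in input order into shards of at most
#' `shard_capacity` atoms; each shard is searched exactly and results are
#' merged by score summation, so with a large enough k the partitioning does
#' not affect scores.
#'
#' @param embeddings n x d matrix of compound-atom embeddings.
#' @param compound_id character vector, length n: owning compound per atom.
#' @param atom_index integer vector, length n: atom index within compound.
#' @param shard_capacity maximal atoms per shard (default: all in one shard).
#' @param checkpoint_id optional model id recorded on the index.
#' @return an `EmbeddingIndex`.
#' @export
build_index <- function(embeddings, compound_id,
                        atom_index = stats::ave(
                          seq_along(compound_id), compound_id,
                          FUN = seq_along),
                        shard_capacity = nrow(embeddings),
                        checkpoint_id = NULL) {
  embeddings <- as.matrix(embeddings)
  n <- nrow(embeddings)
  stopifnot(n >= 1L, length(compound_id) == n, shard_capacity >= 1L)
  shard_of <- ceiling(seq_len(n) / shard_capacity)
  shards <- lapply(split(seq_len(n), shard_of), function(idx) {
    list(emb = embeddings[idx, , drop = FALSE],
         compound_id = compound_id[idx],
         atom_index = as.integer(atom_index[idx]))
  })
  structure(list(shards = shards, d = ncol(embeddings),
                 compounds = unique(compound_id),
                 checkpoint_id = checkpoint_id),
            class = "EmbeddingIndex")
}

#' @export
print.EmbeddingIndex <- function(x, ...) {
  cat(sprintf(
    "EmbeddingIndex: %d shard(s), %d atoms of %d compounds, d = %d\n",
    length(x$shards), sum(vapply(x$shards, function(s) nrow(s$emb),
                                 integer(1))),
    length(x$compounds), x$d))
  invisible(x)
}

#' Score all compounds in an index against one pocket
#'
#' For each pocket-atom embedding the k nearest compound-atom embeddings are
#' retrieved in every shard; each retrieved distance becomes a similarity via
#' [pair_similarity()] and the score `S(P, Cn)` of compound Cn is the sum of
#' similarities of retrieved pairs involving its atoms. Compounds never
#' retrieved (or whose every retrieved pair clamps to 0) score 0.
#'
#' @param pocket_embeddings q x d matrix of pocket surface-atom embeddings.
#' @param index an [build_index()] result.
#' @param k neighbours retrieved per pocket atom per shard.
#' @param cal a [calibrate()] result; must carry the same `checkpoint_id` as
#'   the index when both are set.
#' @return a `ScreenResult` data.frame: `compound_id`, `score`, `rank`
#'   (1-based, score descending, ties by id), `contributing_pairs` (retrieved
#'   pairs with positive similarity).
#' @export
score_compounds <- function(pocket_embeddings, index, k, cal) {
  stopifnot(inherits(index, "EmbeddingIndex"),
            inherits(cal, "SimilarityCalibration"))
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  pocket_embeddings <- as.matrix(pocket_embeddings)
  if (ncol(pocket_embeddings) != index$d) {
    stop(sprintf("embedding dimension mismatch: pocket %d vs index %d",
                 ncol(pocket_embeddings), index$d), call. = FALSE)
  }
  if (!is.null(cal$checkpoint_id) && !is.null(index$checkpoint_id) &&
      !identical(cal$checkpoint_id, index$checkpoint_id)) {
    stop("calibration and index come from different checkpoints; re-embed or recalibrate",
         call. = FALSE)
  }
  score <- stats::setNames(numeric(length(index$compounds)), index$compounds)
  npairs <- score
  if (nrow(pocket_embeddings)) {
    for (sh in index$shards) {
      D <- cross_dist(pocket_embeddings, sh$emb)
      kk <- min(k, ncol(D))
      for (r in seq_len(nrow(D))) {
        ord <- order(D[r, ], seq_len(ncol(D)))[seq_len(kk)]
        s <- pair_similarity(D[r, ord], cal)
        contrib <- rowsum(s, sh$compound_id[ord])
        score[rownames(contrib)] <- score[rownames(contrib)] + contrib[, 1L]
        pos <- rowsum(as.numeric(s > 0), sh$compound_id[ord])
        npairs[rownames(pos)] <- npairs[rownames(pos)] + pos[, 1L]
      }
    }
  }
  res <- data.frame(compound_id = names(score), score = as.numeric(score),
                    contributing_pairs = as.integer(npairs),
                    stringsAsFactors = FALSE)
  res <- res[order(-res$score, res$compound_id), ]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  class(res) <- c("ScreenResult", class(res))
  res
}

#' Exhaustive all-pairs scoring oracle
#'
#' Brute-force double loop over every (pocket atom, compound atom) pair; the
#' reference against which the sharded kNN accumulation is tested at
#' exhaustive k.
#'
#' @inheritParams score_compounds
#' @param compound_embeddings n x d matrix.
#' @param compound_id owning compound per row.
#' @return named numeric vector of scores.
#' @export
score_compounds_bruteforce <- function(pocket_embeddings, compound_embeddings,
                                       compound_id, cal) {
  D <- cross_dist(as.matrix(pocket_embeddings), as.matrix(compound_embeddings))
  s <- matrix(pair_similarity(as.numeric(D), cal), nrow(D), ncol(D))
  tot <- colSums(s)
  v <- rowsum(tot, compound_id)
  stats::setNames(v[, 1L], rownames(v))
}
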