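# Screen evaluation. The enrichment factor at down-sampling fraction d
# compares the share of actives recovered among the top-scoring d of a
# ranked library with the share expected by chance:
#   EF_d = (|A_d| / |A|) / (|S_d| / |S|),
# where S = A u N is the library, S_d its |S_d| = max(1, round(d |S|))
# top-scoring entries, and A_d the actives among them. EF = 1 is chance;
# |S|/|A| is the maximum, attained when S_d is saturated with actives.

#' Retained count for a down-sampling fraction
#'
#' @param library_size total number of compounds (>= 1).
#' @param d fraction in (0, 1].
#' @return `round(d * library_size)`, floored at 1.
#' @export
topN_from_fraction <- function(library_size, d) {
  stopifnot(library_size >= 1)
  if (d <= 0 || d > 1) stop("d must lie in (0, 1]", call. = FALSE)
  max(1L, as.integer(round(d * library_size)))
}

#' Enrichment factor of a labelled screen
#'
#' Ties at the retention boundary are broken by ascending compound id
#' (stable, documented), so the result is deterministic.
#'
#' @param scores numeric vector of per-compound scores.
#' @param labels logical (or 0/1) vector: `TRUE` for actives; aligned with
#'   `scores`.
#' @param d down-sampling fraction in (0, 1].
#' @param ids optional compound ids used for tie-breaking; defaults to the
#'   element order.
#' @return the enrichment factor `EF_d` (>= 0).
#' @export
enrichment_factor <- function(scores, labels, d, ids = seq_along(scores)) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  if (!any(labels)) stop("screen contains no actives", call. = FALSE)
  if (d <= 0 || d > 1) stop("d must lie in (0, 1]", call. = FALSE)
  S <- length(scores)
  A <- sum(labels)
  Sd <- topN_from_fraction(S, d)
  top <- order(-scores, ids)[seq_len(Sd)]
  Ad <- sum(labels[top])
  (Ad / A) / (Sd / S)
}

#' Enrichment factors at several fractions, optionally per target
#'
#' @param screens either a single data.frame with columns `compound_id`,
#'   `score`, `active`, or a named list of such data.frames (one per
#'   target).
#' @param fractions down-sampling fractions (default 1\%, 0.5\%, 0.01\%).
#' @param pool when several targets are given: `FALSE` (default) reports the
#'   unweighted mean of per-target EFs, `TRUE` pools all compounds into one
#'   screen first.
#' @return data.frame with columns `fraction` and `EF` (plus `target` for
#'   per-target rows when `pool = FALSE`).
#' @export
ef_table <- function(screens, fractions = c(0.01, 0.005, 1e-4),
                     pool = FALSE) {
  if (is.data.frame(screens)) screens <- list(screen = screens)
  if (pool) {
    all <- do.call(rbind, screens)
    screens <- list(pooled = all)
  }
  rows <- lapply(names(screens), function(nm) {
    sc <- screens[[nm]]
    data.frame(target = nm, fraction = fractions,
               EF = vapply(fractions, function(d)
                 enrichment_factor(sc$score, sc$active, d, sc$compound_id),
                 numeric(1)))
  })
  per <- do.call(rbind, rows)
  if (length(screens) == 1L) return(per[, c("fraction", "EF")])
  mean_rows <- stats::aggregate(EF ~ fraction, per, mean)
  mean_rows$target <- "mean"
  rbind(per, mean_rows[, c("target", "fraction", "EF")])
}

#' Inverted search: rank pockets by accumulated similarity to a query
#'
#' Same accumulation as [score_compounds()] with the roles swapped: the
#' database holds pocket surface-atom embeddings (grouped by pocket id) and
#' the query is the atom-embedding set of a ligand (toxicology / off-target
#' use) or of another pocket (functional similarity). Targets for which no
#' retrieved pair clears the noise threshold score 0 and are reported
#' unranked (`rank = NA`).
#'
#' @param query_embeddings q x d matrix (ligand or pocket atom embeddings).
#' @param target_index an [build_index()] over pocket atom embeddings, where
#'   `compound_id` holds the pocket id of each atom.
#' @param k neighbours per query atom per shard.
#' @param cal a [calibrate()] result.
#' @return data.frame `target_id`, `score`, `rank` (NA when score is 0),
#'   `contributing_pairs`.
#' @export
invert_screen <- function(query_embeddings, target_index, k, cal) {
  res <- score_compounds(query_embeddings, target_index, k, cal)
  out <- data.frame(target_id = res$compound_id, score = res$score,
                    rank = ifelse(res$score > 0, res$rank, NA_integer_),
                    contributing_pairs = res$contributing_pairs,
                    stringsAsFactors = FALSE)
  out
}
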