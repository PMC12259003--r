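# Contrastive training. Interacting atom pairs (protein atom and ligand atom
# within 4 A in a complex) give anchor-positive pairs; three typed negatives
# are drawn per pair:
#   random - an interacting atom from another complex in the batch,
#   self   - an atom of the positive molecule among the 25% most distant (in
#            3D) from the anchor,
#   hard   - an atom from a non-active molecule that is nevertheless close to
#            the anchor in embedding space, drawn from a distance-percentile
#            pool that shrinks linearly from the 99th to the 5th percentile
#            over the first 50 epochs.
# The anchor role (pocket atom vs ligand atom) alternates between batches.
# The positive-margin loss pulls positives within an absolute distance m of
# the anchor and pushes negatives beyond n > m.

#' Extract interacting atom pairs from a complex
#'
#' All (pocket node, ligand atom) pairs within `cutoff` Angstrom (closed
#' threshold). Pocket atoms are indexed by their node index local to the
#' pocket graph.
#'
#' @param pocket a `PocketGraph`.
#' @param ligand a `MoleculeGraph` carrying 3D `coords` (training complexes).
#' @param cutoff interaction distance in Angstrom, default 4.
#' @return data.frame with columns `pocket_atom`, `ligand_atom`, `distance`.
#' @export
extract_interacting_pairs <- function(pocket, ligand, cutoff = 4.0) {
  stopifnot(inherits(pocket, "PocketGraph"), inherits(ligand, "MoleculeGraph"))
  if (is.null(ligand$coords)) {
    stop("ligand has no 3D coordinates; training requires complex geometry",
         call. = FALSE)
  }
  D <- cross_dist(pocket$coords, ligand$coords)
  idx <- which(D <= cutoff, arr.ind = TRUE)
  o <- order(idx[, 1L], idx[, 2L])
  data.frame(pocket_atom = idx[o, 1L], ligand_atom = idx[o, 2L],
             distance = D[idx][o])
}

#' Hard-negative sampling schedule
#'
#' @param start_pool_percentile pool percentile at epoch 0 (99: exclude only
#'   the 1\% most distant candidates).
#' @param end_pool_percentile final percentile (5: only the 5\% closest).
#' @param end_epoch epoch at which the final percentile locks in.
#' @return a `HardNegativeSchedule` list.
#' @export
hard_negative_schedule <- function(start_pool_percentile = 99,
                                   end_pool_percentile = 5,
                                   end_epoch = 50L) {
  stopifnot(start_pool_percentile > end_pool_percentile,
            end_pool_percentile > 0, end_epoch >= 1L)
  structure(list(start_pool_percentile = start_pool_percentile,
                 end_pool_percentile = end_pool_percentile,
                 end_epoch = as.integer(end_epoch)),
            class = "HardNegativeSchedule")
}

#' Hard-negative pool percentile at a given epoch
#'
#' Decreases linearly from the start percentile to the end percentile,
#' constant from `end_epoch` on.
#'
#' @param epoch integer epoch (0-based).
#' @param schedule a [hard_negative_schedule()].
#' @return percentile in (0, 100].
#' @export
hard_negative_pool_percentile <- function(epoch,
                                          schedule = hard_negative_schedule()) {
  stopifnot(epoch >= 0)
  s <- schedule
  frac <- pmin(epoch, s$end_epoch) / s$end_epoch
  s$start_pool_percentile -
    (s$start_pool_percentile - s$end_pool_percentile) * frac
}

#' Draw a random negative from another complex in the batch
#'
#' Selects a different complex uniformly, then one of its interacting pairs
#' uniformly; the atom on `side` of that pair is the negative. Only
#' interacting atoms are used as negatives. Uses R's RNG.
#'
#' @param batch_pairs named list: complex id -> interacting-pair data.frame.
#' @param current_complex id of the anchor's complex.
#' @param side `"ligand"` or `"pocket"`: which atom of the foreign pair is
#'   returned.
#' @return list with `complex_id`, `pocket_atom`, `ligand_atom`, `atom`.
#' @export
sample_random_negative <- function(batch_pairs, current_complex,
                                   side = c("ligand", "pocket")) {
  side <- match.arg(side)
  others <- setdiff(names(batch_pairs), current_complex)
  if (!length(others)) {
    stop("random negatives need a batch of at least 2 complexes", call. = FALSE)
  }
  cid <- others[sample.int(length(others), 1L)]
  pairs <- batch_pairs[[cid]]
  r <- sample.int(nrow(pairs), 1L)
  list(complex_id = cid,
       pocket_atom = pairs$pocket_atom[r],
       ligand_atom = pairs$ligand_atom[r],
       atom = if (side == "ligand") pairs$ligand_atom[r]
              else pairs$pocket_atom[r])
}

#' Draw a self negative: a distant atom of the positive molecule
#'
#' Eligible atoms are the `ceiling(0.25 * n)` atoms of the partner molecule
#' most distant (in complex 3D coordinates) from the anchor atom, excluding
#' the positive atom itself. Returns `NA` with a warning when no eligible
#' atom remains.
#'
#' @param anchor_coord length-3 coordinates of the anchor atom.
#' @param partner_coords n x 3 coordinates of the positive molecule's atoms.
#' @param positive_atom row index of the positive atom in `partner_coords`.
#' @return sampled atom index, or `NA_integer_`.
#' @export
sample_self_negative <- function(anchor_coord, partner_coords, positive_atom) {
  n <- nrow(partner_coords)
  if (n < 4L) {
    warning("molecule too small for a self negative (< 4 atoms); pair skipped")
    return(NA_integer_)
  }
  d <- sqrt(colSums((t(partner_coords) - as.numeric(anchor_coord))^2))
  k <- ceiling(0.25 * n)
  eligible <- order(-d, seq_len(n))[seq_len(k)]
  eligible <- setdiff(eligible, positive_atom)
  if (!length(eligible)) {
    warning("no self-negative candidate distinct from the positive; pair skipped")
    return(NA_integer_)
  }
  eligible[sample.int(length(eligible), 1L)]
}

#' Draw a hard negative from the epoch's embedding-distance pool
#'
#' Candidates are atoms of molecules not active against the anchor's pocket.
#' The pool is those candidates whose embedding distance to the anchor lies
#' within the epoch's percentile (see
#' [hard_negative_pool_percentile()]); one is drawn uniformly. An empty pool
#' falls back to `NA` (caller substitutes a random negative).
#'
#' @param anchor_emb length-d anchor embedding.
#' @param candidate_embs m x d matrix of candidate embeddings.
#' @param eligible logical vector: candidate permitted (not the positive
#'   molecule, not an active of the anchor pocket).
#' @param epoch 0-based epoch.
#' @param schedule a [hard_negative_schedule()].
#' @return candidate row index, or `NA_integer_` when no candidate exists.
#' @export
sample_hard_negative <- function(anchor_emb, candidate_embs, eligible, epoch,
                                 schedule = hard_negative_schedule()) {
  ok <- which(eligible)
  if (!length(ok)) return(NA_integer_)
  d <- sqrt(colSums((t(candidate_embs[ok, , drop = FALSE]) -
                       as.numeric(anchor_emb))^2))
  p <- hard_negative_pool_percentile(epoch, schedule) / 100
  pool <- ok[d <= stats::quantile(d, p, names = FALSE)]
  if (!length(pool)) return(NA_integer_)
  pool[sample.int(length(pool), 1L)]
}

#' Positive margin loss
#'
#' `L = mean(max(0, D+ - m) + max(0, n - D-))` over triplets: zero exactly
#' when every positive lies within absolute distance `m` of its anchor and
#' every negative at least `n` away.
#'
#' @param D_plus anchor-positive embedding distances.
#' @param D_minus anchor-negative embedding distances (same length).
#' @param m positive margin (> 0).
#' @param n negative margin (> m).
#' @return scalar loss.
#' @export
positive_margin_loss <- function(D_plus, D_minus, m = 1.0, n = 2.0) {
  stopifnot(length(D_plus) == length(D_minus), m > 0, n > m)
  if (any(D_plus < 0) || any(D_minus < 0)) {
    stop("distances must be nonnegative", call. = FALSE)
  }
  mean(pmax(0, D_plus - m) + pmax(0, n - D_minus))
}

#' Standard triplet margin loss (reference)
#'
#' `L = mean(max(0, D+ - D- + margin))`. Provided as the classical baseline
#' the positive-margin loss modifies: whenever the positive-margin loss is
#' zero with `n - m >= margin`, this loss is zero too.
#'
#' @inheritParams positive_margin_loss
#' @param margin relative margin, default 1.
#' @return scalar loss.
#' @export
triplet_margin_loss <- function(D_plus, D_minus, margin = 1.0) {
  stopifnot(length(D_plus) == length(D_minus))
  mean(pmax(0, D_plus - D_minus + margin))
}

# Concatenate per-complex encoder inputs into one block-diagonal batch.
batch_compound_inputs <- function(inputs) {
  offs <- cumsum(c(0L, vapply(inputs, `[[`, integer(1), "n")))
  list(
    X = do.call(rbind, lapply(inputs, `[[`, "X")),
    src = unlist(lapply(seq_along(inputs),
                        function(q) inputs[[q]]$src + offs[q])),
    dst = unlist(lapply(seq_along(inputs),
                        function(q) inputs[[q]]$dst + offs[q])),
    edge_attr = do.call(rbind, lapply(inputs, `[[`, "edge_attr")),
    n = offs[length(offs)], offsets = offs[-length(offs)]
  )
}

batch_pocket_inputs <- function(inputs) {
  offs <- cumsum(c(0L, vapply(inputs, `[[`, integer(1), "n")))
  list(
    X = do.call(rbind, lapply(inputs, `[[`, "X")),
    src = unlist(lapply(seq_along(inputs),
                        function(q) inputs[[q]]$src + offs[q])),
    dst = unlist(lapply(seq_along(inputs),
                        function(q) inputs[[q]]$dst + offs[q])),
    edge_dist = do.call(rbind, lapply(inputs, `[[`, "edge_dist")),
    n = offs[length(offs)], offsets = offs[-length(offs)]
  )
}

adam_state <- function(weights) {
  list(m = lapply(weights, function(w) w * 0),
       v = lapply(weights, function(w) w * 0), t = 0L)
}

adam_step <- function(weights, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(weights)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    weights[[nm]] <- weights[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(weights = weights, state = state)
}

#' Train the twin encoders with the positive-margin contrastive objective
#'
#' @param complexes list of training complexes; each element is a list with
#'   `complex_id`, `pocket` (a `PocketGraph`), `ligand` (a `MoleculeGraph`
#'   with coords) and optionally `pairs` (precomputed interacting pairs).
#' @param config an [encoder_config()].
#' @param m,n positive and negative margins of the loss (n > m).
#' @param schedule hard-negative [hard_negative_schedule()].
#' @param epochs number of epochs.
#' @param batch_size complexes per batch (>= 2).
#' @param lr Adam learning rate.
#' @param seed seed controlling initialisation, batching, negative sampling
#'   and dropout.
#' @param active_map optional two-column data.frame (`pocket_complex`,
#'   `ligand_complex`) of known activity beyond each complex's own ligand;
#'   hard negatives never come from molecules active against the anchor
#'   pocket.
#' @param restarts number of independent training runs (different
#'   initialisation and sampling streams, deterministically derived from
#'   `seed`); the run with the lowest mean loss over its final two epochs is
#'   kept. The contrastive objective is non-convex and runs occasionally
#'   settle in a poorly-separated basin recognisable by an elevated training
#'   loss, so restart selection uses the training loss only.
#' @param verbose print per-epoch mean loss.
#' @return list with `model` (config + both weight sets + checkpoint id),
#'   `trace` (data.frame: epoch, batch, anchor_role, loss, of the selected
#'   run) and `restart_losses`.
#' @export
train_encoders <- function(complexes, config = encoder_config(),
                           m = 1.0, n = 2.0,
                           schedule = hard_negative_schedule(),
                           epochs = 30L, batch_size = 8L, lr = 3e-3,
                           seed = 1L, active_map = NULL, restarts = 1L,
                           verbose = FALSE) {
  stopifnot(restarts >= 1L)
  if (restarts > 1L) {
    runs <- lapply(seq_len(restarts) - 1L, function(r)
      train_encoders(complexes, config, m, n, schedule, epochs, batch_size,
                     lr,
                     seed = as.integer((as.numeric(seed) * 101 + r) %%
                                         .Machine$integer.max),
                     active_map = active_map,
                     restarts = 1L, verbose = verbose))
    final_loss <- vapply(runs, function(fit) {
      tr <- fit$trace
      mean(tr$loss[tr$epoch >= max(tr$epoch) - 1L])
    }, numeric(1))
    best <- runs[[which.min(final_loss)]]
    best$restart_losses <- final_loss
    return(best)
  }
  stopifnot(length(complexes) >= 2L, batch_size >= 2L, n > m, epochs >= 1L)
  ids <- vapply(complexes, `[[`, character(1), "complex_id")
  names(complexes) <- ids

  prep <- lapply(complexes, function(cx) {
    pairs <- cx$pairs %||% extract_interacting_pairs(cx$pocket, cx$ligand)
    if (!nrow(pairs)) {
      stop("complex ", cx$complex_id, " yields no interacting pairs",
           call. = FALSE)
    }
    list(id = cx$complex_id,
         pocket = cx$pocket, ligand = cx$ligand, pairs = pairs,
         pin = prepare_pocket_input(cx$pocket),
         lin = prepare_compound_input(cx$ligand))
  })

  is_active <- function(pocket_id, ligand_id) {
    if (pocket_id == ligand_id) return(TRUE)
    if (is.null(active_map)) return(FALSE)
    any(active_map$pocket_complex == pocket_id &
          active_map$ligand_complex == ligand_id)
  }

  set.seed(seed)
  Wc <- encoder_init(config, "compound",
                     seed = sample.int(.Machine$integer.max, 1L))
  Wp <- encoder_init(config, "pocket",
                     seed = sample.int(.Machine$integer.max, 1L))
  stc <- adam_state(Wc); stp <- adam_state(Wp)

  trace <- list()
  batch_counter <- 0L
  hard_fallbacks <- 0L

  for (epoch in seq_len(epochs) - 1L) {
    ord <- sample(length(prep))
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    batches <- Filter(function(b) length(b) >= 2L, batches)
    for (bi in seq_along(batches)) {
      batch <- prep[batches[[bi]]]
      role <- if (batch_counter %% 2L == 0L) "pocket" else "ligand"
      batch_counter <- batch_counter + 1L

      cb <- batch_compound_inputs(lapply(batch, `[[`, "lin"))
      pb <- batch_pocket_inputs(lapply(batch, `[[`, "pin"))
      tape <- new_tape()
      pnc <- param_nodes(tape, Wc)
      pnp <- param_nodes(tape, Wp)
      Zl <- encoder_forward(tape, pnc, cb, config, "compound", train = TRUE)
      Zp <- encoder_forward(tape, pnp, pb, config, "pocket", train = TRUE)

      # global row lookup
      lrow <- function(q, atom) cb$offsets[q] + atom
      prow <- function(q, node) pb$offsets[q] + node
      batch_pairs <- lapply(batch, `[[`, "pairs")
      names(batch_pairs) <- names(batch)

      anchor_rows <- integer(0); pos_rows <- integer(0); neg_rows <- integer(0)
      # candidate table for hard negatives (non-anchor side)
      if (role == "pocket") {
        cand_rows <- unlist(lapply(seq_along(batch), function(q)
          lrow(q, seq_len(batch[[q]]$lin$n))))
        cand_cx <- rep(names(batch),
                       vapply(batch, function(b) b$lin$n, integer(1)))
        cand_emb <- Zl$val[cand_rows, , drop = FALSE]
      } else {
        cand_rows <- unlist(lapply(seq_along(batch), function(q)
          prow(q, batch[[q]]$pin$keep)))
        cand_cx <- rep(names(batch),
                       vapply(batch, function(b) length(b$pin$keep),
                              integer(1)))
        cand_emb <- Zp$val[cand_rows, , drop = FALSE]
      }

      for (q in seq_along(batch)) {
        bq <- batch[[q]]
        surf_ok <- bq$pairs$pocket_atom %in% bq$pin$keep
        pr <- bq$pairs[surf_ok, , drop = FALSE]
        for (r in seq_len(nrow(pr))) {
          pi <- pr$pocket_atom[r]; cj <- pr$ligand_atom[r]
          if (role == "pocket") {
            a_row <- prow(q, pi); p_row <- lrow(q, cj)
            anchor_node_val <- Zp$val[a_row, ]
            rn <- sample_random_negative(batch_pairs, bq$id, "ligand")
            rn_row <- lrow(match(rn$complex_id, names(batch)), rn$atom)
            sn <- sample_self_negative(bq$pocket$coords[pi, ],
                                       bq$ligand$coords, cj)
            sn_row <- if (is.na(sn)) NA_integer_ else lrow(q, sn)
          } else {
            a_row <- lrow(q, cj); p_row <- prow(q, pi)
            anchor_node_val <- Zl$val[a_row, ]
            rn <- sample_random_negative(batch_pairs, bq$id, "pocket")
            rn_row <- prow(match(rn$complex_id, names(batch)), rn$atom)
            surf <- bq$pin$keep
            sn <- sample_self_negative(bq$ligand$coords[cj, ],
                                       bq$pocket$coords[surf, , drop = FALSE],
                                       match(pi, surf))
            sn_row <- if (is.na(sn)) NA_integer_ else prow(q, surf[sn])
          }
          eligible <- cand_cx != bq$id
          if (!is.null(active_map)) {
            act <- vapply(unique(cand_cx[eligible]), function(cc)
              is_active(if (role == "pocket") bq$id else cc,
                        if (role == "pocket") cc else bq$id), logical(1))
            eligible <- eligible & !(cand_cx %in%
                                       names(act)[as.logical(act)])
          }
          hn <- sample_hard_negative(anchor_node_val, cand_emb, eligible,
                                     epoch, schedule)
          if (is.na(hn)) {
            hard_fallbacks <- hard_fallbacks + 1L
            hn_row <- rn_row
          } else {
            hn_row <- cand_rows[hn]
          }
          negs <- c(rn_row, sn_row, hn_row)
          negs <- negs[!is.na(negs)]
          anchor_rows <- c(anchor_rows, rep(a_row, length(negs)))
          pos_rows <- c(pos_rows, rep(p_row, length(negs)))
          neg_rows <- c(neg_rows, negs)
        }
      }

      anchor_node <- if (role == "pocket") Zp else Zl
      other_node <- if (role == "pocket") Zl else Zp
      A <- ad_rows(anchor_node, anchor_rows)
      P <- ad_rows(other_node, pos_rows)
      N <- ad_rows(other_node, neg_rows)
      Dp <- ad_pair_dist(A, P)
      Dm <- ad_pair_dist(A, N)
      Lp <- ad_relu(ad_shift(Dp, -m))
      Lm <- ad_relu(ad_shift(ad_scale(Dm, -1), n))
      loss <- ad_mean(ad_add(Lp, Lm))
      if (!is.finite(loss$val)) {
        stop(sprintf(
          "non-finite loss at epoch %d, batch %d (lr = %g); aborting",
          epoch, bi, lr))
      }
      ad_backward(loss)

      up_c <- adam_step(Wc, lapply(pnc, `[[`, "grad"), stc, lr)
      Wc <- up_c$weights; stc <- up_c$state
      up_p <- adam_step(Wp, lapply(pnp, `[[`, "grad"), stp, lr)
      Wp <- up_p$weights; stp <- up_p$state

      trace[[length(trace) + 1L]] <- data.frame(
        epoch = epoch, batch = bi, anchor_role = role,
        loss = as.numeric(loss$val))
    }
    if (verbose) {
      tr <- do.call(rbind, trace)
      message(sprintf("epoch %3d  mean loss %.4f", epoch,
                      mean(tr$loss[tr$epoch == epoch])))
    }
  }
  if (hard_fallbacks > 0L) {
    message(sprintf(
      "hard-negative pool was empty %d time(s); fell back to random negatives",
      hard_fallbacks))
  }
  model <- list(config = config, compound_weights = Wc, pocket_weights = Wp)
  model$checkpoint_id <- checkpoint_id(model)
  list(model = model, trace = do.call(rbind, trace))
}
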