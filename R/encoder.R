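# Twin graph-attention encoders. Both the compound and the pocket encoder
# share one architecture: node one-hots are lifted linearly to the working
# width, then passed through residual blocks. Each block applies two
# multi-head GATv2-style attention operations, a SiLU nonlinearity, and
# appends (concatenates) the result to the block input; during training a
# dropout layer follows. No normalization layers are used. A final linear
# layer projects to the embedding dimension d.
#
# The compound encoder feeds the hop-class one-hot of each edge into the
# attention score. The pocket encoder's sole edge feature is a learned
# nonnegative scalar weight obtained by passing the inter-atomic distance
# through a small ReLU map; this scalar multiplies each attention-weighted
# message. Only pairwise distances enter, so pocket embeddings are invariant
# to rigid motions of the structure.

#' Encoder configuration
#'
#' @param embed_dim output embedding dimension d.
#' @param n_blocks number of residual attention blocks.
#' @param n_heads attention heads per GAT operation.
#' @param head_dim features per head; each GAT op outputs
#'   `n_heads * head_dim` features (heads concatenated).
#' @param dropout_p dropout probability applied after each block during
#'   training only.
#' @param edge_mlp_dim hidden width of the pocket edge-weight map.
#' @param seed seed for weight initialisation.
#' @return an `EncoderConfig` list.
#' @export
encoder_config <- function(embed_dim = 64L, n_blocks = 3L, n_heads = 4L,
                           head_dim = 8L, dropout_p = 0.1,
                           edge_mlp_dim = 8L, seed = 1L) {
  stopifnot(embed_dim >= 1L, n_blocks >= 1L, n_heads >= 1L, head_dim >= 1L,
            dropout_p >= 0, dropout_p < 1, edge_mlp_dim >= 1L)
  cfg <- list(embed_dim = as.integer(embed_dim),
              n_blocks = as.integer(n_blocks),
              n_heads = as.integer(n_heads),
              head_dim = as.integer(head_dim),
              dropout_p = dropout_p,
              edge_mlp_dim = as.integer(edge_mlp_dim),
              seed = as.integer(seed))
  class(cfg) <- "EncoderConfig"
  cfg
}

compound_feature_dim <- function() {
  length(element_vocabulary()) + H_COUNT_MAX + 1L
}

pocket_feature_dim <- function() length(element_vocabulary())

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# Flat named list of weight matrices for one encoder.
encoder_init <- function(config, kind = c("compound", "pocket"),
                         seed = config$seed) {
  kind <- match.arg(kind)
  in_dim <- if (kind == "compound") compound_feature_dim()
            else pocket_feature_dim()
  edge_dim <- if (kind == "compound") 3L else 0L
  w0 <- config$n_heads * config$head_dim
  with_seed(seed, {
    W <- list(lift_W = glorot(in_dim, w0), lift_b = matrix(0, 1L, w0))
    width <- w0
    for (b in seq_len(config$n_blocks)) {
      for (g in 1:2) {
        gin <- if (g == 1L) width else w0
        for (h in seq_len(config$n_heads)) {
          p <- sprintf("b%d.g%d.h%d.", b, g, h)
          W[[paste0(p, "Wsrc")]] <- glorot(gin, config$head_dim)
          W[[paste0(p, "Wdst")]] <- glorot(gin, config$head_dim)
          if (edge_dim > 0L) {
            W[[paste0(p, "We")]] <- glorot(edge_dim, config$head_dim)
          }
          W[[paste0(p, "a")]] <- glorot(config$head_dim, 1L)
          W[[paste0(p, "b")]] <- matrix(0, 1L, config$head_dim)
        }
      }
      width <- width + w0
    }
    if (kind == "pocket") {
      W$ew_W1 <- glorot(1L, config$edge_mlp_dim)
      W$ew_b1 <- matrix(0, 1L, config$edge_mlp_dim)
      W$ew_W2 <- glorot(config$edge_mlp_dim, 1L)
      # positive output bias keeps the ReLU edge-weight map active at
      # initialisation; a zero start would silence every pocket message and
      # its own gradient (dead unit)
      W$ew_b2 <- matrix(1, 1L, 1L)
    }
    W$out_W <- glorot(width, config$embed_dim)
    W$out_b <- matrix(0, 1L, config$embed_dim)
    W
  })
}

# Directed-edge arrays and feature matrices consumed by the forward pass.
prepare_compound_input <- function(g) {
  stopifnot(inherits(g, "MoleculeGraph"))
  X <- node_features(g$elements, g$h_counts)
  if (nrow(g$edges)) {
    src <- c(g$edges[, 1L], g$edges[, 2L])
    dst <- c(g$edges[, 2L], g$edges[, 1L])
    hop <- rep(g$hop_class, 2L)
    ea <- matrix(0, length(hop), 3L)
    ea[cbind(seq_along(hop), hop)] <- 1
  } else {
    src <- dst <- integer(0)
    ea <- matrix(0, 0L, 3L)
  }
  list(X = X, src = src, dst = dst, edge_attr = ea, n = g$n_nodes,
       keep = seq_len(g$n_nodes))
}

prepare_pocket_input <- function(g) {
  stopifnot(inherits(g, "PocketGraph"))
  X <- node_features(g$elements)
  src <- c(g$edges[, 1L], g$edges[, 2L])
  dst <- c(g$edges[, 2L], g$edges[, 1L])
  dist <- matrix(rep(g$edge_dist, 2L), ncol = 1L)
  list(X = X, src = src, dst = dst, edge_dist = dist, n = g$n_nodes,
       keep = which(g$surface_mask))
}

param_nodes <- function(tape, weights) {
  lapply(weights, function(w) ad_input(tape, w, requires_grad = TRUE))
}

gat_op <- function(X, src, dst, n, pn, prefix, config,
                   edge_attr = NULL, edge_weight = NULL) {
  tape <- X$tape
  out <- NULL
  for (h in seq_len(config$n_heads)) {
    p <- sprintf("%s.h%d.", prefix, h)
    hs <- ad_matmul(X, pn[[paste0(p, "Wsrc")]])
    hd <- ad_matmul(X, pn[[paste0(p, "Wdst")]])
    if (length(src)) {
      m <- ad_add(ad_rows(hs, src), ad_rows(hd, dst))
      if (!is.null(edge_attr)) {
        m <- ad_add(m, ad_matmul(edge_attr, pn[[paste0(p, "We")]]))
      }
      m <- ad_add(m, pn[[paste0(p, "b")]])
      score <- ad_matmul(ad_leaky_relu(m), pn[[paste0(p, "a")]])
      alpha <- ad_segment_softmax(score, dst)
      msg <- ad_colscale(ad_rows(hs, src), alpha)
      if (!is.null(edge_weight)) msg <- ad_colscale(msg, edge_weight)
      oh <- ad_scatter_sum(msg, dst, n)
    } else {
      oh <- ad_scale(hs, 0)   # isolated nodes receive no messages
    }
    out <- if (is.null(out)) oh else ad_cbind(out, oh)
  }
  out
}

# Full forward pass on a tape; returns the n x d embedding node.
encoder_forward <- function(tape, pn, input, config,
                            kind = c("compound", "pocket"), train = FALSE) {
  kind <- match.arg(kind)
  Xn <- ad_input(tape, input$X)
  edge_attr <- NULL
  edge_weight <- NULL
  if (kind == "compound") {
    if (length(input$src)) edge_attr <- ad_input(tape, input$edge_attr)
  } else if (length(input$src)) {
    dn <- ad_input(tape, input$edge_dist)
    hidden <- ad_relu(ad_add(ad_matmul(dn, pn$ew_W1), pn$ew_b1))
    edge_weight <- ad_relu(ad_add(ad_matmul(hidden, pn$ew_W2), pn$ew_b2))
  }
  H <- ad_add(ad_matmul(Xn, pn$lift_W), pn$lift_b)
  for (b in seq_len(config$n_blocks)) {
    g1 <- gat_op(H, input$src, input$dst, input$n, pn,
                 sprintf("b%d.g1", b), config, edge_attr, edge_weight)
    g2 <- gat_op(g1, input$src, input$dst, input$n, pn,
                 sprintf("b%d.g2", b), config, edge_attr, edge_weight)
    H <- ad_cbind(H, ad_silu(g2))
    if (train && config$dropout_p > 0) H <- ad_dropout(H, config$dropout_p)
  }
  ad_add(ad_matmul(H, pn$out_W), pn$out_b)
}

embed_graph <- function(input, config, weights, kind, mode) {
  stopifnot(mode %in% c("train", "eval"))
  check_weight_shapes(weights, config, kind)
  tape <- new_tape()
  pn <- param_nodes(tape, weights)
  Z <- encoder_forward(tape, pn, input, config, kind, train = mode == "train")
  emb <- Z$val[input$keep, , drop = FALSE]
  if (any(!is.finite(emb))) stop("encoder produced non-finite embeddings")
  emb
}

check_weight_shapes <- function(weights, config, kind) {
  ref <- encoder_shapes(config, kind)
  if (!identical(sort(names(weights)), sort(names(ref)))) {
    stop("weights do not match the encoder configuration (parameter set differs)",
         call. = FALSE)
  }
  for (nm in names(ref)) {
    if (!identical(dim(weights[[nm]]), ref[[nm]])) {
      stop(sprintf(
        "weights do not match the encoder configuration: '%s' has shape %s, expected %s",
        nm, paste(dim(weights[[nm]]), collapse = "x"),
        paste(ref[[nm]], collapse = "x")), call. = FALSE)
    }
  }
  invisible(TRUE)
}

encoder_shapes <- function(config, kind) {
  w <- encoder_init(config, kind, seed = 0L)
  lapply(w, dim)
}

#' Embed every atom of a compound graph
#'
#' @param graph a `MoleculeGraph`.
#' @param config an `EncoderConfig`.
#' @param weights weight list from [encoder_init()] or a loaded checkpoint.
#' @param mode `"eval"` (deterministic) or `"train"` (dropout active).
#' @return numeric matrix, one row per heavy atom, `embed_dim` columns;
#'   attributes `parent_id` and `atom_index`.
#' @export
embed_compound <- function(graph, config, weights, mode = "eval") {
  input <- prepare_compound_input(graph)
  emb <- embed_graph(input, config, weights, "compound", mode)
  structure(emb, parent_id = graph$mol_id, atom_index = input$keep)
}

#' Embed the surface atoms of a pocket graph
#'
#' Message passing runs over the full pocket graph; embeddings are returned
#' for surface atoms only.
#'
#' @inheritParams embed_compound
#' @param graph a `PocketGraph`.
#' @return numeric matrix, one row per surface atom; attributes `parent_id`
#'   and `atom_index` (node indices local to the graph).
#' @export
embed_pocket <- function(graph, config, weights, mode = "eval") {
  input <- prepare_pocket_input(graph)
  emb <- embed_graph(input, config, weights, "pocket", mode)
  structure(emb, parent_id = graph$pocket_id, atom_index = input$keep)
}

#' Save a trained model checkpoint
#'
#' Single-file JSON archive holding both encoders' weights and the
#' configuration; [load_checkpoint()] refuses files whose weights do not
#' match their stored configuration.
#'
#' @param model list with `config`, `compound_weights`, `pocket_weights`.
#' @param path output file.
#' @return the checkpoint id, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  ser <- function(W) lapply(W, function(m) list(dim = dim(m), data = as.numeric(m)))
  obj <- list(
    format = "atomscreen-checkpoint-v1",
    checkpoint_id = checkpoint_id(model),
    config = unclass(model$config),
    compound_weights = ser(model$compound_weights),
    pocket_weights = ser(model$pocket_weights)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(obj$checkpoint_id)
}

#' Load a model checkpoint written by [save_checkpoint()]
#'
#' @param path checkpoint file.
#' @return list with `config`, `compound_weights`, `pocket_weights`,
#'   `checkpoint_id`.
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "atomscreen-checkpoint-v1")) {
    stop("not an atomscreen checkpoint: ", path, call. = FALSE)
  }
  des <- function(L) lapply(L, function(e) matrix(e$data, e$dim[1], e$dim[2]))
  cfg <- do.call(encoder_config, obj$config[names(formals(encoder_config))])
  model <- list(config = cfg,
                compound_weights = des(obj$compound_weights),
                pocket_weights = des(obj$pocket_weights),
                checkpoint_id = obj$checkpoint_id)
  check_weight_shapes(model$compound_weights, cfg, "compound")
  check_weight_shapes(model$pocket_weights, cfg, "pocket")
  model
}

# Content-derived identifier tying indexes and calibrations to a checkpoint.
checkpoint_id <- function(model) {
  s <- sum(vapply(model$compound_weights,
                  function(m) sum(abs(m)), numeric(1))) +
       sum(vapply(model$pocket_weights,
                  function(m) sum(abs(m)), numeric(1)))
  sprintf("ck-d%d-b%d-%012.0f", model$config$embed_dim,
          model$config$n_blocks, s * 1e6)
}
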