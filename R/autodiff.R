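# Minimal reverse-mode automatic differentiation on a tape of matrix nodes.
#
# Every value is a numeric matrix. Operations append nodes to a tape; each
# node stores its parents and a pullback closure that maps the node's
# cotangent (grad) into its parents' cotangents. ad_backward() walks the tape
# in reverse creation order. This is all the machinery the graph-attention
# encoders need: matmul, broadcast add, elementwise activations, row
# gather/scatter, per-group softmax, concatenation, dropout and a pairwise
# Euclidean distance.

new_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  class(t) <- "ad_tape"
  t
}

ad_node <- function(tape, val, parents = list(), pullback = NULL,
                    requires_grad = TRUE) {
  node <- new.env(parent = emptyenv())
  node$val <- val
  node$grad <- NULL
  node$parents <- parents
  node$pullback <- pullback
  node$requires_grad <- requires_grad
  node$tape <- tape
  class(node) <- "ad_value"
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    length(tape$nodes) <- 2L * length(tape$nodes)
  }
  tape$nodes[[tape$n]] <- node
  node
}

#' @noRd
ad_input <- function(tape, x, requires_grad = FALSE) {
  if (!is.matrix(x)) x <- as.matrix(x)
  ad_node(tape, x, requires_grad = requires_grad)
}

ad_accum <- function(node, g) {
  if (!node$requires_grad) return(invisible(NULL))
  if (is.null(node$grad)) {
    node$grad <- g
  } else {
    node$grad <- node$grad + g
  }
  invisible(NULL)
}

#' Run backpropagation from a scalar (1x1) loss node.
#' @noRd
ad_backward <- function(loss) {
  stopifnot(inherits(loss, "ad_value"), length(loss$val) == 1L)
  tape <- loss$tape
  loss$grad <- matrix(1, 1L, 1L)
  for (i in seq.int(tape$n, 1L)) {
    node <- tape$nodes[[i]]
    if (!is.null(node$grad) && !is.null(node$pullback)) {
      node$pullback(node$grad)
    }
  }
  invisible(NULL)
}

ad_matmul <- function(a, b) {
  v <- a$val %*% b$val
  ad_node(a$tape, v, list(a, b), function(g) {
    if (a$requires_grad) ad_accum(a, g %*% t(b$val))
    if (b$requires_grad) ad_accum(b, t(a$val) %*% g)
  }, requires_grad = a$requires_grad || b$requires_grad)
}

# b may be a 1 x k row vector (bias), broadcast over rows of a.
ad_add <- function(a, b) {
  bv <- b$val
  broadcast <- nrow(bv) == 1L && nrow(a$val) > 1L
  v <- if (broadcast) sweep(a$val, 2L, as.numeric(bv), "+") else a$val + bv
  ad_node(a$tape, v, list(a, b), function(g) {
    if (a$requires_grad) ad_accum(a, g)
    if (b$requires_grad) {
      ad_accum(b, if (broadcast) matrix(colSums(g), 1L) else g)
    }
  }, requires_grad = a$requires_grad || b$requires_grad)
}

ad_sub <- function(a, b) {
  ad_node(a$tape, a$val - b$val, list(a, b), function(g) {
    if (a$requires_grad) ad_accum(a, g)
    if (b$requires_grad) ad_accum(b, -g)
  }, requires_grad = a$requires_grad || b$requires_grad)
}

# Elementwise product, identical shapes.
ad_mul <- function(a, b) {
  ad_node(a$tape, a$val * b$val, list(a, b), function(g) {
    if (a$requires_grad) ad_accum(a, g * b$val)
    if (b$requires_grad) ad_accum(b, g * a$val)
  }, requires_grad = a$requires_grad || b$requires_grad)
}

# Multiply every column of a (m x k) by the column vector s (m x 1).
ad_colscale <- function(a, s) {
  sv <- as.numeric(s$val)
  v <- a$val * sv
  ad_node(a$tape, v, list(a, s), function(g) {
    if (a$requires_grad) ad_accum(a, g * sv)
    if (s$requires_grad) ad_accum(s, matrix(rowSums(g * a$val), ncol = 1L))
  }, requires_grad = a$requires_grad || s$requires_grad)
}

ad_scale <- function(a, k) {
  ad_node(a$tape, a$val * k, list(a), function(g) {
    if (a$requires_grad) ad_accum(a, g * k)
  }, requires_grad = a$requires_grad)
}

ad_shift <- function(a, k) {
  ad_node(a$tape, a$val + k, list(a), function(g) {
    if (a$requires_grad) ad_accum(a, g)
  }, requires_grad = a$requires_grad)
}

ad_rows <- function(a, idx) {
  idx <- as.integer(idx)
  v <- a$val[idx, , drop = FALSE]
  ad_node(a$tape, v, list(a), function(g) {
    if (a$requires_grad) {
      ga <- matrix(0, nrow(a$val), ncol(a$val))
      rs <- rowsum(g, idx, reorder = FALSE)
      ga[as.integer(rownames(rs)), ] <- rs
      ad_accum(a, ga)
    }
  }, requires_grad = a$requires_grad)
}

# Sum rows of a (m x k) into n bins given by idx (length m, values in 1..n).
ad_scatter_sum <- function(a, idx, n) {
  idx <- as.integer(idx)
  v <- matrix(0, n, ncol(a$val))
  rs <- rowsum(a$val, idx, reorder = FALSE)
  v[as.integer(rownames(rs)), ] <- rs
  ad_node(a$tape, v, list(a), function(g) {
    if (a$requires_grad) ad_accum(a, g[idx, , drop = FALSE])
  }, requires_grad = a$requires_grad)
}

ad_relu <- function(a) {
  mask <- a$val > 0
  ad_node(a$tape, a$val * mask, list(a), function(g) {
    if (a$requires_grad) ad_accum(a, g * mask)
  }, requires_grad = a$requires_grad)
}

ad_leaky_relu <- function(a, slope = 0.2) {
  pos <- a$val > 0
  v <- ifelse(pos, a$val, slope * a$val)
  ad_node(a$tape, v, list(a), function(g) {
    if (a$requires_grad) ad_accum(a, g * ifelse(pos, 1, slope))
  }, requires_grad = a$requires_grad)
}

ad_silu <- function(a) {
  s <- 1 / (1 + exp(-a$val))
  v <- a$val * s
  ad_node(a$tape, v, list(a), function(g) {
    if (a$requires_grad) ad_accum(a, g * (s * (1 + a$val * (1 - s))))
  }, requires_grad = a$requires_grad)
}

# Softmax of scores (m x 1) within groups; groups is an integer vector of
# length m. Numerically stabilised by per-group max subtraction.
ad_segment_softmax <- function(a, groups) {
  groups <- as.integer(groups)
  x <- as.numeric(a$val)
  gmax <- tapply(x, groups, max)
  ex <- exp(x - as.numeric(gmax[as.character(groups)]))
  gsum <- tapply(ex, groups, sum)
  alpha <- ex / as.numeric(gsum[as.character(groups)])
  v <- matrix(alpha, ncol = 1L)
  ad_node(a$tape, v, list(a), function(g) {
    if (a$requires_grad) {
      gv <- as.numeric(g)
      dot <- tapply(alpha * gv, groups, sum)
      ga <- alpha * (gv - as.numeric(dot[as.character(groups)]))
      ad_accum(a, matrix(ga, ncol = 1L))
    }
  }, requires_grad = a$requires_grad)
}

ad_cbind <- function(a, b) {
  ka <- ncol(a$val)
  v <- cbind(a$val, b$val)
  ad_node(a$tape, v, list(a, b), function(g) {
    if (a$requires_grad) ad_accum(a, g[, seq_len(ka), drop = FALSE])
    if (b$requires_grad) ad_accum(b, g[, -seq_len(ka), drop = FALSE])
  }, requires_grad = a$requires_grad || b$requires_grad)
}

# Inverted dropout; the Bernoulli mask is drawn from R's RNG at forward time,
# so seeding the training loop makes runs reproducible.
ad_dropout <- function(a, p) {
  if (p <= 0) return(a)
  keep <- matrix(stats::runif(length(a$val)) >= p,
                 nrow(a$val), ncol(a$val)) / (1 - p)
  ad_node(a$tape, a$val * keep, list(a), function(g) {
    if (a$requires_grad) ad_accum(a, g * keep)
  }, requires_grad = a$requires_grad)
}

ad_sum <- function(a) {
  ad_node(a$tape, matrix(sum(a$val), 1L, 1L), list(a), function(g) {
    if (a$requires_grad) {
      ad_accum(a, matrix(as.numeric(g), nrow(a$val), ncol(a$val)))
    }
  }, requires_grad = a$requires_grad)
}

ad_mean <- function(a) ad_scale(ad_sum(a), 1 / length(a$val))

# Rowwise Euclidean distance between equal-shaped matrices a and b -> m x 1.
# A small floor keeps the derivative finite at coincident points.
ad_pair_dist <- function(a, b, eps = 1e-12) {
  d2 <- rowSums((a$val - b$val)^2) + eps
  d <- sqrt(d2)
  v <- matrix(d, ncol = 1L)
  ad_node(a$tape, v, list(a, b), function(g) {
    diff <- (a$val - b$val) / d
    gd <- as.numeric(g) * diff
    if (a$requires_grad) ad_accum(a, gd)
    if (b$requires_grad) ad_accum(b, -gd)
  }, requires_grad = a$requires_grad || b$requires_grad)
}
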