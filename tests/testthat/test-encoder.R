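# Encoder contracts: cardinality, eval-mode determinism, permutation
# equivariance, rigid-motion invariance of the pocket encoder, edge-weight
# behaviour, gradient flow, and checkpoint round-trips.

ns <- asNamespace("atomscreen")

make_random_molecule <- function(n, seed) {
  set.seed(seed)
  bonds <- cbind(seq_len(n - 1L), 2:n)  # path graph + one chord
  if (n >= 5L) bonds <- rbind(bonds, c(1L, n))
  els <- sample(c("C", "N", "O", "S"), n, replace = TRUE)
  ns$new_molecule_graph(sprintf("rnd%d", seed), els,
                        sample(0:3, n, replace = TRUE), bonds)
}

test_that("one embedding per atom; surface-only rows for pockets", {
  cfg <- tiny_config()
  Wc <- ns$encoder_init(cfg, "compound")
  g1 <- build_compound_graph("C", "methane")
  e <- embed_compound(g1, cfg, Wc)
  expect_equal(dim(e), c(1L, cfg$embed_dim))

  protein <- random_cloud(25L, seed = 6L)
  S <- 1:9
  pg <- build_pocket_graph(protein, rep(c("C", "N", "O", "S", "C"), 5L), S,
                           x = 3L, y = 2L, z = 2L)
  Wp <- ns$encoder_init(cfg, "pocket")
  ep <- embed_pocket(pg, cfg, Wp)
  expect_equal(nrow(ep), sum(pg$surface_mask))
  expect_true(all(is.finite(ep)))
})

test_that("eval mode is deterministic; train mode applies dropout", {
  cfg <- tiny_config()
  Wc <- ns$encoder_init(cfg, "compound")
  g <- build_compound_graph("CCO", "ethanol")
  e1 <- embed_compound(g, cfg, Wc, mode = "eval")
  e2 <- embed_compound(g, cfg, Wc, mode = "eval")
  expect_identical(e1, e2)
  set.seed(1)
  t1 <- embed_compound(g, cfg, Wc, mode = "train")
  set.seed(2)
  t2 <- embed_compound(g, cfg, Wc, mode = "train")
  expect_false(identical(t1, t2))
})

test_that("compound encoder is permutation-equivariant", {
  cfg <- tiny_config()
  Wc <- ns$encoder_init(cfg, "compound")
  for (seed in 1:5) {
    g <- make_random_molecule(7L, seed)
    set.seed(seed + 100)
    perm <- sample(7L)              # new position i holds old atom perm[i]
    inv <- order(perm)
    gp <- ns$new_molecule_graph(g$mol_id, g$elements[perm],
                                g$h_counts[perm],
                                cbind(inv[g$bonds[, 1L]],
                                      inv[g$bonds[, 2L]]))
    e <- embed_compound(g, cfg, Wc)
    ep <- embed_compound(gp, cfg, Wc)
    expect_lt(max(abs(ep - e[perm, , drop = FALSE])), 1e-5)
  }
})

test_that("pocket embeddings are invariant to rigid motion", {
  cfg <- tiny_config()
  Wp <- ns$encoder_init(cfg, "pocket")
  protein <- random_cloud(30L, seed = 13L)
  els <- rep(c("C", "N", "O"), 10L)
  S <- 1:12
  g0 <- build_pocket_graph(protein, els, S, x = 4L, y = 3L, z = 3L)
  # random rotation (QR of a Gaussian matrix) + translation
  set.seed(99)
  Q <- qr.Q(qr(matrix(rnorm(9), 3L)))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  moved <- protein %*% Q + matrix(rep(c(5, -3, 2), each = 30L), 30L)
  g1 <- build_pocket_graph(moved, els, S, x = 4L, y = 3L, z = 3L)
  e0 <- embed_pocket(g0, cfg, Wp)
  e1 <- embed_pocket(g1, cfg, Wp)
  expect_lt(max(abs(e0 - e1)), 1e-5)
})

test_that("equal edge distances give equal edge weights", {
  cfg <- tiny_config()
  Wp <- ns$encoder_init(cfg, "pocket")
  # unit square: all E1 edges at distance 1 when x = 1
  protein <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1), 0)
  g <- build_pocket_graph(protein, rep("C", 4L), 1:4, x = 1L, y = 1L,
                          z = 1L)
  input <- ns$prepare_pocket_input(g)
  tape <- ns$new_tape()
  pn <- ns$param_nodes(tape, Wp)
  dn <- ns$ad_input(tape, input$edge_dist)
  hidden <- ns$ad_relu(ns$ad_add(ns$ad_matmul(dn, pn$ew_W1), pn$ew_b1))
  w <- ns$ad_relu(ns$ad_add(ns$ad_matmul(hidden, pn$ew_W2), pn$ew_b2))
  expect_equal(diff(range(w$val)), 0)
})

test_that("gradients reach every block of both encoders", {
  cfg <- tiny_config()
  for (kind in c("compound", "pocket")) {
    W <- ns$encoder_init(cfg, kind)
    if (kind == "compound") {
      input <- ns$prepare_compound_input(build_compound_graph("CCO", "x"))
    } else {
      protein <- random_cloud(15L, seed = 21L)
      g <- build_pocket_graph(protein, rep("C", 15L), 1:6, x = 2L, y = 2L,
                              z = 2L)
      input <- ns$prepare_pocket_input(g)
    }
    tape <- ns$new_tape()
    pn <- ns$param_nodes(tape, W)
    Z <- ns$encoder_forward(tape, pn, input, cfg, kind)
    loss <- ns$ad_mean(ns$ad_silu(Z))
    ns$ad_backward(loss)
    for (b in seq_len(cfg$n_blocks)) {
      blk <- grep(sprintf("^b%d\\.", b), names(pn), value = TRUE)
      gnorm <- sum(vapply(blk, function(nm)
        if (is.null(pn[[nm]]$grad)) 0 else sum(abs(pn[[nm]]$grad)),
        numeric(1)))
      expect_gt(gnorm, 0)
    }
  }
})

test_that("checkpoints round trip and refuse mismatched configurations", {
  cfg <- tiny_config()
  model <- list(config = cfg,
                compound_weights = ns$encoder_init(cfg, "compound"),
                pocket_weights = ns$encoder_init(cfg, "pocket"))
  path <- tempfile(fileext = ".json")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_equal(back$compound_weights, model$compound_weights,
               tolerance = 1e-12)
  expect_equal(back$config$embed_dim, cfg$embed_dim)
  g <- build_compound_graph("CCO", "ethanol")
  expect_equal(embed_compound(g, back$config, back$compound_weights),
               embed_compound(g, cfg, model$compound_weights),
               tolerance = 1e-10)
  # weights shaped for a different config are refused
  other <- encoder_config(embed_dim = 4L, n_blocks = 1L, n_heads = 1L,
                          head_dim = 2L)
  expect_error(embed_compound(g, other, model$compound_weights),
               "do not match")
})
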