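# Shared fixtures: a tiny encoder configuration, a quick synthetic world and
# helpers to build random clouds/graphs. Everything is generated in code
# under fixed seeds.

tiny_config <- function(seed = 1L) {
  encoder_config(embed_dim = 8L, n_blocks = 2L, n_heads = 2L, head_dim = 4L,
                 dropout_p = 0.1, edge_mlp_dim = 4L, seed = seed)
}

quick_world <- function(noise = 0, seed = 7L) {
  synthetic_world(n_types = 4L, feature_noise = noise, seed = seed)
}

random_cloud <- function(n, seed, spread = 10) {
  with_seed <- function(s, code) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(s); code
  }
  with_seed(seed, matrix(stats::runif(3L * n, -spread, spread), n, 3L))
}

# Exact kNN by full sort -- the independent oracle for pocket-graph edges.
brute_knn <- function(coords, query, pool, k) {
  lapply(query, function(q) {
    d <- sqrt(colSums((t(coords[pool, , drop = FALSE]) - coords[q, ])^2))
    d[pool == q] <- Inf
    ord <- order(d, pool)
    pool[ord[seq_len(min(k, sum(is.finite(d))))]]
  })
}

# Unordered edge key for set comparisons.
ekey <- function(e) paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))

smiles_fixture <- c(
  "CCO", "CC(=O)O", "c1ccccc1", "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
  "CN1C=NC2=C1C(=O)N(C(=O)N2C)C", "C1CCCCC1", "OCC(O)CO",
  "CC(N)C(=O)O", "c1ccc2ccccc2c1", "CC#N", "ClCCl", "NC(=O)c1ccccc1")
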