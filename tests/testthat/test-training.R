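# Triplet construction, negative-sampling rules, the hard-negative schedule
# and the positive-margin loss.

test_that("interacting pairs match the brute-force all-pairs filter", {
  world <- quick_world()
  cx <- generate_complex(world, 35L, 10L, seed = 17L)
  D <- outer(seq_len(cx$pocket$n_nodes), seq_len(cx$ligand$n_nodes),
             Vectorize(function(i, j)
               sqrt(sum((cx$pocket$coords[i, ] - cx$ligand$coords[j, ])^2))))
  oracle <- which(D <= 4.0, arr.ind = TRUE)
  expect_equal(nrow(cx$pairs), nrow(oracle))
  expect_setequal(paste(cx$pairs$pocket_atom, cx$pairs$ligand_atom),
                  paste(oracle[, 1L], oracle[, 2L]))
  expect_true(all(cx$pairs$distance <= 4.0))
})

test_that("the 4 A boundary is closed and separated clouds give no pairs", {
  # hand geometry: single protein atom exactly 4.0 A from a ligand atom
  protein <- rbind(c(0, 0, 0), c(0, 0.5, 0), c(1, 0, 0), c(0, 1, 0),
                   c(1, 1, 0), c(8, 8, 8))
  pg <- build_pocket_graph(protein, rep("C", 6L), S = 1:5, x = 2L, y = 2L,
                           z = 2L)
  lig <- asNamespace("atomscreen")$new_molecule_graph(
    "l", rep("C", 4L), rep(1L, 4L), cbind(1:3, 2:4),
    coords = rbind(c(4, 0, 0), c(30, 0, 0), c(31, 0, 0), c(32, 0, 0)))
  pr <- extract_interacting_pairs(pg, lig, 4.0)
  expect_true(any(pr$ligand_atom == 1L & abs(pr$distance - 4.0) < 1e-12))
  lig_far <- asNamespace("atomscreen")$new_molecule_graph(
    "f", rep("C", 4L), rep(1L, 4L), cbind(1:3, 2:4),
    coords = matrix(50, 4L, 3L) + diag(4)[, 1:3])
  expect_equal(nrow(extract_interacting_pairs(pg, lig_far, 4.0)), 0L)
  lig_nc <- asNamespace("atomscreen")$new_molecule_graph(
    "n", rep("C", 4L), rep(1L, 4L), cbind(1:3, 2:4))
  expect_error(extract_interacting_pairs(pg, lig_nc), "coordinates")
})

test_that("random negatives come from other complexes, roughly uniformly", {
  pairs <- list(
    a = data.frame(pocket_atom = 1:3, ligand_atom = 1:3, distance = 3),
    b = data.frame(pocket_atom = 1L, ligand_atom = 2L, distance = 3),
    c = data.frame(pocket_atom = 2L, ligand_atom = 4L, distance = 3),
    d = data.frame(pocket_atom = 5L, ligand_atom = 1L, distance = 3))
  set.seed(1)
  draws <- replicate(1000L,
    sample_random_negative(pairs, "a", "ligand")$complex_id)
  expect_false(any(draws == "a"))
  freq <- table(draws) / 1000
  expect_true(all(abs(freq - 1 / 3) < 0.05))
  # batch of one complex is an error
  expect_error(sample_random_negative(pairs["a"], "a"), "at least 2")
  # b = 2: the only other complex is always chosen
  expect_true(all(replicate(20L,
    sample_random_negative(pairs[c("a", "b")], "a")$complex_id) == "b"))
})

test_that("self negatives respect the most-distant-25% rule", {
  anchor <- c(0, 0, 0)
  # 8 atoms at distances 1..8: eligible set is exactly {7, 8}
  coords <- cbind(1:8, 0, 0)
  set.seed(2)
  draws <- replicate(200L, sample_self_negative(anchor, coords, 1L))
  expect_setequal(unique(draws), c(7L, 8L))
  # 4 atoms: single most distant is eligible
  c4 <- cbind(c(1, 2, 3, 9), 0, 0)
  expect_equal(unique(replicate(50L, sample_self_negative(anchor, c4, 1L))),
               4L)
  # positive atom never drawn even when it is among the most distant
  expect_warning(res <- sample_self_negative(anchor, c4, 4L),
                 "no self-negative candidate")
  expect_true(is.na(res))
  expect_warning(sample_self_negative(anchor, coords[1:3, ], 1L),
                 "too small")
})

test_that("hard-negative pool percentile follows the linear schedule", {
  sch <- hard_negative_schedule()
  expect_equal(hard_negative_pool_percentile(0, sch), 99)
  expect_equal(hard_negative_pool_percentile(25, sch), 52)
  expect_equal(hard_negative_pool_percentile(50, sch), 5)
  expect_equal(hard_negative_pool_percentile(120, sch), 5)
  expect_true(all(diff(vapply(0:60, hard_negative_pool_percentile,
                              numeric(1), schedule = sch)) <= 0))
})

test_that("hard negatives come from the nearest eligible pool at end schedule", {
  set.seed(3)
  anchor <- rep(0, 4L)
  cand <- matrix(rnorm(100L * 4L), 100L)
  d <- sqrt(rowSums(cand^2))
  nearest5 <- order(d)[1:5]
  draws <- replicate(300L,
    sample_hard_negative(anchor, cand, rep(TRUE, 100L), epoch = 60L))
  expect_true(all(draws %in% nearest5))
  # exclusions respected; empty pool returns NA
  elig <- rep(FALSE, 100L)
  expect_true(is.na(sample_hard_negative(anchor, cand, elig, 60L)))
  elig[7L] <- TRUE
  expect_equal(sample_hard_negative(anchor, cand, elig, 60L), 7L)
})

test_that("positive margin loss: hand arithmetic and zero characterisation", {
  expect_equal(positive_margin_loss(0.5, 3.0, m = 1, n = 2), 0)
  expect_equal(positive_margin_loss(1.5, 1.0, m = 1, n = 2), 1.5)
  expect_equal(positive_margin_loss(1, 2, m = 1, n = 2), 0)   # closed bounds
  expect_equal(positive_margin_loss(c(0.2, 1.4), c(2.5, 2.5), m = 1, n = 2),
               0.2)
  expect_error(positive_margin_loss(-0.1, 1, m = 1, n = 2), "nonnegative")
  expect_error(positive_margin_loss(1, 1, m = 2, n = 1))
  # zero iff all D+ <= m and all D- >= n (property over random cases)
  set.seed(4)
  for (i in 1:50) {
    Dp <- runif(6L, 0, 3); Dm <- runif(6L, 0, 3)
    L <- positive_margin_loss(Dp, Dm, m = 1, n = 2)
    expect_equal(L == 0, all(Dp <= 1) && all(Dm >= 2))
    expect_gte(L, 0)
  }
})

test_that("configurations at zero positive-margin loss also zero the classic triplet loss", {
  set.seed(5)
  for (i in 1:50) {
    Dp <- runif(5L, 0, 1)         # within m = 1
    Dm <- runif(5L, 2, 4)         # beyond n = 2
    expect_equal(positive_margin_loss(Dp, Dm, m = 1, n = 2), 0)
    # n - m = 1 >= margin  =>  classic loss is 0 as well
    expect_equal(triplet_margin_loss(Dp, Dm, margin = 1), 0)
  }
  # the converse does not hold: relatively-ordered but distant pairs
  expect_equal(triplet_margin_loss(5, 7, margin = 1), 0)
  expect_gt(positive_margin_loss(5, 7, m = 1, n = 2), 0)
})

test_that("zero learning rate leaves the loss trace constant", {
  world <- quick_world()
  cxs <- generate_training_set(world, 4L, seed = 3L, n_pocket_atoms = 25L,
                               n_ligand_atoms = 6L)
  cfg <- tiny_config()
  fit <- suppressMessages(
    train_encoders(cxs, cfg, epochs = 3L, batch_size = 4L, lr = 0,
                   seed = 11L))
  # no updates: final weights equal the seed-derived initialisation
  ns <- asNamespace("atomscreen")
  set.seed(11L)
  Wc0 <- ns$encoder_init(cfg, "compound",
                         seed = sample.int(.Machine$integer.max, 1L))
  Wp0 <- ns$encoder_init(cfg, "pocket",
                         seed = sample.int(.Machine$integer.max, 1L))
  expect_equal(fit$model$compound_weights, Wc0, tolerance = 1e-12)
  expect_equal(fit$model$pocket_weights, Wp0, tolerance = 1e-12)
})

test_that("training is reproducible under a fixed seed", {
  world <- quick_world()
  cxs <- generate_training_set(world, 4L, seed = 5L, n_pocket_atoms = 25L,
                               n_ligand_atoms = 6L)
  cfg <- tiny_config()
  f1 <- suppressMessages(train_encoders(cxs, cfg, epochs = 2L,
                                        batch_size = 4L, seed = 9L))
  f2 <- suppressMessages(train_encoders(cxs, cfg, epochs = 2L,
                                        batch_size = 4L, seed = 9L))
  expect_equal(f1$trace$loss, f2$trace$loss, tolerance = 1e-6)
  expect_equal(f1$model$compound_weights, f2$model$compound_weights,
               tolerance = 1e-8)
})

test_that("a short training run reduces the loss on the synthetic fixture", {
  world <- quick_world(noise = 0)
  cxs <- generate_training_set(world, 10L, seed = 2L, n_pocket_atoms = 30L,
                               n_ligand_atoms = 8L)
  cfg <- tiny_config()
  fit <- suppressMessages(
    train_encoders(cxs, cfg, epochs = 8L, batch_size = 5L, seed = 1L,
                   active_map = synthetic_active_map(cxs)))
  tr <- fit$trace
  expect_lt(mean(tr$loss[tr$epoch == max(tr$epoch)]),
            mean(tr$loss[tr$epoch == 0L]))
})
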