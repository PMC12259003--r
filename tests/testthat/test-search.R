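# Similarity calibration, sharded index and score accumulation against
# exhaustive oracles.

test_that("calibration: boundary pairs, degenerate-but-valid and error cases", {
  set.seed(1)
  # sample with one clearly maximal pair
  d <- c(runif(150L, 0.2, 2), 5)
  cal <- calibrate(d)
  expect_equal(cal$D_max, 5)
  expect_equal(pair_similarity(5, cal), 0)       # most distant pair -> 0
  # all distances equal: valid, t = 0, every similarity 0
  cal0 <- calibrate(rep(2, 200L))
  expect_equal(cal0$D_max, 2)
  expect_equal(cal0$t, 0)
  expect_equal(pair_similarity(2, cal0), 0)
  expect_error(calibrate(rep(0, 200L)), "degenerate")
  expect_error(calibrate(runif(50L)), "at least 100")
})

test_that("noise threshold recovers a known 99th percentile", {
  set.seed(2)
  # distances ~ |N(3, 1)|: s' = D_max - d; t estimates q99(s')
  reps <- replicate(40L, {
    d <- abs(rnorm(1000L, 3, 1))
    cal <- calibrate(d)
    cal$t - unname(quantile(cal$D_max - d, 0.99))
  })
  expect_true(all(abs(reps) < 1e-12))  # definitionally exact on the sample
  # against the population value, within a bootstrap-scale band
  d <- abs(rnorm(5000L, 3, 1))
  cal <- calibrate(d)
  pop_t <- cal$D_max - qnorm(0.01, 3, 1)  # q1 of distances
  expect_lt(abs(cal$t - pop_t), 0.15)
})

test_that("pair similarity is the clamped shifted distance", {
  cal <- structure(list(D_max = 10, t = 2), class = "SimilarityCalibration")
  expect_equal(pair_similarity(5, cal), 3)
  expect_equal(pair_similarity(0, cal), 8)
  expect_equal(pair_similarity(10, cal), 0)
  expect_equal(pair_similarity(8.5, cal), 0)       # beyond D_max - t
  d <- seq(0, 12, by = 0.5)
  s <- pair_similarity(d, cal)
  expect_true(all(diff(s) <= 0))
  expect_true(all(s >= 0))
})

test_that("sharding: ceiling-division sizes and payload round trip", {
  set.seed(3)
  E <- matrix(rnorm(10L * 4L), 10L)
  ids <- sprintf("c%02d", rep(1:5, each = 2L))
  idx <- build_index(E, ids, shard_capacity = 4L)
  expect_equal(unname(vapply(idx$shards, function(s) nrow(s$emb), integer(1))),
               c(4L, 4L, 2L))
  expect_equal(unlist(lapply(idx$shards, `[[`, "compound_id"),
                      use.names = FALSE), ids)
})

test_that("score accumulation equals the brute-force double loop at exhaustive k", {
  set.seed(4)
  n_cmpd <- 50L
  atoms_per <- 10L
  E <- matrix(rnorm(n_cmpd * atoms_per * 6L), n_cmpd * atoms_per)
  ids <- rep(sprintf("c%03d", seq_len(n_cmpd)), each = atoms_per)
  P <- matrix(rnorm(8L * 6L), 8L)
  cal <- calibrate(runif(500L, 0.5, 6))
  oracle <- score_compounds_bruteforce(P, E, ids, cal)
  res <- score_compounds(P, build_index(E, ids), k = nrow(E), cal)
  expect_lt(max(abs(res$score - oracle[res$compound_id])), 1e-6)
  # shard invariance: scores identical for random partitions at full k
  for (cap in c(37L, 100L, 211L)) {
    r2 <- score_compounds(P, build_index(E, ids, shard_capacity = cap),
                          k = nrow(E), cal)
    expect_equal(r2$score[order(r2$compound_id)],
                 res$score[order(res$compound_id)], tolerance = 1e-9)
  }
})

test_that("scores are nonnegative, unretrieved compounds score 0, k grows scores", {
  set.seed(5)
  E <- matrix(rnorm(200L * 4L), 200L)
  ids <- rep(sprintf("c%02d", 1:20), each = 10L)
  P <- matrix(rnorm(5L * 4L), 5L)
  cal <- calibrate(runif(300L, 0.2, 5))
  prev <- NULL
  for (k in c(1L, 4L, 16L, 64L, 200L)) {
    r <- score_compounds(P, build_index(E, ids), k = k, cal)
    sc <- r$score[order(r$compound_id)]
    expect_true(all(sc >= 0))
    if (!is.null(prev)) expect_true(all(sc >= prev - 1e-12))
    prev <- sc
  }
  # all-zero case: distances beyond D_max - t
  calfar <- structure(list(D_max = 0.01, t = 0.005),
                      class = "SimilarityCalibration")
  r0 <- score_compounds(P, build_index(E, ids), k = 10L, calfar)
  expect_true(all(r0$score == 0))
  expect_true(all(r0$contributing_pairs == 0L))
  # ranks are a permutation sorted by score
  r <- score_compounds(P, build_index(E, ids), k = 10L, cal)
  expect_setequal(r$rank, seq_len(20L))
  expect_true(all(diff(r$score) <= 0))
  expect_error(score_compounds(P, build_index(E, ids), k = 0L, cal), "k")
})

test_that("mismatched dimensions and checkpoints are refused", {
  E <- matrix(rnorm(40L), 10L)
  cal <- calibrate(runif(200L, 0.5, 3), checkpoint_id = "ck-A")
  idx <- build_index(E, rep("a", 10L), checkpoint_id = "ck-B")
  expect_error(score_compounds(matrix(0, 2L, 3L), idx, 2L, cal),
               "dimension mismatch")
  expect_error(score_compounds(matrix(0, 2L, 4L), idx, 2L, cal),
               "different checkpoints")
})
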