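# Enrichment factors and inverted (ligand-to-pocket, pocket-to-pocket)
# searches.

test_that("EF: perfect ranking, identity case and parameter errors", {
  # 1240 compounds, 40 actives ranked first, d = 1%: |S_d| = 12, all active
  scores <- c(seq(100, 61), runif(1200L, 0, 50))
  labels <- rep(c(TRUE, FALSE), c(40L, 1200L))
  expect_equal(enrichment_factor(scores, labels, 0.01), (12 / 40) / (12 / 1240))
  expect_equal(enrichment_factor(scores, labels, 0.01), 31.0)
  expect_equal(enrichment_factor(scores, labels, 1), 1)
  # maximal EF at saturating d equals |S|/|A|
  expect_equal(enrichment_factor(scores, labels, 40 / 1240),
               1240 / 40)
  expect_error(enrichment_factor(scores, labels, 0), "\\(0, 1\\]")
  expect_error(enrichment_factor(scores, labels, 1.2), "\\(0, 1\\]")
  expect_error(enrichment_factor(scores, rep(FALSE, 1240L), 0.01),
               "no actives")
})

test_that("EF of random scores averages 1 over shuffles", {
  set.seed(6)
  labels <- rep(c(TRUE, FALSE), c(40L, 360L))
  efs <- replicate(2000L,
    enrichment_factor(runif(400L), labels, 0.1))
  expect_lt(abs(mean(efs) - 1), 0.1)
})

test_that("EF is invariant to monotone score transformations", {
  set.seed(7)
  for (i in 1:20) {
    sc <- runif(100L)
    lb <- runif(100L) < 0.2
    if (!any(lb)) lb[1L] <- TRUE
    e1 <- enrichment_factor(sc, lb, 0.13)
    expect_equal(enrichment_factor(exp(3 * sc) + 2, lb, 0.13), e1)
    expect_equal(enrichment_factor(rank(sc), lb, 0.13), e1)
  }
})

test_that("EF equals the count-based definition on random configurations", {
  set.seed(8)
  for (i in 1:100) {
    n <- sample(20:200, 1L)
    sc <- runif(n)
    lb <- runif(n) < runif(1L, 0.05, 0.5)
    if (!any(lb)) lb[sample(n, 1L)] <- TRUE
    d <- runif(1L, 0.02, 1)
    Sd <- max(1L, round(d * n))
    top <- order(-sc)[seq_len(Sd)]
    expected <- (sum(lb[top]) / sum(lb)) / (Sd / n)
    expect_equal(enrichment_factor(sc, lb, d), expected)
  }
})

test_that("retained counts reproduce the library-scale arithmetic", {
  expect_equal(topN_from_fraction(600e6, 1e-6), 600L)
  expect_equal(topN_from_fraction(600e6, 0.01), 6000000L)
  expect_equal(topN_from_fraction(1234L, 1), 1234L)
  expect_equal(topN_from_fraction(10L, 0.001), 1L)   # floor at 1
  expect_error(topN_from_fraction(100L, 0), "\\(0, 1\\]")
})

test_that("ef_table reports per-target EFs and their unweighted mean", {
  sc1 <- data.frame(compound_id = sprintf("c%02d", 1:40),
                    score = c(seq(40, 21), runif(20L, 0, 10)),
                    active = rep(c(TRUE, FALSE), each = 20L))
  sc2 <- data.frame(compound_id = sprintf("c%02d", 1:40),
                    score = runif(40L),
                    active = rep(c(TRUE, FALSE), each = 20L))
  tab <- ef_table(list(t1 = sc1, t2 = sc2), fractions = 0.5)
  expect_equal(tab$EF[tab$target == "mean"],
               mean(tab$EF[tab$target != "mean"]))
  expect_equal(tab$EF[tab$target == "t1"], 2)   # perfect ranking at d = 0.5
})

test_that("inverted search ranks the self pocket first and leaves zero scores unranked", {
  set.seed(9)
  # 10 synthetic pockets: atoms cluster around a pocket-specific centre
  centres <- matrix(rnorm(10L * 5L, sd = 4), 10L)
  pocket_embs <- lapply(1:10, function(i)
    centres[rep(i, 12L), ] + matrix(rnorm(60L, sd = 0.05), 12L))
  db <- do.call(rbind, pocket_embs)
  ids <- rep(sprintf("p%02d", 1:10), each = 12L)
  cal <- calibrate(runif(500L, 1, 10))
  idx <- build_index(db, ids)
  res <- invert_screen(pocket_embs[[3L]], idx, k = nrow(db), cal)
  expect_equal(res$target_id[which(res$rank == 1L)], "p03")
  # all-zero similarities: a distant query leaves everything unranked
  calz <- structure(list(D_max = 1e-6, t = 0),
                    class = "SimilarityCalibration")
  rz <- invert_screen(pocket_embs[[1L]] + 100, idx, k = 5L, calz)
  expect_true(all(is.na(rz$rank)))
  expect_true(all(rz$score == 0))
})

test_that("pocket-to-pocket accumulation matches the exhaustive oracle and is symmetric", {
  set.seed(10)
  centres <- matrix(rnorm(8L * 4L, sd = 3), 8L)
  pocket_embs <- lapply(1:8, function(i)
    centres[rep(i, 9L), ] + matrix(rnorm(36L, sd = 0.1), 9L))
  db <- do.call(rbind, pocket_embs)
  ids <- rep(sprintf("p%d", 1:8), each = 9L)
  cal <- calibrate(runif(300L, 0.5, 8))
  idx <- build_index(db, ids)
  for (q in c(2L, 5L)) {
    res <- invert_screen(pocket_embs[[q]], idx, k = nrow(db), cal)
    oracle <- score_compounds_bruteforce(pocket_embs[[q]], db, ids, cal)
    expect_equal(res$score[order(res$target_id)],
                 unname(oracle[sort(names(oracle))]), tolerance = 1e-9)
  }
  # symmetry at exhaustive k: S(q -> t) == S(t -> q)
  s12 <- score_compounds_bruteforce(pocket_embs[[1L]],
                                    pocket_embs[[2L]],
                                    rep("x", 9L), cal)
  s21 <- score_compounds_bruteforce(pocket_embs[[2L]],
                                    pocket_embs[[1L]],
                                    rep("x", 9L), cal)
  expect_equal(unname(s12), unname(s21), tolerance = 1e-9)
})
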