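test_that("ranking sorts descending with deterministic and seeded tie handling", {
  scores <- c(0.9, 0.1, 0.5, 0.7, 0.3)
  labels <- c(1, 0, 0, 1, 0)
  scr <- rank_screen(scores, labels)
  expect_equal(scr$score, sort(scores, decreasing = TRUE))
  expect_equal(attr(scr, "N"), 5)
  expect_equal(attr(scr, "A"), 2)

  # all-equal scores fall back to id order
  ids <- c("e", "b", "a", "d", "c")
  tie <- rank_screen(rep(1, 5), labels, ids = ids)
  expect_equal(tie$compound_id, sort(ids))

  # 5-item toy with one tie: documented order (score desc, then id)
  toy <- rank_screen(c(3, 2, 2, 1, 0), c(1, 1, 0, 0, 0),
                     ids = c("a", "c", "b", "d", "e"))
  expect_equal(toy$compound_id, c("a", "b", "c", "d", "e"))

  # seeded shuffle mode is reproducible
  s1 <- rank_screen(rep(1, 5), labels, ids = ids, tie_seed = 9)
  s2 <- rank_screen(rep(1, 5), labels, ids = ids, tie_seed = 9)
  expect_identical(s1$compound_id, s2$compound_id)
  expect_error(rank_screen(numeric(0), logical(0)), "empty")
})

test_that("enrichment factors match the printed maxima and the brute-force count", {
  # perfect ranking on the inactive-enriched benchmark composition
  perfect <- rank_screen(seq(3443, 1), c(rep(1, 67), rep(0, 3443 - 67)))
  expect_equal(round(ef_fraction(perfect), 2), 50.75)
  expect_equal(round(max_ef_fraction(3443, 67), 2), 50.75)
  expect_equal(round(max_ef_fraction(3426, 57), 2), 59.65)

  # top-bin hit density equal to the overall rate gives EF 1
  even <- rank_screen(seq(200, 1), rep(c(1, 0), 100))
  expect_equal(ef_fraction(even), 1)

  # N = 200, A = 10, one active in the top 2 -> (1/10)/0.01 = 10
  lab <- rep(0, 200); lab[2] <- 1; lab[150:158] <- 1
  scr <- rank_screen(seq(200, 1), lab)
  expect_equal(ef_fraction(scr), 10)

  # when all actives fit the top bin the maximum hits 1/f exactly
  expect_equal(max_ef_fraction(5000, 10), 100)
  # integer identity (nonempty top bin): maxEF * A * f = min(floor(f N), A)
  for (N in c(150, 200, 3443)) for (A in c(1, 5, 67)) {
    expect_equal(max_ef_fraction(N, A, 0.01) * A * 0.01,
                 min(floor(0.01 * N), A))
  }
})

test_that("NEF normalizes into [0, 1] with the published random baselines", {
  perfect <- rank_screen(seq(100, 1), c(rep(1, 10), rep(0, 90)))
  expect_equal(nef_fraction(perfect), 1)
  # EF1% = 1 corresponds to the random baselines 0.020 / 0.017
  expect_equal(round(1 / max_ef_fraction(3443, 67), 3), 0.020)
  expect_equal(round(1 / max_ef_fraction(3426, 57), 3), 0.017)
  # invariance under monotone score transforms
  set.seed(8)
  sc <- runif(300); lb <- rbinom(300, 1, 0.1); lb[which.max(sc)] <- 1
  n1 <- nef_fraction(rank_screen(sc, lb))
  n2 <- nef_fraction(rank_screen(qlogis(sc / 2 + 0.25), lb))
  expect_equal(n1, n2)
})

test_that("precision-recall curves behave at the extremes and integrate by steps", {
  perfect <- rank_screen(seq(20, 1), c(rep(1, 5), rep(0, 15)))
  pr <- pr_curve(perfect)
  expect_true(all(pr$points$precision[pr$points$recall <= 1 &
                                        pr$points$recall > 0][1:5] == 1))
  expect_equal(max(pr$points$recall), 1)
  expect_gt(pr$auc, 0.99)

  # inverted ranking minimizes the area among all orderings of a 6-item
  # toy: enumerate every placement of the 2 actives among 6 ranks
  worst <- pr_curve(rank_screen(6:1, c(0, 0, 0, 0, 1, 1)))$auc
  placements <- utils::combn(6, 2)
  areas <- apply(placements, 2, function(pos) {
    lb <- rep(0, 6); lb[pos] <- 1
    pr_curve(rank_screen(6:1, lb))$auc
  })
  expect_equal(min(areas), worst, tolerance = 1e-12)

  # long random list: area concentrates near the active fraction
  set.seed(42)
  areas <- replicate(30, {
    lb <- sample(c(rep(1, 30), rep(0, 570)))
    pr_curve(rank_screen(seq(600, 1), lb))$auc
  })
  expect_lt(abs(mean(areas) - 30 / 600), 0.02)
})

test_that("median-run selection follows the closest-to-median rule with seeded ties", {
  expect_equal(select_median_run(c(0.3, 0.7, 0.5)), 3)
  # [0.2, 0.4, 0.6, 0.8]: median 0.5, both 0.4 and 0.6 tie
  pick <- select_median_run(c(0.2, 0.4, 0.6, 0.8), tie_seed = 5)
  expect_true(pick %in% c(2, 3))
  expect_identical(pick, select_median_run(c(0.2, 0.4, 0.6, 0.8),
                                           tie_seed = 5))
  # all-equal values: reproducible seeded choice
  p1 <- select_median_run(rep(0.5, 6), tie_seed = 2)
  expect_identical(p1, select_median_run(rep(0.5, 6), tie_seed = 2))
})

test_that("dissimilar filtering and nearest-neighbor lookup match brute force", {
  set.seed(31)
  train <- lapply(1:3, function(k) rbinom(128, 1, 0.3))
  test <- lapply(1:5, function(k) rbinom(128, 1, 0.3))
  # plant one test molecule nearly identical to a training molecule
  test[[2]] <- train[[1]]; test[[2]][1:3] <- 1 - test[[2]][1:3]
  sim_matrix <- sapply(train, function(tr)
    sapply(test, function(te) brute_force_tanimoto(te, tr)))
  max_sim <- apply(sim_matrix, 1, max)
  cutoff <- max(max_sim) - 1e-9  # guarantees exactly the top pair removed
  keep <- dissimilar_filter(test, train, cutoff = cutoff)
  expect_equal(keep, max_sim < cutoff)
  expect_equal(sum(!keep), 1)
  # boundary cases
  expect_equal(sum(dissimilar_filter(test, train, cutoff = 0)), 0)
  zero_train <- list(c(1, rep(0, 127)))
  zeroish <- lapply(1:4, function(k) c(0, rep(0, 126), 1))
  expect_true(all(dissimilar_filter(zeroish, zero_train, cutoff = 0.7)))
  # monotone in cutoff
  for (ct in c(0.2, 0.5, 0.8)) {
    expect_lte(sum(dissimilar_filter(test, train, cutoff = ct)),
               sum(dissimilar_filter(test, train, cutoff = ct + 0.1)))
  }

  nn <- nearest_training_similarity(test[[2]], train,
                                    train_ids = c("t1", "t2", "t3"),
                                    train_labels = c("inactive", "active",
                                                     "active"))
  expect_equal(nn$train_id, "t1")
  expect_equal(nn$train_label, "inactive")
  expect_equal(nn$similarity, max_sim[2])
  exact <- nearest_training_similarity(train[[3]], train)
  expect_equal(exact$similarity, 1)
  expect_equal(exact$train_id, "3")
  expect_error(nearest_training_similarity(test[[1]], list()), "empty")
})

test_that("similarity clustering takes transitive closure and ignores input order", {
  base <- c(rep(1, 20), rep(0, 108))
  a <- base
  b <- base; b[1:6] <- 0; b[21:26] <- 1      # sim(a,b) moderate
  c_ <- b;   c_[7:12] <- 0; c_[27:32] <- 1   # sim(b,c) moderate, sim(a,c) low
  sim_ab <- tanimoto(a, b); sim_bc <- tanimoto(b, c_); sim_ac <- tanimoto(a, c_)
  cutoff <- min(sim_ab, sim_bc) - 1e-9
  expect_lt(sim_ac, cutoff)  # chain premise: a-b and b-c linked, a-c not
  cl <- cluster_by_similarity(list(a, b, c_), ids = c("a", "b", "c"),
                              cutoff = cutoff)
  expect_equal(cl$n_clusters, 1)

  # identical molecules collapse; mutually dissimilar ones stay apart
  expect_equal(cluster_by_similarity(list(a, a, a))$n_clusters, 1)
  singletons <- list(c(1, rep(0, 63)), c(0, 1, rep(0, 62)),
                     c(0, 0, 1, rep(0, 61)))
  expect_equal(cluster_by_similarity(singletons)$n_clusters, 3)

  # order invariance of the partition
  fps <- lapply(1:8, function(k) { set.seed(k); rbinom(64, 1, 0.4) })
  ids <- letters[1:8]
  cl1 <- cluster_by_similarity(fps, ids, cutoff = 0.55)
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  cl2 <- cluster_by_similarity(fps[perm], ids[perm], cutoff = 0.55)
  expect_equal(cl1$assignment[ids], cl2$assignment[ids])
})

test_that("NEF group comparison runs Shapiro-Wilk then Welch", {
  g <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  same <- compare_nef_groups(g, g)
  expect_equal(same$welch_p, 1)  # identical groups: statistic 0
  expect_true(all(!is.na(same$normality_p)))

  set.seed(12)
  res <- compare_nef_groups(rnorm(30), rnorm(30, mean = 5))
  expect_lt(res$welch_p, 1e-3)
  expect_equal(unname(res$medians["b"] > res$medians["a"]), TRUE)

  expect_error(compare_nef_groups(c(1, 2), c(1, 2, 3)), "at least 3")
  const <- compare_nef_groups(rep(0.2, 5), c(0.1, 0.3, 0.5))
  expect_true(const$constant["a"])
  expect_true(is.na(const$normality_p["a"]))
})
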