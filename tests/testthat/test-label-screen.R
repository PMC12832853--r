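test_that("candidate set applies the strict-exceed percentile rule", {
  # 131 distinct errors at the median threshold: exactly 65 candidates
  set.seed(1)
  e <- sample(seq_len(131))
  expect_length(candidate_set(e, 50), 65)
  # all errors equal: nothing strictly exceeds the threshold
  expect_length(candidate_set(rep(2, 10), 50), 0)
  # brute-force check on a tiny vector: 50th pct of (1,2,3,4) is 2.5
  expect_equal(sort(candidate_set(c(1, 2, 3, 4), 50)), c(3L, 4L))
  # floor(N/2) whenever the errors are distinct
  for (n in c(10, 33, 131)) {
    e <- runif(n)
    expect_length(candidate_set(e, 50), floor(n / 2))
  }
})

test_that("consensus counts flags over 12 sets with the >= 8 rule", {
  cfg <- screen_config()
  sets <- c(replicate(8, c(1L, 5L), simplify = FALSE),
            replicate(4, c(2L, 5L), simplify = FALSE))
  # sample 1 in 8 of 12 sets -> flagged; sample 2 in 4 -> not
  out <- consensus(sets, cfg, n = 6)
  expect_true(1L %in% out$anomaly)
  expect_false(2L %in% out$anomaly)
  expect_true(5L %in% out$anomaly)
  expect_equal(out$frequency[1], 8)
  # one fewer appearance drops it
  sets7 <- c(replicate(7, 1L, simplify = FALSE),
             replicate(5, 2L, simplify = FALSE))
  expect_length(consensus(sets7, cfg, n = 3)$anomaly, 0)
  # identical sets are returned unchanged in both modes
  same <- replicate(12, c(3L, 9L), simplify = FALSE)
  expect_equal(consensus(same, cfg, n = 10)$anomaly, c(3L, 9L))
  strict <- screen_config(consensus_mode = "strict_all_models")
  expect_equal(consensus(replicate(3, c(3L, 9L), simplify = FALSE),
                         strict)$anomaly, c(3L, 9L))
  # disjoint sets give an empty consensus
  expect_length(consensus(list(1L, 2L, 3L), strict)$anomaly, 0)
})

test_that("frequency consensus shrinks as the count threshold grows", {
  set.seed(4)
  sets <- replicate(12, sample.int(50, 25), simplify = FALSE)
  sizes <- vapply(5:12, function(k)
    length(consensus(sets, screen_config(consensus_min_count = k), n = 50)$anomaly),
    numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("probe errors are near zero for an exactly linear clean cohort", {
  set.seed(2)
  x <- matrix(rnorm(60 * 3), 60, 3)
  y <- as.vector(x %*% c(2, -1, 3)) + 10
  e <- probe_errors(x, y, "ols", screen_config())
  expect_true(all(e < 1e-6))
})

test_that("probe errors are deterministic given the seed", {
  set.seed(2)
  x <- matrix(rnorm(40 * 5), 40, 5)
  y <- rnorm(40)
  set.seed(9); e1 <- probe_errors(x, y, "svr_rbf", screen_config())
  set.seed(9); e2 <- probe_errors(x, y, "svr_rbf", screen_config())
  expect_identical(e1, e2)
})

test_that("a duplicated sample with conflicting labels incurs large error", {
  set.seed(13)
  x <- matrix(rnorm(40 * 2), 40, 2)
  x[40, ] <- x[39, ]
  y <- as.vector(x %*% c(1, 1))
  y[40] <- y[39] + 20
  e <- probe_errors(x, y, "ols", screen_config(n_repeats_per_replicate = 10))
  expect_gt(max(e[39:40]), 10)  # at least one of the pair >= half the gap
})

test_that("screening recovers strongly corrupted gait-cohort labels", {
  cfg <- gen_config(label_noise_frac = 42 / 131,
                    label_noise_range = c(15L, 25L), seed = 7)
  cohort <- generate_cohort(cfg, n_test = 0)
  x <- extract_features(cohort)
  z <- predict(fit_normalizer(x), x)
  scr <- suppressWarnings(screen_labels(z, cohort$bbs, screen_config(seed = 7)))
  inj <- which(cohort$truth$is_noisy)
  expect_length(inj, 42)
  expect_gte(mean(inj %in% scr$anomaly), 0.8)
  # masks partition the training set
  expect_true(all(xor(scr$labeled_mask, scr$unlabeled_mask)))
  expect_equal(sum(scr$labeled_mask) + sum(scr$unlabeled_mask), 131)
  expect_true(all(scr$anomaly %in% which(scr$unlabeled_mask)))
})

test_that("consensus flags never exceed one candidate-set's size", {
  # with the strict-exceed median rule every set holds floor(n/2) samples,
  # so the frequency consensus is bounded above by that size
  lc <- linear_cohort(n = 131, d = 20, noise_sd = 1, seed = 3)
  scr <- suppressWarnings(screen_labels(lc$x, lc$y, screen_config(seed = 3)))
  expect_lte(length(scr$anomaly), 65)
  expect_true(all(lengths(scr$candidate_sets) == 65))
})

test_that("strict mode returns a subset of every model's aggregate set", {
  lc <- linear_cohort(n = 60, d = 10, noise_sd = 3, seed = 5)
  cfg <- screen_config(consensus_mode = "strict_all_models", seed = 5)
  scr <- screen_labels(lc$x, lc$y, cfg)
  for (kind in cfg$probe_models) {
    agg <- candidate_set(scr$errors[, kind], cfg$error_percentile)
    expect_true(all(scr$anomaly %in% agg))
  }
})

test_that("score-dependent noise leads to flagging lower-scored samples", {
  set.seed(17)
  cfg <- gen_config(n_subjects = 131, label_noise_frac = 42 / 131,
                    score_dependent = TRUE, seed = 17)
  cohort <- generate_cohort(cfg, n_test = 0)
  x <- extract_features(cohort)
  z <- predict(fit_normalizer(x), x)
  scr <- suppressWarnings(screen_labels(z, cohort$bbs, screen_config(seed = 17)))
  truth <- cohort$truth
  flagged <- seq_len(131) %in% scr$anomaly
  expect_lt(mean(truth$true_bbs[flagged]), mean(truth$true_bbs[!flagged]))
})
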