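test_that("distance series is Euclidean, normalized and clipped", {
  arena <- arena_spec("rectangle", width_cm = 60, height_cm = 60,
                      target_x_cm = 0, target_y_cm = 0, norm_radius_cm = 25,
                      zone_inner_cm = 5, zone_outer_cm = 17)
  traj <- data.frame(frame_index = 0:3, x_cm = c(0, 3, 25, 28),
                     y_cm = c(0, 4, 0, 0))
  ds <- compute_distance_series(traj, arena)
  expect_equal(ds$distance_cm, c(0, 5, 25, 28))
  expect_equal(ds$distance_norm, c(0, 0.2, 1, 1))  # beyond-normalizer clips
})

test_that("binned rates average spikes per frame within each bin", {
  cfg <- tuning_config(n_bins = 2, n_shuffles = 10)
  ds <- data.frame(distance_cm = c(2, 2, 18, 18),
                   distance_norm = c(0.1, 0.1, 0.9, 0.9))
  class(ds) <- c("distance_series", "data.frame")
  spk <- matrix(c(2, 0, 1, 1), 1)
  b <- bin_firing_by_distance(spk, ds, cfg)
  expect_equal(unname(b$rates[1, ]), c(1.0, 1.0))
  expect_equal(b$occupancy, c(2L, 2L))
  # all frames in one bin leaves the rest undefined
  ds2 <- ds; ds2$distance_norm <- rep(0.05, 4)
  b2 <- bin_firing_by_distance(spk, ds2, tuning_config(n_bins = 4, n_shuffles = 10))
  expect_false(is.na(b2$rates[1, 1]))
  expect_true(all(is.na(b2$rates[1, 2:4])))
  expect_error(bin_firing_by_distance(matrix(1, 1, 5), ds, cfg), "alignment")
})

test_that("occupancy-weighted bin-rate mean equals the global mean rate", {
  arena <- feeding_arena()
  traj <- gen_trajectory(arena, 3000, 1.5, seed = 6)
  ds <- compute_distance_series(traj, arena)
  truth <- sim_truth(5, tuned = c(TRUE, TRUE, FALSE, FALSE, FALSE),
                     preferred_distance_norm = c(0.2, 0.8, 0.5, 0.5, 0.5),
                     amplitude = 0.8, baseline = 0.3)
  spk <- gen_tuned_spikes(traj, arena, truth, seed = 7)
  b <- bin_firing_by_distance(spk, ds)
  occ <- b$occupancy
  for (i in 1:5) {
    r <- b$rates[i, ]
    expect_equal(sum(r * occ, na.rm = TRUE) / sum(occ), mean(spk[i, ]),
                 tolerance = 1e-9)
  }
})

test_that("peak zones follow the 5/17 cm feeding and 10/20 cm social radii", {
  food <- feeding_arena()
  expect_equal(classify_peak_zone(c(3, 10, 20), food),
               c("pro", "neutral", "anti"))
  expect_equal(classify_peak_zone(c(5, 17), food), c("pro", "neutral"))
  soc <- social_arena()
  expect_equal(classify_peak_zone(c(9, 15, 21), soc),
               c("pro", "neutral", "anti"))
})

test_that("rotary shuffle is a circular shift preserving the multiset", {
  x <- c(1, 2, 3, 4)
  expect_equal(rotary_shuffle(x, offset = 1), c(4, 1, 2, 3))
  expect_equal(rotary_shuffle(x, offset = 4), x)     # full turn
  set.seed(2)
  y <- rnorm(50)
  s <- rotary_shuffle(y, seed = 9)
  expect_equal(sort(s), sort(y))
  expect_equal(mean(s), mean(y))
  expect_equal(sum(s), sum(y))
  expect_warning(rotary_shuffle(5), "length")
})

test_that("permutation p-values: add-one formula, constant and zero trains", {
  arena <- feeding_arena()
  traj <- gen_trajectory(arena, 600, 2, seed = 1)
  ds <- compute_distance_series(traj, arena)
  cfg <- tuning_config(n_shuffles = 100, seed = 3)
  # constant train: every shuffle identical -> p = 1; all-zero train -> p = 1
  spk <- rbind(rep(2, 600), rep(0, 600))
  expect_equal(unname(tuning_pvalues(spk, ds, cfg)), c(1, 1))
  # p is never 0 and is bounded below by 1/(n_shuffles + 1)
  traj3 <- gen_trajectory(arena, 3000, 2, seed = 2)
  ds3 <- compute_distance_series(traj3, arena)
  truth <- sim_truth(1, tuned = TRUE, preferred_distance_norm = 0.5,
                     amplitude = 3, baseline = 0.05)
  strong <- gen_tuned_spikes(traj3, arena, truth, seed = 4)
  p <- tuning_pvalues(strong, ds3, cfg)
  expect_equal(unname(p), 1 / 101)   # 0 of 100 exceedances
})

test_that("fft and direct shuffle routes give identical p-values", {
  arena <- feeding_arena()
  traj <- gen_trajectory(arena, 700, 2, seed = 11)
  ds <- compute_distance_series(traj, arena)
  truth <- sim_truth(4, tuned = c(TRUE, FALSE, TRUE, FALSE),
                     preferred_distance_norm = c(0.2, 0.5, 0.9, 0.5),
                     amplitude = 0.5, baseline = 0.2)
  spk <- gen_tuned_spikes(traj, arena, truth, seed = 12)
  cfg <- tuning_config(n_shuffles = 150, seed = 5)
  expect_identical(tuning_pvalues(spk, ds, cfg, method = "fft"),
                   tuning_pvalues(spk, ds, cfg, method = "direct"))
})

test_that("each neuron's p-value is independent of neuron order", {
  arena <- feeding_arena()
  traj <- gen_trajectory(arena, 500, 2, seed = 8)
  ds <- compute_distance_series(traj, arena)
  truth <- sim_truth(4, tuned = TRUE,
                     preferred_distance_norm = c(0.1, 0.4, 0.6, 0.9),
                     amplitude = 0.6, baseline = 0.2)
  spk <- gen_tuned_spikes(traj, arena, truth, seed = 9)
  cfg <- tuning_config(n_shuffles = 50, seed = 2)
  p_all <- tuning_pvalues(spk, ds, cfg)
  perm <- c(3, 1, 4, 2)
  p_perm <- tuning_pvalues(spk[perm, ], ds, cfg)
  expect_identical(p_perm, p_all[perm])
  p_sub <- tuning_pvalues(spk[2:3, , drop = FALSE], ds, cfg)
  expect_identical(p_sub, p_all[2:3])
})

test_that("BH flags match brute-force step-up on known and random vectors", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.2, 0.9), 0.05),
               c(TRUE, TRUE, FALSE, FALSE))
  expect_false(any(bh_adjust(rep(1, 5), 0.05)))
  expect_true(bh_adjust(0.01, 0.05))
  set.seed(33)
  for (rep in 1:200) {
    m <- sample(1:12, 1)
    p <- round(runif(m), 3)
    p[p == 0] <- 0.001
    q <- sample(c(0.01, 0.05, 0.1, 0.25), 1)
    expect_identical(bh_adjust(p, q), bh_bruteforce(p, q))
  }
  expect_error(bh_adjust(c(0.5, 0)), "p-values")
})

test_that("composition test verdicts against degenerate and enriched cases", {
  cfg <- tuning_config(n_shuffles = 500, seed = 4)
  # target population = entire pool -> every resample identical -> ns
  pops <- list(only = rep(c("pro", "anti"), 25))
  expect_equal(composition_test(pops, "only", "pro", cfg)$verdict, "ns")
  # pool at 50% pro, target all pro -> above (hypergeometric tail ~ 0)
  pops2 <- list(a = rep("pro", 20),
                b = rep(c("pro", "neutral"), c(120, 160)))
  ct <- composition_test(pops2, "a", "pro", cfg)
  expect_equal(ct$observed_pct, 100)
  expect_equal(ct$verdict, "above")
  expect_equal(ct$n_selected, 20)
  # exact hypergeometric agreement: P(X >= 20) with 140 pro in a pool of 300
  expect_lt(phyper(19, 140, 160, 20, lower.tail = FALSE), 0.025)
  expect_error(composition_test(list(a = rep("pro", 10)), "a", "pro",
                                tuning_config(n_shuffles = 5)), NA)
})

test_that("composition verdicts agree with exact hypergeometric quantiles", {
  cfg <- tuning_config(n_shuffles = 1000, seed = 10)
  set.seed(91)
  agree <- logical(40)
  for (i in seq_along(agree)) {
    pool_n <- sample(100:300, 1)
    p_pro <- runif(1, 0.1, 0.6)
    labels <- sample(c("pro", "other"), pool_n, replace = TRUE,
                     prob = c(p_pro, 1 - p_pro))
    N <- sample(20:60, 1)
    pops <- list(tgt = sample(labels, N), rest = labels)
    ct <- composition_test(pops, "tgt", "pro",
                           tuning_config(n_shuffles = 1000, seed = i))
    pool <- c(pops$tgt, pops$rest)
    m <- sum(pool == "pro")
    k_obs <- sum(pops$tgt == "pro")
    lo_e <- qhyper(cfg$tail, m, length(pool) - m, N)
    hi_e <- qhyper(1 - cfg$tail, m, length(pool) - m, N)
    exact <- if (k_obs > hi_e) "above" else if (k_obs < lo_e) "below" else "ns"
    agree[i] <- ct$verdict == exact
  }
  expect_gte(mean(agree), 0.95)
})

test_that("distance_tuning fit recovers planted tuning and exposes methods", {
  arena <- feeding_arena()
  traj <- gen_trajectory(arena, 9000, 1.5, seed = 21)
  truth <- sim_truth(12, tuned = rep(c(TRUE, FALSE), 6),
                     preferred_distance_norm = seq(0.1, 0.9, length.out = 12),
                     amplitude = 0.6, baseline = 0.2)
  spk <- gen_tuned_spikes(traj, arena, truth, seed = 22)
  fit <- distance_tuning(spk, traj, arena,
                         tuning_config(n_shuffles = 1000, seed = 23))
  expect_s3_class(fit, "distance_tuning")
  r <- fit$results
  expect_equal(nrow(r), 12)
  expect_true(all(r$p_value > 0 & r$p_value <= 1))
  tuned <- truth$tuned
  expect_gte(mean(r$significant[tuned]), 0.5)
  # peaks of tuned neurons land near the planted bins
  true_bin <- pmin(floor(truth$preferred_distance_norm * 31) + 1, 31)
  expect_lte(median(abs(r$peak_bin[tuned] - true_bin[tuned])), 2)
  expect_output(print(fit), "Distance tuning")
  s <- summary(fit)
  expect_output(print(s), "significant")
  expect_equal(unname(coef(fit)), r$peak_distance_cm)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
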