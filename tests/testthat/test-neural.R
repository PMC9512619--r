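test_that("alignment crops 300-sample windows and z-scores per trial", {
  cfg <- synth_config(session_duration = 60, n_neurons = 6, n_fidgets = 3,
                      seed = 21)
  ev <- schedule_fidgets(cfg)
  tr <- simulate_traces(cfg, ev, NULL, NULL)
  al <- align_and_zscore(tr$dff, ev)
  expect_identical(dim(al$z), c(6L, 3L, 300L))
  # baseline samples of every trial have mean 0 and SD 1 by construction
  for (i in 1:6) for (e in 1:3) {
    b <- al$z[i, e, 1:100]
    expect_lt(abs(mean(b)), 1e-9)
    expect_equal(sd(b), 1, tolerance = 1e-9)
  }
  # events without a full pre window are dropped
  early <- tibble::tibble(onset_frame = 50L, offset_frame = 70L)
  al2 <- align_and_zscore(tr$dff, dplyr::bind_rows(early, ev))
  expect_equal(al2$n_dropped_events, 1)
  expect_identical(dim(al2$z)[2], 3L)
})

test_that("zero-SD baselines are excluded or stabilized per config", {
  dff <- rbind(c(rep(0.2, 150), rep(0.5, 250)),   # constant baseline
               rnorm(400, 0, 0.1))
  ev <- tibble::tibble(onset_frame = 150L, offset_frame = 170L)
  al <- align_and_zscore(dff, ev)
  expect_equal(al$n_zero_sd_trials, 1)
  expect_true(all(is.na(al$z[1, 1, ])))
  al2 <- align_and_zscore(dff, ev, zero_sd = "epsilon")
  expect_equal(al2$n_zero_sd_trials, 0)
  expect_false(anyNA(al2$z[1, 1, ]))
  # mean_responses flags the unusable neuron
  mr <- mean_responses(al, min_trials = 1)
  expect_false(mr$summary$clusterable[1])
  expect_true(mr$summary$clusterable[2])
})

test_that("clustering recovers generator truth and is order-invariant", {
  cfg <- synth_config(session_duration = 120, n_neurons = 300, n_fidgets = 8,
                      noise_sd = 0, seed = 31)
  ev <- schedule_fidgets(cfg)
  tr <- simulate_traces(cfg, ev, NULL, NULL)
  # noise-free: tiny jitter avoids degenerate zero baseline SDs
  set.seed(1)
  dff <- tr$dff + rnorm(length(tr$dff), 0, 1e-4)
  al <- align_and_zscore(dff, ev)
  mr <- mean_responses(al)
  post <- mr$mean_z[, 101:300]
  cl <- cluster_mean_responses(post, k = 4, seed = 3)
  # adjusted Rand index 1 against truth on noise-free data
  expect_equal(adjusted_rand(cl$assignments$cluster, tr$truth$type), 1)
  # neuron order invariance (same seed)
  perm <- sample(nrow(post))
  cl2 <- cluster_mean_responses(post[perm, ], k = 4, seed = 3)
  expect_equal(adjusted_rand(cl2$assignments$cluster,
                             cl$assignments$cluster[perm]), 1)
  # same seed, same assignments
  cl3 <- cluster_mean_responses(post, k = 4, seed = 3)
  expect_identical(cl$assignments, cl3$assignments)
})

test_that("gap statistic selects one cluster for a single Gaussian", {
  set.seed(9)
  g <- matrix(rnorm(400 * 40), 400, 40)
  cl <- cluster_mean_responses(g, k_range = 1:5, n_ref = 10, seed = 2)
  expect_equal(cl$k, 1)
  expect_error(cluster_mean_responses(g, k_range = integer(0)), "k_range")
})

test_that("cluster labeling follows the M/P/L rule", {
  flat <- rep(0, 200)
  sustained_up <- rep(1, 200)
  sustained_down <- rep(-1, 200)
  phasic <- response_templates()$waveforms["phasic", 101:300] * 3
  cents <- rbind(flat, sustained_up, sustained_down, phasic)
  labs <- label_clusters(cents)
  expect_equal(unname(labs), c("neutral", "active", "depressed", "phasic"))
  # full 300-sample centroids work through the pre argument
  cents300 <- cbind(matrix(0, 4, 100), cents)
  expect_equal(unname(label_clusters(cents300, pre = 100)), unname(labs))
})

test_that("threshold criteria relabel only non-neutral neurons", {
  ass <- tibble::tibble(
    neuron_id = 1:4,
    type_label = c("phasic", "active", "neutral", "depressed"),
    mean_dff_post = c(0.07, 0.03, 0.10, -0.08),
    max_dff_post = c(0.12, 0.04, 0.15, 0.00),
    min_dff_post = c(-0.01, -0.01, -0.01, -0.09))
  out <- apply_threshold_criteria(ass, "mean_post")   # > 6%
  expect_equal(out$type_label_criteria,
               c("phasic", "criteria neutral", "neutral", "depressed"))
  out2 <- apply_threshold_criteria(ass, "max_post")   # > 5%
  expect_equal(out2$type_label_criteria[2], "criteria neutral")
  # neutral is never promoted, whatever its dF/F
  expect_equal(out$type_label_criteria[3], "neutral")
  # stricter thresholds give a subset of the looser threshold's passes
  loose <- apply_threshold_criteria(ass, "mean_post", threshold = 0.02)
  strict <- apply_threshold_criteria(ass, "mean_post", threshold = 0.06)
  expect_true(all(which(strict$passes_criterion) %in%
                    which(loose$passes_criterion)))
})

test_that("type distributions are proper percentages by stratum", {
  set.seed(5)
  probs <- c(neutral = 0.528, phasic = 0.139, active = 0.12,
             depressed = 0.213)
  areas <- c("VISp", "VISpm", "VISal", "VISl")
  ass <- tibble::tibble(
    neuron_id = 1:20000,
    type_label = sample(names(probs), 20000, TRUE, probs),
    area = rep(areas, each = 5000),
    depth_um = rep(c(175, 275, 350, 375), times = 5000))
  dist <- type_distribution(ass, "area")
  sums <- tapply(dist$percent, dist$stratum, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  expect_equal(sum(dist$n), 20000)
  # homogeneous cohort: inter-area spread under binomial sampling at
  # n = 5000/area stays below 5 percentage points for every type
  spread <- tapply(dist$percent, dist$type_label, function(x) diff(range(x)))
  expect_true(all(spread < 5))
  dist_l <- type_distribution(ass, "layer")
  expect_setequal(unique(as.character(dist_l$stratum)),
                  c("L2/3", "L4", "L5"))
  expect_error(type_distribution(dplyr::select(ass, -area), "area"), "area")
})
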