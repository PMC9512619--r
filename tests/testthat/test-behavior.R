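test_that("preprocessing normalizes, gamma-compresses and crops", {
  fr <- array(runif(80 * 80 * 4, 0, 255), c(80, 80, 4))
  out <- preprocess_frames(fr, crop = c(10, 10, 74, 74), gamma = 0.5)
  expect_identical(dim(out), c(64L, 64L, 4L))
  expect_true(all(out >= 0 & out <= 1))
  # gamma = 1 is the identity on normalized intensities
  id <- preprocess_frames(fr, gamma = 1)
  rng <- range(fr)
  expect_equal(id[, , 1], (fr[, , 1] - rng[1]) / diff(rng), tolerance = 1e-12)
  # constant stack stays constant
  const <- preprocess_frames(array(0.7, c(40, 40, 2)))
  expect_true(all(const == const[1]))
  expect_error(preprocess_frames(fr, crop = c(0, 1, 10, 10)), "outside")
  expect_error(preprocess_frames(fr, crop = c(10, 10, 90, 20)), "outside")
})

test_that("HOG dimensionality follows the cell/bin layout", {
  fr <- array(runif(64 * 64 * 3), c(64, 64, 3))
  feats <- hog_features(fr, bins = 8, cell_px = 32)
  expect_equal(dim(feats), c(3, (64 / 32)^2 * 8))  # 32 features
  # constant frames have zero gradients everywhere
  flat <- hog_features(array(0.4, c(64, 64, 2)))
  expect_true(all(flat == 0))
  expect_error(hog_features(array(0, c(16, 16, 1))), "smaller")
})

test_that("block features concatenate PCA-reduced frames per second", {
  # 128-px frames give 128 HOG features, enough for 50 components
  fr <- array(runif(128 * 128 * 60), c(128, 128, 60))
  fb <- extract_block_features(fr, fps = 30, n_components = 50)
  expect_identical(dim(fb$blocks), c(2L, 30L * 50L))  # 1500-long vectors
  expect_equal(fb$block_frames$start_frame, c(1L, 31L))
  # inference projects with the stored basis and matches training blocks
  fb2 <- extract_block_features(fr, fps = 30, pca = fb$pca)
  expect_equal(fb$blocks, fb2$blocks, tolerance = 1e-12)
  # refitting on different frames changes the basis (PCA hygiene guard)
  fr2 <- array(runif(128 * 128 * 60), c(128, 128, 60))
  fb3 <- extract_block_features(fr2, fps = 30, n_components = 50)
  expect_false(isTRUE(all.equal(fb3$pca$rotation, fb$pca$rotation)))
  expect_warning(extract_block_features(fr[, , 1:10], fps = 30), "block")
})

test_that("detector trains, grid-searches and round-trips predictions", {
  cfg1 <- tiny_config(session_duration = 40, n_fidgets = 3, seed = 101)
  cfg2 <- tiny_config(session_duration = 40, n_fidgets = 3, seed = 102)
  v1 <- simulate_video(cfg1); v2 <- simulate_video(cfg2)
  det <- train_fidget_detector(list(v1$frames, v2$frames),
                               list(v1$labels, v2$labels),
                               crop = c(8, 8, 72, 72),
                               cost_grid = c(1, 10), gamma_grid = c(0.01, 0.1),
                               cv_folds = 2, seed = 5)
  expect_s3_class(det, "fidget_detector")
  # the selected pair attains the maximal CV score in the grid
  tun <- tidy(det)
  expect_equal(tun$cv_accuracy[tun$selected], max(tun$cv_accuracy))
  expect_equal(nrow(tun), 4)
  # serialization round-trip reproduces a stored validation block label
  rt <- unserialize(serialize(det, NULL))
  expect_identical(as.character(predict(rt$svm, rt$validation$block)),
                   rt$validation$label)
  # prediction covers every frame, deterministic
  tr1 <- predict(det, v1$frames)
  expect_equal(nrow(tr1), dim(v1$frames)[3])
  expect_identical(tr1, predict(det, v1$frames))
  expect_error(train_fidget_detector(list(v1$frames), list(v1$labels),
                                     cost_grid = numeric(0)), "grid")
})

test_that("detector rejects single-class training labels", {
  cfg <- tiny_config(session_duration = 20, n_fidgets = 0, seed = 7)
  v <- simulate_video(cfg)
  lab <- v$labels
  lab$label <- factor("resting", levels = behavior_levels())
  expect_error(train_fidget_detector(v$frames, lab), "single class")
})

test_that("block predictions broadcast to frames with resting tail", {
  # synthetic 95-frame track built from a fake 3-block prediction
  cfg <- tiny_config(session_duration = 40, n_fidgets = 4, seed = 110)
  v <- simulate_video(cfg)
  det <- train_fidget_detector(v$frames, v$labels, crop = c(8, 8, 72, 72),
                               cost_grid = 10, gamma_grid = 0.01,
                               cv_folds = 2, seed = 5)
  track <- predict(det, v$frames[, , 1:95])
  expect_equal(nrow(track), 95)
  # trailing partial block (frames 91-95) is resting by contract
  expect_true(all(track$label[91:95] == "resting"))
  # full blocks are constant within each 30-frame span
  expect_equal(length(unique(track$label[1:30])), 1L)
  expect_equal(length(unique(track$label[31:60])), 1L)
})

test_that("event extraction merges, filters and conserves frames", {
  lab <- rep("resting", 9)
  lab[c(1, 2, 3, 6, 7)] <- "fidget"
  ev <- extract_events(lab, min_duration = 2, merge_gap = 0)
  expect_equal(ev$onset_frame, c(1L, 6L))
  expect_equal(ev$offset_frame, c(4L, 8L))
  ev2 <- extract_events(lab, min_duration = 3, merge_gap = 0)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$onset_frame, 1L)
  # merging across a small gap fuses the two runs
  ev3 <- extract_events(lab, min_duration = 2, merge_gap = 2)
  expect_equal(nrow(ev3), 1)
  expect_equal(ev3$duration_frames, 7L)
  expect_equal(nrow(extract_events(rep("resting", 5))), 0)
  # conservation: merge_gap 0, min_duration 1 preserves fidget frame count
  set.seed(3)
  for (i in 1:20) {
    lab <- sample(c("fidget", "resting", "movement"), 60, replace = TRUE)
    ev <- extract_events(lab, min_duration = 1, merge_gap = 0)
    expect_equal(sum(ev$duration_frames), sum(lab == "fidget"))
  }
})

test_that("detection scoring handles overlap, symmetry and edge cases", {
  truth <- tibble::tibble(onset_frame = c(10L, 50L),
                          offset_frame = c(20L, 60L))
  # perfect prediction
  m <- score_detection(truth, truth)
  expect_equal(m$precision, 1); expect_equal(m$recall, 1)
  # one overlapping + one spurious prediction
  pred <- tibble::tibble(onset_frame = c(12L, 80L), offset_frame = c(18L, 90L))
  m2 <- score_detection(pred, truth)
  expect_equal(m2$precision, 0.5); expect_equal(m2$recall, 0.5)
  # swapping prediction and truth swaps precision and recall
  m3 <- score_detection(truth, pred)
  expect_equal(m3$precision, m2$recall); expect_equal(m3$recall, m2$precision)
  # no predictions
  none <- tibble::tibble(onset_frame = integer(), offset_frame = integer())
  m4 <- score_detection(none, truth)
  expect_equal(m4$precision, 0); expect_equal(m4$recall, 0)
  expect_equal(m4$flag, "no predictions")
  m5 <- score_detection(pred, none)
  expect_true(is.na(m5$recall)); expect_equal(m5$flag, "no true events")
  # frame-level scoring agrees with hand-counted confusion
  mf <- score_detection(pred, truth, level = "frame", n_frames = 100)
  expect_equal(mf$precision, 6 / 16)   # 6 overlapping of 16 predicted frames
  expect_equal(mf$recall, 6 / 20)
})

test_that("normalized fidget rate follows the gray-baseline formula", {
  # 4 one-minute epochs: gray at 1/min, gratings at 2/min, per-epoch rates
  # (1, 2, 1, 2) have SD sqrt(1/3)... construct instead epochs whose rates
  # are (1, 2, 1.5, 0.5) with gray = 1 and SD computed explicitly.
  fps <- 30
  stim <- tibble::tibble(
    start_frame = as.integer(c(1, 1801, 3601, 5401)),
    end_frame = as.integer(c(1801, 3601, 5401, 7201)),
    stimulus_type = c("gray", "grating", "gray", "grating"),
    direction_deg = c(NA, 0, NA, 45),
    temporal_frequency_hz = c(NA, 1, NA, 1))
  onsets <- as.integer(c(100, 1900, 2000, 2100, 3700, 5500, 5600))
  ev <- tibble::tibble(onset_frame = onsets)
  out <- normalized_fidget_rate(ev, stim, fps = fps)
  rates <- c(1, 3, 1, 2)  # events/min per epoch
  expected_sd <- sd(rates)
  gray_rate <- 2 / 2      # 2 events in 2 gray minutes
  grating_rate <- 5 / 2
  norm <- (grating_rate - gray_rate) / expected_sd
  expect_equal(out$rate_per_min[out$stimulus_type == "grating"], grating_rate)
  expect_equal(out$normalized_rate[out$stimulus_type == "grating"], norm)
  expect_equal(out$normalized_rate[out$stimulus_type == "gray"], 0)
  expect_error(normalized_fidget_rate(ev, dplyr::mutate(
    stim, stimulus_type = "grating")), "gray")
})
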