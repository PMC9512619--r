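# A minimal stimulus table: `conds` rows of (direction, tf), each trial
# `len` frames with no gaps, starting at `start`.
stim_from_conds <- function(conds, len = 10L, start = 1L) {
  n <- nrow(conds)
  tibble::tibble(
    start_frame = start + (seq_len(n) - 1L) * len,
    end_frame = start + seq_len(n) * len,
    stimulus_type = "grating",
    direction_deg = conds$direction_deg,
    temporal_frequency_hz = conds$temporal_frequency_hz)
}

test_that("preferred condition is the argmax with documented tie-break", {
  conds <- expand.grid(direction_deg = seq(0, 315, 45),
                       temporal_frequency_hz = c(1, 2, 4, 8, 15))
  stim <- stim_from_conds(conds)
  dff <- matrix(0, 2, max(stim$end_frame))
  # neuron 1 responds only to (90, 4)
  sel <- which(conds$direction_deg == 90 & conds$temporal_frequency_hz == 4)
  dff[1, stim$start_frame[sel]:(stim$end_frame[sel] - 1)] <- 1
  # neuron 2 ties exactly between (0, 2) and (45, 8)
  for (s in which((conds$direction_deg == 0 & conds$temporal_frequency_hz == 2) |
                  (conds$direction_deg == 45 & conds$temporal_frequency_hz == 8))) {
    dff[2, stim$start_frame[s]:(stim$end_frame[s] - 1)] <- 1
  }
  pref <- preferred_condition(dff, stim)
  expect_equal(pref$direction_deg[1], 90)
  expect_equal(pref$temporal_frequency_hz[1], 4)
  expect_equal(pref$direction_deg[2], 0)    # lower direction wins the tie
  expect_equal(pref$temporal_frequency_hz[2], 2)
  expect_true(all(pref$temporal_frequency_hz %in% c(1, 2, 4, 8, 15)))
  expect_error(preferred_condition(dff, dplyr::mutate(
    stim, stimulus_type = "gray")), "grating")
})

test_that("state modulation implements Cohen's d with the SD norm", {
  # one condition, 6 frames per trial, 2 trials; state 1 covers trial 1
  stim <- stim_from_conds(tibble::tibble(direction_deg = 0,
                                         temporal_frequency_hz = 1)[c(1, 1), ],
                          len = 3L)
  x1 <- c(-1, 2, 5)   # mean 2, sd 3
  x2 <- c(-3, 1, 5)   # mean 1, sd 4
  dff <- matrix(c(x1, x2), 1)
  mask <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  pref <- preferred_condition(dff, stim)
  out <- state_modulation(dff, stim, mask, pref)
  expect_equal(out$cohens_d, (2 - 1) / 5)        # s = sqrt(9 + 16)
  out_pooled <- state_modulation(dff, stim, mask, pref, sd_norm = "pooled")
  expect_equal(out_pooled$cohens_d, 1 / sqrt(25 / 2))
  # swapping states negates d
  out_sw <- state_modulation(dff, stim, !mask, pref)
  expect_equal(out_sw$cohens_d, -out$cohens_d)
  # identical distributions give d = 0
  dff0 <- matrix(rep(x1, 2), 1)
  out0 <- state_modulation(dff0, stim, mask, preferred_condition(dff0, stim))
  expect_equal(out0$cohens_d, 0)
  # a state with no preferred-condition frames is flagged
  outNA <- state_modulation(dff, stim, rep(FALSE, 6), pref)
  expect_equal(outNA$flag, "undefined")
})

test_that("per-cell KS + BH significance matches the step-up enumeration", {
  set.seed(8)
  # identical samples: p = 1, not significant
  s <- rnorm(20)
  out <- per_cell_significance(list(s), list(s))
  expect_equal(out$p_value, 1)
  expect_false(out$q_significant)
  # insufficient samples flagged untestable
  out2 <- per_cell_significance(list(1), list(rnorm(5)))
  expect_equal(out2$flag, "untestable")
  # BH step-up against exhaustive oracle on random p-vectors (n <= 12)
  for (i in 1:50) {
    m <- sample(1:12, 1)
    p <- round(runif(m), 3)
    flags <- p.adjust(p, "BH") < 0.05
    expect_identical(flags, bh_stepup_oracle(p, 0.05))
  }
  # the spec-style worked example: exactly the two smallest rejected
  p <- c(0.01, 0.02, 0.04, 0.8)
  expect_identical(bh_stepup_oracle(p, 0.05), c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(unname(p.adjust(p, "BH") < 0.05),
                   c(TRUE, TRUE, FALSE, FALSE))
})

test_that("modulation interaction reports covariance and joint fractions", {
  d <- rnorm(50)
  out <- modulation_interaction(d, d, rep(TRUE, 50), rep(TRUE, 50))
  expect_equal(out$correlation, 1)
  # sig_running = {a,b,c,d}, sig_fidget = {a}: fraction 0.25
  sr <- c(rep(TRUE, 4), rep(FALSE, 46))
  sf <- c(TRUE, rep(FALSE, 49))
  out2 <- modulation_interaction(d, rnorm(50), sf, sr)
  expect_equal(out2$joint_fraction, 0.25)
  # independent d vectors are uncorrelated within sampling bounds
  set.seed(13)
  a <- rnorm(1000); b <- rnorm(1000)
  out3 <- modulation_interaction(a, b, a > 1, b > 1)
  expect_lt(abs(out3$correlation), 0.1)
  # no running-modulated cells: fraction undefined
  out4 <- modulation_interaction(d, d, sf, rep(FALSE, 50))
  expect_true(is.na(out4$joint_fraction))
  # per-type breakdown covers all supplied cells
  out5 <- modulation_interaction(d, d, sf, sr,
                                 type_label = rep(c("phasic", "neutral"), 25))
  expect_equal(sum(out5$by_type$n), 50)
})

test_that("tuning metrics compute DSI with the opposite-direction null", {
  conds <- expand.grid(direction_deg = seq(0, 315, 45),
                       temporal_frequency_hz = c(1, 2, 4, 8, 15))
  stim <- stim_from_conds(conds)
  dff <- matrix(0, 3, max(stim$end_frame))
  put <- function(i, dir, tf, val) {
    s <- which(conds$direction_deg == dir & conds$temporal_frequency_hz == tf)
    dff[i, stim$start_frame[s]:(stim$end_frame[s] - 1)] <<- val
  }
  put(1, 90, 4, 1)                   # responds only at preferred: DSI = 1
  put(2, 0, 1, 3); put(2, 180, 1, 1) # R_pref 3, R_null 1: DSI = 0.5
  for (d in seq(0, 315, 45)) put(3, d, 2, 1)  # no direction preference
  tm <- tuning_metrics(dff, stim)
  expect_equal(tm$dsi[1], 1)
  expect_equal(tm$dsi[2], 0.5)
  expect_equal(tm$dsi[3], 0)
  expect_equal(tm$pref_orientation[1], 90)
  expect_equal(tm$pref_orientation[2], 0)
})

test_that("state masks split frames into fidget and sustained running", {
  ev <- tibble::tibble(onset_frame = 10L, offset_frame = 20L)
  speed <- rep(0, 100)
  speed[40:80] <- 10        # sustained running
  speed[15] <- 5            # brief blip inside a fidget
  speed[90] <- 30           # sub-second blip
  m <- state_masks(100, ev, speed, fps = 30, min_duration_s = 1)
  expect_true(all(m$fidget[10:19])); expect_false(any(m$fidget[-(10:19)]))
  expect_true(all(m$running[40:80]))
  expect_false(m$running[90])       # too brief to count as running
  expect_false(any(m$fidget & m$running))
})
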