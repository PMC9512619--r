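test_that("response templates are causal, typed and indicator-shaped", {
  tpl <- response_templates(indicator_decay_tau = 0.7, fps = 30)
  w <- tpl$waveforms
  expect_identical(dim(w), c(4L, 300L))
  # pre-onset causality for every archetype
  expect_true(all(w[, 1:100] == 0))
  # neutral is identically zero
  expect_true(all(w["neutral", ] == 0))
  # phasic decays exponentially: 3 s past the peak it is down to exp(-3/0.7)
  peak_idx <- which.max(w["phasic", ])
  val <- unname(w["phasic", peak_idx + 90])   # 3 s at 30 fps
  expect_equal(val / max(w["phasic", ]), exp(-3 / 0.7), tolerance = 0.01)
  # active sustains, depressed is its negative-going counterpart
  expect_gt(mean(w["active", 200:300]), 0.9)
  expect_lt(mean(w["depressed", 200:300]), -0.9)
  expect_error(response_templates(indicator_decay_tau = 0), "tau")
})

test_that("stimulus table lays out the drifting-grating protocol", {
  cfg <- synth_config(session_duration = 40 * 60, seed = 2)  # long session
  stim <- simulate_stimulus(cfg, n_repeats = 15)
  gr <- stim[stim$stimulus_type == "grating", ]
  expect_equal(nrow(gr), 8 * 5 * 15)
  expect_setequal(unique(gr$direction_deg), seq(0, 315, by = 45))
  expect_setequal(unique(gr$temporal_frequency_hz), c(1, 2, 4, 8, 15))
  # 2 s gratings and 1 s gray gaps at 30 Hz
  expect_true(all(gr$end_frame - gr$start_frame == 60))
  gaps <- stim[stim$stimulus_type == "gray", ]
  expect_true(all(gaps$end_frame - gaps$start_frame == 30))
  # blanks appear roughly once every 20 gratings
  expect_equal(sum(stim$stimulus_type == "blank"), nrow(gr) %/% 20,
               tolerance = 1)
  # epochs tile without overlap
  expect_true(all(stim$start_frame[-1] == head(stim$end_frame, -1)))
})

test_that("stimulus table rejects impossible requests and allows empty ones", {
  cfg <- synth_config(session_duration = 60)
  expect_error(simulate_stimulus(cfg, n_repeats = 15), "too short")
  empty <- simulate_stimulus(cfg, n_repeats = 0)
  expect_equal(sum(empty$stimulus_type == "grating"), 0)
  expect_true(nrow(empty) >= 1)  # still a valid table with a gray epoch
})

test_that("video session has consistent frames, labels and truth", {
  cfg <- tiny_config(session_duration = 20, n_fidgets = 2)
  v <- simulate_video(cfg)
  expect_identical(dim(v$frames), c(80L, 80L, 600L))
  expect_equal(nrow(v$labels), 600)
  expect_true(all(v$frames >= 0 & v$frames <= 1))
  # label consistency: fidget-labeled frames equal summed true durations
  expect_equal(sum(v$labels$label == "fidget"),
               sum(v$events$duration_frames))
  # all events inside the session
  expect_true(all(v$events$onset_frame >= 1 &
                    v$events$offset_frame <= 600 + 1))
})

test_that("generator is deterministic and respects n_fidgets = 0", {
  cfg <- tiny_config(session_duration = 15)
  v1 <- simulate_video(cfg)
  v2 <- simulate_video(cfg)
  expect_identical(v1$frames, v2$frames)
  expect_identical(v1$labels, v2$labels)
  v0 <- simulate_video(tiny_config(session_duration = 15, n_fidgets = 0))
  expect_equal(sum(v0$labels$label == "fidget"), 0)
  expect_equal(nrow(v0$events), 0)
})

test_that("trace generator embeds exact templates at zero noise", {
  cfg <- synth_config(session_duration = 30, n_neurons = 40, n_fidgets = 1,
                      noise_sd = 0, seed = 11,
                      type_probs = c(0, 1, 0, 0))  # all phasic
  ev <- schedule_fidgets(cfg)
  tr <- simulate_traces(cfg, ev, NULL, NULL)
  tpl <- response_templates()$waveforms["phasic", 101:300]
  o <- ev$onset_frame[1]
  for (i in c(1, 20)) {
    seg <- tr$dff[i, o:(o + 199)]
    expect_lt(max(abs(seg - tr$truth$event_scale[i] * tpl)), 1e-9)
  }
  # pre-onset trace is flat at zero noise
  expect_lt(max(abs(tr$dff[1, 1:(o - 1)])), 1e-12)
})

test_that("trace generator validates probabilities and recovers prevalences", {
  cfg <- tiny_config()
  expect_error(simulate_traces(cfg, NULL, NULL, NULL,
                               type_probs = c(0.5, 0.5, 0.5, 0.5)), "sum")
  # chi-square GOF: empirical type frequencies match type_probs at n = 10,000
  cfg2 <- synth_config(session_duration = 10, n_neurons = 10000,
                       n_fidgets = 0, seed = 77)
  tr <- simulate_traces(cfg2, NULL, NULL, NULL)
  counts <- table(tr$truth$type)
  gof <- chisq.test(counts, p = cfg2$type_probs[names(counts)])
  expect_gt(gof$p.value, 0.01)
})

test_that("cohorts cycle metadata and apply area prevalence shifts", {
  cfg <- tiny_config(session_duration = 30, n_fidgets = 1, n_neurons = 4)
  coh <- simulate_cohort(12, cfg)
  areas <- vapply(coh, function(s) s$meta$area, character(1))
  expect_equal(unique(table(areas))[[1]], 3L)  # 12 sessions over 4 areas
  expect_equal(length(coh), 12)
  # null cohort: every session generated from identical type probabilities
  expect_equal(cfg$area_effect, 0)
  # positive control arithmetic on the truth side
  p <- shift_type_probs(cfg$type_probs, "phasic", 0.2)
  expect_equal(unname(p["phasic"]), unname(cfg$type_probs["phasic"]) + 0.2)
  expect_equal(sum(p), 1)
  expect_error(simulate_cohort(0, cfg), "n_sessions")
  expect_error(simulate_cohort(2, cfg, areas = character(0)), "areas")
})

test_that("depth maps to layer per the cohort convention", {
  expect_equal(depth_to_layer(c(175, 275, 350, 375)),
               c("L2/3", "L4", "L4", "L5"))
  expect_error(depth_to_layer(200), "unknown")
})
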