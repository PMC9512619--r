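#' Run the full fidget analysis pipeline on a synthetic cohort
#'
#' Orchestrates every stage end to end on generated data: simulate a cohort,
#' detect fidgets on the behavioral video of the held-out session (detector
#' trained on the remaining sessions), quantify event magnitudes with
#' optical flow, align and z-score the neural traces of every session to
#' the true fidget onsets, cluster mean responses and label the four types,
#' tabulate type distributions by area and layer, test area/layer
#' decodability against shuffled baselines, and compute fidget/running
#' modulation statistics. All stage outputs are written to `out_dir` as CSV
#' or JSON together with a markdown report and the resolved configuration;
#' the run is deterministic given `seed`.
#'
#' Stage seeds are derived from the global `seed` by fixed offsets, so
#' individual stages can be reproduced in isolation.
#'
#' @param config Base [synth_config()] for the cohort sessions.
#' @param out_dir Output directory (created if needed).
#' @param n_sessions Number of sessions in the cohort.
#' @param seed Global seed; overrides `config$seed`.
#' @param detect_video Train/apply the video detector on the last session
#'   (the slowest stage; when `FALSE`, ground-truth labels stand in for
#'   detected ones and no video is rendered).
#' @param n_shuffles Shuffle repetitions for the decode baseline.
#' @return Invisibly, a list with each stage's outputs.
#' @export
run_fidget_pipeline <- function(config, out_dir, n_sessions = 4L,
                                seed = 1L, detect_video = FALSE,
                                n_shuffles = 5L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config$seed <- as.integer(seed)
  cfg_json <- unclass(config)
  cfg_json$type_probs <- as.list(cfg_json$type_probs)
  jsonlite::write_json(cfg_json, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)

  # stage 1: simulate
  cohort <- simulate_cohort(n_sessions, config, render = FALSE)

  # stage 2: behavior (optional video detection on the held-out session)
  detection <- NULL
  if (detect_video) {
    if (n_sessions < 2) abort("video detection needs >= 2 sessions")
    train_idx <- seq_len(n_sessions - 1L)
    videos <- lapply(train_idx, function(i) {
      function() render_session_frames(cohort[[i]]$config,
                                       cohort[[i]]$events,
                                       cohort[[i]]$running_bouts)
    })
    labels <- lapply(train_idx, function(i) cohort[[i]]$labels)
    det <- train_fidget_detector(videos, labels,
                                 seed = derive_seed(seed, 201L))
    rm(videos)
    test <- cohort[[n_sessions]]
    test_frames <- render_session_frames(test$config, test$events,
                                         test$running_bouts)
    track <- predict(det, test_frames,
                     stride = max(1L, as.integer(round(config$fps / 2))))
    pred_events <- extract_events(track)
    pred_events <- event_magnitude(
      preprocess_frames(test_frames, crop = det$feature_config$crop,
                        gamma = det$feature_config$gamma), pred_events)
    rm(test_frames)
    metrics <- score_detection(pred_events, test$events)
    write_events_csv(pred_events, file.path(out_dir, "detected_events.csv"))
    readr::write_csv(metrics, file.path(out_dir, "detection_metrics.csv"))
    detection <- list(detector = det, events = pred_events,
                      metrics = metrics)
  }

  # stage 3: neural alignment + clustering across the cohort
  per_session <- lapply(seq_along(cohort), function(i) {
    s <- cohort[[i]]
    aligned <- align_and_zscore(s$dff, s$events)
    mr <- mean_responses(aligned)
    keep <- mr$summary$clusterable
    tibble(session = i, neuron_id = mr$summary$neuron_id,
           n_trials = mr$summary$n_trials,
           mean_dff_post = mr$summary$mean_dff_post,
           max_dff_post = mr$summary$max_dff_post,
           min_dff_post = mr$summary$min_dff_post,
           clusterable = keep,
           area = s$meta$area, depth_um = s$meta$depth_um,
           layer = s$meta$layer, cre_line = s$meta$cre_line,
           true_type = as.character(s$truth$type)) |>
      bind_cols(as_tibble(mr$mean_z[, (aligned$pre + 1L):(aligned$pre + aligned$post),
                                    drop = FALSE],
                          .name_repair = ~ paste0("z", seq_len(200L))))
  })
  neurons <- list_rbind(per_session) |> filter(.data$clusterable)
  post_z <- as.matrix(neurons[, paste0("z", 1:200)])
  clus <- cluster_mean_responses(post_z, seed = derive_seed(seed, 202L))
  types <- label_clusters(clus$centroids)
  assignments <- neurons |>
    select(-dplyr::starts_with("z")) |>
    mutate(cluster = clus$assignments$cluster,
           type_label = types[clus$assignments$cluster])
  readr::write_csv(assignments, file.path(out_dir, "assignments.csv"))
  dist_area <- type_distribution(assignments, "area")
  dist_layer <- type_distribution(assignments, "layer")
  readr::write_csv(dist_area, file.path(out_dir, "type_distribution_area.csv"))
  readr::write_csv(dist_layer, file.path(out_dir, "type_distribution_layer.csv"))

  # stage 4: decodability with shuffled baseline (label sets that vary)
  label_sets <- c(area = "area", layer = "layer")
  label_sets <- label_sets[vapply(label_sets, function(l) {
    length(unique(assignments[[l]])) >= 2
  }, logical(1))]
  emb <- embed_responses(
    post_z,
    n_neighbors = min(20L, nrow(post_z) - 1L),
    seed = derive_seed(seed, 203L))
  decode <- lapply(label_sets, function(lbl) {
    r <- train_and_score_decoder(emb, assignments[[lbl]],
                                 seed = derive_seed(seed, 204L))
    r$label_set <- lbl
    shuffle_baseline(emb, assignments[[lbl]], n_shuffles = n_shuffles,
                     seed = derive_seed(seed, 205L), result = r)
  })
  jsonlite::write_json(
    lapply(decode, function(r) list(label_set = r$label_set,
                                    mean_f1 = r$mean_f1,
                                    baseline_mean_f1 = r$baseline_mean_f1,
                                    per_class = r$f1)),
    file.path(out_dir, "decode_results.json"), auto_unbox = TRUE, digits = NA)

  # stage 5: modulation on the first session
  s1 <- cohort[[1]]
  masks <- state_masks(ncol(s1$dff), s1$events, s1$running_speed,
                       fps = config$fps)
  pref <- preferred_condition(s1$dff, s1$stim_table)
  mod_fidget <- state_modulation(s1$dff, s1$stim_table, masks$fidget, pref,
                                 "fidget/nonfidget")
  mod_running <- state_modulation(s1$dff, s1$stim_table, masks$running, pref,
                                  "running/stationary")
  sig_f <- significance_from_modulation(s1$dff, s1$stim_table, masks$fidget,
                                        pref)
  sig_r <- significance_from_modulation(s1$dff, s1$stim_table, masks$running,
                                        pref)
  s1_types <- rep(NA_character_, nrow(s1$dff))
  s1_ass <- assignments[assignments$session == 1, ]
  s1_types[s1_ass$neuron_id] <- s1_ass$type_label
  interaction <- modulation_interaction(
    mod_fidget$cohens_d, mod_running$cohens_d,
    sig_f$q_significant, sig_r$q_significant,
    type_label = s1_types[mod_fidget$neuron_id])
  tuning <- tuning_metrics(s1$dff, s1$stim_table)
  mod_table <- tibble(neuron_id = mod_fidget$neuron_id,
                      d_fidget = mod_fidget$cohens_d,
                      d_running = mod_running$cohens_d,
                      p_fidget = sig_f$p_value, p_running = sig_r$p_value,
                      q_sig_fidget = sig_f$q_significant,
                      q_sig_running = sig_r$q_significant) |>
    left_join(tuning, by = "neuron_id")
  readr::write_csv(mod_table, file.path(out_dir, "modulation.csv"))

  report <- c(
    "# Fidget pipeline report", "",
    sprintf("Sessions: %d; neurons clustered: %d; seed: %d",
            n_sessions, nrow(assignments), seed),
    "",
    sprintf("Gap-selected k: %d; non-neutral fraction: %.1f%%", clus$k,
            100 * mean(assignments$type_label != "neutral")),
    "",
    "## Decodability (mean F1 vs shuffled baseline)",
    vapply(decode, function(r) {
      sprintf("- %s: %.3f vs %.3f", r$label_set, r$mean_f1,
              r$baseline_mean_f1)
    }, character(1)),
    "",
    sprintf("## Modulation: joint fraction %.3f, correlation %.3f",
            interaction$joint_fraction, interaction$correlation))
  if (detect_video) {
    report <- c(report, "",
                sprintf("## Detection: recall %.3f, precision %.3f",
                        detection$metrics$recall,
                        detection$metrics$precision))
  }
  writeLines(report, file.path(out_dir, "report.md"))

  invisible(list(cohort_meta = list_rbind(lapply(cohort, `[[`, "meta")),
                 detection = detection, assignments = assignments,
                 clusters = clus,
                 type_distribution = list(area = dist_area,
                                          layer = dist_layer),
                 decode = decode,
                 modulation = list(table = mod_table,
                                   interaction = interaction)))
}

# KS-test significance of preferred-condition dF/F between a state and its
# complement, BH-corrected across neurons.
significance_from_modulation <- function(dff, stim_table, state_mask, pref) {
  gr <- stim_table[stim_table$stimulus_type == "grating", , drop = FALSE]
  s1 <- vector("list", nrow(dff))
  s2 <- vector("list", nrow(dff))
  for (i in seq_len(nrow(dff))) {
    sel <- gr$direction_deg == pref$direction_deg[i] &
      gr$temporal_frequency_hz == pref$temporal_frequency_hz[i]
    frames <- unlist(lapply(which(sel), function(tr) {
      gr$start_frame[tr]:(gr$end_frame[tr] - 1L)
    }))
    s1[[i]] <- dff[i, frames[state_mask[frames]]]
    s2[[i]] <- dff[i, frames[!state_mask[frames]]]
  }
  per_cell_significance(s1, s2)
}
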