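#' Simulate dF/F traces with known response types
#'
#' Builds a neurons x frames dF/F matrix. Each neuron is assigned one of the
#' four fidget response types (`neutral`, `phasic`, `active`, `depressed`)
#' with probabilities `config$type_probs`; at every fidget onset the type's
#' template waveform, scaled to the neuron's response amplitude in dF/F
#' units, is added to the trace. Every neuron additionally carries a
#' drifting-grating visual response tuned to a preferred direction (von
#' Mises weighting) and temporal frequency (log-Gaussian weighting); a
#' `running_fraction` subset has that visual response multiplied by a gain
#' while the animal runs. Gaussian noise of `config$noise_sd` completes the
#' trace.
#'
#' @param config A [synth_config()].
#' @param events Fidget event tibble (needs `onset_frame`).
#' @param stim_table Stimulus table from [simulate_stimulus()]; may be `NULL`
#'   to skip visual responses.
#' @param running_speed Per-frame speed in cm/s; may be `NULL`.
#' @param type_probs Optional override of `config$type_probs` (used by the
#'   cohort generator for per-area prevalence shifts).
#' @param tau Indicator decay constant in seconds for the templates.
#' @param running_gain Multiplicative visual-response gain while running.
#' @return A list with `dff` (n_neurons x n_frames matrix) and `truth`, a
#'   tibble with per-neuron `type`, `event_scale` (dF/F), `visual_amp`,
#'   `pref_direction`, `pref_tf`, `running_modulated`.
#' @examples
#' cfg <- synth_config(session_duration = 60, n_neurons = 10, n_fidgets = 2)
#' ev <- schedule_fidgets(cfg)
#' tr <- simulate_traces(cfg, ev, NULL, NULL)
#' dim(tr$dff)
#' @export
simulate_traces <- function(config, events, stim_table = NULL,
                            running_speed = NULL, type_probs = NULL,
                            tau = 0.7, running_gain = 1.5) {
  stopifnot(inherits(config, "synth_config"))
  probs <- type_probs %||% config$type_probs
  if (abs(sum(probs) - 1) > 1e-9 || any(probs < 0)) {
    abort("type probabilities must be non-negative and sum to 1")
  }
  n <- config$n_neurons
  total <- n_frames(config)
  types <- response_type_levels()
  tpl <- response_templates(tau, config$fps)$waveforms

  with_seed(derive_seed(config$seed, 14L), {
    type <- sample(types, n, replace = TRUE, prob = probs)
    event_scale <- rlnorm(n, log(0.15), 0.1)          # dF/F peak at events
    visual_amp <- rlnorm(n, log(0.10), 0.4)           # dF/F at preference
    pref_direction <- sample(seq(0, 315, by = 45), n, replace = TRUE)
    pref_tf <- sample(c(1, 2, 4, 8, 15), n, replace = TRUE)
    running_modulated <- runif(n) < config$running_fraction

    dff <- matrix(rnorm(n * total, 0, config$noise_sd), n, total)

    # fidget responses: add the scaled post-onset template at every onset
    if (!is.null(events) && nrow(events) && n > 0) {
      post <- tpl[, 101:300, drop = FALSE]
      for (e in seq_len(nrow(events))) {
        o <- events$onset_frame[e]
        len <- min(200L, total - o + 1L)
        if (len <= 0) next
        idx <- o:(o + len - 1L)
        dff[, idx] <- dff[, idx] +
          post[type, seq_len(len), drop = FALSE] * event_scale
      }
    }

    # visual responses during gratings
    if (!is.null(stim_table) && n > 0) {
      gr <- stim_table[stim_table$stimulus_type == "grating", , drop = FALSE]
      if (nrow(gr)) {
        kappa <- 2
        g_len <- as.integer(gr$end_frame[1] - gr$start_frame[1])
        kern <- 1 - exp(-(0:(g_len - 1)) / (tau * config$fps))
        for (tr in seq_len(nrow(gr))) {
          idx <- gr$start_frame[tr]:(gr$end_frame[tr] - 1L)
          dir_w <- exp(kappa * (cospi((gr$direction_deg[tr] - pref_direction) / 180) - 1))
          tf_w <- exp(-(log2(gr$temporal_frequency_hz[tr]) - log2(pref_tf))^2 / 2)
          amp <- visual_amp * dir_w * tf_w
          if (!is.null(running_speed) &&
              mean(running_speed[idx]) > 1) {
            amp <- amp * ifelse(running_modulated, running_gain, 1)
          }
          dff[, idx] <- dff[, idx] + outer(amp, kern[seq_along(idx)])
        }
      }
    }

    list(dff = dff,
         truth = tibble(
           neuron_id = seq_len(n),
           type = factor(type, levels = types),
           event_scale = event_scale,
           visual_amp = visual_amp,
           pref_direction = pref_direction,
           pref_tf = pref_tf,
           running_modulated = running_modulated))
  })
}

#' Simulate a full session
#'
#' Composes [simulate_video()], [simulate_stimulus()] and
#' [simulate_traces()] into one session object carrying observables (video,
#' dF/F, stimulus table, running speed), ground truth (frame labels, event
#' schedule, per-neuron types) and metadata (area, depth, Cre line).
#'
#' @param config A [synth_config()].
#' @param area Visual area name (VISp, VISpm, VISal, VISl).
#' @param depth_um Imaging depth; one of 175, 275, 350, 375.
#' @param cre_line Transgenic driver line name.
#' @param render Render the video frames (set `FALSE` for neural-only work).
#' @param type_probs Optional per-session override of the type prevalences.
#' @return A list of class `synth_session`.
#' @examples
#' s <- simulate_session(synth_config(session_duration = 60, n_neurons = 5,
#'                                    n_fidgets = 2), render = FALSE)
#' names(s)
#' @export
simulate_session <- function(config, area = "VISp", depth_um = 175,
                             cre_line = "Cux2", render = TRUE,
                             type_probs = NULL) {
  depth_to_layer(depth_um)  # validates the depth
  video <- simulate_video(config, render = render)
  stim <- simulate_stimulus(config)
  traces <- simulate_traces(config, video$events, stim, video$running_speed,
                            type_probs = type_probs)
  structure(
    list(frames = video$frames,
         labels = video$labels,
         events = video$events,
         dff = traces$dff,
         stim_table = stim,
         running_speed = video$running_speed,
         running_bouts = video$running_bouts,
         truth = traces$truth,
         meta = tibble(area = area, depth_um = depth_um,
                       layer = depth_to_layer(depth_um), cre_line = cre_line),
         config = config),
    class = "synth_session")
}

#' @export
print.synth_session <- function(x, ...) {
  cat(sprintf("<synth_session> %s %d um (%s), %s: %d neurons, %d fidgets, %d frames%s\n",
              x$meta$area, x$meta$depth_um, x$meta$layer, x$meta$cre_line,
              nrow(x$dff), nrow(x$events), n_frames(x$config),
              if (is.null(x$frames)) " (video not rendered)" else ""))
  invisible(x)
}

# Shift the type probability vector for a positive-control cohort: add
# `effect` to `target` and rescale the remaining types proportionally.
shift_type_probs <- function(probs, target, effect) {
  if (effect == 0) return(probs)
  p <- probs
  if (p[target] + effect > 1) abort("area_effect pushes a prevalence above 1")
  others <- setdiff(names(p), target)
  p[others] <- p[others] * (1 - p[target] - effect) / (1 - p[target])
  p[target] <- p[target] + effect
  p
}

# Which type each area over-represents in a positive-control cohort.
area_boost_map <- function() {
  c(VISp = "phasic", VISpm = "active", VISal = "depressed", VISl = "neutral")
}

#' Simulate a multi-session cohort
#'
#' Generates `n_sessions` sessions whose metadata cycles through the
#' requested areas, depths and Cre lines. With `config$area_effect == 0` the
#' cohort is a null cohort: every session draws neuron types from the same
#' prevalence vector, so any decodable area/layer structure downstream is a
#' false positive. With `area_effect > 0` each area over-represents one
#' response type (VISp: phasic, VISpm: active, VISal: depressed, VISl:
#' neutral) by that amount, giving a positive-control cohort with real
#' structure to detect.
#'
#' @param n_sessions Number of sessions (>= 1).
#' @param config Base [synth_config()]; per-session seeds are derived from
#'   `config$seed`.
#' @param areas,depths,cre_lines Metadata values to cycle through.
#' @param render Render behavioral video for each session (off by default;
#'   neural analyses do not need it).
#' @return A list of `synth_session` objects.
#' @examples
#' coh <- simulate_cohort(2, synth_config(session_duration = 60,
#'                                        n_neurons = 5, n_fidgets = 2))
#' length(coh)
#' @export
simulate_cohort <- function(n_sessions, config,
                            areas = c("VISp", "VISpm", "VISal", "VISl"),
                            depths = c(175, 275, 375),
                            cre_lines = c("Cux2", "Rorb", "Rbp4"),
                            render = FALSE) {
  if (n_sessions < 1) abort("`n_sessions` must be >= 1")
  if (!length(areas)) abort("`areas` must be non-empty")
  boost <- area_boost_map()
  lapply(seq_len(n_sessions), function(i) {
    area <- areas[((i - 1L) %% length(areas)) + 1L]
    depth <- depths[(((i - 1L) %/% length(areas)) %% length(depths)) + 1L]
    cre <- cre_lines[(((i - 1L) %/% (length(areas) * length(depths))) %%
                        length(cre_lines)) + 1L]
    cfg_i <- config
    cfg_i$seed <- derive_seed(config$seed, 100L + i)
    probs <- config$type_probs
    if (config$area_effect > 0 && area %in% names(boost)) {
      probs <- shift_type_probs(probs, boost[[area]], config$area_effect)
    }
    simulate_session(cfg_i, area = area, depth_um = depth, cre_line = cre,
                     render = render, type_probs = probs)
  })
}
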