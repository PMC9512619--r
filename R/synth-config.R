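#' Configuration for a synthetic fidget session
#'
#' Bundles every knob of the synthetic-session generator: the behavioral video
#' (frame rate, geometry, number and kinematics of fidget events), the
#' simulated two-photon recording (number of neurons, response-type
#' prevalences, noise), and the behavioral-state structure (running bouts,
#' fraction of running-modulated neurons). The defaults describe a 10 min
#' side-view recording at 30 Hz with ~20 fidgets and a population whose
#' response-type prevalences are uniform across cortical areas.
#'
#' @param fps Video and imaging frame rate in frames/s.
#' @param session_duration Session length in seconds.
#' @param image_size Height and width of the rendered video frames, pixels.
#' @param n_fidgets Number of fidget events to schedule.
#' @param fidget_duration_range Closed range of fidget durations, in frames.
#'   The default 15--45 frames corresponds to 0.5--1.5 s at 30 Hz.
#' @param fidget_amplitude_cv Coefficient of variation of the peak fidget
#'   displacement across events (unitless). Fidgets are highly stereotyped,
#'   so the default CV is 0.1.
#' @param min_event_gap_s Minimum separation between consecutive fidgets in
#'   seconds. The default (10.2 s) keeps events a full 100-pre/200-post
#'   analysis window apart, so event-triggered averages contain no echoes
#'   of neighboring events; lower it (>= 1 s) for dense, video-only
#'   sessions.
#' @param n_neurons Number of simulated neurons.
#' @param type_probs Named length-4 probability vector over response types
#'   `neutral`, `phasic`, `active`, `depressed`; must sum to 1.
#' @param noise_sd Standard deviation of additive Gaussian trace noise, in
#'   dF/F units.
#' @param running_fraction Probability that a neuron's visual response is
#'   multiplicatively boosted while the animal runs.
#' @param area_effect Per-area shift of `type_probs` used by
#'   [simulate_cohort()]: 0 gives a homogeneous (null) cohort, a positive
#'   value adds that amount to one area-specific type (positive control).
#' @param seed Integer seed; every stochastic draw of the generator is a
#'   deterministic function of the config including this seed.
#'
#' @return An object of class `synth_config` (a named list).
#' @examples
#' cfg <- synth_config(session_duration = 60, n_fidgets = 3, n_neurons = 20)
#' cfg$fps
#' @export
synth_config <- function(fps = 30,
                         session_duration = 600,
                         image_size = c(80, 80),
                         n_fidgets = 20,
                         fidget_duration_range = c(15, 45),
                         fidget_amplitude_cv = 0.1,
                         min_event_gap_s = 10.2,
                         n_neurons = 200,
                         type_probs = c(neutral = 0.528, phasic = 0.139,
                                        active = 0.120, depressed = 0.213),
                         noise_sd = 0.05,
                         running_fraction = 0.3,
                         area_effect = 0,
                         seed = 1L) {
  if (!is.numeric(fps) || fps <= 0) abort("`fps` must be > 0.")
  if (session_duration < 0) abort("`session_duration` must be >= 0.")
  if (length(image_size) != 2 || any(image_size < 8)) {
    abort("`image_size` must be (height, width), each >= 8 pixels.")
  }
  if (n_fidgets < 0 || n_neurons < 0) abort("counts must be >= 0.")
  if (length(type_probs) != 4) abort("`type_probs` must have length 4.")
  if (abs(sum(type_probs) - 1) > 1e-9) {
    abort("`type_probs` must sum to 1 (tolerance 1e-9).")
  }
  if (any(type_probs < 0)) abort("`type_probs` must be non-negative.")
  if (fidget_duration_range[1] > fidget_duration_range[2] ||
      fidget_duration_range[1] < 2) {
    abort("`fidget_duration_range` must be an increasing range of >= 2 frames.")
  }
  names(type_probs) <- response_type_levels()
  structure(
    list(fps = fps,
         session_duration = session_duration,
         image_size = as.integer(image_size),
         n_fidgets = as.integer(n_fidgets),
         fidget_duration_range = as.integer(fidget_duration_range),
         fidget_amplitude_cv = fidget_amplitude_cv,
         min_event_gap_s = max(1, min_event_gap_s),
         n_neurons = as.integer(n_neurons),
         type_probs = type_probs,
         noise_sd = noise_sd,
         running_fraction = running_fraction,
         area_effect = area_effect,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf("  %g s at %g fps (%d frames), %dx%d px\n",
              x$session_duration, x$fps, n_frames(x),
              x$image_size[1], x$image_size[2]))
  cat(sprintf("  %d fidgets (%d-%d frames, amplitude CV %.2f)\n",
              x$n_fidgets, x$fidget_duration_range[1],
              x$fidget_duration_range[2], x$fidget_amplitude_cv))
  cat(sprintf("  %d neurons, type probs [%s], noise sd %.3f\n",
              x$n_neurons,
              paste(sprintf("%s %.3f", names(x$type_probs), x$type_probs),
                    collapse = ", "),
              x$noise_sd))
  invisible(x)
}

# Response-type factor levels used throughout the package.
response_type_levels <- function() c("neutral", "phasic", "active", "depressed")

n_frames <- function(config) as.integer(round(config$fps * config$session_duration))

#' Map imaging depth to cortical layer
#'
#' Imaging depths used in the simulated cohorts map onto cortical layers as
#' 175 um -> L2/3, 275 and 350 um -> L4, 375 um -> L5.
#'
#' @param depth_um Numeric vector of imaging depths in micrometers.
#' @return Character vector of layer names.
#' @examples
#' depth_to_layer(c(175, 275, 350, 375))
#' @export
depth_to_layer <- function(depth_um) {
  out <- dplyr::case_when(
    depth_um == 175 ~ "L2/3",
    depth_um %in% c(275, 350) ~ "L4",
    depth_um == 375 ~ "L5",
    TRUE ~ NA_character_
  )
  if (anyNA(out)) {
    abort(sprintf("unknown imaging depth(s): %s",
                  paste(unique(depth_um[is.na(out)]), collapse = ", ")))
  }
  out
}
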