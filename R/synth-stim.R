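#' Simulate a drifting-grating stimulus table
#'
#' Lays out a drifting-grating protocol on the session's frame clock: each
#' grating lasts 2 s and is followed by 1 s of mean-luminance gray; gratings
#' cover 8 directions (45 degree steps) crossed with 5 temporal frequencies
#' (1, 2, 4, 8, 15 Hz), each condition repeated `n_repeats` times in random
#' order; a blank sweep (gray in place of a grating) is inserted once every
#' 20 gratings.
#'
#' @param config A [synth_config()].
#' @param n_repeats Repeats per (direction, temporal frequency) condition.
#'   `NULL` (default) fits as many complete repeats as the session allows.
#' @param grating_s,gray_s Grating and interstimulus-gray durations, seconds.
#' @param blank_every One blank sweep per this many gratings (0 disables).
#' @return A tibble with columns `start_frame`, `end_frame` (half-open,
#'   1-based), `stimulus_type` (`grating`/`gray`/`blank`), `direction_deg`,
#'   `temporal_frequency_hz` (NA for gray and blank rows).
#' @examples
#' stim <- simulate_stimulus(synth_config(session_duration = 120))
#' table(stim$stimulus_type)
#' @export
simulate_stimulus <- function(config, n_repeats = NULL,
                              grating_s = 2, gray_s = 1, blank_every = 20) {
  stopifnot(inherits(config, "synth_config"))
  fps <- config$fps
  total <- n_frames(config)
  g_len <- as.integer(round(grating_s * fps))
  gap_len <- as.integer(round(gray_s * fps))
  slot <- g_len + gap_len
  directions <- seq(0, 315, by = 45)
  tfs <- c(1, 2, 4, 8, 15)
  n_cond <- length(directions) * length(tfs)

  slots_for <- function(reps) {
    n_gr <- n_cond * reps
    n_blank <- if (blank_every > 0) n_gr %/% blank_every else 0L
    n_gr + n_blank
  }
  avail <- (total - gap_len) %/% slot
  if (is.null(n_repeats)) {
    n_repeats <- 0L
    while (slots_for(n_repeats + 1L) <= avail) n_repeats <- n_repeats + 1L
  } else if (n_repeats > 0 && slots_for(n_repeats) > avail) {
    abort(sprintf(
      "session too short: %d repeats need %d stimulus slots, only %d fit",
      n_repeats, slots_for(n_repeats), avail))
  }

  conditions <- expand.grid(direction_deg = directions,
                            temporal_frequency_hz = tfs)
  conditions <- conditions[rep(seq_len(n_cond), times = n_repeats), ,
                           drop = FALSE]
  order <- with_seed(derive_seed(config$seed, 11L),
                     sample.int(nrow(conditions)))
  conditions <- conditions[order, , drop = FALSE]

  rows <- list()
  cursor <- 1L
  # lead-in gray
  rows[[1]] <- tibble(start_frame = cursor, end_frame = cursor + gap_len,
                      stimulus_type = "gray",
                      direction_deg = NA_real_,
                      temporal_frequency_hz = NA_real_)
  cursor <- cursor + gap_len
  gr_done <- 0L
  i <- 1L
  while (i <= nrow(conditions)) {
    if (blank_every > 0 && gr_done > 0 && gr_done %% blank_every == 0 &&
        (length(rows) == 1L ||
         rows[[length(rows)]]$stimulus_type != "blank")) {
      rows[[length(rows) + 1L]] <- tibble(
        start_frame = cursor, end_frame = cursor + g_len,
        stimulus_type = "blank",
        direction_deg = NA_real_, temporal_frequency_hz = NA_real_)
      cursor <- cursor + g_len
      rows[[length(rows) + 1L]] <- tibble(
        start_frame = cursor, end_frame = cursor + gap_len,
        stimulus_type = "gray",
        direction_deg = NA_real_, temporal_frequency_hz = NA_real_)
      cursor <- cursor + gap_len
      gr_done <- 0L  # reset the blank counter window
      next
    }
    rows[[length(rows) + 1L]] <- tibble(
      start_frame = cursor, end_frame = cursor + g_len,
      stimulus_type = "grating",
      direction_deg = conditions$direction_deg[i],
      temporal_frequency_hz = conditions$temporal_frequency_hz[i])
    cursor <- cursor + g_len
    rows[[length(rows) + 1L]] <- tibble(
      start_frame = cursor, end_frame = cursor + gap_len,
      stimulus_type = "gray",
      direction_deg = NA_real_, temporal_frequency_hz = NA_real_)
    cursor <- cursor + gap_len
    gr_done <- gr_done + 1L
    i <- i + 1L
  }
  out <- list_rbind(rows)
  stopifnot(all(out$end_frame <= total + 1L))
  out
}

#' Simulate a running-speed trace
#'
#' Alternates stationary periods with running bouts. During a bout the speed
#' ramps to a bout-specific plateau (10--25 cm/s) with slow fluctuations;
#' outside bouts the speed is small jitter around zero.
#'
#' @param config A [synth_config()].
#' @return A list with `speed` (cm/s per frame) and `bouts`, a tibble of
#'   half-open frame intervals (`start_frame`, `end_frame`).
#' @examples
#' run <- simulate_running(synth_config(session_duration = 60))
#' mean(run$speed > 1)
#' @export
simulate_running <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  total <- n_frames(config)
  fps <- config$fps
  with_seed(derive_seed(config$seed, 12L), {
    speed <- abs(rnorm(total, 0, 0.15))
    bouts <- list()
    cursor <- 1L + as.integer(round(fps * stats::rexp(1, 1 / 20)))
    while (cursor < total) {
      len <- as.integer(round(fps * (5 + stats::rexp(1, 1 / 10))))
      end <- min(cursor + len, total + 1L)
      if (end - cursor >= fps) {
        bouts[[length(bouts) + 1L]] <- tibble(start_frame = cursor,
                                              end_frame = end)
        idx <- cursor:(end - 1L)
        plateau <- runif(1, 10, 25)
        ramp <- pmin(1, seq_along(idx) / fps) *
          pmin(1, rev(seq_along(idx)) / fps)
        wobble <- 1 + 0.15 * sin(2 * pi * 0.3 * seq_along(idx) / fps +
                                   runif(1, 0, 2 * pi))
        speed[idx] <- plateau * ramp * wobble + abs(rnorm(length(idx), 0, 0.3))
      }
      cursor <- end + as.integer(round(fps * (10 + stats::rexp(1, 1 / 20))))
    }
    bouts <- if (length(bouts)) list_rbind(bouts) else
      tibble(start_frame = integer(), end_frame = integer())
    list(speed = speed, bouts = bouts)
  })
}
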