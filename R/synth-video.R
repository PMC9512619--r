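#' Schedule fidget events within a session
#'
#' Draws `n_fidgets` non-overlapping fidget intervals with durations uniform
#' over `fidget_duration_range` and peak displacement amplitudes with the
#' configured coefficient of variation. Events are kept clear of running
#' bouts, of each other (`min_event_gap_s`, by default one full analysis
#' window so event-triggered averages have no cross-event echoes), and of
#' the session edges so that a full 100-frame pre / 200-frame post neural
#' window exists around every onset.
#'
#' @param config A [synth_config()].
#' @param exclude Optional tibble of half-open frame intervals (e.g. running
#'   bouts) that events must not touch.
#' @return A tibble with `event_id`, `onset_frame`, `offset_frame`
#'   (half-open), `duration_frames`, `amplitude_px`.
#' @examples
#' schedule_fidgets(synth_config(session_duration = 120, n_fidgets = 4))
#' @export
schedule_fidgets <- function(config, exclude = NULL) {
  stopifnot(inherits(config, "synth_config"))
  total <- n_frames(config)
  n <- config$n_fidgets
  empty <- tibble(event_id = integer(), onset_frame = integer(),
                  offset_frame = integer(), duration_frames = integer(),
                  amplitude_px = double())
  if (n == 0L) return(empty)
  margin_pre <- 105L
  margin_post <- 205L
  min_gap <- as.integer(round(config$fps * config$min_event_gap_s))
  guard <- as.integer(config$fps)    # keep clear of running bouts

  ex <- if (!is.null(exclude) && nrow(exclude)) {
    cbind(pmax(1L, exclude$start_frame - guard),
          pmin(total + 1L, exclude$end_frame + guard))
  } else matrix(integer(), 0, 2)

  with_seed(derive_seed(config$seed, 13L), {
    durations <- sample(seq(config$fidget_duration_range[1],
                            config$fidget_duration_range[2]), n,
                        replace = TRUE)
    amp_mean <- 0.075 * config$image_size[1]
    amplitudes <- rnorm(n, amp_mean, config$fidget_amplitude_cv * amp_mean)
    amplitudes <- pmax(amplitudes, 0.1 * amp_mean)

    lo <- margin_pre + 1L
    hi <- total - margin_post
    if (hi - lo < max(durations)) {
      abort("session too short to place a fidget with full neural windows")
    }
    # free intervals: the allowed onset span minus excluded zones
    base <- matrix(c(lo, hi), 1)
    if (nrow(ex)) {
      pieces <- list()
      cur <- lo
      for (b in order(ex[, 1])) {
        if (ex[b, 1] > cur) {
          pieces[[length(pieces) + 1L]] <- c(cur, min(ex[b, 1], hi))
        }
        cur <- max(cur, ex[b, 2])
        if (cur >= hi) break
      }
      if (cur < hi) pieces[[length(pieces) + 1L]] <- c(cur, hi)
      base <- do.call(rbind, pieces)
      base <- base[base[, 2] - base[, 1] >= min(durations), , drop = FALSE]
      if (!nrow(base)) {
        abort("could not schedule the requested fidgets without overlap; reduce `n_fidgets` or lengthen the session")
      }
    }

    # sequential placement with exact free-interval bookkeeping; a dead end
    # (fragmentation) restarts the whole layout
    for (attempt in 1:100) {
      free <- base
      onsets <- integer(n); placed <- TRUE
      for (i in seq_len(n)) {
        d <- durations[i]
        fits <- which(free[, 2] - free[, 1] >= d)
        if (!length(fits)) { placed <- FALSE; break }
        w <- free[fits, 2] - free[fits, 1] - d + 1
        iv <- fits[sample.int(length(fits), 1L, prob = w)]
        onset <- free[iv, 1] + sample.int(free[iv, 2] - free[iv, 1] - d + 1L,
                                          1L) - 1L
        onsets[i] <- onset
        left <- c(free[iv, 1], onset - min_gap)
        right <- c(onset + d + min_gap, free[iv, 2])
        free <- rbind(free[-iv, , drop = FALSE],
                      if (left[2] - left[1] >= min(durations)) left,
                      if (right[2] - right[1] >= min(durations)) right)
      }
      if (placed) break
    }
    if (!placed) {
      abort("could not schedule the requested fidgets without overlap; reduce `n_fidgets` or lengthen the session")
    }
    ord <- order(onsets)
    tibble(event_id = seq_len(n),
           onset_frame = as.integer(onsets[ord]),
           offset_frame = as.integer(onsets[ord] + durations[ord]),
           duration_frames = as.integer(durations[ord]),
           amplitude_px = amplitudes[ord])
  })
}

# Body geometry shared by the renderer, in pixels, derived from frame size.
body_geometry <- function(config) {
  h <- config$image_size[1]
  w <- config$image_size[2]
  list(cx = 0.5 * w, cy = 0.66 * h, rx = 0.30 * w, ry = 0.17 * h,
       amp_ref = 0.075 * h)
}

# Separable box blur, used to give the body and background smooth texture.
box_blur <- function(m, k = 3L, times = 2L) {
  kern <- rep(1 / k, k)
  for (i in seq_len(times)) {
    m <- apply(m, 2, function(col) stats::filter(col, kern, circular = TRUE))
    m <- t(apply(m, 1, function(row) stats::filter(row, kern, circular = TRUE)))
  }
  m
}

#' Render a synthetic behavioral video
#'
#' Draws a textured, deformable body-shaped blob on a static background at
#' 30 Hz (or the configured rate). During each scheduled fidget the blob is
#' lifted vertically with a half-sine time course of the event's amplitude
#' while contracting horizontally and stretching vertically (an arching
#' posture change). During running bouts the blob sways and bobs with a small
#' periodic limb-motion signature. Light per-frame sensor noise is added.
#'
#' @param config A [synth_config()].
#' @param events Fidget schedule from [schedule_fidgets()].
#' @param bouts Running-bout intervals from [simulate_running()].
#' @return A numeric array `height x width x n_frames` with values in
#'   \[0, 1\].
#' @keywords internal
render_session_frames <- function(config, events, bouts) {
  h <- config$image_size[1]
  w <- config$image_size[2]
  total <- n_frames(config)
  fps <- config$fps
  geo <- body_geometry(config)

  with_seed(derive_seed(config$seed, 15L), {
    # static background: vertical gradient + coarse texture
    bg <- matrix(rep(seq(0.25, 0.42, length.out = h), w), h, w)
    bg <- bg + 0.06 * box_blur(matrix(runif(h * w, -1, 1), h, w), 5L, 2L)

    # body texture attached to body-local coordinates
    nt <- 64L
    tex <- box_blur(matrix(runif(nt * nt), nt, nt), 5L, 2L)
    tex <- 0.5 + 0.45 * (tex - min(tex)) / diff(range(tex))

    sway_phase <- runif(1, 0, 2 * pi)

    # per-frame kinematics
    dx <- numeric(total); dy <- numeric(total)
    sx <- rep(1, total); sy <- rep(1, total)
    if (nrow(bouts)) {
      for (b in seq_len(nrow(bouts))) {
        idx <- bouts$start_frame[b]:(bouts$end_frame[b] - 1L)
        ph <- 2 * pi * 2.4 * (idx / fps) + sway_phase
        dx[idx] <- 1.8 * sin(ph)
        dy[idx] <- -1.0 * abs(sin(ph))
      }
    }
    if (nrow(events)) {
      for (e in seq_len(nrow(events))) {
        idx <- events$onset_frame[e]:(events$offset_frame[e] - 1L)
        phase <- sin(pi * (seq_along(idx) - 0.5) / length(idx))
        a <- events$amplitude_px[e]
        dy[idx] <- -a * phase
        sx[idx] <- 1 - 0.25 * phase * (a / geo$amp_ref)
        sy[idx] <- 1 + 0.15 * phase * (a / geo$amp_ref)
      }
    }

    # bounding box that contains the body under any displacement
    max_lift <- max(c(geo$amp_ref * (1 + 4 * config$fidget_amplitude_cv),
                      if (nrow(events)) max(events$amplitude_px) else 0))
    r0 <- max(1L, floor(geo$cy - geo$ry * 1.3 - max_lift - 2))
    r1 <- min(h, ceiling(geo$cy + geo$ry * 1.3 + 3))
    c0 <- max(1L, floor(geo$cx - geo$rx * 1.15 - 4))
    c1 <- min(w, ceiling(geo$cx + geo$rx * 1.15 + 4))
    ys <- rep(r0:r1, times = c1 - c0 + 1L)
    xs <- rep(c0:c1, each = r1 - r0 + 1L)

    frames <- array(0, dim = c(h, w, total))
    noise_sd <- 0.004
    for (f in seq_len(total)) {
      fr <- bg
      u <- (xs - geo$cx - dx[f]) / (geo$rx * sx[f])
      v <- (ys - geo$cy - dy[f]) / (geo$ry * sy[f])
      r2 <- u * u + v * v
      inside <- r2 < 1
      if (any(inside)) {
        ui <- u[inside]; vi <- v[inside]
        tx <- (ui + 1) / 2 * (nt - 1) + 1
        ty <- (vi + 1) / 2 * (nt - 1) + 1
        ix <- pmin(pmax(floor(tx), 1L), nt - 1L)
        iy <- pmin(pmax(floor(ty), 1L), nt - 1L)
        fx <- tx - ix; fy <- ty - iy
        tv <- tex[cbind(iy, ix)] * (1 - fx) * (1 - fy) +
          tex[cbind(iy, ix + 1L)] * fx * (1 - fy) +
          tex[cbind(iy + 1L, ix)] * (1 - fx) * fy +
          tex[cbind(iy + 1L, ix + 1L)] * fx * fy
        tv <- tv * (1 - 0.22 * vi)           # vertical shading
        alpha <- pmin(1, (1 - r2[inside]) / 0.15)
        lin <- (xs[inside] - 1L) * h + ys[inside]
        fr[lin] <- fr[lin] * (1 - alpha) + tv * alpha
      }
      frames[, , f] <- fr + rnorm(h * w, 0, noise_sd)
    }
    frames[frames < 0] <- 0
    frames[frames > 1] <- 1
    frames
  })
}

#' Simulate a behavioral video session
#'
#' Generates running bouts, schedules fidget events away from them, renders
#' the video, and produces the ground-truth per-frame label track (`fidget`
#' during events, `movement` during running bouts, `resting` otherwise).
#'
#' @param config A [synth_config()].
#' @param render Logical; if `FALSE`, skip rendering (frames are `NULL`) but
#'   still produce identical labels, events and running trace.
#' @return A list of class `synth_video` with `frames`, `labels` (tibble
#'   `frame`, `label`), `events`, `running_speed`, `running_bouts`, `config`.
#' @examples
#' v <- simulate_video(synth_config(session_duration = 30, n_fidgets = 2,
#'                                  n_neurons = 0))
#' dim(v$frames)
#' @export
simulate_video <- function(config, render = TRUE) {
  stopifnot(inherits(config, "synth_config"))
  run <- simulate_running(config)
  events <- schedule_fidgets(config, run$bouts)
  total <- n_frames(config)
  label <- rep("resting", total)
  if (nrow(run$bouts)) {
    for (b in seq_len(nrow(run$bouts))) {
      label[run$bouts$start_frame[b]:(run$bouts$end_frame[b] - 1L)] <- "movement"
    }
  }
  if (nrow(events)) {
    for (e in seq_len(nrow(events))) {
      label[events$onset_frame[e]:(events$offset_frame[e] - 1L)] <- "fidget"
    }
  }
  frames <- if (render) render_session_frames(config, events, run$bouts) else NULL
  structure(
    list(frames = frames,
         labels = tibble(frame = seq_len(total),
                         label = factor(label, levels = behavior_levels())),
         events = events,
         running_speed = run$speed,
         running_bouts = run$bouts,
         config = config),
    class = "synth_video")
}

# Behavior class levels, fidget first.
behavior_levels <- function() c("fidget", "movement", "resting")
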