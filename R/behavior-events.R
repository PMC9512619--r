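#' Extract fidget events from a frame label track
#'
#' Finds maximal runs of fidget-labeled frames, merges runs separated by at
#' most `merge_gap` non-fidget frames, and drops merged runs shorter than
#' `min_duration` frames. With `merge_gap = 0` and `min_duration = 1` the
#' summed event durations equal the number of fidget-labeled frames exactly.
#' The defaults (10-frame minimum, 5-frame gap) suppress sub-330-ms label
#' jitter at 30 Hz.
#'
#' @param track A tibble with a `label` column (as returned by
#'   [predict.fidget_detector()] or [simulate_video()]) or a plain
#'   label vector.
#' @param min_duration Minimum event duration, frames.
#' @param merge_gap Maximum gap, in frames, across which adjacent fidget
#'   runs are merged.
#' @return A tibble `event_id`, `onset_frame`, `offset_frame` (half-open),
#'   `duration_frames`, sorted and disjoint.
#' @examples
#' lab <- rep("resting", 9)
#' lab[c(1, 2, 3, 6, 7)] <- "fidget"
#' extract_events(lab, min_duration = 2, merge_gap = 0)
#' @export
extract_events <- function(track, min_duration = 10L, merge_gap = 5L) {
  lab <- if (is.data.frame(track)) as.character(track$label) else as.character(track)
  is_f <- lab == "fidget"
  empty <- tibble(event_id = integer(), onset_frame = integer(),
                  offset_frame = integer(), duration_frames = integer())
  if (!any(is_f)) return(empty)
  r <- rle(is_f)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- starts[r$values]
  off <- ends[r$values] + 1L
  # merge runs separated by <= merge_gap
  if (length(on) > 1 && merge_gap > 0) {
    keep_on <- on[1]; keep_off <- off[1]
    m_on <- integer(0); m_off <- integer(0)
    for (i in 2:length(on)) {
      if (on[i] - keep_off <= merge_gap) {
        keep_off <- off[i]
      } else {
        m_on <- c(m_on, keep_on); m_off <- c(m_off, keep_off)
        keep_on <- on[i]; keep_off <- off[i]
      }
    }
    on <- c(m_on, keep_on); off <- c(m_off, keep_off)
  }
  dur <- off - on
  keep <- dur >= min_duration
  if (!any(keep)) return(empty)
  tibble(event_id = seq_len(sum(keep)),
         onset_frame = as.integer(on[keep]),
         offset_frame = as.integer(off[keep]),
         duration_frames = as.integer(dur[keep]))
}

#' Score detected events against ground truth
#'
#' At the event level a true event counts as recalled if any predicted event
#' overlaps it, and a predicted event is a true positive if it overlaps any
#' true event; precision is the true-positive fraction of predictions and
#' recall the recalled fraction of truth. At the frame level, per-frame
#' fidget/non-fidget confusion counts are used instead (both event tables
#' are rasterized over `n_frames` frames).
#'
#' @param pred_events,true_events Event tibbles (see [extract_events()]).
#' @param level `"event"` (default) or `"frame"`.
#' @param n_frames Total frame count; required for frame-level scoring.
#' @return A one-row tibble: `level`, `precision`, `recall`,
#'   `n_events_true`, `n_events_pred`, `flag` (`"ok"`, or a note when a
#'   side is empty and the corresponding metric is degenerate).
#' @examples
#' truth <- tibble::tibble(onset_frame = c(10L, 50L), offset_frame = c(20L, 60L))
#' pred <- tibble::tibble(onset_frame = c(12L, 80L), offset_frame = c(18L, 90L))
#' score_detection(pred, truth)
#' @export
score_detection <- function(pred_events, true_events,
                            level = c("event", "frame"), n_frames = NULL) {
  level <- match.arg(level)
  np <- nrow(pred_events); nt <- nrow(true_events)
  flag <- "ok"
  if (level == "event") {
    overlaps <- function(a_on, a_off, b_on, b_off) {
      vapply(seq_along(a_on), function(i) {
        any(a_on[i] < b_off & a_off[i] > b_on)
      }, logical(1))
    }
    tp_pred <- if (np) sum(overlaps(pred_events$onset_frame,
                                    pred_events$offset_frame,
                                    true_events$onset_frame,
                                    true_events$offset_frame)) else 0L
    recalled <- if (nt) sum(overlaps(true_events$onset_frame,
                                     true_events$offset_frame,
                                     pred_events$onset_frame,
                                     pred_events$offset_frame)) else 0L
    precision <- if (np > 0) tp_pred / np else { flag <- "no predictions"; 0 }
    recall <- if (nt > 0) recalled / nt else { flag <- "no true events"; NA_real_ }
  } else {
    if (is.null(n_frames)) abort("`n_frames` is required for frame-level scoring")
    rasterize <- function(ev) {
      m <- logical(n_frames)
      for (i in seq_len(nrow(ev))) {
        m[ev$onset_frame[i]:(ev$offset_frame[i] - 1L)] <- TRUE
      }
      m
    }
    p <- rasterize(pred_events); t_ <- rasterize(true_events)
    tp <- sum(p & t_)
    precision <- if (sum(p) > 0) tp / sum(p) else { flag <- "no predictions"; 0 }
    recall <- if (sum(t_) > 0) tp / sum(t_) else { flag <- "no true events"; NA_real_ }
  }
  tibble(level = level, precision = precision, recall = recall,
         n_events_true = nt, n_events_pred = np, flag = flag)
}

#' Normalized fidget rate per stimulus type
#'
#' Computes the rate of fidget initiations per minute within epochs of each
#' stimulus type and normalizes it by subtracting the baseline rate during
#' interstimulus gray and dividing by the standard deviation of the
#' per-epoch rates of the session.
#'
#' @param events Event tibble (uses `onset_frame`).
#' @param stim_table Stimulus table with `start_frame`, `end_frame`,
#'   `stimulus_type` covering the session; must contain gray epochs.
#' @param fps Frames per second (converts frames to minutes).
#' @return A tibble per stimulus type: `stimulus_type`, `time_min`,
#'   `n_events`, `rate_per_min`, `normalized_rate`, `flag` (`"ok"` or
#'   `"zero rate SD"` when normalization is undefined).
#' @export
normalized_fidget_rate <- function(events, stim_table, fps = 30) {
  if (!any(stim_table$stimulus_type == "gray")) {
    abort("stimulus table has no gray epochs; baseline rate undefined")
  }
  dur_min <- (stim_table$end_frame - stim_table$start_frame) / fps / 60
  n_ev <- vapply(seq_len(nrow(stim_table)), function(i) {
    sum(events$onset_frame >= stim_table$start_frame[i] &
          events$onset_frame < stim_table$end_frame[i])
  }, numeric(1))
  epoch_rate <- n_ev / dur_min
  rate_sd <- sd(epoch_rate)
  per_type <- tibble(stimulus_type = stim_table$stimulus_type,
                     time_min = dur_min, n_events = n_ev) |>
    group_by(.data$stimulus_type) |>
    summarise(time_min = sum(.data$time_min),
              n_events = sum(.data$n_events), .groups = "drop") |>
    mutate(rate_per_min = .data$n_events / .data$time_min)
  gray_rate <- per_type$rate_per_min[per_type$stimulus_type == "gray"]
  flag <- if (!is.finite(rate_sd) || rate_sd == 0) "zero rate SD" else "ok"
  per_type |>
    mutate(normalized_rate = if (flag == "ok")
      (.data$rate_per_min - gray_rate) / rate_sd else NA_real_,
      flag = flag)
}
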