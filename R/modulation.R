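#' Preferred drifting-grating condition per neuron
#'
#' Finds, for each neuron, the (direction, temporal frequency) combination
#' eliciting the largest mean dF/F over stimulus-on frames. Exact ties are
#' broken toward the lower direction, then the lower temporal frequency.
#'
#' @param dff Neurons x frames dF/F matrix.
#' @param stim_table Stimulus table with grating rows (see
#'   [simulate_stimulus()]).
#' @return A tibble `neuron_id`, `direction_deg`, `temporal_frequency_hz`,
#'   `mean_response`.
#' @export
preferred_condition <- function(dff, stim_table) {
  gr <- stim_table[stim_table$stimulus_type == "grating", , drop = FALSE]
  if (!nrow(gr)) abort("stimulus table contains no grating trials")
  n <- nrow(dff)
  # mean response per trial, then per condition
  trial_means <- vapply(seq_len(nrow(gr)), function(tr) {
    rowMeans(dff[, gr$start_frame[tr]:(gr$end_frame[tr] - 1L), drop = FALSE])
  }, numeric(n))
  if (n == 1L) trial_means <- matrix(trial_means, nrow = 1L)
  cond <- paste(gr$direction_deg, gr$temporal_frequency_hz)
  conds <- unique(tibble(direction_deg = gr$direction_deg,
                         temporal_frequency_hz = gr$temporal_frequency_hz)) |>
    arrange(.data$direction_deg, .data$temporal_frequency_hz)
  cond_key <- paste(conds$direction_deg, conds$temporal_frequency_hz)
  cond_means <- vapply(cond_key, function(k) {
    rowMeans(trial_means[, cond == k, drop = FALSE])
  }, numeric(n))
  if (n == 1L) cond_means <- matrix(cond_means, nrow = 1L)
  # conds is sorted, so which.max's first-hit rule is the documented tie-break
  best <- apply(cond_means, 1, which.max)
  tibble(neuron_id = seq_len(n),
         direction_deg = conds$direction_deg[best],
         temporal_frequency_hz = conds$temporal_frequency_hz[best],
         mean_response = cond_means[cbind(seq_len(n), best)])
}

# Frames and per-trial means of a neuron's preferred-condition trials.
preferred_trial_means <- function(dff_row, stim_table, pref_dir, pref_tf,
                                  state_mask = NULL, state = TRUE) {
  gr <- stim_table[stim_table$stimulus_type == "grating" &
                     stim_table$direction_deg == pref_dir &
                     stim_table$temporal_frequency_hz == pref_tf, ,
                   drop = FALSE]
  out <- numeric(0)
  for (tr in seq_len(nrow(gr))) {
    idx <- gr$start_frame[tr]:(gr$end_frame[tr] - 1L)
    if (!is.null(state_mask)) idx <- idx[state_mask[idx] == state]
    if (length(idx)) out <- c(out, mean(dff_row[idx]))
  }
  out
}

#' Behavioral-state modulation of visual responses (Cohen's d)
#'
#' Compares each neuron's dF/F during its preferred grating condition
#' between two behavioral states (fidget vs non-fidget, or running vs
#' stationary): `d = (x1 - x2) / s` with `x1`, `x2` the state means and `s`
#' the Euclidean norm `sqrt(s1^2 + s2^2)` of the two state SDs (a pooled
#' `sqrt((s1^2 + s2^2) / 2)` variant is available). Samples are per-frame
#' dF/F values within preferred-condition stimulus windows, split by the
#' per-frame state mask.
#'
#' @param dff Neurons x frames dF/F matrix.
#' @param stim_table Stimulus table.
#' @param state_mask Logical per-frame vector (`TRUE` = state 1).
#' @param preferred Preferred conditions from [preferred_condition()].
#' @param state_pair Name recorded in the output, e.g.
#'   `"fidget/nonfidget"`.
#' @param sd_norm `"euclidean"` (default) or `"pooled"`.
#' @return A tibble per neuron: state means and SDs, `cohens_d`, `n1`,
#'   `n2`, `state_pair`, `flag` (`"ok"` or `"undefined"` when a state has
#'   no preferred-condition frames or the SD norm is 0).
#' @export
state_modulation <- function(dff, stim_table, state_mask, preferred,
                             state_pair = "fidget/nonfidget",
                             sd_norm = c("euclidean", "pooled")) {
  sd_norm <- match.arg(sd_norm)
  if (length(state_mask) != ncol(dff)) {
    abort("`state_mask` must have one entry per frame")
  }
  gr <- stim_table[stim_table$stimulus_type == "grating", , drop = FALSE]
  n <- nrow(dff)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    pref <- preferred[preferred$neuron_id == i, ]
    sel <- gr$direction_deg == pref$direction_deg &
      gr$temporal_frequency_hz == pref$temporal_frequency_hz
    frames <- unlist(lapply(which(sel), function(tr) {
      gr$start_frame[tr]:(gr$end_frame[tr] - 1L)
    }))
    x1 <- dff[i, frames[state_mask[frames]]]
    x2 <- dff[i, frames[!state_mask[frames]]]
    if (!length(x1) || !length(x2)) {
      out[[i]] <- tibble(neuron_id = i, mean_dff_state1 = NA_real_,
                         mean_dff_state2 = NA_real_, sd_state1 = NA_real_,
                         sd_state2 = NA_real_, cohens_d = NA_real_,
                         n1 = length(x1), n2 = length(x2),
                         state_pair = state_pair, flag = "undefined")
      next
    }
    s1 <- if (length(x1) > 1) sd(x1) else 0
    s2 <- if (length(x2) > 1) sd(x2) else 0
    s <- switch(sd_norm,
                euclidean = sqrt(s1^2 + s2^2),
                pooled = sqrt((s1^2 + s2^2) / 2))
    d <- if (s > 0) (mean(x1) - mean(x2)) / s else NA_real_
    out[[i]] <- tibble(neuron_id = i, mean_dff_state1 = mean(x1),
                       mean_dff_state2 = mean(x2), sd_state1 = s1,
                       sd_state2 = s2, cohens_d = d,
                       n1 = length(x1), n2 = length(x2),
                       state_pair = state_pair,
                       flag = if (s > 0) "ok" else "undefined")
  }
  list_rbind(out)
}

#' Per-cell significance with Benjamini-Hochberg correction
#'
#' Runs a two-sided two-sample Kolmogorov-Smirnov test per cell between the
#' two states' samples and corrects across cells with the Benjamini-
#' Hochberg false-discovery-rate procedure at level `q`.
#'
#' @param samples_state1,samples_state2 Lists of numeric vectors, one pair
#'   per cell.
#' @param q FDR level.
#' @return A tibble `cell`, `p_value`, `q_significant`, `flag`
#'   (`"untestable"` when a state has < 2 samples).
#' @export
per_cell_significance <- function(samples_state1, samples_state2, q = 0.05) {
  stopifnot(length(samples_state1) == length(samples_state2))
  p <- vapply(seq_along(samples_state1), function(i) {
    x <- samples_state1[[i]]; y <- samples_state2[[i]]
    if (length(x) < 2 || length(y) < 2) return(NA_real_)
    suppressWarnings(ks.test(x, y)$p.value)
  }, numeric(1))
  adj <- p.adjust(p, method = "BH")
  tibble(cell = seq_along(p), p_value = p,
         q_value = adj,
         q_significant = !is.na(adj) & adj < q,
         flag = ifelse(is.na(p), "untestable", "ok"))
}

#' Interaction between fidget and running modulation
#'
#' Relates per-cell fidget and running Cohen's d values: their covariance
#' and correlation, the fraction of running-modulated cells that are also
#' fidget-modulated, and a per-type breakdown.
#'
#' @param d_fidget,d_running Aligned per-cell Cohen's d vectors.
#' @param sig_fidget,sig_running Aligned logical significance flags.
#' @param type_label Optional per-cell response-type labels for the
#'   breakdown table.
#' @return A list: `covariance`, `correlation`, `joint_fraction`
#'   (`|running & fidget| / |running|`, `NA` when no cell is
#'   running-modulated), `scatter` tibble, and `by_type` breakdown (when
#'   types are given).
#' @export
modulation_interaction <- function(d_fidget, d_running, sig_fidget,
                                   sig_running, type_label = NULL) {
  stopifnot(length(d_fidget) == length(d_running))
  keep <- is.finite(d_fidget) & is.finite(d_running)
  covariance <- if (sum(keep) >= 2) cov(d_fidget[keep], d_running[keep])
    else NA_real_
  correlation <- if (sum(keep) >= 2 && sd(d_fidget[keep]) > 0 &&
                       sd(d_running[keep]) > 0)
    cor(d_fidget[keep], d_running[keep]) else NA_real_
  n_run <- sum(sig_running, na.rm = TRUE)
  joint <- sum(sig_running & sig_fidget, na.rm = TRUE)
  scatter <- tibble(cell = seq_along(d_fidget), d_fidget = d_fidget,
                    d_running = d_running, sig_fidget = sig_fidget,
                    sig_running = sig_running)
  by_type <- NULL
  if (!is.null(type_label)) {
    scatter$type_label <- type_label
    by_type <- scatter |>
      group_by(.data$type_label) |>
      summarise(n = n(),
                pct_sig_fidget = 100 * mean(.data$sig_fidget, na.rm = TRUE),
                pct_sig_running = 100 * mean(.data$sig_running, na.rm = TRUE),
                .groups = "drop")
  }
  list(covariance = covariance, correlation = correlation,
       joint_fraction = if (n_run > 0) joint / n_run else NA_real_,
       n_sig_running = n_run, n_joint = joint,
       scatter = scatter, by_type = by_type)
}

#' Direction and temporal-frequency tuning metrics
#'
#' Computes, per neuron, the direction selectivity index
#' `DSI = (R_pref - R_null) / (R_pref + R_null)` (with `R_null` the mean
#' response 180 degrees opposite the preferred direction), the preferred
#' orientation (`direction mod 180`) and the preferred temporal frequency.
#'
#' @param dff Neurons x frames dF/F matrix.
#' @param stim_table Stimulus table with grating rows.
#' @return A tibble `neuron_id`, `dsi`, `pref_direction`,
#'   `pref_orientation`, `pref_tf`, `flag` (`"undefined"` when
#'   `R_pref + R_null <= 0`).
#' @export
tuning_metrics <- function(dff, stim_table) {
  pref <- preferred_condition(dff, stim_table)
  gr <- stim_table[stim_table$stimulus_type == "grating", , drop = FALSE]
  n <- nrow(dff)
  dsi <- numeric(n); flag <- rep("ok", n)
  for (i in seq_len(n)) {
    pd <- pref$direction_deg[i]; ptf <- pref$temporal_frequency_hz[i]
    r_pref <- pref$mean_response[i]
    null_dir <- (pd + 180) %% 360
    r_null <- mean(preferred_trial_means(dff[i, ], stim_table, null_dir, ptf))
    if (!is.finite(r_null) || r_pref + r_null <= 0) {
      dsi[i] <- NA_real_; flag[i] <- "undefined"
    } else {
      dsi[i] <- (r_pref - r_null) / (r_pref + r_null)
    }
  }
  tibble(neuron_id = pref$neuron_id, dsi = dsi,
         pref_direction = pref$direction_deg,
         pref_orientation = pref$direction_deg %% 180,
         pref_tf = pref$temporal_frequency_hz, flag = flag)
}

#' Per-frame state masks from events and running speed
#'
#' Builds the mutually exclusive frame masks used by the modulation
#' analysis: fidget frames (inside detected events) and running frames
#' (speed above `threshold` cm/s sustained for at least `min_duration_s`).
#'
#' @param n_frames Session length in frames.
#' @param events Fidget event tibble.
#' @param running_speed Per-frame speed, cm/s.
#' @param fps Frames per second.
#' @param threshold Running speed threshold, cm/s.
#' @param min_duration_s Minimum sustained duration to count as running.
#' @return A list of logical vectors `fidget` and `running` (running frames
#'   exclude fidget frames).
#' @export
state_masks <- function(n_frames, events, running_speed, fps = 30,
                        threshold = 1, min_duration_s = 1) {
  fidget <- logical(n_frames)
  for (e in seq_len(nrow(events))) {
    fidget[events$onset_frame[e]:(events$offset_frame[e] - 1L)] <- TRUE
  }
  fast <- running_speed > threshold
  r <- rle(fast)
  r$values <- r$values & r$lengths >= fps * min_duration_s
  running <- inverse.rle(r) & !fidget
  list(fidget = fidget, running = running)
}
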