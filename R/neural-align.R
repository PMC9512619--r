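#' Align dF/F traces to fidget onsets and z-score per trial
#'
#' Crops a 300-sample window around each fidget onset (100 frames, ~3 s,
#' before onset; 200 frames, ~6 s, after) for every neuron and normalizes
#' each trial by subtracting the mean and dividing by the SD of its own
#' 100-frame baseline. Events without a full window are dropped and counted;
#' trials whose baseline SD is zero are excluded (default) or stabilized
#' with a small epsilon.
#'
#' @param dff Numeric matrix, neurons x frames, in dF/F units.
#' @param events Event tibble with `onset_frame` (1-based; onset is the
#'   first post window sample).
#' @param pre,post Window sizes in frames.
#' @param zero_sd How to treat trials with zero baseline SD: `"drop"`
#'   (default) or `"epsilon"` (stabilize the SD with 1e-6).
#' @return An object of class `aligned_trials`: list with `z` and `raw`
#'   arrays (neurons x retained events x (pre + post)), `retained_events`,
#'   `n_dropped_events` (no full window), `dropped_trials` (neuron/event
#'   pairs excluded for zero baseline SD), `pre`, `post`.
#' @export
align_and_zscore <- function(dff, events, pre = 100L, post = 200L,
                             zero_sd = c("drop", "epsilon")) {
  zero_sd <- match.arg(zero_sd)
  n <- nrow(dff); total <- ncol(dff)
  ok <- events$onset_frame - pre >= 1L & events$onset_frame + post - 1L <= total
  retained <- events[ok, , drop = FALSE]
  ne <- nrow(retained)
  win <- pre + post
  raw <- array(NA_real_, dim = c(n, ne, win))
  z <- array(NA_real_, dim = c(n, ne, win))
  dropped <- 0L
  for (e in seq_len(ne)) {
    o <- retained$onset_frame[e]
    idx <- (o - pre):(o + post - 1L)
    tr <- dff[, idx, drop = FALSE]
    raw[, e, ] <- tr
    bmean <- rowMeans(tr[, seq_len(pre), drop = FALSE])
    bsd <- apply(tr[, seq_len(pre), drop = FALSE], 1, sd)
    bad <- bsd == 0
    if (any(bad)) {
      if (zero_sd == "epsilon") {
        bsd[bad] <- 1e-6
        bad[] <- FALSE
      } else {
        dropped <- dropped + sum(bad)
      }
    }
    zt <- (tr - bmean) / bsd
    zt[bad, ] <- NA_real_
    z[, e, ] <- zt
  }
  structure(
    list(z = z, raw = raw, retained_events = retained,
         n_dropped_events = sum(!ok), n_zero_sd_trials = dropped,
         pre = as.integer(pre), post = as.integer(post)),
    class = "aligned_trials")
}

#' @export
print.aligned_trials <- function(x, ...) {
  cat(sprintf("<aligned_trials> %d neurons x %d events x %d samples (%d pre + %d post); %d events dropped, %d zero-SD trials\n",
              dim(x$z)[1], dim(x$z)[2], dim(x$z)[3], x$pre, x$post,
              x$n_dropped_events, x$n_zero_sd_trials))
  invisible(x)
}

#' Per-neuron mean responses
#'
#' Averages the per-trial z-scored windows into each neuron's mean z-scored
#' trace and computes post-window raw dF/F summary statistics (used by the
#' threshold criteria). Neurons with fewer than `min_trials` usable trials
#' are flagged and excluded from downstream clustering.
#'
#' @param aligned An [align_and_zscore()] result.
#' @param min_trials Minimum usable trials for a neuron to be clustered.
#' @return A list with `mean_z` (neurons x window matrix), `summary`
#'   (tibble `neuron_id`, `n_trials`, `mean_dff_post`, `max_dff_post`,
#'   `clusterable`), and the window sizes.
#' @export
mean_responses <- function(aligned, min_trials = 3L) {
  stopifnot(inherits(aligned, "aligned_trials"))
  n <- dim(aligned$z)[1]
  win <- dim(aligned$z)[3]
  post_idx <- (aligned$pre + 1L):win
  mean_z <- matrix(NA_real_, n, win)
  n_trials <- integer(n)
  mean_post <- numeric(n); max_post <- numeric(n); min_post <- numeric(n)
  for (i in seq_len(n)) {
    zi <- aligned$z[i, , , drop = FALSE]
    dim(zi) <- dim(aligned$z)[2:3]
    usable <- stats::complete.cases(zi)
    n_trials[i] <- sum(usable)
    if (n_trials[i] > 0) {
      mean_z[i, ] <- colMeans(zi[usable, , drop = FALSE])
      ri <- aligned$raw[i, , , drop = FALSE]
      dim(ri) <- dim(aligned$raw)[2:3]
      post_raw <- colMeans(ri[usable, post_idx, drop = FALSE])
      mean_post[i] <- mean(post_raw)
      max_post[i] <- max(post_raw)
      min_post[i] <- min(post_raw)
    } else {
      mean_post[i] <- NA_real_; max_post[i] <- NA_real_
      min_post[i] <- NA_real_
    }
  }
  list(mean_z = mean_z,
       summary = tibble(neuron_id = seq_len(n), n_trials = n_trials,
                        mean_dff_post = mean_post, max_dff_post = max_post,
                        min_dff_post = min_post,
                        clusterable = n_trials >= min_trials),
       pre = aligned$pre, post = aligned$post)
}
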