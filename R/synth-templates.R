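#' Canonical fidget response templates
#'
#' Builds the four archetypal event-aligned response waveforms used by the
#' trace generator and by cluster labeling: `neutral` (flat), `phasic`
#' (transient rise at fidget onset decaying with the calcium-indicator time
#' constant), `active` (rise to a plateau sustained through the whole
#' post-onset window) and `depressed` (sustained negative deflection). Each
#' waveform has 300 samples at `fps` Hz: samples 1--100 precede onset and are
#' identically zero (responses are causal), samples 101--300 follow onset.
#' Non-neutral waveforms are normalized to unit peak absolute amplitude.
#'
#' @param indicator_decay_tau Calcium indicator decay time constant in
#'   seconds. The default 0.7 s is typical GCaMP6f kinetics.
#' @param fps Sampling rate in frames/s.
#' @return An object of class `response_templates`: a list with `waveforms`
#'   (4 x 300 matrix, rows named by type), `tau`, `fps`.
#' @examples
#' tpl <- response_templates()
#' round(tpl$waveforms["phasic", 101:104], 3)
#' @export
response_templates <- function(indicator_decay_tau = 0.7, fps = 30) {
  if (!is.numeric(indicator_decay_tau) || indicator_decay_tau <= 0) {
    abort("`indicator_decay_tau` must be > 0.")
  }
  n_pre <- 100L
  n_post <- 200L
  t_post <- (0:(n_post - 1)) / fps   # seconds since onset
  decay <- exp(-t_post / indicator_decay_tau)

  post <- rbind(
    neutral   = rep(0, n_post),
    phasic    = decay,                                     # impulse * indicator
    active    = 1 - exp(-t_post / indicator_decay_tau),    # step * indicator
    depressed = -(1 - exp(-t_post / indicator_decay_tau))
  )
  # unit peak magnitude for the non-flat archetypes
  for (i in 2:4) post[i, ] <- post[i, ] / max(abs(post[i, ]))

  waveforms <- cbind(matrix(0, 4, n_pre), post)
  rownames(waveforms) <- response_type_levels()
  structure(list(waveforms = waveforms,
                 tau = indicator_decay_tau, fps = fps),
            class = "response_templates")
}

#' @export
print.response_templates <- function(x, ...) {
  cat(sprintf("<response_templates> 4 x %d samples at %g fps, tau = %g s\n",
              ncol(x$waveforms), x$fps, x$tau))
  invisible(x)
}

#' @rdname response_templates
#' @param x A `response_templates` object.
#' @param ... Unused.
#' @return `tidy()` returns one row per (type, sample) with the time relative
#'   to fidget onset in seconds.
#' @export
tidy.response_templates <- function(x, ...) {
  n <- ncol(x$waveforms)
  tibble(
    type = factor(rep(rownames(x$waveforms), each = n),
                  levels = response_type_levels()),
    sample = rep(seq_len(n), times = 4),
    time_s = rep((seq_len(n) - 101) / x$fps, times = 4),
    value = as.vector(t(x$waveforms))
  )
}

#' @rdname response_templates
#' @param object A `response_templates` object.
#' @export
autoplot.response_templates <- function(object, ...) {
  ggplot(tidy(object), aes(.data$time_s, .data$value, colour = .data$type)) +
    geom_line() +
    labs(x = "time from fidget onset (s)", y = "template amplitude (a.u.)",
         colour = "response type") +
    theme_minimal()
}
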