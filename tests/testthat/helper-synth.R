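# Small factory configs shared across tests. Sessions are kept short so the
# default suite stays fast; acceptance-scale runs live in test-acceptance.R.

tiny_config <- function(session_duration = 30, n_fidgets = 2, n_neurons = 8,
                        seed = 42L, ...) {
  synth_config(session_duration = session_duration, n_fidgets = n_fidgets,
               n_neurons = n_neurons, image_size = c(80, 80), seed = seed,
               min_event_gap_s = 1, ...)
}

# A frame stack containing a textured square that translates `shift` pixels
# to the right between consecutive frames.
translating_frames <- function(n_frames = 2, shift = 3, size = 64,
                               patch = 40, seed = 1) {
  set.seed(seed)
  tex <- matrix(runif(patch * patch), patch, patch)
  arr <- array(0.5, dim = c(size, size, n_frames))
  r0 <- (size - patch) %/% 2
  for (f in seq_len(n_frames)) {
    c0 <- r0 + (f - 1L) * shift
    arr[(r0 + 1):(r0 + patch), (c0 + 1):(c0 + patch), f] <- tex
  }
  arr
}

# Adjusted Rand index between two labelings (used for recovery checks).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

# Exhaustive Benjamini-Hochberg step-up: reject H_(1..k*) where k* is the
# largest k with p_(k) <= k q / m. Independent oracle for p.adjust-based
# significance flags.
bh_stepup_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k_star <- 0L
  for (k in seq_len(m)) if (ps[k] <= k * q / m) k_star <- k
  reject <- logical(m)
  if (k_star > 0) reject[ord[seq_len(k_star)]] <- TRUE
  reject
}
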