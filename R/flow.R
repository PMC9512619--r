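# Dense two-frame optical flow by polynomial expansion (Farneback).
#
# Each image is locally approximated as a quadratic polynomial
# f(x) ~ x'Ax + b'x + c under a Gaussian applicability; equating the
# expansions of the two frames gives, per pixel, A d = delta_b for the
# displacement d, which is solved in a least-squares sense over an
# averaging window. The estimate is refined over a coarse-to-fine pyramid
# with warping iterations.

# Cache of banded 1-D correlation matrices and warp grids, keyed by size
# and kernel. Correlation with replicate edge padding becomes two BLAS
# matrix products, which is the fastest route in R for small frames.
.flow_cache <- new.env(parent = emptyenv())

conv1_matrix <- function(n, kern) {
  key <- paste0("K", n, "_", paste(signif(kern, 12), collapse = ","))
  hit <- .flow_cache[[key]]
  if (!is.null(hit)) return(hit)
  r <- (length(kern) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (j in seq_along(kern)) {
    src <- pmin(pmax(seq_len(n) + (j - r - 1L), 1L), n)
    K[cbind(seq_len(n), src)] <- K[cbind(seq_len(n), src)] + kern[j]
  }
  .flow_cache[[key]] <- K
  K
}

# Separable 2-D correlation with replicate edge padding. Kernels must have
# odd length; `w_row` runs down columns (y), `w_col` across rows (x).
conv_cor <- function(img, w_row, w_col) {
  conv1_matrix(nrow(img), w_row) %*% img %*%
    t(conv1_matrix(ncol(img), w_col))
}

# Quadratic polynomial expansion of an image. Returns per-pixel fields of
# f ~ x'Ax + b'x + c with A = [[axx, axy], [axy, ayy]] and b = (bx, by),
# x = (col, row) offsets.
poly_expansion <- function(img, poly_n = 7L, poly_sigma = 1.5) {
  stopifnot(poly_n %% 2 == 1)
  r <- (poly_n - 1L) %/% 2L
  x <- -r:r
  g <- exp(-x^2 / (2 * poly_sigma^2)); g <- g / sum(g)
  xg <- x * g
  x2g <- x^2 * g
  m00 <- conv_cor(img, g, g)
  m10 <- conv_cor(img, g, xg)          # x moment (columns)
  m01 <- conv_cor(img, xg, g)          # y moment (rows)
  m20 <- conv_cor(img, g, x2g)
  m02 <- conv_cor(img, x2g, g)
  m11 <- conv_cor(img, xg, xg)

  s0 <- sum(g); s2 <- sum(x2g); s4 <- sum(x^4 * g)
  # G = sum a * phi phi' over basis (1, x, y, x^2, y^2, xy), separable weights
  G <- matrix(0, 6, 6)
  G[1, 1] <- s0 * s0
  G[2, 2] <- s2 * s0; G[3, 3] <- s0 * s2
  G[1, 4] <- G[4, 1] <- s2 * s0
  G[1, 5] <- G[5, 1] <- s0 * s2
  G[4, 4] <- s4 * s0; G[5, 5] <- s0 * s4
  G[4, 5] <- G[5, 4] <- s2 * s2
  G[6, 6] <- s2 * s2
  Gi <- solve(G)
  m <- list(m00, m10, m01, m20, m02, m11)
  coef <- function(i) {
    out <- 0
    for (j in 1:6) if (Gi[i, j] != 0) out <- out + Gi[i, j] * m[[j]]
    out
  }
  list(c0 = coef(1), bx = coef(2), by = coef(3),
       axx = coef(4), ayy = coef(5), axy = coef(6) / 2)
}

# Box mean filter of odd width.
box_mean <- function(m, k) {
  box <- rep(1 / k, k)
  conv_cor(m, box, box)
}

# Bilinear warp of img sampled at (x + u, y + v), clamped to the frame.
warp_image <- function(img, u, v) {
  h <- nrow(img); w <- ncol(img)
  key <- paste0("G", h, "x", w)
  grids <- .flow_cache[[key]]
  if (is.null(grids)) {
    grids <- list(X = matrix(rep(seq_len(w), each = h), h, w),
                  Y = matrix(rep(seq_len(h), times = w), h, w))
    .flow_cache[[key]] <- grids
  }
  X <- grids$X + u
  Y <- grids$Y + v
  X <- pmin(pmax(X, 1), w); Y <- pmin(pmax(Y, 1), h)
  x0 <- pmin(floor(X), w - 1L); y0 <- pmin(floor(Y), h - 1L)
  fx <- X - x0; fy <- Y - y0
  idx <- function(yy, xx) (xx - 1L) * h + yy
  img[idx(y0, x0)] * (1 - fx) * (1 - fy) +
    img[idx(y0, x0 + 1L)] * fx * (1 - fy) +
    img[idx(y0 + 1L, x0)] * (1 - fx) * fy +
    img[idx(y0 + 1L, x0 + 1L)] * fx * fy
}

downsample2 <- function(img) {
  h2 <- nrow(img) %/% 2L; w2 <- ncol(img) %/% 2L
  img <- img[seq_len(2L * h2), seq_len(2L * w2), drop = FALSE]
  0.25 * (img[seq(1, 2 * h2, 2), seq(1, 2 * w2, 2)] +
            img[seq(2, 2 * h2, 2), seq(1, 2 * w2, 2)] +
            img[seq(1, 2 * h2, 2), seq(2, 2 * w2, 2)] +
            img[seq(2, 2 * h2, 2), seq(2, 2 * w2, 2)])
}

upsample2 <- function(m, h, w) {
  big <- m[pmin(((seq_len(h) - 1L) %/% 2L) + 1L, nrow(m)),
           pmin(((seq_len(w) - 1L) %/% 2L) + 1L, ncol(m)), drop = FALSE]
  big
}

# Single-level displacement refinement with `iterations` warping passes.
flow_single_level <- function(f1, f2, u, v, winsize, iterations,
                              poly_n, poly_sigma) {
  win <- as.integer(winsize)
  if (win %% 2L == 0L) win <- win + 1L   # symmetric averaging window
  blur <- function(m) box_mean(m, win)
  p1 <- poly_expansion(f1, poly_n, poly_sigma)
  for (it in seq_len(iterations)) {
    f2w <- if (all(u == 0) && all(v == 0)) f2 else warp_image(f2, u, v)
    p2 <- poly_expansion(f2w, poly_n, poly_sigma)
    a <- (p1$axx + p2$axx) / 2
    b <- (p1$ayy + p2$ayy) / 2
    cc <- (p1$axy + p2$axy) / 2
    dbx <- -0.5 * (p2$bx - p1$bx) + a * u + cc * v
    dby <- -0.5 * (p2$by - p1$by) + cc * u + b * v
    g11 <- blur(a * a + cc * cc)
    g12 <- blur(a * cc + cc * b)
    g22 <- blur(cc * cc + b * b)
    h1 <- blur(a * dbx + cc * dby)
    h2 <- blur(cc * dbx + b * dby)
    det <- g11 * g22 - g12 * g12
    det[abs(det) < 1e-12] <- Inf       # degenerate: leave displacement at 0
    u <- (g22 * h1 - g12 * h2) / det
    v <- (g11 * h2 - g12 * h1) / det
  }
  list(u = u, v = v)
}

#' Dense Farneback optical flow between two frames
#'
#' Estimates the per-pixel displacement field from `frame_a` to `frame_b`
#' using two-frame motion estimation based on quadratic polynomial
#' expansion, with a 30-pixel averaging window by default, three pyramid
#' levels at scale 0.5, and three warping iterations per level.
#'
#' @param frame_a,frame_b Same-shape grayscale frame matrices.
#' @param kernel_size Averaging window size in pixels.
#' @param levels Pyramid levels (levels that would shrink a dimension below
#'   16 px are skipped).
#' @param iterations Warping iterations per level.
#' @param poly_n,poly_sigma Polynomial expansion neighborhood (odd) and
#'   Gaussian applicability width.
#' @return An object of class `flow_field`: list with matrices `u`
#'   (horizontal, +x right) and `v` (vertical, +y down) in pixels/frame.
#' @examples
#' a <- matrix(runif(64 * 64), 64, 64)
#' fl <- farneback_flow(a, a)
#' max(abs(fl$u))
#' @export
farneback_flow <- function(frame_a, frame_b, kernel_size = 30L, levels = 3L,
                           iterations = 3L, poly_n = 7L, poly_sigma = 1.5) {
  if (!all(dim(frame_a) == dim(frame_b))) {
    abort("frames must have identical dimensions")
  }
  pyr_a <- list(frame_a); pyr_b <- list(frame_b)
  while (length(pyr_a) < levels &&
         min(dim(pyr_a[[length(pyr_a)]])) >= 32) {
    pyr_a[[length(pyr_a) + 1L]] <- downsample2(pyr_a[[length(pyr_a)]])
    pyr_b[[length(pyr_b) + 1L]] <- downsample2(pyr_b[[length(pyr_b)]])
  }
  u <- v <- matrix(0, nrow(pyr_a[[length(pyr_a)]]), ncol(pyr_a[[length(pyr_a)]]))
  for (lev in rev(seq_along(pyr_a))) {
    f1 <- pyr_a[[lev]]; f2 <- pyr_b[[lev]]
    if (nrow(u) != nrow(f1) || ncol(u) != ncol(f1)) {
      u <- 2 * upsample2(u, nrow(f1), ncol(f1))
      v <- 2 * upsample2(v, nrow(f1), ncol(f1))
    }
    win <- max(5L, as.integer(round(kernel_size / 2^(lev - 1L))))
    fl <- flow_single_level(f1, f2, u, v, win, iterations, poly_n, poly_sigma)
    u <- fl$u; v <- fl$v
  }
  structure(list(u = u, v = v), class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("<flow_field> %d x %d, mean |flow| = %.3f px\n",
              nrow(x$u), ncol(x$u), mean(sqrt(x$u^2 + x$v^2))))
  invisible(x)
}

#' Integrated optical-flow magnitude of fidget events
#'
#' For each event, sums the per-pixel L2 norm of the Farneback flow field
#' over all consecutive frame pairs inside the event window. Magnitude is
#' non-negative and, for a lift-and-return movement, proportional to the
#' total path length traveled by the body, so it tracks event amplitude
#' rather than duration.
#'
#' @param frames Frame array (cropped/preprocessed video).
#' @param events Event tibble with `onset_frame`, `offset_frame`.
#' @param ... Passed to [farneback_flow()].
#' @return The events tibble with columns `magnitude` and `flag`
#'   (`"single frame"` when an event spans < 2 frames and the magnitude is
#'   0 by convention).
#' @export
event_magnitude <- function(frames, events, ...) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  total <- dim(frames)[3]
  mags <- numeric(nrow(events))
  flags <- rep("ok", nrow(events))
  for (e in seq_len(nrow(events))) {
    on <- events$onset_frame[e]; off <- events$offset_frame[e]
    if (on < 1 || off > total + 1L) abort("event lies outside the frame range")
    if (off - on < 2L) {
      flags[e] <- "single frame"
      next
    }
    m <- 0
    for (f in on:(off - 2L)) {
      fl <- farneback_flow(frames[, , f], frames[, , f + 1L], ...)
      m <- m + sum(sqrt(fl$u^2 + fl$v^2))
    }
    mags[e] <- m
  }
  events |> mutate(magnitude = mags, flag = flags)
}

#' Stereotypy of fidget magnitudes
#'
#' Measures how standardized fidget events are: the fraction of events whose
#' integrated flow magnitude lies within 30% of the maximum magnitude
#' (i.e. magnitude >= 0.7 * max), together with the cumulative distribution
#' of magnitudes for plotting.
#'
#' @param magnitudes Numeric vector of event magnitudes (>= 1 value).
#' @param within Fractional band below the maximum (default 0.3).
#' @return An object of class `fidget_stereotypy`: list with `fraction`,
#'   `threshold`, `n`, and `cdf` (tibble `magnitude`, `cum_prob`).
#' @examples
#' magnitude_stereotypy(c(10, 8, 5, 2))$fraction
#' @export
magnitude_stereotypy <- function(magnitudes, within = 0.3) {
  if (!length(magnitudes)) abort("at least one magnitude is required")
  thr <- (1 - within) * max(magnitudes)
  m <- sort(magnitudes)
  structure(
    list(fraction = mean(magnitudes >= thr),
         threshold = thr,
         n = length(magnitudes),
         cdf = tibble(magnitude = m,
                      cum_prob = seq_along(m) / length(m))),
    class = "fidget_stereotypy")
}

#' @export
print.fidget_stereotypy <- function(x, ...) {
  cat(sprintf("<fidget_stereotypy> %.1f%% of %d events within %.0f%% of the max magnitude\n",
              100 * x$fraction, x$n, 100 * (1 - x$threshold / max(x$cdf$magnitude))))
  invisible(x)
}

#' @rdname magnitude_stereotypy
#' @param object A `fidget_stereotypy` object.
#' @param ... Unused.
#' @export
autoplot.fidget_stereotypy <- function(object, ...) {
  ggplot(object$cdf, aes(.data$magnitude, .data$cum_prob)) +
    geom_step() +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dashed") +
    labs(x = "integrated flow magnitude", y = "cumulative probability") +
    theme_minimal()
}
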