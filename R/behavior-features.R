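#' Preprocess behavioral video frames
#'
#' Normalizes a grayscale frame stack to \[0, 1\] (min-max over the whole
#' stack), applies power-law (gamma) compression, and crops to a rectangle.
#' The crop uses pixel coordinates with origin at the top-left corner and is
#' half-open on the high edge, so `crop = c(10, 10, 74, 74)` yields 64 x 64
#' output frames.
#'
#' @param frames Numeric array `height x width x n_frames` (a single frame
#'   matrix is also accepted).
#' @param crop Crop rectangle `c(x0, y0, x1, y1)`; `NULL` keeps the full
#'   frame.
#' @param gamma Power-law exponent applied to normalized intensities;
#'   `gamma = 1` is the identity, the default 0.5 brightens shadows.
#' @return Cropped numeric array with intensities in \[0, 1\].
#' @examples
#' fr <- array(runif(80 * 80 * 3), c(80, 80, 3))
#' dim(preprocess_frames(fr, crop = c(8, 8, 72, 72)))
#' @export
preprocess_frames <- function(frames, crop = NULL, gamma = 0.5) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  stopifnot(length(dim(frames)) == 3)
  h <- dim(frames)[1]; w <- dim(frames)[2]
  rng <- range(frames)   # normalization range over the full (uncropped) stack
  if (!is.null(crop)) {
    x0 <- crop[1]; y0 <- crop[2]; x1 <- crop[3]; y1 <- crop[4]
    if (x1 <= x0 || y1 <= y0) abort("crop rectangle must have positive size")
    if (x0 < 1 || y0 < 1 || x1 > w + 1 || y1 > h + 1) {
      abort("crop rectangle lies outside the frame")
    }
    # cropping first is pointwise-equivalent and avoids full-stack copies
    frames <- frames[y0:(y1 - 1L), x0:(x1 - 1L), , drop = FALSE]
  }
  if (rng[2] > rng[1]) {
    frames <- (frames - rng[1]) / (rng[2] - rng[1])
  } else {
    frames <- frames - rng[1]  # constant stack -> constant zeros
  }
  frames^gamma
}

#' Histogram-of-oriented-gradients features per frame
#'
#' Computes HOG descriptors with unsigned gradient orientations binned into
#' `bins` histogram bins over non-overlapping square cells of `cell_px`
#' pixels, one cell per block and no cross-cell normalization. A frame of
#' 64 x 64 pixels with 32-pixel cells and 8 bins yields
#' (64/32)^2 x 8 = 32 features.
#'
#' @param frames Numeric array `height x width x n_frames`.
#' @param bins Number of orientation bins over \[0, 180) degrees.
#' @param cell_px Cell side length in pixels; frame dimensions are truncated
#'   to whole cells.
#' @return Matrix `n_frames x n_features` of gradient-magnitude-weighted
#'   orientation histograms.
#' @examples
#' fr <- array(runif(64 * 64 * 2), c(64, 64, 2))
#' dim(hog_features(fr))
#' @export
hog_features <- function(frames, bins = 8L, cell_px = 32L) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  h <- dim(frames)[1]; w <- dim(frames)[2]; nf <- dim(frames)[3]
  ncy <- h %/% cell_px; ncx <- w %/% cell_px
  if (ncy < 1 || ncx < 1) {
    abort(sprintf("frame (%d x %d) smaller than one %d-px cell", h, w, cell_px))
  }
  hu <- ncy * cell_px; wu <- ncx * cell_px
  # cell id and, within each frame, (cell, bin) accumulation indices
  cell_of <- matrix(0L, hu, wu)
  cy <- (seq_len(hu) - 1L) %/% cell_px
  cx <- (seq_len(wu) - 1L) %/% cell_px
  cell_of[] <- rep(cy, times = wu) + rep(cx, each = hu) * ncy  # 0-based cell
  n_cells <- ncy * ncx
  n_feat <- n_cells * bins

  out <- matrix(0, nf, n_feat)
  for (f in seq_len(nf)) {
    img <- frames[seq_len(hu), seq_len(wu), f]
    gx <- matrix(0, hu, wu)
    gy <- matrix(0, hu, wu)
    gx[, 2:(wu - 1)] <- (img[, 3:wu] - img[, 1:(wu - 2)]) / 2
    gy[2:(hu - 1), ] <- (img[3:hu, ] - img[1:(hu - 2), ]) / 2
    mag <- sqrt(gx * gx + gy * gy)
    ang <- atan2(gy, gx) * 180 / pi        # (-180, 180]
    ang <- ang %% 180                      # unsigned orientation [0, 180)
    bin <- pmin(floor(ang / (180 / bins)), bins - 1L)
    idx <- cell_of * bins + bin + 1L       # 1-based (cell, bin) slot
    acc <- rowsum(as.vector(mag), as.vector(idx))
    out[f, as.integer(rownames(acc))] <- acc[, 1]
  }
  out
}

#' Extract one-second block features
#'
#' The per-frame HOG descriptors are reduced with PCA and concatenated into
#' non-overlapping one-second blocks (`fps` consecutive frames), the feature
#' unit the fidget detector classifies. The PCA basis must be fit on
#' training frames only: when `pca` is `NULL` a basis is fit on the supplied
#' frames and returned; at inference the stored basis must be passed in, and
#' is never refit.
#'
#' @param frames Preprocessed frame array (see [preprocess_frames()]).
#' @param fps Frames per second, i.e. frames per block.
#' @param bins,cell_px HOG parameters, see [hog_features()].
#' @param n_components Number of principal components (capped at the number
#'   of HOG features and at the number of frames).
#' @param pca Optional PCA basis (as returned in `$pca`) to project with.
#' @return A list with `blocks` (matrix `n_blocks x (fps * n_components)`),
#'   `block_frames` (tibble `block`, `start_frame`, `end_frame`, half-open),
#'   and `pca` (list `center`, `rotation`).
#' @examples
#' fr <- array(runif(64 * 64 * 60), c(64, 64, 60))
#' fb <- extract_block_features(fr, fps = 30, n_components = 5)
#' dim(fb$blocks)
#' @export
extract_block_features <- function(frames, fps = 30, bins = 8L,
                                   cell_px = 32L, n_components = 50L,
                                   pca = NULL) {
  feats <- hog_features(frames, bins = bins, cell_px = cell_px)
  nf <- nrow(feats)
  fpb <- as.integer(round(fps))
  n_blocks <- nf %/% fpb
  if (n_blocks < 1) {
    warn("fewer frames than one block; returning no blocks")
  }
  if (is.null(pca)) {
    k <- min(n_components, ncol(feats), nf)
    fit <- prcomp(feats, center = TRUE, scale. = FALSE, rank. = k)
    pca <- list(center = fit$center, rotation = fit$rotation)
  }
  reduced <- sweep(feats, 2, pca$center) %*% pca$rotation
  k <- ncol(reduced)
  blocks <- matrix(0, n_blocks, fpb * k)
  if (n_blocks >= 1) {
    for (b in seq_len(n_blocks)) {
      rows <- ((b - 1L) * fpb + 1L):(b * fpb)
      blocks[b, ] <- as.vector(t(reduced[rows, , drop = FALSE]))
    }
  }
  list(blocks = blocks,
       block_frames = tibble(
         block = seq_len(max(n_blocks, 0L)),
         start_frame = (seq_len(max(n_blocks, 0L)) - 1L) * fpb + 1L,
         end_frame = seq_len(max(n_blocks, 0L)) * fpb + 1L),
       pca = pca)
}

# Majority-vote reduction of per-frame labels to per-block labels: a block
# is `fidget` when more than half of its frames are fidget-labeled,
# otherwise the more frequent of movement/resting.
block_labels_from_frames <- function(labels, fps) {
  fpb <- as.integer(round(fps))
  n_blocks <- length(labels) %/% fpb
  vapply(seq_len(n_blocks), function(b) {
    lab <- labels[((b - 1L) * fpb + 1L):(b * fpb)]
    if (mean(lab == "fidget") > 0.5) return("fidget")
    if (sum(lab == "movement") >= sum(lab == "resting")) "movement" else "resting"
  }, character(1))
}
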