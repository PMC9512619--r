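#' Train the fidget detector
#'
#' Fits the video classification pipeline: per-frame HOG descriptors reduced
#' by PCA (basis fit on the training frames only), concatenated into
#' one-second blocks, and classified into fidget / movement / resting by a
#' radial-basis-function SVM whose cost and kernel-width parameters are
#' selected by a cross-validated grid search. Training blocks are labeled by
#' majority vote over their frames (a block is `fidget` when more than half
#' of its frames are). Classes are weighted inversely to their block
#' frequency so the rare fidget class is not swamped.
#'
#' @param videos A frame array or list of frame arrays (one per session).
#'   A list element may also be a zero-argument function returning the
#'   array: sessions are then rendered/loaded one at a time and released
#'   after featurization, which keeps hour-scale cohorts within memory.
#' @param labels Per-frame label vector/factor, or list matching `videos`.
#' @param crop Optional crop rectangle passed to [preprocess_frames()].
#' @param gamma Power-law exponent for preprocessing.
#' @param fps Frames per second (frames per block).
#' @param bins,cell_px,n_components Feature parameters, see
#'   [hog_features()] and [extract_block_features()].
#' @param cost_grid,gamma_grid Grids for the SVM cost C and RBF width.
#' @param cv_folds Cross-validation folds for the grid search.
#' @param seed Seed for fold assignment.
#' @return An object of class `fidget_detector` with the SVM, the PCA basis,
#'   the feature configuration and the grid-search table.
#' @export
train_fidget_detector <- function(videos, labels, crop = NULL, gamma = 0.5,
                                  fps = 30, bins = 8L, cell_px = 32L,
                                  n_components = 50L,
                                  cost_grid = c(1, 10, 100),
                                  gamma_grid = c(0.001, 0.01, 0.1),
                                  cv_folds = 3L, seed = 1L) {
  if (!is.list(videos)) videos <- list(videos)
  if (is.data.frame(labels) || !is.list(labels)) labels <- list(labels)
  stopifnot(length(videos) == length(labels))
  if (!length(cost_grid) || !length(gamma_grid)) {
    abort("the (C, gamma) grid must be non-empty")
  }
  fpb <- as.integer(round(fps))

  feats <- vector("list", length(videos))
  blab <- vector("list", length(videos))
  for (i in seq_along(videos)) {
    vi <- if (is.function(videos[[i]])) videos[[i]]() else videos[[i]]
    fr <- preprocess_frames(vi, crop = crop, gamma = gamma)
    rm(vi)
    feats[[i]] <- hog_features(fr, bins = bins, cell_px = cell_px)
    rm(fr)
    lab <- labels[[i]]
    if (is.data.frame(lab)) lab <- lab$label
    blab[[i]] <- block_labels_from_frames(as.character(lab), fps)
  }
  all_feats <- do.call(rbind, feats)
  k <- min(n_components, ncol(all_feats), nrow(all_feats))
  fit <- prcomp(all_feats, center = TRUE, scale. = FALSE, rank. = k)
  pca <- list(center = fit$center, rotation = fit$rotation)

  blocks <- do.call(rbind, lapply(feats, function(fm) {
    reduce_and_block(fm, pca, fpb)
  }))
  y <- factor(unlist(blab), levels = behavior_levels())
  present <- levels(droplevels(y))
  if (length(present) < 2) abort("training labels contain a single class")

  wts <- length(y) / (length(present) * table(droplevels(y)))
  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid)
  folds <- with_seed(derive_seed(seed, 21L), {
    f <- integer(length(y))
    for (cl in present) {
      idx <- which(y == cl)
      f[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
    }
    f
  })
  cv_acc <- vapply(seq_len(nrow(grid)), function(g) {
    accs <- vapply(seq_len(cv_folds), function(fold) {
      tr <- folds != fold
      if (length(unique(y[tr])) < 2 || !any(!tr)) return(NA_real_)
      m <- e1071::svm(blocks[tr, , drop = FALSE], droplevels(y[tr]),
                      kernel = "radial", cost = grid$cost[g],
                      gamma = grid$gamma[g],
                      class.weights = wts[levels(droplevels(y[tr]))],
                      scale = FALSE)
      mean(as.character(predict(m, blocks[!tr, , drop = FALSE])) ==
             as.character(y[!tr]))
    }, numeric(1))
    mean(accs, na.rm = TRUE)
  }, numeric(1))
  best <- which.max(cv_acc)
  tuning <- as_tibble(grid) |> mutate(cv_accuracy = cv_acc,
                                      selected = seq_along(cv_acc) == best)

  svm_fit <- e1071::svm(blocks, droplevels(y), kernel = "radial",
                        cost = grid$cost[best], gamma = grid$gamma[best],
                        class.weights = wts[present], scale = FALSE)
  structure(
    list(svm = svm_fit, pca = pca,
         feature_config = list(crop = crop, gamma = gamma, fps = fps,
                               bins = bins, cell_px = cell_px,
                               n_components = k),
         classes = present,
         tuning = tuning,
         validation = list(block = blocks[1, , drop = FALSE],
                           label = as.character(predict(
                             svm_fit, blocks[1, , drop = FALSE])))),
    class = "fidget_detector")
}

# Project per-frame features with a fixed PCA basis and tile into 1-s blocks.
reduce_and_block <- function(feats, pca, fpb) {
  reduced <- sweep(feats, 2, pca$center) %*% pca$rotation
  n_blocks <- nrow(reduced) %/% fpb
  blocks <- matrix(0, n_blocks, fpb * ncol(reduced))
  for (b in seq_len(n_blocks)) {
    rows <- ((b - 1L) * fpb + 1L):(b * fpb)
    blocks[b, ] <- as.vector(t(reduced[rows, , drop = FALSE]))
  }
  blocks
}

#' @export
print.fidget_detector <- function(x, ...) {
  sel <- x$tuning[x$tuning$selected, ]
  cat(sprintf("<fidget_detector> RBF SVM (C = %g, gamma = %g), %d PCA components, %d-frame blocks\n",
              sel$cost, sel$gamma, x$feature_config$n_components,
              as.integer(round(x$feature_config$fps))))
  invisible(x)
}

#' @rdname train_fidget_detector
#' @param x,object A `fidget_detector`.
#' @param ... Unused.
#' @return `tidy()` returns the grid-search table; `glance()` a one-row
#'   summary with the selected parameters and CV accuracy.
#' @export
tidy.fidget_detector <- function(x, ...) x$tuning

#' @rdname train_fidget_detector
#' @export
glance.fidget_detector <- function(x, ...) {
  sel <- x$tuning[x$tuning$selected, ]
  tibble(cost = sel$cost, gamma = sel$gamma, cv_accuracy = sel$cv_accuracy,
         n_classes = length(x$classes))
}

#' Predict per-frame behavior labels
#'
#' Runs the detector on a video: preprocessing and block features are built
#' with the model's stored configuration and PCA basis (never refit), each
#' block's predicted class is broadcast to its frames, and any trailing
#' frames not covered by a full block are labeled `resting`.
#'
#' With the default `stride` (one full block) blocks tile the video without
#' overlap, exactly as in training. A smaller stride slides the one-second
#' window by that many frames, removing the sensitivity of short events to
#' the arbitrary block phase: each frame takes the fidget label if any
#' covering block predicts fidget (movement beats resting likewise).
#'
#' @param object A `fidget_detector`.
#' @param frames Raw frame array for one session.
#' @param stride Block stride in frames; defaults to the block length
#'   (non-overlapping). Use e.g. half a block for phase-robust detection.
#' @param ... Unused.
#' @return A tibble (`frame`, `label`) covering every input frame.
#' @export
predict.fidget_detector <- function(object, frames, stride = NULL, ...) {
  fc <- object$feature_config
  fpb <- as.integer(round(fc$fps))
  stride <- as.integer(stride %||% fpb)
  stopifnot(stride >= 1L, stride <= fpb)
  fr <- preprocess_frames(frames, crop = fc$crop, gamma = fc$gamma)
  feats <- hog_features(fr, bins = fc$bins, cell_px = fc$cell_px)
  total <- dim(frames)[3]
  lab <- rep("resting", total)
  rank <- c(resting = 1L, movement = 2L, fidget = 3L)
  score <- rep(1L, total)
  for (off in seq(0L, fpb - 1L, by = stride)) {
    n_blocks <- (nrow(feats) - off) %/% fpb
    if (n_blocks < 1L) next
    blocks <- reduce_and_block(feats[(off + 1L):nrow(feats), , drop = FALSE],
                               object$pca, fpb)
    if (ncol(blocks) != ncol(object$svm$SV)) {
      abort("feature length mismatch: frames are incompatible with the model's feature configuration")
    }
    pred <- as.character(predict(object$svm, blocks))
    for (b in seq_along(pred)) {
      idx <- (off + (b - 1L) * fpb + 1L):min(off + b * fpb, total)
      r <- rank[[pred[b]]]
      upd <- r > score[idx]
      score[idx][upd] <- r
      lab[idx][upd] <- pred[b]
    }
  }
  tibble(frame = seq_len(total),
         label = factor(lab, levels = behavior_levels()))
}
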