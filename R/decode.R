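#' Embed post-fidget responses
#'
#' Projects each neuron's 200-sample mean z-scored post-fidget trace into a
#' low-dimensional embedding for decoding. The default is a 2-D UMAP with
#' `min_dist = 0` and `n_neighbors = 20`; the robustness variants used by
#' the decodability analysis are UMAP with `n_neighbors` 5 or 200, UMAP in
#' three dimensions, and PCA with 10 components.
#'
#' @param post_z Matrix, neurons x samples (post-onset window).
#' @param method `"umap"` or `"pca"`.
#' @param n_components Embedding dimensionality (2 or 3 for UMAP, 10 for
#'   the PCA variant).
#' @param n_neighbors,min_dist UMAP hyperparameters.
#' @param seed Seed; embeddings are deterministic given it.
#' @return A tibble of embedding coordinates (`dim1`, `dim2`, ...), with
#'   attributes `method` and `params`.
#' @export
embed_responses <- function(post_z, method = c("umap", "pca"),
                            n_components = 2L, n_neighbors = 20L,
                            min_dist = 0, seed = 1L) {
  method <- match.arg(method)
  x <- as.matrix(post_z)
  if (method == "umap") {
    if (nrow(x) < n_neighbors + 1L) {
      abort("too few neurons for the requested n_neighbors")
    }
    coords <- with_seed(derive_seed(seed, 41L),
      uwot::umap(x, n_neighbors = n_neighbors, min_dist = min_dist,
                 n_components = n_components, n_threads = 1,
                 n_sgd_threads = 1, batch = TRUE))
    params <- list(n_neighbors = n_neighbors, min_dist = min_dist,
                   n_components = n_components)
  } else {
    k <- min(n_components, ncol(x), nrow(x))
    coords <- prcomp(x, center = TRUE, rank. = k)$x
    params <- list(n_components = k)
  }
  out <- as_tibble(as.data.frame(coords), .name_repair = "minimal")
  names(out) <- paste0("dim", seq_len(ncol(out)))
  attr(out, "method") <- method
  attr(out, "params") <- params
  out
}

#' Balance classes by subsampling
#'
#' Randomly subsamples every class down to the count of the least prevalent
#' class, without replacement.
#'
#' @param labels Class label vector.
#' @param seed Seed for the draw.
#' @return Sorted integer indices of the retained samples.
#' @examples
#' labs <- rep(c("A", "A", "B", "C"), 10)
#' table(labs[balance_classes(labs)])
#' @export
balance_classes <- function(labels, seed = 1L) {
  tab <- table(labels)
  if (any(tab == 0) || !length(tab)) abort("every class must have >= 1 sample")
  m <- min(tab)
  with_seed(derive_seed(seed, 42L), {
    idx <- unlist(lapply(names(tab), function(cl) {
      i <- which(labels == cl)
      if (length(i) > m) sample(i, m) else i
    }))
    sort(idx)
  })
}

# Per-class F1 = TP / (TP + 0.5 (FP + FN)) from predicted/true label vectors.
per_class_f1 <- function(pred, truth, classes) {
  vapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    if (tp + 0.5 * (fp + fn) == 0) return(0)
    tp / (tp + 0.5 * (fp + fn))
  }, numeric(1))
}

# One multiclass boosted-tree fit (softmax objective, single thread).
train_booster <- function(x, y_int, n_class, max_depth, eta, nrounds) {
  xgboost::xgb.train(
    params = list(objective = "multi:softmax", num_class = n_class,
                  max_depth = max_depth, learning_rate = eta, nthread = 1),
    data = xgboost::xgb.DMatrix(x, label = y_int),
    nrounds = nrounds, verbose = 0)
}

# Grid-searched gradient-boosted-tree classifier: 5-fold CV on the training
# set selects (max_depth, eta, nrounds); returns the refit booster.
fit_gbt <- function(x, y_int, n_class, folds, grid, seed) {
  cv_err <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    errs <- numeric(max(folds))
    for (f in seq_len(max(folds))) {
      tr <- folds != f
      if (length(unique(y_int[tr])) < n_class) { errs[f] <- NA; next }
      bst <- train_booster(x[tr, , drop = FALSE], y_int[tr], n_class,
                           grid$max_depth[g], grid$eta[g], grid$nrounds[g])
      pred <- predict(bst, xgboost::xgb.DMatrix(x[!tr, , drop = FALSE]))
      errs[f] <- mean(pred != y_int[!tr])
    }
    cv_err[g] <- mean(errs, na.rm = TRUE)
  }
  best <- which.min(cv_err)
  bst <- train_booster(x, y_int, n_class, grid$max_depth[best],
                       grid$eta[best], grid$nrounds[best])
  list(booster = bst, grid = grid, cv_error = cv_err, best = best)
}

#' Train and score a decodability classifier
#'
#' Tests whether a label (area, layer, Cre line) can be decoded from
#' embedded post-fidget responses: a stratified 85-15 train-test split,
#' independent class balancing of the training and test sets, a
#' gradient-boosted-tree classifier grid-searched with five-fold
#' cross-validation on the training set, and per-class F1
#' (`TP / (TP + 0.5 (FP + FN))`) on the held-out test set.
#'
#' @param embedding Coordinates (tibble or matrix), one row per neuron.
#' @param labels Class label per neuron.
#' @param split Training fraction of the train-test split.
#' @param folds Cross-validation folds for the grid search.
#' @param grid Data frame over `max_depth`, `eta`, `nrounds`.
#' @param seed Seed for split, balancing and training.
#' @return An object of class `decode_result`: `f1` tibble (per class),
#'   `mean_f1`, `label_set`, `tuning`, `seed`; `baseline_mean_f1` is `NA`
#'   until [shuffle_baseline()] fills it.
#' @export
train_and_score_decoder <- function(embedding, labels, split = 0.85,
                                    folds = 5L,
                                    grid = expand.grid(
                                      max_depth = c(2, 4, 6),
                                      eta = c(0.1, 0.3),
                                      nrounds = 100),
                                    seed = 1L) {
  x <- as.matrix(embedding)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (any(table(labels) < 2)) abort("every class needs >= 2 samples")
  res <- with_seed(derive_seed(seed, 43L), {
    # stratified 85-15 split
    test_idx <- unlist(lapply(classes, function(cl) {
      i <- which(labels == cl)
      sample(i, max(1L, round((1 - split) * length(i))))
    }))
    train_idx <- setdiff(seq_along(labels), test_idx)
    # balance train and test independently
    tr_keep <- train_idx[balance_classes(labels[train_idx],
                                         seed = stats::runif(1) * 1e6)]
    te_keep <- test_idx[balance_classes(labels[test_idx],
                                        seed = stats::runif(1) * 1e6)]
    ytr <- match(labels[tr_keep], classes) - 1L
    yte <- match(labels[te_keep], classes) - 1L
    fold_id <- sample(rep_len(seq_len(folds), length(tr_keep)))
    fit <- fit_gbt(x[tr_keep, , drop = FALSE], ytr, length(classes),
                   fold_id, grid, seed)
    pred <- predict(fit$booster,
                    xgboost::xgb.DMatrix(x[te_keep, , drop = FALSE]))
    f1 <- per_class_f1(pred, yte, seq_along(classes) - 1L)
    list(f1 = f1, fit = fit, n_train = length(tr_keep),
         n_test = length(te_keep))
  })
  structure(
    list(f1 = tibble(class = classes, f1 = unname(res$f1)),
         mean_f1 = mean(res$f1),
         baseline_mean_f1 = NA_real_,
         baseline_f1 = NULL,
         label_set = "labels",
         tuning = as_tibble(res$fit$grid) |>
           mutate(cv_error = res$fit$cv_error,
                  selected = seq_along(res$fit$cv_error) == res$fit$best),
         n_train = res$n_train, n_test = res$n_test,
         split = split, folds = folds, seed = seed),
    class = "decode_result")
}

#' Shuffled-label chance baseline
#'
#' Estimates chance-level decoding by repeating the full protocol of
#' [train_and_score_decoder()] on randomly permuted labels (marginal class
#' counts preserved) and averaging the mean F1 across repetitions.
#'
#' @param embedding,labels,split,folds,grid As in
#'   [train_and_score_decoder()].
#' @param n_shuffles Number of label permutations.
#' @param seed Seed.
#' @param result Optional `decode_result` to attach the baseline to.
#' @return If `result` is supplied, that object with `baseline_mean_f1` and
#'   `baseline_f1` filled in; otherwise a tibble of per-shuffle mean F1.
#' @export
shuffle_baseline <- function(embedding, labels, n_shuffles = 20L,
                             seed = 1L, split = 0.85, folds = 5L,
                             grid = expand.grid(max_depth = c(2, 4, 6),
                                                eta = c(0.1, 0.3),
                                                nrounds = 100),
                             result = NULL) {
  labels <- as.character(labels)
  means <- vapply(seq_len(n_shuffles), function(s) {
    perm <- with_seed(derive_seed(seed, 44L + s),
                      sample(labels))
    r <- train_and_score_decoder(embedding, perm, split = split,
                                 folds = folds, grid = grid,
                                 seed = derive_seed(seed, 440L + s))
    r$mean_f1
  }, numeric(1))
  tab <- tibble(shuffle = seq_len(n_shuffles), mean_f1 = means)
  if (is.null(result)) return(tab)
  result$baseline_mean_f1 <- mean(means)
  result$baseline_f1 <- tab
  result
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("<decode_result> mean F1 = %.3f over %d classes (baseline %s)\n",
              x$mean_f1, nrow(x$f1),
              if (is.na(x$baseline_mean_f1)) "not computed"
              else sprintf("%.3f", x$baseline_mean_f1)))
  invisible(x)
}

#' @rdname train_and_score_decoder
#' @param x,object A `decode_result`.
#' @param ... Unused.
#' @export
tidy.decode_result <- function(x, ...) x$f1

#' @rdname train_and_score_decoder
#' @export
glance.decode_result <- function(x, ...) {
  tibble(mean_f1 = x$mean_f1, baseline_mean_f1 = x$baseline_mean_f1,
         n_classes = nrow(x$f1), n_train = x$n_train, n_test = x$n_test)
}

#' @rdname train_and_score_decoder
#' @export
autoplot.decode_result <- function(object, ...) {
  p <- ggplot(object$f1, aes(.data$class, .data$f1)) +
    geom_col(fill = "grey40") +
    labs(x = NULL, y = "F1 score") +
    theme_minimal()
  if (!is.na(object$baseline_mean_f1)) {
    p <- p + geom_hline(yintercept = object$baseline_mean_f1,
                        linetype = "dashed")
  }
  p
}
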