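# k-means++ seeding followed by Lloyd refinement via stats::kmeans.
kmeanspp <- function(x, k, nstart = 3L, iter.max = 50L) {
  n <- nrow(x)
  if (k >= n) {
    return(kmeans(x, centers = min(k, n), iter.max = iter.max))
  }
  if (k == 1L) return(kmeans(x, centers = 1L, iter.max = iter.max))
  best <- NULL
  for (s in seq_len(nstart)) {
    centers <- matrix(NA_real_, k, ncol(x))
    centers[1, ] <- x[sample.int(n, 1L), ]
    d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
    for (j in 2:k) {
      if (all(d2 == 0)) {
        pick <- sample.int(n, 1L)
      } else {
        pick <- sample.int(n, 1L, prob = d2)
      }
      centers[j, ] <- x[pick, ]
      d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                         byrow = TRUE))^2))
    }
    fit <- suppressWarnings(
      kmeans(x, centers = centers, iter.max = iter.max))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

#' Cluster mean fidget responses with gap-statistic model selection
#'
#' Clusters each neuron's mean z-scored post-fidget trace with k-means++
#' and selects the number of clusters by the gap statistic: for each k the
#' log within-cluster dispersion is compared against `n_ref` reference
#' datasets drawn uniformly over the data's bounding box in its principal-
#' component frame. The chosen k is, by default, the smallest k whose gap
#' reaches the globally maximal gap minus its standard error
#' (`"globalSEmax"`); the classic rule
#' `gap(k) >= gap(k + 1) - s(k + 1)` (`"Tibs2001SEmax"`) is available but
#' reads a non-monotone gap curve poorly when one response type dominates
#' the population (it stops at k = 1 before the curve's true maximum).
#'
#' @param mean_z Matrix of mean z-scored traces, neurons x samples. Pass the
#'   post-onset window (or a full 300-sample window; clustering then uses
#'   all supplied samples).
#' @param k_range Candidate cluster counts (contiguous, starting at 1 is
#'   recommended so a featureless dataset can select a single cluster).
#' @param n_ref Number of uniform reference datasets for the gap statistic.
#' @param seed Seed controlling seeding and the reference draws.
#' @param k Optional: skip model selection and fit exactly this k.
#' @param nstart k-means++ restarts per fit.
#' @param se_method Gap selection rule, a [cluster::maxSE()] method.
#' @return An object of class `fidget_clusters`: `assignments` tibble
#'   (`neuron_id`, `cluster`, `distance_to_centroid`), `centroids`
#'   (k x samples), `gap` (tibble per k), `k`, `seed`.
#' @export
cluster_mean_responses <- function(mean_z, k_range = 1:8, n_ref = 20L,
                                   seed = 1L, k = NULL, nstart = 3L,
                                   se_method = "globalSEmax") {
  if (is.null(k) && !length(k_range)) abort("`k_range` must be non-empty")
  x <- as.matrix(mean_z)
  if (anyNA(x)) abort("`mean_z` contains NA; filter unclusterable neurons first")
  if (nrow(x) < max(if (is.null(k)) k_range else k)) {
    abort("need at least max(k_range) neurons")
  }
  gap_tab <- NULL
  if (is.null(k)) {
    gs <- with_seed(derive_seed(seed, 31L),
      cluster::clusGap(x, FUNcluster = function(xx, kk) kmeanspp(xx, kk, nstart = nstart),
                       K.max = max(k_range), B = n_ref,
                       d.power = 2, spaceH0 = "scaledPCA", verbose = FALSE))
    tab <- gs$Tab[k_range, , drop = FALSE]
    k <- k_range[cluster::maxSE(tab[, "gap"], tab[, "SE.sim"],
                                method = se_method)]
    gap_tab <- as_tibble(tab) |> mutate(k = k_range, .before = 1)
  }
  fit <- with_seed(derive_seed(seed, 32L), kmeanspp(x, k, nstart = nstart))
  d <- sqrt(rowSums((x - fit$centers[fit$cluster, , drop = FALSE])^2))
  structure(
    list(assignments = tibble(neuron_id = seq_len(nrow(x)),
                              cluster = fit$cluster,
                              distance_to_centroid = d),
         centroids = fit$centers,
         gap = gap_tab,
         k = k,
         seed = seed),
    class = "fidget_clusters")
}

#' @export
print.fidget_clusters <- function(x, ...) {
  cat(sprintf("<fidget_clusters> %d neurons in k = %d clusters%s\n",
              nrow(x$assignments), x$k,
              if (is.null(x$gap)) " (k fixed)" else " (gap-selected)"))
  invisible(x)
}

#' @rdname cluster_mean_responses
#' @param x,object A `fidget_clusters` object.
#' @param ... Unused.
#' @export
tidy.fidget_clusters <- function(x, ...) x$assignments

#' @rdname cluster_mean_responses
#' @export
glance.fidget_clusters <- function(x, ...) {
  tibble(k = x$k, n_neurons = nrow(x$assignments),
         gap_at_k = if (is.null(x$gap)) NA_real_ else
           x$gap$gap[x$gap$k == x$k])
}

#' Name clusters by their response archetype
#'
#' Assigns each cluster centroid one of the four semantic response types
#' from simple post-window statistics: with M the mean post-onset z, P the
#' peak post-onset z (signed, largest magnitude) and L the fraction of the
#' post window above half the peak, a centroid is `neutral` when |M| and |P|
#' are small, `depressed` when M < -theta, `phasic` when M > theta with a
#' brief supra-half-peak extent (L <= l_cut), and `active` when M > theta
#' with a sustained extent (L > l_cut). Centroids matching no rule are
#' labeled by the nearest archetype template, with a warning.
#'
#' @param centroids Matrix of centroid traces (k x samples); either full
#'   300-sample windows or post-only windows.
#' @param pre Number of pre-onset samples included in `centroids` (0 for
#'   post-only centroids).
#' @param theta Mean-z threshold separating modulated from neutral.
#' @param p_small Peak-z threshold below which a centroid can be neutral.
#' @param l_cut Sustainedness cutoff on L.
#' @return Character vector of type labels, one per centroid row.
#' @export
label_clusters <- function(centroids, pre = 0L, theta = 0.25,
                           p_small = 0.5, l_cut = 0.5) {
  centroids <- as.matrix(centroids)
  post <- centroids[, (pre + 1L):ncol(centroids), drop = FALSE]
  vapply(seq_len(nrow(post)), function(i) {
    tr <- post[i, ]
    m <- mean(tr)
    p <- tr[which.max(abs(tr))]
    l <- if (p != 0) mean(tr > p / 2) else 1
    if (abs(m) <= theta && abs(p) <= p_small) return("neutral")
    if (m < -theta) return("depressed")
    if (m > theta) return(if (l > l_cut) "active" else "phasic")
    # ambiguous (e.g. |M| small but large transient peak): nearest archetype
    warn("ambiguous centroid; labeling by nearest archetype")
    tpl <- response_templates(fps = max(30, ncol(post) / 10))$waveforms
    tpl_post <- tpl[, 101:300, drop = FALSE]
    tpl_rs <- t(apply(tpl_post, 1, function(w) {
      stats::approx(seq_along(w), w, n = length(tr))$y
    }))
    scaled <- tpl_rs * max(abs(tr))
    types <- response_type_levels()
    types[which.min(rowSums((scaled - matrix(tr, 4, length(tr),
                                             byrow = TRUE))^2))]
  }, character(1))
}

#' Apply a dF/F threshold criterion
#'
#' Relabels neurons whose raw post-fidget dF/F fails a modulation criterion
#' as `criteria neutral`: the `mean_post` criterion requires the mean
#' post-window dF/F to exceed the threshold (default 6%), the `max_post`
#' criterion requires the post-window maximum to exceed it (default 5%).
#' Only non-neutral neurons can be relabeled; neutral neurons are never
#' promoted. For `depressed` neurons the magnitude of the (negative)
#' deflection is compared against the threshold.
#'
#' @param assignments Tibble with `neuron_id`, `type_label` and the raw
#'   post-window statistics `mean_dff_post`, `max_dff_post`.
#' @param kind Criterion kind: `"mean_post"` or `"max_post"`.
#' @param threshold dF/F fraction (e.g. 0.06 for 6%).
#' @return The assignments tibble with `passes_criterion` and
#'   `type_label_criteria` (original label, or `"criteria neutral"`).
#' @export
apply_threshold_criteria <- function(assignments,
                                     kind = c("mean_post", "max_post"),
                                     threshold = NULL) {
  kind <- match.arg(kind)
  threshold <- threshold %||% switch(kind, mean_post = 0.06, max_post = 0.05)
  if (threshold <= 0) abort("`threshold` must be > 0")
  stat <- switch(kind,
                 mean_post = abs(assignments$mean_dff_post),
                 max_post = if ("min_dff_post" %in% names(assignments))
                   pmax(abs(assignments$max_dff_post),
                        abs(assignments$min_dff_post))
                 else abs(assignments$max_dff_post))
  passes <- stat > threshold
  assignments |>
    mutate(passes_criterion = passes,
           type_label_criteria = ifelse(
             .data$type_label != "neutral" & !passes,
             "criteria neutral", as.character(.data$type_label)))
}

#' Response-type distribution by cortical stratum
#'
#' Tabulates the percentage of each response type within strata defined by
#' visual area, cortical layer (derived from imaging depth) or Cre line.
#'
#' @param assignments Tibble with `type_label` plus metadata columns
#'   (`area`, `depth_um` and/or `layer`, `cre_line`).
#' @param stratify_by `"area"`, `"layer"` or `"cre"`.
#' @return A tibble with `stratum`, `type_label`, `n`, `percent`;
#'   percentages sum to 100 within each stratum.
#' @export
type_distribution <- function(assignments,
                              stratify_by = c("area", "layer", "cre")) {
  stratify_by <- match.arg(stratify_by)
  col <- switch(stratify_by, area = "area", layer = "layer", cre = "cre_line")
  if (col == "layer" && !"layer" %in% names(assignments)) {
    assignments$layer <- depth_to_layer(assignments$depth_um)
  }
  if (!col %in% names(assignments)) {
    abort(sprintf("assignments lack a `%s` column", col))
  }
  assignments |>
    mutate(stratum = .data[[col]],
           type_label = factor(.data$type_label,
                               levels = union(response_type_levels(),
                                              unique(.data$type_label)))) |>
    count(.data$stratum, .data$type_label, .drop = FALSE) |>
    group_by(.data$stratum) |>
    mutate(percent = 100 * .data$n / sum(.data$n)) |>
    ungroup()
}
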