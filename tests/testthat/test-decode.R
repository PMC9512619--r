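test_that("embeddings have the requested geometry", {
  set.seed(4)
  x <- matrix(rnorm(120 * 20), 120, 20)
  emb <- embed_responses(x, n_neighbors = 10, seed = 2)
  expect_identical(dim(emb), c(120L, 2L))
  emb3 <- embed_responses(x, n_components = 3, n_neighbors = 10, seed = 2)
  expect_identical(ncol(emb3), 3L)
  pca <- embed_responses(x, method = "pca", n_components = 10)
  expect_identical(dim(pca), c(120L, 10L))
  # deterministic given the seed
  emb2 <- embed_responses(x, n_neighbors = 10, seed = 2)
  expect_equal(as.matrix(emb), as.matrix(emb2))
  # duplicated inputs land on near-coincident embedded points (median
  # over pairs; individual SGD layouts can leave an occasional straggler)
  xx <- rbind(x, x[1:5, ])
  e <- as.matrix(embed_responses(xx, n_neighbors = 10, seed = 3))
  diam <- max(dist(e))
  d <- vapply(1:5, function(i) sqrt(sum((e[120 + i, ] - e[i, ])^2)),
              numeric(1))
  expect_lt(median(d), 0.05 * diam)
  expect_lt(max(d), 0.25 * diam)
  expect_error(embed_responses(x[1:5, ], n_neighbors = 20), "too few")
})

test_that("class balancing subsamples to the smallest class", {
  labs <- c(rep("A", 100), rep("B", 40), rep("C", 70))
  idx <- balance_classes(labs, seed = 1)
  expect_equal(unname(table(labs[idx])), rep(40L, 3), ignore_attr = TRUE)
  expect_true(all(table(labs[idx]) == 40))
  # already balanced: everything retained
  bal <- rep(c("A", "B"), each = 10)
  expect_equal(sort(balance_classes(bal)), 1:20)
  # seeded reproducibility
  expect_identical(balance_classes(labs, seed = 7),
                   balance_classes(labs, seed = 7))
  expect_error(balance_classes(factor(character(0))), "class")
})

test_that("per-class F1 matches the direct formula", {
  # TP = 3, FP = 1, FN = 1 for class "a": F1 = 3 / (3 + 0.5 * 2) = 0.75
  truth <- c("a", "a", "a", "a", "b", "b", "b")
  pred <- c("a", "a", "a", "b", "a", "b", "b")
  f1 <- fidgetr:::per_class_f1(pred, truth, c("a", "b"))
  expect_equal(unname(f1["a"]), 0.75)
  expect_equal(unname(f1["b"]), 2 / (2 + 0.5 * 2))
  # perfect prediction
  expect_equal(unname(fidgetr:::per_class_f1(truth, truth, c("a", "b"))),
               c(1, 1))
})

test_that("decoder recovers a perfectly encoded label and reports chance for noise", {
  set.seed(11)
  n <- 240
  labs <- rep(c("w", "x", "y", "z"), each = n / 4)
  # label perfectly encoded by one coordinate
  enc <- cbind(match(labs, c("w", "x", "y", "z")) + rnorm(n, 0, 0.01),
               rnorm(n))
  small_grid <- expand.grid(max_depth = 2, eta = 0.3, nrounds = 50)
  r <- train_and_score_decoder(enc, labs, grid = small_grid, seed = 3)
  expect_true(all(r$f1$f1 == 1))
  # features carry no label information: mean F1 near chance (0.25)
  means <- vapply(1:8, function(s) {
    noise <- matrix(rnorm(n * 2), n, 2)
    train_and_score_decoder(noise, labs, grid = small_grid,
                            seed = s)$mean_f1
  }, numeric(1))
  expect_lt(abs(mean(means) - 0.25), 0.05)
})

test_that("shuffle baseline preserves marginals and sits at chance", {
  set.seed(12)
  n <- 200
  labs <- rep(c("p", "q"), each = n / 2)
  x <- matrix(rnorm(n * 2), n, 2)
  small_grid <- expand.grid(max_depth = 2, eta = 0.3, nrounds = 40)
  tab <- shuffle_baseline(x, labs, n_shuffles = 6, seed = 5,
                          grid = small_grid)
  expect_equal(nrow(tab), 6)
  # balanced two-class chance level is 0.5
  expect_equal(mean(tab$mean_f1), 0.5, tolerance = 0.1)
  # attaching to a result fills the baseline fields
  r <- train_and_score_decoder(x, labs, grid = small_grid, seed = 2)
  r <- shuffle_baseline(x, labs, n_shuffles = 4, seed = 5,
                        grid = small_grid, result = r)
  expect_false(is.na(r$baseline_mean_f1))
  expect_equal(nrow(r$baseline_f1), 4)
  # seeded reproducibility of the permutations
  tab2 <- shuffle_baseline(x, labs, n_shuffles = 6, seed = 5,
                           grid = small_grid)
  expect_identical(tab$mean_f1, tab2$mean_f1)
})
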