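test_that("confusion-derived rates match hand computations", {
  r <- eval_metrics(rep(c("a", "b"), c(4, 2)), rep(c("a", "b"), c(4, 2)))
  expect_equal(r$accuracy, 1)
  expect_equal(r$macro_precision, 1)
  expect_equal(r$macro_f1, 1)

  # binary confusion [[50,10],[5,35]]
  y_t <- rep(c("pos", "neg"), c(60, 40))
  y_p <- c(rep("pos", 50), rep("neg", 10), rep("pos", 5), rep("neg", 35))
  r2 <- eval_metrics(y_t, y_p, classes = c("pos", "neg"))
  expect_equal(r2$accuracy, 0.85)
  expect_equal(unname(r2$confusion["pos", "neg"]), 10)

  expect_warning(r3 <- eval_metrics(c("a", "a", "b"), c("a", "a", "a")))
  expect_equal(r3$per_class$precision[r3$per_class$class == "b"], 0)
  expect_error(eval_metrics(character(0), character(0)),
               class = "pcgfusion_empty_input")
})

test_that("kappa matches the hand-derived value and its bounds", {
  cm <- matrix(c(50, 5, 10, 35), 2)   # rows = truth
  expect_equal(cohen_kappa(cm), (0.85 - 0.51) / (1 - 0.51), tolerance = 1e-6)
  expect_equal(cohen_kappa(cm), 0.6939, tolerance = 1e-4)
  expect_equal(cohen_kappa(diag(c(10, 20, 5))), 1)
  # independence structure: p_o == p_e
  ind <- outer(c(30, 70), c(40, 60)) / 100
  expect_equal(cohen_kappa(ind), 0, tolerance = 1e-12)
  expect_error(cohen_kappa(matrix(c(5, 0, 0, 0), 2)),
               class = "pcgfusion_degenerate_marginals")
})

test_that("polygon area metric matches the shoelace oracle and scales quadratically", {
  expect_equal(polygon_area_metric(1, 1, 1, 1, 1, 1), 1)
  expect_equal(polygon_area_metric(0.5, 0.5, 0.5, 0.5, 0.5, 0.5), 0.25)
  shoelace <- function(r) {
    th <- (0:5) * pi / 3
    x <- r * cos(th); y <- r * sin(th)
    j <- c(2:6, 1)
    0.5 * abs(sum(x * y[j] - x[j] * y)) / (3 * sqrt(3) / 2)
  }
  withr::with_seed(8, {
    for (i in 1:100) {
      r <- runif(6)
      expect_equal(do.call(polygon_area_metric, as.list(r)), shoelace(r),
                   tolerance = 1e-12)
    }
  })
  expect_error(polygon_area_metric(1, 1, 1, 1, 1, 1.2),
               class = "pcgfusion_metric_range")
})

test_that("k-fold splits are disjoint, exhaustive, balanced and stratified", {
  f <- kfold_split(10, 5, seed = 1)
  expect_length(f, 5)
  expect_equal(sort(unlist(f)), 1:10)
  expect_true(all(lengths(f) == 2))
  expect_identical(kfold_split(10, 5, seed = 1), kfold_split(10, 5, seed = 1))

  labs <- rep(c("a", "b"), c(20, 10))
  fs <- kfold_split(30, 5, seed = 2, labels = labs)
  for (fold in fs) {
    expect_equal(sum(labs[fold] == "a"), 4)
    expect_equal(sum(labs[fold] == "b"), 2)
  }
  expect_error(kfold_split(10, 5, labels = rep(c("a", "b"), c(8, 2))),
               class = "pcgfusion_class_too_small")
})

test_that("cross-validation keeps synthetic rows out of validation folds", {
  # imbalanced separable fixture; small pipeline settings for speed
  fx <- separable_classes(n_per = 14, d = 8, shift = 3.5, sd = 0.5, seed = 4)
  keep <- c(1:14, 15:22, 29:42, 43:56, 57:70)   # class c2 cut to 8 rows
  data <- tibble::as_tibble(as.data.frame(fx$X[keep, ])) |>
    dplyr::mutate(label = fx$y[keep],
                  record_id = sprintf("r%03d", dplyr::row_number()))
  rep <- cross_validate(data, k = 2, seed = 3, smote_k = 2,
                        n_particles = 5, n_iter = 3, fis_inputs = 2,
                        xcnn = xcnn_config(n_filters1 = 4, n_filters2 = 6,
                                           epochs = 4, dropout = 0.2,
                                           batch_size = 8))
  expect_equal(nrow(rep$folds), 2)
  expect_equal(sum(rep$confusion), nrow(data))   # only real rows validated
  expect_true(all(rep$folds$accuracy >= 0 & rep$folds$accuracy <= 1))
  expect_true(rep$pam >= 0 && rep$pam <= 1)
})
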