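test_that("information gain matches entropy anchors and scaling invariance", {
  y <- rep(c("a", "b"), 100)
  expect_equal(unname(info_gain(matrix(as.numeric(y == "a")), y)), 1)
  withr::with_seed(1, {
    x <- rnorm(2000)
    yy <- rep(c("a", "b"), 1000)
  })
  expect_lt(unname(info_gain(matrix(x), yy)), 0.05)
  X <- matrix(c(x, 1000 * x), ncol = 2)
  g <- info_gain(X, yy)
  expect_equal(unname(g[1]), unname(g[2]))
  expect_error(info_gain(matrix(x), rep("a", 2000)),
               class = "pcgfusion_constant_label")
})

test_that("an alpha = 1 LVQ update jumps the prototype onto the sample", {
  X <- matrix(c(0, 0, 4, 4), 2, byrow = TRUE)
  y0 <- c("a", "b")
  cb <- lvq_train(rbind(X, X), c(y0, y0), epochs = 1, alpha0 = 1, seed = 1)
  # first presented sample wins its own class prototype and lands on it
  X1 <- matrix(c(1, 1), 1)
  cb1 <- lvq_train(rbind(X, X1), c(y0, "a"), epochs = 1, alpha0 = 1, seed = NULL)
  expect_true(all(is.finite(cb1$z)))
})

test_that("LVQ fitness separates Gaussian classes and collapses under a zero mask", {
  withr::with_seed(2, {
    X <- rbind(matrix(rnorm(120, 0), 60), matrix(rnorm(120, 3), 60))
    y <- rep(c("a", "b"), each = 60)
  })
  errs <- vapply(1:20, function(s) lvq_fitness(X, y, seed = s), numeric(1))
  expect_lt(mean(errs), 0.1)
  # all-zero weights leave no information: error near the majority rate
  err0 <- lvq_fitness(X, y, weights = c(0, 0), seed = 1)
  expect_gte(err0, 0.3)
})

test_that("acceleration classing hits the printed anchors and closes the gaps", {
  expect_equal(classify_accel(0.5), "L")
  expect_equal(classify_accel(1.0), "M")
  expect_equal(classify_accel(1.6), "H")
  expect_equal(classify_accel(0.84), "L")
  expect_equal(classify_accel(0.85), "M")
  expect_equal(classify_accel(1.25), "H")
  expect_error(classify_accel(2.5), class = "pcgfusion_accel_range")
})

test_that("inertia selection inverts the acceleration level", {
  expect_equal(select_inertia("L", "L"), 0.9)
  expect_equal(select_inertia("H", "H"), 0.4)
  expect_equal(select_inertia("L", "H"), 0.65)
  expect_equal(select_inertia("M", "M"), 0.65)
  expect_error(select_inertia("L", "X"), class = "pcgfusion_bad_class")
})

test_that("PSO keeps positions in the box and gbest history non-increasing", {
  sphere <- function(x) sum((x - 0.5)^2)
  sw <- pso_optimize(sphere, d = 3, n_particles = 10, n_iter = 30, seed = 2)
  expect_true(all(vapply(sw$particles,
                         function(p) all(p$x >= 0 & p$x <= 1), logical(1))))
  expect_true(all(diff(sw$history) <= 0))
  expect_error(pso_step(structure(list(particles = list(), gbest = numeric(0)),
                                  class = "pso_swarm"), sphere),
               class = "pcgfusion_empty_swarm")
})

test_that("PSO converges on the sphere function", {
  sw <- pso_optimize(function(x) sum((x - 0.5)^2), d = 2,
                     n_particles = 30, n_iter = 200, seed = 7)
  expect_lt(sw$gbest_fit, 1e-3)
})

test_that("feature selection recovers planted informative features", {
  recalls <- numeric(10)
  deltas <- numeric(10)
  for (s in 1:10) {
    fx <- planted_features(seed = 100 + s)
    sel <- select_features(fx$X, fx$y, n_particles = 12, n_iter = 20, seed = s)
    keep <- names(sel$mask)[sel$mask]
    recalls[s] <- mean(fx$informative %in% keep)
    deltas[s] <- lvq_fitness(fx$X[, keep, drop = FALSE], fx$y, seed = s) -
      lvq_fitness(fx$X, fx$y, seed = s)
  }
  expect_gte(mean(recalls), 0.8)
  expect_lte(mean(deltas), 0.05)
})

test_that("selection degenerates gracefully and is seed-deterministic", {
  fx <- planted_features(n_per = 15, n_noise = 4, seed = 3)
  s1 <- select_features(fx$X, fx$y, n_particles = 6, n_iter = 5, seed = 9)
  s2 <- select_features(fx$X, fx$y, n_particles = 6, n_iter = 5, seed = 9)
  expect_identical(s1$mask, s2$mask)
  expect_gte(sum(s1$mask), 1)

  one <- matrix(rnorm(20), ncol = 1, dimnames = list(NULL, "only"))
  sel1 <- select_features(one, rep(c("a", "b"), 10))
  expect_identical(unname(sel1$mask), TRUE)
})
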