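test_that("membership functions hit their analytic anchors", {
  expect_equal(membership(mf_gaussian(0, 1), 0), 1)
  expect_equal(membership(mf_gaussian(0, 1), 1), exp(-0.5))
  expect_equal(membership(mf_triangular(0, 1, 2), 0.5), 0.5)
  expect_equal(membership(mf_triangular(0, 1, 2), c(-1, 3)), c(0, 0))
  expect_equal(membership(mf_bell(1, 1, 0), 1), 0.5)
  expect_equal(membership(mf_bell(1, 2, 3), 3), 1)
  expect_error(mf_triangular(1, 1, 2))
  expect_error(mf_gaussian(0, 0))
})

test_that("the five-layer forward pass normalizes and defuzzifies correctly", {
  # single rule: output equals its consequent at x
  m1 <- fis_model(list(list(mf_gaussian(0, 1))),
                  consequents = matrix(c(2, 1), 1))
  fw <- fis_forward(m1, 0.4)
  expect_equal(fw$g, 2 * 0.4 + 1)
  expect_equal(fw$trace$layer3, 1)

  # two equally firing rules average their consequents
  m2 <- fis_model(list(list(mf_gaussian(-1, 1), mf_gaussian(1, 1))),
                  consequents = rbind(c(0, 3), c(0, 7)))
  fw2 <- fis_forward(m2, 0)
  expect_equal(fw2$g, 5)
  expect_equal(sum(fw2$trace$layer3), 1)

  # layer-3 normalization sums to one wherever coverage is nonzero
  withr::with_seed(1, {
    m3 <- fis_model(purrr::map(1:2, ~ list(mf_gaussian(0, 1), mf_gaussian(1, 1))),
                    consequents = matrix(rnorm(12), 4))
    for (i in 1:10)
      expect_equal(sum(fis_forward(m3, runif(2))$trace$layer3), 1)
  })
})

test_that("hybrid learning represents a linear target essentially exactly", {
  x <- matrix(seq(0, 1, length.out = 41))
  y <- 2 * drop(x) + 1
  fit <- fis_train_hybrid(x, y, epochs = 10)
  expect_lt(sqrt(mean((fis_eval(fit, x) - y)^2)), 1e-3)
})

test_that("an LSE step never increases the loss", {
  withr::with_seed(4, {
    X <- matrix(runif(80), 40, 2)
    y <- sin(3 * X[, 1]) + X[, 2]^2 + rnorm(40, sd = 0.05)
  })
  model <- fis_train_hybrid(X, y, epochs = 1)
  for (i in 1:5) {
    model <- pcgfusion:::fis_premise_step(model, X, y, 0.05)
    before <- fis_loss(model, X, y)
    model <- fis_lse_step(model, X, y)
    expect_lte(fis_loss(model, X, y), before + 1e-12)
  }
})

test_that("premise gradients match central finite differences", {
  withr::with_seed(5, {
    X <- matrix(runif(60), 30, 2)
    y <- sin(X[, 1]) + X[, 2]^2
  })
  model <- fis_train_hybrid(X, y, epochs = 3)
  gr <- pcgfusion:::fis_premise_grad(model, X, y)
  h <- 1e-6
  for (i in 1:2) for (j in seq_along(model$mfs[[i]])) for (p in c("m", "sigma")) {
    mp <- model; mm <- model
    mp$mfs[[i]][[j]][[p]] <- mp$mfs[[i]][[j]][[p]] + h
    mm$mfs[[i]][[j]][[p]] <- mm$mfs[[i]][[j]][[p]] - h
    fd <- (fis_loss(mp, X, y) - fis_loss(mm, X, y)) / (2 * h)
    an <- gr[[i]][if (p == "m") 1 else 2, j]
    expect_equal(an, fd, tolerance = 1e-5)
  }
})

test_that("fuzzy risk scores separate normal from disease fixtures", {
  withr::with_seed(6, {
    X <- rbind(matrix(rnorm(80, 0, 0.5), 40), matrix(rnorm(80, 2, 0.5), 40))
    y <- rep(c(0, 1), each = 40)
  })
  fis <- fis_train_hybrid(X, y, epochs = 10)
  s_norm <- fuzzy_risk_score(fis, colMeans(X[1:40, , drop = FALSE]))
  s_dis <- fuzzy_risk_score(fis, colMeans(X[41:80, , drop = FALSE]))
  expect_lt(s_norm, 0.5)
  expect_gt(s_dis, 0.5)
  scores <- fuzzy_risk_score(fis, X)
  expect_true(all(scores >= 0 & scores <= 1))
})

test_that("activations and losses hit their closed-form anchors", {
  expect_equal(activation("sigmoid", 0), 0.5)
  expect_equal(activation("tanh", 0), 0)
  expect_equal(activation("relu", -3), 0)
  expect_equal(activation("leaky_relu", -2, list(m = 0.01)), -0.02)
  expect_equal(activation("prelu", -2, list(u = 0.25)), -0.5)
  expect_identical(activation("noisy_relu", 1, list(sd = 0.1), seed = 1),
                   activation("noisy_relu", 1, list(sd = 0.1), seed = 1))
  expect_error(activation("swish", 1))

  expect_equal(cnn_loss("cross_entropy", c(1, 0, 0), c(1, 0, 0)), 0,
               tolerance = 1e-10)
  expect_equal(cnn_loss("hinge", 2, 1), 0)
  expect_equal(cnn_loss("hinge", 0.2, 1), 0.8)
  expect_equal(cnn_loss("euclidean", c(1, 2), c(1, 2)), 0)
  expect_gte(cnn_loss("cross_entropy", c(0.2, 0.8), c(1, 0)), 0)
})

test_that("softmax is a shift-invariant distribution", {
  expect_equal(softmax(rep(0, 5)), rep(0.2, 5))
  withr::with_seed(7, z <- rnorm(6))
  expect_equal(softmax(z), softmax(z + 100))
  expect_equal(sum(softmax(z)), 1, tolerance = 1e-12)
  M <- matrix(rnorm(12), 3)
  expect_equal(rowSums(softmax(M)), rep(1, 3), tolerance = 1e-12)
})

test_that("every XCNN gradient matches central finite differences", {
  withr::with_seed(9, {
    B <- 2; L <- 16
    X <- matrix(rnorm(B * L), B, L)
    fz <- runif(B)
    Y <- diag(2)[c(1, 2), ]
    params <- pcgfusion:::xcnn_init_params(L, 4, 6, 2, TRUE)
  })
  res <- xcnn_loss_grads(params, X, fz, Y)
  h <- 1e-5
  for (nm in names(params)) {
    for (i in seq_along(params[[nm]])) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - h
      fd <- (xcnn_loss_grads(pp, X, fz, Y)$loss -
               xcnn_loss_grads(pm, X, fz, Y)$loss) / (2 * h)
      an <- res$grads[[nm]][i]
      expect_lt(abs(fd - an) / max(1e-6, abs(fd), abs(an)), 1e-4)
    }
  }
})

test_that("XCNN trains to high accuracy on a separable fixture", {
  fx <- separable_classes(n_per = 50, seed = 11)
  withr::with_seed(11, fz <- runif(nrow(fx$X)))
  m <- xcnn_train(fx$X, fx$y, fuzzy = fz,
                  cfg = xcnn_config(epochs = 30, seed = 3, batch_size = 8,
                                    dropout = 0.2))
  expect_gte(m$final_train_accuracy, 0.95)
  expect_lt(tail(m$loss_curve, 1), m$loss_curve[1])

  pred <- xcnn_predict(m, fx$X, fz)
  expect_equal(rowSums(pred$probs), rep(1, nrow(fx$X)), tolerance = 1e-9)
  expect_identical(pred, xcnn_predict(m, fx$X, fz))
  expect_equal(mean(pred$labels == fx$y), m$final_train_accuracy)
})

test_that("disabling fusion only narrows the dense layer by one input", {
  fx <- separable_classes(n_per = 10, d = 8, seed = 2)
  withr::with_seed(2, fz <- runif(nrow(fx$X)))
  m_f <- xcnn_train(fx$X, fx$y, fuzzy = fz,
                    cfg = xcnn_config(n_filters1 = 4, n_filters2 = 6,
                                      epochs = 2, use_fuzzy = TRUE))
  m_n <- xcnn_train(fx$X, fx$y,
                    cfg = xcnn_config(n_filters1 = 4, n_filters2 = 6,
                                      epochs = 2, use_fuzzy = FALSE))
  expect_equal(nrow(m_f$params$Wf), nrow(m_n$params$Wf) + 1)
  expect_equal(dim(m_f$params$W1), dim(m_n$params$W1))
  expect_equal(dim(m_f$params$Wp), dim(m_n$params$Wp))
})
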