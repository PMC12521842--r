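# Small Xception-style 1-D network: conv(k=5) -> batchnorm -> ReLU ->
# maxpool(2) -> depthwise-separable conv(k=3) -> batchnorm -> ReLU ->
# maxpool(2) -> global average pool -> [concat fuzzy risk score] -> dense ->
# dropout -> softmax. Forward and backward passes are written out
# explicitly (reverse-mode, batch matrix algebra) and optimized with Adam.

#' Elementwise activation functions
#'
#' @param kind One of `"sigmoid"`, `"tanh"`, `"relu"`, `"leaky_relu"`,
#'   `"noisy_relu"`, `"prelu"`.
#' @param x Numeric input.
#' @param params List of extras: `m` leak factor (leaky, default 0.01), `u`
#'   trainable slope (prelu, default 0.25), `sd` noise level (noisy, default
#'   `sd(x)`).
#' @param seed Seed for the stochastic noisy ReLU.
#' @return Numeric vector of activations.
#' @export
#' @examples
#' activation("sigmoid", 0)             # 0.5
#' activation("leaky_relu", -2, list(m = 0.01))  # -0.02
activation <- function(kind, x, params = list(), seed = NULL) {
  kind <- match.arg(kind, c("sigmoid", "tanh", "relu", "leaky_relu",
                            "noisy_relu", "prelu"))
  switch(kind,
    sigmoid = 1 / (1 + exp(-x)),
    tanh = tanh(x),
    relu = pmax(0, x),
    leaky_relu = {
      m <- params$m %||% 0.01
      ifelse(x > 0, x, m * x)
    },
    noisy_relu = {
      s <- params$sd %||% (if (length(x) > 1) sd(x) else 0)
      with_seed_or_not(seed, pmax(0, x + rnorm(length(x), sd = s)))
    },
    prelu = {
      u <- params$u %||% 0.25
      ifelse(x > 0, x, u * x)
    })
}

#' Numerically stable softmax
#'
#' @param logits Numeric vector, or matrix with one row per sample.
#' @return Probabilities of the same shape; each (row) sums to 1.
#' @export
#' @examples
#' softmax(rep(0, 5))
softmax <- function(logits) {
  if (is.matrix(logits)) {
    z <- logits - apply(logits, 1, max)
    e <- exp(z)
    e / rowSums(e)
  } else {
    z <- logits - max(logits)
    e <- exp(z)
    e / sum(e)
  }
}

#' Classification and regression losses
#'
#' `"cross_entropy"`: `-sum(j * log(w))` per sample (mean over rows), with
#' probabilities floored at 1e-12; `"euclidean"`: `1/(2 D) * sum((w - j)^2)`;
#' `"hinge"`: `sum(max(0, c - (2 j - 1) * w))` for binary targets
#' `j in {0, 1}` and raw scores `w`.
#'
#' @param kind Loss name.
#' @param predicted Predicted values (distribution rows for cross-entropy).
#' @param target Targets (one-hot rows for cross-entropy).
#' @param margin Hinge margin `c`.
#' @return Scalar loss (>= 0).
#' @export
#' @examples
#' cnn_loss("hinge", 2, 1)  # 0
cnn_loss <- function(kind, predicted, target, margin = 1) {
  kind <- match.arg(kind, c("cross_entropy", "euclidean", "hinge"))
  if (length(predicted) != length(target) && kind != "hinge")
    stop_pcg("dimension mismatch", "dim_mismatch")
  switch(kind,
    cross_entropy = {
      w <- pmax(as.matrix(predicted), 1e-12)
      j <- as.matrix(target)
      mean(-rowSums(j * log(w)) / 1)
    },
    euclidean = sum((predicted - target)^2) / (2 * length(predicted)),
    hinge = sum(pmax(0, margin - (2 * target - 1) * predicted)))
}

#' XCNN training configuration
#'
#' @param n_filters1,n_filters2 Channels of the first conv and the separable
#'   conv block.
#' @param dropout Dropout probability applied before the softmax.
#' @param lr Adam learning rate.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param use_fuzzy Concatenate the fuzzy risk score before the dense layer.
#' @param standardize `"column"` (feature-style inputs; train-set statistics
#'   stored in the model) or `"row"` (per-sample z-score, for envelope
#'   segments).
#' @param seed Seed for initialization, shuffling and dropout.
#' @return A list of class `xcnn_config`.
#' @export
xcnn_config <- function(n_filters1 = 32L, n_filters2 = 64L, dropout = 0.5,
                        lr = 0.001, epochs = 30L, batch_size = 16L,
                        use_fuzzy = TRUE, standardize = c("column", "row"),
                        seed = 1L) {
  structure(list(n_filters1 = as.integer(n_filters1),
                 n_filters2 = as.integer(n_filters2),
                 dropout = dropout, lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), use_fuzzy = use_fuzzy,
                 standardize = match.arg(standardize),
                 seed = as.integer(seed)),
            class = "xcnn_config")
}

# ---- low-level pieces -----------------------------------------------------

# shift matrix columns by s (positive s pulls later samples forward); zero pad
shift2 <- function(M, s) {
  L <- ncol(M)
  out <- matrix(0, nrow(M), L)
  if (s >= 0) { if (s < L) out[, 1:(L - s)] <- M[, (1 + s):L] }
  else { s <- -s; if (s < L) out[, (1 + s):L] <- M[, 1:(L - s)] }
  out
}

# same, along dim 2 of a 3-D array
shift3 <- function(A, s) {
  d <- dim(A)
  out <- array(0, d)
  L <- d[2]
  if (s >= 0) { if (s < L) out[, 1:(L - s), ] <- A[, (1 + s):L, , drop = FALSE] }
  else { s <- -s; if (s < L) out[, (1 + s):L, ] <- A[, 1:(L - s), , drop = FALSE] }
  out
}

bn_forward <- function(M, g, be, eps = 1e-5) {
  mu <- colMeans(M)
  v <- colMeans(M^2) - mu^2
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(M, 2, mu), 2, invstd, "*")
  y <- sweep(sweep(xhat, 2, g, "*"), 2, be, "+")
  list(y = y, xhat = xhat, invstd = invstd, mu = mu, v = v)
}

bn_backward <- function(dY, cache, g) {
  N <- nrow(dY)
  dxhat <- sweep(dY, 2, g, "*")
  dg <- colSums(dY * cache$xhat)
  dbe <- colSums(dY)
  # dX = invstd/N * (N*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dX <- sweep(N * dxhat, 2, s1) - sweep(cache$xhat, 2, s2, "*")
  dX <- sweep(dX, 2, cache$invstd / N, "*")
  list(dX = dX, dg = dg, dbe = dbe)
}

bn_infer <- function(M, g, be, mu, v, eps = 1e-5) {
  xhat <- sweep(sweep(M, 2, mu), 2, 1 / sqrt(v + eps), "*")
  sweep(sweep(xhat, 2, g, "*"), 2, be, "+")
}

xcnn_init_params <- function(L, c1, c2, n_classes, use_fuzzy) {
  he <- function(n, fan) rnorm(n) * sqrt(2 / fan)
  d_dense <- c2 + as.integer(use_fuzzy)
  list(
    W1 = matrix(he(5 * c1, 5), 5, c1), b1 = numeric(c1),
    g1 = rep(1, c1), be1 = numeric(c1),
    Wd = matrix(he(3 * c1, 3), 3, c1),
    Wp = matrix(he(c1 * c2, c1), c1, c2), bp = numeric(c2),
    g2 = rep(1, c2), be2 = numeric(c2),
    Wf = matrix(he(d_dense * n_classes, d_dense), d_dense, n_classes),
    bf = numeric(n_classes)
  )
}

# full forward + (optionally) backward pass in training mode.
# X: B x L input rows; fz: length-B fuzzy scores or NULL; Y: B x K one-hot.
# drop_mask: NULL disables dropout (deterministic path).
xcnn_pass <- function(params, X, fz, Y, drop_mask = NULL, dropout = 0,
                      want_grads = TRUE) {
  B <- nrow(X); L <- ncol(X)
  c1 <- ncol(params$W1); c2 <- ncol(params$Wp); K <- ncol(params$Wf)
  stopifnot(L %% 4 == 0)
  offs5 <- -2:2; offs3 <- -1:1

  shifts0 <- lapply(offs5, function(s) shift2(X, s))
  Z1 <- array(0, c(B, L, c1))
  for (t in 1:5) Z1 <- Z1 + outer(shifts0[[t]], params$W1[t, ])
  Z1 <- Z1 + rep(params$b1, each = B * L)

  M1 <- matrix(Z1, B * L, c1)
  bn1 <- bn_forward(M1, params$g1, params$be1)
  R1 <- pmax(bn1$y, 0)
  A1 <- array(R1, c(B, L, c1))
  L2 <- L %/% 2
  Ao <- A1[, seq(1, L, 2), , drop = FALSE]
  Ae <- A1[, seq(2, L, 2), , drop = FALSE]
  mask1 <- Ao >= Ae
  P1 <- ifelse(mask1, Ao, Ae)                      # B x L2 x c1

  shiftsd <- lapply(offs3, function(s) shift3(P1, s))
  Zd <- array(0, c(B, L2, c1))
  for (t in 1:3) Zd <- Zd + shiftsd[[t]] * rep(params$Wd[t, ], each = B * L2)
  Md <- matrix(Zd, B * L2, c1)
  Mp <- Md %*% params$Wp
  Mp <- sweep(Mp, 2, params$bp, "+")               # (B L2) x c2
  bn2 <- bn_forward(Mp, params$g2, params$be2)
  R2 <- pmax(bn2$y, 0)
  A2 <- array(R2, c(B, L2, c2))
  L4 <- L2 %/% 2
  Bo <- A2[, seq(1, L2, 2), , drop = FALSE]
  Be <- A2[, seq(2, L2, 2), , drop = FALSE]
  mask2 <- Bo >= Be
  P2 <- ifelse(mask2, Bo, Be)                      # B x L4 x c2

  G <- apply(P2, c(1, 3), sum) / L4                # B x c2
  H <- if (!is.null(fz)) cbind(G, fz) else G
  if (!is.null(drop_mask)) H <- H * drop_mask / (1 - dropout)
  logits <- sweep(H %*% params$Wf, 2, params$bf, "+")
  probs <- softmax(logits)
  loss <- mean(-rowSums(as.matrix(Y) * log(pmax(probs, 1e-12))))

  out <- list(loss = loss, probs = probs,
              bn1_stats = list(mu = bn1$mu, v = bn1$v),
              bn2_stats = list(mu = bn2$mu, v = bn2$v))
  if (!want_grads) return(out)

  dlogits <- (probs - Y) / B
  gWf <- t(H) %*% dlogits
  gbf <- colSums(dlogits)
  dH <- dlogits %*% t(params$Wf)
  if (!is.null(drop_mask)) dH <- dH * drop_mask / (1 - dropout)
  dG <- dH[, seq_len(c2), drop = FALSE]
  dP2 <- outer(dG / L4, rep(1, L4))                # B x c2 x L4
  dP2 <- aperm(dP2, c(1, 3, 2))                    # B x L4 x c2

  dA2 <- array(0, c(B, L2, c2))
  dA2[, seq(1, L2, 2), ] <- ifelse(mask2, dP2, 0)
  dA2[, seq(2, L2, 2), ] <- ifelse(mask2, 0, dP2)
  dR2 <- matrix(dA2, B * L2, c2)
  dbn2y <- dR2 * (bn2$y > 0)
  bb2 <- bn_backward(dbn2y, bn2, params$g2)
  dMp <- bb2$dX
  gWp <- t(Md) %*% dMp
  gbp <- colSums(dMp)
  dMd <- dMp %*% t(params$Wp)
  dZd <- array(dMd, c(B, L2, c1))

  gWd <- matrix(0, 3, c1)
  dP1 <- array(0, c(B, L2, c1))
  for (t in 1:3) {
    gWd[t, ] <- colSums(matrix(shiftsd[[t]] * dZd, B * L2, c1))
    dP1 <- dP1 + shift3(dZd * rep(params$Wd[t, ], each = B * L2), -offs3[t])
  }

  dA1 <- array(0, c(B, L, c1))
  dA1[, seq(1, L, 2), ] <- ifelse(mask1, dP1, 0)
  dA1[, seq(2, L, 2), ] <- ifelse(mask1, 0, dP1)
  dR1 <- matrix(dA1, B * L, c1)
  dbn1y <- dR1 * (bn1$y > 0)
  bb1 <- bn_backward(dbn1y, bn1, params$g1)
  dZ1 <- array(bb1$dX, c(B, L, c1))

  gW1 <- matrix(0, 5, c1)
  for (t in 1:5) gW1[t, ] <- colSums(matrix(outer(shifts0[[t]], rep(1, c1)) *
                                              dZ1, B * L, c1))
  gb1 <- colSums(matrix(dZ1, B * L, c1))

  out$grads <- list(W1 = gW1, b1 = gb1, g1 = bb1$dg, be1 = bb1$dbe,
                    Wd = gWd, Wp = gWp, bp = gbp, g2 = bb2$dg, be2 = bb2$dbe,
                    Wf = gWf, bf = gbf)
  out
}

# inference-mode forward using running batchnorm statistics
xcnn_infer <- function(model, X, fz) {
  p <- model$params
  B <- nrow(X); L <- ncol(X)
  c1 <- ncol(p$W1); c2 <- ncol(p$Wp)
  shifts0 <- lapply(-2:2, function(s) shift2(X, s))
  Z1 <- array(0, c(B, L, c1))
  for (t in 1:5) Z1 <- Z1 + outer(shifts0[[t]], p$W1[t, ])
  Z1 <- Z1 + rep(p$b1, each = B * L)
  R1 <- pmax(bn_infer(matrix(Z1, B * L, c1), p$g1, p$be1,
                      model$bn1$mu, model$bn1$v), 0)
  A1 <- array(R1, c(B, L, c1))
  L2 <- L %/% 2
  P1 <- pmax(A1[, seq(1, L, 2), , drop = FALSE],
             A1[, seq(2, L, 2), , drop = FALSE])
  Zd <- array(0, c(B, L2, c1))
  for (t in 1:3) Zd <- Zd + shift3(P1, (-1:1)[t]) * rep(p$Wd[t, ], each = B * L2)
  Mp <- sweep(matrix(Zd, B * L2, c1) %*% p$Wp, 2, p$bp, "+")
  R2 <- pmax(bn_infer(Mp, p$g2, p$be2, model$bn2$mu, model$bn2$v), 0)
  A2 <- array(R2, c(B, L2, c2))
  L4 <- L2 %/% 2
  P2 <- pmax(A2[, seq(1, L2, 2), , drop = FALSE],
             A2[, seq(2, L2, 2), , drop = FALSE])
  G <- apply(P2, c(1, 3), sum) / L4
  H <- if (!is.null(fz)) cbind(G, fz) else G
  softmax(sweep(H %*% p$Wf, 2, p$bf, "+"))
}

#' Train the fuzzy-fused separable-convolution classifier
#'
#' Trains the 1-D XCNN stack (conv 5 -> BN -> ReLU -> pool -> separable conv
#' 3 -> BN -> ReLU -> pool -> global average pool -> optional fuzzy-score
#' concat -> dense -> dropout -> softmax) with Adam on categorical
#' cross-entropy. Inputs shorter than a multiple of 4 are zero-padded.
#'
#' @param X Numeric matrix, one input row per sample (feature vector or
#'   envelope segment).
#' @param y Class labels.
#' @param fuzzy Optional numeric vector of fuzzy risk scores (one per row).
#' @param cfg An [xcnn_config()].
#' @return An `xcnn_model` with `params`, running batchnorm statistics,
#'   `classes`, `loss_curve` (per-epoch training loss), and
#'   `final_train_accuracy` (inference mode on the training set).
#' @export
xcnn_train <- function(X, y, fuzzy = NULL, cfg = xcnn_config()) {
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (cfg$use_fuzzy && is.null(fuzzy))
    stop_pcg("cfg$use_fuzzy is TRUE but no fuzzy scores given", "missing_fuzzy")
  if (!cfg$use_fuzzy) fuzzy <- NULL

  if (cfg$standardize == "column") {
    mu <- colMeans(X); sg <- apply(X, 2, sd); sg[sg == 0] <- 1
    X <- sweep(sweep(X, 2, mu), 2, sg, "/")
    input_stats <- list(mu = mu, sg = sg)
  } else {
    X <- t(apply(X, 1, function(r) (r - mean(r)) / max(sd(r), 1e-8)))
    input_stats <- NULL
  }
  pad <- (4 - ncol(X) %% 4) %% 4
  if (pad > 0) X <- cbind(X, matrix(0, nrow(X), pad))
  L <- ncol(X)
  Y <- outer(y, classes, `==`) * 1
  K <- length(classes)
  n <- nrow(X)

  with_seed_or_not(cfg$seed, {
    params <- xcnn_init_params(L, cfg$n_filters1, cfg$n_filters2, K,
                               cfg$use_fuzzy)
    mstate <- purrr::map(params, ~ .x * 0)
    vstate <- purrr::map(params, ~ .x * 0)
    t_adam <- 0
    bn1 <- list(mu = numeric(cfg$n_filters1), v = rep(1, cfg$n_filters1))
    bn2 <- list(mu = numeric(cfg$n_filters2), v = rep(1, cfg$n_filters2))
    loss_curve <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; n_b <- 0
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1, n)]
        if (length(idx) < 2) next                 # batchnorm needs >= 2 rows
        d_dense <- cfg$n_filters2 + as.integer(cfg$use_fuzzy)
        dm <- if (cfg$dropout > 0)
          matrix(runif(length(idx) * d_dense) > cfg$dropout,
                 length(idx), d_dense) * 1
        else NULL
        pass <- xcnn_pass(params, X[idx, , drop = FALSE],
                          fuzzy[idx], Y[idx, , drop = FALSE],
                          drop_mask = dm, dropout = cfg$dropout)
        if (!is.finite(pass$loss))
          stop_pcg(sprintf("NaN/Inf loss at epoch %d", ep), "nan_loss")
        t_adam <- t_adam + 1
        for (nm in names(params)) {
          g <- pass$grads[[nm]]
          mstate[[nm]] <- 0.9 * mstate[[nm]] + 0.1 * g
          vstate[[nm]] <- 0.999 * vstate[[nm]] + 0.001 * g^2
          mhat <- mstate[[nm]] / (1 - 0.9^t_adam)
          vhat <- vstate[[nm]] / (1 - 0.999^t_adam)
          params[[nm]] <- params[[nm]] - cfg$lr * mhat / (sqrt(vhat) + 1e-8)
        }
        bn1$mu <- 0.9 * bn1$mu + 0.1 * pass$bn1_stats$mu
        bn1$v  <- 0.9 * bn1$v  + 0.1 * pass$bn1_stats$v
        bn2$mu <- 0.9 * bn2$mu + 0.1 * pass$bn2_stats$mu
        bn2$v  <- 0.9 * bn2$v  + 0.1 * pass$bn2_stats$v
        ep_loss <- ep_loss + pass$loss; n_b <- n_b + 1
      }
      loss_curve[ep] <- ep_loss / n_b
    }
    model <- structure(list(params = params, bn1 = bn1, bn2 = bn2,
                            classes = classes, cfg = cfg, pad = pad,
                            input_stats = input_stats,
                            loss_curve = loss_curve),
                       class = "xcnn_model")
    probs <- xcnn_infer(model, X, fuzzy)
    model$final_train_accuracy <-
      mean(classes[max.col(probs, ties.method = "first")] == y)
    model
  })
}

#' @export
print.xcnn_model <- function(x, ...) {
  cat(sprintf("<xcnn_model> %d classes, filters %d/%d, %d epochs, train acc %.3f\n",
              length(x$classes), ncol(x$params$W1), ncol(x$params$Wp),
              length(x$loss_curve), x$final_train_accuracy))
  invisible(x)
}

#' @export
glance.xcnn_model <- function(x, ...) {
  tibble::tibble(final_loss = tail(x$loss_curve, 1),
                 initial_loss = x$loss_curve[1],
                 train_accuracy = x$final_train_accuracy,
                 epochs = length(x$loss_curve))
}

#' @rdname xcnn_train
#' @param object An `xcnn_model`.
#' @param ... Unused.
#' @export
autoplot.xcnn_model <- function(object, ...) {
  d <- tibble::tibble(epoch = seq_along(object$loss_curve),
                      loss = object$loss_curve)
  ggplot2::ggplot(d, ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "training cross-entropy")
}

#' Predict class probabilities with a trained XCNN
#'
#' Deterministic inference: dropout disabled, batchnorm uses running
#' statistics.
#'
#' @param model An `xcnn_model`.
#' @param X Input matrix shaped like the training input.
#' @param fuzzy Fuzzy risk scores when the model was trained with fusion.
#' @return A list with `probs` (rows sum to 1) and `labels`.
#' @export
xcnn_predict <- function(model, X, fuzzy = NULL) {
  X <- as.matrix(X)
  if (!model$cfg$use_fuzzy) fuzzy <- NULL
  else if (is.null(fuzzy)) stop_pcg("model expects fuzzy scores", "missing_fuzzy")
  if (!is.null(model$input_stats)) {
    X <- sweep(sweep(X, 2, model$input_stats$mu), 2, model$input_stats$sg, "/")
  } else {
    X <- t(apply(X, 1, function(r) (r - mean(r)) / max(sd(r), 1e-8)))
  }
  if (model$pad > 0) X <- cbind(X, matrix(0, nrow(X), model$pad))
  probs <- xcnn_infer(model, X, fuzzy)
  colnames(probs) <- model$classes
  list(probs = probs,
       labels = model$classes[max.col(probs, ties.method = "first")])
}

#' Loss and exact gradients of the XCNN at given parameters
#'
#' Training-mode pass (batch statistics, dropout off) exposing the loss and
#' the gradient of every trainable tensor; intended for gradient
#' verification and diagnostics.
#'
#' @param params Parameter list as inside an `xcnn_model`.
#' @param X Input rows (already standardized/padded to a multiple of 4).
#' @param fuzzy Fuzzy score vector or `NULL`.
#' @param Y One-hot target matrix.
#' @return List with `loss` and `grads` (same shapes as `params`).
#' @export
xcnn_loss_grads <- function(params, X, fuzzy, Y) {
  pass <- xcnn_pass(params, as.matrix(X), fuzzy, as.matrix(Y))
  list(loss = pass$loss, grads = pass$grads)
}

#' Envelope segments as fixed-length XCNN input rows
#'
#' Shannon envelope of each recording resampled to `len` points (linear
#' interpolation); the envelope is band-limited by its smoothing filter, so
#' a few hundred points retain its shape.
#'
#' @param recs List of [pcg_recording()].
#' @param len Segment length (multiple of 4).
#' @return Numeric matrix with one row per recording.
#' @export
envelope_segments <- function(recs, len = 512L) {
  if (inherits(recs, "pcg_recording")) recs <- list(recs)
  rows <- purrr::map(recs, function(r) {
    env <- shannon_envelope(r)
    approx(seq_along(env), env, n = len)$y
  })
  do.call(rbind, rows)
}
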