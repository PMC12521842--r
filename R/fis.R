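# Five-layer Sugeno fuzzy inference system: (1) membership degrees,
# (2) rule firing strengths by product T-norm, (3) normalization, (4) rule
# consequents (first-order linear) weighted by normalized strengths,
# (5) summation = firing-strength-weighted mean (centroid defuzzification
# for a Sugeno system). Trained by hybrid learning: least squares for the
# consequents with premises fixed, gradient descent on the Gaussian premise
# parameters.

#' Membership functions
#'
#' Constructors for the three membership shapes and the evaluator. Gaussian:
#' `exp(-(x - m)^2 / (2 * sigma^2))`; triangular with corners
#' `w < r < e`: linear ramps to 1 at the peak `r`; generalized bell:
#' `1 / (1 + |(x - m) / u|^(2 v))`.
#'
#' @param m Center (gaussian, bell).
#' @param sigma Gaussian width (> 0).
#' @param w,r,e Triangular lower corner, peak, upper corner (`w < r < e`).
#' @param u Bell half-width (> 0).
#' @param v Bell slope (> 0).
#' @return An object of class `membership_fn`.
#' @export
#' @examples
#' membership(mf_gaussian(0, 1), 0)        # 1
#' membership(mf_triangular(0, 1, 2), 0.5) # 0.5
#' membership(mf_bell(1, 1, 0), 1)         # 0.5
mf_gaussian <- function(m, sigma) {
  stopifnot(sigma > 0)
  structure(list(kind = "gaussian", m = m, sigma = sigma), class = "membership_fn")
}

#' @rdname mf_gaussian
#' @export
mf_triangular <- function(w, r, e) {
  stopifnot(w < r, r < e)
  structure(list(kind = "triangular", w = w, r = r, e = e), class = "membership_fn")
}

#' @rdname mf_gaussian
#' @export
mf_bell <- function(u, v, m) {
  stopifnot(u > 0, v > 0)
  structure(list(kind = "bell", u = u, v = v, m = m), class = "membership_fn")
}

#' @rdname mf_gaussian
#' @param fn A `membership_fn`.
#' @param x Numeric vector of evaluation points.
#' @return `membership()` returns degrees in \[0, 1\].
#' @export
membership <- function(fn, x) {
  stopifnot(inherits(fn, "membership_fn"))
  switch(fn$kind,
    gaussian = exp(-(x - fn$m)^2 / (2 * fn$sigma^2)),
    triangular = {
      up <- (x - fn$w) / (fn$r - fn$w)
      dn <- (fn$e - x) / (fn$e - fn$r)
      pmax(0, pmin(up, dn, 1))
    },
    bell = 1 / (1 + abs((x - fn$m) / fn$u)^(2 * fn$v))
  )
}

#' Construct a Sugeno FIS model
#'
#' Rules are the full grid of one membership function per input; each rule
#' carries a first-order consequent `g_r(x) = w_r . x + e_r`.
#'
#' @param mfs A list (one element per input) of lists of `membership_fn`.
#' @param input_names Names of the inputs.
#' @param consequents Matrix `n_rules x (k + 1)` of linear consequent
#'   parameters (last column = intercept); defaults to zeros.
#' @param rule_weights Per-rule multiplicative weights (default 1).
#' @return An object of class `fis_model`.
#' @export
fis_model <- function(mfs, input_names = NULL,
                      consequents = NULL, rule_weights = NULL) {
  k <- length(mfs)
  input_names <- input_names %||% paste0("x", seq_len(k))
  rules <- as.matrix(expand.grid(lapply(mfs, seq_along)))
  colnames(rules) <- input_names
  n_rules <- nrow(rules)
  consequents <- consequents %||% matrix(0, n_rules, k + 1)
  stopifnot(nrow(consequents) == n_rules, ncol(consequents) == k + 1)
  rule_weights <- rule_weights %||% rep(1, n_rules)
  structure(list(inputs = input_names, mfs = mfs, rules = rules,
                 consequents = consequents, rule_weights = rule_weights),
            class = "fis_model")
}

#' @export
print.fis_model <- function(x, ...) {
  cat(sprintf("<fis_model> %d inputs, %s MFs, %d rules\n",
              length(x$inputs),
              paste(purrr::map_int(x$mfs, length), collapse = "x"),
              nrow(x$rules)))
  invisible(x)
}

# membership degrees for all samples: list over inputs of n x m_i matrices.
# gaussian/bell memberships are floored at a tiny positive value: they are
# mathematically positive everywhere, and the floor keeps the rule-firing
# product from underflowing to an all-zero layer for far-out inputs
# (triangular memberships keep their exact zeros).
fis_memberships <- function(model, X) {
  purrr::map(seq_along(model$mfs), function(i)
    do.call(cbind, purrr::map(model$mfs[[i]], function(fn) {
      mu <- membership(fn, X[, i])
      if (fn$kind %in% c("gaussian", "bell")) pmax(mu, 1e-45) else mu
    })))
}

# firing-strength matrix n x n_rules (layer 2)
fis_firing <- function(model, mu) {
  R <- nrow(model$rules)
  n <- nrow(mu[[1]])
  fire <- matrix(1, n, R)
  for (i in seq_along(model$mfs))
    fire <- fire * mu[[i]][, model$rules[, i], drop = FALSE]
  sweep(fire, 2, model$rule_weights, "*")
}

#' Evaluate a Sugeno FIS
#'
#' `fis_forward()` runs one input vector through the five layers and exposes
#' the full layer trace; `fis_eval()` evaluates a batch.
#'
#' @param model A [fis_model()].
#' @param x Input vector of length `k` (`fis_forward`) or an `n x k` matrix
#'   (`fis_eval`).
#' @return `fis_forward()`: list with the crisp output `g` and `trace`
#'   (layers 1--5: memberships, firing strengths, normalized strengths,
#'   weighted consequent outputs, output). `fis_eval()`: numeric vector of
#'   outputs.
#' @export
fis_forward <- function(model, x) {
  X <- matrix(x, nrow = 1)
  mu <- fis_memberships(model, X)
  fire <- fis_firing(model, mu)
  s <- sum(fire)
  if (s <= 0) stop_pcg("no rule coverage at this input", "no_coverage")
  norm <- fire / s
  g_r <- rowSums(cbind(X[rep(1, nrow(model$rules)), , drop = FALSE], 1) *
                   model$consequents)
  weighted <- drop(norm) * g_r
  g <- sum(weighted)
  list(g = g,
       trace = list(layer1 = purrr::map(mu, drop),
                    layer2 = drop(fire),
                    layer3 = drop(norm),
                    layer4 = weighted,
                    layer5 = g))
}

#' @rdname fis_forward
#' @export
fis_eval <- function(model, x) {
  X <- as.matrix(x)
  mu <- fis_memberships(model, X)
  fire <- fis_firing(model, mu)
  s <- rowSums(fire)
  if (any(s <= 0)) stop_pcg("no rule coverage for some inputs", "no_coverage")
  norm <- fire / s
  Xb <- cbind(X, 1)
  G <- Xb %*% t(model$consequents)     # n x R rule outputs
  rowSums(norm * G)
}

# normalized-firing design matrix for the consequent LSE:
# columns ordered rule-major: [norm_r * x_1, ..., norm_r * x_k, norm_r]
fis_design <- function(model, X) {
  mu <- fis_memberships(model, X)
  fire <- fis_firing(model, mu)
  s <- rowSums(fire)
  norm <- fire / s
  Xb <- cbind(X, 1)
  cols <- purrr::map(seq_len(nrow(model$rules)), function(r) norm[, r] * Xb)
  do.call(cbind, cols)
}

#' Train a Sugeno FIS by hybrid learning
#'
#' Per epoch: (forward pass) the consequent parameters are solved exactly by
#' linear least squares with the premises fixed — this step can only lower
#' the squared-error loss; (backward pass) the Gaussian premise centers and
#' widths take one gradient-descent step on the squared error.
#'
#' @param X Input matrix (`k <= 6` columns; the rule grid is exponential in
#'   `k`).
#' @param y Real-valued targets.
#' @param epochs Training epochs.
#' @param lr Learning rate of the premise update.
#' @param mfs_per_input Gaussian membership functions per input.
#' @return A fitted [fis_model()] with attribute `loss_curve` (MSE after
#'   each epoch's LSE step).
#' @export
#' @examples
#' x <- matrix(seq(0, 1, length.out = 21))
#' fit <- fis_train_hybrid(x, 2 * drop(x) + 1, epochs = 5)
#' sqrt(mean((fis_eval(fit, x) - (2 * drop(x) + 1))^2))
fis_train_hybrid <- function(X, y, epochs = 30L, lr = 0.05, mfs_per_input = 2L) {
  X <- as.matrix(X)
  if (ncol(X) > 6) stop_pcg("more than 6 FIS inputs (rule explosion)", "too_many_inputs")
  mfs <- purrr::map(seq_len(ncol(X)), function(i) {
    rng <- range(X[, i])
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    centers <- seq(rng[1], rng[2], length.out = mfs_per_input)
    sigma <- diff(rng) / max(1, (mfs_per_input - 1)) / 1.5
    purrr::map(centers, mf_gaussian, sigma = sigma)
  })
  model <- fis_model(mfs, input_names = colnames(X))
  loss_curve <- numeric(0)
  for (ep in seq_len(epochs)) {
    model <- fis_lse_step(model, X, y)
    loss_curve <- c(loss_curve, fis_loss(model, X, y))
    model <- fis_premise_step(model, X, y, lr)
  }
  model <- fis_lse_step(model, X, y)   # final consequent polish
  loss_curve <- c(loss_curve, fis_loss(model, X, y))
  attr(model, "loss_curve") <- loss_curve
  model
}

#' @rdname fis_train_hybrid
#' @param model A [fis_model()].
#' @return `fis_lse_step()` returns the model with consequents re-solved by
#'   (ridge-guarded) least squares; `fis_loss()` the mean squared error.
#' @export
fis_lse_step <- function(model, X, y) {
  X <- as.matrix(X)
  Phi <- fis_design(model, X)
  theta <- tryCatch(qr.solve(Phi, y), error = function(e) NULL)
  if (is.null(theta)) {
    rlang::warn("singular LSE system; ridge fallback")
    A <- crossprod(Phi)
    b <- crossprod(Phi, y)
    scale <- max(mean(diag(A)), 1e-300)
    for (lambda in scale * 10^c(-8, -6, -4, -2)) {
      theta <- tryCatch(solve(A + diag(lambda, ncol(A)), b),
                        error = function(e) NULL)
      if (!is.null(theta)) break
    }
    if (is.null(theta)) stop_pcg("consequent LSE failed", "lse_failure")
  }
  k <- length(model$inputs)
  model$consequents <- matrix(theta, ncol = k + 1, byrow = TRUE)
  model
}

#' @rdname fis_train_hybrid
#' @export
fis_loss <- function(model, X, y) mean((fis_eval(model, as.matrix(X)) - y)^2)

# analytic gradient of the MSE wrt every gaussian premise parameter;
# returns list over inputs of matrices (2 x m_i): rows d/dm, d/dsigma
fis_premise_grad <- function(model, X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  mu <- fis_memberships(model, X)
  fire <- fis_firing(model, mu)
  s <- rowSums(fire)
  norm <- fire / s
  Xb <- cbind(X, 1)
  G <- Xb %*% t(model$consequents)
  g <- rowSums(norm * G)
  resid2 <- 2 * (g - y) / n            # dE/dg per sample
  purrr::map(seq_along(model$mfs), function(i) {
    out <- matrix(0, 2, length(model$mfs[[i]]))
    for (j in seq_along(model$mfs[[i]])) {
      fn <- model$mfs[[i]][[j]]
      use <- which(model$rules[, i] == j)
      # dg/dp_r = (G_r - g) / s; dp_r/dtheta = p_r * q_theta
      p_use <- fire[, use, drop = FALSE]
      dg_dp_sum <- rowSums((G[, use, drop = FALSE] - g) / s * p_use)
      q_m <- (X[, i] - fn$m) / fn$sigma^2
      q_s <- (X[, i] - fn$m)^2 / fn$sigma^3
      out[1, j] <- sum(resid2 * dg_dp_sum * q_m)
      out[2, j] <- sum(resid2 * dg_dp_sum * q_s)
    }
    out
  })
}

fis_premise_step <- function(model, X, y, lr) {
  gr <- fis_premise_grad(model, X, y)
  for (i in seq_along(model$mfs)) {
    for (j in seq_along(model$mfs[[i]])) {
      fn <- model$mfs[[i]][[j]]
      fn$m <- fn$m - lr * gr[[i]][1, j]
      fn$sigma <- max(1e-4, fn$sigma - lr * gr[[i]][2, j])
      model$mfs[[i]][[j]] <- fn
    }
  }
  model
}

#' Fuzzy risk score for feature rows
#'
#' Evaluates a FIS trained on a binary risk target (0 = normal, 1 = disease)
#' and clips the Sugeno output to `[0, 1]`.
#'
#' @param fis A fitted [fis_model()].
#' @param x Feature row (length-k vector) or `n x k` matrix over the FIS
#'   inputs.
#' @return Scores in \[0, 1\].
#' @export
fuzzy_risk_score <- function(fis, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  pmin(1, pmax(0, fis_eval(fis, x)))
}
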