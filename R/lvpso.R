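# Linear-vectored particle swarm optimization: PSO over continuous
# feature-weight vectors in [0,1]^d whose fitness is the held-out error of a
# learning-vector-quantization (LVQ1) classifier with information-gain-
# weighted distances. Acceleration coefficients are drawn in [0,2] each step
# and classed low/medium/high; the inertia weight follows from the class
# pair (opposing the acceleration level, so strong acceleration gets weak
# inertia and vice versa).

#' Per-feature information gain
#'
#' Mutual information (bits) between each equal-width-binned feature and the
#' class label. Invariant to feature scaling since bins are taken on the
#' per-feature range.
#'
#' @param X Numeric matrix or data frame of features.
#' @param y Class labels (>= 2 distinct values).
#' @param n_bins Number of equal-width bins (>= 2).
#' @return Named numeric vector of gains, all >= 0.
#' @export
info_gain <- function(X, y, n_bins = 10L) {
  X <- as.matrix(X)
  stopifnot(is_count(n_bins, 2))
  y <- as.character(y)
  if (length(unique(y)) < 2) stop_pcg("label is constant", "constant_label")
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  h_y <- ent(table(y) / length(y))
  gains <- apply(X, 2, function(x) {
    rng <- range(x)
    b <- if (diff(rng) == 0) rep(1L, length(x))
         else pmin(n_bins, 1L + floor((x - rng[1]) / diff(rng) * n_bins))
    tab <- table(b, y)
    p_b <- rowSums(tab) / sum(tab)
    h_cond <- sum(p_b * apply(tab, 1, function(r) ent(r / sum(r))))
    max(0, h_y - h_cond)
  })
  setNames(as.numeric(gains), colnames(X))
}

#' Train an LVQ1 codebook with gain-weighted distances
#'
#' One prototype per class, initialized at the class mean. For each training
#' sample the winning prototype (minimum of
#' `sum(gains * weights * (x - z)^2)`) is pulled toward the sample if its
#' class matches, pushed away otherwise; the learning rate decays linearly
#' from `alpha0` to 0 over the presentation schedule.
#'
#' @param X Numeric matrix of training samples.
#' @param y Class labels.
#' @param gains Distance weights (e.g. [info_gain()]); default all-ones.
#' @param weights Feature mask/weights in `[0, 1]` (PSO particle position).
#' @param epochs Presentation passes over the data.
#' @param alpha0 Initial learning rate in (0, 1].
#' @param seed Seed for the presentation order.
#' @return An `lvq_codebook`: prototype matrix `z` (class x feature), class
#'   names, the effective distance weights, and class priors for tie-breaks.
#' @export
lvq_train <- function(X, y, gains = NULL, weights = NULL, epochs = 20L,
                      alpha0 = 0.3, seed = 1L) {
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- sort(unique(y))
  gains <- gains %||% rep(1, ncol(X))
  weights <- weights %||% rep(1, ncol(X))
  dw <- gains * weights
  z <- do.call(rbind, lapply(classes, function(cl)
    colMeans(X[y == cl, , drop = FALSE])))
  rownames(z) <- classes
  prior <- as.numeric(table(factor(y, classes)))
  n <- nrow(X)
  total <- epochs * n
  step <- 0L
  with_seed_or_not(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (i in ord) {
        alpha <- alpha0 * (1 - step / total)
        d2 <- colSums(dw * (t(z) - X[i, ])^2)
        win <- order(d2, -prior)[1]     # tie -> most frequent class
        if (classes[win] == y[i]) z[win, ] <- z[win, ] + alpha * (X[i, ] - z[win, ])
        else                      z[win, ] <- z[win, ] - alpha * (X[i, ] - z[win, ])
        step <- step + 1L
      }
    }
  })
  structure(list(z = z, classes = classes, dw = dw, prior = prior),
            class = "lvq_codebook")
}

#' @rdname lvq_train
#' @param codebook An `lvq_codebook`.
#' @param newdata Matrix of samples to classify.
#' @return `lvq_predict()` returns the predicted class labels.
#' @export
lvq_predict <- function(codebook, newdata) {
  newdata <- as.matrix(newdata)
  apply(newdata, 1, function(x) {
    d2 <- colSums(codebook$dw * (t(codebook$z) - x)^2)
    codebook$classes[order(d2, -codebook$prior)[1]]
  })
}

#' Held-out LVQ error of a feature weighting
#'
#' Standardizes the features, splits 70/30 stratified by class (seeded),
#' trains [lvq_train()] on the training part with information-gain-weighted
#' distances, and returns the held-out misclassification rate. This is the
#' PSO fitness: lower is better.
#'
#' @param X Feature matrix.
#' @param y Class labels (every class must appear in the training split).
#' @param weights Feature weights in `[0, 1]`.
#' @param epochs,alpha0 LVQ training controls.
#' @param seed Seed for split and presentation order.
#' @return Error rate in \[0, 1\].
#' @export
lvq_fitness <- function(X, y, weights = NULL, epochs = 10L, alpha0 = 0.3,
                        seed = 1L) {
  X <- as.matrix(X)
  y <- as.character(y)
  mu <- colMeans(X); sg <- apply(X, 2, sd); sg[sg == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sg, "/")
  idx_tr <- with_seed_or_not(seed, {
    unlist(lapply(split(seq_along(y), y), function(ix)
      sample(ix, max(1L, round(0.7 * length(ix))))))
  })
  idx_te <- setdiff(seq_along(y), idx_tr)
  if (length(idx_te) == 0) idx_te <- idx_tr
  if (length(unique(y[idx_tr])) < length(unique(y)))
    stop_pcg("a class is absent from the training split", "class_absent")
  gains <- info_gain(Xs[idx_tr, , drop = FALSE], y[idx_tr])
  cb <- lvq_train(Xs[idx_tr, , drop = FALSE], y[idx_tr], gains = gains,
                  weights = weights, epochs = epochs, alpha0 = alpha0,
                  seed = seed)
  mean(lvq_predict(cb, Xs[idx_te, , drop = FALSE]) != y[idx_te])
}

#' Classify an acceleration coefficient as low / medium / high
#'
#' Coefficients in `[0, 0.8]` are low, `[0.9, 1.2]` medium, `[1.3, 2]` high;
#' the gaps between the printed intervals are closed at their midpoints
#' (0.85 and 1.25) so the function is total on `[0, 2]`.
#'
#' @param e Acceleration coefficient in `[0, 2]`.
#' @return `"L"`, `"M"` or `"H"`.
#' @export
#' @examples
#' classify_accel(0.5); classify_accel(1.0); classify_accel(1.6)
classify_accel <- function(e) {
  if (!is.numeric(e) || any(e < 0 | e > 2))
    stop_pcg("acceleration coefficient must lie in [0, 2]", "accel_range")
  ifelse(e < 0.85, "L", ifelse(e < 1.25, "M", "H"))
}

#' Inertia weight from the acceleration class pair
#'
#' Strong acceleration pairs get weak inertia and vice versa: both low ->
#' 0.9 (high inertia, global search), both high -> 0.4 (low inertia, local
#' search), any other combination -> 0.65 (the mean of the two).
#'
#' @param class1,class2 Acceleration classes from [classify_accel()].
#' @return Inertia weight `w`.
#' @export
#' @examples
#' select_inertia("L", "L"); select_inertia("H", "H"); select_inertia("L", "H")
select_inertia <- function(class1, class2) {
  ok <- c("L", "M", "H")
  if (!(class1 %in% ok) || !(class2 %in% ok))
    stop_pcg("classes must be L, M or H", "bad_class")
  if (class1 == "L" && class2 == "L") return(0.9)
  if (class1 == "H" && class2 == "H") return(0.4)
  0.65
}

#' Initialize a particle swarm
#'
#' @param n_particles Swarm size.
#' @param d Dimension of the search space (positions live in `[0, 1]^d`).
#' @param fitness Function mapping a position vector to a scalar to minimize.
#' @return A `pso_swarm` list: `particles` (each with `x`, `v`, `pbest`,
#'   `pbest_fit`), `gbest`, `gbest_fit`, `history`.
#' @export
pso_init <- function(n_particles, d, fitness) {
  particles <- purrr::map(seq_len(n_particles), function(i) {
    x <- runif(d)
    list(x = x, v = numeric(d), pbest = x, pbest_fit = fitness(x))
  })
  fits <- purrr::map_dbl(particles, "pbest_fit")
  g <- which.min(fits)
  structure(list(particles = particles, gbest = particles[[g]]$pbest,
                 gbest_fit = fits[g], history = fits[g]),
            class = "pso_swarm")
}

#' One particle-swarm iteration
#'
#' Per particle: acceleration coefficients `e1, e2 ~ U(0, 2)` are drawn and
#' classed; the inertia weight follows from [select_inertia()]; per-dimension
#' random factors `phi_i = e_i * U(0, 1)` scale the pulls toward the personal
#' and global bests; velocities are clamped to `|v| <= 0.5` and positions to
#' `[0, 1]`. Personal and global bests are updated and the global best
#' fitness appended to the (non-increasing) history.
#'
#' @param swarm A `pso_swarm`.
#' @param fitness Fitness function (minimized).
#' @return The updated swarm.
#' @export
pso_step <- function(swarm, fitness) {
  if (length(swarm$particles) == 0) stop_pcg("empty swarm", "empty_swarm")
  d <- length(swarm$gbest)
  swarm$particles <- purrr::map(swarm$particles, function(p) {
    e <- runif(2, 0, 2)
    w <- select_inertia(classify_accel(e[1]), classify_accel(e[2]))
    phi1 <- e[1] * runif(d)
    phi2 <- e[2] * runif(d)
    v <- w * p$v + phi1 * (p$pbest - p$x) + phi2 * (swarm$gbest - p$x)
    v <- pmax(pmin(v, 0.5), -0.5)
    x <- pmax(pmin(p$x + v, 1), 0)
    fit <- fitness(x)
    if (fit < p$pbest_fit) { p$pbest <- x; p$pbest_fit <- fit }
    p$x <- x; p$v <- v
    p
  })
  fits <- purrr::map_dbl(swarm$particles, "pbest_fit")
  g <- which.min(fits)
  if (fits[g] < swarm$gbest_fit) {
    swarm$gbest_fit <- fits[g]
    swarm$gbest <- swarm$particles[[g]]$pbest
  }
  swarm$history <- c(swarm$history, swarm$gbest_fit)
  swarm
}

#' Run PSO to minimize a fitness function over `[0, 1]^d`
#'
#' @inheritParams pso_init
#' @param n_iter Iterations of [pso_step()].
#' @param seed Integer seed covering initialization and all steps.
#' @return The final `pso_swarm`.
#' @export
#' @examples
#' sw <- pso_optimize(function(x) sum((x - 0.5)^2), d = 2,
#'                    n_particles = 20, n_iter = 50, seed = 7)
#' sw$gbest_fit
pso_optimize <- function(fitness, d, n_particles = 20L, n_iter = 50L, seed = 1L) {
  with_seed_or_not(seed, {
    sw <- pso_init(n_particles, d, fitness)
    for (i in seq_len(n_iter)) sw <- pso_step(sw, fitness)
    sw
  })
}

#' Particle-swarm feature selection with LVQ fitness
#'
#' Runs PSO over feature-weight vectors; the fitness of a position is the
#' held-out [lvq_fitness()] of the weighted features. The final mask keeps
#' features whose global-best weight exceeds `threshold` (at least one
#' feature is always kept: the top weight survives an empty cut).
#'
#' @param data Feature table with a `label` column, or a numeric matrix
#'   (then supply `y`).
#' @param y Labels when `data` is a matrix.
#' @param n_particles,n_iter Swarm size and iteration count.
#' @param threshold Weight cut for inclusion (default 0.5).
#' @param seed Integer seed (swarm and LVQ splits).
#' @param epochs LVQ epochs inside the fitness.
#' @param penalty Parsimony pressure: the fitness is the LVQ error plus
#'   `penalty * mean(weights)`, so a feature is only worth keeping if it
#'   buys more error reduction than `penalty / d`.
#' @return A list of class `lvpso_selection`: `mask` (named logical),
#'   `weights` (final global-best position), `history` (gbest fitness per
#'   iteration), `report` (tibble of per-feature weight and keep flag).
#' @export
select_features <- function(data, y = NULL, n_particles = 15L, n_iter = 30L,
                            threshold = 0.5, seed = 1L, epochs = 8L,
                            penalty = 0.05) {
  if (is.data.frame(data)) {
    stopifnot("label" %in% names(data))
    y <- data$label
    X <- as.matrix(data[feature_names(data)])
  } else X <- as.matrix(data)
  d <- ncol(X)
  nms <- colnames(X) %||% paste0("f", seq_len(d))
  if (d < 1) stop_pcg("no features", "no_features")
  if (d == 1) {
    return(structure(list(mask = setNames(TRUE, nms), weights = setNames(1, nms),
                          history = numeric(0),
                          report = tibble::tibble(feature = nms, weight = 1,
                                                  keep = TRUE)),
                     class = "lvpso_selection"))
  }
  # weights below the mask threshold are zeroed inside the fitness so the
  # swarm optimizes exactly the subsets the final cut produces
  fitness <- function(w) {
    w_eff <- ifelse(w > threshold, w, 0)
    if (all(w_eff == 0)) return(1 + penalty)
    lvq_fitness(X, y, weights = w_eff, epochs = epochs, seed = seed) +
      penalty * mean(w_eff > 0)
  }
  sw <- pso_optimize(fitness, d, n_particles, n_iter, seed = seed)
  weights <- setNames(sw$gbest, nms)
  mask <- weights > threshold
  if (!any(mask)) mask[which.max(weights)] <- TRUE
  structure(list(mask = mask, weights = weights, history = sw$history,
                 report = tibble::tibble(feature = nms, weight = weights,
                                         keep = unname(mask))),
            class = "lvpso_selection")
}

#' @export
print.lvpso_selection <- function(x, ...) {
  cat(sprintf("<lvpso_selection> %d / %d features kept; final fitness %.4f\n",
              sum(x$mask), length(x$mask),
              if (length(x$history)) tail(x$history, 1) else NA_real_))
  invisible(x)
}

#' @export
tidy.lvpso_selection <- function(x, ...) x$report

#' @rdname select_features
#' @param object An `lvpso_selection`.
#' @param ... Unused.
#' @export
autoplot.lvpso_selection <- function(object, ...) {
  d <- tibble::tibble(iteration = seq_along(object$history),
                      gbest_error = object$history)
  ggplot2::ggplot(d, ggplot2::aes(.data$iteration, .data$gbest_error)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "PSO iteration", y = "global-best LVQ error")
}
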