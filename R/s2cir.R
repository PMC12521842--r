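# Support-scalar cardiac impact rate: a soft-margin linear hyperplane fit
# whose regularized objective ("impact rate") and primal weights drive a
# per-feature impact score. The dual problem is solved by a deterministic
# SMO (sequential minimal optimization) with maximal-violating-pair
# selection, so repeated fits are bit-identical.

#' Fit a soft-margin linear hyperplane
#'
#' Solves `min 1/2 ||s||^2 + C * sum(xi)` subject to
#' `y_i (s . x_i + v) >= 1 - xi_i`, `xi_i >= 0` via SMO on the dual with
#' maximal-violating-pair working-set selection (KKT tolerance `tol`).
#' The decision rule is `sign(s . x + v)`.
#'
#' @param X Numeric matrix, one row per sample.
#' @param y Labels in `{-1, +1}` (or a 2-level factor, mapped in level order).
#' @param C Regularization weight (> 0).
#' @param tol KKT violation tolerance for the stopping rule.
#' @param max_iter Cap on SMO pair updates.
#' @return An `impact_model`: list with weight vector `s`, bias `v`, slack
#'   `xi`, `C`, `impact_rate` (objective at the solution), `margin`
#'   (`2 / ||s||`), dual coefficients `alpha`, and `feature_impacts`
#'   (`|s_j| * sd(X_j)`).
#' @export
#' @examples
#' m <- fit_hyperplane(matrix(c(-1, 1)), c(-1, 1), C = 100)
#' c(m$s, m$v, m$impact_rate)
fit_hyperplane <- function(X, y, C = 1, tol = 1e-6, max_iter = 100000L) {
  X <- as.matrix(X)
  if (is.factor(y) || is.character(y)) {
    lev <- sort(unique(as.character(y)))
    if (length(lev) != 2) stop_pcg("need exactly two classes", "single_class")
    y <- ifelse(as.character(y) == lev[2], 1, -1)
  }
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1)) || length(unique(y)) < 2)
    stop_pcg("labels must contain both -1 and +1", "single_class")
  if (C <= 0) stop_pcg("C must be positive", "bad_C")
  n <- nrow(X)
  if (max(dist(X)) == 0)
    stop_pcg("degenerate geometry: all samples identical", "degenerate")

  K <- X %*% t(X)
  alpha <- numeric(n)
  f <- numeric(n)                      # f_i = sum_j alpha_j y_j K_ij
  for (it in seq_len(max_iter)) {
    yg <- y - f                        # y_i * gradient of the dual
    up <- (y == 1 & alpha < C - 1e-12) | (y == -1 & alpha > 1e-12)
    lo <- (y == -1 & alpha < C - 1e-12) | (y == 1 & alpha > 1e-12)
    if (!any(up) || !any(lo)) break
    i <- which(up)[which.max(yg[up])]
    j <- which(lo)[which.min(yg[lo])]
    if (yg[i] - yg[j] < tol) break
    eta <- K[i, i] + K[j, j] - 2 * K[i, j]
    if (eta <= 1e-12) eta <- 1e-12
    delta <- (yg[i] - yg[j]) / eta
    # feasible range keeping both alphas in [0, C]
    rng_i <- if (y[i] == 1) c(-alpha[i], C - alpha[i]) else c(alpha[i] - C, alpha[i])
    rng_j <- if (y[j] == 1) c(alpha[j] - C, alpha[j]) else c(-alpha[j], C - alpha[j])
    delta <- min(max(delta, rng_i[1], rng_j[1]), rng_i[2], rng_j[2])
    if (delta == 0) break
    alpha[i] <- alpha[i] + y[i] * delta
    alpha[j] <- alpha[j] - y[j] * delta
    f <- f + delta * (K[, i] - K[, j])
  }
  s <- drop(t(X) %*% (alpha * y))
  free <- alpha > 1e-8 & alpha < C - 1e-8
  v <- if (any(free)) mean((y - f)[free]) else {
    yg <- y - f
    up <- (y == 1 & alpha < C - 1e-12) | (y == -1 & alpha > 1e-12)
    lo <- (y == -1 & alpha < C - 1e-12) | (y == 1 & alpha > 1e-12)
    (max(yg[up]) + min(yg[lo])) / 2
  }
  xi <- pmax(0, 1 - y * (drop(X %*% s) + v))
  obj <- 0.5 * sum(s^2) + C * sum(xi)
  structure(
    list(s = s, v = v, xi = xi, C = C, alpha = alpha,
         impact_rate = obj, margin = 2 / max(sqrt(sum(s^2)), 1e-300),
         feature_impacts = abs(s) * apply(X, 2, sd),
         levels = if (exists("lev", inherits = FALSE)) lev else c(-1, 1)),
    class = "impact_model"
  )
}

#' @export
print.impact_model <- function(x, ...) {
  cat(sprintf("<impact_model> d = %d, C = %g, impact rate = %.6g, margin = %.4g\n",
              length(x$s), x$C, x$impact_rate, x$margin))
  invisible(x)
}

#' Impact rate of a fitted hyperplane
#'
#' The regularized soft-margin objective `1/2 ||s||^2 + C * sum(xi)` at the
#' solution; the geometric margin `2 / ||s||` is exposed alongside.
#'
#' @param model An `impact_model` from [fit_hyperplane()].
#' @return The objective value (>= 0).
#' @export
impact_rate <- function(model) {
  if (!inherits(model, "impact_model")) stop_pcg("unfitted model", "unfitted")
  model$impact_rate
}

#' @export
tidy.impact_model <- function(x, ...) {
  tibble::tibble(term = c(paste0("s", seq_along(x$s)), "bias"),
                 estimate = c(x$s, x$v))
}

#' @export
glance.impact_model <- function(x, ...) {
  tibble::tibble(impact_rate = x$impact_rate, margin = x$margin,
                 C = x$C, n_sv = sum(x$alpha > 1e-8),
                 total_slack = sum(x$xi))
}

#' Rank features by hyperplane impact
#'
#' Fits one-vs-rest hyperplanes per class and scores each feature as
#' `|s_j| * sd(X_j)` (scale-corrected weight magnitude), aggregated across
#' classes by the maximum. Ties are broken by column position.
#'
#' @param data Feature table with a `label` column (>= 2 feature columns),
#'   or a numeric matrix (then supply `y`).
#' @param y Labels when `data` is a matrix.
#' @param C Regularization weight.
#' @return A tibble `feature`, `score`, `rank` in descending score order.
#' @export
feature_impacts <- function(data, y = NULL, C = 1) {
  if (is.data.frame(data)) {
    stopifnot("label" %in% names(data))
    y <- data$label
    X <- as.matrix(data[feature_names(data)])
  } else {
    X <- as.matrix(data)
    if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  }
  if (ncol(X) < 2) stop_pcg("need at least two features", "too_few_features")
  classes <- sort(unique(as.character(y)))
  scores <- purrr::map(classes, function(cl) {
    yy <- ifelse(y == cl, 1, -1)
    if (length(unique(yy)) < 2) return(rep(0, ncol(X)))
    fit_hyperplane(X, yy, C = C)$feature_impacts
  })
  score <- unname(do.call(pmax, scores))
  tibble::tibble(feature = colnames(X), score = score) |>
    dplyr::arrange(dplyr::desc(.data$score),
                   match(.data$feature, colnames(X))) |>
    dplyr::mutate(rank = dplyr::row_number())
}
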