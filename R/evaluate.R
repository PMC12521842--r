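# Multi-class evaluation: confusion matrix with per-class precision /
# recall / F1, accuracy, Cohen's kappa, a polygon-area summary of six
# metrics, stratified k-fold splitting, and leakage-free cross-validation
# of the full classification pipeline.

#' Confusion matrix and classification rates
#'
#' Per-class precision, recall and F1 with unweighted macro averages,
#' overall accuracy, Cohen's kappa and the macro Jaccard index. Zero
#' denominators yield 0 with a warning.
#'
#' @param y_true,y_pred Label vectors of equal length.
#' @param classes Class set (default: union of observed labels, sorted).
#' @return An `eval_report` list: `confusion` (matrix, rows = truth),
#'   `per_class` tibble, `accuracy`, `macro_precision`, `macro_recall`,
#'   `macro_f1`, `kappa`, `jaccard`.
#' @export
#' @examples
#' r <- eval_metrics(c("a", "a", "b"), c("a", "b", "b"))
#' r$accuracy
eval_metrics <- function(y_true, y_pred, classes = NULL) {
  if (length(y_true) == 0) stop_pcg("empty input", "empty_input")
  stopifnot(length(y_true) == length(y_pred))
  classes <- classes %||% sort(unique(c(as.character(y_true),
                                        as.character(y_pred))))
  cm <- table(factor(y_true, classes), factor(y_pred, classes))
  cm <- unclass(matrix(cm, length(classes), length(classes),
                       dimnames = list(truth = classes, predicted = classes)))
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(a, b, what) {
    out <- unname(ifelse(b > 0, a / b, 0))
    if (any(b == 0))
      rlang::warn(sprintf("%s undefined for class(es) %s; reported as 0", what,
                          paste(classes[b == 0], collapse = ", ")))
    out
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  jac <- ifelse(tp + fp + fn > 0, tp / (tp + fp + fn), 0)
  structure(
    list(confusion = cm,
         per_class = tibble::tibble(class = classes, precision = precision,
                                    recall = recall, f1 = f1, jaccard = jac,
                                    support = unname(rowSums(cm))),
         accuracy = sum(tp) / sum(cm),
         macro_precision = mean(precision), macro_recall = mean(recall),
         macro_f1 = mean(f1), jaccard = mean(jac),
         kappa = cohen_kappa(cm)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.3f, macro F1 %.3f, kappa %.3f\n",
              x$accuracy, x$macro_f1, x$kappa))
  print(x$per_class)
  invisible(x)
}

#' @export
tidy.eval_report <- function(x, ...) x$per_class

#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, macro_precision = x$macro_precision,
                 macro_recall = x$macro_recall, macro_f1 = x$macro_f1,
                 kappa = x$kappa, jaccard = x$jaccard)
}

#' Cohen's kappa from a confusion matrix
#'
#' `(p_o - p_e) / (1 - p_e)` with observed agreement `p_o = trace / total`
#' and chance agreement `p_e` from the row/column marginals.
#'
#' @param cm Square confusion matrix of counts (rows = truth).
#' @return Kappa in \[-1, 1\].
#' @export
#' @examples
#' cohen_kappa(matrix(c(50, 5, 10, 35), 2))  # 0.6939
cohen_kappa <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  if (n <= 0) stop_pcg("empty confusion matrix", "empty_input")
  p_o <- sum(diag(cm)) / n
  p_e <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (p_e >= 1) stop_pcg("degenerate marginals (p_e = 1)", "degenerate_marginals")
  (p_o - p_e) / (1 - p_e)
}

#' Polygon area metric
#'
#' The six metrics are laid out as radii of a hexagon at 60-degree spacing;
#' the shoelace area of that polygon is normalized by the area of the unit
#' hexagon (`3 * sqrt(3) / 2`). Scaling all metrics by `a` scales the PAM by
#' `a^2`.
#'
#' @param precision,recall,f1,accuracy,auc,jaccard Metrics in \[0, 1\].
#' @return PAM in \[0, 1\].
#' @export
#' @examples
#' polygon_area_metric(1, 1, 1, 1, 1, 1)               # 1
#' polygon_area_metric(0.5, 0.5, 0.5, 0.5, 0.5, 0.5)   # 0.25
polygon_area_metric <- function(precision, recall, f1, accuracy, auc, jaccard) {
  r <- c(precision, recall, f1, accuracy, auc, jaccard)
  if (any(r < 0 | r > 1)) stop_pcg("metrics must lie in [0, 1]", "metric_range")
  theta <- (seq_len(6) - 1) * pi / 3
  x <- r * cos(theta); y <- r * sin(theta)
  i2 <- c(2:6, 1)
  area <- 0.5 * abs(sum(x * y[i2] - x[i2] * y))
  area / (3 * sqrt(3) / 2)
}

# macro one-vs-rest AUC from a probability matrix (columns named by class)
macro_auc <- function(y_true, probs) {
  classes <- colnames(probs)
  aucs <- purrr::map_dbl(classes, function(cl) {
    pos <- y_true == cl
    if (!any(pos) || all(pos)) return(NA_real_)
    r <- rank(probs[, cl])
    (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
  })
  mean(aucs, na.rm = TRUE)
}

#' Stratified k-fold split
#'
#' Disjoint, exhaustive folds with sizes differing by at most one, drawn
#' per class when `labels` are given.
#'
#' @param n Number of samples.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @param labels Optional class labels for stratification; every class must
#'   have at least `k` members.
#' @return List of `k` integer index vectors.
#' @export
kfold_split <- function(n, k, seed = 1L, labels = NULL) {
  stopifnot(is_count(k, 2), n >= k)
  if (!is.null(labels)) {
    stopifnot(length(labels) == n)
    cnt <- table(labels)
    if (any(cnt < k))
      stop_pcg(sprintf("class %s has fewer than k = %d members",
                       names(cnt)[which.min(cnt)], k), "class_too_small")
  }
  with_seed_or_not(seed, {
    folds <- vector("list", k)
    groups <- if (is.null(labels)) list(seq_len(n)) else split(seq_len(n), labels)
    for (g in groups) {
      g <- sample(g)
      asg <- rep(seq_len(k), length.out = length(g))
      for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], g[asg == f])
    }
    purrr::map(folds, sort)
  })
}

#' Cross-validate the full classification pipeline
#'
#' For each stratified fold: the training rows are SMOTE-rebalanced, feature
#' impacts are ranked on the (rebalanced) training data, LV-PSO selects a
#' feature subset, a Sugeno FIS is trained on the binary risk target (normal
#' vs disease) over the top impact-ranked selected features, and the fused
#' FIS + XCNN classifier is trained on the selected features. All fitting —
#' including oversampling — happens inside the training fold only;
#' validation rows are always real recordings.
#'
#' @param data Feature table (from [extract_features()]) with `record_id`,
#'   `label` and numeric feature columns.
#' @param k Number of folds.
#' @param seed Integer seed for folds and every stochastic stage.
#' @param smote_k SMOTE neighbour count (skipped when classes are balanced).
#' @param n_particles,n_iter LV-PSO controls.
#' @param fis_inputs Number of top-impact selected features feeding the FIS.
#' @param xcnn XCNN configuration ([xcnn_config()]).
#' @param normal_class Label treated as "no disease" for the risk target.
#' @return An `eval_report` with extra fields `folds` (per-fold glance
#'   tibble), `fold_models` summaries, `pam`, `auc`.
#' @export
cross_validate <- function(data, k = 5L, seed = 1L, smote_k = 5L,
                           n_particles = 12L, n_iter = 20L, fis_inputs = 4L,
                           xcnn = xcnn_config(epochs = 40L, dropout = 0.5),
                           normal_class = "NHF") {
  stopifnot(all(c("label") %in% names(data)))
  data <- tibble::as_tibble(data)
  classes <- sort(unique(data$label))
  folds <- kfold_split(nrow(data), k, seed = seed, labels = data$label)
  feats <- feature_names(data)

  y_true_all <- character(0); y_pred_all <- character(0)
  probs_all <- NULL
  fold_rows <- list(); fold_models <- list()
  for (f in seq_len(k)) {
    te <- folds[[f]]
    tr_data <- data[-te, , drop = FALSE]
    te_data <- data[te, , drop = FALSE]
    cnt <- table(tr_data$label)
    if (max(cnt) > min(cnt))
      tr_data <- smote_oversample(tr_data, k = min(smote_k, min(cnt) - 1L),
                                  seed = seed + f)
    ranks <- feature_impacts(tr_data)
    sel <- select_features(tr_data, n_particles = n_particles, n_iter = n_iter,
                           seed = seed + f)
    kept <- names(sel$mask)[sel$mask]
    fis_feats <- ranks$feature[ranks$feature %in% kept]
    fis_feats <- head(fis_feats, fis_inputs)
    Xf_tr <- as.matrix(tr_data[fis_feats])
    risk <- as.numeric(tr_data$label != normal_class)
    fis <- fis_train_hybrid(Xf_tr, risk, epochs = 10L)
    fz_tr <- fuzzy_risk_score(fis, Xf_tr)
    X_tr <- as.matrix(tr_data[kept])
    xcnn_f <- xcnn; xcnn_f$seed <- xcnn$seed + f
    model <- xcnn_train(X_tr, tr_data$label, fuzzy = fz_tr, cfg = xcnn_f)
    fz_te <- fuzzy_risk_score(fis, as.matrix(te_data[fis_feats]))
    pred <- xcnn_predict(model, as.matrix(te_data[kept]), fuzzy = fz_te)
    rep_f <- eval_metrics(te_data$label, pred$labels, classes)
    fold_rows[[f]] <- dplyr::mutate(glance(rep_f), fold = f, .before = 1)
    fold_models[[f]] <- list(selected = kept, fis_inputs = fis_feats,
                             train_accuracy = model$final_train_accuracy)
    y_true_all <- c(y_true_all, te_data$label)
    y_pred_all <- c(y_pred_all, pred$labels)
    probs_all <- rbind(probs_all, pred$probs)
  }
  report <- eval_metrics(y_true_all, y_pred_all, classes)
  report$folds <- dplyr::bind_rows(fold_rows)
  report$fold_models <- fold_models
  report$auc <- macro_auc(y_true_all, probs_all)
  report$pam <- polygon_area_metric(report$macro_precision, report$macro_recall,
                                    report$macro_f1, report$accuracy,
                                    report$auc, report$jaccard)
  report
}

#' @rdname cross_validate
#' @param object An `eval_report` with fold results.
#' @param ... Unused.
#' @export
autoplot.eval_report <- function(object, ...) {
  d <- tibble::as_tibble(as.data.frame(as.table(object$confusion)))
  names(d) <- c("truth", "predicted", "n")
  ggplot2::ggplot(d, ggplot2::aes(.data$predicted, .data$truth,
                                  fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(title = sprintf("accuracy %.3f, macro F1 %.3f",
                                  object$accuracy, object$macro_f1))
}
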