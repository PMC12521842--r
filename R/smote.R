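# SMOTE class rebalancing on the feature table: each synthetic minority row
# is drawn on the line segment between a minority sample and one of its k
# nearest same-class neighbours.

#' SMOTE oversampling of minority classes
#'
#' For every class below the target count, synthetic rows are generated as
#' `x + alpha * (x_nn - x)` with `alpha ~ U(0, 1)` and `x_nn` one of the `k`
#' nearest same-class neighbours of `x` under Euclidean distance (distance
#' ties broken by row index). Original rows are preserved unchanged and
#' flagged `synthetic = FALSE`.
#'
#' @param data A tibble/data frame with a `label` column and numeric feature
#'   columns; non-feature metadata columns (`record_id`, `label`,
#'   `synthetic`) are carried through.
#' @param k Neighbour count; must be smaller than every oversampled class.
#' @param target `"match-majority"` (default) or a named vector of per-class
#'   target counts.
#' @param seed Integer seed.
#' @return The input rows plus synthetic rows, with a logical `synthetic`
#'   column; class counts reach the target.
#' @export
#' @examples
#' d <- tibble::tibble(f1 = c(0, 1, 5, 6, 7, 8), f2 = c(0, 1, 5, 6, 7, 8),
#'                     label = c("a", "a", "b", "b", "b", "b"))
#' dplyr::count(smote_oversample(d, k = 1, seed = 1), label)
smote_oversample <- function(data, k = 5L, target = "match-majority", seed = 1L) {
  stopifnot(is.data.frame(data), "label" %in% names(data), is_count(k))
  data <- tibble::as_tibble(data)
  if (!"synthetic" %in% names(data)) data$synthetic <- FALSE
  feat_cols <- setdiff(names(data)[purrr::map_lgl(data, is.numeric)],
                       c("synthetic"))
  if (length(feat_cols) == 0) stop_pcg("no numeric feature columns", "no_features")
  counts <- table(data$label)
  if (length(counts) < 2) stop_pcg("need at least two classes", "single_class")
  if (identical(target, "match-majority")) {
    tgt <- setNames(rep(max(counts), length(counts)), names(counts))
  } else {
    stopifnot(!is.null(names(target)))
    tgt <- target
  }
  new_rows <- with_seed_or_not(seed, {
    purrr::map_dfr(names(tgt), function(cl) {
      need <- tgt[[cl]] - sum(data$label == cl)
      if (need <= 0) return(NULL)
      idx <- which(data$label == cl)
      if (length(idx) <= k)
        stop_pcg(sprintf("class %s has %d rows; needs more than k = %d",
                         cl, length(idx), k), "class_too_small")
      X <- as.matrix(data[idx, feat_cols])
      D <- as.matrix(dist(X))
      diag(D) <- Inf
      # k nearest same-class neighbours, ties by row index
      nn <- t(apply(D, 1, function(d) order(d, seq_along(d))[seq_len(k)]))
      base_i <- rep_len(seq_along(idx), need)
      nn_pick <- nn[cbind(base_i, sample.int(k, need, replace = TRUE))]
      alpha <- runif(need)
      syn <- X[base_i, , drop = FALSE] +
        alpha * (X[nn_pick, , drop = FALSE] - X[base_i, , drop = FALSE])
      out <- tibble::as_tibble(as.data.frame(syn))
      names(out) <- feat_cols
      out$label <- cl
      out$synthetic <- TRUE
      if ("record_id" %in% names(data))
        out$record_id <- sprintf("%s_syn%03d", cl, seq_len(need))
      out
    })
  })
  dplyr::bind_rows(data, new_rows)
}
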