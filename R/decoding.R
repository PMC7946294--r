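#' Standardize features with training-set statistics
#'
#' Per-feature z-scoring: the training set is standardized by its own mean
#' and standard deviation, and the test set is transformed with the training
#' statistics — never its own. The population convention (divide by n) is
#' used for the standard deviation. Zero-variance features map to 0 in both
#' sets, avoiding NaNs.
#'
#' @param train,test Numeric feature matrices with the same columns.
#' @return List with `train` and `test` standardized matrices.
#' @examples
#' zscore_fit_apply(cbind(c(1, 3)), cbind(2))$train  # -1, 1
#' @export
zscore_fit_apply <- function(train, test) {
  train <- as.matrix(train)
  test <- as.matrix(test)
  if (nrow(train) == 0) stop("empty training set")
  if (ncol(train) != ncol(test)) stop("feature dimensions differ")
  mu <- colMeans(train)
  sd_pop <- sqrt(colMeans(sweep(train, 2, mu)^2))
  scale_safe <- function(m) {
    out <- sweep(m, 2, mu)
    for (j in seq_len(ncol(out))) {
      out[, j] <- if (sd_pop[j] > 0) out[, j] / sd_pop[j] else 0
    }
    out
  }
  list(train = scale_safe(train), test = scale_safe(test))
}

#' Train a linear support vector classifier
#'
#' L2-regularized L2-loss support vector classification (the classic linear
#' SVM dual, solved by cyclic coordinate descent) with penalty parameter
#' `cost`; deterministic given its inputs, and numerically stable across the
#' whole study cost grid from `2^-50` to `2^50`. There is no bias term: the
#' decision function passes through the origin, which is appropriate for
#' z-scored features ([zscore_fit_apply()]); no internal scaling is applied.
#'
#' @param x Numeric feature matrix (rows = samples).
#' @param y Two-level factor (or coercible) of labels. The first level is
#'   coded +1.
#' @param cost Penalty parameter C.
#' @return An object of class `iis_svm` with the weight vector `w`, usable
#'   with `predict()`.
#' @export
train_linear_svm <- function(x, y, cost) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) stop("training set must contain two classes")
  ysign <- ifelse(y == levels(y)[1], 1, -1)
  w <- cpp_svm_l2l2(x, ysign, cost)
  structure(list(w = w, levels = levels(y), cost = cost), class = "iis_svm")
}

#' @export
predict.iis_svm <- function(object, newdata, ...) {
  scores <- as.matrix(newdata) %*% object$w
  factor(ifelse(scores >= 0, object$levels[1], object$levels[2]),
         levels = object$levels)
}

#' Default cost grid for the SVM search
#'
#' `2^-50` to `2^50` in exponent steps of 10 (11 values).
#'
#' @return Numeric vector of costs.
#' @export
cost_grid_default <- function() 2^seq(-50, 50, by = 10)

#' Nested leave-one-pair-out cross-validation
#'
#' Samples come in matched pairs (one wake and one anesthesia observation
#' with the same pair id). The outer loop holds out one pair; the inner loop
#' runs leave-one-pair-out over the remaining pairs at every cost in the
#' grid, and the cost with the best inner validation accuracy is selected —
#' ties (after averaging over inner folds) go to the lowest cost. A final
#' model trained on all inner pairs at the chosen cost is scored on the
#' held-out pair; the reported accuracy is the mean over outer folds.
#' Z-scoring is fit on each training set and applied to the corresponding
#' validation/test set.
#'
#' @param features Numeric matrix, one row per sample.
#' @param labels Two-level factor/vector, one per sample.
#' @param pair_id Pair identifier per sample; each id must occur exactly
#'   twice, once per label.
#' @param cost_grid Candidate costs (default [cost_grid_default()]).
#' @return A list of class `iis_cv`: `accuracy`, `fold_accuracy` (one value
#'   per outer fold), `chosen_costs` (cost picked in each outer fold),
#'   `n_pairs`.
#' @export
nested_loo_pair_cv <- function(features, labels, pair_id,
                               cost_grid = cost_grid_default()) {
  features <- as.matrix(features)
  labels <- as.factor(labels)
  pairs <- unique(pair_id)
  if (length(pairs) < 3) stop("nested CV needs at least 3 pairs")
  for (p in pairs) {
    sel <- labels[pair_id == p]
    if (length(sel) != 2 || nlevels(droplevels(sel)) != 2) {
      stop("each pair must hold exactly one sample of each class")
    }
  }
  cost_grid <- sort(cost_grid)
  fold_acc <- numeric(length(pairs))
  chosen <- numeric(length(pairs))
  for (o in seq_along(pairs)) {
    outer_test <- pair_id == pairs[o]
    inner_pairs <- pairs[-o]
    inner_acc <- numeric(length(cost_grid))
    for (ci in seq_along(cost_grid)) {
      accs <- vapply(inner_pairs, function(v) {
        val <- pair_id == v
        tr <- !outer_test & !val
        z <- zscore_fit_apply(features[tr, , drop = FALSE],
                              features[val, , drop = FALSE])
        fit <- train_linear_svm(z$train, labels[tr], cost_grid[ci])
        mean(predict(fit, z$test) == labels[val])
      }, numeric(1))
      inner_acc[ci] <- mean(accs)
    }
    best <- which(inner_acc >= max(inner_acc) - 1e-12)[1]  # tie -> lowest cost
    chosen[o] <- cost_grid[best]
    tr <- !outer_test
    z <- zscore_fit_apply(features[tr, , drop = FALSE],
                          features[outer_test, , drop = FALSE])
    fit <- train_linear_svm(z$train, labels[tr], chosen[o])
    fold_acc[o] <- mean(predict(fit, z$test) == labels[outer_test])
  }
  structure(list(accuracy = mean(fold_acc), fold_accuracy = fold_acc,
                 chosen_costs = chosen, n_pairs = length(pairs)),
            class = "iis_cv")
}

#' Decode arousal state from study features
#'
#' Classifies wake versus anesthesia for each channel set with nested
#' leave-one-pair-out cross-validation, either within subjects (pairs are
#' the matched epochs of one subject; repeated per subject) or across
#' subjects (pairs are the matched conditions of one subject at a fixed
#' epoch; repeated per epoch).
#'
#' @param results An `iis_study_result` from [run_study()].
#' @param feature `"iis"` (all mechanism phi values), `"big_phi"` (1
#'   feature) or `"mechanism"` (1 feature; see `mechanism`).
#' @param mechanism Mechanism label (e.g. `"13"`) when
#'   `feature = "mechanism"`.
#' @param mode `"within"` (per subject) or `"across"` (per epoch).
#' @param cost_grid Candidate SVM costs.
#' @return Tibble with one row per (set_id, unit): `accuracy`, `n_pairs`,
#'   `unit` (subject or epoch), plus `feature`.
#' @export
decode_study <- function(results, feature = c("iis", "big_phi", "mechanism"),
                         mechanism = NULL, mode = c("within", "across"),
                         cost_grid = cost_grid_default()) {
  feature <- match.arg(feature)
  mode <- match.arg(mode)
  fmat <- function(rows) {
    switch(feature,
      iis = do.call(rbind, rows$iis),
      big_phi = cbind(rows$big_phi),
      mechanism = {
        if (is.null(mechanism)) stop("supply `mechanism` for feature = 'mechanism'")
        cbind(vapply(rows$iis, function(v) v[[mechanism]], numeric(1)))
      })
  }
  unit_col <- if (mode == "within") "subject" else "epoch"
  pair_col <- if (mode == "within") "epoch" else "subject"
  grid <- unique(results[, c("set_id", unit_col)])
  out <- lapply(seq_len(nrow(grid)), function(i) {
    rows <- results[results$set_id == grid$set_id[i] &
                      results[[unit_col]] == grid[[unit_col]][i], ]
    cv <- nested_loo_pair_cv(fmat(rows), rows$condition, rows[[pair_col]],
                             cost_grid = cost_grid)
    tibble::tibble(set_id = grid$set_id[i], unit = grid[[unit_col]][i],
                   accuracy = cv$accuracy, n_pairs = cv$n_pairs)
  })
  out <- dplyr::bind_rows(out)
  out$feature <- if (feature == "mechanism") paste0("mechanism_", mechanism) else feature
  out
}

#' Decode from every single mechanism and aggregate by size
#'
#' Runs [decode_study()] once per mechanism (1 feature each) and averages
#' the resulting accuracies across all mechanisms of each size (4, 6, 4 and
#' 1 mechanisms for sizes 1-4 of a 4-channel set).
#'
#' @inheritParams decode_study
#' @return List with `per_mechanism` (tibble: set_id, unit, mechanism,
#'   accuracy) and `by_size` (tibble: set_id, unit, size, accuracy).
#' @export
decode_mechanisms <- function(results, mode = c("within", "across"),
                              cost_grid = cost_grid_default()) {
  mode <- match.arg(mode)
  mechs <- names(results$iis[[1]])
  per <- lapply(mechs, function(m) {
    d <- decode_study(results, feature = "mechanism", mechanism = m,
                      mode = mode, cost_grid = cost_grid)
    d$mechanism <- m
    d
  })
  per <- dplyr::bind_rows(per)
  list(per_mechanism = per, by_size = aggregate_by_mechanism_size(per))
}

#' Average per-mechanism accuracies by mechanism size
#'
#' @param per_mechanism Tibble with columns `set_id`, `unit`, `mechanism`,
#'   `accuracy` covering the complete mechanism census.
#' @return Tibble with one row per (set_id, unit, size).
#' @export
aggregate_by_mechanism_size <- function(per_mechanism) {
  stopifnot(all(c("mechanism", "accuracy") %in% names(per_mechanism)))
  sizes <- nchar(per_mechanism$mechanism)
  k <- max(sizes)
  expected <- choose(k, seq_len(k))
  census <- table(factor(sizes, levels = seq_len(k))) /
    nrow(unique(per_mechanism[, c("set_id", "unit")]))
  if (!all(census == expected)) {
    stop("incomplete mechanism census: need all 2^k - 1 mechanisms per unit")
  }
  per_mechanism$size <- sizes
  dplyr::summarise(
    dplyr::group_by(per_mechanism, .data$set_id, .data$unit, .data$size),
    accuracy = mean(.data$accuracy), .groups = "drop"
  )
}
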