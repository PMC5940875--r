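#' Configuration for the weighted linear SVM
#'
#' Fixes the training contract: a linear-kernel soft-margin SVM with penalty
#' `C` and per-class misclassification weights that scale `C`. Defaults match
#' the study protocol: `C = 0.5` with the metastasis-positive class weighted
#' 1.2 and the negative class 1.0. Features are used unscaled so that `C`
#' keeps its meaning on the raw entropy gradients.
#'
#' @param C Penalty on the training error (> 0).
#' @param positive_weight,negative_weight Per-class weights (> 0) applied to
#'   `C` for the `+1` / `-1` class.
#' @param seed Integer seed controlling fold shuffling in [egsvm_cv()].
#' @param tolerance Termination tolerance of the quadratic-program solver.
#' @return A list of class `"egsvm_config"`.
#' @export
egsvm_config <- function(C = 0.5, positive_weight = 1.2,
                         negative_weight = 1.0, seed = 1L,
                         tolerance = 1e-4) {
  if (C <= 0) stop_egsvm("C must be positive")
  if (positive_weight <= 0 || negative_weight <= 0)
    stop_egsvm("class weights must be positive")
  structure(list(kernel = "linear", C = C,
                 positive_weight = positive_weight,
                 negative_weight = negative_weight,
                 seed = as.integer(seed),
                 tolerance = tolerance),
            class = "egsvm_config")
}

# Split a labelled data frame into (x, y). The label column holds +1 / -1;
# every other numeric column is a feature.
split_labelled <- function(data, label = "label") {
  if (!is.data.frame(data)) stop_egsvm("data must be a data frame")
  if (!label %in% names(data)) stop_egsvm("no '", label, "' column in data")
  y <- data[[label]]
  if (!all(y %in% c(-1, 1))) stop_egsvm("labels must be +1 or -1")
  feat_cols <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], label)
  if (length(feat_cols) == 0) stop_egsvm("no numeric feature columns in data")
  x <- as.matrix(data[feat_cols])
  if (anyNA(x)) stop_egsvm("feature matrix contains missing values")
  list(x = x, y = as.integer(y), features = feat_cols)
}

#' Train the weighted linear SVM
#'
#' Fits `sign(w'x + b)` by the usual soft-margin quadratic program with
#' per-class weights multiplying the penalty `C`. The optimisation is done
#' by libsvm (through \pkg{e1071}); the trained model is stored as the
#' explicit hyperplane `(w, b)`, so prediction is a deterministic dot
#' product. Decision values of exactly zero are classified as `-1`.
#'
#' @param data Data frame with a `label` column in `{+1, -1}` and numeric
#'   feature columns (e.g. the output of [extract_feature_table()]).
#' @param config An [egsvm_config()].
#' @param label Name of the label column.
#' @return An object of class `"egsvm_model"` with fields `w` (named weight
#'   vector), `b` (intercept), `config`, `features`, `n`.
#' @export
egsvm_train <- function(data, config = egsvm_config(), label = "label") {
  d <- split_labelled(data, label)
  if (length(unique(d$y)) < 2)
    stop_egsvm("training requires at least one sample of each class")
  yf <- factor(d$y, levels = c(-1, 1))
  wts <- c("-1" = config$negative_weight, "1" = config$positive_weight)
  fit <- e1071::svm(x = d$x, y = yf, kernel = "linear", cost = config$C,
                    class.weights = wts, scale = FALSE,
                    tolerance = config$tolerance)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # Orient (w, b) so that a positive decision value means class +1.
  dv <- drop(d$x %*% w) + b
  pred <- as.integer(as.character(stats::predict(fit, d$x)))
  if (mean(sign(dv) == pred, na.rm = TRUE) < mean(sign(-dv) == pred, na.rm = TRUE)) {
    w <- -w
    b <- -b
  }
  names(w) <- d$features
  structure(list(w = w, b = unname(b), config = config,
                 features = d$features, n = nrow(d$x)),
            class = "egsvm_model")
}

#' @export
print.egsvm_model <- function(x, ...) {
  cat(sprintf("<egsvm_model> linear SVM, %d features, trained on %d samples\n",
              length(x$w), x$n))
  cat(sprintf("  C = %g, class weights (+1/-1) = %g / %g\n",
              x$config$C, x$config$positive_weight, x$config$negative_weight))
  invisible(x)
}

#' Predict metastasis labels with a trained model
#'
#' @param object An `"egsvm_model"`.
#' @param newdata A numeric feature vector, a feature matrix (rows =
#'   samples), or a data frame containing the model's feature columns.
#' @param type `"label"` for `+1`/`-1` calls (ties at a decision value of
#'   exactly 0 go to `-1`), `"score"` for the raw decision values.
#' @param ... Unused.
#' @return Integer labels or numeric scores, one per sample.
#' @export
predict.egsvm_model <- function(object, newdata, type = c("label", "score"),
                                ...) {
  type <- match.arg(type)
  x <- newdata
  if (is.data.frame(x)) {
    missing <- setdiff(object$features, names(x))
    if (length(missing) > 0)
      stop_egsvm("newdata lacks feature columns: ",
                 paste(utils::head(missing, 3), collapse = ", "))
    x <- as.matrix(x[object$features])
  } else if (is.null(dim(x))) {
    x <- matrix(x, nrow = 1)
  }
  if (ncol(x) != length(object$w))
    stop_egsvm(sprintf("feature length %d does not match model length %d",
                       ncol(x), length(object$w)))
  score <- drop(x %*% object$w) + object$b
  if (type == "score") return(score)
  ifelse(score > 0, 1L, -1L)
}

confusion_from_calls <- function(truth, call) {
  c(tp = sum(truth == 1 & call == 1), fp = sum(truth == -1 & call == 1),
    tn = sum(truth == -1 & call == -1), fn = sum(truth == 1 & call == -1))
}

metric_row <- function(counts) {
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  tp <- counts["tp"]; fp <- counts["fp"]; tn <- counts["tn"]; fn <- counts["fn"]
  tibble::tibble(
    sensitivity = pct(tp, tp + fn),
    specificity = pct(tn, tn + fp),
    accuracy = pct(tp + tn, tp + fp + tn + fn),
    ppv = pct(tp, tp + fp),
    npv = pct(tn, tn + fn))
}

# Deterministic fold assignment. Stratified: shuffle within each class and
# deal round-robin, so fold sizes differ by at most one per class.
assign_folds <- function(y, k, seed, stratify = TRUE) {
  n <- length(y)
  fold <- integer(n)
  with_seed(seed, {
    if (stratify) {
      for (cls in sort(unique(y))) {
        idx <- which(y == cls)
        fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      fold[sample.int(n)] <- rep_len(seq_len(k), n)
    }
  })
  fold
}

#' k-fold cross-validation of the weighted linear SVM
#'
#' The study protocol: randomly partition the samples into `k` subsets
#' (stratified by label, so no test fold is single-class), train on `k - 1`
#' and test on the held-out subset, rotating through all folds; report the
#' across-fold averages of sensitivity, specificity, accuracy, PPV and NPV
#' together with the pooled confusion counts. Bit-reproducible for a given
#' seed and dataset.
#'
#' @param data Data frame with a `label` column in `{+1, -1}` and numeric
#'   feature columns.
#' @param k Number of folds (default 9).
#' @param config An [egsvm_config()]; its `seed` drives the fold shuffle
#'   unless `seed` is given.
#' @param seed Fold-shuffling seed; defaults to `config$seed`.
#' @param stratify Stratify folds by label (default `TRUE`).
#' @param label Name of the label column.
#' @return An object of class `"egsvm_cv"`: `folds` (per-fold counts and
#'   metrics), `summary` (across-fold average of each metric, in percent),
#'   `pooled` (summed confusion counts), plus `k`, `seed`, `config`.
#' @seealso [tidy.egsvm_cv()], [glance.egsvm_cv()], [autoplot.egsvm_cv()]
#' @export
egsvm_cv <- function(data, k = 9, config = egsvm_config(), seed = NULL,
                     stratify = TRUE, label = "label") {
  if (k < 2 || k != floor(k)) stop_egsvm("fold count k must be an integer >= 2")
  d <- split_labelled(data, label)
  n <- length(d$y)
  if (n < k) stop_egsvm("dataset smaller than the number of folds")
  if (is.null(seed)) seed <- config$seed
  fold <- assign_folds(d$y, k, seed, stratify)
  data_df <- tibble::as_tibble(as.data.frame(d$x))
  data_df[[label]] <- d$y
  per_fold <- purrr::map(seq_len(k), function(f) {
    test <- fold == f
    model <- egsvm_train(data_df[!test, , drop = FALSE], config, label)
    calls <- predict(model, data_df[test, , drop = FALSE])
    counts <- confusion_from_calls(d$y[test], calls)
    dplyr::bind_cols(tibble::tibble(fold = f, n_test = sum(test),
                                    tp = counts["tp"], fp = counts["fp"],
                                    tn = counts["tn"], fn = counts["fn"]),
                     metric_row(counts))
  })
  folds <- dplyr::bind_rows(per_fold)
  metrics <- c("sensitivity", "specificity", "accuracy", "ppv", "npv")
  avg <- purrr::map_dbl(folds[metrics], mean, na.rm = TRUE)
  pooled <- c(tp = sum(folds$tp), fp = sum(folds$fp),
              tn = sum(folds$tn), fn = sum(folds$fn))
  structure(list(folds = folds,
                 summary = tibble::as_tibble(as.list(avg)),
                 pooled = pooled, k = as.integer(k),
                 seed = as.integer(seed), config = config,
                 stratified = stratify, n = n),
            class = "egsvm_cv")
}

#' @export
print.egsvm_cv <- function(x, ...) {
  cat(sprintf("<egsvm_cv> %d-fold cross-validation, %d samples (seed %d)\n",
              x$k, x$n, x$seed))
  s <- x$summary
  cat(sprintf("  averaged: sens %.1f%%  spec %.1f%%  acc %.1f%%  PPV %.1f%%  NPV %.1f%%\n",
              s$sensitivity, s$specificity, s$accuracy, s$ppv, s$npv))
  cat(sprintf("  pooled counts: TP %d  FP %d  TN %d  FN %d\n",
              x$pooled["tp"], x$pooled["fp"], x$pooled["tn"], x$pooled["fn"]))
  invisible(x)
}

#' Tidy per-fold cross-validation results
#'
#' @param x An `"egsvm_cv"` object.
#' @param ... Unused.
#' @return A tibble with one row per fold: confusion counts and the five
#'   metrics in percent.
#' @exportS3Method generics::tidy
tidy.egsvm_cv <- function(x, ...) x$folds

#' One-row summary of a cross-validation run
#'
#' @param x An `"egsvm_cv"` object.
#' @param ... Unused.
#' @return A one-row tibble: the five across-fold averaged metrics (percent),
#'   pooled confusion counts, `k`, `n`, `seed`.
#' @exportS3Method generics::glance
glance.egsvm_cv <- function(x, ...) {
  dplyr::bind_cols(x$summary,
                   tibble::tibble(tp = x$pooled["tp"], fp = x$pooled["fp"],
                                  tn = x$pooled["tn"], fn = x$pooled["fn"],
                                  k = x$k, n = x$n, seed = x$seed))
}

#' Tidy the hyperplane of a trained model
#'
#' @param x An `"egsvm_model"`.
#' @param ... Unused.
#' @return A tibble of terms: the intercept followed by one row per feature
#'   weight.
#' @exportS3Method generics::tidy
tidy.egsvm_model <- function(x, ...) {
  tibble::tibble(term = c("(intercept)", names(x$w)),
                 estimate = c(x$b, unname(x$w)))
}

#' One-row summary of a trained model
#'
#' @param x An `"egsvm_model"`.
#' @param ... Unused.
#' @return A one-row tibble: sample count, feature count, `C` and class
#'   weights.
#' @exportS3Method generics::glance
glance.egsvm_model <- function(x, ...) {
  tibble::tibble(n = x$n, n_features = length(x$w), C = x$config$C,
                 positive_weight = x$config$positive_weight,
                 negative_weight = x$config$negative_weight)
}
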