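#' Wald confidence interval for a proportion
#'
#' Normal-approximation interval `p +/- z * sqrt(p(1-p)/n)` on the percent
#' scale, clipped to `[0, 100]`. This is the interval form that reproduces
#' the diagnostic-accuracy confidence bounds reported for this classifier's
#' evaluation tables. Wilson and Clopper-Pearson exact intervals are
#' available via `method` for users who prefer them.
#'
#' @param successes,n Counts, `0 <= successes <= n`, `n > 0`.
#' @param level Confidence level (default 0.95).
#' @param method `"wald"` (default), `"wilson"`, or `"exact"`.
#' @param digits Decimal places for half-up rounding of the bounds; `NULL`
#'   for unrounded.
#' @return Named numeric `c(lo, hi)` in percent.
#' @examples
#' wald_ci(39, 46)  # (74.4, 95.2)
#' @export
wald_ci <- function(successes, n, level = 0.95,
                    method = c("wald", "wilson", "exact"), digits = 1) {
  method <- match.arg(method)
  if (n <= 0) stop_egsvm("n must be positive")
  if (successes < 0 || successes > n)
    stop_egsvm("successes must lie in [0, n]")
  p <- successes / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- switch(method,
    wald = {
      half <- z * sqrt(p * (1 - p) / n)
      c(p - half, p + half)
    },
    wilson = {
      denom <- 1 + z^2 / n
      centre <- (p + z^2 / (2 * n)) / denom
      half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
      c(centre - half, centre + half)
    },
    exact = as.numeric(stats::binom.test(successes, n,
                                         conf.level = level)$conf.int))
  out <- clip(100 * ci, 0, 100)
  if (!is.null(digits)) out <- round_half_up(out, digits)
  c(lo = out[1], hi = out[2])
}

#' Diagnostic-accuracy metrics from confusion counts
#'
#' Sensitivity, specificity, accuracy, positive and negative predictive
#' value as percentages (half-up rounded to one decimal) with confidence
#' intervals from [wald_ci()]. A metric whose denominator is zero is
#' reported as `NA` (undefined), never as 0.
#'
#' @param tp,fp,tn,fn Non-negative integer counts of true/false
#'   positives/negatives.
#' @param level Confidence level for the intervals.
#' @param method Interval method passed to [wald_ci()].
#' @return A tibble with one row per metric: `metric`, `successes`, `n`,
#'   `estimate`, `conf_low`, `conf_high` (percent, 1 decimal).
#' @examples
#' confusion_metrics(tp = 39, fp = 10, tn = 34, fn = 7)
#' @export
confusion_metrics <- function(tp, fp, tn, fn, level = 0.95, method = "wald") {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop_egsvm("confusion counts must be non-negative integers")
  if (sum(counts) == 0) stop_egsvm("all confusion counts are zero")
  defs <- list(sensitivity = c(tp, tp + fn),
               specificity = c(tn, tn + fp),
               accuracy = c(tp + tn, tp + fp + tn + fn),
               ppv = c(tp, tp + fp),
               npv = c(tn, tn + fn))
  purrr::map_dfr(names(defs), function(m) {
    s <- defs[[m]][1]
    n <- defs[[m]][2]
    if (n == 0) {
      return(tibble::tibble(metric = m, successes = s, n = n,
                            estimate = NA_real_, conf_low = NA_real_,
                            conf_high = NA_real_))
    }
    ci <- wald_ci(s, n, level = level, method = method, digits = 1)
    tibble::tibble(metric = m, successes = s, n = n,
                   estimate = round_half_up(100 * s / n, 1),
                   conf_low = ci[["lo"]], conf_high = ci[["hi"]])
  })
}

#' Youden's index and likelihood ratios
#'
#' Computed from the *rounded* one-decimal percentages, matching the
#' reporting arithmetic of diagnostic-accuracy tables built from rounded
#' sensitivity and specificity: `youden = (sens + spec)/100 - 1` (3
#' decimals), `LR+ = sens / (100 - spec)` and `LR- = (100 - sens) / spec`
#' (4 decimals).
#'
#' @param sensitivity,specificity Percentages in `[0, 100]`, typically
#'   already rounded to one decimal.
#' @return A one-row tibble: `youden`, `lr_pos`, `lr_neg`. `lr_pos` is `Inf`
#'   when specificity is 100; `lr_neg` is `NA` when specificity is 0.
#' @examples
#' youden_lr(84.8, 77.3)
#' @export
youden_lr <- function(sensitivity, specificity) {
  if (sensitivity < 0 || sensitivity > 100 ||
      specificity < 0 || specificity > 100)
    stop_egsvm("sensitivity and specificity must be percentages in [0, 100]")
  lr_pos <- if (specificity == 100) Inf else
    round_half_up(sensitivity / (100 - specificity), 4)
  lr_neg <- if (specificity == 0) NA_real_ else
    round_half_up((100 - sensitivity) / specificity, 4)
  tibble::tibble(
    youden = round_half_up((sensitivity + specificity) / 100 - 1, 3),
    lr_pos = lr_pos, lr_neg = lr_neg)
}

#' Prevalence of a finding
#'
#' Percentage of positive cases among cases, half-up rounded to one decimal.
#'
#' @param cases Total case count (> 0).
#' @param positive_cases Positive count, `0 <= positive_cases <= cases`.
#' @return Prevalence in percent.
#' @export
prevalence <- function(cases, positive_cases) {
  if (cases <= 0) stop_egsvm("cases must be positive")
  if (positive_cases < 0 || positive_cases > cases)
    stop_egsvm("positive_cases must lie in [0, cases]")
  round_half_up(100 * positive_cases / cases, 1)
}

#' Paired cross-classification of two diagnostic tests
#'
#' Cross-classifies the calls of a new test and a reference test on the same
#' patients, stratified by true disease status. Each stratum gives four
#' counts in the fixed order (new+, ref+), (new+, ref-), (new-, ref+),
#' (new-, ref-).
#'
#' @param positive,negative Length-4 non-negative integer vectors of counts
#'   for the truly diseased / truly disease-free stratum, in the order
#'   above.
#' @return A tibble of class `"paired_outcomes"` with columns `truth`,
#'   `new_pos_ref_pos`, `new_pos_ref_neg`, `new_neg_ref_pos`,
#'   `new_neg_ref_neg`.
#' @examples
#' paired_outcomes(positive = c(29, 10, 5, 2), negative = c(1, 9, 6, 28))
#' @export
paired_outcomes <- function(positive, negative) {
  for (v in list(positive, negative)) {
    if (length(v) != 4 || any(v < 0) || any(v != floor(v)))
      stop_egsvm("each stratum needs four non-negative integer counts")
  }
  out <- tibble::tibble(
    truth = c("positive", "negative"),
    new_pos_ref_pos = c(positive[1], negative[1]),
    new_pos_ref_neg = c(positive[2], negative[2]),
    new_neg_ref_pos = c(positive[3], negative[3]),
    new_neg_ref_neg = c(positive[4], negative[4]))
  class(out) <- c("paired_outcomes", class(out))
  out
}

#' Paired noninferiority test on diagnostic accuracy
#'
#' Tests whether a new test's accuracy is noninferior to a reference test's
#' on the same patients, with margin `delta`. Each patient contributes a
#' correctness pair (a call is correct when it matches the true status);
#' with `b` = patients the new test gets right and the reference wrong,
#' `c` = the reverse, and `n` patients in total, the accuracy difference is
#' `d = (b - c) / n` and the Wald statistic for paired proportions is
#' `z = (d + delta) / SE`, `SE = sqrt((b + c) - (b - c)^2 / n) / n`, with
#' one-sided p-value `1 - pnorm(z)`. Noninferiority is concluded when
#' `p < alpha`. When `b + c = 0` the standard error degenerates; the
#' conclusion is then reported directly from the sign of `d + delta` with
#' `z` and `p` set to `NA`.
#'
#' @param table A [paired_outcomes()] table.
#' @param delta Noninferiority margin on the accuracy scale (default 0.10).
#' @param alpha One-sided significance level (default 0.05).
#' @return A one-row tibble: `b`, `c`, `n`, `accuracy_diff`, `z`,
#'   `p_one_sided`, `delta`, `alpha`, `noninferior` (logical).
#' @examples
#' tab <- paired_outcomes(positive = c(29, 10, 5, 2),
#'                        negative = c(1, 9, 6, 28))
#' noninferiority_paired(tab, delta = 0.10)
#' @export
noninferiority_paired <- function(table, delta = 0.10, alpha = 0.05) {
  if (!inherits(table, "paired_outcomes"))
    stop_egsvm("table must be built with paired_outcomes()")
  pos <- table[table$truth == "positive", ]
  neg <- table[table$truth == "negative", ]
  # correct call = positive in the diseased stratum, negative otherwise
  b <- pos$new_pos_ref_neg + neg$new_neg_ref_pos  # new correct, ref wrong
  cc <- pos$new_neg_ref_pos + neg$new_pos_ref_neg  # ref correct, new wrong
  n <- sum(as.matrix(table[-1]))
  if (n <= 0) stop_egsvm("table totals must be positive")
  d <- (b - cc) / n
  if (b + cc == 0) {
    return(tibble::tibble(b = b, c = cc, n = n, accuracy_diff = d,
                          z = NA_real_, p_one_sided = NA_real_,
                          delta = delta, alpha = alpha,
                          noninferior = (d + delta) > 0))
  }
  se <- sqrt((b + cc) - (b - cc)^2 / n) / n
  z <- (d + delta) / se
  p <- 1 - stats::pnorm(z)
  tibble::tibble(b = b, c = cc, n = n, accuracy_diff = d, z = z,
                 p_one_sided = p, delta = delta, alpha = alpha,
                 noninferior = p < alpha)
}

#' Swap the roles of the two tests in a paired table
#'
#' Convenience for checking antisymmetry: the accuracy difference of the
#' swapped table is the negative of the original's.
#'
#' @param table A [paired_outcomes()] table.
#' @return A [paired_outcomes()] table with new and reference interchanged.
#' @export
swap_tests <- function(table) {
  if (!inherits(table, "paired_outcomes"))
    stop_egsvm("table must be built with paired_outcomes()")
  paired_outcomes(
    positive = as.numeric(table[table$truth == "positive",
                                c("new_pos_ref_pos", "new_neg_ref_pos",
                                  "new_pos_ref_neg", "new_neg_ref_neg")]),
    negative = as.numeric(table[table$truth == "negative",
                                c("new_pos_ref_pos", "new_neg_ref_pos",
                                  "new_pos_ref_neg", "new_neg_ref_neg")]))
}
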