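# Cohort evaluation: confusion counts of a binary alert against ground
# truth, sensitivity/specificity, and exact (Clopper-Pearson) binomial
# confidence intervals obtained from beta quantiles.

#' 2x2 confusion counts
#'
#' @param predictions named logical vector: alert positive per episode.
#' @param labels named logical vector over the same episode ids: ground
#'   truth.
#' @return a `confusion_counts` list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(predictions, labels) {
  if (is.null(names(predictions)) || is.null(names(labels))) {
    if (length(predictions) != length(labels)) {
      stop("predictions and labels must have identical key sets", call. = FALSE)
    }
  } else {
    if (!setequal(names(predictions), names(labels))) {
      stop("predictions and labels must have identical key sets", call. = FALSE)
    }
    labels <- labels[names(predictions)]
  }
  structure(list(
    tp = sum(predictions & labels),
    fp = sum(predictions & !labels),
    tn = sum(!predictions & !labels),
    fn = sum(!predictions & labels)
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion: tp=%d fp=%d tn=%d fn=%d>\n", x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Sensitivity (true-positive rate)
#'
#' @param c a [confusion()] object.
#' @return `tp / (tp + fn)`; `NA` with a warning when no positives exist.
#' @export
sensitivity <- function(c) {
  if (c$tp + c$fn == 0L) {
    warning("sensitivity undefined: no positive cases (tp + fn = 0)")
    return(NA_real_)
  }
  c$tp / (c$tp + c$fn)
}

#' Specificity (true-negative rate)
#'
#' @param c a [confusion()] object.
#' @return `tn / (tn + fp)`; `NA` with a warning when no negatives exist.
#' @export
specificity <- function(c) {
  if (c$tn + c$fp == 0L) {
    warning("specificity undefined: no negative cases (tn + fp = 0)")
    return(NA_real_)
  }
  c$tn / (c$tn + c$fp)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Inverts the binomial tails through the beta-quantile identity:
#' `lower = qbeta(alpha/2, x, n - x + 1)` (0 when `x = 0`) and
#' `upper = qbeta(1 - alpha/2, x + 1, n - x)` (1 when `x = n`).
#'
#' @param x number of successes, `0 <= x <= n`.
#' @param n number of trials, `n >= 1`.
#' @param level confidence level, default 0.95.
#' @return a `proportion_ci` list with `estimate`, `lower`, `upper`, `level`,
#'   `method = "clopper-pearson"`.
#' @examples
#' ci <- exact_binomial_ci(6, 12)
#' round(100 * c(ci$lower, ci$upper), 2)   # 21.09 78.91
#' @export
exact_binomial_ci <- function(x, n, level = 0.95) {
  if (length(x) != 1L || length(n) != 1L || is.na(x) || is.na(n) ||
      n < 1 || x < 0 || x > n || x != trunc(x) || n != trunc(n)) {
    stop("need integers 0 <= x <= n with n >= 1", call. = FALSE)
  }
  stopifnot(level > 0, level < 1)
  alpha <- 1 - level
  lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  structure(list(estimate = x / n, lower = lower, upper = upper,
                 level = level, method = "clopper-pearson"),
            class = "proportion_ci")
}

#' @export
print.proportion_ci <- function(x, ...) {
  cat(sprintf("%.2f%% (%d%% CI %.2f–%.2f%%, %s)\n", 100 * x$estimate,
              round(100 * x$level), 100 * x$lower, 100 * x$upper, x$method))
  invisible(x)
}

.default_truth <- list(
  focality = function(ep) identical(ep$label, "focal"),
  pnes = function(ep) identical(ep$label, "pnes"),
  jacksonian = NULL,
  sudep = NULL
)

#' Score an extrapolation function on a labeled cohort
#'
#' Runs one rule function over every episode, tallies its positive alerts
#' against ground truth, and reports sensitivity and specificity with exact
#' confidence intervals. For focality and pnes the truth defaults to the
#' episodes' ground-truth labels (`focal` / `pnes`); for jacksonian and
#' sudep an explicit `truth` is required, since those alerts flag a feature,
#' not a diagnosis.
#'
#' @param cohort list of `ds_episode`s carrying ground-truth labels.
#' @param fn one of `"focality"`, `"pnes"`, `"jacksonian"`, `"sudep"`.
#' @param config a [rule_config()].
#' @param truth optional logical vector (one per episode) overriding the
#'   label-derived truth.
#' @param level confidence level for the intervals.
#' @return a `cohort_evaluation` list: `fn`, `counts`,
#'   `sensitivity`/`specificity` (`proportion_ci` or `NULL` when undefined),
#'   `n`.
#' @export
evaluate_cohort <- function(cohort, fn = c("focality", "pnes", "jacksonian",
                                           "sudep"),
                            config = rule_config(), truth = NULL,
                            level = 0.95) {
  fn <- match.arg(fn)
  check <- switch(fn,
                  focality = check_focality,
                  pnes = check_pnes,
                  jacksonian = function(ep, cfg) {
                    st <- if (length(detect_jacksonian(ep, cfg))) "positive"
                          else "inconclusive"
                    list(status = st)
                  },
                  sudep = check_sudep)
  ids <- vapply(cohort, `[[`, "", "id")
  preds <- vapply(cohort, function(ep) {
    identical(check(ep, config)$status, "positive")
  }, FALSE)
  names(preds) <- ids
  if (is.null(truth)) {
    tf <- .default_truth[[fn]]
    if (is.null(tf)) {
      stop(sprintf("'%s' has no label-derived truth; supply `truth`", fn),
           call. = FALSE)
    }
    truth <- vapply(cohort, tf, FALSE)
  }
  stopifnot(length(truth) == length(cohort))
  names(truth) <- ids
  cts <- confusion(preds, truth)
  sens <- if (cts$tp + cts$fn > 0) {
    exact_binomial_ci(cts$tp, cts$tp + cts$fn, level)
  } else NULL
  spec <- if (cts$tn + cts$fp > 0) {
    exact_binomial_ci(cts$tn, cts$tn + cts$fp, level)
  } else NULL
  structure(list(fn = fn, counts = cts, sensitivity = sens,
                 specificity = spec, n = length(cohort)),
            class = "cohort_evaluation")
}

#' @export
print.cohort_evaluation <- function(x, ...) {
  cat(sprintf("Evaluation of '%s' on %d episodes\n", x$fn, x$n))
  print(x$counts)
  fmt <- function(ci) {
    if (is.null(ci)) "undefined (no cases)" else
      sprintf("%.2f%% (%d%% CI %.2f–%.2f%%)", 100 * ci$estimate,
              round(100 * ci$level), 100 * ci$lower, 100 * ci$upper)
  }
  cat("  sensitivity:", fmt(x$sensitivity), "\n")
  cat("  specificity:", fmt(x$specificity), "\n")
  invisible(x)
}

#' @export
as.data.frame.cohort_evaluation <- function(x, ...) {
  ci_or_na <- function(ci, what) {
    if (is.null(ci)) rep(NA_real_, 3L) else
      c(ci$estimate, ci$lower, ci$upper)
  }
  se <- ci_or_na(x$sensitivity)
  sp <- ci_or_na(x$specificity)
  data.frame(fn = x$fn, n = x$n, tp = x$counts$tp, fp = x$counts$fp,
             tn = x$counts$tn, fn_count = x$counts$fn,
             sensitivity = se[1L], sens_lower = se[2L], sens_upper = se[3L],
             specificity = sp[1L], spec_lower = sp[2L], spec_upper = sp[3L],
             stringsAsFactors = FALSE)
}
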