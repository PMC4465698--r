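# Chart-review performance arithmetic: the 2x2 confusion tally and
# PPV / NPV / sensitivity / specificity / accuracy, plus the percent
# formatter.  Published percentages for this class of validation study are
# consistent with TRUNCATION at one decimal (138/267 = 51.68 -> "51.6"),
# so truncation is the default formatter and plain rounding is a flag.

#' Tally a 2x2 confusion matrix from predicted and true labels
#'
#' @param predicted,truth Either tibbles with columns `subject_id` and
#'   `label`, or named character vectors mapping subject to label; labels
#'   must be `"positive"` or `"negative"`.  The two key sets must match
#'   exactly.
#' @return A `confusion_counts` object with fields `tp`, `fp`, `tn`, `fn`;
#'   `tp + fp + tn + fn` equals the number of subjects.
#' @examples
#' pred <- c(a = "positive", b = "positive", c = "negative")
#' truth <- c(a = "positive", b = "negative", c = "negative")
#' confusion_counts(pred, truth)
#' @export
confusion_counts <- function(predicted, truth) {
  predicted <- as_label_map(predicted, "predicted")
  truth <- as_label_map(truth, "truth")
  if (!setequal(names(predicted), names(truth)) ||
      length(predicted) != length(truth)) {
    abort("predicted and truth must cover exactly the same subjects")
  }
  truth <- truth[names(predicted)]
  new_confusion_counts(
    tp = sum(predicted == "positive" & truth == "positive"),
    fp = sum(predicted == "positive" & truth == "negative"),
    tn = sum(predicted == "negative" & truth == "negative"),
    fn = sum(predicted == "negative" & truth == "positive")
  )
}

as_label_map <- function(x, what) {
  if (is.data.frame(x)) {
    if (!all(c("subject_id", "label") %in% names(x))) {
      abort(sprintf("%s must have columns subject_id and label", what))
    }
    x <- stats::setNames(as.character(x$label), x$subject_id)
  }
  if (is.null(names(x)) || anyDuplicated(names(x))) {
    abort(sprintf("%s must be keyed by unique subject ids", what))
  }
  if (!all(x %in% c("positive", "negative"))) {
    abort(sprintf("%s labels must be 'positive' or 'negative'", what))
  }
  x
}

#' Construct confusion counts directly from review tallies
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return A `confusion_counts` object.
#' @examples
#' as_confusion_counts(tp = 138, fp = 129, tn = 295, fn = 5)
#' @export
as_confusion_counts <- function(tp, fp, tn, fn) {
  new_confusion_counts(tp, fp, tn, fn)
}

new_confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("confusion counts must be non-negative integers")
  }
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(as.list(counts), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts>\n")
  cat(sprintf("  TP %d  FP %d\n  FN %d  TN %d  (n = %d)\n",
              x$tp, x$fp, x$fn, x$tn, x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

metric_ratio <- function(num, den, name) {
  if (den == 0) {
    abort(sprintf("%s is undefined: its denominator is zero", name))
  }
  num / den
}

#' Predictive values, sensitivity, specificity and accuracy
#'
#' Exact ratios over the confusion counts: `ppv = TP/(TP+FP)`,
#' `npv = TN/(TN+FN)`, `sensitivity = TP/(TP+FN)`,
#' `specificity = TN/(TN+FP)`, `accuracy = (TP+TN)/(TP+FP+TN+FN)`.
#' A zero denominator is an error, never silently 0.
#'
#' @param counts A `confusion_counts` object.
#' @return Numeric proportion in \[0, 1\].
#' @examples
#' cc <- as_confusion_counts(tp = 138, fp = 129, tn = 295, fn = 5)
#' ppv(cc)      # 138/267
#' npv(cc)      # 295/300
#' accuracy(cc) # 433/567
#' @export
ppv <- function(counts) metric_ratio(counts$tp, counts$tp + counts$fp, "PPV")

#' @rdname ppv
#' @export
npv <- function(counts) metric_ratio(counts$tn, counts$tn + counts$fn, "NPV")

#' @rdname ppv
#' @export
sensitivity <- function(counts) {
  metric_ratio(counts$tp, counts$tp + counts$fn, "sensitivity")
}

#' @rdname ppv
#' @export
specificity <- function(counts) {
  metric_ratio(counts$tn, counts$tn + counts$fp, "specificity")
}

#' @rdname ppv
#' @export
accuracy <- function(counts) {
  metric_ratio(counts$tp + counts$tn,
               counts$tp + counts$fp + counts$tn + counts$fn, "accuracy")
}

#' Format a proportion as a percentage, truncating (default) or rounding
#'
#' `format_percent_trunc()` multiplies by 100 and floors toward zero at
#' `decimals` places — the convention that reproduces published
#' chart-review percentages (0.51685 -> "51.6").  `format_percent()`
#' exposes plain rounding as an alternative `method`.
#'
#' @param x Proportion in \[0, 1\].
#' @param decimals Decimal places to keep.
#' @param method `"truncate"` or `"round"`.
#' @return Character scalar (vectorized over `x`).
#' @examples
#' format_percent_trunc(138 / 267, 1) # "51.6"
#' format_percent_trunc(295 / 300, 1) # "98.3"
#' format_percent_trunc(0.999, 0)     # "99"
#' @export
format_percent_trunc <- function(x, decimals = 1) {
  format_percent(x, decimals, method = "truncate")
}

#' @rdname format_percent_trunc
#' @export
format_percent <- function(x, decimals = 1,
                           method = c("truncate", "round")) {
  method <- match.arg(method)
  stopifnot(all(x >= 0 & x <= 1))
  scale <- 10^decimals
  # the 1e-9 guard keeps exact decimal ratios (e.g. 0.515) from flooring one
  # ulp low in binary floating point
  v <- switch(method,
    truncate = floor(x * 100 * scale + 1e-9) / scale,
    round = round(x * 100 * scale) / scale
  )
  formatC(v, format = "f", digits = decimals)
}

#' @export
tidy.confusion_counts <- function(x, ...) {
  safe <- function(f) tryCatch(f(x), error = function(e) NA_real_)
  tibble(
    metric = c("ppv", "npv", "sensitivity", "specificity", "accuracy"),
    estimate = c(safe(ppv), safe(npv), safe(sensitivity), safe(specificity),
                 safe(accuracy))
  )
}

#' @export
glance.confusion_counts <- function(x, ...) {
  safe <- function(f) tryCatch(f(x), error = function(e) NA_real_)
  tibble(
    tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn,
    n = x$tp + x$fp + x$tn + x$fn,
    ppv = safe(ppv), npv = safe(npv), sensitivity = safe(sensitivity),
    specificity = safe(specificity), accuracy = safe(accuracy)
  )
}

#' Evaluate phenotype assignments against reviewed truth labels
#'
#' Maps algorithm statuses to a positive/negative prediction (case tiers in
#' `positive_statuses` are positive; `control` is negative; other statuses
#' are outside the evaluable set and dropped), joins with truth labels, and
#' tallies the confusion counts.
#'
#' @param assignments Result of [run_phenotyping()].
#' @param truth Tibble with `subject_id` and `true_status`
#'   (`"positive"`/`"negative"`).
#' @param positive_statuses Statuses counted as a positive prediction.
#' @return A `confusion_counts` object; use [tidy()] / [glance()] for the
#'   derived metrics.
#' @export
evaluate_assignments <- function(assignments, truth,
                                 positive_statuses = c("case_definite",
                                                       "case_potential")) {
  pred <- tibble(
    subject_id = assignments$subject_id,
    label = dplyr::case_when(
      as.character(assignments$status) %in% positive_statuses ~ "positive",
      as.character(assignments$status) == "control" ~ "negative",
      TRUE ~ NA_character_
    )
  ) %>% filter(!is.na(.data$label))
  tr <- tibble(subject_id = truth$subject_id,
               label = as.character(truth$true_status)) %>%
    semi_join(pred, by = "subject_id")
  confusion_counts(pred, tr)
}
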