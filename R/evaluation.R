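# Confusion matrices and AAMI-style classification metrics.

#' The four AAMI classification target classes
#'
#' Fixed class order: N (normal-like), S (supraventricular ectopic),
#' V (ventricular ectopic), F (fusion).
#'
#' @return character vector `c("N", "S", "V", "F")`.
#' @export
aami_classes <- function() c("N", "S", "V", "F")

#' Round half-up to a number of decimals
#'
#' Percentage rounding convention used when reporting metrics to one
#' decimal (0.05 always rounds up, unlike banker's rounding).
#'
#' @param x numeric.
#' @param digits decimals to keep.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

#' Confusion matrix over the four AAMI classes
#'
#' Rows are true classes, columns predicted classes, both in the fixed
#' order N, S, V, F.
#'
#' @param y_true,y_pred character vectors of equal length with values in
#'   N, S, V, F.
#' @return 4 x 4 integer matrix with dimnames `true` x `predicted`.
#' @export
confusion_matrix <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  cls <- aami_classes()
  bad <- setdiff(unique(c(y_true, y_pred)), cls)
  if (length(bad) > 0) {
    stop("unknown class label: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  m <- table(factor(y_true, levels = cls), factor(y_pred, levels = cls))
  m <- matrix(as.integer(m), 4, 4,
              dimnames = list(true = cls, predicted = cls))
  m
}

#' Per-class TP/TN/FP/FN counts
#'
#' @param cm a 4 x 4 confusion matrix (true rows, predicted columns).
#' @param class one of N, S, V, F.
#' @return named integer vector `c(TP, TN, FP, FN)`.
#' @export
class_counts <- function(cm, class) {
  i <- match(class, aami_classes())
  stopifnot(!is.na(i))
  tp <- cm[i, i]
  fn <- sum(cm[i, ]) - tp
  fp <- sum(cm[, i]) - tp
  tn <- sum(cm) - tp - fn - fp
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

#' Classification metrics from a confusion matrix
#'
#' Per class: sensitivity `SE = TP/(TP+FN)`, specificity `SP = TN/(TN+FP)`,
#' positive predictive value `PPV = TP/(TP+FP)` and accuracy
#' `ACC = (TP+TN)/total`; plus overall accuracy (trace / total) and the
#' geometric means of the per-class sensitivities and of the per-class
#' PPVs. Ratios with a zero denominator are reported as `NA` (an explicit
#' undefined marker) and excluded from the geometric means with a warning.
#'
#' @param cm a 4 x 4 confusion matrix.
#' @return list with `per_class` (data frame of SE, SP, PPV, ACC in
#'   percent, unrounded), `overall_accuracy`, `g_mean_se`, `g_mean_ppv`
#'   (percent, unrounded).
#' @export
classification_metrics <- function(cm) {
  cls <- aami_classes()
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  per <- do.call(rbind, lapply(cls, function(cl) {
    ct <- class_counts(cm, cl)
    data.frame(
      class = cl,
      SE = ratio(ct["TP"], ct["TP"] + ct["FN"]),
      SP = ratio(ct["TN"], ct["TN"] + ct["FP"]),
      PPV = ratio(ct["TP"], ct["TP"] + ct["FP"]),
      ACC = ratio(ct["TP"] + ct["TN"], sum(ct)),
      row.names = NULL
    )
  }))
  total <- sum(cm)
  overall <- if (total == 0) NA_real_ else 100 * sum(diag(cm)) / total
  gm <- function(x, what) {
    if (anyNA(x)) {
      warning("undefined per-class ", what,
              " excluded from the geometric mean")
      x <- x[!is.na(x)]
    }
    if (length(x) == 0) NA_real_ else g_mean(x)
  }
  list(
    per_class = per,
    overall_accuracy = overall,
    g_mean_se = gm(per$SE, "sensitivities"),
    g_mean_ppv = gm(per$PPV, "positive predictive values")
  )
}

#' Geometric mean
#'
#' k-th root of the product of k nonnegative values; for two values this is
#' the classical `sqrt(x_pos * x_neg)` imbalance-robust summary, and the
#' four-class tables use k = 4. Any zero entry gives 0.
#'
#' @param ... nonnegative numerics (vectors are flattened).
#' @return scalar geometric mean.
#' @export
g_mean <- function(...) {
  x <- c(...)
  stopifnot(length(x) > 0)
  if (any(x < 0)) stop("negative values have no geometric mean", call. = FALSE)
  if (any(x == 0)) return(0)
  exp(mean(log(x)))
}
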