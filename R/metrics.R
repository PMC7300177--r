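#' Confusion matrix for a one-vs-all comparison
#'
#' Lightweight container for pooled binary classification counts. The
#' positive class is the experience group the model is trained to detect;
#' the negative class pools the remaining runners.
#'
#' @param tp,fp,fn,tn Non-negative integer counts (true positive, false
#'   positive, false negative, true negative).
#' @return An object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("confusion matrix entries must be non-negative integers")
  if (sum(counts) == 0)
    stop("confusion matrix must contain at least one case")
  structure(as.list(as.integer(counts)), names = names(counts),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(actual = c("pos", "neg"),
                              predicted = c("pos", "neg")))
  print(m)
  invisible(x)
}

#' Matthews correlation coefficient
#'
#' Computes the MCC from pooled binary counts. When any of the four
#' marginals (predicted-positive, actual-positive, predicted-negative,
#' actual-negative) is zero the coefficient is undefined; `NA_real_` is
#' returned as a distinct "undefined" signal, which the forward-selection
#' routine consumes to trigger its effect-size fallback. This is not an
#' error condition.
#'
#' @param cm A [confusion_matrix()].
#' @return MCC in \[-1, 1\], or `NA_real_` when undefined.
#' @export
mcc <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  marg <- c(cm$tp + cm$fp, cm$tp + cm$fn, cm$tn + cm$fp, cm$tn + cm$fn)
  if (any(marg == 0)) return(NA_real_)
  # products can overflow integer range; work in double
  num <- as.numeric(cm$tp) * cm$tn - as.numeric(cm$fp) * cm$fn
  num / sqrt(prod(as.numeric(marg)))
}

#' Precision, recall, F1 and accuracy
#'
#' Quantities whose denominator is zero are reported as `NA_real_`
#' (undefined) rather than raising an error, so callers can decide how to
#' treat degenerate pooled matrices.
#'
#' @param cm A [confusion_matrix()].
#' @return Named list with `precision`, `recall`, `f1`, `accuracy`.
#' @export
prf1 <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  precision <- if (cm$tp + cm$fp > 0) cm$tp / (cm$tp + cm$fp) else NA_real_
  recall    <- if (cm$tp + cm$fn > 0) cm$tp / (cm$tp + cm$fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall)
  else if (!is.na(precision) && !is.na(recall)) 0
  else NA_real_
  accuracy <- (cm$tp + cm$tn) / (cm$tp + cm$fp + cm$fn + cm$tn)
  list(precision = precision, recall = recall, f1 = f1, accuracy = accuracy)
}

#' Minimum significant accuracy from a critical binomial test
#'
#' The smallest accuracy a classifier must reach before its success count
#' becomes statistically incompatible with a no-information classifier
#' that guesses the majority class. Uses the exact binomial upper tail:
#' the smallest integer `k` with `P(X >= k | n, p0) < 1 - confidence`
#' under `X ~ Binomial(n, p0)`, returned as `k / n`. No normal
#' approximation is used.
#'
#' @param n Number of classified cases.
#' @param p0 No-information success probability (the majority-class
#'   proportion in a one-vs-all split). Must lie strictly in (0, 1).
#' @param confidence Confidence level, default 0.95.
#' @param strict Logical; if `TRUE` (default) the tail must be strictly
#'   below `1 - confidence`, otherwise `<=` is used.
#' @return The minimum significant accuracy as a fraction in (0, 1\].
#' @export
min_significant_accuracy <- function(n, p0, confidence = 0.95, strict = TRUE) {
  if (!is.finite(n) || n < 1 || n != round(n))
    stop("n must be a positive integer")
  if (!is.finite(p0) || p0 <= 0 || p0 >= 1)
    stop("p0 must lie strictly between 0 and 1")
  alpha <- 1 - confidence
  k <- 0:n
  tail <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)  # P(X >= k)
  ok <- if (strict) tail < alpha else tail <= alpha
  if (!any(ok)) stop("no accuracy level reaches significance at this n")
  k[which(ok)[1]] / n
}

#' Cohen's d effect size
#'
#' Absolute standardized mean difference with the pooled standard
#' deviation (`n_a + n_b - 2` denominator). A zero pooled SD with a
#' nonzero mean difference yields `Inf` (an "infinite separation"
#' signal); two identical constant groups yield 0.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return Non-negative effect size (possibly `Inf`).
#' @export
cohens_d <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("both groups need at least 2 values")
  na <- length(group_a); nb <- length(group_b)
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  diff <- abs(mean(group_a) - mean(group_b))
  if (sp2 == 0) {
    if (diff == 0) return(0)
    return(Inf)
  }
  diff / sqrt(sp2)
}
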