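# Outcome measures and hypothesis tests for refractive prediction error.

#' Refractive prediction error
#'
#' The signed difference between what the eye actually refracted to and what
#' the formula predicted: `postop_se - predicted`. Positive values are
#' hyperopic surprises, negative values myopic surprises.
#'
#' @param postop_se Postoperative spherical equivalent, diopters.
#' @param predicted Formula-predicted refraction, diopters.
#' @return Signed error(s) in diopters.
#' @examples
#' prediction_error(-0.25, -0.50)  # +0.25 D hyperopic
#' @export
prediction_error <- function(postop_se, predicted) {
  stopifnot(all(is.finite(postop_se)), all(is.finite(predicted)))
  postop_se - predicted
}

#' Summarize a set of refractive prediction errors
#'
#' Computes the standard refractive-outcome summary: mean signed error, mean
#' absolute error (MAE), median absolute error (MedAE), the interquartile
#' range of the absolute errors (linear-interpolation quartiles), the range
#' of signed errors, and the count/percentage of eyes within each absolute
#' threshold.
#'
#' @param errors Signed prediction errors, diopters (length >= 1).
#' @param thresholds Absolute thresholds in diopters
#'   (default 0.25, 0.50, 0.75, 1.00).
#' @return An object of class `iol_error_summary`: a list with elements `n`,
#'   `mean_error`, `mae`, `medae`, `iqr` (lower/upper quartile of |error|),
#'   `range` (of signed errors), `pct_within` and `counts_within` (named by
#'   threshold), and `errors`.
#' @examples
#' summarize_errors(c(-0.1, 0.2, -0.3))
#' @export
summarize_errors <- function(errors, thresholds = c(0.25, 0.50, 0.75, 1.00)) {
  if (length(errors) < 1L) stop("no errors to summarize", call. = FALSE)
  stopifnot(all(is.finite(errors)), all(thresholds > 0))
  ae <- abs(errors)
  counts <- vapply(thresholds, function(t) sum(ae <= t), integer(1))
  names(counts) <- sprintf("%.2f", thresholds)
  structure(
    list(n = length(errors),
         mean_error = mean(errors),
         mae = mean(ae),
         medae = stats::median(ae),
         iqr = stats::quantile(ae, c(0.25, 0.75), names = FALSE, type = 7),
         range = range(errors),
         pct_within = 100 * counts / length(errors),
         counts_within = counts,
         errors = errors),
    class = "iol_error_summary")
}

#' @export
print.iol_error_summary <- function(x, ...) {
  cat(sprintf("Refractive prediction errors (n = %d)\n", x$n))
  cat(sprintf("  mean error %.2f D (range %.2f to %.2f)\n",
              x$mean_error, x$range[1], x$range[2]))
  cat(sprintf("  MAE %.2f D   MedAE %.2f D (IQR %.2f: %.2f)\n",
              x$mae, x$medae, x$iqr[1], x$iqr[2]))
  for (i in seq_along(x$pct_within))
    cat(sprintf("  within ±%s D: %d (%.1f%%)\n",
                names(x$pct_within)[i], x$counts_within[i], x$pct_within[i]))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two independent samples. The U statistic
#' is reported for the first sample. By default the p-value uses the exact
#' Wilcoxon distribution when the pooled data are tie-free and
#' `n1 * n2 <= 400`, and a tie-corrected, continuity-corrected normal
#' approximation otherwise.
#'
#' @param x,y Numeric samples (both non-empty).
#' @param method `"auto"` (the default dispatch above), or force `"exact"`
#'   (tie-free data only) or `"normal"`.
#' @return List with `U`, `p`, and `method` (`"exact"`, `"normal"`, or
#'   `"degenerate"` when all observations are identical).
#' @examples
#' mann_whitney(c(1, 2, 3, 4), c(2.5, 3.5, 4.5, 5.5))
#' @export
mann_whitney <- function(x, y, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  stopifnot(length(x) >= 1L, length(y) >= 1L,
            all(is.finite(x)), all(is.finite(y)))
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  if (method == "auto")
    method <- if (!ties && n1 * n2 <= 400) "exact" else "normal"
  if (method == "exact") {
    if (ties)
      stop("exact Mann-Whitney p-values require tie-free data", call. = FALSE)
    p_lo <- stats::pwilcox(U, n1, n2)
    p_hi <- 1 - stats::pwilcox(U - 1, n1, n2)
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    nt <- table(r)
    tie_term <- sum(nt^3 - nt) / ((n1 + n2) * (n1 + n2 - 1))
    sigma2 <- n1 * n2 / 12 * (n1 + n2 + 1 - tie_term)
    if (sigma2 <= 0) return(list(U = U, p = 1, method = "degenerate"))
    dev <- max(abs(U - n1 * n2 / 2) - 0.5, 0)  # continuity correction
    p <- 2 * stats::pnorm(-dev / sqrt(sigma2))
  }
  list(U = U, p = p, method = method)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Compares two proportions from counts `a/(a+b)` versus `c/(c+d)`. The
#' default is the uncorrected Pearson statistic
#' `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` on 1 df; set `correct = TRUE` for
#' the Yates continuity correction.
#'
#' @param a,b First group's success/failure counts.
#' @param c_,d_ Second group's success/failure counts.
#' @param correct Apply the Yates continuity correction? Default `FALSE`.
#' @return List with `chisq` and `p`.
#' @examples
#' chi_square_2x2(34, 6, 23, 17)
#' @export
chi_square_2x2 <- function(a, b, c_, d_, correct = FALSE) {
  counts <- c(a, b, c_, d_)
  stopifnot(all(counts >= 0), sum(counts) >= 1)
  n <- sum(counts)
  margins <- c(a + b, c_ + d_, a + c_, b + d_)
  if (any(margins == 0))
    stop("2x2 table has a zero marginal; proportions are undefined",
         call. = FALSE)
  dev <- abs(a * d_ - b * c_)
  if (correct) dev <- max(dev - n / 2, 0)
  chisq <- n * dev^2 / prod(margins)
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Two-sample Student's t-test (pooled variance)
#'
#' @param x,y Numeric samples with at least 2 observations each.
#' @return List with `t`, `df`, `p`.
#' @export
student_t <- function(x, y) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (stats::var(c(x, y)) == 0) return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
  ht <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Squared Pearson correlation
#'
#' @param x,y Paired numeric vectors (n >= 2, non-degenerate variance).
#' @return R-squared, the squared Pearson correlation coefficient.
#' @export
pearson_r2 <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("degenerate variance: correlation undefined", call. = FALSE)
  stats::cor(x, y)^2
}
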