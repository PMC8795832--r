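#' Repetition sample summary
#'
#' Mean, sample standard deviation (n - 1 denominator) and count of a set
#' of repeated measurements, either computed from the raw vector or
#' entered directly from a printed summary table.
#'
#' @param x Numeric vector of measurements, or the sample mean when
#'   \code{sd} and \code{n} are given.
#' @param sd Sample standard deviation (with \code{n}, bypasses the vector
#'   form).
#' @param n Repetition count (>= 2).
#' @return An object of class \code{sample_summary} with fields
#'   \code{mean}, \code{sd}, \code{n}.
#' @export
sample_summary <- function(x, sd = NULL, n = NULL) {
  if (is.null(sd)) {
    if (length(x) < 2L) stop("need at least 2 measurements")
    out <- list(mean = mean(x), sd = stats::sd(x), n = length(x))
  } else {
    if (is.null(n) || n < 2L) stop("n must be >= 2")
    if (sd < 0) stop("sd must be >= 0")
    out <- list(mean = x, sd = sd, n = as.integer(n))
  }
  structure(out, class = "sample_summary")
}

#' Two-tailed Student-t critical value
#'
#' The quantile \eqn{t_{\alpha/2}} with \code{df} degrees of freedom for a
#' two-sided confidence level \code{confidence} (\eqn{\alpha = 1 - C}).
#'
#' @param confidence Confidence level in (0, 1).
#' @param df Degrees of freedom (>= 1).
#' @return The critical value.
#' @examples
#' t_critical(0.95, 19) # 2.093
#' @export
t_critical <- function(confidence, df) {
  if (!is.finite(confidence) || confidence <= 0 || confidence >= 1)
    stop("confidence must lie strictly between 0 and 1")
  if (df < 1L) stop("df must be >= 1")
  qt(1 - (1 - confidence) / 2, df)
}

#' Margin of error of a repetition mean
#'
#' \eqn{E = t_{\alpha/2} S / \sqrt{n}}. By default the critical value is
#' rounded to 3 decimals before multiplying -- the convention under which
#' summary tables that print \eqn{t_{\alpha/2}} to three decimals are
#' reproduced digit-for-digit; pass \code{t_digits = NULL} for the
#' full-precision quantile.
#'
#' @param summary A [sample_summary()].
#' @param confidence Confidence level (default 0.95).
#' @param t_digits Decimals to which the critical value is rounded
#'   (default 3; \code{NULL} = no rounding).
#' @return The margin of error E (0 when S = 0).
#' @export
margin_of_error <- function(summary, confidence = 0.95, t_digits = 3L) {
  stopifnot(inherits(summary, "sample_summary"))
  tc <- t_critical(confidence, summary$n - 1L)
  if (!is.null(t_digits)) tc <- round(tc, t_digits)
  tc * summary$sd / sqrt(summary$n)
}

#' Student-t confidence interval for the population mean
#'
#' @inheritParams margin_of_error
#' @return An object of class \code{ci_report}: \code{confidence},
#'   \code{t_crit}, \code{margin}, \code{lower}, \code{upper}. Bounds are
#'   stored at full precision; the print method shows them to 2 decimals.
#' @examples
#' confidence_interval(sample_summary(64.33, sd = 1.98, n = 20))
#' @export
confidence_interval <- function(summary, confidence = 0.95, t_digits = 3L) {
  e <- margin_of_error(summary, confidence, t_digits)
  structure(list(confidence = confidence,
                 t_crit = t_critical(confidence, summary$n - 1L),
                 margin = e,
                 lower = summary$mean - e, upper = summary$mean + e),
            class = "ci_report")
}

#' @export
print.ci_report <- function(x, ...) {
  cat(sprintf("%.0f%% CI: %.2f < mu < %.2f  (E = %.6f)\n",
              100 * x$confidence, x$lower, x$upper, x$margin))
  invisible(x)
}

#' APA-style one-sample t-test statement
#'
#' Produces the reporting record for the test of \eqn{H_0: \mu =
#' \mu_0} at the given confidence level: the APA statement
#' \code{t(df) = <critical value>, p = .05} and the accept/reject decision
#' by confidence-interval duality. Testing against the sample mean itself
#' (the default) is trivially accepted; the record reproduces that
#' reporting convention without endorsing it as inference.
#'
#' @inheritParams margin_of_error
#' @param mu0 Hypothesized population mean (defaults to the sample mean).
#' @return A list of class \code{t_test_statement}: \code{statement},
#'   \code{df}, \code{t_crit}, \code{alpha}, \code{mu0}, \code{decision}
#'   (\code{"accept"} or \code{"reject"}).
#' @export
t_test_statement <- function(summary, confidence = 0.95,
                             mu0 = summary$mean, t_digits = 3L) {
  ci <- confidence_interval(summary, confidence, t_digits)
  alpha <- 1 - confidence
  df <- summary$n - 1L
  decision <- if (mu0 >= ci$lower && mu0 <= ci$upper) "accept" else "reject"
  statement <- sprintf("t(%d) = %.3f, p = %s", df, ci$t_crit,
                       sub("^0", "", sprintf("%.2f", alpha)))
  structure(list(statement = statement, df = df, t_crit = ci$t_crit,
                 alpha = alpha, mu0 = mu0, decision = decision),
            class = "t_test_statement")
}

#' @export
print.t_test_statement <- function(x, ...) {
  cat(x$statement, "->", x$decision, "H0\n")
  invisible(x)
}
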