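#' One-way random-effects analysis of variance
#'
#' Decomposes a balanced repeated-measures table into between-subject and
#' within-subject mean squares under the two-level random-effect model
#' \deqn{X_{ij} = \mu + b_i + e_{ij}, \quad b_i \sim N(0, \sigma_B^2),
#'   \ e_{ij} \sim N(0, \sigma_W^2).}
#' For a balanced design `MSB = k * var(row means)` and `MSW` is the mean
#' of the per-subject sample variances. The method-of-moments component
#' \eqn{\hat\sigma_B^2 = (MSB - MSW) / k} may be negative; it is reported
#' unclamped.
#'
#' @param data a [repeated_measures()] table (or matrix coercible to one).
#' @return an object of class `variance_components`: `ms_between`,
#'   `ms_within`, `sigma2_between`, `sigma2_within`, `df_between` (`n - 1`),
#'   `df_within` (`n (k - 1)`), plus `n` and `k`.
#' @seealso [icc_oneway()]
#' @export
anova_oneway <- function(data) {
  data <- as_repeated_measures(data)
  x <- data$values
  n <- data$n
  k <- data$k
  row_means <- rowMeans(x)
  ms_between <- k * stats::var(row_means)
  ms_within <- mean(apply(x, 1L, stats::var))
  structure(
    list(
      ms_between = ms_between,
      ms_within = ms_within,
      sigma2_between = (ms_between - ms_within) / k,
      sigma2_within = ms_within,
      df_between = n - 1L,
      df_within = n * (k - 1L),
      n = n, k = k
    ),
    class = "variance_components"
  )
}

#' One-way random-effects intraclass correlation coefficient
#'
#' Estimates the single-measurement, one-way random-effects ICC
#' \deqn{ICC = \sigma_B^2 / (\sigma_B^2 + \sigma_W^2)}
#' by the ANOVA estimator \eqn{(MSB - MSW) / (MSB + (k-1) MSW)} and tests
#' \eqn{H_0: ICC \le \rho_0} against \eqn{H_1: ICC > \rho_0} with the
#' F-statistic
#' \deqn{F = \frac{MSB}{MSW} \cdot \frac{1 - \rho_0}{1 + (k - 1)\rho_0}}
#' referred to an F distribution on \eqn{(n - 1, n(k - 1))} degrees of
#' freedom (one-sided upper tail). With `rho0 = 0` this is the classical
#' one-way ANOVA F-test. The default null `rho0 = 0.20` is the boundary
#' between "poor" and "fair" agreement on the benchmark scale, so a
#' significant result indicates at least fair agreement.
#'
#' The estimate can be negative in small samples with little between-subject
#' spread; it is reported unclamped (clamping would bias simulation
#' summaries) and [icc_benchmark()] maps any value at or below 0.20 to
#' `"poor"`.
#'
#' @param data a [repeated_measures()] table (or matrix coercible to one).
#' @param rho0 null ICC value in `[0, 1)`; default 0.20.
#' @return an object of class `icc_result`: `estimate`, `components`
#'   (a `variance_components`), `rho0`, `f_statistic`, `df1`, `df2`,
#'   `p_value`, `benchmark`, `n`, `k`.
#' @examples
#' x <- rbind(c(1, 3), c(2, 2), c(6, 4), c(5, 7))
#' icc_oneway(x, rho0 = 0.20)
#' @export
icc_oneway <- function(data, rho0 = 0.20) {
  data <- as_repeated_measures(data)
  if (!is.numeric(rho0) || length(rho0) != 1L || rho0 < 0 || rho0 >= 1) {
    stop_rhino("input", "`rho0` must be a single value in [0, 1)")
  }
  vc <- anova_oneway(data)
  n <- vc$n
  k <- vc$k
  if (vc$ms_within == 0 && vc$ms_between == 0) {
    stop_rhino("agreement_undefined",
               "all values identical: agreement is undefined (no variance at all)")
  }
  if (vc$ms_within == 0) {
    estimate <- 1
    f_statistic <- Inf
    p_value <- 0
  } else {
    estimate <- (vc$ms_between - vc$ms_within) /
      (vc$ms_between + (k - 1) * vc$ms_within)
    f_statistic <- (vc$ms_between / vc$ms_within) * (1 - rho0) / (1 + (k - 1) * rho0)
    p_value <- stats::pf(f_statistic, vc$df_between, vc$df_within, lower.tail = FALSE)
  }
  structure(
    list(
      estimate = estimate,
      components = vc,
      rho0 = rho0,
      f_statistic = f_statistic,
      df1 = vc$df_between,
      df2 = vc$df_within,
      p_value = p_value,
      benchmark = icc_benchmark(estimate),
      n = n, k = k
    ),
    class = "icc_result"
  )
}

#' Agreement benchmark for an ICC value
#'
#' The conventional qualitative scale: at or below 0.20 "poor", (0.20, 0.40]
#' "fair", (0.40, 0.60] "moderate", (0.60, 0.80] "substantial", above 0.80
#' "excellent". Intervals are half-open on the left so every value (including
#' negative estimates, which fall in "poor") receives exactly one label.
#'
#' @param icc numeric vector of ICC values, each `<= 1` (negative allowed).
#' @return character vector of labels.
#' @examples
#' icc_benchmark(c(-0.05, 0.15, 0.35, 0.81))
#' @export
icc_benchmark <- function(icc) {
  if (!is.numeric(icc) || any(icc > 1 + 1e-12, na.rm = TRUE)) {
    stop_rhino("input", "ICC values must be <= 1")
  }
  labels <- c("poor", "fair", "moderate", "substantial", "excellent")
  idx <- ifelse(icc <= 0.20, 1L,
         ifelse(icc <= 0.40, 2L,
         ifelse(icc <= 0.60, 3L,
         ifelse(icc <= 0.80, 4L, 5L))))
  labels[idx]
}

#' @export
print.icc_result <- function(x, digits = 3, ...) {
  cat(sprintf("One-way random-effects ICC (n = %d subjects, k = %d replicates)\n",
              x$n, x$k))
  cat(sprintf("  estimate = %.*f  (%s agreement)\n", digits, x$estimate, x$benchmark))
  cat(sprintf("  H0: ICC <= %.2f   F(%d, %d) = %.*f,  p = %.4g\n",
              x$rho0, x$df1, x$df2, digits, x$f_statistic, x$p_value))
  invisible(x)
}

#' @export
print.variance_components <- function(x, digits = 4, ...) {
  cat(sprintf("One-way ANOVA components (n = %d, k = %d)\n", x$n, x$k))
  cat(sprintf("  MSB = %.*g (df %d), MSW = %.*g (df %d)\n",
              digits, x$ms_between, x$df_between, digits, x$ms_within, x$df_within))
  cat(sprintf("  sigma2_between = %.*g, sigma2_within = %.*g\n",
              digits, x$sigma2_between, digits, x$sigma2_within))
  invisible(x)
}
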