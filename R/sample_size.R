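#' Sample size for testing an ICC against a null value (Zou's method)
#'
#' Number of subjects per group needed to reject \eqn{H_0: ICC \le \rho_0}
#' in favour of \eqn{H_1: ICC > \rho_0} when the true ICC is `rho1`, with
#' `k` replicates per subject, based on the asymptotic normality of the
#' log-transformed F ratio. The raw solution is
#' \deqn{n = 1 + \frac{2 k (z_{1-\alpha/\mathrm{tails}} + z_{\mathrm{power}})^2}
#'   {(k - 1)\,[\ln(C_1 / C_0)]^2}, \qquad
#'   C(\rho) = \frac{1 + (k - 1)\rho}{1 - \rho},}
#' and the returned `n` is its ceiling (never rounded down: the design must
#' reach, not approximate, the nominal power).
#'
#' `tails` is exposed explicitly because published designs use both
#' conventions: with five replicates, expected ICC 0.70 against null 0.20,
#' alpha 0.05 and power 0.90 the two-sided computation gives 10 subjects
#' per group, while the same design with two replicates gives 21 under the
#' one-sided critical value.
#'
#' @param rho1 expected (alternative) ICC, `rho0 < rho1 < 1`.
#' @param rho0 null ICC; default 0.20 (the poor/fair boundary).
#' @param k replicates per subject, integer >= 2.
#' @param alpha significance level in (0, 1); default 0.05.
#' @param power target power in (0, 1); default 0.90.
#' @param tails 1 or 2; critical value is `z[1 - alpha/tails]`. Default 2.
#' @return an object of class `sample_size_result`: `n` (integer subjects
#'   per group), `n_raw` (pre-ceiling solution), `request` (echoed inputs).
#' @examples
#' icc_sample_size(rho1 = 0.70, rho0 = 0.20, k = 5)           # 10
#' icc_sample_size(rho1 = 0.70, rho0 = 0.20, k = 2, tails = 1) # 21
#' @export
icc_sample_size <- function(rho1, rho0 = 0.20, k = 5, alpha = 0.05,
                            power = 0.90, tails = 2) {
  if (!tails %in% c(1, 2)) stop_rhino("input", "`tails` must be 1 or 2")
  if (k < 2) stop_rhino("design", "need k >= 2 replicates per subject")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop_rhino("input", "`alpha` and `power` must lie in (0, 1)")
  }
  if (rho0 < 0 || rho1 >= 1 || rho1 <= rho0) {
    stop_rhino("infeasible_design",
               "need 0 <= rho0 < rho1 < 1, got rho0 = %g, rho1 = %g", rho0, rho1)
  }
  Cfun <- function(rho) (1 + (k - 1) * rho) / (1 - rho)
  z <- stats::qnorm(1 - alpha / tails) + stats::qnorm(power)
  n_raw <- 1 + 2 * k * z^2 / ((k - 1) * log(Cfun(rho1) / Cfun(rho0))^2)
  new_sample_size_result(
    n_raw,
    request = list(rho1 = rho1, rho0 = rho0, k = k, alpha = alpha,
                   power = power, tails = tails),
    method = "icc_zou"
  )
}

#' Sample size for a Bland-Altman agreement study
#'
#' Number of paired differences needed so that, with probability `power`,
#' both estimated 95% limits of agreement together with their one-sided
#' `1 - alpha` confidence bounds fall inside the clinically acceptable
#' region `[-max_allowed_diff, +max_allowed_diff]`. Differences are assumed
#' normal with mean `mean_diff` and standard deviation `sd_diff`; the
#' standard error of an estimated limit \eqn{\bar d \pm 1.96 s} is
#' \eqn{s \sqrt{1/n + 1.96^2 / (2(n-1))}}.
#'
#' The power at a given `n` is computed by exact numerical integration over
#' the joint distribution of the sample mean (normal) and sample SD
#' (scaled chi) of the differences, and the returned `n` is the smallest
#' integer whose power reaches the target; `n_raw` is the continuous
#' solution. No closed-form approximation is used, so a simulation of the
#' same acceptance rule reproduces the nominal power directly.
#'
#' @param mean_diff expected mean of the paired differences.
#' @param sd_diff expected standard deviation of the differences (> 0).
#' @param max_allowed_diff maximum clinically acceptable absolute
#'   difference (> 0); the agreement region is symmetric about zero.
#' @param alpha one-sided level for the confidence bounds on each limit;
#'   default 0.05.
#' @param power target probability that both bounded limits fall inside
#'   the region; default 0.80.
#' @return an object of class `sample_size_result` (see
#'   [icc_sample_size()]), with `power_at_n` attached in `request`.
#' @examples
#' ba_sample_size(mean_diff = 0.20, sd_diff = 0.10, max_allowed_diff = 0.50)
#' @export
ba_sample_size <- function(mean_diff, sd_diff, max_allowed_diff,
                           alpha = 0.05, power = 0.80) {
  if (sd_diff <= 0 || max_allowed_diff <= 0) {
    stop_rhino("input", "`sd_diff` and `max_allowed_diff` must be positive")
  }
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop_rhino("input", "`alpha` and `power` must lie in (0, 1)")
  }
  if (abs(mean_diff) + 1.96 * sd_diff >= max_allowed_diff) {
    stop_rhino("infeasible_agreement",
               "|mean_diff| + 1.96 sd_diff = %.4g >= max_allowed_diff = %.4g: no sample size can demonstrate agreement",
               abs(mean_diff) + 1.96 * sd_diff, max_allowed_diff)
  }
  f <- function(n) {
    ba_agreement_power(n, mean_diff, sd_diff, max_allowed_diff, alpha) - power
  }
  lo <- 3
  hi <- 8
  while (f(hi) < 0 && hi < 1e7) hi <- hi * 2
  if (f(hi) < 0) stop_rhino("infeasible_agreement", "required sample size exceeds 1e7")
  n_raw <- if (f(lo) >= 0) lo else stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
  n <- ceiling(n_raw)
  # guard against roundoff at the integer boundary
  while (ba_agreement_power(n, mean_diff, sd_diff, max_allowed_diff, alpha) < power) {
    n <- n + 1
  }
  new_sample_size_result(
    n_raw, n = n,
    request = list(mean_diff = mean_diff, sd_diff = sd_diff,
                   max_allowed_diff = max_allowed_diff, alpha = alpha,
                   power = power,
                   power_at_n = ba_agreement_power(n, mean_diff, sd_diff,
                                                   max_allowed_diff, alpha)),
    method = "bland_altman_agreement"
  )
}

#' Exact power of the Bland-Altman agreement rule
#'
#' Probability, at sample size `n`, that both 95% limits of agreement with
#' their one-sided `1 - alpha` confidence bounds fall inside
#' `[-delta, delta]`, for normally distributed differences. Integrates over
#' the chi-square distribution of the sample variance; `n` may be
#' non-integer (continuous degrees of freedom), which the sample-size
#' search exploits.
#'
#' @param n sample size (>= 3; may be fractional).
#' @param mean_diff,sd_diff true mean and SD of the differences.
#' @param delta half-width of the symmetric agreement region.
#' @param alpha one-sided level of the confidence bounds.
#' @return the power, a probability.
#' @keywords internal
#' @export
ba_agreement_power <- function(n, mean_diff, sd_diff, delta, alpha = 0.05) {
  df <- n - 1
  z_a <- stats::qnorm(1 - alpha)
  se_mult <- sqrt(1 / n + 1.96^2 / (2 * df))
  integrand <- function(q) {
    s <- sd_diff * sqrt(q / df)
    margin <- delta - (1.96 + z_a * se_mult) * s
    p <- stats::pnorm((margin - mean_diff) / (sd_diff / sqrt(n))) -
      stats::pnorm((-margin - mean_diff) / (sd_diff / sqrt(n)))
    stats::dchisq(q, df) * pmax(p, 0)
  }
  stats::integrate(integrand, 0, stats::qchisq(1 - 1e-10, df),
                   rel.tol = 1e-8)$value
}

new_sample_size_result <- function(n_raw, request, method, n = ceiling(n_raw)) {
  structure(
    list(n = as.integer(n), n_raw = n_raw, request = request, method = method),
    class = "sample_size_result"
  )
}

#' @export
print.sample_size_result <- function(x, ...) {
  cat(sprintf("Required sample size: %d subjects (raw %.4f; method %s)\n",
              x$n, x$n_raw, x$method))
  invisible(x)
}
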