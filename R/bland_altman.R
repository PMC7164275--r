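#' Bland-Altman agreement between two measurement occasions
#'
#' Computes pairwise differences (`first - second`; in the study pipeline
#' the first occasion is day 1, so a positive bias means the later value
#' decreased) against pairwise means, the mean difference (bias), and
#' limits of agreement. The default nonparametric limits are the 5th and
#' 95th percentiles of the differences, recommended when differences are
#' not normally distributed; the parametric mode gives the classical
#' `bias +/- 1.96 SD` limits. Percentiles use the package-wide convention
#' described at [rhino_quantile()].
#'
#' Heteroscedasticity — the size of the difference growing with the size of
#' the measurement — is commonly judged visually; as a numeric companion
#' the Spearman rank correlation between `|difference|` and the pairwise
#' mean is reported (two-sided test), so pipelines can auto-recommend a
#' log transformation when it is significant. With `log_scale = TRUE` the
#' analysis is performed on log-transformed values (all inputs must then
#' be positive) and differences are log-ratios.
#'
#' @param first,second numeric vectors of equal length >= 3, paired
#'   measurements on the two occasions.
#' @param mode `"nonparametric"` (percentile limits, default) or
#'   `"parametric"` (`bias +/- 1.96 SD`).
#' @param log_scale analyse on the natural-log scale; requires positive
#'   values.
#' @param loa_probs percentile pair for the nonparametric limits; default
#'   `c(0.05, 0.95)`.
#' @return an object of class `paired_agreement`: `differences`, `means`,
#'   `bias`, `loa_lower`, `loa_upper`, `mode`, `log_transformed`,
#'   `hetero_rho`, `hetero_p`, `n`.
#' @examples
#' set.seed(1)
#' a <- rlnorm(30); b <- a * rlnorm(30, 0, 0.1)
#' bland_altman(a, b)
#' @export
bland_altman <- function(first, second,
                         mode = c("nonparametric", "parametric"),
                         log_scale = FALSE,
                         loa_probs = c(0.05, 0.95)) {
  mode <- match.arg(mode)
  if (length(first) != length(second)) {
    stop_rhino("input", "`first` and `second` must have equal length (%d vs %d)",
               length(first), length(second))
  }
  if (length(first) < 3L) {
    stop_rhino("design", "need at least 3 pairs, got %d", length(first))
  }
  if (anyNA(first) || anyNA(second)) {
    stop_rhino("input", "missing values are not allowed")
  }
  if (log_scale) {
    if (any(first <= 0) || any(second <= 0)) {
      stop_rhino("positivity", "log-scale analysis requires strictly positive values")
    }
    first <- log(first)
    second <- log(second)
  }
  d <- first - second
  m <- (first + second) / 2
  bias <- mean(d)
  if (mode == "nonparametric") {
    loa <- rhino_quantile(d, loa_probs)
  } else {
    loa <- bias + c(-1.96, 1.96) * stats::sd(d)
  }
  ad <- abs(d)
  if (stats::sd(ad) == 0 || stats::sd(m) == 0) {
    # constant |differences| or means: no trend is detectable
    hetero_rho <- 0
    hetero_p <- 1
  } else {
    ct <- suppressWarnings(
      stats::cor.test(ad, m, method = "spearman", exact = FALSE)
    )
    hetero_rho <- unname(ct$estimate)
    hetero_p <- ct$p.value
  }
  structure(
    list(
      differences = d, means = m, bias = bias,
      loa_lower = loa[1], loa_upper = loa[2],
      mode = mode, log_transformed = log_scale,
      hetero_rho = hetero_rho, hetero_p = hetero_p,
      n = length(d)
    ),
    class = "paired_agreement"
  )
}

#' @export
print.paired_agreement <- function(x, digits = 3, ...) {
  cat(sprintf("Bland-Altman agreement (%s%s, %d pairs)\n",
              x$mode, if (x$log_transformed) ", log scale" else "", x$n))
  cat(sprintf("  bias = %.*f, limits of agreement [%.*f, %.*f]\n",
              digits, x$bias, digits, x$loa_lower, digits, x$loa_upper))
  cat(sprintf("  heteroscedasticity: Spearman rho = %.*f, p = %.4g\n",
              digits, x$hetero_rho, x$hetero_p))
  invisible(x)
}
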