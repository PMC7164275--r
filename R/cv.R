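#' Coefficient of variation of one subject's replicates
#'
#' `CV_i = s_i / m_i`: the sample standard deviation (denominator
#' `length - 1`) of a subject's replicate measurements divided by their
#' sample mean. The CV is meaningful only on a ratio scale; the
#' measurements entering it must be positive, so a nonpositive sample mean
#' is an error rather than a sign flip.
#'
#' @param values numeric vector of length >= 2, one subject's replicates.
#' @return the dimensionless CV.
#' @examples
#' cv_per_subject(c(8, 12)) # 0.2828...
#' @export
cv_per_subject <- function(values) {
  if (!is.numeric(values) || length(values) < 2L) {
    stop_rhino("design", "need at least 2 replicate values")
  }
  if (anyNA(values)) {
    stop_rhino("input", "missing values are not allowed")
  }
  m <- mean(values)
  if (m <= 0) {
    stop_rhino("positivity",
               "sample mean is %.4g; CV requires positive measurements on a ratio scale", m)
  }
  stats::sd(values) / m
}

#' Mean per-subject coefficient of variation
#'
#' Computes `CV_i` row-wise over a repeated-measures table and averages
#' across subjects. The conventional acceptability threshold is a mean CV
#' strictly below 15%; a mean CV of exactly 0.15 is therefore not
#' acceptable.
#'
#' @param data a [repeated_measures()] table (or matrix coercible to one).
#' @param threshold acceptability cut-off on the mean CV; default 0.15.
#' @return an object of class `cv_result`: `per_subject` (named by subject
#'   id), `mean_cv`, `threshold`, `acceptable` (`mean_cv < threshold`).
#' @export
cv_mean <- function(data, threshold = 0.15) {
  data <- as_repeated_measures(data)
  per <- vapply(seq_len(data$n), function(i) {
    tryCatch(
      cv_per_subject(data$values[i, ]),
      rhinorep_error_positivity = function(e) {
        stop_rhino("positivity", "subject %s: %s", data$subject_ids[i], conditionMessage(e))
      }
    )
  }, numeric(1))
  names(per) <- data$subject_ids
  mean_cv <- mean(per)
  structure(
    list(per_subject = per, mean_cv = mean_cv, threshold = threshold,
         acceptable = mean_cv < threshold),
    class = "cv_result"
  )
}

#' Pooled coefficient of variation
#'
#' The sample standard deviation of all `n * k` values in the table divided
#' by their grand mean, ignoring the subject structure. This is the variant
#' the Monte-Carlo engine reports for the mixed-model batch (see
#' [simulate_batch2()]); unlike the mean per-subject CV it also absorbs
#' between-subject spread.
#'
#' @param data a [repeated_measures()] table (or matrix coercible to one).
#' @return the dimensionless pooled CV.
#' @export
cv_pooled <- function(data) {
  data <- as_repeated_measures(data)
  v <- as.vector(data$values)
  m <- mean(v)
  if (m <= 0) {
    stop_rhino("positivity",
               "grand mean is %.4g; CV requires positive measurements on a ratio scale", m)
  }
  stats::sd(v) / m
}

#' @export
print.cv_result <- function(x, digits = 3, ...) {
  cat(sprintf("Mean per-subject CV over %d subjects: %.*f (%sacceptable at < %.2f)\n",
              length(x$per_subject), digits, x$mean_cv,
              if (x$acceptable) "" else "not ", x$threshold))
  invisible(x)
}
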