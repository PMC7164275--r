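#' Repeated-measures table
#'
#' The unit of all ICC and CV computation: a complete rectangular table of
#' `n` subjects (rows) by `k` replicate measurements (columns). For the
#' one-way random-effects analysis the column order carries no meaning;
#' replicates are exchangeable within a subject.
#'
#' Missing values are rejected, never imputed: drop incomplete subjects
#' before constructing the table.
#'
#' @param values numeric matrix (or object coercible to one) with `n >= 2`
#'   rows and `k >= 2` columns and no missing entries. Units are whatever
#'   the measurement carries (Pa.s/cm3 for nasal resistances).
#' @param subject_ids optional character vector of length `n`; defaults to
#'   row names or `S1..Sn`.
#' @return an object of class `repeated_measures` with elements `values`
#'   (numeric matrix), `subject_ids`, `n`, `k`.
#' @examples
#' rm <- repeated_measures(rbind(c(1, 3), c(2, 2), c(6, 4), c(5, 7)))
#' icc_oneway(rm)
#' @export
repeated_measures <- function(values, subject_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop_rhino("input", "`values` must be a numeric matrix")
  }
  n <- nrow(values)
  k <- ncol(values)
  if (n < 2L || k < 2L) {
    stop_rhino("design", "need at least 2 subjects and 2 replicates, got %d x %d", n, k)
  }
  if (anyNA(values)) {
    stop_rhino("input", "missing values are not allowed; drop incomplete subjects first")
  }
  if (is.null(subject_ids)) {
    subject_ids <- rownames(values) %||% paste0("S", seq_len(n))
  }
  if (length(subject_ids) != n) {
    stop_rhino("input", "`subject_ids` must have length %d", n)
  }
  dimnames(values) <- NULL
  structure(
    list(values = values, subject_ids = as.character(subject_ids), n = n, k = k),
    class = "repeated_measures"
  )
}

as_repeated_measures <- function(x) {
  if (inherits(x, "repeated_measures")) x else repeated_measures(x)
}

#' @export
print.repeated_measures <- function(x, ...) {
  cat(sprintf("<repeated_measures: %d subjects x %d replicates>\n", x$n, x$k))
  invisible(x)
}
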