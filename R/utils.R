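# Classed conditions so callers (and the CLI) can react to specific failures
# without string-matching messages.
stop_rhino <- function(code, message, ...) {
  stop(structure(
    class = c(paste0("rhinorep_error_", code), "rhinorep_error", "error", "condition"),
    list(message = sprintf(message, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quantile convention used throughout the package
#'
#' Percentile `p` of `m` sorted values is taken at rank `1 + p * (m - 1)`
#' with linear interpolation between order statistics (the default
#' continuous-quantile definition, [stats::quantile()] type 7). A single
#' declared convention keeps Bland-Altman limits exactly reproducible.
#'
#' @param x numeric vector.
#' @param probs probabilities in `[0, 1]`.
#' @return numeric vector of quantiles.
#' @keywords internal
rhino_quantile <- function(x, probs) {
  unname(stats::quantile(x, probs = probs, type = 7, names = FALSE))
}

# Derive a per-cell seed from a root seed by a fixed counter scheme:
# seed_i = (root + 7919 * i) mod (2^31 - 1). Cell i always receives the same
# substream regardless of which other cells run, so grids are reproducible
# under partial execution.
cell_seed <- function(root_seed, i) {
  as.integer((as.numeric(root_seed) + 7919 * as.numeric(i)) %% 2147483647)
}
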