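#' Configuration for the fixed-CV simulation batch
#'
#' First Monte-Carlo batch: data are generated under a *CV-truth* model and
#' the ICC is estimated. Each of `n_subjects` subjects has a fixed mean
#' `mu_i` taken from `mu_grid` (equally spaced 5 to 8 by default — the
#' between-subject spread is deterministic, not redrawn per replicate),
#' and `k_replicates` values are drawn from `Normal(mu_i, mu_i * CV)` for
#' each true CV on `cv_grid`.
#'
#' @param n_subjects subjects per replicate dataset; default 10.
#' @param k_replicates measurements per subject; default 5.
#' @param mu_grid fixed subject means, length `n_subjects`, all positive;
#'   default 10 equally spaced values from 5 to 8.
#' @param cv_grid true CV values in (0, 1); default 50 equally spaced
#'   values from 0.01 to 0.99 (step 0.02).
#' @param replicates Monte-Carlo replicates per CV value; default 1000.
#' @param seed root seed; per-cell substreams are derived from it (see
#'   Details in [simulate_batch1()]).
#' @return a `batch1_config` list.
#' @export
batch1_config <- function(n_subjects = 10, k_replicates = 5,
                          mu_grid = seq(5, 8, length.out = n_subjects),
                          cv_grid = seq(0.01, 0.99, length.out = 50),
                          replicates = 1000, seed = 1) {
  if (length(mu_grid) != n_subjects) {
    stop_rhino("config", "`mu_grid` must have length n_subjects = %d", n_subjects)
  }
  if (any(mu_grid <= 0)) stop_rhino("config", "all `mu_grid` values must be positive")
  if (any(cv_grid <= 0 | cv_grid >= 1)) {
    stop_rhino("config", "all `cv_grid` values must lie in (0, 1)")
  }
  if (n_subjects < 2 || k_replicates < 2 || replicates < 1) {
    stop_rhino("config", "need n_subjects >= 2, k_replicates >= 2, replicates >= 1")
  }
  structure(
    list(n_subjects = n_subjects, k_replicates = as.integer(k_replicates),
         mu_grid = mu_grid, cv_grid = cv_grid,
         replicates = as.integer(replicates), seed = as.integer(seed)),
    class = "batch1_config"
  )
}

#' Configuration for the mixed-model simulation batch
#'
#' Second Monte-Carlo batch: data are generated under an *ICC-truth*
#' two-level model and the CV is estimated. For each combination of
#' overall mean `gamma`, between-subject SD `sigma_b` and true ICC, the
#' within-subject SD is derived as
#' `sigma_w = sigma_b * sqrt((1 - ICC) / ICC)` (see [derive_sigma_w()]);
#' subject means are drawn `Normal(gamma, sigma_b)` and replicates
#' `Normal(mu_i, sigma_w)`. Negative draws at small `gamma` are kept as-is:
#' the CV ratio estimator is heavy-tailed there by design.
#'
#' @param n_subjects subjects; default 10.
#' @param k_replicates measurements per subject; default 5.
#' @param gamma_grid overall means; default 1..10.
#' @param sigma_b_grid between-subject SDs; default `c(1, 2, 3)`
#'   (variances 1, 4, 9).
#' @param icc_grid true ICC values in (0, 1); default 0.10..0.90 by 0.10.
#' @param replicates Monte-Carlo replicates per cell; default 1000.
#' @param seed root seed.
#' @return a `batch2_config` list.
#' @export
batch2_config <- function(n_subjects = 10, k_replicates = 5,
                          gamma_grid = 1:10, sigma_b_grid = c(1, 2, 3),
                          icc_grid = seq(0.1, 0.9, by = 0.1),
                          replicates = 1000, seed = 1) {
  if (any(icc_grid <= 0 | icc_grid >= 1)) {
    stop_rhino("config", "all `icc_grid` values must lie in (0, 1)")
  }
  if (any(sigma_b_grid <= 0)) stop_rhino("config", "all `sigma_b_grid` values must be positive")
  if (n_subjects < 2 || k_replicates < 2 || replicates < 1) {
    stop_rhino("config", "need n_subjects >= 2, k_replicates >= 2, replicates >= 1")
  }
  structure(
    list(n_subjects = n_subjects, k_replicates = as.integer(k_replicates),
         gamma_grid = gamma_grid, sigma_b_grid = sigma_b_grid,
         icc_grid = icc_grid, replicates = as.integer(replicates),
         seed = as.integer(seed)),
    class = "batch2_config"
  )
}

#' Within-subject SD implied by a target ICC
#'
#' Inverts `ICC = sigma_b^2 / (sigma_b^2 + sigma_w^2)`:
#' `sigma_w = sigma_b * sqrt((1 - icc) / icc)`. Round-trips exactly:
#' `sigma_b^2 / (sigma_b^2 + derive_sigma_w(sigma_b, icc)^2)` recovers
#' `icc` to machine precision.
#'
#' @param sigma_b between-subject SD (> 0); vectorised.
#' @param icc target ICC in (0, 1); vectorised.
#' @return the within-subject SD.
#' @examples
#' derive_sigma_w(1, 0.10) # 3
#' derive_sigma_w(3, 0.40) # 3.674...
#' @export
derive_sigma_w <- function(sigma_b, icc) {
  if (any(icc <= 0 | icc >= 1)) stop_rhino("input", "`icc` must lie strictly in (0, 1)")
  if (any(sigma_b <= 0)) stop_rhino("input", "`sigma_b` must be positive")
  sigma_b * sqrt((1 - icc) / icc)
}

# Vectorised one-way ICC estimates for `reps` stacked n x k datasets held in
# an n x k x reps array. Equals icc_oneway()$estimate column by column.
icc_estimates_array <- function(a) {
  n <- dim(a)[1]; k <- dim(a)[2]
  b <- aperm(a, c(2, 1, 3))                 # k x n x reps
  sm <- colMeans(b, dims = 1)               # n x reps subject means
  sm2 <- colMeans(b^2, dims = 1)
  within_var <- (sm2 - sm^2) * k / (k - 1)  # per-subject sample variances
  msw <- colMeans(within_var)
  grand <- colMeans(sm)
  msb <- k * colSums(sweep(sm, 2, grand)^2) / (n - 1)
  (msb - msw) / (msb + (k - 1) * msw)
}

#' Run the fixed-CV batch (ICC estimated under a CV-truth model)
#'
#' For each true CV on the grid, `replicates` datasets are generated from
#' the fixed-mean normal model of [batch1_config()] and the one-way ICC
#' estimate of each is recorded (negative estimates enter the mean
#' unclamped). Randomness is fully determined by the root seed: cell `i`
#' of the grid uses the substream seed `(seed + 7919 * i) mod (2^31 - 1)`,
#' so any subset of cells reproduces identically.
#'
#' @param cfg a [batch1_config()].
#' @return a `simulation_grid` object: data frame `cells` with columns
#'   `true_cv`, `mean_index`, `mc_se` (SD of per-replicate estimates over
#'   `sqrt(replicates)`), `n_replicates`; `index_name = "estimated_icc"`.
#' @export
simulate_batch1 <- function(cfg = batch1_config()) {
  stopifnot(inherits(cfg, "batch1_config"))
  n <- cfg$n_subjects; k <- cfg$k_replicates; reps <- cfg$replicates
  cells <- lapply(seq_along(cfg$cv_grid), function(i) {
    cv <- cfg$cv_grid[i]
    set.seed(cell_seed(cfg$seed, i))
    a <- array(stats::rnorm(n * k * reps, mean = cfg$mu_grid,
                            sd = cfg$mu_grid * cv),
               dim = c(n, k, reps))
    est <- icc_estimates_array(a)
    data.frame(true_cv = cv, mean_index = mean(est),
               mc_se = stats::sd(est) / sqrt(reps), n_replicates = reps)
  })
  new_simulation_grid(do.call(rbind, cells), "estimated_icc", cfg)
}

#' Run the mixed-model batch (CV estimated under an ICC-truth model)
#'
#' For each `(gamma, sigma_b, icc)` cell, `replicates` datasets are
#' generated from the two-level model of [batch2_config()] and the CV of
#' each is recorded. The default estimator is the pooled CV (sample SD of
#' all `n * k` values over their grand mean), whose large-`gamma`
#' expectation is `sqrt(sigma_b^2 + sigma_w^2) / gamma` by the delta
#' method; `estimator = "per_subject"` averages per-subject CVs instead
#' (a sensitivity mode — it excludes between-subject spread and gives
#' systematically smaller values). Seeding follows the same per-cell
#' substream scheme as [simulate_batch1()], with cells enumerated in
#' `expand.grid(gamma, sigma_b, icc)` order.
#'
#' @param cfg a [batch2_config()].
#' @param estimator `"pooled"` (default) or `"per_subject"`.
#' @return a `simulation_grid` object: data frame `cells` with columns
#'   `gamma`, `sigma_b`, `icc`, `sigma_w`, `mean_index`, `mc_se`,
#'   `n_replicates`; `index_name = "estimated_cv"`.
#' @export
simulate_batch2 <- function(cfg = batch2_config(),
                            estimator = c("pooled", "per_subject")) {
  stopifnot(inherits(cfg, "batch2_config"))
  estimator <- match.arg(estimator)
  n <- cfg$n_subjects; k <- cfg$k_replicates; reps <- cfg$replicates
  grid <- expand.grid(gamma = cfg$gamma_grid, sigma_b = cfg$sigma_b_grid,
                      icc = cfg$icc_grid, KEEP.OUT.ATTRS = FALSE)
  grid$sigma_w <- derive_sigma_w(grid$sigma_b, grid$icc)
  cells <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    set.seed(cell_seed(cfg$seed, i))
    mu <- matrix(stats::rnorm(n * reps, mean = g$gamma, sd = g$sigma_b), n, reps)
    noise <- array(stats::rnorm(n * k * reps, sd = g$sigma_w), dim = c(n, k, reps))
    # broadcast subject means (n x reps) along the replicate-measurement axis
    a <- noise + aperm(array(mu, dim = c(n, reps, k)), c(1, 3, 2))
    if (estimator == "pooled") {
      flat <- matrix(a, n * k, reps)
      m <- colMeans(flat)
      s <- sqrt(colSums(sweep(flat, 2, m)^2) / (n * k - 1))
      est <- s / m
    } else {
      b <- aperm(a, c(2, 1, 3))
      sm <- colMeans(b, dims = 1)
      sm2 <- colMeans(b^2, dims = 1)
      sv <- sqrt(pmax((sm2 - sm^2) * k / (k - 1), 0))
      est <- colMeans(sv / sm)
    }
    data.frame(g, mean_index = mean(est), mc_se = stats::sd(est) / sqrt(reps),
               n_replicates = reps, row.names = NULL)
  })
  out <- new_simulation_grid(do.call(rbind, cells), "estimated_cv", cfg)
  out$estimator <- estimator
  out
}

new_simulation_grid <- function(cells, index_name, config) {
  rownames(cells) <- NULL
  structure(list(cells = cells, index_name = index_name, config = config),
            class = "simulation_grid")
}

#' @export
print.simulation_grid <- function(x, ...) {
  cat(sprintf("<simulation_grid: %s, %d cells, %d replicates each>\n",
              x$index_name, nrow(x$cells), x$cells$n_replicates[1]))
  invisible(x)
}

#' Export a simulation grid as a publication-shaped table
#'
#' `"icc_curve"` (fixed-CV batch only) returns two columns: the true CV
#' and the mean estimated ICC. `"cv_wide"` (mixed-model batch only)
#' returns one row per `(sigma_b, sigma_w, icc)` with one mean-CV column
#' per overall mean `gamma`.
#'
#' @param grid a `simulation_grid` from [simulate_batch1()] or
#'   [simulate_batch2()].
#' @param layout `"icc_curve"` or `"cv_wide"`.
#' @return a data frame.
#' @export
grid_to_table <- function(grid, layout = c("icc_curve", "cv_wide")) {
  layout <- match.arg(layout)
  if (!inherits(grid, "simulation_grid") || nrow(grid$cells) == 0) {
    stop_rhino("structure", "`grid` must be a non-empty simulation_grid")
  }
  if (layout == "icc_curve") {
    if (grid$index_name != "estimated_icc") {
      stop_rhino("structure", "icc_curve layout requires an estimated_icc grid")
    }
    data.frame(true_cv = grid$cells$true_cv, mean_icc = grid$cells$mean_index)
  } else {
    if (grid$index_name != "estimated_cv") {
      stop_rhino("structure", "cv_wide layout requires an estimated_cv grid")
    }
    cells <- grid$cells
    keys <- unique(cells[order(cells$sigma_b, cells$icc), c("sigma_b", "sigma_w", "icc")])
    gammas <- sort(unique(cells$gamma))
    wide <- keys
    for (g in gammas) {
      col <- vapply(seq_len(nrow(keys)), function(j) {
        cells$mean_index[cells$sigma_b == keys$sigma_b[j] &
                           cells$icc == keys$icc[j] & cells$gamma == g]
      }, numeric(1))
      wide[[sprintf("mu_%g", g)]] <- col
    }
    rownames(wide) <- NULL
    wide
  }
}
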