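#' Extract a subjects-by-replicates matrix of baseline measurements
#'
#' Pulls the visit-1 (day 0) replicates for one group / parameter / phase /
#' side combination from a study dataset into a complete
#' subjects x replicates matrix. `phase = "combined"` with `side = "TOT"`
#' returns the combined total: total inspiratory plus total expiratory,
#' summed replicate-wise (the resistance totals are additive). Subjects
#' with incomplete replicate sets are dropped; the number dropped is
#' attached as attribute `"n_dropped"`.
#'
#' @param data a `study_dataset`.
#' @param group,parameter,phase,side key of the sub-table; `side` one of
#'   `"R"`, `"L"`, `"TOT"`.
#' @return numeric matrix with subject ids as row names.
#' @keywords internal
#' @export
visit1_matrix <- function(data, group, parameter, phase, side = "TOT") {
  if (phase == "combined") {
    a <- visit1_matrix(data, group, parameter, "inspiratory", "TOT")
    b <- visit1_matrix(data, group, parameter, "expiratory", "TOT")
    common <- intersect(rownames(a), rownames(b))
    out <- a[common, , drop = FALSE] + b[common, , drop = FALSE]
    attr(out, "n_dropped") <- attr(a, "n_dropped") + attr(b, "n_dropped")
    return(out)
  }
  m <- data$measurements
  sel <- m$day == 0 & m$group == group & m$parameter == parameter &
    m$phase == phase & m$side == side
  sub <- m[sel, ]
  if (nrow(sub) == 0) {
    stop_rhino("structure", "no baseline rows for (%s, %s, %s, %s)",
               group, parameter, phase, side)
  }
  tab <- tapply(sub$value, list(sub$subject_id, sub$replicate), mean)
  complete <- stats::complete.cases(tab)
  out <- tab[complete, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!complete)
  out
}

# Combined-total value per subject at a follow-up day (single replicate).
followup_combined <- function(data, group, parameter, day) {
  m <- data$measurements
  sel <- m$day == day & m$group == group & m$parameter == parameter &
    m$side == "TOT"
  sub <- m[sel, ]
  tab <- tapply(sub$value, list(sub$subject_id, sub$phase), mean)
  rowSums(tab) # inspiratory + expiratory; NA if either missing
}

#' Within-day repeatability table (ICC and CV per group and parameter)
#'
#' For every combination of group, parameter, phase (inspiratory,
#' expiratory, and the combined total) and side (R, L, TOT; combined rows
#' use TOT only), builds the baseline repeated-measures table and applies
#' [icc_oneway()] (testing `H0: ICC <= rho0`) and [cv_mean()]. All numbers
#' are produced by those two functions on the extracted sub-table — the
#' pipeline performs no arithmetic of its own. Groups whose values violate
#' CV positivity (possible under the normal noise family) get `NA` CV
#' columns.
#'
#' @param data a `study_dataset`.
#' @param rho0 null ICC for the significance test; default 0.20.
#' @return a data frame of class `repeatability_table`: one row per key
#'   with `n_subjects`, `icc`, `icc_f`, `icc_p`, `benchmark`, `mean_cv`,
#'   `cv_acceptable`.
#' @export
within_day_repeatability <- function(data, rho0 = 0.20) {
  stopifnot(inherits(data, "study_dataset"))
  groups <- unique(data$measurements$group)
  keys <- rbind(
    expand.grid(group = groups, parameter = aar_parameters,
                phase = aar_phases, side = c("R", "L", "TOT"),
                stringsAsFactors = FALSE),
    expand.grid(group = groups, parameter = aar_parameters,
                phase = "combined", side = "TOT", stringsAsFactors = FALSE)
  )
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    key <- keys[i, ]
    mat <- visit1_matrix(data, key$group, key$parameter, key$phase, key$side)
    icc <- icc_oneway(mat, rho0 = rho0)
    cv <- tryCatch(cv_mean(mat), rhinorep_error_positivity = function(e) NULL)
    data.frame(
      key, n_subjects = nrow(mat), n_dropped = attr(mat, "n_dropped"),
      icc = icc$estimate, icc_f = icc$f_statistic, icc_p = icc$p_value,
      benchmark = icc$benchmark,
      mean_cv = if (is.null(cv)) NA_real_ else cv$mean_cv,
      cv_acceptable = if (is.null(cv)) NA else cv$acceptable
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "rho0") <- rho0
  class(out) <- c("repeatability_table", "data.frame")
  out
}

#' Between-day reproducibility table (CV, two-occasion ICC, Bland-Altman)
#'
#' For every group, parameter and day pair (baseline vs each follow-up),
#' pairs each subject's day-1 summary of the combined total — by default
#' the mean of the five baseline replicates, configurably the first
#' replicate — with the single follow-up value, then applies
#' [icc_oneway()] with `k = 2`, the mean two-point per-subject CV
#' ([cv_mean()]), and [bland_altman()] in nonparametric mode with
#' differences taken as day 1 minus the later day. If the
#' heteroscedasticity companion test is significant (p < 0.05) and all
#' values are positive, the Bland-Altman analysis is repeated on the log
#' scale and reported alongside.
#'
#' @param data a `study_dataset` with follow-up days present.
#' @param rho0 null ICC; default 0.20.
#' @param day0_summary `"mean"` (default) or `"first"` baseline replicate.
#' @return a data frame of class `reproducibility_table`: one row per
#'   (group, parameter, day) with `n`, `cv`, `icc`, `icc_p`, `bias`,
#'   `loa_lower`, `loa_upper`, `hetero_rho`, `hetero_p`, `log_bias`,
#'   `log_loa_lower`, `log_loa_upper` (NA unless the log rerun triggered).
#'   The paired differences for plotting are attached as attribute
#'   `"agreements"` (a named list of `paired_agreement` objects).
#' @export
between_day_reproducibility <- function(data, rho0 = 0.20,
                                        day0_summary = c("mean", "first")) {
  stopifnot(inherits(data, "study_dataset"))
  day0_summary <- match.arg(day0_summary)
  days <- sort(unique(data$measurements$day))
  days <- days[days > 0]
  if (length(days) == 0) stop_rhino("structure", "no follow-up days in dataset")
  groups <- unique(data$measurements$group)
  agreements <- list()
  rows <- list()
  for (g in groups) for (p in aar_parameters) {
    mat0 <- visit1_matrix(data, g, p, "combined", "TOT")
    x0_all <- if (day0_summary == "mean") rowMeans(mat0) else mat0[, 1]
    for (d in days) {
      xd_all <- followup_combined(data, g, p, d)
      common <- intersect(names(x0_all), names(xd_all)[!is.na(xd_all)])
      x0 <- x0_all[common]
      xd <- xd_all[common]
      pair <- cbind(x0, xd)
      icc <- icc_oneway(pair, rho0 = rho0)
      cv <- tryCatch(cv_mean(pair), rhinorep_error_positivity = function(e) NULL)
      ba <- bland_altman(x0, xd, mode = "nonparametric")
      log_ba <- NULL
      if (!is.na(ba$hetero_p) && ba$hetero_p < 0.05 &&
          all(x0 > 0) && all(xd > 0)) {
        log_ba <- bland_altman(x0, xd, mode = "nonparametric", log_scale = TRUE)
      }
      key <- sprintf("%s.%s.day%d", g, p, d)
      agreements[[key]] <- ba
      rows[[key]] <- data.frame(
        group = g, parameter = p, day = d, n = length(common),
        n_dropped = length(x0_all) - length(common),
        cv = if (is.null(cv)) NA_real_ else cv$mean_cv,
        icc = icc$estimate, icc_p = icc$p_value,
        bias = ba$bias, loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
        hetero_rho = ba$hetero_rho, hetero_p = ba$hetero_p,
        log_bias = if (is.null(log_ba)) NA_real_ else log_ba$bias,
        log_loa_lower = if (is.null(log_ba)) NA_real_ else log_ba$loa_lower,
        log_loa_upper = if (is.null(log_ba)) NA_real_ else log_ba$loa_upper
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "agreements") <- agreements
  attr(out, "day0_summary") <- day0_summary
  class(out) <- c("reproducibility_table", "data.frame")
  out
}

#' Baseline descriptive table with group comparisons
#'
#' Mean +/- SD per group for quantitative covariates with a
#' Kruskal-Wallis test across groups, and count (percent) for categorical
#' covariates with a chi-square test. With a single group the comparison
#' column is omitted with a warning; a covariate that is constant
#' everywhere gets a degenerate-test warning and an `NA` p-value.
#'
#' @param data a `study_dataset`.
#' @param quantitative,categorical covariate names from the subjects
#'   table.
#' @return a data frame: one row per covariate, one summary column per
#'   group plus `all`, and `p_value` / `test`.
#' @export
baseline_table <- function(data,
                           quantitative = c("age", "weight", "height", "bmi"),
                           categorical = c("sex", "symptoms")) {
  stopifnot(inherits(data, "study_dataset"))
  s <- data$subjects
  groups <- unique(s$group)
  single <- length(groups) < 2
  if (single) warning("only one group present; comparison p-values omitted")
  fmt_q <- function(v) sprintf("%.2f ± %.2f", mean(v), stats::sd(v))
  fmt_c <- function(v) {
    pos <- if (is.logical(v)) sum(v) else sum(v == sort(unique(v))[1])
    sprintf("%d (%.1f%%)", pos, 100 * pos / length(v))
  }
  one_row <- function(var, type) {
    v <- s[[var]]
    fmt <- if (type == "quantitative") fmt_q else fmt_c
    cells <- vapply(groups, function(g) fmt(v[s$group == g]), character(1))
    p <- NA_real_
    test <- NA_character_
    if (!single) {
      if (length(unique(v)) < 2) {
        warning(sprintf("covariate '%s' is constant; test omitted", var))
      } else if (type == "quantitative") {
        p <- stats::kruskal.test(v, factor(s$group))$p.value
        test <- "kruskal-wallis"
      } else {
        p <- suppressWarnings(stats::chisq.test(table(s$group, v), correct = FALSE)$p.value)
        test <- "chi-square"
      }
    }
    out <- data.frame(variable = var, type = type)
    out[groups] <- as.list(cells)
    out$all <- fmt(v)
    out$p_value <- p
    out$test <- test
    out
  }
  rows <- c(lapply(quantitative, one_row, type = "quantitative"),
            lapply(categorical, one_row, type = "categorical"))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' ROC performance of AAR parameters against current rhinitis symptoms
#'
#' For every parameter and scale (total inspiratory, total expiratory,
#' combined total), the per-subject predictor is the mean of the baseline
#' replicates and the outcome is the binary current-symptoms indicator.
#' Reports the full-sample nonparametric AUC with DeLong confidence
#' interval ([delong_ci()]) and the stratified five-fold cross-validated
#' AUC ([cross_validated_auc()]) side by side.
#'
#' @param data a `study_dataset`.
#' @param folds cross-validation folds; default 5.
#' @param seed fold-assignment seed; default 1.
#' @param level confidence level; default 0.95.
#' @return a data frame of class `roc_table`: one row per (parameter,
#'   scale) with `auc`, `se`, `ci_low`, `ci_high`, `p_value`, `cv_auc`.
#' @export
roc_table <- function(data, folds = 5, seed = 1, level = 0.95) {
  stopifnot(inherits(data, "study_dataset"))
  s <- data$subjects
  labels <- s$symptoms
  scales <- c(inspiratory = "Total Inspiratory", expiratory = "Total Expiratory",
              combined = "Combined Total")
  rows <- list()
  for (p in aar_parameters) for (ph in names(scales)) {
    per_group <- lapply(unique(s$group), function(g) {
      rowMeans(visit1_matrix(data, g, p, ph, "TOT"))
    })
    score_by_id <- unlist(unname(per_group))
    score <- unname(score_by_id[s$subject_id])
    dl <- delong_ci(score, labels, level = level)
    cv_auc <- cross_validated_auc(score, labels, folds = folds, seed = seed)
    rows[[paste(p, ph)]] <- data.frame(
      parameter = p, scale = scales[[ph]],
      auc = dl$auc, se = dl$delong_se,
      ci_low = dl$ci95[1], ci_high = dl$ci95[2], p_value = dl$p_value,
      cv_auc = as.numeric(cv_auc)
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "folds") <- folds
  attr(out, "seed") <- seed
  class(out) <- c("roc_table", "data.frame")
  out
}
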