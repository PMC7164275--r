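#' AAR parameters and phases
#'
#' The four nasal-resistance parameters read from a rhinomanometry
#' pressure-flow curve (Broms' radius-2 resistance and the resistances at
#' 75, 100 and 150 Pa) and the two breathing phases.
#' @keywords internal
aar_parameters <- c("R2", "R75", "R100", "R150")
aar_phases <- c("inspiratory", "expiratory")

#' Group profile for the synthetic study generator
#'
#' Ground truth for one diagnosis group: mean and SD of the *total*
#' (right + left nostril) resistance for every parameter/phase, the true
#' within-day ICC, the probability of current rhinitis symptoms, and a
#' multiplicative drift applied at follow-up visits (e.g. a decreasing
#' drift for seasonal allergic rhinitis measured during the pollen season,
#' whose resistances fall as the season wanes).
#'
#' @param label group label, e.g. `"HC"`.
#' @param mean_total,sd_total numeric 4 x 2 matrices (rows
#'   `R2, R75, R100, R150`; columns `inspiratory, expiratory`) of the
#'   total-resistance mean and SD, all positive.
#' @param true_icc within-day ICC in (0, 1) used to split the total
#'   variance into between- and within-subject components.
#' @param symptom_prob marginal probability of current rhinitis symptoms.
#' @param day_drift named numeric vector of multiplicative trends per
#'   follow-up day, e.g. `c("14" = 1, "28" = 1)`.
#' @param symptom_link_slope slope of the logistic link between the
#'   (standardised log) latent resistance and symptom probability; 0
#'   decouples symptoms from resistance.
#' @return a `group_profile` list.
#' @export
group_profile <- function(label, mean_total, sd_total, true_icc,
                          symptom_prob, day_drift = c("14" = 1, "28" = 1),
                          symptom_link_slope = 1) {
  mean_total <- as.matrix(mean_total)
  sd_total <- as.matrix(sd_total)
  dimnames(mean_total) <- dimnames(sd_total) <- list(aar_parameters, aar_phases)
  if (any(mean_total <= 0) || any(sd_total <= 0)) {
    stop_rhino("config", "group %s: means and SDs must be positive", label)
  }
  if (true_icc <= 0 || true_icc >= 1) {
    stop_rhino("config", "group %s: true_icc must lie in (0, 1)", label)
  }
  if (symptom_prob < 0 || symptom_prob > 1) {
    stop_rhino("config", "group %s: symptom_prob must lie in [0, 1]", label)
  }
  structure(
    list(label = label, mean_total = mean_total, sd_total = sd_total,
         true_icc = true_icc, symptom_prob = symptom_prob,
         day_drift = day_drift, symptom_link_slope = symptom_link_slope),
    class = "group_profile"
  )
}

#' Default five-group calibration
#'
#' Profiles for healthy controls (HC), non-allergic rhinitis (NAR),
#' perennial allergic rhinitis (PAR), and seasonal allergic rhinitis
#' outside (SAR-O) and during (SAR-D) the pollen season. Total-resistance
#' means and SDs are calibrated to published group summaries for children
#' aged 10-16 (e.g. HC R2 total inspiratory 1.17 +/- 0.52, SAR-D
#' 8.85 +/- 11.77 Pa.s/cm3); true ICCs default to the observed within-day
#' range (healthy groups near 0.5, allergic groups 0.75-0.85); symptom
#' prevalences to 0.60 (HC) through 1.00 (SAR). SAR-D carries a decreasing
#' follow-up drift. These defaults are conveniences for emulation, not
#' claims about any cohort.
#'
#' @return a named list of five [group_profile()] objects.
#' @export
default_group_profiles <- function() {
  m <- function(insp, exp) cbind(inspiratory = insp, expiratory = exp)
  list(
    HC = group_profile(
      "HC",
      mean_total = m(c(1.17, 1.09, 1.09, 1.10), c(1.06, 0.93, 0.93, 0.64)),
      sd_total   = m(c(0.52, 0.47, 0.47, 0.61), c(0.50, 0.48, 0.51, 0.52)),
      true_icc = 0.50, symptom_prob = 0.60
    ),
    NAR = group_profile(
      "NAR",
      mean_total = m(c(1.18, 1.06, 1.03, 0.81), c(1.20, 0.80, 0.68, 0.62)),
      sd_total   = m(c(0.66, 0.66, 0.66, 0.80), c(0.71, 0.88, 0.84, 0.89)),
      true_icc = 0.55, symptom_prob = 0.80
    ),
    PAR = group_profile(
      "PAR",
      mean_total = m(c(1.91, 1.85, 1.80, 1.88), c(1.82, 1.85, 1.56, 1.47)),
      sd_total   = m(c(1.69, 1.53, 1.52, 1.80), c(1.52, 1.59, 1.47, 1.63)),
      true_icc = 0.85, symptom_prob = 0.90
    ),
    `SAR-O` = group_profile(
      "SAR-O",
      mean_total = m(c(2.56, 2.20, 1.99, 2.57), c(1.86, 2.38, 1.90, 1.98)),
      sd_total   = m(c(5.16, 2.40, 2.43, 5.15), c(3.18, 2.41, 1.80, 3.28)),
      true_icc = 0.80, symptom_prob = 1.00
    ),
    `SAR-D` = group_profile(
      "SAR-D",
      mean_total = m(c(8.85, 8.48, 7.98, 8.88), c(8.39, 8.87, 6.41, 8.41)),
      sd_total   = m(c(11.77, 8.57, 8.75, 11.77), c(10.69, 7.63, 4.74, 10.68)),
      true_icc = 0.75, symptom_prob = 1.00,
      day_drift = c("14" = 0.85, "28" = 0.70)
    )
  )
}

#' Study configuration for the synthetic generator
#'
#' Encodes the clinical design being emulated: `n_per_group` subjects per
#' diagnosis group, five replicate measurements per nostril at the
#' baseline visit, and one measurement per nostril at each follow-up visit
#' (nominally days 14 and 28).
#'
#' The default noise family is lognormal: nasal resistances are positive
#' and their group SDs are of the order of the means, which a normal model
#' cannot produce without negative values. The normal family exists to
#' match the assumptions of the simulation batches exactly and is the
#' right choice for estimator-recovery experiments.
#'
#' @param groups list of [group_profile()]s; default
#'   [default_group_profiles()].
#' @param n_per_group subjects per group (>= 2); default 10.
#' @param replicates_visit1 baseline replicates (>= 2); default 5.
#' @param followup_days integer vector of follow-up days; default
#'   `c(14, 28)`.
#' @param noise_family `"lognormal"` (default) or `"normal"`.
#' @param day_effect_frac SD of the extra day-level random effect at
#'   follow-up visits, as a fraction of the within-subject SD; makes
#'   between-day ICC lower than within-day ICC. Default 0.5.
#' @param seed root seed; default 1.
#' @return a `study_config` list.
#' @export
study_config <- function(groups = default_group_profiles(), n_per_group = 10,
                         replicates_visit1 = 5, followup_days = c(14, 28),
                         noise_family = c("lognormal", "normal"),
                         day_effect_frac = 0.5, seed = 1) {
  noise_family <- match.arg(noise_family)
  if (n_per_group < 2 || replicates_visit1 < 2) {
    stop_rhino("config", "need n_per_group >= 2 and replicates_visit1 >= 2")
  }
  if (any(followup_days <= 0)) stop_rhino("config", "follow-up days must be positive")
  structure(
    list(groups = groups, n_per_group = as.integer(n_per_group),
         replicates_visit1 = as.integer(replicates_visit1),
         followup_days = as.integer(followup_days),
         noise_family = noise_family, day_effect_frac = day_effect_frac,
         seed = as.integer(seed)),
    class = "study_config"
  )
}

#' Generate a synthetic rhinomanometry study dataset
#'
#' Emulates the study design of [study_config()]. For every subject,
#' parameter, phase and nostril side, a latent subject level is drawn
#' around the group's per-side mean (half the calibrated total) with
#' between-subject variance `true_icc * total`, and replicate measurements
#' are drawn around it with within-subject variance `(1 - true_icc) *
#' total`, where `total` is the per-side variance (half the calibrated
#' total-resistance variance, the two sides being generated independently
#' and symmetrically). In lognormal mode the same decomposition is applied
#' on the log scale with moment-matched parameters, so all values are
#' strictly positive. Follow-up visits add an independent day-level random
#' effect (SD `day_effect_frac` times the within-subject SD) and apply the
#' group's multiplicative `day_drift`, so between-day reproducibility is
#' genuinely worse than within-day repeatability.
#'
#' `TOT` rows are the arithmetic sum of the matched `R` and `L` records.
#' The binary current-symptoms outcome is drawn per subject with the
#' group's `symptom_prob` tilted by a logistic link on the subject's
#' standardised log latent R2 level (slope `symptom_link_slope`), which
#' makes ROC performance against resistance tunable; a total five-symptom
#' score (0-15) and simple demographics are attached for descriptive
#' tables.
#'
#' @param cfg a [study_config()].
#' @return an object of class `study_dataset`: `measurements` (long data
#'   frame with `subject_id, group, day, parameter, phase, side, replicate,
#'   value`), `subjects` (one row per subject: demographics, `symptoms`,
#'   `t5ss`), and `config` metadata including the seed.
#' @export
generate_study <- function(cfg = study_config()) {
  stopifnot(inherits(cfg, "study_config"))
  set.seed(cfg$seed)
  n <- cfg$n_per_group
  k1 <- cfg$replicates_visit1
  days <- cfg$followup_days
  meas <- list()
  subj <- list()
  for (g in cfg$groups) {
    ids <- sprintf("%s-%02d", g$label, seq_len(n))
    latent_r2 <- numeric(n) # per-subject log latent R2 inspiratory total, for the symptom link
    for (p in aar_parameters) for (f in aar_phases) {
      m_side <- g$mean_total[p, f] / 2
      v_side <- g$sd_total[p, f]^2 / 2
      if (cfg$noise_family == "normal") {
        sb <- sqrt(g$true_icc * v_side)
        sw <- sqrt((1 - g$true_icc) * v_side)
        draw <- function(latent, sd) stats::rnorm(length(latent), latent, sd)
        lat0 <- m_side
      } else {
        s2_log <- log(1 + v_side / m_side^2)
        sb <- sqrt(g$true_icc * s2_log)
        sw <- sqrt((1 - g$true_icc) * s2_log)
        lat0 <- log(m_side) - s2_log / 2
      }
      for (side in c("R", "L")) {
        lat <- lat0 + stats::rnorm(n, 0, sb)
        if (p == "R2" && f == "inspiratory") {
          on_log <- if (cfg$noise_family == "normal") log(pmax(lat, 1e-6)) else lat
          latent_r2 <- latent_r2 + on_log / 2
        }
        v1 <- matrix(stats::rnorm(n * k1, mean = rep(lat, k1), sd = sw), n, k1)
        if (cfg$noise_family == "lognormal") v1 <- exp(v1)
        meas[[length(meas) + 1L]] <- data.frame(
          subject_id = rep(ids, k1), group = g$label, day = 0L,
          parameter = p, phase = f, side = side,
          replicate = rep(seq_len(k1), each = n), value = as.vector(v1)
        )
        for (d in days) {
          drift <- g$day_drift[as.character(d)]
          if (is.na(drift)) drift <- 1
          dayeff <- stats::rnorm(n, 0, cfg$day_effect_frac * sw)
          vd <- stats::rnorm(n, mean = lat + dayeff, sd = sw)
          vd <- if (cfg$noise_family == "lognormal") exp(vd) * drift else vd * drift
          meas[[length(meas) + 1L]] <- data.frame(
            subject_id = ids, group = g$label, day = d,
            parameter = p, phase = f, side = side,
            replicate = 1L, value = vd
          )
        }
      }
    }
    # subject-level outcomes and demographics
    z <- as.vector(scale(latent_r2))
    if (any(!is.finite(z))) z <- rep(0, n)
    p_base <- min(max(g$symptom_prob, 0.02), 0.98)
    p_sym <- stats::plogis(stats::qlogis(p_base) + g$symptom_link_slope * z)
    if (g$symptom_prob >= 1) p_sym <- rep(1, n)
    if (g$symptom_prob <= 0) p_sym <- rep(0, n)
    symptoms <- stats::rbinom(n, 1L, p_sym) == 1L
    t5ss <- if (g$label == "HC") {
      stats::rbinom(n, 15L, 0.12)
    } else {
      pmin(6L + stats::rbinom(n, 9L, 0.35), 15L)
    }
    age <- pmin(pmax(stats::rnorm(n, 11.8, 1.7), 10), 16)
    sex <- ifelse(stats::rbinom(n, 1L, 0.48) == 1L, "F", "M")
    height <- stats::rnorm(n, 152.7, 12.1)
    weight <- pmax(stats::rnorm(n, 49.8, 12.0), 25)
    subj[[length(subj) + 1L]] <- data.frame(
      subject_id = ids, group = g$label, symptoms = symptoms, t5ss = t5ss,
      age = age, sex = sex, weight = weight, height = height,
      bmi = weight / (height / 100)^2
    )
  }
  measurements <- do.call(rbind, meas)
  # TOT = R + L, record-wise
  wide_key <- c("subject_id", "group", "day", "parameter", "phase", "replicate")
  r_side <- measurements[measurements$side == "R", ]
  l_side <- measurements[measurements$side == "L", ]
  ord <- function(df) df[do.call(order, df[wide_key]), ]
  r_side <- ord(r_side)
  l_side <- ord(l_side)
  tot <- r_side
  tot$side <- "TOT"
  tot$value <- r_side$value + l_side$value
  measurements <- rbind(measurements, tot)
  rownames(measurements) <- NULL
  structure(
    list(measurements = measurements, subjects = do.call(rbind, subj),
         config = list(n_per_group = n, replicates_visit1 = k1,
                       followup_days = days, noise_family = cfg$noise_family,
                       day_effect_frac = cfg$day_effect_frac, seed = cfg$seed,
                       groups = vapply(cfg$groups, `[[`, "", "label"),
                       true_icc = vapply(cfg$groups, `[[`, 0, "true_icc"))),
    class = "study_dataset"
  )
}

#' Named study fixtures
#'
#' Deterministic datasets for tests and examples:
#' `"tiny"` (2 groups x 3 subjects, loads in well under a second and passes
#' every pipeline stage), `"paper_scale"` (the full emulated design: 5
#' groups x 10 children, 5 baseline replicates per nostril, follow-ups at
#' days 14 and 28, lognormal noise), and `"recovery"` (5 groups x 200
#' subjects, normal noise, no follow-up day effect confound at baseline —
#' sized for estimator-recovery checks).
#'
#' @param name fixture name.
#' @param seed root seed; default 20200417.
#' @return a `study_dataset`.
#' @export
make_fixture <- function(name = c("tiny", "paper_scale", "recovery"),
                         seed = 20200417) {
  name <- match.arg(name)
  cfg <- switch(
    name,
    tiny = {
      gp <- default_group_profiles()[c("HC", "PAR")]
      # moderate prevalences so both outcome classes are populated even
      # with 3 subjects per group and the ROC stage can run
      gp$HC$symptom_prob <- 0.30
      gp$PAR$symptom_prob <- 0.70
      study_config(groups = gp, n_per_group = 3, seed = seed)
    },
    paper_scale = study_config(seed = seed),
    recovery = study_config(n_per_group = 200, noise_family = "normal",
                            seed = seed)
  )
  generate_study(cfg)
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf(
    "<study_dataset: %d subjects in %d groups, %d measurement rows, seed %d>\n",
    nrow(x$subjects), length(unique(x$subjects$group)),
    nrow(x$measurements), x$config$seed
  ))
  invisible(x)
}
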