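#' Configuration for the synthetic ADNI-like cohort generator
#'
#' Defines the study design emulated by [generate_cohort()]: three diagnostic
#' groups (Normal, MCI, AD) followed over four annual CSF sampling visits.
#' Group sizes, MMSE distributions and demographics default to the published
#' ADNI-1 longitudinal CSF subset (Normal n = 135, MMSE 29 +/- 1; MCI n = 155,
#' MMSE 27 +/- 2; AD n = 18, MMSE 24 +/- 2).  Raw per-group CSF marker means
#' are not public for that subset, so the marker scale is a package default
#' chosen to match typical CSF immunoassay magnitudes, not a claim about ADNI
#' values.
#'
#' @param group_sizes Named integer vector: subjects per diagnostic group.
#' @param marker_means_normal Named numeric: Normal-group marker means, pg/mL.
#' @param group_effect_multipliers Named list of per-group multiplicative
#'   shifts applied to the Normal means.  The AD entry must move markers in the
#'   AD-typical direction: abeta multiplier < 1, tau and ptau multipliers > 1.
#' @param longitudinal_drift Named list of per-group fractional change per 12
#'   months (e.g. -0.04 means a 4% decline per year), compounded over visits.
#' @param subject_cv Coefficient of variation of the lognormal between-subject
#'   random effect on the true (noise-free) marker levels.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   within-visit measurement noise.
#' @param mmse_params List with `mean` and `sd` per group plus `coupling`, the
#'   number of MMSE points lost per standard deviation of latent network
#'   severity, and `resid_sd_frac`, the fraction of the group sd left as
#'   severity-independent noise.
#' @param age_params List with `mean` and `sd` per group (years).
#' @param male_frac Named numeric: probability of male sex per group.
#' @param visits Visit months.
#' @param dropout Per-visit probability that a subject-visit is missing.  The
#'   emulated study excluded incomplete subjects, so the default is 0.
#' @param seed Integer seed making the cohort fully reproducible.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @export
#' @examples
#' cfg <- cohort_config(seed = 1)
#' cfg$group_sizes
cohort_config <- function(
    group_sizes = c(Normal = 135, MCI = 155, AD = 18),
    marker_means_normal = c(abeta = 205, tau = 70, ptau = 25),
    group_effect_multipliers = list(
      Normal = c(abeta = 1, tau = 1, ptau = 1),
      MCI    = c(abeta = 0.82, tau = 1.35, ptau = 1.40),
      AD     = c(abeta = 0.66, tau = 1.75, ptau = 1.85)
    ),
    longitudinal_drift = list(
      Normal = c(abeta = 0, tau = 0, ptau = 0),
      MCI    = c(abeta = -0.030, tau = 0.035, ptau = 0.035),
      AD     = c(abeta = -0.050, tau = 0.055, ptau = 0.060)
    ),
    subject_cv = 0.10,
    noise_cv = 0.15,
    mmse_params = list(
      mean = c(Normal = 29, MCI = 27, AD = 24),
      sd = c(Normal = 1, MCI = 2, AD = 2),
      coupling = 1.5,
      resid_sd_frac = 0.5
    ),
    age_params = list(
      mean = c(Normal = 79, MCI = 77, AD = 74),
      sd = c(Normal = 5, MCI = 6, AD = 7)
    ),
    male_frac = c(Normal = 71 / 131, MCI = 106 / 155, AD = 6 / 18),
    visits = c(12, 24, 36, 48),
    dropout = 0,
    seed = 20160119) {
  cfg <- list(
    group_sizes = group_sizes,
    marker_means_normal = marker_means_normal,
    group_effect_multipliers = group_effect_multipliers,
    longitudinal_drift = longitudinal_drift,
    subject_cv = subject_cv,
    noise_cv = noise_cv,
    mmse_params = mmse_params,
    age_params = age_params,
    male_frac = male_frac,
    visits = visits,
    dropout = dropout,
    seed = seed
  )
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  groups <- names(cfg$group_sizes)
  if (is.null(groups) || !all(c("Normal", "MCI", "AD") %in% groups)) {
    abort("`group_sizes` must be named with Normal, MCI and AD")
  }
  if (any(cfg$group_sizes < 0) || any(cfg$group_sizes != round(cfg$group_sizes))) {
    abort("group sizes must be non-negative integers")
  }
  cfg$marker_means_normal <- as_marker_vector(cfg$marker_means_normal)
  if (any(cfg$marker_means_normal <= 0)) {
    abort("`marker_means_normal` must be strictly positive", class = "minibalance_config_error")
  }
  for (g in groups) {
    cfg$group_effect_multipliers[[g]] <-
      as_marker_vector(cfg$group_effect_multipliers[[g]], require_positive = TRUE)
    dr <- cfg$longitudinal_drift[[g]]
    if (is.null(dr)) abort(sprintf("missing longitudinal_drift for group %s", g))
    names(dr) <- names(dr) %||% marker_names()
    cfg$longitudinal_drift[[g]] <- dr[marker_names()]
  }
  ad <- cfg$group_effect_multipliers$AD
  if (!(ad[["abeta"]] < 1 && ad[["tau"]] > 1 && ad[["ptau"]] > 1)) {
    abort("AD multipliers must lower abeta and raise tau and ptau",
          class = "minibalance_config_error")
  }
  if (cfg$noise_cv < 0 || cfg$subject_cv < 0) abort("noise CVs must be >= 0")
  check_fraction(cfg$dropout, "dropout", open_lo = FALSE)
  if (length(cfg$visits) < 1 || any(cfg$visits < 0)) abort("invalid visit months")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  groups: ",
      paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes), collapse = ", "),
      "\n", sep = "")
  cat("  visits (months): ", paste(x$visits, collapse = ", "), "\n", sep = "")
  cat("  normal marker means (pg/mL): ",
      paste(sprintf("%s=%g", marker_names(), x$marker_means_normal), collapse = ", "),
      "\n", sep = "")
  cat("  noise cv: ", x$noise_cv, "; subject cv: ", x$subject_cv,
      "; dropout: ", x$dropout, "; seed: ", x$seed, "\n", sep = "")
  invisible(x)
}
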