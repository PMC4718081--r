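#' Generate a synthetic ADNI-like longitudinal cohort
#'
#' Simulates subject-by-visit CSF marker records with known ground truth.  Each
#' subject carries a lognormal between-subject random effect; the true
#' (noise-free) level of marker k for a subject in group g at month m is
#'
#'   normal_mean_k x multiplier_{g,k} x subject_effect x (1 + drift_{g,k})^(m/12)
#'
#' and the observed level adds multiplicative lognormal measurement noise.
#' Both lognormal factors have mean exactly 1, so group sample means converge
#' to mean x multiplier x drift factor.  A subject-visit's latent severity is
#' the Euclidean distance between the true normalized marker vector and the
#' normal state (1, 1, 1); MMSE is drawn around the group mean with a negative
#' coupling to standardized severity, then rounded and clipped to [0, 30].
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per subject-visit: `subject_id`, `group`
#'   (factor Normal/MCI/AD), `month`, `abeta`, `tau`, `ptau` (pg/mL), `mmse`,
#'   `age`, `sex`, plus the generator ground-truth column `latent_severity`
#'   (excluded from the CSV written by [write_cohort()]).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(
#'   group_sizes = c(Normal = 5, MCI = 5, AD = 5), seed = 1))
#' dplyr::count(cohort, group)
generate_cohort <- function(config = cohort_config()) {
  config <- validate_cohort_config(unclass(config))
  groups <- names(config$group_sizes)
  n_total <- sum(config$group_sizes)
  empty <- tibble::tibble(
    subject_id = character(), group = factor(character(), levels = groups),
    month = numeric(), abeta = numeric(), tau = numeric(), ptau = numeric(),
    mmse = integer(), age = numeric(), sex = character(),
    latent_severity = numeric()
  )
  if (n_total == 0) return(empty)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  sd_subj <- sqrt(log(1 + config$subject_cv^2))
  sd_noise <- sqrt(log(1 + config$noise_cv^2))
  means <- config$marker_means_normal

  subjects <- purrr::map_dfr(groups, function(g) {
    n <- config$group_sizes[[g]]
    if (n == 0) return(NULL)
    tibble::tibble(
      group = g,
      subject_effect = purrr::map(seq_len(n), function(i) {
        rlnorm(3, meanlog = -sd_subj^2 / 2, sdlog = sd_subj)
      }),
      age = rnorm(n, config$age_params$mean[[g]], config$age_params$sd[[g]]),
      sex = ifelse(runif(n) < config$male_frac[[g]], "male", "female")
    )
  })
  subjects$subject_id <- sprintf("S%04d", seq_len(nrow(subjects)))

  records <- tidyr::expand_grid(subjects, month = config$visits)
  mult <- config$group_effect_multipliers
  drift <- config$longitudinal_drift

  true_levels <- purrr::pmap(
    list(records$group, records$subject_effect, records$month),
    function(g, eff, m) {
      means * mult[[g]] * eff * (1 + drift[[g]])^(m / 12)
    }
  )
  true_mat <- do.call(rbind, true_levels)
  colnames(true_mat) <- marker_names()
  noise <- matrix(
    rlnorm(length(true_mat), meanlog = -sd_noise^2 / 2, sdlog = sd_noise),
    nrow = nrow(true_mat)
  )
  obs_mat <- true_mat * noise

  severity <- sqrt(rowSums((sweep(true_mat, 2, means, "/") - 1)^2))
  sev_sd <- sd(severity)
  z <- if (is.na(sev_sd) || sev_sd == 0) rep(0, length(severity)) else
    (severity - mean(severity)) / sev_sd

  mp <- config$mmse_params
  mmse_raw <- mp$mean[records$group] - mp$coupling * z +
    rnorm(nrow(records), 0, mp$resid_sd_frac * mp$sd[records$group])
  mmse <- as.integer(round(pmin(30, pmax(0, mmse_raw))))

  out <- tibble::tibble(
    subject_id = records$subject_id,
    group = factor(records$group, levels = groups),
    month = records$month,
    abeta = obs_mat[, "abeta"],
    tau = obs_mat[, "tau"],
    ptau = obs_mat[, "ptau"],
    mmse = mmse,
    age = round(records$age, 1),
    sex = records$sex,
    latent_severity = severity
  )
  if (config$dropout > 0) {
    out <- out[runif(nrow(out)) >= config$dropout, , drop = FALSE]
  }
  dplyr::arrange(out, .data$subject_id, .data$month)
}

#' Normal-state reference marker vector
#'
#' The per-marker mean over all Normal-group records.  This vector is the
#' normal state Vb of the disruption parameters and the normalization
#' denominator used throughout the package.
#'
#' @param data Cohort tibble (from [generate_cohort()] or [read_cohort()]).
#' @return Named numeric vector (abeta, tau, ptau) of Normal-group means.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(
#'   group_sizes = c(Normal = 20, MCI = 0, AD = 0), seed = 1))
#' reference_state(cohort)
reference_state <- function(data) {
  normal <- dplyr::filter(data, .data$group == "Normal")
  if (nrow(normal) == 0) {
    abort("no Normal-group records: cannot estimate the reference state",
          class = "minibalance_estimation_error")
  }
  vapply(normal[, marker_names()], mean, numeric(1))
}
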