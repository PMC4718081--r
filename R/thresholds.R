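#' Calibrate disruption thresholds from the Normal group
#'
#' Subjects whose disruption parameters exceed the upper whisker of the
#' Normal group's boxplot are considered at high disease risk.  For each
#' parameter the threshold is the Tukey upper whisker: the largest
#' observation not exceeding Q3 + 1.5 IQR.  K enters as its deviation from
#' the normal-state value, |K - 1|.
#'
#' @param normal_params Tibble of Normal-group records with `U`, `K`, `phi`
#'   columns (from [cohort_disruption()]); at least 5 rows.
#' @return An object of class `disruption_thresholds`: list with `u_max`,
#'   `k_dev_max`, `phi_max`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(
#'   group_sizes = c(Normal = 30, MCI = 0, AD = 0), seed = 1))
#' params <- cohort_disruption(cohort, reference_state(cohort))
#' calibrate_thresholds(dplyr::filter(params, group == "Normal"))
calibrate_thresholds <- function(normal_params) {
  if (nrow(normal_params) < 5) {
    abort("need at least 5 Normal-group parameter triples to calibrate",
          class = "minibalance_calibration_error")
  }
  upper_whisker <- function(x) {
    q <- quantile(x, c(0.25, 0.75), names = FALSE)
    fence <- q[2] + 1.5 * (q[2] - q[1])
    max(x[x <= fence])
  }
  disruption_thresholds(
    u_max = upper_whisker(normal_params$U),
    k_dev_max = upper_whisker(abs(normal_params$K - 1)),
    phi_max = upper_whisker(normal_params$phi)
  )
}

#' Disruption thresholds
#'
#' @param u_max,k_dev_max,phi_max Non-negative thresholds on U, |K - 1| and
#'   phi; not all zero.  `Inf` disables a parameter, giving a
#'   single-parameter criterion.
#' @return An object of class `disruption_thresholds`.
#' @export
disruption_thresholds <- function(u_max, k_dev_max, phi_max) {
  th <- c(u_max = u_max, k_dev_max = k_dev_max, phi_max = phi_max)
  if (any(th < 0) || anyNA(th)) abort("thresholds must be >= 0")
  if (all(th == 0)) abort("thresholds must not all be zero")
  structure(as.list(th), class = "disruption_thresholds")
}

#' @export
print.disruption_thresholds <- function(x, ...) {
  cat(sprintf("<disruption_thresholds> u_max=%g, k_dev_max=%g, phi_max=%g\n",
              x$u_max, x$k_dev_max, x$phi_max))
  invisible(x)
}

#' Classify parameter triples as disrupted
#'
#' Under the default any-exceedance rule a state is disrupted when U > u_max
#' OR |K - 1| > k_dev_max OR phi > phi_max.  The all-exceedance (AND) variant
#' requires every parameter to exceed its threshold.
#'
#' @param params Data frame with `U`, `K`, `phi` columns (any number of
#'   rows), or a one-row triple.
#' @param thresholds A [disruption_thresholds()].
#' @param rule `"any"` (OR, default) or `"all"` (AND).
#' @return Logical vector, one flag per row.
#' @export
#' @examples
#' th <- disruption_thresholds(1, 0.2, 0.5)
#' is_disrupted(tibble::tibble(U = c(0, 2), K = 1, phi = 0), th)
is_disrupted <- function(params, thresholds, rule = c("any", "all")) {
  rule <- match.arg(rule)
  exceed <- cbind(
    params$U > thresholds$u_max,
    abs(params$K - 1) > thresholds$k_dev_max,
    params$phi > thresholds$phi_max
  )
  if (rule == "any") rowSums(exceed) > 0 else rowSums(exceed) == 3
}
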