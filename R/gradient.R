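#' Gradient simulation of the disruption parameters
#'
#' Reproduces the simulation experiment that gives the three parameters their
#' physiological reading.  For each gradient g three perturbation scenarios
#' build a pathological vector Va from the reference Vb:
#'
#' * `single-marker` — one marker (default abeta) changes by +g, the others
#'   stay at reference: probes sensitivity to isolated variation.
#' * `multi-marker-1` — all markers increase by g together (consistent
#'   variation): K deviates by exactly g while phi stays 0.
#' * `multi-marker-2` — the first marker increases by g and the other two
#'   decrease by g (inconsistent variation): phi and U respond, K barely.
#'
#' K is reported as `|K - 1| x 100` (percent deviation from the normal-state
#' value 1); phi is reported in radians, with a `phi_pct` display column
#' (radians x 100); U in squared normalized units.
#'
#' @param gradients Fractional gradients in (0, 1], e.g. `c(0.1, 0.2, 0.5)`.
#' @param scenarios Subset of the three scenario names.
#' @param vb Reference vector (positive); default the normalized normal state.
#' @param single_marker Which marker the single-marker scenario perturbs.
#' @return Tibble with `scenario`, `gradient`, `K`, `phi`, `U`, `K_pct`,
#'   `phi_pct`.
#' @export
#' @examples
#' run_gradient_experiment(c(0.1, 0.2, 0.5))
run_gradient_experiment <- function(
    gradients = c(0.1, 0.2, 0.5),
    scenarios = c("single-marker", "multi-marker-1", "multi-marker-2"),
    vb = c(abeta = 1, tau = 1, ptau = 1),
    single_marker = "abeta") {
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  single_marker <- match.arg(single_marker, marker_names())
  vb <- as_marker_vector(vb, require_positive = TRUE)
  for (g in gradients) check_fraction(g, "gradient")

  build_va <- function(scenario, g) {
    switch(
      scenario,
      "single-marker" = {
        va <- vb
        va[single_marker] <- va[single_marker] * (1 + g)
        va
      },
      "multi-marker-1" = vb * (1 + g),
      "multi-marker-2" = {
        dir <- setNames(c(1, -1, -1), marker_names())
        vb * (1 + g * dir[marker_names()])
      }
    )
  }

  tidyr::expand_grid(scenario = scenarios, gradient = gradients) |>
    dplyr::mutate(
      params = purrr::map2(.data$scenario, .data$gradient, function(s, g) {
        disruption_params(build_va(s, g), vb)
      })
    ) |>
    tidyr::unnest("params") |>
    dplyr::mutate(K_pct = abs(.data$K - 1) * 100,
                  phi_pct = .data$phi * 100)
}
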