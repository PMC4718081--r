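#' Monte Carlo configuration
#'
#' Controls the adaptive estimator of network disruption probability.  After
#' every batch the relative error of the running estimate pf = d/D is
#'
#'   eps_p = t_(alpha/2, D-1) * sqrt(pf (1 - pf)) / (pf sqrt(D)),
#'
#' the relative half-width of the binomial confidence interval, and sampling
#' stops once eps_p falls below `target_relative_error` (or `max_iterations`
#' is reached).
#'
#' @param alpha Significance level of the t quantile (default 0.05).
#' @param batch_size Draws between convergence checks.
#' @param max_iterations Hard cap on total draws.
#' @param target_relative_error Stopping threshold on eps_p (default 0.05).
#' @return An object of class `mc_config`.
#' @export
mc_config <- function(alpha = 0.05, batch_size = 100,
                      max_iterations = 1e6, target_relative_error = 0.05) {
  check_fraction(alpha, "alpha", open_hi = TRUE)
  check_fraction(target_relative_error, "target_relative_error",
                 hi = Inf, open_hi = TRUE)
  if (batch_size < 1 || max_iterations < batch_size) {
    abort("`max_iterations` must be >= `batch_size` >= 1")
  }
  structure(list(alpha = alpha, batch_size = as.integer(batch_size),
                 max_iterations = as.integer(max_iterations),
                 target_relative_error = target_relative_error),
            class = "mc_config")
}

#' Relative error of a Monte Carlo probability estimate
#'
#' @param pf Estimated probability in (0, 1].
#' @param D Number of iterations performed (>= 2).
#' @param alpha Significance level for the t quantile (D - 1 degrees of
#'   freedom; converges to the normal quantile for large D).
#' @return The relative error eps_p, as a fraction.  `pf = 1` gives 0 (zero
#'   variance); `pf = 0` is an error, since no disruptions means convergence
#'   cannot be assessed.
#' @export
#' @examples
#' relative_error(0.5, 100)  # about 0.196
relative_error <- function(pf, D, alpha = 0.05) {
  if (D < 2) abort("`D` must be >= 2")
  if (pf == 0) {
    abort("no disruptions observed (pf = 0); cannot assess convergence",
          class = "minibalance_no_disruption")
  }
  check_fraction(pf, "pf")
  qt(1 - alpha / 2, df = D - 1) * sqrt(pf * (1 - pf)) / (pf * sqrt(D))
}

#' Perturbation specification
#'
#' Random perturbations are multiplicative lognormal around the subject's
#' observed level: each targeted marker is multiplied by exp(Z) with
#' Z ~ N(-sigma^2/2, sigma^2), so the perturbation has mean 1; untargeted
#' markers stay at the observed level.
#'
#' @param targets Markers to perturb (non-empty subset of [marker_names()]).
#' @param sigma Lognormal sigma, either one value or one per target.
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(targets = marker_names(), sigma = 0.25) {
  targets <- match.arg(targets, marker_names(), several.ok = TRUE)
  if (length(targets) == 0) abort("`targets` must be non-empty")
  if (any(sigma <= 0)) abort("`sigma` must be > 0")
  sigma <- rep_len(sigma, length(targets))
  structure(list(targets = targets, sigma = setNames(sigma, targets)),
            class = "perturbation_spec")
}

#' Estimate the network disruption probability
#'
#' Adaptive Monte Carlo estimation of the probability that a random
#' perturbation of the subject's marker levels drives the network into a
#' disrupted state.  Each iteration draws a lognormal perturbation of the
#' targeted markers, forms the pathological vector Va (static mode: the
#' perturbed vector itself; coupled mode: the perturbed vector propagated
#' through the transit-compartment network for `horizon` months), normalizes
#' by the reference, computes (U, K, phi) against the normal state and tests
#' the disruption rule.  After each batch the estimate pf = d/D and its
#' relative error are updated; sampling stops when the relative error drops
#' below the configured target.
#'
#' @param subject Marker vector of the subject's observed raw levels.
#' @param reference Normal-state marker vector (positive).
#' @param thresholds A [disruption_thresholds()].
#' @param spec A [perturbation_spec()].
#' @param mc An [mc_config()].
#' @param mode `"static"` or `"coupled"`.
#' @param model A [build_network()] model on the normalized scale (baseline
#'   (1,1,1)); required for coupled mode.
#' @param horizon Propagation horizon in months (coupled mode).
#' @param rule Disruption rule, see [is_disrupted()].
#' @param seed Integer seed; the run is fully reproducible from it.
#' @return An object of class `mc_result`: list with `pf`, `d`, `D`,
#'   `epsilon`, `converged`, `status`.  When no disruption is ever observed,
#'   `pf = 0`, `converged = FALSE` and `status = "no-disruption"`.
#' @export
#' @examples
#' th <- disruption_thresholds(0.05, Inf, Inf)
#' estimate_disruption_probability(
#'   c(abeta = 150, tau = 90, ptau = 35),
#'   c(abeta = 205, tau = 70, ptau = 25),
#'   th, mc = mc_config(max_iterations = 5000), seed = 1)
estimate_disruption_probability <- function(subject, reference, thresholds,
                                            spec = perturbation_spec(),
                                            mc = mc_config(),
                                            mode = c("static", "coupled"),
                                            model = NULL, horizon = 1,
                                            rule = c("any", "all"),
                                            seed = 1L) {
  mode <- match.arg(mode)
  rule <- match.arg(rule)
  subject <- as_marker_vector(subject, require_positive = TRUE)
  reference <- as_marker_vector(reference, require_positive = TRUE)
  if (mode == "coupled" && is.null(model)) {
    abort("coupled mode needs a `model` (see build_network())")
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))

  subj_norm <- subject / reference
  vb <- c(1, 1, 1)
  d <- 0L
  D <- 0L
  epsilon <- NA_real_
  converged <- FALSE

  while (D < mc$max_iterations) {
    b <- min(mc$batch_size, mc$max_iterations - D)
    # draws: b x 3 matrix of multiplicative perturbations (mean 1)
    mult <- matrix(1, nrow = b, ncol = 3,
                   dimnames = list(NULL, marker_names()))
    for (tgt in spec$targets) {
      s <- spec$sigma[[tgt]]
      mult[, tgt] <- rlnorm(b, meanlog = -s^2 / 2, sdlog = s)
    }
    va <- sweep(mult, 2, subj_norm, "*")
    if (mode == "coupled") {
      va <- t(apply(va, 1, function(v) {
        propagate_perturbation(model, setNames(v, marker_names()), horizon)
      }))
    }
    dev <- sweep(va, 2, vb, "-")
    params <- tibble::tibble(
      U = rowSums(dev^2),
      K = sqrt(rowSums(va^2)) / sqrt(sum(vb^2)),
      phi = acos(pmin(1, pmax(-1, (va %*% vb) / (sqrt(rowSums(va^2)) * sqrt(sum(vb^2))))))
    )
    d <- d + sum(is_disrupted(params, thresholds, rule))
    D <- D + b
    pf <- d / D
    if (d > 0) {
      epsilon <- relative_error(pf, D, mc$alpha)
      if (epsilon < mc$target_relative_error) {
        converged <- TRUE
        break
      }
    }
  }

  pf <- d / D
  structure(
    list(pf = pf, d = as.integer(d), D = as.integer(D), epsilon = epsilon,
         converged = converged,
         status = if (d == 0) "no-disruption" else if (converged) "converged" else "max-iterations",
         mode = mode, rule = rule, seed = as.integer(seed)),
    class = "mc_result"
  )
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("<mc_result> pf = %.4f (d = %d, D = %d), eps = %s, %s\n",
              x$pf, x$d, x$D,
              if (is.na(x$epsilon)) "NA" else sprintf("%.4f", x$epsilon),
              x$status))
  invisible(x)
}

#' @export
tidy.mc_result <- function(x, ...) {
  tibble::tibble(pf = x$pf, d = x$d, D = x$D, epsilon = x$epsilon,
                 converged = x$converged, status = x$status)
}

#' @export
glance.mc_result <- function(x, ...) tidy.mc_result(x)

#' Marker contribution to network disruption
#'
#' Ranks single markers and marker groups by their contribution to network
#' disruption: for each subset only those markers are perturbed (the others
#' stay at the subject's observed level), the disruption probability is
#' estimated, and contributions are reported as each subset's pf as a
#' percentage of the sum over evaluated subsets.
#'
#' @inheritParams estimate_disruption_probability
#' @param subsets List of character vectors of marker names; defaults to the
#'   three single markers.
#' @param sigma Lognormal sigma applied to every perturbed marker.
#' @return Tibble with `subset`, `pf`, `d`, `D`, `epsilon`, `converged`,
#'   `contribution_pct`.
#' @export
#' @examples
#' th <- disruption_thresholds(0.05, Inf, Inf)
#' marker_contributions(
#'   c(abeta = 150, tau = 90, ptau = 35),
#'   c(abeta = 205, tau = 70, ptau = 25),
#'   th, mc = mc_config(max_iterations = 2000), seed = 1)
marker_contributions <- function(subject, reference, thresholds,
                                 subsets = as.list(marker_names()),
                                 sigma = 0.25, mc = mc_config(),
                                 mode = c("static", "coupled"),
                                 model = NULL, horizon = 1,
                                 rule = c("any", "all"), seed = 1L) {
  if (length(subsets) == 0) abort("`subsets` must be non-empty")
  mode <- match.arg(mode)
  rule <- match.arg(rule)
  rows <- purrr::imap_dfr(subsets, function(sub, i) {
    res <- estimate_disruption_probability(
      subject, reference, thresholds,
      spec = perturbation_spec(targets = sub, sigma = sigma),
      mc = mc, mode = mode, model = model, horizon = horizon, rule = rule,
      seed = as.integer(seed) + i - 1L
    )
    dplyr::mutate(tidy.mc_result(res),
                  subset = paste(sub, collapse = "+"), .before = 1)
  })
  total <- sum(rows$pf)
  rows$contribution_pct <- if (total > 0) rows$pf / total * 100 else NA_real_
  rows
}
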