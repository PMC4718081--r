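#' A transit-compartment chain between two marker nodes
#'
#' Indirect biochemical links between markers (e.g. amyloid-beta raising AChE
#' activity which activates GSK-3beta and hence tau phosphorylation) are
#' abstracted as a first-order transit chain: a cascade of `n_compartments`
#' stages, each with mean transit time `tau`, whose final stage stimulates the
#' target's production.  The chain's impulse response is an Erlang density
#' with shape `n_compartments` and mean `n_compartments * tau`.
#'
#' @param source,target Marker names (see [marker_names()]).
#' @param n_compartments Number of cascade stages (>= 1).
#' @param tau Mean transit time per stage, months.
#' @param gain Dimensionless stimulation strength: at steady state the chain
#'   multiplies the target's production by (1 + gain).
#' @param label Identifier used for compartment columns in trajectories.
#' @return An object of class `transit_chain`.
#' @export
#' @examples
#' transit_chain("abeta", "ptau", gain = 0.3, label = "ab_gsk")
transit_chain <- function(source, target, n_compartments = 3, tau = 0.5,
                          gain = 0.2, label = paste(source, target, sep = "_")) {
  source <- match.arg(source, marker_names())
  target <- match.arg(target, marker_names())
  if (n_compartments < 1 || n_compartments != round(n_compartments)) {
    abort("`n_compartments` must be a positive integer")
  }
  if (tau <= 0) abort("`tau` must be > 0")
  if (gain < 0) abort("`gain` must be >= 0")
  structure(
    list(source = source, target = target,
         n_compartments = as.integer(n_compartments), tau = tau,
         gain = gain, label = label),
    class = "transit_chain"
  )
}

#' Default crosstalk topology
#'
#' The four directed edges of the mini network: two parallel amyloid-beta to
#' P-tau routes (the AChE/GSK-3beta kinase route and the calcium-channel
#' route), the P-tau to amyloid-beta route through AChE/presenilin-1, and
#' direct phosphorylation of tau into P-tau.  Chain lengths, transit times and
#' gains are package defaults for this reduced representation, documented in
#' the methods vignette; they are not literature rate constants.
#'
#' @param n_compartments,tau Shared chain settings.
#' @return List of [transit_chain()] objects.
#' @export
default_chains <- function(n_compartments = 3, tau = 0.5) {
  list(
    transit_chain("abeta", "ptau", n_compartments, tau, gain = 0.30,
                  label = "ab_ptau_gsk"),
    transit_chain("abeta", "ptau", n_compartments, tau, gain = 0.20,
                  label = "ab_ptau_ca"),
    transit_chain("ptau", "abeta", n_compartments, tau, gain = 0.25,
                  label = "ptau_ab_ps1"),
    transit_chain("tau", "ptau", n_compartments, tau, gain = 0.30,
                  label = "tau_ptau_phos")
  )
}

#' Build a calibrated mini crosstalk network
#'
#' Each marker node X follows first-order turnover with stimulated production,
#'
#'   dX/dt = prod_X * (1 + sum_c gain_c * C_last,c / S_baseline,c) - clear_X * X,
#'
#' where the sum runs over chains ending at X and C_last,c is the final
#' compartment of chain c (normalized by its source's baseline so gains are
#' dimensionless).  Each chain obeys dC_1/dt = (S - C_1)/tau and
#' dC_i/dt = (C_(i-1) - C_i)/tau.  Production rates are solved so the supplied
#' baseline is a steady state (calibration, not fitting):
#' prod_X = clear_X * baseline_X / (1 + sum of incoming gains).
#'
#' @param baseline Marker vector at homeostasis (strictly positive).  In the
#'   analysis pipeline this is the normalized normal state (1, 1, 1).
#' @param clearance Named first-order clearance rates, per month.
#' @param chains List of [transit_chain()] objects.
#' @return An object of class `mini_network`.
#' @export
#' @examples
#' net <- build_network(c(abeta = 1, tau = 1, ptau = 1))
#' steady_state(net)
build_network <- function(baseline = c(abeta = 1, tau = 1, ptau = 1),
                          clearance = c(abeta = 1, tau = 1, ptau = 1),
                          chains = default_chains()) {
  baseline <- as_marker_vector(baseline, require_positive = TRUE)
  clearance <- as_marker_vector(clearance, require_positive = TRUE)
  stopifnot(all(vapply(chains, inherits, logical(1), "transit_chain")))
  labels <- vapply(chains, `[[`, character(1), "label")
  if (anyDuplicated(labels)) abort("chain labels must be unique")

  gain_in <- setNames(numeric(3), marker_names())
  for (ch in chains) gain_in[ch$target] <- gain_in[ch$target] + ch$gain
  production <- clearance * baseline / (1 + gain_in)
  if (any(production <= 0) || anyNA(production)) {
    abort("no positive production solution for the requested baseline",
          class = "minibalance_construction_error")
  }

  comp_names <- unlist(lapply(chains, function(ch) {
    paste0(ch$label, "_", seq_len(ch$n_compartments))
  }))
  structure(
    list(baseline = baseline, clearance = clearance, production = production,
         chains = chains, state_names = c(marker_names(), comp_names)),
    class = "mini_network"
  )
}

#' @export
print.mini_network <- function(x, ...) {
  cat("<mini_network> 3 marker nodes,", length(x$chains), "transit chains\n")
  cat("  baseline:", paste(sprintf("%s=%g", marker_names(), x$baseline),
                           collapse = ", "), "\n")
  for (ch in x$chains) {
    cat(sprintf("  %s -> %s  (%s: n=%d, tau=%g, gain=%g)\n",
                ch$source, ch$target, ch$label, ch$n_compartments,
                ch$tau, ch$gain))
  }
  invisible(x)
}

# full state vector with markers at `markers` and compartments at their
# baseline steady-state values (each compartment equals its source's baseline)
baseline_state <- function(model, markers = model$baseline) {
  markers <- as_marker_vector(markers)
  comp <- unlist(lapply(model$chains, function(ch) {
    rep(model$baseline[[ch$source]], ch$n_compartments)
  }))
  setNames(c(markers, comp), model$state_names)
}

# ODE right-hand side; exported for use as an independent check surface
# (numerical Jacobians, residuals) as well as by the integrator
#' Evaluate the network's time derivatives
#'
#' @param model A [build_network()] model.
#' @param state Full named state vector (markers then chain compartments).
#' @return Named vector of derivatives.
#' @export
network_rhs <- function(model, state) {
  markers <- state[marker_names()]
  stim <- setNames(numeric(3), marker_names())
  idx <- 4L
  d_comp <- numeric(length(state) - 3L)
  for (ch in model$chains) {
    n <- ch$n_compartments
    comp <- state[idx:(idx + n - 1L)]
    inflow <- c(markers[[ch$source]], comp[-n])
    d_comp[(idx - 3L):(idx + n - 4L)] <- (inflow - comp) / ch$tau
    stim[ch$target] <- stim[ch$target] +
      ch$gain * comp[[n]] / model$baseline[[ch$source]]
    idx <- idx + n
  }
  d_markers <- model$production * (1 + stim) - model$clearance * markers
  setNames(c(d_markers, d_comp), model$state_names)
}

#' Algebraic steady state of the network
#'
#' At a fixed point every chain compartment equals its source level, reducing
#' the system to three linear equations in the marker levels, solved directly.
#'
#' @param model A [build_network()] model.
#' @return Named marker vector at steady state.
#' @export
steady_state <- function(model) {
  mk <- marker_names()
  A <- diag(model$clearance)
  dimnames(A) <- list(mk, mk)
  for (ch in model$chains) {
    A[ch$target, ch$source] <- A[ch$target, ch$source] -
      model$production[[ch$target]] * ch$gain / model$baseline[[ch$source]]
  }
  setNames(drop(solve(A, model$production)), mk)
}

#' Integrate the network dynamics
#'
#' Adaptive stiff-capable integration (deSolve's lsoda) on a fixed output
#' grid; absolute tolerance 1e-9, relative 1e-6.
#'
#' @param model A [build_network()] model.
#' @param initial Full named state vector; defaults to the baseline state.
#' @param duration Integration horizon (months), > 0.
#' @param step Output grid spacing (months).
#' @return A `network_trajectory` tibble: `time`, the three markers, and one
#'   column per chain compartment.
#' @export
simulate_network <- function(model, initial = NULL, duration, step = 0.05) {
  if (duration <= 0) abort("`duration` must be > 0")
  if (step <= 0) abort("`step` must be > 0")
  initial <- initial %||% baseline_state(model)
  if (!identical(names(initial), model$state_names)) {
    initial <- setNames(initial, model$state_names)
  }
  times <- seq(0, duration, by = step)
  if (times[length(times)] < duration) times <- c(times, duration)
  sol <- deSolve::ode(
    y = initial, times = times,
    func = function(t, y, p) list(unname(network_rhs(model, setNames(y, model$state_names)))),
    parms = NULL, method = "lsoda", atol = 1e-9, rtol = 1e-6
  )
  if (anyNA(sol) || any(!is.finite(sol))) {
    abort("network integration failed: non-finite state encountered",
          class = "minibalance_numerical_error")
  }
  tbl <- tibble::as_tibble(as.data.frame(sol))
  vals <- as.matrix(tbl[, -1])
  if (any(vals < -1e-8)) {
    abort("network integration produced negative compartment levels",
          class = "minibalance_numerical_error")
  }
  vals[vals < 0] <- 0
  tbl[, -1] <- as.data.frame(vals)
  class(tbl) <- c("network_trajectory", class(tbl))
  tbl
}

#' Propagate a marker perturbation through the network
#'
#' Sets the marker nodes to the perturbed levels, leaves the transit
#' compartments at baseline, integrates for `horizon` months, and returns the
#' marker vector at the horizon.  This is the pathological state vector Va in
#' the network-coupled operating mode; in static mode the perturbed vector is
#' used directly.
#'
#' @param model A [build_network()] model.
#' @param perturbed Marker vector of perturbed levels (positive).
#' @param horizon Months to integrate; 0 returns `perturbed` unchanged.
#' @return Named marker vector at the horizon.
#' @export
propagate_perturbation <- function(model, perturbed, horizon = 1) {
  perturbed <- as_marker_vector(perturbed, require_positive = TRUE)
  if (horizon == 0) return(perturbed)
  traj <- simulate_network(model, baseline_state(model, perturbed),
                           duration = horizon, step = horizon / 40)
  as_marker_vector(traj[nrow(traj), marker_names()])
}

#' Impulse response of an isolated transit chain
#'
#' Integrates a single chain with a unit bolus in its first compartment and
#' no further input; the outflux of the final compartment follows the
#' Erlang(n, 1/tau) density, with mean transit time n * tau.
#'
#' @param chain A [transit_chain()].
#' @param t_max Integration horizon; defaults to 12 mean transit times.
#' @param n_steps Output grid resolution.
#' @return Tibble with `time` and `flux` (outflux of the last compartment).
#' @export
chain_impulse_response <- function(chain, t_max = NULL,
                                   n_steps = 2000) {
  n <- chain$n_compartments
  t_max <- t_max %||% (12 * n * chain$tau)
  y0 <- c(1, numeric(n - 1))
  times <- seq(0, t_max, length.out = n_steps + 1)
  sol <- deSolve::ode(
    y = y0, times = times,
    func = function(t, y, p) {
      inflow <- c(0, y[-n])
      list((inflow - y) / chain$tau)
    },
    parms = NULL, method = "lsoda", atol = 1e-12, rtol = 1e-10
  )
  tibble::tibble(time = sol[, 1], flux = sol[, n + 1] / chain$tau)
}

#' Measured mean transit time of a chain
#'
#' First moment of the simulated impulse-response outflux (trapezoidal
#' quadrature); equals n * tau up to integration error.
#'
#' @inheritParams chain_impulse_response
#' @return Mean transit time (months).
#' @export
mean_transit_time <- function(chain, t_max = NULL, n_steps = 2000) {
  ir <- chain_impulse_response(chain, t_max = t_max, n_steps = n_steps)
  trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  trapz(ir$time, ir$time * ir$flux) / trapz(ir$time, ir$flux)
}
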