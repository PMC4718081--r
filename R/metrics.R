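#' Integral disruption parameters K, phi and U
#'
#' The integral variation of the mini network between a pathological marker
#' vector Va and the normal-state reference Vb is summarized by three
#' parameters:
#'
#' * `K = |Va| / |Vb|` — the modulus ratio (dimensionless); responds to a
#'   consistent rise or fall of all markers together.
#' * `phi = arccos(Va . Vb / (|Va| |Vb|))` — the angle between the vectors,
#'   radians in `[0, pi]`; responds to inconsistent, direction-changing
#'   variation and is invariant to overall scale.
#' * `U = (Va - Vb) (Va - Vb)^T` — the squared Euclidean distance; responds to
#'   total variation of either kind.
#'
#' At the normal state (Va = Vb) the triple is (K, phi, U) = (1, 0, 0); the
#' further K moves from 1 and phi and U from 0, the more disrupted the
#' network.
#'
#' @param va,vb Marker vectors (numeric length 3, see [as_marker_vector()]).
#'   Vectors of any common dimension are accepted by the individual
#'   functions, for `compute_U` this is the only requirement.
#' @return `compute_K`, `compute_phi`, `compute_U`: a scalar.
#'   `disruption_params`: a one-row tibble with columns `U`, `K`, `phi`.
#' @export
#' @examples
#' compute_K(c(1.1, 1.1, 1.1), c(1, 1, 1))   # 1.1
#' compute_phi(c(1, 0, 0), c(0, 1, 0))       # pi/2
#' compute_U(c(2, 1, 1), c(1, 1, 1))         # 1
#' disruption_params(c(1.1, 0.9, 1.2), c(1, 1, 1))
compute_K <- function(va, vb) {
  nb <- vnorm(vb)
  if (nb == 0) {
    abort("reference vector Vb has zero length: K is undefined",
          class = "minibalance_reference_error")
  }
  vnorm(va) / nb
}

#' @rdname compute_K
#' @export
compute_phi <- function(va, vb) {
  na_ <- vnorm(va)
  nb <- vnorm(vb)
  if (na_ == 0 || nb == 0) {
    abort("zero-length vector: the angle phi is undefined",
          class = "minibalance_reference_error")
  }
  # clip guards floating-point overshoot of |cos| past 1
  acos(min(1, max(-1, sum(va * vb) / (na_ * nb))))
}

#' @rdname compute_K
#' @export
compute_U <- function(va, vb) {
  if (length(va) != length(vb)) {
    abort("Va and Vb must have the same dimension",
          class = "minibalance_input_error")
  }
  sum((va - vb)^2)
}

#' @rdname compute_K
#' @export
disruption_params <- function(va, vb) {
  tibble::tibble(
    U = compute_U(va, vb),
    K = compute_K(va, vb),
    phi = compute_phi(va, vb)
  )
}

#' Disruption parameters for every cohort record
#'
#' Computes (U, K, phi) for each subject-visit against the normal-state
#' reference.  By default marker levels are normalized by the reference
#' (component-wise division) before the comparison, so the normal state maps
#' to Vb = (1, 1, 1); this puts the three markers, whose raw magnitudes
#' differ by an order of magnitude, on a common scale.  Set
#' `normalize = FALSE` to work on raw pg/mL levels.
#'
#' @param data Cohort tibble with `abeta`, `tau`, `ptau` columns.
#' @param reference Normal-state marker vector, typically
#'   [reference_state()]`(data)`.
#' @param normalize Divide levels by the reference before Eqs. of K/phi/U.
#' @return The input tibble with `U`, `K`, `phi` columns appended.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(
#'   group_sizes = c(Normal = 10, MCI = 0, AD = 5), seed = 1))
#' cohort_disruption(cohort, reference_state(cohort))
cohort_disruption <- function(data, reference, normalize = TRUE) {
  reference <- as_marker_vector(reference, require_positive = normalize)
  m <- as.matrix(data[, marker_names()])
  if (normalize) {
    m <- sweep(m, 2, reference, "/")
    vb <- c(1, 1, 1)
  } else {
    vb <- unname(reference)
  }
  params <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
    disruption_params(m[i, ], vb)
  })
  dplyr::bind_cols(data, params)
}
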