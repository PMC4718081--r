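#' Canonical marker order
#'
#' All marker vectors in the package are ordered (abeta, tau, ptau); CSF
#' amyloid-beta 1-42, total tau and phosphorylated tau-181, in pg/mL on the
#' raw scale.
#'
#' @return Character vector of the three marker names.
#' @export
#' @examples
#' marker_names()
marker_names <- function() c("abeta", "tau", "ptau")

#' Coerce to a named marker vector
#'
#' Accepts a numeric vector of length 3 (named or in canonical order) or a
#' one-row data frame containing abeta/tau/ptau columns, and returns a named
#' numeric vector in canonical order.
#'
#' @param x Numeric vector of length 3 or one-row data frame.
#' @param require_positive Require all components strictly positive.
#' @return Named numeric vector (abeta, tau, ptau).
#' @export
#' @examples
#' as_marker_vector(c(tau = 70, abeta = 205, ptau = 25))
as_marker_vector <- function(x, require_positive = FALSE) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) {
      abort("a marker vector built from a data frame needs exactly one row")
    }
    x <- unlist(x[, marker_names()], use.names = TRUE)
    names(x) <- marker_names()
  }
  if (!is.numeric(x) || length(x) != 3L) {
    abort("a marker vector must be numeric of length 3 (abeta, tau, ptau)")
  }
  if (!is.null(names(x)) && all(marker_names() %in% names(x))) {
    x <- x[marker_names()]
  } else {
    names(x) <- marker_names()
  }
  if (anyNA(x)) abort("marker vector contains missing values")
  if (require_positive && any(x <= 0)) {
    abort("marker vector must be strictly positive")
  }
  if (any(x < 0)) abort("marker levels must be non-negative")
  x
}

# internal: squared Euclidean norm
vnorm <- function(x) sqrt(sum(x^2))

# internal: stop unless a scalar probability-like value
check_fraction <- function(x, name, lo = 0, hi = 1, open_lo = TRUE,
                           open_hi = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (open_lo) x > lo else x >= lo) &&
    (if (open_hi) x < hi else x <= hi)
  if (!ok) abort(sprintf("`%s` must be a scalar in %s%g, %g%s",
                         name, if (open_lo) "(" else "[", lo, hi,
                         if (open_hi) ")" else "]"))
  invisible(x)
}
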