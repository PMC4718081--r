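#' Mini network balance map
#'
#' The balance map plots a subject's three normalized marker levels as radii
#' on axes at 90 degrees (abeta), 210 degrees (tau) and 330 degrees (ptau);
#' joining the three vertices gives a triangle.  In the normal state all radii
#' equal 1 and the triangle is equilateral; the further the shape departs from
#' an equilateral triangle, the more imbalanced the network.
#'
#' @param subject Marker vector of the subject's raw levels.
#' @param reference Normal-state marker vector (strictly positive).
#' @return An object of class `balance_map`: a list with `radii` (named
#'   subject/reference ratios) and `vertices` (tibble of marker, angle in
#'   degrees, radius, x, y).
#' @export
#' @examples
#' bm <- balance_map(c(abeta = 150, tau = 90, ptau = 30),
#'                   c(abeta = 205, tau = 70, ptau = 25))
#' bm$radii
balance_map <- function(subject, reference) {
  subject <- as_marker_vector(subject)
  reference <- as_marker_vector(reference)
  if (any(reference <= 0)) {
    abort("reference components must be strictly positive to normalize",
          class = "minibalance_normalization_error")
  }
  radii <- subject / reference
  angles <- c(abeta = 90, tau = 210, ptau = 330)
  vertices <- tibble::tibble(
    marker = marker_names(),
    angle = unname(angles[marker_names()]),
    radius = unname(radii[marker_names()]),
    x = .data$radius * cos(.data$angle * pi / 180),
    y = .data$radius * sin(.data$angle * pi / 180)
  )
  structure(list(radii = radii, vertices = vertices), class = "balance_map")
}

#' Side lengths of a balance-map triangle
#'
#' @param map A [balance_map()].
#' @return Numeric vector of the three side lengths (abeta-tau, tau-ptau,
#'   ptau-abeta).
#' @export
balance_map_sides <- function(map) {
  v <- map$vertices
  idx <- rbind(c(1, 2), c(2, 3), c(3, 1))
  apply(idx, 1, function(ij) {
    sqrt((v$x[ij[1]] - v$x[ij[2]])^2 + (v$y[ij[1]] - v$y[ij[2]])^2)
  })
}

#' @export
print.balance_map <- function(x, ...) {
  cat("<balance_map> radii:",
      paste(sprintf("%s=%.3f", names(x$radii), x$radii), collapse = ", "),
      "\n")
  invisible(x)
}

#' Plot a balance map
#'
#' Draws the triangle of normalized marker levels over the equilateral
#' normal-state triangle (radii 1).
#'
#' @param object A [balance_map()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.balance_map <- function(object, ...) {
  ref <- balance_map(c(abeta = 1, tau = 1, ptau = 1),
                     c(abeta = 1, tau = 1, ptau = 1))
  close_tri <- function(v) v[c(seq_len(nrow(v)), 1), ]
  ggplot2::ggplot(close_tri(object$vertices), ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path(data = close_tri(ref$vertices), linetype = "dashed",
                       colour = "grey50") +
    ggplot2::geom_path(colour = "firebrick") +
    ggplot2::geom_point(data = object$vertices, colour = "firebrick") +
    ggplot2::geom_text(data = object$vertices,
                       ggplot2::aes(label = .data$marker),
                       nudge_y = 0.12, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Mini network balance map",
                  subtitle = "dashed: normal state (equilateral)") +
    ggplot2::theme_minimal()
}
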