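# Hille-equation pore geometry: conductance <-> diameter.
#
# Model: a cylindrical channel of diameter d and length l in a solution of
# conductivity sigma, in series with two orifice access resistances:
#   G = sigma / (4 l / (pi d^2) + 1 / d)
# With d, l in nm and sigma in S/m the conductance comes out in nS
# (1 S/m = 1 nS/nm).

#' Pore geometry
#'
#' @param diameter Pore diameter in nm.
#' @param length Channel length in nm (default 5.0).
#' @param conductivity Solution conductivity in S/m (default 10.5,
#'   approximately 1 M KCl at room temperature).
#' @return An object of class \code{"pore_geometry"}.
#' @export
pore_geometry <- function(diameter, length = 5.0, conductivity = 10.5) {
  if (!is.numeric(diameter) || any(diameter <= 0))
    stop("diameter must be positive", call. = FALSE)
  if (length < 0) stop("length must be non-negative", call. = FALSE)
  if (conductivity <= 0) stop("conductivity must be positive", call. = FALSE)
  structure(list(diameter = diameter, length = length,
                 conductivity = conductivity),
            class = "pore_geometry")
}

#' @export
print.pore_geometry <- function(x, ...) {
  cat(sprintf("Pore: d = %.3g nm, l = %.3g nm, sigma = %.3g S/m\n",
              x$diameter, x$length, x$conductivity))
  cat(sprintf("  Hille conductance: %.3f nS, open area: %.3f nm^2\n",
              hille_conductance(x), pore_area(x$diameter)))
  invisible(x)
}

#' Open-pore conductance from geometry (Hille equation)
#'
#' @param geometry A [pore_geometry()].
#' @return Conductance in nS.
#' @examples
#' hille_conductance(pore_geometry(2.0, 5.0, 10.5))
#' @export
hille_conductance <- function(geometry) {
  stopifnot(inherits(geometry, "pore_geometry"))
  d <- geometry$diameter; l <- geometry$length; s <- geometry$conductivity
  s / (4 * l / (pi * d^2) + 1 / d)
}

#' Pore diameter from open conductance (inverse Hille equation)
#'
#' Positive root of \eqn{\sigma d^2 - G d - 4 G l / \pi = 0}; exact
#' algebraic inverse of [hille_conductance()].
#'
#' @param conductance Open-pore conductance in nS.
#' @param length Channel length in nm.
#' @param conductivity Solution conductivity in S/m.
#' @return Diameter in nm.
#' @export
hille_diameter <- function(conductance, length = 5.0, conductivity = 10.5) {
  if (any(conductance <= 0)) stop("conductance must be positive", call. = FALSE)
  if (length < 0 || conductivity <= 0)
    stop("invalid geometry parameters", call. = FALSE)
  conductance * (1 + sqrt(1 + 16 * conductivity * length /
                            (pi * conductance))) / (2 * conductivity)
}

#' Open-pore cross-sectional area
#'
#' @param diameter Pore diameter in nm.
#' @return Area \eqn{\pi (d/2)^2} in nm^2.
#' @export
pore_area <- function(diameter) {
  if (any(diameter <= 0)) stop("diameter must be positive", call. = FALSE)
  pi * (diameter / 2)^2
}

#' Pore-diameter histogram from open conductances
#'
#' Converts each open-pore conductance to a diameter through the inverse
#' Hille equation and bins the diameters. The geometry assumptions (length,
#' conductivity) are recorded in the result because the diameters cannot be
#' interpreted without them.
#'
#' @param open_conductances Numeric vector of open conductances in nS.
#' @param length,conductivity Hille parameters, see [hille_diameter()].
#' @param bin_width Histogram bin width in nm (default 0.1).
#' @return List with \code{diameters}, \code{breaks}, \code{counts},
#'   \code{length}, \code{conductivity}; class \code{"pore_size_histogram"}.
#' @export
pore_size_histogram <- function(open_conductances, length = 5.0,
                                conductivity = 10.5, bin_width = 0.1) {
  if (!length(open_conductances))
    stop("open_conductances must be nonempty", call. = FALSE)
  d <- hille_diameter(open_conductances, length, conductivity)
  lo <- floor(min(d) / bin_width) * bin_width
  hi <- ceiling(max(d) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  structure(list(diameters = d, breaks = h$breaks, counts = h$counts,
                 length = length, conductivity = conductivity),
            class = "pore_size_histogram")
}

#' @export
print.pore_size_histogram <- function(x, ...) {
  cat(sprintf("Pore diameters from %d conductances (l = %.3g nm, sigma = %.3g S/m)\n",
              length(x$diameters), x$length, x$conductivity))
  cat(sprintf("  range %.2f-%.2f nm, mode bin %.2f-%.2f nm\n",
              min(x$diameters), max(x$diameters),
              x$breaks[which.max(x$counts)], x$breaks[which.max(x$counts) + 1]))
  invisible(x)
}

#' @export
plot.pore_size_histogram <- function(x, ...) {
  graphics::hist(x$diameters, breaks = x$breaks,
                 xlab = "Pore diameter (nm)", main = "Pore-size distribution",
                 ...)
  invisible(x)
}
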