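#' Rigid test-tube crypt surface
#'
#' The basement membrane is modeled as a rigid "test tube": a hemisphere of
#' radius \code{R} (the crypt base, pole at the origin) capped by a cylinder
#' of the same radius for z in [R, H]. The surface is C1 at the junction
#' z = R. The meridian arc from pole to rim has length (pi/2) R + (H - R).
#'
#' @param radius hemisphere/cylinder radius in um (crypt_diameter / 2).
#' @param height total crypt height H in um; must exceed \code{radius}.
#' @return An object of class \code{crypt_surface}.
#' @export
crypt_surface <- function(radius = 30, height = 160) {
  stopifnot(is.finite(radius), is.finite(height), radius > 0)
  if (height <= radius) stop("crypt height must exceed its radius")
  structure(list(R = radius, H = height), class = "crypt_surface")
}

#' @export
#' @method print crypt_surface
print.crypt_surface <- function(x, ...) {
  cat(sprintf("<crypt_surface> R = %g um, H = %g um, meridian arc %.2f um\n",
              x$R, x$H, total_arc(x)))
  invisible(x)
}

#' Total meridian arc length from base pole to rim
#' @param surface a \code{crypt_surface}.
#' @return Arc length in um: (pi/2) R + (H - R).
#' @export
total_arc <- function(surface) {
  (pi / 2) * surface$R + (surface$H - surface$R)
}

.as_points <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3, byrow = TRUE)
  storage.mode(p) <- "double"
  p
}

#' Distance, inward normal and foot point on the crypt wall
#'
#' @param surface a \code{crypt_surface}.
#' @param p a 3-vector or an n x 3 matrix of points (um).
#' @return A list with \code{distance} (unsigned, um), \code{normal}
#'   (n x 3 unit vectors pointing from the wall into the lumen) and
#'   \code{foot} (n x 3 nearest wall points).
#' @export
surface_query <- function(surface, p) {
  cpp_surface_query(.as_points(p), surface$R, surface$H)
}

#' Meridian arc coordinate ("wall height") of a point
#'
#' Arc length along the wall from the base pole to the wall projection of
#' \code{p}; continuous and strictly increasing along any meridian. Reported
#' niche heights are this quantity divided by the cell diameter.
#'
#' @inheritParams surface_query
#' @return Numeric vector of arc coordinates (um).
#' @export
wall_height <- function(surface, p) {
  cpp_wall_height(.as_points(p), surface$R, surface$H)
}

#' Downhill tangent of the wall at a point
#'
#' Unit vector tangent to the wall at the foot of \code{p}, pointing toward
#' decreasing arc coordinate (the direction of active Paneth-cell
#' migration); the zero vector at the base pole where no downhill direction
#' exists.
#'
#' @inheritParams surface_query
#' @return n x 3 matrix of tangent vectors.
#' @export
downhill_tangent <- function(surface, p) {
  cpp_downhill_tangent(.as_points(p), surface$R, surface$H)
}
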