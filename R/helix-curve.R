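#' Construct a helical curve
#'
#' A helical curve in 3-D is parameterized by its radius \code{r} (distance of
#' the trace from the axis, Angstrom), per-residue rise \code{p} (axial
#' advance per residue, Angstrom), turn angle \code{t} (rotation about the
#' axis per residue, degrees), an origin translation and a proper rotation
#' matrix orienting the axis.  In the canonical frame (identity rotation,
#' zero origin) the curve is \code{(r sin(u t), r cos(u t), u p)} with the
#' axis along +z; integer steps of the parameter \code{u} advance the curve
#' by one residue.  A left-handed curve negates the angular argument.
#'
#' @param r radius in Angstrom, \code{> 0}.
#' @param p rise per residue in Angstrom, \code{>= 0}.
#' @param t turn angle per residue in degrees, in \code{(0, 360)}.
#' @param origin numeric 3-vector, Angstrom.
#' @param rotation 3x3 proper orthonormal matrix (axis = rotation \%*\%
#'   \code{c(0, 0, 1)}).
#' @param handedness \code{"right"} or \code{"left"}.
#' @return An object of class \code{"helical_curve"}.
#' @examples
#' hc <- helical_curve(2.314, 1.516, 100.1)
#' curve_point(hc, 0:3)
#' @export
helical_curve <- function(r, p, t, origin = c(0, 0, 0), rotation = diag(3),
                          handedness = c("right", "left")) {
  handedness <- match.arg(handedness)
  stopifnot(is.numeric(r), length(r) == 1L, r > 0,
            is.numeric(p), length(p) == 1L, p >= 0,
            is.numeric(t), length(t) == 1L, t > 0, t < 360,
            is.numeric(origin), length(origin) == 3L, all(is.finite(origin)))
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      det(rotation) < 0)
    stop("'rotation' must be a proper orthonormal 3x3 matrix")
  structure(list(r = r, p = p, t = t, origin = as.numeric(origin),
                 rotation = rotation, handedness = handedness),
            class = "helical_curve")
}

#' @export
print.helical_curve <- function(x, ...) {
  cat(sprintf("helical_curve: r=%.4f A  p=%.4f A  t=%.3f deg  (%s-handed)\n",
              x$r, x$p, x$t, x$handedness))
  invisible(x)
}

#' Evaluate points on a helical curve
#'
#' @param curve a \code{\link{helical_curve}}.
#' @param u numeric vector of residue-index parameters (integers land on
#'   consecutive residues, one per unit).
#' @return A \code{length(u)} x 3 matrix of coordinates in Angstrom.
#' @export
curve_point <- function(curve, u) {
  stopifnot(inherits(curve, "helical_curve"), is.numeric(u))
  trad <- curve$t * pi / 180
  ang <- u * trad
  if (curve$handedness == "left") ang <- -ang
  local <- cbind(curve$r * sin(ang), curve$r * cos(ang), u * curve$p)
  pts <- local %*% t(curve$rotation)
  sweep(pts, 2L, curve$origin, "+")
}

#' Turn angle from radius, rise and consecutive C-alpha distance
#'
#' Inverts the chord identity \code{d^2 = p^2 + 4 r^2 sin^2(t/2)}:
#' \code{t = 2 asin(0.5 sqrt(d^2 - p^2) / r)}.  Geometrically impossible
#' inputs (\code{d <= p}, or arcsine argument above 1) return \code{NA},
#' which grid-search callers treat as a skipped cell.
#'
#' @param r radius, Angstrom.
#' @param p rise per residue, Angstrom.
#' @param d distance between consecutive C-alpha atoms, Angstrom.
#' @return Turn angle in degrees in \code{(0, 180]}, or \code{NA_real_}.
#' @export
turn_angle_from_rp <- function(r, p, d) {
  if (!is.finite(r) || !is.finite(p) || !is.finite(d) || r <= 0 || p < 0)
    return(NA_real_)
  if (d <= p) return(NA_real_)
  arg <- 0.5 * sqrt(d^2 - p^2) / r
  if (arg > 1) return(NA_real_)
  2 * asin(arg) * 180 / pi
}

#' Chord length between consecutive residues of a helical curve
#'
#' Closed form \code{sqrt(p^2 + 4 r^2 sin^2(t/2))}; the consecutive
#' C-alpha--C-alpha distance implied by the curve parameters.
#'
#' @inheritParams turn_angle_from_rp
#' @param t turn angle, degrees.
#' @return Distance in Angstrom.
#' @export
chord_length <- function(r, p, t) {
  sqrt(p^2 + 4 * r^2 * sin(t * pi / 360)^2)
}

#' Mirror coordinates through the x = 0 plane
#'
#' Negates the x component of every point, leaving y and z unchanged.
#' Mirroring flips helix handedness: the mirrored trace of a right-handed
#' helix is exactly the trace of the left-handed curve with the same
#' (r, p, t) in the canonical frame, so left-handed helices are detected by
#' fitting right-handed curves to mirrored coordinates.
#'
#' @param points n x 3 numeric matrix.
#' @return n x 3 matrix with column 1 negated.
#' @export
mirror_coordinates <- function(points) {
  points <- rbind(points)
  stopifnot(ncol(points) == 3L)
  points[, 1L] <- -points[, 1L]
  points
}

#' Distance from a point to its closest point on a helical curve
#'
#' Minimizes \code{|point - curve_point(u)|} over a bracketing parameter
#' window by bounded one-dimensional minimization (tolerance 1e-8 on
#' \code{u}).  Callers pass a window of +/- 1 residue around the expected
#' index so the search cannot capture the next turn of the helix.
#'
#' @param curve a \code{\link{helical_curve}}.
#' @param point numeric 3-vector.
#' @param u_window length-2 numeric interval bracketing the parameter.
#' @return Minimum distance in Angstrom.
#' @export
closest_point_distance <- function(curve, point, u_window) {
  stopifnot(length(point) == 3L, length(u_window) == 2L,
            u_window[1] < u_window[2])
  f <- function(u) {
    d <- curve_point(curve, u)[1L, ] - point
    sum(d * d)
  }
  opt <- stats::optimize(f, interval = u_window, tol = 1e-8)
  ## optimize() can miss an endpoint minimum by its tolerance; guard both ends
  sqrt(min(opt$objective, f(u_window[1]), f(u_window[2])))
}
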