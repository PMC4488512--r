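#' Grid specification for the (r, p) search
#'
#' The curve fit enumerates radius values in \code{[r_m - d_r, r_m + d_r]}
#' and rise values in \code{[p_m - d_p, p_m + d_p]} (endpoints inclusive)
#' around the analytic initial estimates, at the given step.  Defaults:
#' half-widths 0.25 Angstrom, step 0.01 Angstrom.
#'
#' @param d_r half-width of the radius interval, Angstrom.
#' @param d_p half-width of the rise interval, Angstrom.
#' @param step grid step for both intervals, Angstrom.
#' @return Object of class \code{"grid_spec"}.
#' @export
grid_spec <- function(d_r = 0.25, d_p = 0.25, step = 0.01) {
  stopifnot(step > 0, step <= d_r, step <= d_p)
  structure(list(d_r = d_r, d_p = d_p, step = step), class = "grid_spec")
}

#' Initial (r, p, t) estimates for a C-alpha quadruple
#'
#' Geometric construction seeding the grid search.  The axis direction is
#' the cross product of the two successive differences of the three virtual
#' bond vectors (the bond differences are perpendicular to the axis of any
#' genuine helix); the radius and axis position come from an algebraic
#' (Kasa) circle fit to the four points projected on the axis-normal plane;
#' the rise is the mean axial advance per bond; the turn angle follows from
#' the chord identity.  For a quadruple lying exactly on a helical curve the
#' construction reproduces that curve's (r, p, t) to machine precision.
#'
#' @param quad 4 x 3 matrix of consecutive C-alpha coordinates.
#' @return List with \code{r}, \code{p}, \code{t} (degrees), unit
#'   \code{axis} (oriented with positive projection on the first-to-last
#'   displacement) and \code{valid}.  Collinear or otherwise degenerate
#'   quadruples return \code{valid = FALSE}.
#' @export
initial_estimates <- function(quad) {
  quad <- rbind(quad)
  stopifnot(nrow(quad) == 4L, ncol(quad) == 3L)
  invalid <- list(r = NA_real_, p = NA_real_, t = NA_real_,
                  axis = rep(NA_real_, 3L), valid = FALSE)
  v <- diff(quad)                       # 3 virtual bonds
  bl <- sqrt(rowSums(v^2))
  if (any(bl < 1e-8)) return(invalid)
  w1 <- v[1L, ] - v[2L, ]
  w2 <- v[2L, ] - v[3L, ]
  ax <- cross3(w1, w2)
  nax <- sqrt(sum(ax^2))
  if (nax < 1e-10 * max(bl)^2) return(invalid)  # collinear / planar-degenerate
  ax <- ax / nax
  disp <- quad[4L, ] - quad[1L, ]
  if (sum(ax * disp) < 0) ax <- -ax
  p <- mean(v %*% ax)
  ## project on the axis-normal plane and fit a circle (Kasa)
  e1 <- w1 - sum(w1 * ax) * ax
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(ax, e1)
  xy <- cbind(quad %*% e1, quad %*% e2)
  a <- cbind(xy, 1)
  rhs <- -rowSums(xy^2)
  coef <- tryCatch(qr.solve(a, rhs), error = function(e) NULL)
  if (is.null(coef)) return(invalid)
  cen <- -coef[1:2] / 2
  r2 <- sum(cen^2) - coef[3L]
  if (!is.finite(r2) || r2 <= 0) return(invalid)
  r <- sqrt(r2)
  t <- turn_angle_from_rp(r, p, mean(bl))
  list(r = r, p = max(p, 0), t = t, axis = ax, valid = TRUE)
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Best-fit helical curve for one C-alpha quadruple
#'
#' Step 1 of the assignment method.  Enumerates the (r, p) grid around the
#' initial estimates; for each cell the turn angle comes from the chord
#' identity with the mean consecutive C-alpha distance, the canonical curve
#' points at u = 0..3 are superposed onto the quadruple by Kabsch/SVD, and
#' the cell minimizing the index-paired RMSD wins (ties break to the
#' first-encountered cell, ascending r then p).  The reported \code{delta}
#' is the closest-point RMSD of the four atoms to the winning curve after
#' superposition; the paired objective is kept as \code{rmsd_paired}.
#'
#' @param quad 4 x 3 matrix of consecutive C-alpha coordinates.
#' @param grid a \code{\link{grid_spec}}.
#' @param handedness label recorded on the fit (\code{"left"} means the
#'   caller already mirrored the coordinates).
#' @return Object of class \code{"quadruple_fit"}: \code{r}, \code{p},
#'   \code{t} (degrees), \code{delta}, \code{rmsd_paired}, \code{rotation},
#'   \code{origin}, unit \code{axis} (positive projection on the
#'   first-to-last displacement), \code{point_distances} (closest-point
#'   distance of each atom), \code{curve}, \code{handedness}, \code{valid}.
#' @export
fit_quadruple <- function(quad, grid = grid_spec(),
                          handedness = c("right", "left")) {
  handedness <- match.arg(handedness)
  quad <- rbind(quad)
  stopifnot(nrow(quad) == 4L, ncol(quad) == 3L, inherits(grid, "grid_spec"))
  bad <- structure(list(r = NA_real_, p = NA_real_, t = NA_real_,
                        delta = NA_real_, rmsd_paired = NA_real_,
                        rotation = NULL, origin = NULL,
                        axis = rep(NA_real_, 3L),
                        point_distances = rep(NA_real_, 4L), curve = NULL,
                        handedness = handedness, valid = FALSE),
                   class = "quadruple_fit")
  est <- initial_estimates(quad)
  if (!est$valid) return(bad)
  k_r <- round(grid$d_r / grid$step)
  k_p <- round(grid$d_p / grid$step)
  r_grid <- est$r + (-k_r:k_r) * grid$step
  p_grid <- est$p + (-k_p:k_p) * grid$step
  dbar <- mean(sqrt(rowSums(diff(quad)^2)))
  res <- cpp_fit_grid(quad, r_grid, p_grid, dbar)
  if (!res$valid) return(bad)
  curve <- helical_curve(res$r, res$p, res$t, origin = res$translation,
                         rotation = res$rotation)
  pd <- vapply(1:4, function(j)
    closest_point_distance(curve, quad[j, ], c(j - 2, j)), numeric(1))
  axis <- as.numeric(res$rotation %*% c(0, 0, 1))
  if (sum(axis * (quad[4L, ] - quad[1L, ])) < 0) axis <- -axis
  structure(list(r = res$r, p = res$p, t = res$t,
                 delta = sqrt(mean(pd^2)), rmsd_paired = res$rmsd_paired,
                 rotation = res$rotation,
                 origin = as.numeric(res$translation), axis = axis,
                 point_distances = pd, curve = curve,
                 handedness = handedness, valid = TRUE),
            class = "quadruple_fit")
}

#' @export
print.quadruple_fit <- function(x, ...) {
  if (!x$valid) cat("quadruple_fit: invalid (degenerate geometry)\n")
  else cat(sprintf(
    "quadruple_fit: r=%.4f p=%.4f t=%.2f delta=%.4f (%s-handed)\n",
    x$r, x$p, x$t, x$delta, x$handedness))
  invisible(x)
}

#' Angle between two successive helix axes
#'
#' @param prev_axis,cur_axis unit 3-vectors (axes oriented along the chain).
#' @return Angle in degrees in \code{[0, 180]}.
#' @export
axis_angle <- function(prev_axis, cur_axis) {
  n1 <- sqrt(sum(prev_axis^2)); n2 <- sqrt(sum(cur_axis^2))
  if (n1 < 1e-12 || n2 < 1e-12) stop("zero-length axis vector")
  acos(max(-1, min(1, sum(prev_axis * cur_axis) / (n1 * n2)))) * 180 / pi
}

#' Seven-residue C-alpha RMSD (delta) for one residue
#'
#' Pools, over the available quadruple fits starting at residues i-2, i-1,
#' i and i+1, the closest-point distances of each quadruple's four atoms to
#' its own best-fit curve, and returns their root mean square.  Measures
#' how well up to four consecutive helical curves jointly fit the seven
#' C-alpha atoms centred near residue i; used to terminate 3-10 helices and
#' to gate alpha-helix merging.
#'
#' @param fits list of \code{quadruple_fit}, element k holding the fit for
#'   the quadruple starting at residue k.
#' @param i residue index (1-based).
#' @return RMSD in Angstrom, or \code{NA_real_} when no covering quadruple
#'   exists (callers treat \code{NA} as failing every delta threshold).
#' @export
delta_rmsd <- function(fits, i) {
  ks <- (i - 2):(i + 1)
  ks <- ks[ks >= 1L & ks <= length(fits)]
  d2 <- unlist(lapply(ks, function(k) {
    f <- fits[[k]]
    if (is.null(f) || !f$valid) NULL else f$point_distances^2
  }))
  if (is.null(d2) || !length(d2)) return(NA_real_)
  sqrt(mean(d2))
}

#' Per-residue helical profile of a chain segment
#'
#' Slides a four-residue window over the segment, fitting a helical curve
#' to every quadruple, and derives for each residue the fitted (r, p, t),
#' the quadruple RMSD Delta, the helix-axis angle a (angle to the previous
#' window's axis; 0 for the first profiled residue), the seven-residue RMSD
#' delta, and, when class parameters are supplied, the three helix scores
#' h, g, pi.  For left-handed profiling the coordinates are mirrored first.
#'
#' @param xyz n x 3 C-alpha coordinate matrix of one contiguous segment.
#' @param grid a \code{\link{grid_spec}}.
#' @param handedness \code{"right"} or \code{"left"}.
#' @param classes class parameter list from
#'   \code{\link{default_class_params}}, or \code{NULL} to skip scores.
#' @param combiner score combiner, see \code{\link{helix_scores}}.
#' @return Object of class \code{"helix_profile"}: list with \code{profile}
#'   (data frame, one row per residue: index, r, p, t, delta, a,
#'   small_delta, h, g, pi), \code{fits} (list of \code{quadruple_fit}; one
#'   per window start, i.e. residues 1..n-3), \code{handedness}, \code{n}.
#'   Segments shorter than 4 residues yield zero fits and an all-NA profile.
#' @export
profile_segment <- function(xyz, grid = grid_spec(),
                            handedness = c("right", "left"),
                            classes = default_class_params(),
                            combiner = c("sum", "product")) {
  handedness <- match.arg(handedness)
  combiner <- match.arg(combiner)
  xyz <- rbind(xyz)
  stopifnot(ncol(xyz) == 3L)
  n <- nrow(xyz)
  work <- if (handedness == "left") mirror_coordinates(xyz) else xyz
  nfit <- max(n - 3L, 0L)
  fits <- vector("list", nfit)
  for (k in seq_len(nfit))
    fits[[k]] <- fit_quadruple(work[k:(k + 3L), , drop = FALSE], grid,
                               handedness)
  prof <- data.frame(index = seq_len(n), r = NA_real_, p = NA_real_,
                     t = NA_real_, delta = NA_real_, a = NA_real_,
                     small_delta = NA_real_, h = NA_real_, g = NA_real_,
                     pi = NA_real_)
  first_valid <- TRUE
  for (k in seq_len(nfit)) {
    f <- fits[[k]]
    if (!f$valid) next
    prof$r[k] <- f$r; prof$p[k] <- f$p; prof$t[k] <- f$t
    prof$delta[k] <- f$delta
    if (first_valid) {
      prof$a[k] <- 0
      first_valid <- FALSE
    } else if (k > 1L && fits[[k - 1L]]$valid) {
      prof$a[k] <- axis_angle(fits[[k - 1L]]$axis, f$axis)
    }
    if (!is.null(classes)) {
      sc <- helix_scores(f, classes, combiner)
      prof$h[k] <- sc$h; prof$g[k] <- sc$g; prof$pi[k] <- sc$pi
    }
  }
  for (i in seq_len(n)) prof$small_delta[i] <- delta_rmsd(fits, i)
  structure(list(profile = prof, fits = fits, handedness = handedness,
                 n = n),
            class = "helix_profile")
}

#' @export
print.helix_profile <- function(x, ...) {
  cat(sprintf("helix_profile: %d residues, %d window fits (%s-handed)\n",
              x$n, length(x$fits), x$handedness))
  print(utils::head(x$profile, 10L))
  if (x$n > 10L) cat("...\n")
  invisible(x)
}
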