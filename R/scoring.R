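#' Normal-distribution parameters of the three standard protein helices
#'
#' For each helix class the stored means (mu_r, mu_p, mu_t) define its
#' standard helical curve and, with the sigmas and the Delta parameters,
#' the terms of the helix scores.  mu_delta is stored for completeness but
#' does not enter the scores (the Delta term is Delta^2 / sigma_Delta^2).
#'
#' @return Named list (\code{alpha}, \code{"310"}, \code{pi}) of
#'   \code{"helix_class_params"} objects with fields \code{mu_r},
#'   \code{sigma_r}, \code{mu_p}, \code{sigma_p} (Angstrom), \code{mu_t},
#'   \code{sigma_t} (degrees), \code{mu_delta}, \code{sigma_delta}
#'   (Angstrom).
#' @export
default_class_params <- function() {
  mk <- function(label, mu_r, sigma_r, mu_p, sigma_p, mu_t, sigma_t,
                 mu_delta, sigma_delta)
    structure(list(label = label, mu_r = mu_r, sigma_r = sigma_r,
                   mu_p = mu_p, sigma_p = sigma_p, mu_t = mu_t,
                   sigma_t = sigma_t, mu_delta = mu_delta,
                   sigma_delta = sigma_delta),
              class = "helix_class_params")
  list(alpha = mk("alpha", 2.314, 0.061, 1.516, 0.086, 100.1, 2.56,
                  0.020, 0.031),
       "310" = mk("310",   2.109, 0.118, 1.829, 0.138, 107.4, 5.90,
                  0.045, 0.038),
       pi    = mk("pi",    2.779, 0.086, 1.196, 0.056,  82.8, 2.80,
                  0.129, 0.056))
}

#' Assignment thresholds
#'
#' The ten thresholds of the assignment algorithm.  Score thresholds
#' h_T, g_T, pi_T gate the start/extension of alpha, 3-10 and pi runs;
#' h_max gates alpha merging and C-terminal extension.  Axis-angle
#' thresholds (degrees): a_T (alpha start), a_G (3-10 start), a_I (pi
#' start), a_max (merge/extension).  delta thresholds (Angstrom): delta_G
#' (3-10 C-terminal extension), delta_max (alpha merge).
#'
#' @param h_T,h_max,g_T,pi_T score thresholds (dimensionless).
#' @param a_T,a_max,a_G,a_I axis-angle thresholds, degrees.
#' @param delta_G,delta_max RMSD thresholds, Angstrom.
#' @return Object of class \code{"threshold_config"}.
#' @export
threshold_config <- function(h_T = 20.0, h_max = 160.0, g_T = 6.0,
                             pi_T = 14.0, a_T = 20.0, a_max = 40.0,
                             a_G = 10.0, a_I = 20.0, delta_G = 0.12,
                             delta_max = 0.3) {
  th <- list(h_T = h_T, h_max = h_max, g_T = g_T, pi_T = pi_T, a_T = a_T,
             a_max = a_max, a_G = a_G, a_I = a_I, delta_G = delta_G,
             delta_max = delta_max)
  stopifnot(all(vapply(th, function(x)
    is.numeric(x) && length(x) == 1L && x > 0, logical(1))),
    h_T < h_max)
  structure(th, class = "threshold_config")
}

#' Helix scores of a fitted quadruple
#'
#' For each helix class the score combines four standardized deviation
#' terms of the fitted parameters from the class's standard helix:
#' (r - mu_r)^2/sigma_r^2, (p - mu_p)^2/sigma_p^2, (t - mu_t)^2/sigma_t^2
#' and Delta^2/sigma_Delta^2.  The default \code{"sum"} combiner adds the
#' four squared z-scores (a Mahalanobis-style distance: zero exactly at the
#' class mean with Delta = 0, growing quadratically with deviation), which
#' is the combiner the default thresholds are calibrated against.  The
#' \code{"product"} combiner multiplies the four terms with the conventional
#' 1/2 variance factors ((x - mu)^2 / (2 sigma^2)); it collapses to zero
#' whenever any single parameter sits at its class mean and is provided for
#' comparison experiments only.
#'
#' @param fit a \code{\link{fit_quadruple}} result.
#' @param classes list from \code{\link{default_class_params}}.
#' @param combiner \code{"sum"} (default) or \code{"product"}.
#' @return List with numeric scores \code{h} (alpha), \code{g} (3-10),
#'   \code{pi}; all \code{NA} for an invalid fit (an undefined score fails
#'   every threshold).
#' @export
helix_scores <- function(fit, classes = default_class_params(),
                         combiner = c("sum", "product")) {
  combiner <- match.arg(combiner)
  stopifnot(inherits(fit, "quadruple_fit"))
  if (!fit$valid)
    return(list(h = NA_real_, g = NA_real_, pi = NA_real_))
  one <- function(cp) {
    z2 <- c((fit$r - cp$mu_r)^2 / cp$sigma_r^2,
            (fit$p - cp$mu_p)^2 / cp$sigma_p^2,
            (fit$t - cp$mu_t)^2 / cp$sigma_t^2,
            fit$delta^2 / cp$sigma_delta^2)
    if (combiner == "sum") sum(z2) else prod(z2 / 2)
  }
  list(h = one(classes$alpha), g = one(classes$"310"), pi = one(classes$pi))
}
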