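#' Fit a normal distribution to a sample
#'
#' Plain moment fit: \code{mu} is the sample mean, \code{sigma} the
#' population (denominator n) standard deviation.  Used when re-calibrating
#' class parameters from fitted helix populations.
#'
#' @param samples numeric vector, length >= 2.
#' @return List with \code{mu}, \code{sigma}, \code{n_samples}.
#' @export
fit_normal <- function(samples) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop("need at least 2 samples")
  mu <- mean(samples)
  list(mu = mu, sigma = sqrt(mean((samples - mu)^2)),
       n_samples = length(samples))
}

#' Average the leading three (r, p, t) triples of a pi-helix
#'
#' Pi-helix calibration statistics use, for each helix, the component-wise
#' mean of the (r, p, t) fitted to its first three residues rather than
#' per-residue values.
#'
#' @param first_three 3 x 3 matrix (rows = residues, columns r, p, t) or a
#'   list of three numeric triples.
#' @return Numeric triple \code{c(r, p, t)}.
#' @export
pi_average <- function(first_three) {
  if (is.list(first_three)) first_three <- do.call(rbind, first_three)
  first_three <- rbind(first_three)
  if (nrow(first_three) != 3L || ncol(first_three) != 3L)
    stop("expected exactly three (r, p, t) triples")
  colMeans(first_three)
}

#' Greedy leader clustering of equal-length helices by RMSD
#'
#' Processes helices in input order: each one joins the first existing
#' cluster whose representative (founder) it superposes onto within the
#' RMSD threshold (\code{\link{kabsch_superpose}}), otherwise it founds a
#' new cluster.  Deterministic for a fixed input order.  All members must
#' have the same residue count.
#'
#' @param helices list of m x 3 C-alpha coordinate matrices, equal m >= 3.
#' @param threshold RMSD threshold in Angstrom (default 1.5).
#' @return List of clusters, each with \code{representative} (index into
#'   the input), \code{members} (indices) and \code{rmsd_threshold}.
#' @export
cluster_helices <- function(helices, threshold = 1.5) {
  stopifnot(length(helices) >= 1L, threshold > 0)
  lens <- vapply(helices, nrow, integer(1))
  if (length(unique(lens)) != 1L)
    stop("all helices must have the same residue count")
  if (lens[1L] < 3L) stop("helices must have at least 3 residues")
  clusters <- list()
  for (i in seq_along(helices)) {
    placed <- FALSE
    for (k in seq_along(clusters)) {
      rep_xyz <- helices[[clusters[[k]]$representative]]
      fit <- tryCatch(kabsch_superpose(helices[[i]], rep_xyz),
                      error = function(e) NULL)
      if (!is.null(fit) && fit$rmsd <= threshold) {
        clusters[[k]]$members <- c(clusters[[k]]$members, i)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      clusters[[length(clusters) + 1L]] <-
        list(representative = i, members = i, rmsd_threshold = threshold)
  }
  clusters
}

#' Summarize clusters as JSON
#'
#' @param clusters result of \code{\link{cluster_helices}}.
#' @return JSON text with cluster sizes and representative indices.
#' @export
cluster_summary_json <- function(clusters) {
  as.character(jsonlite::toJSON(list(
    n_clusters = length(clusters),
    sizes = vapply(clusters, function(cl) length(cl$members), integer(1)),
    representatives = vapply(clusters, `[[`, integer(1), "representative")),
    auto_unbox = TRUE))
}
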