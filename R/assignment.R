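## Threshold test helper: undefined values (NA, out of range) fail every
## comparison, so residues without a window fit can never start or extend a
## helix.
.lt <- function(x, thr) !is.na(x) && x < thr
.le <- function(x, thr) !is.na(x) && x <= thr
.at <- function(v, i) if (i >= 1L && i <= length(v)) v[i] else NA_real_

.runs_df <- function(runs, type, handedness) {
  if (!length(runs))
    return(data.frame(start = integer(), end = integer(),
                      helix_type = character(), handedness = character(),
                      stringsAsFactors = FALSE))
  data.frame(start = vapply(runs, `[`, integer(1), 1L),
             end = vapply(runs, `[`, integer(1), 2L),
             helix_type = type, handedness = handedness,
             stringsAsFactors = FALSE)
}

## Drop runs shorter than min_len, returning their residues to the
## unassigned pool.
.filter_min_len <- function(runs, min_len, b) {
  keep <- list()
  for (r in runs) {
    if (r[2L] - r[1L] + 1L >= min_len) keep[[length(keep) + 1L]] <- r
    else b[r[1L]:r[2L]] <- FALSE
  }
  list(runs = keep, b = b)
}

#' Assign pi-helices on one segment profile
#'
#' First pass of the sequential assignment.  A pi-helix starts at an
#' unassigned residue whose pi score is below pi_T and whose three axis
#' angles a_i, a_(i+1), a_(i+2) are all below a_I; it extends while the pi
#' score stays below pi_T on unassigned residues with index <= n - 3, and
#' then claims the four trailing residues of the window (clipped to the
#' segment end and to unassigned residues).  Runs shorter than 5 residues
#' are discarded and their residues returned to the pool.
#'
#' @param profile a \code{\link{profile_segment}} result (scores included).
#' @param thresholds a \code{\link{threshold_config}}.
#' @param state logical per-residue assigned flags, or \code{NULL} for a
#'   fresh segment.
#' @return List with \code{annotations} (data frame: start, end,
#'   helix_type, handedness; segment-local 1-based indices) and updated
#'   \code{state}.
#' @export
assign_pi <- function(profile, thresholds = threshold_config(),
                      state = NULL) {
  pr <- profile$profile
  n <- profile$n
  b <- if (is.null(state)) rep(FALSE, n) else state
  th <- thresholds
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (!b[i] && .lt(pr$pi[i], th$pi_T) && .lt(.at(pr$a, i), th$a_I) &&
        .lt(.at(pr$a, i + 1L), th$a_I) && .lt(.at(pr$a, i + 2L), th$a_I)) {
      start <- i
      b[i] <- TRUE
      i <- i + 1L
      while (i <= n - 3L && !b[i] && .lt(pr$pi[i], th$pi_T)) {
        b[i] <- TRUE
        i <- i + 1L
      }
      end <- i - 1L
      for (j in i:min(i + 3L, n)) {
        if (j > n || b[j]) break
        b[j] <- TRUE
        end <- j
      }
      runs[[length(runs) + 1L]] <- c(start, end)
      i <- end + 1L
    } else i <- i + 1L
  }
  fl <- .filter_min_len(runs, 5L, b)
  list(annotations = .runs_df(fl$runs, "pi", profile$handedness),
       state = fl$b)
}

#' Assign 3-10 helices on one segment profile
#'
#' Second pass.  A 3-10 helix starts at an unassigned residue with g < g_T
#' and axis angle a < a_G, extends while g < g_T on unassigned residues,
#' and, when the seven-residue RMSDs of the two following residues both
#' fall below delta_G, claims those two further residues (clipped to the
#' segment and to unassigned residues).  Runs shorter than 3 residues are
#' discarded.
#'
#' @inheritParams assign_pi
#' @return As \code{\link{assign_pi}}.
#' @export
assign_310 <- function(profile, thresholds = threshold_config(),
                       state = NULL) {
  pr <- profile$profile
  n <- profile$n
  b <- if (is.null(state)) rep(FALSE, n) else state
  th <- thresholds
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (!b[i] && .lt(pr$g[i], th$g_T) && .lt(.at(pr$a, i), th$a_G)) {
      start <- i
      b[i] <- TRUE
      i <- i + 1L
      while (i <= n && !b[i] && .lt(pr$g[i], th$g_T)) {
        b[i] <- TRUE
        i <- i + 1L
      }
      end <- i - 1L
      if (.lt(.at(pr$small_delta, i), th$delta_G) &&
          .lt(.at(pr$small_delta, i + 1L), th$delta_G)) {
        for (j in i:min(i + 1L, n)) {
          if (j > n || b[j]) break
          b[j] <- TRUE
          end <- j
        }
      }
      runs[[length(runs) + 1L]] <- c(start, end)
      i <- end + 1L
    } else i <- i + 1L
  }
  fl <- .filter_min_len(runs, 3L, b)
  list(annotations = .runs_df(fl$runs, "310", profile$handedness),
       state = fl$b)
}

#' Assign alpha-helices on one segment profile
#'
#' Final pass.  An alpha-helix starts at an unassigned residue with
#' h < h_T, axis angle a < a_T and the next residue's h also below h_T; it
#' extends while h < h_T on unassigned residues.  The raw runs then pass
#' through \code{\link{merge_alpha}} and \code{\link{extend_alpha}}, and
#' final helices shorter than 4 residues are discarded.
#'
#' @inheritParams assign_pi
#' @return As \code{\link{assign_pi}}.
#' @export
assign_alpha <- function(profile, thresholds = threshold_config(),
                         state = NULL) {
  pr <- profile$profile
  n <- profile$n
  b <- if (is.null(state)) rep(FALSE, n) else state
  th <- thresholds
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (!b[i] && .lt(pr$h[i], th$h_T) && .lt(.at(pr$a, i), th$a_T) &&
        .lt(.at(pr$h, i + 1L), th$h_T)) {
      start <- i
      b[i] <- TRUE
      i <- i + 1L
      while (i <= n && !b[i] && .lt(pr$h[i], th$h_T)) {
        b[i] <- TRUE
        i <- i + 1L
      }
      runs[[length(runs) + 1L]] <- c(start, i - 1L)
    } else i <- i + 1L
  }
  mg <- merge_alpha(runs, profile, th, b)
  ex <- extend_alpha(mg$runs, profile, th, mg$state)
  fl <- .filter_min_len(ex$runs, 4L, ex$state)
  list(annotations = .runs_df(fl$runs, "alpha", profile$handedness),
       state = fl$b)
}

#' Merge adjacent alpha-helices across gentle bends
#'
#' Two alpha-helices separated by fewer than four residues merge (gap
#' included) when every intermediate residue is unassigned and has axis
#' angle a <= a_max, score h < h_max and seven-residue RMSD
#' delta < delta_max.  Merging is applied left to right and cascades.
#'
#' @param runs list of \code{c(start, end)} integer pairs, sequence-sorted.
#' @param profile a \code{\link{profile_segment}} result.
#' @param thresholds a \code{\link{threshold_config}}.
#' @param state logical assigned flags.
#' @return List with merged \code{runs} and updated \code{state}.
#' @export
merge_alpha <- function(runs, profile, thresholds = threshold_config(),
                        state = NULL) {
  pr <- profile$profile
  b <- if (is.null(state)) rep(FALSE, profile$n) else state
  th <- thresholds
  if (length(runs) < 2L) return(list(runs = runs, state = b))
  out <- list(runs[[1L]])
  for (k in 2:length(runs)) {
    cur <- out[[length(out)]]
    nxt <- runs[[k]]
    gap <- (cur[2L] + 1L):(nxt[1L] - 1L)
    if (nxt[1L] - cur[2L] <= 1L) gap <- integer()   # touching runs
    ok <- nxt[1L] - cur[2L] - 1L < 4L &&
      all(vapply(gap, function(i)
        !b[i] && .le(pr$a[i], th$a_max) && .lt(pr$h[i], th$h_max) &&
          .lt(pr$small_delta[i], th$delta_max), logical(1)))
    if (ok) {
      b[gap] <- TRUE
      out[[length(out)]] <- c(cur[1L], nxt[2L])
    } else out[[length(out) + 1L]] <- nxt
  }
  list(runs = out, state = b)
}

#' Extend alpha-helix C-termini
#'
#' After merging, an alpha-helix ending at residue j - 1 whose next residue
#' j is unassigned with h < h_max and axis angle a < a_max gains residues j
#' and j + 1 (each clipped to the segment end and to unassigned residues).
#'
#' @inheritParams merge_alpha
#' @return List with extended \code{runs} and updated \code{state}.
#' @export
extend_alpha <- function(runs, profile, thresholds = threshold_config(),
                         state = NULL) {
  pr <- profile$profile
  n <- profile$n
  b <- if (is.null(state)) rep(FALSE, n) else state
  th <- thresholds
  for (k in seq_along(runs)) {
    j <- runs[[k]][2L] + 1L
    if (j <= n && !b[j] && .lt(pr$h[j], th$h_max) &&
        .lt(pr$a[j], th$a_max)) {
      b[j] <- TRUE
      runs[[k]][2L] <- j
      j2 <- j + 1L
      if (j2 <= n && !b[j2]) {
        b[j2] <- TRUE
        runs[[k]][2L] <- j2
      }
    }
  }
  list(runs = runs, state = b)
}

#' Full helix assignment of one contiguous segment
#'
#' Orchestrates the sequential assignment: profiles the segment
#' right-handed and runs the pi, 3-10 and alpha passes (with merging and
#' C-terminal extension for alpha); then mirrors the coordinates,
#' re-profiles, and repeats the three passes on the still-unassigned
#' residues, emitting left-handed annotations.  A residue is never assigned
#' twice.  Segments shorter than 4 residues yield no annotations.
#'
#' @param xyz n x 3 C-alpha coordinate matrix of one contiguous segment.
#' @param grid a \code{\link{grid_spec}}.
#' @param classes class parameters, see \code{\link{default_class_params}}.
#' @param thresholds a \code{\link{threshold_config}}.
#' @param combiner score combiner, see \code{\link{helix_scores}}.
#' @param handedness_passes character vector controlling which passes run.
#' @return Data frame of annotations (start, end, helix_type, handedness;
#'   segment-local 1-based indices) sorted by start.
#' @export
assign_segment <- function(xyz, grid = grid_spec(),
                           classes = default_class_params(),
                           thresholds = threshold_config(),
                           combiner = c("sum", "product"),
                           handedness_passes = c("right", "left")) {
  combiner <- match.arg(combiner)
  xyz <- rbind(xyz)
  n <- nrow(xyz)
  empty <- .runs_df(list(), character(), character())
  if (n < 4L) return(empty)
  b <- rep(FALSE, n)
  out <- list(empty)
  for (hand in handedness_passes) {
    prof <- profile_segment(xyz, grid, hand, classes, combiner)
    for (pass in list(assign_pi, assign_310, assign_alpha)) {
      res <- pass(prof, thresholds, b)
      b <- res$state
      out[[length(out) + 1L]] <- res$annotations
    }
  }
  ann <- do.call(rbind, out)
  ann[order(ann$start), , drop = FALSE]
}
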