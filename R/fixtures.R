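#' Generate an ideal (optionally noise-perturbed) C-alpha trace
#'
#' Places \code{n_residues} points at integer parameters of a helical curve
#' and optionally adds isotropic Gaussian coordinate noise.  With
#' \code{noise_sigma = 0} the points lie exactly on the curve and the result
#' is deterministic; otherwise the supplied seed fully determines the draw
#' (the caller's RNG state is left untouched).
#'
#' @param curve a \code{\link{helical_curve}}.
#' @param n_residues number of C-alpha positions, \code{>= 1}.
#' @param noise_sigma isotropic Gaussian sigma per coordinate, Angstrom.
#' @param seed integer seed used when \code{noise_sigma > 0}.
#' @return \code{n_residues} x 3 coordinate matrix.
#' @examples
#' xyz <- generate_ideal_calphas(helical_curve(2.314, 1.516, 100.1), 10)
#' @export
generate_ideal_calphas <- function(curve, n_residues, noise_sigma = 0,
                                   seed = 1L) {
  stopifnot(inherits(curve, "helical_curve"),
            n_residues >= 1, noise_sigma >= 0)
  pts <- curve_point(curve, seq_len(n_residues) - 1)
  if (noise_sigma > 0) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
    pts <- pts + matrix(stats::rnorm(3L * n_residues, sd = noise_sigma),
                        ncol = 3L)
  }
  pts
}

## Parameters of an ideal extended strand (beta/E-like geometry) used as the
## non-helical flank in composite fixtures.
strand_curve <- function() helical_curve(0.96, 3.34, 177.9)

#' Standard curve for a helix class
#'
#' The curve whose (r, p, t) are the stored mean parameters of the given
#' class (the "standard protein helix" the scores are measured against).
#'
#' @param class one of \code{"alpha"}, \code{"310"}, \code{"pi"}.
#' @param handedness \code{"right"} or \code{"left"}.
#' @return A \code{\link{helical_curve}}.
#' @export
standard_curve <- function(class = c("alpha", "310", "pi"),
                           handedness = c("right", "left")) {
  class <- match.arg(class)
  handedness <- match.arg(handedness)
  cp <- default_class_params()[[class]]
  helical_curve(cp$mu_r, cp$mu_p, cp$mu_t, handedness = handedness)
}

## Rigidly append piece B after piece A so the junction Calpha-Calpha
## distance is `gap` along the continuation of A's last bond.
append_piece <- function(a, b, gap = 3.8) {
  if (is.null(a)) return(b)
  if (nrow(a) >= 2L) {
    dir <- a[nrow(a), ] - a[nrow(a) - 1L, ]
    dir <- dir / sqrt(sum(dir^2))
  } else dir <- c(1, 0, 0)
  shift <- a[nrow(a), ] + gap * dir - b[1L, ]
  rbind(a, sweep(b, 2L, shift, "+"))
}

#' Composite fixture: a helix embedded in extended-strand flanks
#'
#' Builds coil(n_flank) + helix(n_helix) + coil(n_flank), joining the pieces
#' at a 3.8 Angstrom C-alpha step, and records the planted helix range.
#' The flanks are ideal extended strands, whose fitted parameters are far
#' from every standard helix, so only the planted region should score as
#' helical.
#'
#' @param class helix class of the planted helix.
#' @param n_helix residues in the planted helix.
#' @param n_flank residues in each strand flank.
#' @param noise_sigma,seed passed to \code{\link{generate_ideal_calphas}}.
#' @param handedness handedness of the planted helix.
#' @return List with \code{xyz} (coordinate matrix), \code{helix_start},
#'   \code{helix_end} (1-based planted range) and \code{class}.
#' @export
make_helix_in_coil <- function(class = c("alpha", "310", "pi"),
                               n_helix = 12L, n_flank = 6L,
                               noise_sigma = 0, seed = 1L,
                               handedness = c("right", "left")) {
  class <- match.arg(class)
  handedness <- match.arg(handedness)
  helix <- generate_ideal_calphas(standard_curve(class, handedness),
                                  n_helix, noise_sigma, seed)
  flank <- generate_ideal_calphas(strand_curve(), n_flank, noise_sigma,
                                  seed + 1L)
  xyz <- append_piece(append_piece(flank, helix), flank)
  list(xyz = xyz, helix_start = n_flank + 1L, helix_end = n_flank + n_helix,
       class = class, handedness = handedness)
}

#' Composite fixture: two helices meeting at a kink
#'
#' Two ideal helices of the same class whose axes meet at a prescribed
#' angle, joined at a 3.8 Angstrom step.  Used to test that the axis-angle
#' restraints split (and the merge rule refuses to join) kinked helices.
#'
#' @param class helix class of both arms.
#' @param n_each residues per arm.
#' @param kink_deg angle between the two helix axes, degrees.
#' @param noise_sigma,seed passed to \code{\link{generate_ideal_calphas}}.
#' @return List with \code{xyz} and \code{junction} (index of the last
#'   residue of the first arm).
#' @export
make_kinked_pair <- function(class = c("alpha", "310", "pi"), n_each = 10L,
                             kink_deg = 60, noise_sigma = 0, seed = 1L) {
  class <- match.arg(class)
  arm1 <- generate_ideal_calphas(standard_curve(class), n_each,
                                 noise_sigma, seed)
  th <- kink_deg * pi / 180
  rot <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  cp <- default_class_params()[[class]]
  arm2curve <- helical_curve(cp$mu_r, cp$mu_p, cp$mu_t, rotation = rot)
  arm2 <- generate_ideal_calphas(arm2curve, n_each, noise_sigma, seed + 1L)
  xyz <- append_piece(arm1, arm2)
  list(xyz = xyz, junction = n_each, class = class)
}

#' Write a C-alpha-only PDB fixture file
#'
#' Serializes a coordinate matrix as CA ATOM records (residue type ALA,
#' chain \code{chain_id}, residues numbered from 1) preceded by REMARK lines
#' recording the generator provenance, so test oracles can recover planted
#' boundaries from the file alone.
#'
#' @param xyz n x 3 coordinate matrix.
#' @param file output path; when \code{NULL} the text is returned invisibly.
#' @param chain_id single chain identifier character.
#' @param remarks character vector of free-text provenance notes.
#' @return The PDB text, invisibly when written to a file.
#' @export
write_calpha_pdb <- function(xyz, file = NULL, chain_id = "A",
                             remarks = character()) {
  xyz <- rbind(xyz)
  stopifnot(ncol(xyz) == 3L, nchar(chain_id) == 1L)
  hdr <- sprintf("REMARK 999 %s", remarks)
  atoms <- sprintf(
    "ATOM  %5d  CA  ALA %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(nrow(xyz)), chain_id, seq_len(nrow(xyz)),
    xyz[, 1L], xyz[, 2L], xyz[, 3L], 1.0, 0.0)
  txt <- paste(c(hdr, atoms, "TER", "END"), collapse = "\n")
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}
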