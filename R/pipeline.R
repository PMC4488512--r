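#' Assign helices in a PDB file or parsed chain set
#'
#' End-to-end driver: reads C-alpha chains, splits them at geometric
#' breaks, profiles and assigns every segment of at least four residues
#' (right-handed passes, then left-handed on the remainder), and maps the
#' segment-local results back to author residue numbering.
#'
#' @param input path to a PDB file, PDB text, or the chain list returned by
#'   \code{\link{read_calpha_chains}}.
#' @param grid a \code{\link{grid_spec}}.
#' @param classes class parameters, see \code{\link{default_class_params}}.
#' @param thresholds a \code{\link{threshold_config}}.
#' @param combiner score combiner, see \code{\link{helix_scores}}.
#' @param handedness_passes which handedness passes to run.
#' @param break_window chain-break distance window in Angstrom.
#' @return List with \code{annotations} (data frame: chain_id, start_resno,
#'   start_icode, start_resname, end_resno, end_icode, end_resname,
#'   helix_type, handedness, length) and \code{profiles} (per-residue data
#'   frame: chain_id, resno, icode, r, p, t, delta, a, small_delta, h, g,
#'   pi, helix_type, handedness; right-handed pass values).
#' @examples
#' \dontrun{
#' res <- assign_helices("structure.pdb")
#' res$annotations
#' }
#' @export
assign_helices <- function(input, grid = grid_spec(),
                           classes = default_class_params(),
                           thresholds = threshold_config(),
                           combiner = c("sum", "product"),
                           handedness_passes = c("right", "left"),
                           break_window = c(2.5, 4.3)) {
  combiner <- match.arg(combiner)
  chains <- if (is.list(input) && !is.data.frame(input) &&
                all(vapply(input, inherits, logical(1), "calpha_chain")))
    input else read_calpha_chains(input)
  ann_list <- list()
  prof_list <- list()
  for (chain in chains) {
    cid <- attr(chain, "chain_id")
    for (seg in split_on_breaks(chain, break_window)) {
      n <- nrow(seg)
      xyz <- as.matrix(seg[, c("x", "y", "z")])
      ptype <- rep(NA_character_, n)
      phand <- rep(NA_character_, n)
      if (n >= 4L) {
        ann <- assign_segment(xyz, grid, classes, thresholds, combiner,
                              handedness_passes)
        if (nrow(ann)) {
          for (k in seq_len(nrow(ann))) {
            idx <- ann$start[k]:ann$end[k]
            ptype[idx] <- ann$helix_type[k]
            phand[idx] <- ann$handedness[k]
          }
          ann_list[[length(ann_list) + 1L]] <- data.frame(
            chain_id = cid,
            start_resno = seg$resno[ann$start],
            start_icode = seg$icode[ann$start],
            start_resname = seg$resname[ann$start],
            end_resno = seg$resno[ann$end],
            end_icode = seg$icode[ann$end],
            end_resname = seg$resname[ann$end],
            helix_type = ann$helix_type,
            handedness = ann$handedness,
            length = ann$end - ann$start + 1L,
            stringsAsFactors = FALSE)
        }
      }
      prof <- if (n >= 4L)
        profile_segment(xyz, grid, "right", classes, combiner)$profile
      else data.frame(index = seq_len(n), r = NA_real_, p = NA_real_,
                      t = NA_real_, delta = NA_real_, a = NA_real_,
                      small_delta = NA_real_, h = NA_real_, g = NA_real_,
                      pi = NA_real_)
      prof_list[[length(prof_list) + 1L]] <- data.frame(
        chain_id = cid, resno = seg$resno, icode = seg$icode,
        prof[, c("r", "p", "t", "delta", "a", "small_delta",
                 "h", "g", "pi")],
        helix_type = ptype, handedness = phand, stringsAsFactors = FALSE)
    }
  }
  list(annotations = if (length(ann_list)) do.call(rbind, ann_list)
       else data.frame(chain_id = character(), start_resno = integer(),
                       start_icode = character(),
                       start_resname = character(),
                       end_resno = integer(), end_icode = character(),
                       end_resname = character(), helix_type = character(),
                       handedness = character(), length = integer(),
                       stringsAsFactors = FALSE),
       profiles = do.call(rbind, prof_list))
}
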