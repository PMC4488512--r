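## Fixed-column field extraction from PDB coordinate records.
.pdb_field <- function(lines, from, to) substr(lines, from, to)

.pdb_num <- function(lines, from, to, what, lineno) {
  txt <- trimws(.pdb_field(lines, from, to))
  out <- suppressWarnings(as.numeric(txt))
  bad <- which(is.na(out) & nzchar(txt) | !nzchar(txt))
  if (length(bad))
    stop(sprintf("unparsable %s field at line %d: '%s'",
                 what, lineno[bad[1L]], lines[bad[1L]]), call. = FALSE)
  out
}

.water_resnames <- c("HOH", "DOD", "WAT", "SOL")

#' Read C-alpha chains from a PDB-format file
#'
#' Extracts one C-alpha per residue from ATOM/HETATM records of the first
#' model, grouped by chain identifier in file order.  Alternate locations
#' are resolved by highest occupancy, ties by lowest altloc letter.
#' HETATM C-alpha records of modified amino acids (e.g. MSE) are retained;
#' waters and non-carbon "CA" atoms (calcium ions) are ignored.
#'
#' @param file path to a PDB-format file, or a character vector of lines.
#' @return Named list of \code{"calpha_chain"} data frames (columns
#'   \code{resno}, \code{icode}, \code{resname}, \code{x}, \code{y},
#'   \code{z}, \code{occ}; attribute \code{chain_id}), one per chain.
#' @export
read_calpha_chains <- function(file) {
  lines <- if (length(file) == 1L && !grepl("\n", file) && file.exists(file))
    readLines(file) else unlist(strsplit(file, "\n", fixed = TRUE))
  endmdl <- which(.pdb_field(lines, 1, 6) == "ENDMDL")
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1L] - 1L)]
  rec <- .pdb_field(lines, 1, 6)
  sel <- which(rec == "ATOM  " | rec == "HETATM")
  al <- lines[sel]
  name <- trimws(.pdb_field(al, 13, 16))
  elem <- trimws(.pdb_field(al, 77, 78))
  resname <- trimws(.pdb_field(al, 18, 20))
  keep <- name == "CA" & (elem == "" | elem == "C") &
    !(resname %in% .water_resnames) & resname != "CA"
  if (!any(keep))
    stop("no C-alpha records found in input", call. = FALSE)
  al <- al[keep]
  lineno <- sel[keep]
  df <- data.frame(
    chain = .pdb_field(al, 22, 22),
    resno = as.integer(.pdb_num(al, 23, 26, "residue number", lineno)),
    icode = .pdb_field(al, 27, 27),
    resname = trimws(.pdb_field(al, 18, 20)),
    alt = .pdb_field(al, 17, 17),
    x = .pdb_num(al, 31, 38, "x coordinate", lineno),
    y = .pdb_num(al, 39, 46, "y coordinate", lineno),
    z = .pdb_num(al, 47, 54, "z coordinate", lineno),
    occ = {
      occtxt <- trimws(.pdb_field(al, 55, 60))
      o <- suppressWarnings(as.numeric(occtxt))
      o[is.na(o)] <- 1.0
      pmin(pmax(o, 0), 1)
    },
    stringsAsFactors = FALSE)
  ## altloc resolution per (chain, resno, icode): highest occupancy, ties to
  ## the lowest altloc letter (blank sorts lowest); file order preserved.
  key <- paste(df$chain, df$resno, df$icode, sep = "\r")
  ord <- order(match(key, unique(key)), -df$occ, df$alt)
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(paste(df$chain, df$resno, df$icode, sep = "\r")), ,
           drop = FALSE]
  lapply(split(df, factor(df$chain, levels = unique(df$chain))),
         function(cd) {
           out <- cd[, c("resno", "icode", "resname", "x", "y", "z", "occ")]
           rownames(out) <- NULL
           attr(out, "chain_id") <- cd$chain[1L]
           class(out) <- c("calpha_chain", "data.frame")
           out
         })
}

#' Split a C-alpha chain at geometric breaks
#'
#' Returns the maximal contiguous runs whose consecutive C-alpha--C-alpha
#' distances all lie inside the window (default 2.5--4.3 Angstrom, covering
#' trans and cis peptides).  Segments shorter than 4 residues are still
#' returned; assignment simply skips them.  Numbering gaps alone do not
#' split: distance is the authority.
#'
#' @param chain a \code{"calpha_chain"} from \code{\link{read_calpha_chains}}.
#' @param window length-2 numeric \code{c(min_d, max_d)} in Angstrom.
#' @return List of \code{"calpha_chain"} segments (chain_id preserved);
#'   their concatenation reproduces the input residue sequence.
#' @export
split_on_breaks <- function(chain, window = c(2.5, 4.3)) {
  stopifnot(inherits(chain, "calpha_chain"), length(window) == 2L,
            window[1] < window[2])
  n <- nrow(chain)
  if (n <= 1L) return(list(chain))
  xyz <- as.matrix(chain[, c("x", "y", "z")])
  d <- sqrt(rowSums(diff(xyz)^2))
  brk <- which(d < window[1] | d > window[2])
  starts <- c(1L, brk + 1L)
  ends <- c(brk, n)
  lapply(seq_along(starts), function(k) {
    seg <- chain[starts[k]:ends[k], , drop = FALSE]
    rownames(seg) <- NULL
    attr(seg, "chain_id") <- attr(chain, "chain_id")
    class(seg) <- c("calpha_chain", "data.frame")
    seg
  })
}

## PDB v3.3 helixClass codes used on output.
.helix_class_code <- function(type, handedness) {
  key <- paste(handedness, type)
  code <- c("right alpha" = 1L, "right pi" = 3L, "right 310" = 5L,
            "left alpha" = 6L, "left 310" = 8L, "left pi" = 10L)[key]
  if (any(is.na(code))) stop("unknown helix type/handedness combination")
  unname(code)
}

#' Serialize helix annotations (and optionally per-residue profiles)
#'
#' Three styles: \code{"tsv"} writes one row per profiled residue (chain,
#' resno, icode, h, g, pi, a, delta, small_delta, assigned type,
#' handedness); \code{"json"} writes machine-readable annotations together
#' with an echo of the configuration; \code{"helix-records"} writes
#' column-exact PDB HELIX lines (class 1 right alpha, 3 right pi, 5 right
#' 3-10, 6 left alpha, 8 left 3-10, 10 left pi).
#'
#' @param annotations data frame with columns \code{chain_id},
#'   \code{start_resno}, \code{start_icode}, \code{start_resname},
#'   \code{end_resno}, \code{end_icode}, \code{end_resname},
#'   \code{helix_type}, \code{handedness}; must be non-overlapping per
#'   chain.
#' @param profiles optional per-residue data frame (columns \code{chain_id},
#'   \code{resno}, \code{icode}, \code{h}, \code{g}, \code{pi}, \code{a},
#'   \code{delta}, \code{small_delta}, \code{helix_type},
#'   \code{handedness}); required for \code{style = "tsv"}.
#' @param style one of \code{"tsv"}, \code{"json"}, \code{"helix-records"}.
#' @param config optional list echoed into the JSON output.
#' @return A single character string (the document text).
#' @export
write_assignments <- function(annotations, profiles = NULL,
                              style = c("tsv", "json", "helix-records"),
                              config = NULL) {
  style <- match.arg(style)
  .check_no_overlap(annotations)
  if (style == "tsv") {
    stopifnot(!is.null(profiles))
    hdr <- paste(c("chain", "resno", "icode", "h", "g", "pi", "a", "delta",
                   "small_delta", "type", "handedness"), collapse = "\t")
    fmtn <- function(x) ifelse(is.na(x), "NA", sprintf("%.6g", x))
    rows <- sprintf("%s\t%d\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s",
                    profiles$chain_id, profiles$resno,
                    ifelse(profiles$icode == " " | profiles$icode == "",
                           ".", profiles$icode),
                    fmtn(profiles$h), fmtn(profiles$g), fmtn(profiles$pi),
                    fmtn(profiles$a), fmtn(profiles$delta),
                    fmtn(profiles$small_delta),
                    ifelse(is.na(profiles$helix_type), ".",
                           profiles$helix_type),
                    ifelse(is.na(profiles$handedness), ".",
                           profiles$handedness))
    return(paste(c(hdr, rows), collapse = "\n"))
  }
  if (style == "json") {
    obj <- list(annotations = annotations,
                config = if (is.null(config)) default_config_echo()
                         else config)
    return(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE,
                                         digits = NA, null = "null")))
  }
  ## helix-records
  if (!nrow(annotations)) return("")
  lines <- vapply(seq_len(nrow(annotations)), function(k) {
    a <- annotations[k, ]
    len <- a$length
    if (is.null(len) || is.na(len)) len <- a$end_resno - a$start_resno + 1L
    sprintf("HELIX  %3d %3s %3s %1s %4d%1s %3s %1s %4d%1s%2d%30s %5d",
            k, sprintf("%d", k %% 1000L),
            a$start_resname, a$chain_id, a$start_resno,
            .blank1(a$start_icode),
            a$end_resname, a$chain_id, a$end_resno, .blank1(a$end_icode),
            .helix_class_code(a$helix_type, a$handedness), "", len)
  }, character(1))
  paste(lines, collapse = "\n")
}

.blank1 <- function(x) if (is.na(x) || x == "" ) " " else substr(x, 1, 1)

.check_no_overlap <- function(annotations) {
  if (!nrow(annotations)) return(invisible(TRUE))
  for (ch in unique(annotations$chain_id)) {
    a <- annotations[annotations$chain_id == ch, , drop = FALSE]
    a <- a[order(a$start_resno, a$start_icode), , drop = FALSE]
    if (nrow(a) > 1L &&
        any(a$start_resno[-1L] <= a$end_resno[-nrow(a)]))
      stop("overlapping annotations in chain ", ch, call. = FALSE)
  }
  invisible(TRUE)
}

## Registry of all method constants, echoed into JSON output.
default_config_echo <- function() {
  list(grid = unclass(grid_spec()),
       thresholds = unclass(threshold_config()),
       classes = lapply(default_class_params(), unclass),
       break_window = c(2.5, 4.3), combiner = "sum")
}

#' Strict column reader for PDB HELIX records
#'
#' Re-parses HELIX lines written by \code{\link{write_assignments}} (or any
#' PDB v3.3 file) using fixed columns only.
#'
#' @param text character scalar or vector of lines.
#' @return Data frame with chain_id, start/end residue identifiers, helix
#'   class code and length.
#' @export
read_helix_records <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  hl <- lines[.pdb_field(lines, 1, 6) == "HELIX "]
  data.frame(
    serial = as.integer(trimws(.pdb_field(hl, 8, 10))),
    start_resname = trimws(.pdb_field(hl, 16, 18)),
    chain_id = .pdb_field(hl, 20, 20),
    start_resno = as.integer(trimws(.pdb_field(hl, 22, 25))),
    start_icode = .pdb_field(hl, 26, 26),
    end_resname = trimws(.pdb_field(hl, 28, 30)),
    end_chain_id = .pdb_field(hl, 32, 32),
    end_resno = as.integer(trimws(.pdb_field(hl, 34, 37))),
    end_icode = .pdb_field(hl, 38, 38),
    helix_class = as.integer(trimws(.pdb_field(hl, 39, 40))),
    length = as.integer(trimws(.pdb_field(hl, 72, 76))),
    stringsAsFactors = FALSE)
}

#' Re-read annotations written as JSON
#'
#' @param text JSON document produced by \code{\link{write_assignments}}.
#' @return Data frame of annotations.
#' @export
read_assignments_json <- function(text) {
  obj <- jsonlite::fromJSON(text)
  ann <- obj$annotations
  if (is.null(ann) || !length(ann))
    return(data.frame())
  as.data.frame(ann, stringsAsFactors = FALSE)
}
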