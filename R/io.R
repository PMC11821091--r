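## Readers and writers for the fixed-column GRO dialect (multi-frame files
## are concatenated blocks) and for plain XYZ.  GRO positions are nm; XYZ is
## Angstrom and converted on read.

#' Read a (multi-frame) GRO coordinate file
#'
#' Parses the fixed-column GROMACS coordinate format.  Velocities, when
#' present, are ignored.  Multi-frame files are read as concatenated
#' title/count/records/box blocks.  Frame times are taken from a
#' `t= <ps>` token in the title line, defaulting to the frame ordinal when
#' absent.
#'
#' @param path path to the file.
#' @param multi_frame read all concatenated frames (default) or just the
#'   first.
#' @return a [trajectory()] with coordinates in nm.  Masses are inferred
#'   from atom names (override them with [assign_species()]).
#' @export
read_gro <- function(path, multi_frame = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  frames <- list()
  topo <- NULL
  i <- 1L
  frame_no <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    title <- lines[i]
    if (i + 1L > length(lines))
      stop("truncated GRO frame: missing atom-count line after line ", i)
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat) || nat < 1)
      stop("bad atom-count line at line ", i + 1L, ": '", lines[i + 1L], "'")
    last_rec <- i + 1L + nat
    if (last_rec + 1L > length(lines))
      stop("truncated GRO frame: expected ", nat,
           " atom records plus a box line, file ends at line ", length(lines))
    rec <- lines[(i + 2L):last_rec]
    parsed <- parse_gro_records(rec, first_line = i + 2L)
    boxline <- strsplit(trimws(lines[last_rec + 1L]), "\\s+")[[1]]
    box <- suppressWarnings(as.numeric(boxline))
    if (any(is.na(box)) || !(length(box) %in% c(3L, 9L)))
      stop("bad box line at line ", last_rec + 1L,
           " (is the atom count on line ", i + 1L, " correct?)")
    if (length(box) == 9L) {
      if (any(abs(box[4:9]) > 1e-9))
        stop("unsupported format: triclinic box (non-zero off-diagonals) ",
             "at line ", last_rec + 1L, "; only orthorhombic boxes are supported")
      box <- box[1:3]
    }
    frame_no <- frame_no + 1L
    tm <- gro_title_time(title)
    if (is.na(tm)) tm <- frame_no - 1
    if (is.null(topo)) {
      topo <- topology(parsed$atom_name, parsed$residue_name, parsed$residue_id)
    } else if (nrow(topo) != nat) {
      stop("frame ", frame_no, " atom count (", nat,
           ") differs from first frame (", nrow(topo), ")")
    }
    frames[[frame_no]] <- md_frame(parsed$coords, box = box, time = tm)
    i <- last_rec + 2L
    if (!multi_frame) break
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  if (frame_no == 0L) stop("no frames found in ", path)
  trajectory(topo, frames)
}

parse_gro_records <- function(rec, first_line) {
  resid <- suppressWarnings(as.integer(substr(rec, 1, 5)))
  resname <- trimws(substr(rec, 6, 10))
  aname <- trimws(substr(rec, 11, 15))
  x <- suppressWarnings(as.numeric(substr(rec, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(rec, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(rec, 37, 44)))
  bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z) |
                 !nzchar(resname) | !nzchar(aname))
  if (length(bad))
    stop("cannot parse GRO atom record at line ", first_line + bad[1] - 1L,
         ": '", rec[bad[1]], "' (atom-count line may be inconsistent)")
  list(residue_id = resid, residue_name = resname, atom_name = aname,
       coords = cbind(x, y, z))
}

gro_title_time <- function(title) {
  m <- regmatches(title, regexpr("t\\s*=\\s*[-0-9.eE+]+", title))
  if (!length(m)) return(NA_real_)
  suppressWarnings(as.numeric(sub("t\\s*=\\s*", "", m)))
}

#' Write a trajectory as a (multi-frame) GRO file
#'
#' Positions are printed in the fixed `%8.3f` dialect (nm, three decimals);
#' each frame becomes one concatenated block.
#'
#' @param traj a [trajectory()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gro <- function(traj, path) {
  if (!inherits(traj, "trajectory") || n_frames(traj) < 1)
    stop("write_gro needs a non-empty trajectory")
  topo <- traj$topology
  con <- file(path, "w")
  on.exit(close(con))
  for (f in traj$frames) {
    if (is.null(f$box))
      stop("cannot write a GRO frame without a box")
    writeLines(sprintf("micellr frame t= %g", f$time), con)
    writeLines(sprintf("%5d", nrow(topo)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       topo$residue_id %% 100000L,
                       substr(topo$residue_name, 1, 5),
                       substr(topo$atom_name, 1, 5),
                       (topo$index + 1L) %% 100000L,
                       f$coords[, 1], f$coords[, 2], f$coords[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", f$box[1], f$box[2], f$box[3]), con)
  }
  invisible(path)
}

#' Read an XYZ coordinate file
#'
#' Standard XYZ: count line, comment, then `element x y z` in Angstrom.
#' Coordinates are converted to nm.  XYZ carries no box; provide one through
#' `box` or downstream periodic analyses will refuse the frames.  A comment
#' line containing `t= <ps>` sets the frame time.
#'
#' @param path path to the file.
#' @param box optional orthorhombic edge lengths in nm applied to every
#'   frame.
#' @return a [trajectory()] in nm.
#' @export
read_xyz <- function(path, box = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  frames <- list(); topo <- NULL
  i <- 1L; frame_no <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1)
      stop("bad XYZ count line at line ", i, ": '", lines[i], "'")
    if (i + 1L + nat > length(lines))
      stop("XYZ count line at line ", i, " announces ", nat,
           " atoms but the file ends at line ", length(lines))
    comment <- lines[i + 1L]
    rec <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(rec), "\\s+")
    nt <- lengths(toks)
    if (any(nt < 4))
      stop("cannot parse XYZ record at line ", i + 1L + which(nt < 4)[1])
    el <- vapply(toks, `[[`, character(1), 1L)
    xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
    if (any(is.na(xyz)))
      stop("non-numeric coordinates in XYZ block starting at line ", i)
    frame_no <- frame_no + 1L
    tm <- gro_title_time(comment)
    if (is.na(tm)) tm <- frame_no - 1
    if (is.null(topo)) {
      topo <- topology(el, residue_name = el, residue_id = seq_along(el))
    } else if (nrow(topo) != nat) {
      stop("XYZ frame ", frame_no, " atom count differs from first frame")
    }
    frames[[frame_no]] <- md_frame(xyz / 10, box = box, time = tm)
    i <- i + 2L + nat
  }
  if (frame_no == 0L) stop("no frames found in ", path)
  trajectory(topo, frames)
}
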