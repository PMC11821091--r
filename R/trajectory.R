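## Core data model: topologies, frames, trajectories, periodic-boundary
## geometry.  All lengths are in nm internally; Angstrom appears only in
## report writers.

#' Construct a topology table
#'
#' A topology is a data frame with one row per atom, in file order.  Masses
#' default to an element guess from the first alphabetic character of the
#' atom name (H, C, N, O, S, P, F, K); a species map can override them.
#'
#' @param atom_name character vector of atom names.
#' @param residue_name character vector of residue names.
#' @param residue_id integer vector; atoms sharing a residue_id form one
#'   molecule.
#' @param mass atomic masses in amu, or `NA` to infer from `atom_name`.
#' @param species species category per atom, one of
#'   `c("Surf","Ch","Cl","HBD","CounterIon","Other")` or `NA` (unassigned).
#' @param site_role optional site role per atom (`"head"`, `"tail"`,
#'   `"bend_center"`, `"donor_heavy"`, `"donor_hydrogen"`, `"acceptor"`,
#'   `"none"`).
#' @return a `data.frame` with columns `index` (0-based, unique), `atom_name`,
#'   `residue_name`, `residue_id`, `mass`, `species`, `site_role`.
#' @export
topology <- function(atom_name, residue_name, residue_id,
                     mass = NA_real_, species = NA_character_,
                     site_role = NA_character_) {
  n <- length(atom_name)
  residue_name <- rep_len(residue_name, n)
  residue_id <- rep_len(residue_id, n)
  mass <- rep_len(as.numeric(mass), n)
  miss <- is.na(mass)
  if (any(miss)) mass[miss] <- infer_mass(atom_name[miss])
  if (any(!is.finite(mass) | mass <= 0))
    stop("all atom masses must be positive and finite")
  data.frame(
    index = seq_len(n) - 1L,
    atom_name = as.character(atom_name),
    residue_name = as.character(residue_name),
    residue_id = as.integer(residue_id),
    mass = mass,
    species = rep_len(as.character(species), n),
    site_role = rep_len(as.character(site_role), n),
    stringsAsFactors = FALSE
  )
}

# Element masses keyed on the first alphabetic character of the atom name.
# Deliberately small: coordinate files rarely carry more context, and the
# species map can override any atom.
.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     S = 32.06, P = 30.974, F = 18.998, K = 39.098,
                     B = 10.81, I = 126.904)

infer_mass <- function(atom_name) {
  first <- toupper(sub("^[^A-Za-z]*([A-Za-z]).*$", "\\1", atom_name))
  m <- unname(.element_masses[first])
  m[is.na(m)] <- 12.011   # unknown elements fall back to carbon
  # common two-letter ions written in all caps in GRO files
  up <- toupper(atom_name)
  m[grepl("^CL", up)] <- 35.45
  m[grepl("^NA\\+?$", up)] <- 22.990
  m[grepl("^BR", up)] <- 79.904
  m
}

#' Construct a single coordinate frame
#'
#' @param coords numeric matrix, one row per atom, columns x/y/z in nm.
#' @param box orthorhombic box edge lengths in nm (length 3, all > 0), or
#'   `NULL` when no box is known (analyses that need periodic boundaries
#'   will refuse such frames).
#' @param time frame time in ps (>= 0).
#' @return an object of class `"md_frame"`.
#' @export
md_frame <- function(coords, box = NULL, time = 0) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must have 3 columns")
  storage.mode(coords) <- "double"
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
      stop("box must be 3 positive edge lengths (nm)")
  }
  structure(list(coords = coords, box = box, time = as.numeric(time)),
            class = "md_frame")
}

#' Construct a trajectory
#'
#' @param topology a topology data frame (see [topology()]).
#' @param frames list of frames (see [md_frame()]); times must be strictly
#'   increasing and each frame must have one coordinate row per atom.
#' @return an object of class `"trajectory"`.
#' @export
trajectory <- function(topology, frames) {
  if (length(frames) < 1) stop("a trajectory needs at least one frame")
  n <- nrow(topology)
  for (f in frames)
    if (nrow(f$coords) != n)
      stop("frame coordinate count (", nrow(f$coords),
           ") does not match topology atom count (", n, ")")
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  structure(list(topology = topology, frames = frames), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", nrow(x$topology), "atoms,", length(x$frames), "frame(s)\n")
  cat("  residues:", paste(unique(x$topology$residue_name), collapse = " "), "\n")
  b <- x$frames[[1]]$box
  if (!is.null(b))
    cat("  box (frame 1):", paste(format(b, digits = 4), collapse = " x "), "nm\n")
  invisible(x)
}

#' Number of frames / atoms
#' @param traj a trajectory.
#' @return integer count.
#' @export
n_frames <- function(traj) length(traj$frames)

#' @rdname n_frames
#' @export
n_atoms <- function(traj) nrow(traj$topology)

#' Minimum-image displacement under an orthorhombic periodic box
#'
#' Returns the displacement b - a with every component wrapped into the
#' half-open interval (-L/2, L/2].  The exact boundary maps to +L/2, which
#' makes the wrap deterministic for constructed geometries.
#'
#' @param a,b points (length-3 vectors) or n x 3 matrices, nm.
#' @param box orthorhombic edge lengths, nm, all > 0.
#' @return displacement(s), same shape as the broadcast of `a` against `b`.
#' @export
minimum_image <- function(a, b, box) {
  box <- as.numeric(box)
  if (length(box) != 3 || any(box <= 0)) stop("box must be 3 positive edges")
  a <- rbind_coords(a); b <- rbind_coords(b)
  d <- sweep_diff(b, a)
  for (k in 1:3)
    d[, k] <- d[, k] - box[k] * ceiling(d[, k] / box[k] - 0.5)
  if (nrow(d) == 1) drop(d) else d
}

rbind_coords <- function(x) {
  if (is.null(dim(x))) matrix(as.numeric(x), ncol = 3) else as.matrix(x)
}

sweep_diff <- function(b, a) {
  if (nrow(a) == nrow(b)) return(b - a)
  if (nrow(a) == 1) return(sweep(b, 2, a[1, ]))
  if (nrow(b) == 1) return(sweep(-a, 2, -b[1, ]))
  stop("incompatible shapes for minimum_image")
}

#' Wrap absolute positions into the primary box [0, L)
#' @param x n x 3 matrix or length-3 vector of positions, nm.
#' @param box edge lengths, nm.
#' @return wrapped positions, same shape.
#' @export
wrap_positions <- function(x, box) {
  m <- rbind_coords(x)
  for (k in 1:3) m[, k] <- m[, k] - box[k] * floor(m[, k] / box[k])
  if (is.null(dim(x))) drop(m) else m
}

#' Make a selection whole across periodic boundaries
#'
#' Translates every selected atom by box multiples so that it sits at its
#' minimum-image position relative to a reference point, chosen as the
#' circular-mean centre of the selection (each axis mapped to an angle on
#' a circle of circumference L and averaged).  Unlike referencing a
#' single atom, this is robust for compact objects of any diameter up to
#' the box edge: micelles that straddle the boundary become whole, and
#' all shape math runs on whole selections.
#'
#' @param coords full n x 3 coordinate matrix, nm.
#' @param sel integer indices (1-based) of the selection.
#' @param box edge lengths, nm.
#' @return the coordinates of the selection (length(sel) x 3), made whole.
#' @export
make_whole <- function(coords, sel, box) {
  x <- coords[sel, , drop = FALSE]
  ref <- circular_mean_point(x, box)
  disp <- rbind_coords(minimum_image(ref, x, box))
  sweep(disp, 2, ref, `+`)
}

# Per-axis circular mean: treat positions as angles on a circle of
# circumference L; the resulting point is a translation-consistent centre
# estimate even when the selection wraps around the boundary.
circular_mean_point <- function(x, box) {
  vapply(1:3, function(k) {
    th <- 2 * pi * x[, k] / box[k]
    a <- atan2(mean(sin(th)), mean(cos(th)))
    (a %% (2 * pi)) * box[k] / (2 * pi)
  }, numeric(1))
}
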