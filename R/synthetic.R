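## Synthetic inputs with known ground truth for every analysis stage:
## ellipsoidal micelles built from radial surfactant chains, analytic
## ellipsoid point clouds, Brownian trajectories with known D, constructed
## hydrogen-bond geometries, and harmonic free-energy ladders with a
## closed-form total.  Every generator is a pure function of (spec, seed)
## and attaches its ground truth to the returned object.

# Run code under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

# Quasi-uniform directions on the unit sphere (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Default surfactant chain template
#'
#' A 13-site dodecyl-sulfate-like chain: an S1 head group (96 amu) on the
#' micelle surface and twelve CH2/CH3 carbons at radial offsets decreasing
#' in 0.12 nm steps, giving a head-to-tail span of about 1.45 nm.  The
#' middle carbon C6 is marked as the bend centre.
#'
#' @return data frame with columns `label`, `offset` (nm, strictly
#'   decreasing), `mass` (amu), `role`.
#' @export
default_chain_sites <- function() {
  labels <- c("S1", paste0("C", 1:12))
  offsets <- c(2.0, seq(1.87, by = -0.12, length.out = 12))
  masses <- c(96.06, rep(14.027, 11), 15.035)
  role <- c("head", rep("none", 11), "tail")
  role[labels == "C6"] <- "bend_center"
  data.frame(label = labels, offset = offsets, mass = masses, role = role,
             stringsAsFactors = FALSE)
}

#' Build a synthetic micelle of radial surfactant chains
#'
#' Places `n_surfactants` chains on quasi-uniform (Fibonacci) directions
#' mapped to the ellipsoid with the given semi-axes, heads outward and
#' tails inward, mirroring how spherical micelles of 60 or 120 surfactants
#' are constructed for simulation.  Each chain runs inward from its head
#' along the local radial direction; an optional bend at the chain's
#' bend-centre site turns the tail segment by the prescribed angle.
#' Isotropic Gaussian jitter perturbs every site; a chain whose head would
#' no longer be the outermost site is redrawn, so "head radius > every tail
#' radius" holds by construction.
#'
#' @param n_surfactants number of chains (> 0), e.g. 60 or 120.
#' @param semi_axes ellipsoid semi-axes (a, b, c) in nm, a >= b >= c > 0.
#' @param chain_sites site table as from [default_chain_sites()]; offsets
#'   must be strictly decreasing head to tail and no larger than the
#'   geometric-mean semi-axis.
#' @param jitter Gaussian jitter standard deviation per coordinate (nm).
#' @param bend_angle angle (degrees) formed at the bend-centre site between
#'   the head and tail segments; 180 = straight chain.
#' @param seed RNG seed; identical inputs give identical output.
#' @return a one-frame [trajectory()] centred in a cubic box with >= 1 nm
#'   margin.  Atoms carry species `"Surf"` and head/tail/bend_center site
#'   roles; the generation spec is attached as the `"micelle_spec"`
#'   attribute.
#' @export
build_micelle <- function(n_surfactants, semi_axes = c(2, 2, 2),
                          chain_sites = default_chain_sites(),
                          jitter = 0, bend_angle = 180, seed = 1L) {
  stopifnot(n_surfactants > 0, length(semi_axes) == 3, all(semi_axes > 0),
            jitter >= 0, bend_angle > 0, bend_angle <= 180)
  if (is.unsorted(rev(semi_axes))) stop("semi-axes must satisfy a >= b >= c")
  off <- chain_sites$offset
  if (any(diff(off) >= 0))
    stop("chain site offsets must be strictly decreasing from head to tail")
  r0 <- prod(semi_axes)^(1 / 3)
  if (max(off) > r0 + 1e-12)
    stop("chain offsets exceed the semi-axes: max offset ", max(off),
         " nm > geometric-mean semi-axis ", signif(r0, 4), " nm")
  ns <- nrow(chain_sites)
  dirs <- fibonacci_sphere(n_surfactants)
  bend_idx <- which(chain_sites$role == "bend_center")
  if (length(bend_idx) > 1) stop("at most one bend_center site")
  theta <- bend_angle * pi / 180
  coords <- with_seed(seed, {
    out <- matrix(NA_real_, n_surfactants * ns, 3)
    for (i in seq_len(n_surfactants)) {
      for (attempt in 1:100) {
        anchor <- dirs[i, ] * semi_axes          # point on the ellipsoid
        u <- anchor / sqrt(sum(anchor^2))        # outward radial direction
        head_pos <- anchor * (off[1] / r0)
        tpar <- off[1] - off                     # arc-length from head
        chain <- sweep(-outer(tpar, u), 2, head_pos, `+`)  # straight inward run
        if (length(bend_idx) == 1 && bend_angle < 180 && bend_idx < ns) {
          p <- random_perpendicular(u)
          v2 <- cos(theta) * u + sin(theta) * p
          after <- seq.int(bend_idx + 1L, ns)
          chain[after, ] <- matrix(chain[bend_idx, ], length(after), 3,
                                   byrow = TRUE) +
            outer(tpar[after] - tpar[bend_idx], v2)
        }
        if (jitter > 0)
          chain <- chain + matrix(stats::rnorm(ns * 3, sd = jitter), ns, 3)
        radii <- sqrt(rowSums(chain^2))
        if (radii[1] > max(radii[-1])) break
        if (attempt == 100)
          stop("could not place chain ", i, " with head outermost; ",
               "reduce jitter or the bend")
      }
      out[(i - 1) * ns + seq_len(ns), ] <- chain
    }
    out
  })
  edge <- 2 * (max(sqrt(rowSums(coords^2))) + 1)
  box <- rep(ceiling(edge * 10) / 10, 3)
  coords <- sweep(coords, 2, box / 2, `+`)
  topo <- topology(
    atom_name = rep(chain_sites$label, n_surfactants),
    residue_name = "SUR",
    residue_id = rep(seq_len(n_surfactants), each = ns),
    mass = rep(chain_sites$mass, n_surfactants),
    species = "Surf",
    site_role = rep(chain_sites$role, n_surfactants))
  traj <- trajectory(topo, list(md_frame(coords, box = box, time = 0)))
  attr(traj, "micelle_spec") <- list(
    n_surfactants = n_surfactants, semi_axes = semi_axes, jitter = jitter,
    bend_angle = bend_angle, seed = seed)
  traj
}

# A unit vector perpendicular to u, rotated by a random angle about u.
random_perpendicular <- function(u) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p1 <- a - sum(a * u) * u
  p1 <- p1 / sqrt(sum(p1^2))
  p2 <- c(u[2] * p1[3] - u[3] * p1[2],
          u[3] * p1[1] - u[1] * p1[3],
          u[1] * p1[2] - u[2] * p1[1])
  phi <- stats::runif(1, 0, 2 * pi)
  cos(phi) * p1 + sin(phi) * p2
}

#' Uniform point cloud on or in an ellipsoid
#'
#' Analytic shape standard for the shape descriptors.  `mode = "solid"`
#' samples uniformly inside the ellipsoid (for a 2:1:1 solid the
#' population eccentricity is exactly 0.5); `mode = "shell"` samples the
#' surface (exactly uniform for a sphere, where Rg -> R).
#'
#' @param semi_axes (a, b, c) in nm.
#' @param n_points number of points (>= 4).
#' @param mode `"shell"` or `"solid"`.
#' @param seed RNG seed.
#' @return an `md_frame` centred at the origin with a generous box;
#'   points are unit-mass.
#' @export
ellipsoid_cloud <- function(semi_axes, n_points, mode = c("solid", "shell"),
                            seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_points >= 4, length(semi_axes) == 3, all(semi_axes > 0))
  pts <- with_seed(seed, {
    g <- matrix(stats::rnorm(n_points * 3), n_points, 3)
    g <- g / sqrt(rowSums(g^2))
    if (mode == "solid")
      g <- g * stats::runif(n_points)^(1 / 3)
    sweep(g, 2, semi_axes, `*`)
  })
  md_frame(pts, box = rep(4 * max(semi_axes), 3), time = 0)
}

#' Brownian (random-walk) trajectory with known diffusion coefficient
#'
#' Each particle takes independent Gaussian steps of per-axis variance
#' 2 * D * dt, so the ensemble MSD is exactly 6 * D * t in expectation.
#' Frames store box-wrapped positions; the unwrapped positions (the MSD
#' ground truth) ride along in the `unwrapped` element of the returned
#' trajectory.
#'
#' @param n_particles number of independent walkers.
#' @param d_true diffusion coefficient, nm^2/ps (> 0, or 0 for a frozen
#'   system).
#' @param dt frame spacing, ps.
#' @param n_steps number of steps (> 1); the trajectory has n_steps + 1
#'   frames.
#' @param box cubic or orthorhombic box edges, nm.
#' @param seed RNG seed.
#' @return a [trajectory()] with `d_true` attached as attribute
#'   `"d_true"` and unwrapped coordinates in `$unwrapped` (list of
#'   matrices, one per frame).
#' @export
brownian_trajectory <- function(n_particles, d_true, dt = 1, n_steps = 100,
                                box = c(10, 10, 10), seed = 1L) {
  stopifnot(n_particles > 0, d_true >= 0, dt > 0, n_steps > 1,
            all(box > 0))
  box <- rep_len(as.numeric(box), 3)
  sd_step <- sqrt(2 * d_true * dt)
  unwrapped <- with_seed(seed, {
    start <- cbind(stats::runif(n_particles, 0, box[1]),
                   stats::runif(n_particles, 0, box[2]),
                   stats::runif(n_particles, 0, box[3]))
    frames <- vector("list", n_steps + 1L)
    frames[[1]] <- start
    pos <- start
    for (s in seq_len(n_steps)) {
      if (sd_step > 0)
        pos <- pos + matrix(stats::rnorm(n_particles * 3, sd = sd_step),
                            n_particles, 3)
      frames[[s + 1L]] <- pos
    }
    frames
  })
  topo <- topology(atom_name = rep("P", n_particles),
                   residue_name = "BRW",
                   residue_id = seq_len(n_particles),
                   mass = 1, species = "Other")
  frames <- lapply(seq_along(unwrapped), function(i)
    md_frame(wrap_positions(unwrapped[[i]], box), box = box, time = (i - 1) * dt))
  traj <- trajectory(topo, frames)
  traj$unwrapped <- unwrapped
  attr(traj, "d_true") <- d_true
  traj
}

#' Ideal-gas (uniform) configuration
#'
#' Uniform independent positions in the box: the null model for radial
#' distribution functions, whose g(r) is 1 at every r.
#'
#' @param n number of atoms (>= 2).
#' @param box edge lengths, nm.
#' @param seed RNG seed.
#' @return a one-frame [trajectory()] of unit-mass atoms.
#' @export
ideal_gas_box <- function(n, box = c(8, 8, 8), seed = 1L) {
  stopifnot(n >= 2, all(box > 0))
  box <- rep_len(as.numeric(box), 3)
  pts <- with_seed(seed, cbind(stats::runif(n, 0, box[1]),
                               stats::runif(n, 0, box[2]),
                               stats::runif(n, 0, box[3])))
  topo <- topology(atom_name = rep("P", n), residue_name = "GAS",
                   residue_id = seq_len(n), mass = 1, species = "Other")
  trajectory(topo, list(md_frame(pts, box = box, time = 0)))
}

#' Construct donor-hydrogen-acceptor geometries with known bond status
#'
#' For each requested (distance, angle) case, places the donor heavy atom
#' on a grid point, the acceptor at the given donor-acceptor distance
#' along x, and the hydrogen 0.1 nm from the donor making exactly the
#' given hydrogen-donor-acceptor angle.  The expected bond status follows
#' the geometric criterion: distance <= 0.35 nm AND angle <= 30 degrees.
#'
#' @param cases data frame with columns `distance` (nm, > 0.12), `angle`
#'   (degrees) and optionally `label` (species pair as `"A-B"`, default
#'   `"HBD-HBD"`).
#' @return list with `traj` (one-frame trajectory; donor and acceptor in
#'   separate molecules, species and roles assigned) and `expected` (data
#'   frame: donor, hydrogen, acceptor 1-based indices, distance, angle,
#'   label, expected_bond).
#' @export
make_hbond_fixture <- function(cases) {
  cases <- as.data.frame(cases)
  stopifnot(all(c("distance", "angle") %in% names(cases)))
  if (any(cases$distance <= 0.12))
    stop("donor-acceptor distances must exceed 0.12 nm")
  if (is.null(cases$label)) cases$label <- "HBD-HBD"
  n <- nrow(cases)
  spacing <- 3
  side <- ceiling(n^(1 / 3))
  grid <- as.matrix(expand.grid(x = seq_len(side), y = seq_len(side),
                                z = seq_len(side)))[seq_len(n), , drop = FALSE] * spacing
  coords <- matrix(NA_real_, 3 * n, 3)
  sp <- strsplit(cases$label, "-", fixed = TRUE)
  species <- character(3 * n); roles <- character(3 * n)
  anames <- character(3 * n); resid <- integer(3 * n)
  for (i in seq_len(n)) {
    g <- grid[i, ]
    th <- cases$angle[i] * pi / 180
    j <- (i - 1) * 3
    coords[j + 1, ] <- g                                        # donor heavy
    coords[j + 2, ] <- g + 0.1 * c(cos(th), sin(th), 0)         # hydrogen
    coords[j + 3, ] <- g + c(cases$distance[i], 0, 0)           # acceptor
    species[j + 1:2] <- sp[[i]][1]
    species[j + 3] <- sp[[i]][2]
    roles[j + 1:3] <- c("donor_heavy", "donor_hydrogen", "acceptor")
    anames[j + 1:3] <- c("OD", "HD", "OA")
    resid[j + 1:3] <- c(2L * i - 1L, 2L * i - 1L, 2L * i)
  }
  box <- rep((side + 1) * spacing, 3)
  topo <- topology(anames, residue_name = "FIX", residue_id = resid,
                   mass = c(15.999, 1.008, 15.999),
                   species = species, site_role = roles)
  traj <- trajectory(topo, list(md_frame(coords, box = box, time = 0)))
  expected <- data.frame(
    donor = seq_len(n) * 3 - 2, hydrogen = seq_len(n) * 3 - 1,
    acceptor = seq_len(n) * 3,
    distance = cases$distance, angle = cases$angle, label = cases$label,
    expected_bond = cases$distance <= 0.35 & cases$angle <= 30)
  list(traj = traj, expected = expected)
}

#' Harmonic free-energy ladder with closed-form total
#'
#' Interpolates a harmonic force constant k(lambda) = (1-lambda) k0 +
#' lambda k1 over a ladder of coupling values and, for each adjacent
#' window, draws positions from the Boltzmann distribution at k(lambda_i)
#' and records the perturbation energies
#' dU = (k(lambda_{i+1}) - k(lambda_i)) x^2 / 2.  The exact free-energy
#' difference of the full transformation is (kB T / 2) ln(k1/k0).
#'
#' @param k0,k1 harmonic force constants, kJ mol^-1 nm^-2 (> 0).
#' @param temperature K (> 0).
#' @param n_lambda number of coupling values from 0 to 1 (>= 2; 21 gives
#'   the conventional 21-stage ladder).
#' @param n_samples samples per window.
#' @param seed RNG seed.
#' @return a [fep_ladder()] whose `truth$dg_total` holds the closed form.
#' @export
harmonic_fep_samples <- function(k0, k1, temperature = 298.15,
                                 n_lambda = 21, n_samples = 1000, seed = 1L) {
  stopifnot(k0 > 0, k1 > 0, temperature > 0, n_lambda >= 2, n_samples >= 1)
  lambda <- seq(0, 1, length.out = n_lambda)
  k <- (1 - lambda) * k0 + lambda * k1
  windows <- with_seed(seed, lapply(seq_len(n_lambda - 1L), function(i) {
    x <- stats::rnorm(n_samples, sd = sqrt(.kB * temperature / k[i]))
    0.5 * (k[i + 1L] - k[i]) * x^2
  }))
  ladder <- fep_ladder(lambda, windows, temperature)
  ladder$truth <- list(dg_total = 0.5 * .kB * temperature * log(k1 / k0),
                       k0 = k0, k1 = k1, seed = seed)
  ladder
}

#' Rigid-body random walk of a one-frame configuration
#'
#' Extends a single-frame system (e.g. a built micelle) into a multi-frame
#' trajectory by translating the whole configuration as a rigid body with
#' Gaussian steps of per-axis variance 2 * D * dt: a minimal model of a
#' micelle diffusing as one object, with known centre-of-mass diffusion
#' coefficient.  Frames are wrapped; unwrapped coordinates ride along.
#'
#' @param traj a one-frame [trajectory()] with a box.
#' @param d_true rigid-body diffusion coefficient, nm^2/ps (>= 0).
#' @param dt frame spacing, ps.
#' @param n_steps number of steps; the result has n_steps + 1 frames.
#' @param seed RNG seed.
#' @return a [trajectory()] with attribute `"d_true"` and `$unwrapped`.
#' @export
rigid_walk_trajectory <- function(traj, d_true, dt = 1, n_steps = 100,
                                  seed = 1L) {
  stopifnot(inherits(traj, "trajectory"), n_steps > 1, dt > 0, d_true >= 0)
  fr0 <- traj$frames[[1]]
  if (is.null(fr0$box)) stop("rigid walk requires a box")
  sd_step <- sqrt(2 * d_true * dt)
  steps <- with_seed(seed, matrix(stats::rnorm(3 * n_steps, sd = sd_step),
                                  n_steps, 3))
  offsets <- rbind(0, apply(steps, 2, cumsum))
  unwrapped <- lapply(seq_len(n_steps + 1L), function(i)
    sweep(fr0$coords, 2, offsets[i, ], `+`))
  frames <- lapply(seq_along(unwrapped), function(i)
    md_frame(wrap_positions(unwrapped[[i]], fr0$box), box = fr0$box,
          time = (i - 1) * dt))
  out <- trajectory(traj$topology, frames)
  out$unwrapped <- unwrapped
  attr(out, "d_true") <- d_true
  out
}
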