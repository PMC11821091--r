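# Independent brute-force oracles used to cross-check the package's
# computational paths.  These deliberately avoid the package internals:
# explicit loops, closed-form eigenvalues, direct pair enumeration.

# Closed-form eigenvalues of a symmetric 3x3 matrix via the characteristic
# polynomial (trigonometric solution), independent of LAPACK.
oracle_sym3_eigen <- function(A) {
  q <- sum(diag(A)) / 3
  p2 <- sum((diag(A) - q)^2) + 2 * (A[1, 2]^2 + A[1, 3]^2 + A[2, 3]^2)
  if (p2 < 1e-30) return(rep(q, 3))
  p <- sqrt(p2 / 6)
  B <- (A - q * diag(3)) / p
  r <- det(B) / 2
  r <- min(1, max(-1, r))
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  sort(c(e1, 3 * q - e1 - e3, e3))
}

# Inertia tensor by an explicit per-atom loop.
oracle_inertia <- function(coords, masses, com) {
  A <- matrix(0, 3, 3)
  for (i in seq_len(nrow(coords))) {
    r <- coords[i, ] - com
    A <- A + masses[i] * (sum(r * r) * diag(3) - outer(r, r))
  }
  A
}

oracle_eccentricity <- function(coords, masses) {
  com <- colSums(coords * masses) / sum(masses)
  ev <- oracle_sym3_eigen(oracle_inertia(coords, masses, com))
  1 - min(ev) / mean(ev)
}

min_image_r <- function(d, box) {
  d - box * ceiling(d / box - 0.5)
}

# Direct O(N_A x N_B) enumeration of in-range pair distances.
oracle_pair_distances <- function(ca, cb, box, r_max, idx_a, idx_b,
                                  mol_a, mol_b, exclude_same_molecule) {
  out <- numeric(0)
  for (i in seq_len(nrow(ca))) {
    for (j in seq_len(nrow(cb))) {
      if (idx_a[i] == idx_b[j]) next
      if (exclude_same_molecule && mol_a[i] == mol_b[j]) next
      d <- sqrt(sum(min_image_r(cb[j, ] - ca[i, ], box)^2))
      if (d > 0 && d <= r_max) out <- c(out, d)
    }
  }
  out
}

# Triple-loop hydrogen-bond detection straight from the geometric
# criterion (inclusive cutoffs, angle at the donor).
oracle_hbonds <- function(coords, box, donors, acceptors, mol,
                          r_da_max = 0.35, angle_max = 30,
                          include_intra = FALSE) {
  hits <- NULL
  for (i in seq_len(nrow(donors))) {
    d <- donors[i, 1]; h <- donors[i, 2]
    vh <- min_image_r(coords[h, ] - coords[d, ], box)
    for (a in acceptors) {
      if (a == d) next
      if (!include_intra && mol[a] == mol[d]) next
      va <- min_image_r(coords[a, ] - coords[d, ], box)
      r <- sqrt(sum(va^2))
      if (r == 0 || r > r_da_max + 1e-12) next
      ang <- acos(min(1, max(-1, sum(vh * va) /
                               (sqrt(sum(vh^2)) * r)))) * 180 / pi
      if (ang <= angle_max + 1e-9)
        hits <- rbind(hits, c(d, h, a))
    }
  }
  if (is.null(hits))
    hits <- matrix(integer(0), 0, 3)
  colnames(hits) <- c("donor", "hydrogen", "acceptor")
  hits
}

# Sort bond triplets so matrices can be compared row-for-row.
sort_bonds <- function(m) {
  if (nrow(m) == 0) return(m)
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed: uniform random rotation
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# A random box of donors (with attached hydrogens) and acceptors for
# detection cross-checks.
random_hbond_frame <- function(seed) {
  set.seed(seed)
  box <- c(4, 4, 4)
  nd <- 25; na <- 35
  donor <- cbind(stats::runif(nd, 0, 4), stats::runif(nd, 0, 4),
                 stats::runif(nd, 0, 4))
  dirs <- matrix(stats::rnorm(nd * 3), nd, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  hyd <- donor + 0.1 * dirs
  acc <- cbind(stats::runif(na, 0, 4), stats::runif(na, 0, 4),
               stats::runif(na, 0, 4))
  co <- rbind(donor, hyd, acc)
  mol <- c(seq_len(nd), seq_len(nd), nd + sample(1:10, na, replace = TRUE))
  topo <- topology(c(rep("OD", nd), rep("HD", nd), rep("OA", na)),
                   "FIX", mol, mass = 1,
                   site_role = c(rep("donor_heavy", nd),
                                 rep("donor_hydrogen", nd),
                                 rep("acceptor", na)))
  list(frame = md_frame(co, box = box), topo = topo, box = box,
       donors = cbind(seq_len(nd), nd + seq_len(nd)),
       acceptors = 2L * nd + seq_len(na), mol = mol)
}
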