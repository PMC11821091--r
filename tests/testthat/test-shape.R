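make_traj <- function(coords, box = c(8, 8, 8), masses = NULL) {
  n <- nrow(coords)
  topo <- topology(rep("P", n), "RES", seq_len(n),
                   mass = if (is.null(masses)) 1 else masses)
  trajectory(topo, list(md_frame(coords, box = box)))
}

test_that("periodic COM reconstructs selections split across the boundary", {
  fr <- md_frame(matrix(c(1.5, 2, 3), 1, 3), box = c(8, 8, 8))
  expect_equal(micelle_com(fr, 1L, masses = 1), c(1.5, 2, 3))
  # two equal masses at 0.1 and L - 0.1: COM wraps to 0, not L/2
  fr2 <- md_frame(matrix(c(0.1, 0, 0, 7.9, 0, 0), 2, 3, byrow = TRUE),
                  box = c(8, 8, 8))
  com <- micelle_com(fr2, 1:2, masses = c(1, 1))
  expect_equal(min(com[1], 8 - com[1]), 0, tolerance = 1e-9)
  # symmetric octahedron about p returns p
  p <- c(4, 3, 5)
  oct <- rbind(p + c(1, 0, 0), p - c(1, 0, 0), p + c(0, 1, 0),
               p - c(0, 1, 0), p + c(0, 0, 1), p - c(0, 0, 1))
  fr3 <- md_frame(oct, box = c(8, 8, 8))
  expect_equal(micelle_com(fr3, 1:6, masses = rep(1, 6)), p)
  expect_error(micelle_com(fr, integer(0), masses = 1), "empty")
})

test_that("inertia tensor matches direct sums and is rotation invariant", {
  oct <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  it <- inertia_tensor(oct, rep(1, 6), c(0, 0, 0))
  expect_equal(it$eigenvalues, c(4, 4, 4))
  set.seed(8)
  pts <- matrix(stats::rnorm(60), 20, 3)
  m <- stats::runif(20, 0.5, 2)
  com <- colSums(pts * m) / sum(m)
  ev <- inertia_tensor(pts, m, com)$eigenvalues
  for (k in 1:5) {
    R <- random_rotation()
    rot <- pts %*% t(R)
    comr <- colSums(rot * m) / sum(m)
    evr <- inertia_tensor(rot, m, comr)$eigenvalues
    expect_equal(evr, ev, tolerance = 1e-10)
  }
  expect_error(inertia_tensor(matrix(1, 3, 3), rep(1, 3), c(1, 1, 1)),
               "degenerate")
})

test_that("eccentricity follows e = 1 - Imin/Imean with a zero sphere limit", {
  expect_equal(eccentricity(c(4, 4, 4)), 0)
  expect_equal(eccentricity(c(0.4, 1.0, 1.0)), 0.5)
  for (x in c(0.1, 1, 50)) expect_equal(eccentricity(c(x, x, x)), 0)
  expect_error(eccentricity(c(0, 0, 0)), "zero")
  expect_error(eccentricity(c(-1, 1, 1)), "non-negative")
})

test_that("radius of gyration matches elementary cases", {
  com <- c(1, 2, 3)
  pts <- matrix(rep(com, 4), 4, 3, byrow = TRUE)
  expect_equal(radius_of_gyration(pts, rep(1, 4), com), 0)
  two <- rbind(c(0.7, 0, 0), c(-0.7, 0, 0))
  expect_equal(radius_of_gyration(two, c(1, 1), c(0, 0, 0)), 0.7)
})

test_that("effective radius reproduces the sqrt(5/3) tabulated pairs", {
  expect_equal(round(effective_radius(15.4), 1), 19.9)
  expect_equal(round(effective_radius(18.8), 1), 24.3)
  expect_equal(round(effective_radius(19.4), 1), 25.0)
  expect_equal(effective_radius(0), 0)
})

test_that("shape pipeline equals the characteristic-polynomial oracle on random sets", {
  set.seed(31)
  for (rep in 1:100) {
    n <- sample(4:40, 1)
    pts <- matrix(stats::rnorm(3 * n, sd = stats::runif(1, 0.5, 3)), n, 3)
    m <- stats::runif(n, 0.5, 5)
    traj <- make_traj(sweep(pts, 2, c(20, 20, 20), `+`), box = c(40, 40, 40),
                      masses = m)
    e_pipe <- shape_series(traj)$mean_e
    expect_equal(e_pipe, oracle_eccentricity(pts, m), tolerance = 1e-8)
  }
})

test_that("eccentricity is invariant under rigid motion and mass rescaling", {
  set.seed(17)
  pts <- matrix(stats::rnorm(90), 30, 3)
  m <- stats::runif(30, 1, 3)
  e0 <- oracle_eccentricity(pts, m)
  for (k in 1:5) {
    R <- random_rotation()
    shift <- stats::runif(3, -2, 2)
    moved <- sweep(pts %*% t(R), 2, shift, `+`)
    traj <- make_traj(sweep(moved, 2, c(20, 20, 20), `+`),
                      box = c(40, 40, 40), masses = m * 7)
    expect_equal(shape_series(traj)$mean_e, e0, tolerance = 1e-9)
  }
})

test_that("run summary keeps Rs/meanRg at sqrt(5/3) and flags drifting Rg", {
  # static geometry repeated: zero variance, no trend flag
  oct <- sweep(rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                     c(0, 0, 1), c(0, 0, -1)), 2, c(4, 4, 4), `+`)
  topo <- topology(rep("P", 6), "RES", 1:6)
  frames <- lapply(0:9, function(t) md_frame(oct, box = c(8, 8, 8), time = t))
  sr <- shape_series(trajectory(topo, frames))
  expect_equal(sr$sd_rg, 0)
  expect_false(sr$rg_trend$flagged)
  expect_equal(sr$rs / sr$mean_rg, sqrt(5 / 3), tolerance = 1e-15)
  # generated sphere micelle: eccentricity stays small
  mic <- build_micelle(60, c(2, 2, 2), jitter = 0.02, seed = 3)
  expect_lt(shape_series(mic)$mean_e, 0.05)
  # linearly growing Rg raises the non-equilibration flag
  grow <- lapply(0:19, function(t) {
    r <- 1 + 0.05 * t
    md_frame(sweep(rbind(c(r, 0, 0), c(-r, 0, 0), c(0, r, 0), c(0, -r, 0),
                         c(0, 0, r), c(0, 0, -r)), 2, c(10, 10, 10), `+`),
             box = c(20, 20, 20), time = t)
  })
  sg <- shape_series(trajectory(topo, grow))
  expect_true(sg$rg_trend$flagged)
})

test_that("Rg of a union of equal-mass sets is at least the smaller individual Rg", {
  set.seed(77)
  for (k in 1:20) {
    a <- matrix(stats::rnorm(30), 10, 3)
    b <- matrix(stats::rnorm(30, mean = stats::runif(1, -2, 2)), 10, 3)
    rg <- function(x) radius_of_gyration(x, rep(1, nrow(x)), colMeans(x))
    expect_gte(rg(rbind(a, b)) + 1e-12, min(rg(a), rg(b)))
  }
})
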