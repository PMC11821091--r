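test_that("spherical micelles are near-spherical by the brute-force inertia oracle", {
  mic <- build_micelle(60, c(2, 2, 2), jitter = 0, seed = 11)
  co <- mic$frames[[1]]$coords
  m <- mic$topology$mass
  expect_lt(oracle_eccentricity(co, m), 0.01)
})

test_that("elongated micelles match the brute-force eccentricity oracle", {
  mic <- build_micelle(120, c(4, 2, 2), jitter = 0, seed = 12)
  co <- mic$frames[[1]]$coords
  m <- mic$topology$mass
  sr <- shape_series(mic)
  expect_equal(sr$mean_e, oracle_eccentricity(co, m), tolerance = 1e-8)
})

test_that("every chain keeps its head outside all its tail sites", {
  for (spec in list(list(n = 60, ax = c(2, 2, 2), jit = 0.05),
                    list(n = 30, ax = c(3, 2.5, 2), jit = 0.1),
                    list(n = 60, ax = c(2, 2, 2), jit = 0, bend = 120))) {
    bend <- if (is.null(spec$bend)) 180 else spec$bend
    mic <- build_micelle(spec$n, spec$ax, jitter = spec$jit,
                         bend_angle = bend, seed = 7)
    co <- sweep(mic$frames[[1]]$coords, 2, mic$frames[[1]]$box / 2)
    radii <- sqrt(rowSums(co^2))
    ns <- nrow(default_chain_sites())
    for (i in seq_len(spec$n)) {
      chain <- radii[(i - 1) * ns + seq_len(ns)]
      expect_gt(chain[1], max(chain[-1]))
    }
  }
})

test_that("micelle eccentricity grows with the axis ratio at fixed jitter", {
  e <- vapply(c(1, 1.5, 2), function(ratio) {
    mic <- build_micelle(80, c(2 * ratio, 2, 2), jitter = 0.02, seed = 5)
    shape_series(mic)$mean_e
  }, numeric(1))
  expect_true(all(diff(e) > 0))
})

test_that("micelle offsets beyond the semi-axes are a geometry error", {
  sites <- default_chain_sites()
  expect_error(build_micelle(10, c(1.5, 1.5, 1.5), chain_sites = sites),
               "exceed")
})

test_that("solid 2:1:1 ellipsoid cloud reaches the analytic eccentricity 0.5", {
  fr <- ellipsoid_cloud(c(2, 1, 1), 200000, mode = "solid", seed = 21)
  m <- rep(1, nrow(fr$coords))
  com <- colMeans(fr$coords)
  ev <- inertia_tensor(fr$coords, m, com)$eigenvalues
  expect_equal(eccentricity(ev), 0.5, tolerance = 0.01)
  # eigenvalue ratios follow (b^2+c^2) : (a^2+c^2) : (a^2+b^2)
  expect_equal(ev / ev[3], c(2, 5, 5) / 5, tolerance = 0.02)
})

test_that("sphere clouds reproduce the closed-form radius of gyration", {
  sh <- ellipsoid_cloud(c(1.5, 1.5, 1.5), 50000, mode = "shell", seed = 2)
  m <- rep(1, nrow(sh$coords))
  expect_equal(radius_of_gyration(sh$coords, m, colMeans(sh$coords)),
               1.5, tolerance = 0.01)
  so <- ellipsoid_cloud(c(1.5, 1.5, 1.5), 200000, mode = "solid", seed = 3)
  m2 <- rep(1, nrow(so$coords))
  expect_equal(radius_of_gyration(so$coords, m2, colMeans(so$coords))^2,
               3 / 5 * 1.5^2, tolerance = 0.01)
})

test_that("Brownian generator is frozen at D = 0 and reproducible by seed", {
  still <- brownian_trajectory(5, 0, dt = 1, n_steps = 20, seed = 9)
  expect_equal(still$frames[[21]]$coords, still$frames[[1]]$coords)
  a <- brownian_trajectory(10, 1e-4, n_steps = 50, seed = 4)
  b <- brownian_trajectory(10, 1e-4, n_steps = 50, seed = 4)
  expect_identical(a$frames[[51]]$coords, b$frames[[51]]$coords)
  expect_identical(a$unwrapped[[51]], b$unwrapped[[51]])
  c_ <- brownian_trajectory(10, 1e-4, n_steps = 50, seed = 5)
  expect_false(identical(a$frames[[51]]$coords, c_$frames[[51]]$coords))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123); before <- stats::runif(1)
  set.seed(123); invisible(build_micelle(10, seed = 1))
  invisible(brownian_trajectory(5, 1e-4, n_steps = 5, seed = 2))
  after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("hydrogen-bond fixtures realise the requested geometry exactly", {
  cases <- data.frame(distance = c(0.30, 0.36, 0.30, 0.35),
                      angle = c(10, 0, 45, 30),
                      label = c("Surf-HBD", "HBD-HBD", "Ch-HBD", "Cl-HBD"))
  fx <- make_hbond_fixture(cases)
  expect_equal(fx$expected$expected_bond, c(TRUE, FALSE, FALSE, TRUE))
  co <- fx$traj$frames[[1]]$coords
  for (i in seq_len(nrow(cases))) {
    d <- co[fx$expected$donor[i], ]
    h <- co[fx$expected$hydrogen[i], ]
    a <- co[fx$expected$acceptor[i], ]
    expect_equal(sqrt(sum((a - d)^2)), cases$distance[i], tolerance = 1e-12)
    expect_equal(sqrt(sum((h - d)^2)), 0.1, tolerance = 1e-12)
    ang <- acos(sum((h - d) * (a - d)) /
                  (sqrt(sum((h - d)^2)) * sqrt(sum((a - d)^2)))) * 180 / pi
    expect_equal(ang, cases$angle[i], tolerance = 1e-9)
  }
  expect_error(make_hbond_fixture(data.frame(distance = 0.1, angle = 0)),
               "0.12")
})

test_that("harmonic ladder fixture carries its closed-form ground truth", {
  flat <- harmonic_fep_samples(200, 200, n_lambda = 5, n_samples = 50,
                               seed = 1)
  expect_true(all(vapply(flat$windows, function(w) all(w == 0), logical(1))))
  expect_equal(flat$truth$dg_total, 0)
  lad <- harmonic_fep_samples(100, 400, temperature = 298.15, seed = 1)
  kb <- 0.0083144621
  expect_equal(lad$truth$dg_total, kb * 298.15 / 2 * log(4))
  expect_equal(length(lad$lambda), 21L)
  lad2 <- harmonic_fep_samples(100, 400, temperature = 298.15, seed = 1)
  expect_identical(lad$windows, lad2$windows)
})
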