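linear_msd_result <- function(d = 0.1, n = 50, dt = 1, c0 = 0) {
  lag <- dt * seq_len(n)
  structure(list(lag = lag, msd = 6 * d * lag + c0, n_entities = 1,
                 mode = "per_particle"), class = "msd_result")
}

test_that("MSD vanishes for frozen systems and is exactly quadratic for drift", {
  still <- brownian_trajectory(5, 0, dt = 1, n_steps = 30, seed = 1)
  expect_true(all(msd(still)$msd == 0))
  # ballistic x = v t
  v <- 0.03; nf <- 40
  topo <- topology(rep("P", 3), "BAL", 1:3)
  frames <- lapply(0:(nf - 1), function(t)
    md_frame(matrix(c(v * t, 0, 0), 3, 3, byrow = TRUE),
             box = c(100, 100, 100), time = t))
  traj <- trajectory(topo, frames)
  traj$unwrapped <- lapply(frames, `[[`, "coords")
  mr <- msd(traj)
  expect_equal(mr$msd, v^2 * mr$lag^2, tolerance = 1e-12)
  bw <- beta_exponent(mr)
  expect_equal(bw$beta, rep(2, length(mr$lag)), tolerance = 1e-9)
  expect_false(bw$diffusive)
})

test_that("beta is identically 1 on an exact Einstein-relation series", {
  mr <- linear_msd_result(d = 0.1)
  bw <- beta_exponent(mr)
  expect_equal(bw$beta, rep(1, length(mr$lag)), tolerance = 1e-12)
  expect_true(bw$diffusive)
  dc <- diffusion_coefficient(mr)
  expect_equal(dc$d, 0.1, tolerance = 1e-12)
  expect_equal(dc$d_si, 0.1 * 1e5)
  # additive constant is absorbed by the fit intercept
  dc2 <- diffusion_coefficient(linear_msd_result(d = 0.1, c0 = 0.7),
                               window = c(1, 50))
  expect_equal(dc2$d, 0.1, tolerance = 1e-12)
})

test_that("beta recovers exact power-law exponents to 1e-6", {
  lag <- seq_len(200) * 0.5
  for (n in c(0.5, 1, 2)) {
    mr <- structure(list(lag = lag, msd = 2.7 * lag^n, n_entities = 1,
                         mode = "per_particle"), class = "msd_result")
    beta <- beta_exponent(mr)$beta
    expect_equal(beta, rep(n, length(lag)), tolerance = 1e-6)
  }
})

test_that("Brownian ground truth is recovered within the stated error", {
  traj <- brownian_trajectory(400, 1e-4, dt = 1, n_steps = 800, seed = 23)
  mr <- msd(traj, origin_stride = 4L)
  bw <- beta_exponent(mr)
  expect_true(bw$diffusive)
  dc <- diffusion_coefficient(mr, window = bw$window)
  expect_lt(abs(dc$d - 1e-4) / 1e-4, 0.05)
})

test_that("replica D estimates bracket the truth within two standard errors", {
  d_hat <- vapply(1:12, function(s) {
    tr <- brownian_trajectory(60, 2e-4, dt = 1, n_steps = 250, seed = 100 + s)
    diffusion_coefficient(msd(tr, origin_stride = 2L), window = c(5, 80))$d
  }, numeric(1))
  se <- stats::sd(d_hat) / sqrt(length(d_hat))
  expect_lt(abs(mean(d_hat) - 2e-4), 2 * se + 1e-7)
})

test_that("MSD is invariant under a global rigid translation", {
  traj <- brownian_trajectory(30, 1e-4, dt = 1, n_steps = 100, seed = 3)
  mr0 <- msd(traj)
  shifted <- traj
  shifted$unwrapped <- lapply(traj$unwrapped, function(m)
    sweep(m, 2, c(3.3, -1.1, 0.7), `+`))
  expect_equal(msd(shifted)$msd, mr0$msd, tolerance = 1e-12)
})

test_that("unwrapping wrapped frames reproduces the stored ground truth", {
  traj <- brownian_trajectory(20, 5e-4, dt = 1, n_steps = 200,
                              box = c(6, 6, 6), seed = 31)
  wrapped_only <- trajectory(traj$topology, traj$frames)
  mr_w <- msd(wrapped_only)
  mr_u <- msd(traj)
  expect_equal(mr_w$msd, mr_u$msd, tolerance = 1e-10)
})

test_that("molecule-COM and selection-COM modes reduce entities correctly", {
  mic <- build_micelle(10, c(2, 2, 2), seed = 2)
  walk <- rigid_walk_trajectory(mic, 2e-4, dt = 1, n_steps = 300, seed = 6)
  mr_com <- msd(walk, mode = "com")
  expect_equal(mr_com$n_entities, 1L)
  mr_mol <- msd(walk, mode = "molecule_com")
  expect_equal(mr_mol$n_entities, 10L)
  # rigid body: every molecule COM moves with the aggregate COM
  expect_equal(mr_mol$msd, mr_com$msd, tolerance = 1e-9)
  # single-walker D is noisy; average over independent walks before
  # comparing to the generator's ground truth
  d_hat <- vapply(1:6, function(s) {
    w <- rigid_walk_trajectory(mic, 2e-4, dt = 1, n_steps = 2000,
                               seed = 40 + s)
    diffusion_coefficient(msd(w, mode = "com"), window = c(5, 60))$d
  }, numeric(1))
  expect_lt(abs(mean(d_hat) - 2e-4) / 2e-4, 0.25)
})

test_that("relative error reproduces printed density-error arithmetic", {
  expect_equal(round(relative_error(1180, 1183.7), 1), 0.3)
  expect_equal(round(relative_error(1240, 1135.6)), 8)
  expect_equal(relative_error(5, 5), 0)
  expect_error(relative_error(0, 1), "non-zero")
})

test_that("degenerate MSD inputs are refused with clear errors", {
  still <- brownian_trajectory(5, 0, dt = 1, n_steps = 30, seed = 1)
  mr <- msd(still)
  expect_error(beta_exponent(mr), "non-positive")
  expect_error(diffusion_coefficient(linear_msd_result(), window = c(1, 2)),
               "3 points")
  short <- brownian_trajectory(3, 1e-4, n_steps = 5, seed = 1)
  expect_error(msd(short), "10 frames")
})
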