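test_that("ideal-gas g(r) is 1 within 3 Poisson standard errors", {
  n <- 5000; box <- c(8, 8, 8)
  gas <- ideal_gas_box(n, box, seed = 41)
  r <- rdf_site_site(gas, 1:n, 1:n, bin_width = 0.05, r_max = 3,
                     exclude_same_molecule = FALSE)
  keep <- r$r > 0.5
  # expected unordered pair count per bin sets the Poisson error
  vol <- prod(box)
  vshell <- 4 * pi / 3 * diff(seq(0, 3, by = 0.05)^3)[keep]
  exp_pairs <- n * (n - 1) / 2 / vol * vshell
  se_mean <- sqrt(sum(1 / exp_pairs)) / sum(keep)
  expect_lt(abs(mean(r$g[keep]) - 1), 3 * se_mean)
})

test_that("an isolated pair lands in exactly one bin at its separation", {
  topo <- topology(c("A", "B"), "PR", 1:2)
  co <- rbind(c(1, 1, 1), c(1.3, 1, 1))
  traj <- trajectory(topo, list(md_frame(co, box = c(6, 6, 6))))
  r <- rdf_site_site(traj, 1L, 2L, bin_width = 0.02, r_max = 2)
  nz <- which(r$counts > 0)
  expect_length(nz, 1L)
  expect_lt(abs(r$r[nz] - 0.3), 0.02)
  expect_equal(sum(r$counts), 1)
})

test_that("pair counts equal the direct O(N^2) enumeration on random frames", {
  set.seed(55)
  for (rep in 1:3) {
    n <- 150; box <- c(5, 6, 7)
    co <- cbind(stats::runif(n, 0, box[1]), stats::runif(n, 0, box[2]),
                stats::runif(n, 0, box[3]))
    mol <- sample(1:40, n, replace = TRUE)
    topo <- topology(rep("A", n), "R", mol)
    traj <- trajectory(topo, list(md_frame(co, box = box)))
    sel_a <- sample(n, 70); sel_b <- sample(n, 80)
    for (excl in c(TRUE, FALSE)) {
      r <- rdf_site_site(traj, sel_a, sel_b, bin_width = 0.1, r_max = 2.4,
                         exclude_same_molecule = excl)
      d <- oracle_pair_distances(co[sel_a, ], co[sel_b, ], box, 2.4,
                                 sel_a, sel_b, mol[sel_a], mol[sel_b], excl)
      expect_equal(sum(r$counts), length(d))
      expect_equal(as.numeric(r$counts),
                   as.numeric(table(cut(d, seq(0, 2.4, by = 0.1)))))
    }
  }
})

test_that("coordination numbers are conserved when the bin width doubles", {
  n <- 2000; box <- c(8, 8, 8)
  gas <- ideal_gas_box(n, box, seed = 19)
  rho <- n / prod(box)
  nc <- vapply(c(0.02, 0.04), function(bw) {
    r <- rdf_site_site(gas, 1:n, 1:n, bin_width = bw, r_max = 2,
                       exclude_same_molecule = FALSE)
    sum(rho * 4 * pi * r$r^2 * r$g * bw)
  }, numeric(1))
  expect_equal(nc[1], nc[2], tolerance = 0.01)
})

test_that("RDF is invariant under atom reordering and rigid translation", {
  n <- 300; box <- c(6, 6, 6)
  gas <- ideal_gas_box(n, box, seed = 3)
  r0 <- rdf_site_site(gas, 1:150, 151:n, bin_width = 0.05, r_max = 2.5)
  co <- gas$frames[[1]]$coords
  shift <- wrap_positions(sweep(co, 2, c(1.7, -2.2, 0.4), `+`), box)
  tr <- trajectory(gas$topology, list(md_frame(shift, box = box)))
  r1 <- rdf_site_site(tr, 1:150, 151:n, bin_width = 0.05, r_max = 2.5)
  expect_equal(r1$counts, r0$counts)
  perm <- sample(n)
  topo_p <- gas$topology[perm, ]
  topo_p$index <- seq_len(n) - 1L
  tp <- trajectory(topology(topo_p$atom_name, topo_p$residue_name,
                            topo_p$residue_id, topo_p$mass),
                   list(md_frame(co[perm, ], box = box)))
  r2 <- rdf_site_site(tp, match(1:150, perm), match(151:n, perm),
                      bin_width = 0.05, r_max = 2.5)
  expect_equal(r2$counts, r0$counts)
})

test_that("r_max beyond the half box and empty selections are refused", {
  gas <- ideal_gas_box(50, c(6, 6, 6), seed = 1)
  expect_error(rdf_site_site(gas, 1:50, 1:50, r_max = 3.5), "half")
  expect_error(rdf_site_site(gas, integer(0), 1:50), "empty")
})

test_that("COM-centred distributions see uniform targets as g = 1", {
  mic <- build_micelle(30, c(1.5, 1.5, 1.5),
                       chain_sites = within(default_chain_sites(),
                                            offset <- offset * 0.7),
                       seed = 2)
  # embed micelle plus a uniform target species in one trajectory
  nt <- 4000
  box <- mic$frames[[1]]$box
  set.seed(66)
  tgt <- cbind(stats::runif(nt, 0, box[1]), stats::runif(nt, 0, box[2]),
               stats::runif(nt, 0, box[3]))
  topo <- rbind(mic$topology,
                topology(rep("W", nt), "SOL",
                         max(mic$topology$residue_id) + seq_len(nt),
                         mass = 18, species = "HBD"))
  topo$index <- seq_len(nrow(topo)) - 1L
  traj <- trajectory(topo, list(md_frame(rbind(mic$frames[[1]]$coords, tgt),
                                         box = box)))
  mic_sel <- which(topo$species == "Surf")
  tgt_sel <- which(topo$species == "HBD")
  r <- rdf_from_com(traj, mic_sel, tgt_sel, bin_width = 0.1)
  far <- r$r > 0.5 & r$r < min(box) / 2
  expect_equal(mean(r$g[far]), 1, tolerance = 0.1)
})

test_that("targets at a fixed COM distance fill a single bin", {
  oct <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  center <- c(5, 5, 5)
  co <- rbind(matrix(center, 1, 3), sweep(1.2 * oct, 2, center, `+`))
  topo <- topology(c("M", rep("T", 6)), c("MIC", rep("TGT", 6)), 1:7)
  traj <- trajectory(topo, list(md_frame(co, box = c(10, 10, 10))))
  r <- rdf_from_com(traj, 1L, 2:7, bin_width = 0.05, r_max = 4)
  nz <- which(r$counts > 0)
  expect_length(nz, 1L)
  expect_lt(abs(r$r[nz] - 1.2), 0.05)
  expect_equal(sum(r$counts), 6)
})

test_that("generated micelles put tail atoms closer to the COM than heads", {
  mic <- build_micelle(60, c(2, 2, 2), jitter = 0.03, seed = 10)
  heads <- select_atoms(mic, site_role = "head")
  tails <- select_atoms(mic, site_role = "tail")
  rh <- rdf_from_com(mic, seq_len(n_atoms(mic)), heads, bin_width = 0.05)
  rt <- rdf_from_com(mic, seq_len(n_atoms(mic)), tails, bin_width = 0.05)
  expect_lt(rt$r[which.max(rt$g)], rh$r[which.max(rh$g)])
})
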