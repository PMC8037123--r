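# Pore envelope counting, crystal-water matching, superposition and RMSD.

test_that("cylinder counting includes exactly the planted waters", {
  ep <- carboxylate_endpoints()
  set.seed(5)
  # 5 waters at the axis midpoint region, 50 parked far away
  near <- cbind(runif(5, -1, 1), runif(5, -1, 1), seq(6, 14, by = 2))
  far <- cbind(runif(50, 30, 60), runif(50, 30, 60), runif(50, 30, 60))
  sys <- make_water_system(rbind(near, far), with_h = FALSE,
                           extra_atoms = ep$atoms, extra_xyz = ep$xyz)
  pore <- pore_definition()
  ords <- waters_in_pore(sys$frame, sys$topology, pore)
  expect_identical(ords, water_oxygens(sys$topology)[1:5])

  # empty pore
  sys0 <- make_water_system(far, with_h = FALSE, extra_atoms = ep$atoms,
                            extra_xyz = ep$xyz)
  expect_length(waters_in_pore(sys0$frame, sys0$topology, pore), 0)

  # closed boundary: a water exactly at the cylinder radius is included
  rim <- rbind(c(5.0, 0, 10), c(5.0 + 1e-6, 0, 30))
  sysr <- make_water_system(rim, with_h = FALSE, extra_atoms = ep$atoms,
                            extra_xyz = ep$xyz)
  expect_length(waters_in_pore(sysr$frame, sysr$topology, pore), 1)

  # unresolvable endpoint residue
  bad <- pore_definition(axis_endpoints = list(
    list(residue_id = 999, atom_name = "CD"),
    list(residue_id = 918, atom_name = "CD")))
  expect_error(waters_in_pore(sys$frame, sys$topology, bad), "resolves to 0")
})

test_that("pore counting is invariant under rigid motion and matches recounts", {
  set.seed(31)
  pore <- pore_definition()
  for (rep in 1:20) {
    ep <- carboxylate_endpoints()
    o <- cbind(runif(12, -6, 6), runif(12, -6, 6), runif(12, -4, 24))
    sys <- make_water_system(o, with_h = FALSE, extra_atoms = ep$atoms,
                             extra_xyz = ep$xyz)
    ords <- waters_in_pore(sys$frame, sys$topology, pore)
    # independent recount: distance from axis segment computed directly
    a <- sys$frame$xyz[atom_select(sys$topology, residue_id = 908,
                                   atom_name = "CD"), ]
    b <- sys$frame$xyz[atom_select(sys$topology, residue_id = 918,
                                   atom_name = "CD"), ]
    u <- (b - a) / sqrt(sum((b - a)^2))
    L <- sqrt(sum((b - a)^2))
    manual <- integer(0)
    for (w in water_oxygens(sys$topology)) {
      rel <- sys$frame$xyz[w, ] - a
      t_ax <- sum(rel * u)
      r <- sqrt(sum(rel^2) - t_ax^2)
      if (t_ax >= -2 && t_ax <= L + 2 && r <= 5) manual <- c(manual, w)
    }
    expect_identical(ords, manual)
    # joint rigid motion of protein and waters leaves the count unchanged
    expect_identical(waters_in_pore(rigid_frame(sys$frame), sys$topology,
                                    pore), ords)
  }
})

test_that("lining-proximity mode provides an alternative envelope", {
  tr <- generate_trajectory(scenario_spec("hydration_onset", n_frames = 5,
                                          seed = 2))
  pore_lin <- pore_definition(mode = "lining")
  f <- tr$frames[[5]]
  # the planted waters sit at the pore wall, within 4.5 A of lining atoms
  expect_gte(length(waters_in_pore(f, tr$topology, pore_lin)), 1)
})

test_that("hydration series reproduces planted occupancy scripts", {
  occ <- data.frame(from = c(1, 6), to = c(5, 10), count = c(4, 9))
  tr <- generate_trajectory(scenario_spec("hydration_onset", n_frames = 10,
                                          occupancy_script = occ, seed = 4))
  h <- hydration_timeseries(tr$frames, tr$topology, pore_definition(),
                            windows = list(c(0, 40), c(50, 90)))
  expect_equal(h$series$count, tr$ground_truth$pore_counts)
  expect_equal(h$window_means$mean_count, c(4, 9))

  # constant occupancy: zero variance
  occc <- data.frame(from = 1, to = 10, count = 4)
  trc <- generate_trajectory(scenario_spec("hydration_onset", n_frames = 10,
                                           occupancy_script = occc, seed = 4))
  hc <- hydration_timeseries(trc$frames, trc$topology, pore_definition())
  expect_equal(unique(hc$series$count), 4L)

  # empty pore throughout
  occ0 <- data.frame(from = 1, to = 10, count = 0)
  tr0 <- generate_trajectory(scenario_spec("hydration_onset", n_frames = 10,
                                           occupancy_script = occ0, seed = 4))
  h0 <- hydration_timeseries(tr0$frames, tr0$topology, pore_definition())
  expect_true(all(h0$series$count == 0))

  # interval below the frame spacing is a configuration error
  expect_error(hydration_timeseries(tr$frames, tr$topology, pore_definition(),
                                    interval_ps = 5), "smaller than")
  # coarser interval subsamples
  h2 <- hydration_timeseries(tr$frames, tr$topology, pore_definition(),
                             interval_ps = 20)
  expect_equal(nrow(h2$series), 5)
})

test_that("crystal matching is greedy, capped and cutoff-monotone", {
  f_at <- function(p) frame(p)
  # identical coordinates: all matched at zero displacement
  p <- rbind(c(0, 0, 0), c(4, 0, 0), c(8, 0, 0))
  ov <- match_crystal_waters(f_at(p), 1:3, f_at(p), 1:3)
  expect_equal(nrow(ov$matches), 3)
  expect_true(all(ov$matches$displacement == 0))

  # a crystal water displaced 2.5 A stays unmatched under a 2 A cutoff
  q <- p; q[2, 1] <- q[2, 1] + 2.5
  ov <- match_crystal_waters(f_at(p), 1:3, f_at(q), 1:3)
  expect_equal(nrow(ov$matches), 2)
  expect_equal(ov$unmatched_crystal, 2L)

  # greedy matching equals the exact assignment on jittered instances
  # (sim waters at physical >= 4.5 A separations, crystal = sim + jitter)
  set.seed(12)
  for (rep in 1:25) {
    n <- sample(4:10, 1)
    grid <- expand.grid(x = seq(0, 15, 5), y = seq(0, 15, 5))
    pick <- sample(nrow(grid), n)
    sim <- cbind(grid$x[pick], grid$y[pick], 0) +
      matrix(runif(3 * n, -0.2, 0.2), ncol = 3)
    k <- sample(0:n, 1)
    crystal <- sim + matrix(rnorm(3 * n, sd = 0.4), ncol = 3)
    if (k > 0) crystal[seq_len(k), ] <- crystal[seq_len(k), ] + 10
    ov <- match_crystal_waters(f_at(sim), 1:n, f_at(crystal), 1:n)
    D <- as.matrix(stats::dist(rbind(sim, crystal)))[1:n, n + 1:n]
    expect_equal(nrow(ov$matches), oracle_assignment(D, 2.0)$n)
    expect_lte(nrow(ov$matches), min(n, n))
    # shrinking the cutoff never increases the match count
    ov1 <- match_crystal_waters(f_at(sim), 1:n, f_at(crystal), 1:n,
                                cutoff_A = 1.0)
    expect_lte(nrow(ov1$matches), nrow(ov$matches))
    expect_true(all(ov$matches$displacement < 2.0))
  }
})

test_that("superposition removes rigid motion and reports exact RMSD", {
  set.seed(8)
  xyz <- matrix(runif(60, 0, 10), ncol = 3)
  ref <- frame(xyz)
  expect_equal(superpose(ref, ref, 1:20)$rmsd, 0, tolerance = 1e-9)

  rot <- rigid_frame(ref, rotation_matrix_test(c(0, 0, 1), 90), c(3, -2, 7))
  sup <- superpose(rot, ref, 1:20)
  expect_equal(sup$rmsd, 0, tolerance = 1e-6)
  expect_lt(max(abs(sup$frame$xyz - ref$xyz)), 1e-6)

  # half the atoms displaced 1 A after fitting on the fixed half:
  # residue RMSD over the displaced half is exactly 1 A
  atoms <- data.frame(atom_name = paste0("C", 1:20), residue_name = "XXX",
                      residue_id = rep(c(1L, 2L), each = 10), chain_id = "A",
                      element = "C")
  top <- topology(atoms, xyz)
  moved <- xyz
  moved[11:20, 1] <- moved[11:20, 1] + 1
  rr <- residue_rmsd_series(list(frame(moved)), top, 2, ref,
                            fit_atoms = 1:10)
  expect_equal(rr$mean, 1, tolerance = 1e-9)
  expect_equal(rr$sd, 0)

  expect_error(superpose(ref, ref, 1:2), "at least 3")
  coll <- frame(cbind(1:10, 0, 0))
  expect_error(superpose(coll, coll, 1:10), "collinear")
})

test_that("residue RMSD series matches chi-distribution expectations", {
  set.seed(21)
  n_fit <- 30; m <- 8; sigma <- 0.3; F_n <- 200
  xyz <- rbind(matrix(runif(3 * n_fit, 0, 20), ncol = 3),
               matrix(runif(3 * m, 0, 5), ncol = 3))
  atoms <- data.frame(atom_name = paste0("C", seq_len(n_fit + m)),
                      residue_name = "XXX",
                      residue_id = rep(c(1L, 2L), c(n_fit, m)),
                      chain_id = "A", element = "C")
  top <- topology(atoms, xyz)
  ref <- frame(xyz)
  frames <- lapply(seq_len(F_n), function(i) {
    x <- xyz
    x[n_fit + 1:m, ] <- x[n_fit + 1:m, ] +
      matrix(rnorm(3 * m, sd = sigma), ncol = 3)
    frame(x, time = i - 1)
  })
  rr <- residue_rmsd_series(frames, top, 2, ref, fit_atoms = seq_len(n_fit))
  mom <- rmsd_chi_moments(sigma, m)
  expect_lt(abs(rr$mean - mom$mean), 3 * mom$sd / sqrt(F_n))

  # static trajectory: exactly zero
  rr0 <- residue_rmsd_series(list(ref, ref), top, 2, ref,
                             fit_atoms = seq_len(n_fit))
  expect_equal(rr0$mean, 0)
  expect_equal(rr0$sd, 0)
  expect_error(residue_rmsd_series(list(ref), top, 99, ref, 1:n_fit),
               "zero heavy atoms")
})

test_that("per-frame RMSD increases monotonically under a planted drift", {
  set.seed(2)
  n <- 25
  xyz <- matrix(runif(3 * n, 0, 15), ncol = 3)
  atoms <- data.frame(atom_name = paste0("C", 1:n), residue_name = "XXX",
                      residue_id = rep(c(1L, 2L), c(n - 5, 5)),
                      chain_id = "A", element = "C")
  top <- topology(atoms, xyz)
  ref <- frame(xyz)
  frames <- lapply(1:10, function(i) {
    x <- xyz
    x[(n - 4):n, 1] <- x[(n - 4):n, 1] + 0.2 * i
    frame(x, time = i)
  })
  rr <- residue_rmsd_series(frames, top, 2, ref, fit_atoms = seq_len(n - 5))
  expect_true(all(diff(rr$per_frame$rmsd) > 0))
})
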