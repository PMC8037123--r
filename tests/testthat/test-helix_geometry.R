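# Hinge-bend angle, backbone i->i+4 hydrogen bond, gating contacts.

test_that("axis fitting recovers construction, equivariance and noise bounds", {
  pts <- helix_points(13)
  ax <- fit_helix_axis(pts)
  expect_lt(acos(abs(sum(ax$axis * c(0, 0, 1)))), 1e-3)
  expect_gt(sum(ax$axis * c(0, 0, 1)), 0)  # oriented N -> C

  set.seed(6)
  for (rep in 1:5) {
    R <- random_rotation()
    ax_r <- fit_helix_axis(pts %*% t(R))
    expect_lt(acos(min(1, abs(sum(ax_r$axis * (R %*% ax$axis))))), 1e-6)
  }

  # noisy helix: axis within 2 degrees of the construction axis in
  # Monte-Carlo expectation (per-sample tilts scatter around ~1.5 deg
  # at this noise level and flank length)
  tilts <- replicate(40, {
    noisy <- helix_points(13) + matrix(rnorm(39, sd = 0.3), ncol = 3)
    acos(abs(sum(fit_helix_axis(noisy)$axis * c(0, 0, 1)))) * 180 / pi
  })
  expect_lt(mean(tilts), 2)

  expect_error(fit_helix_axis(pts[1:2, ]), "at least 3")
})

test_that("bend angle recovers planted kinks within a degree", {
  scaffold <- build_scaffold()
  spec <- helix_bend_spec()
  straight <- bend_angle(scaffold$frame, scaffold$topology, spec)
  expect_lt(straight, 1)

  for (theta in c(10, 15, 25, 30)) {
    tr <- generate_trajectory(scenario_spec(
      "pore_closure", n_frames = 10,
      kink_script = list(onset_frame = 2, final_angle_deg = theta,
                         ramp_frames = 1, contact_from = 8,
                         contact_to = 4.2, backbone_to = 5.2), seed = 1))
    measured <- bend_angle(tr$frames[[10]], tr$topology, spec)
    expect_lt(abs(measured - theta), 1)
  }

  # rigid motion of the whole frame leaves the angle unchanged
  set.seed(14)
  tr <- generate_trajectory(scenario_spec(
    "pore_closure", n_frames = 5,
    kink_script = list(onset_frame = 2, final_angle_deg = 20,
                       ramp_frames = 1, contact_from = 8, contact_to = 4.2,
                       backbone_to = 5.2), seed = 1))
  f <- tr$frames[[5]]
  a0 <- bend_angle(f, tr$topology, spec)
  for (rep in 1:5) {
    expect_equal(bend_angle(rigid_frame(f), tr$topology, spec), a0,
                 tolerance = 1e-6)
  }

  expect_error(helix_bend_spec(pre_hinge_range = c(748, 752)), "at least 6")
  expect_error(helix_bend_spec(pre_hinge_range = c(748, 762)), "disjoint")
})

test_that("backbone i->i+4 distance distinguishes intact from broken", {
  scaffold <- build_scaffold()
  # ideal helix geometry: ~3 A and intact
  bb <- backbone_hbond_distance(scaffold$frame, scaffold$topology, 761, 765)
  expect_equal(bb$distance, 3.0, tolerance = 0.15)
  expect_false(bb$broken)

  # planted separation of 5.2 A flags broken
  tr <- generate_trajectory(scenario_spec("pore_closure", n_frames = 40,
                                          seed = 1))
  bb2 <- backbone_hbond_distance(tr$frames[[40]], tr$topology, 761, 765)
  expect_equal(bb2$distance, 5.2, tolerance = 1e-6)
  expect_true(bb2$broken)

  # closed boundary: exactly at the cutoff counts as intact
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3.5, 0, 0),
               c(4, 1, 0), c(4, 2, 0))
  atoms <- data.frame(atom_name = c("N", "CA", "C", "O", "N", "CA"),
                      residue_name = "ILE",
                      residue_id = c(761L, 761L, 761L, 761L, 765L, 765L),
                      chain_id = "A", element = c("N", "C", "C", "O", "N", "C"))
  top <- topology(atoms, xyz)
  xyz[5, ] <- c(3.5 + 3.5, 0, 0)
  bb3 <- backbone_hbond_distance(frame(xyz), top, 761, 765)
  expect_equal(bb3$distance, 3.5)
  expect_false(bb3$broken)

  expect_error(backbone_hbond_distance(scaffold$frame, scaffold$topology,
                                       761, 9999), "missing")
})

test_that("contact distances support min/centroid modes and the R<5 flag", {
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(4.2, 0, 0), c(9, 0, 0))
  atoms <- data.frame(atom_name = c("NH1", "NH2", "O", "O2"),
                      residue_name = c("ARG", "ARG", "SER", "SER"),
                      residue_id = c(762L, 762L, 915L, 915L),
                      chain_id = "A", element = c("N", "N", "O", "O"))
  top <- topology(atoms, xyz)
  f <- frame(xyz)

  # coincident single atoms
  cd0 <- contact_distance(frame(rbind(c(1, 1, 1), c(1, 1, 1))), top, 1, 2)
  expect_equal(cd0$distance, 0)

  # guanidine N planted 4.2 A from the backbone O: contact under R < 5
  cd <- contact_distance(f, top, 1:2, 3)
  expect_equal(cd$distance, 3.2)  # nearest nitrogen
  expect_true(cd$contact)

  cd_c <- contact_distance(f, top, 1:2, 3, mode = "centroid")
  expect_equal(cd_c$distance, 4.2 - 0.5)

  expect_error(contact_distance(f, top, integer(0), 3), "empty")

  # the minimum-distance mode is bounded by every pairwise distance, and
  # both modes are bounded by the mean pairwise distance (the centroid
  # distance by convexity; the minimum by definition)
  set.seed(19)
  for (rep in 1:100) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    xy <- matrix(runif(3 * (n1 + n2), 0, 10), ncol = 3)
    at <- data.frame(atom_name = paste0("X", seq_len(n1 + n2)),
                     residue_name = "XXX",
                     residue_id = rep(c(1L, 2L), c(n1, n2)), chain_id = "A",
                     element = "C")
    tp <- topology(at, xy)
    fr <- frame(xy)
    pw <- as.matrix(stats::dist(xy))[1:n1, n1 + 1:n2, drop = FALSE]
    d_min <- contact_distance(fr, tp, 1:n1, n1 + 1:n2)$distance
    d_cen <- contact_distance(fr, tp, 1:n1, n1 + 1:n2,
                              mode = "centroid")$distance
    expect_equal(d_min, min(pw), tolerance = 1e-12)
    expect_lte(d_min, mean(pw) + 1e-12)
    expect_lte(d_cen, mean(pw) + 1e-12)
  }

  # for compact groups facing each other (the gating-contact situation)
  # the minimum mode does not exceed the centroid mode
  set.seed(29)
  for (rep in 1:20) {
    a <- matrix(rnorm(9, sd = 0.4), ncol = 3)
    b <- sweep(matrix(rnorm(9, sd = 0.4), ncol = 3), 2, c(8, 0, 0), "+")
    # include the projections of each centroid on the contact axis
    a <- rbind(a, c(max(a[, 1]) + 0.3, 0, 0))
    b <- rbind(b, c(min(b[, 1]) - 0.3, 0, 0))
    at <- data.frame(atom_name = paste0("X", 1:8), residue_name = "XXX",
                     residue_id = rep(c(1L, 2L), each = 4L), chain_id = "A",
                     element = "C")
    tp <- topology(at, rbind(a, b))
    fr <- frame(rbind(a, b))
    expect_lte(contact_distance(fr, tp, 1:4, 5:8)$distance,
               contact_distance(fr, tp, 1:4, 5:8,
                                mode = "centroid")$distance + 1e-12)
  }
})

test_that("geometry series captures the planted closure concomitance", {
  # static straight helix: constant series
  occ <- data.frame(from = 1, to = 5, count = 4)
  tr0 <- generate_trajectory(scenario_spec("hydration_onset", n_frames = 5,
                                           occupancy_script = occ, seed = 3))
  geo0 <- geometry_timeseries(tr0$frames, tr0$topology)
  expect_lt(max(geo0$series$bend_angle) - min(geo0$series$bend_angle), 1e-9)
  expect_lt(diff(range(geo0$series$contact_distance)), 1e-9)

  # single-frame trajectory: length-1 series
  geo1 <- geometry_timeseries(tr0$frames[1], tr0$topology)
  expect_equal(nrow(geo1$series), 1)

  # closure: the three observables cross their thresholds inside the same
  # scripted window (kink up through 10 deg, contact below 5 A, backbone
  # bond beyond 3.5 A)
  tr <- generate_trajectory(scenario_spec("pore_closure", n_frames = 120,
                                          seed = 2))
  ks <- tr$spec$kink_script
  geo <- geometry_timeseries(tr$frames, tr$topology,
                             windows = list(c(0, 200)))
  s <- geo$series
  win <- tr$ground_truth$times[c(ks$onset_frame,
                                 ks$onset_frame + ks$ramp_frames)]
  t_bend <- s$time[which(s$bend_angle >= 10)[1]]
  t_contact <- s$time[which(s$contact_distance < 5)[1]]
  t_bb <- s$time[which(s$backbone_on_distance > 3.5)[1]]
  for (t_cross in c(t_bend, t_contact, t_bb)) {
    expect_gte(t_cross, win[1])
    expect_lte(t_cross, win[2])
  }
  expect_equal(nrow(geo$window_means), 1)
})
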