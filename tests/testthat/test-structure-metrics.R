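# one-frame trajectory with a donor-H-acceptor triple at chosen geometry
hbond_traj <- function(d_HA, angle_deg) {
  # D at origin, H at 1.0 along x; acceptor placed at distance d_HA from H
  # such that the D-H...A angle is angle_deg
  ang <- angle_deg * pi / 180
  H <- c(1, 0, 0)
  A <- H + d_HA * c(-cos(ang), sin(ang), 0)   # angle between H->D and H->A
  atoms <- data.frame(serial = 1:3, name = c("NZ", "HZ", "O1"),
                      element = c("N", "H", "O"),
                      resname = c("LYS", "LYS", "SUB"),
                      resnum = c(146L, 146L, 600L),
                      monomer = c("B", "B", "B"))
  top <- topology_spec(atoms,
                       anchor_donors = list(c("B:146:NZ", "B:146:HZ")),
                       anchor_acceptors = "B:600:O1")
  trajectory(top, matrix(c(0, 0, 0, H, A), nrow = 1))
}

test_that("hydrogen-bond events respect the distance and angle criteria", {
  hit <- detect_anchor_hbonds(hbond_traj(1.872, 180))
  expect_equal(nrow(hit$events), 1L)
  expect_equal(hit$events$d_H_A, 1.872, tolerance = 1e-9)
  expect_equal(hit$events$angle_DHA, 180, tolerance = 1e-6)
  expect_equal(hit$occupancy$occupancy, 1)

  far <- detect_anchor_hbonds(hbond_traj(3.6, 180))
  expect_equal(nrow(far$events), 0L)
  expect_equal(far$occupancy$occupancy, 0)

  bent <- detect_anchor_hbonds(hbond_traj(2.0, 90))
  expect_equal(nrow(bent$events), 0L)

  # the long carboxylate anchor contact is still accepted at defaults
  long <- detect_anchor_hbonds(hbond_traj(3.346, 160))
  expect_equal(nrow(long$events), 1L)
})

test_that("hydrogen-bond detection is invariant under rigid motion and occupancy counts events", {
  t0 <- hbond_traj(2.2, 150)
  moved <- transform_trajectory(t0, random_rigid_motion(5))
  a <- detect_anchor_hbonds(t0); b <- detect_anchor_hbonds(moved)
  expect_equal(b$events$d_H_A, a$events$d_H_A, tolerance = 1e-9)
  expect_equal(b$events$angle_DHA, a$events$angle_DHA, tolerance = 1e-6)

  # multi-frame trajectory: occupancy = events / frames exactly
  xyz <- rbind(t0$xyz, t0$xyz, hbond_traj(3.6, 150)$xyz)
  t3 <- trajectory(t0$topology, xyz)
  occ <- detect_anchor_hbonds(t3)$occupancy
  expect_equal(occ$n_events, 2L)
  expect_equal(occ$occupancy, 2 / 3)
})

test_that("ideal helices are fully helical; displaced residues lose their flags", {
  for (n in c(5L, 12L, 18L)) {
    h <- gen_ideal_helix(n)
    ah <- assign_helix(h$trajectory, "helix")
    expect_true(all(ah$flags[1, ]))
    expect_equal(ah$metrics$longest_run, n)
  }
  h18 <- gen_ideal_helix(18L)
  ah18 <- assign_helix(h18$trajectory, "helix")
  expect_equal(ah18$metrics$n_turns, 5L)

  # displace residues 8-12 by graded >= 5 Angstrom shifts along x (so the
  # displaced block does not move rigidly): they lose helicity
  traj <- h18$trajectory
  xyz <- traj$xyz
  at <- traj$topology$atoms
  for (k in which(at$resnum %in% 8:12))
    xyz[1, 3 * k - 2] <- xyz[1, 3 * k - 2] + 5 * (at$resnum[k] - 7)
  moved <- trajectory(traj$topology, xyz)
  am <- assign_helix(moved, "helix")
  expect_false(any(am$flags[1, as.character(8:12)]))
  expect_true(all(am$flags[1, as.character(c(1:7, 13:18))]))

  # fully extended chain has no helical residues
  ext <- gen_ideal_helix(18L, unwound = 1:18)
  ae <- assign_helix(ext$trajectory, "helix")
  expect_false(any(ae$flags[1, ]))
  expect_equal(ae$metrics$n_turns, 0L)
})

test_that("partial unwinding reproduces the generator's ground truth", {
  h <- gen_ideal_helix(18L, unwound = 1:11)
  ah <- assign_helix(h$trajectory, "helix")
  expect_equal(unname(ah$flags[1, ]), h$ground_truth$flags)
  expect_equal(ah$metrics$longest_run, h$ground_truth$longest_run)
  expect_equal(ah$metrics$n_turns, 2L)   # two of the original five turns
  expect_error(gen_ideal_helix(18L, unwound = 10:20), "outside")
})

test_that("turn counting divides the longest run by 3.6 residues per turn", {
  expect_equal(count_turns(rep(TRUE, 18)), 5L)
  expect_equal(count_turns(rep(TRUE, 25)), 7L)
  expect_equal(count_turns(rep(TRUE, 7)), 2L)
  expect_equal(count_turns(logical(10)), 0L)
  expect_equal(count_turns(c(rep(TRUE, 7), FALSE, rep(TRUE, 3))), 2L)
  # monotone in run length
  runs <- vapply(1:30, function(n) count_turns(rep(TRUE, n)), integer(1))
  expect_true(all(diff(runs) >= 0))
})

test_that("contact distance series track the generator and summarize correctly", {
  static <- gen_contact_pair(5, 12, 12)
  cs <- contact_distance_series(static$trajectory, static$pair)
  expect_equal(cs$mean, 12)
  expect_equal(cs$sd, 0)

  two <- gen_contact_pair(2, 10, 14)
  c2 <- contact_distance_series(two$trajectory, two$pair)
  expect_equal(c2$series$distance, c(10, 14))
  expect_equal(c2$mean, 12)

  drift <- gen_contact_pair(50, 12, 17, noise_sd = 0.4, seed = 6)
  cd <- contact_distance_series(drift$trajectory, drift$pair)
  expect_equal(cd$series$distance, drift$ground_truth, tolerance = 1e-9)

  expect_error(contact_distance_series(static$trajectory,
                                       c("A:1:XX", "B:192:CD2")), "A:1:XX")
})
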