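test_that("multi-model PDB reading preserves frames, atoms and coordinates", {
  atoms <- data.frame(serial = 1:5,
                      name = c("OH", "C13", "H3S", "H3R", "C12"),
                      element = c("O", "C", "H", "H", "C"),
                      resname = c("FEO", rep("SUB", 4)),
                      resnum = c(1L, rep(2L, 4)),
                      monomer = c("A", rep("B", 4)))
  f1 <- matrix(rnorm(15, sd = 3), ncol = 3)
  f2 <- f1 + 0.5
  path <- write_tiny_pdb(list(f1, f2), atoms)
  traj <- read_multimodel_pdb(path)
  expect_equal(n_frames(traj), 2L)
  expect_equal(nrow(traj$topology$atoms), 5L)
  # PDB carries 3 decimals
  expect_equal(frame_coords(traj, 1), round(f1, 3), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(frame_coords(traj, 2), round(f2, 3), ignore_attr = TRUE,
               tolerance = 1e-12)

  single <- write_tiny_pdb(list(f1), atoms)
  t1 <- read_multimodel_pdb(single)
  expect_equal(n_frames(t1), 1L)
  expect_equal(t1$time_ns, 0)
})

test_that("addresses in a config resolve against PDB records; absent residues error", {
  atoms <- data.frame(serial = 1:4,
                      name = c("OH", "C13", "H3S", "H3R"),
                      element = c("O", "C", "H", "H"),
                      resname = c("FEO", rep("SUB", 3)),
                      resnum = c(1L, rep(2L, 3)),
                      monomer = c("A", rep("B", 3)))
  path <- write_tiny_pdb(list(matrix(rnorm(12), ncol = 3)), atoms)
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("cofactor_oxygen: A:1:OH",
               "reactive_carbon: B:2:C13",
               "h_proS: B:2:H3S",
               "h_proR: B:2:H3R"), cfg)
  traj <- read_multimodel_pdb(path, cfg)
  expect_equal(traj$topology$reactive_carbon, "B:2:C13")
  expect_equal(resolve_address(traj$topology, "B:2:C13"), 2L)

  bad <- tempfile(fileext = ".yaml")
  writeLines("cofactor_oxygen: A:9999:OH", bad)
  expect_error(read_multimodel_pdb(path, bad), "A:9999:OH")
})

test_that("frame-table round trip is coordinate-exact and errors are caught", {
  g <- gen_reactive_frames(7, 4, 0.3, seed = 11)
  path <- tempfile(fileext = ".tsv")
  write_frame_table(g$trajectory, path)
  back <- read_frame_table(path)
  expect_identical(back$xyz, g$trajectory$xyz, ignore_attr = TRUE)
  expect_equal(back$time_ns, g$trajectory$time_ns)
  expect_equal(back$frame, g$trajectory$frame)

  # ragged frame: drop one atom row from frame 0
  tab <- readLines(path)
  writeLines(tab[-2L], path)
  expect_error(read_frame_table(path), "ragged")

  empty <- tempfile(fileext = ".tsv")
  writeLines(tab[1L], empty)
  expect_error(read_frame_table(empty), "empty")
})

test_that("atom addressing is order-independent for downstream distances", {
  g <- gen_reactive_frames(5, 4, 0.3, seed = 12)
  rd <- compute_reactive_distances(g$trajectory)
  # permute atom order in the serialized table
  top <- g$trajectory$topology
  perm <- c(3L, 1L, 6L, 2L, 5L, 4L)
  atoms <- top$atoms[perm, ]
  xyz <- matrix(NA_real_, n_frames(g$trajectory), ncol = 18L)
  for (i in seq_len(n_frames(g$trajectory))) {
    co <- frame_coords(g$trajectory, i)[perm, ]
    xyz[i, ] <- as.vector(t(co))
  }
  top2 <- topology_spec(atoms,
                        cofactor_oxygen = top$cofactor_oxygen,
                        reactive_carbon = top$reactive_carbon,
                        h_proS = top$h_proS, h_proR = top$h_proR)
  traj2 <- trajectory(top2, xyz, frame = g$trajectory$frame,
                      time_ns = g$trajectory$time_ns)
  rd2 <- compute_reactive_distances(traj2)
  expect_equal(rd2, rd)
})

test_that("topology invariants are enforced", {
  atoms <- data.frame(serial = c(1L, 1L), name = c("A1", "A2"),
                      element = "C", resname = "UNK", resnum = 1L,
                      monomer = "A")
  expect_error(topology_spec(atoms), "unique")
  atoms2 <- data.frame(serial = 1:2, name = c("A1", "A1"),
                       element = "C", resname = "UNK", resnum = 1L,
                       monomer = "A")
  expect_error(topology_spec(atoms2), "duplicate")
  atoms3 <- data.frame(serial = 1:2, name = c("C1", "H1"),
                       element = c("C", "H"), resname = "UNK", resnum = 1L,
                       monomer = "A")
  expect_error(topology_spec(atoms3, h_proS = "A:1:H1", h_proR = "A:1:H1"),
               "differ")
  expect_error(topology_spec(atoms3, cofactor_oxygen = "A:1:OX"),
               "A:1:OX")
})
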