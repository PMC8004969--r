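test_that("pairwise RMSD is zero for identical/rigidly-moved frames", {
  g <- gen_clustered_frames(c(4L), jitter_sd = 0, seed = 2)
  M <- pairwise_rmsd(g$trajectory)
  expect_equal(M, matrix(0, 4, 4), tolerance = 1e-9, ignore_attr = TRUE)

  # frame j = rigid motion of frame i
  traj <- g$trajectory
  xyz <- traj$xyz
  mo <- random_rigid_motion(8)
  co <- apply_rigid(matrix(xyz[2, ], ncol = 3, byrow = TRUE), mo)
  xyz[2, ] <- as.vector(t(co))
  traj2 <- trajectory(traj$topology, xyz, frame = traj$frame,
                      time_ns = traj$time_ns)
  M2 <- pairwise_rmsd(traj2)
  expect_lt(max(M2), 1e-9)
})

test_that("pairwise RMSD matrix matches per-pair oracle recomputation", {
  g <- gen_clustered_frames(c(10L, 10L), separation = 3, jitter_sd = 0.3,
                            n_atoms = 8L, seed = 21)
  M <- pairwise_rmsd(g$trajectory)
  expect_equal(M, t(M))
  expect_equal(diag(M), rep(0, 20))
  set.seed(33)
  pairs <- cbind(sample(20, 8, replace = TRUE), sample(20, 8, replace = TRUE))
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  idx <- resolve_addresses(g$trajectory$topology,
                           g$trajectory$topology$substrate_heavy_atoms)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    oracle <- oracle_min_rmsd(frame_coords(g$trajectory, i, idx),
                              frame_coords(g$trajectory, j, idx),
                              n_quat = 5000L, seed = k)
    expect_equal(M[i, j], oracle, tolerance = 1e-3)
  }
})

test_that("neighbor-counting clustering recovers planted partitions", {
  # all-zero matrix: one cluster
  z <- cluster_frames(matrix(0, 5, 5), 0.5)
  expect_equal(z$sizes, 5L)
  expect_equal(z$labels, rep(0L, 5))

  g <- gen_clustered_frames(c(7L, 3L), jitter_sd = 0, seed = 3)
  cl <- cluster_frames(pairwise_rmsd(g$trajectory), 0.5)
  expect_equal(cl$sizes, c(7L, 3L))
  expect_equal(cl$labels, g$labels)

  one <- gen_clustered_frames(c(10L), jitter_sd = 0.02, seed = 4)
  c1 <- cluster_frames(pairwise_rmsd(one$trajectory), 0.5)
  expect_equal(c1$n_clusters, 1L)

  skip_if_not_installed("mclust")
  big <- gen_clustered_frames(c(50L, 30L, 20L), jitter_sd = 0.05, seed = 7)
  cb <- cluster_frames(pairwise_rmsd(big$trajectory), 0.5)
  expect_equal(mclust::adjustedRandIndex(cb$labels, big$labels), 1.0)
  expect_equal(cb$sizes, c(50L, 30L, 20L))
})

test_that("clustering agrees with an exhaustive removal-order oracle and validates input", {
  set.seed(17)
  for (rep in 1:4) {
    n <- 12L
    pts <- matrix(rnorm(2 * n), ncol = 2)
    M <- as.matrix(dist(pts))
    cl <- cluster_frames(M, cutoff = 1.2)
    expect_equal(cl$labels, oracle_daura(M, 1.2))
    expect_equal(sum(cl$sizes), n)
    expect_true(all(diff(cl$sizes) <= 0))
  }
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(cluster_frames(bad, 0.5), "symmetric")
  neg <- matrix(c(0, -1, -1, 0), 2, 2)
  expect_error(cluster_frames(neg, 0.5), "non-negative|symmetric")
})

test_that("raising the cutoff never increases the cluster count", {
  set.seed(23)
  for (rep in 1:3) {
    pts <- matrix(rnorm(30), ncol = 2)
    M <- as.matrix(dist(pts))
    cuts <- c(0.2, 0.5, 1, 2, 4)
    ncl <- vapply(cuts, function(ct) cluster_frames(M, ct)$n_clusters,
                  integer(1))
    expect_true(all(diff(ncl) <= 0))
  }
})

test_that("centroid extraction picks the minimal-total-RMSD member", {
  # 3 frames with pair distances (0.1, 0.1, 0.2): middle frame wins
  M <- matrix(c(0, 0.1, 0.2,
                0.1, 0, 0.1,
                0.2, 0.1, 0), 3, 3)
  res <- cluster_frames(M, cutoff = 10)
  expect_equal(extract_centroid(M, res), 2L)

  # planted star: hub at 0.1 from all, others 0.2 apart
  n <- 6L
  M2 <- matrix(0.2, n, n); diag(M2) <- 0
  M2[1, ] <- M2[, 1] <- 0.1; M2[1, 1] <- 0
  res2 <- cluster_frames(M2, cutoff = 10)
  expect_equal(extract_centroid(M2, res2), 1L)

  # singleton most-populated cluster returns that frame
  M3 <- matrix(5, 2, 2); diag(M3) <- 0
  res3 <- cluster_frames(M3, cutoff = 0.5)
  expect_equal(extract_centroid(M3, res3), 1L)

  # idempotence on identical copies: first copy wins ties
  M4 <- matrix(0, 4, 4)
  res4 <- cluster_frames(M4, cutoff = 0.5)
  expect_equal(extract_centroid(M4, res4), 1L)
})
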