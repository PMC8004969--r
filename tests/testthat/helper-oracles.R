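# Independent oracles used by the tests.  Each deliberately avoids the
# package's own code path for the quantity it checks.

# Minimum RMSD over proper rotations by dense random-quaternion scanning
# plus Nelder-Mead refinement of the best candidates (never uses Kabsch).
oracle_min_rmsd <- function(ref, mov, n_quat = 20000L, seed = 1L) {
  set.seed(seed)
  P <- sweep(mov, 2L, colMeans(mov))
  Q <- sweep(ref, 2L, colMeans(ref))
  quat_to_rot <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           nrow = 3L, byrow = TRUE)
  }
  obj_q <- function(q) {
    R <- quat_to_rot(q)
    sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
  }
  qs <- matrix(rnorm(4L * n_quat), ncol = 4L)
  vals <- apply(qs, 1L, obj_q)
  best <- order(vals)[1:5]
  refined <- vapply(best, function(i)
    stats::optim(qs[i, ], obj_q, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))$value,
    numeric(1L))
  min(refined)
}

# Brute-force re-implementation of greedy neighbor-counting clustering,
# written as an explicit removal loop over index sets.
oracle_daura <- function(M, cutoff) {
  n <- nrow(M)
  pool <- seq_len(n)
  labels <- rep(NA_integer_, n)
  cl <- 0L
  while (length(pool) > 0L) {
    counts <- sapply(pool, function(i) sum(M[i, pool] <= cutoff))
    center <- pool[which(counts == max(counts))[1L]]   # lowest index on ties
    members <- pool[M[center, pool] <= cutoff]
    labels[members] <- cl
    pool <- setdiff(pool, members)
    cl <- cl + 1L
  }
  sizes <- as.integer(table(labels))
  first <- sapply(sort(unique(labels)), function(k) min(which(labels == k)))
  ord <- order(-sizes, first)
  relabel <- integer(cl); relabel[ord] <- seq_len(cl) - 1L
  relabel[labels + 1L]
}

# random rigid motion (proper rotation + translation)
random_rigid_motion <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- rnorm(4L); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
              nrow = 3L, byrow = TRUE)
  list(R = R, t = runif(3L, -5, 5))
}

apply_rigid <- function(coords, motion) {
  sweep(coords %*% t(motion$R), 2L, -motion$t)
}

# apply a rigid motion to every frame of a trajectory
transform_trajectory <- function(traj, motion) {
  xyz <- traj$xyz
  for (i in seq_len(nrow(xyz))) {
    co <- apply_rigid(matrix(xyz[i, ], ncol = 3L, byrow = TRUE), motion)
    xyz[i, ] <- as.vector(t(co))
  }
  trajectory(traj$topology, xyz, frame = traj$frame, time_ns = traj$time_ns)
}

# mirror all coordinates through x -> -x
mirror_trajectory <- function(traj) {
  xyz <- traj$xyz
  xyz[, seq(1L, ncol(xyz), by = 3L)] <- -xyz[, seq(1L, ncol(xyz), by = 3L)]
  trajectory(traj$topology, xyz, frame = traj$frame, time_ns = traj$time_ns)
}

# adjusted Rand index from the pair-counting contingency formula
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  sa <- sum(ch2(rowSums(tab)))
  sb <- sum(ch2(colSums(tab)))
  n <- ch2(length(a))
  expected <- sa * sb / n
  (sij - expected) / ((sa + sb) / 2 - expected)
}
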