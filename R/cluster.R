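#' Pairwise RMSD matrix over trajectory frames
#'
#' `M[i, j]` is the RMSD of the `rmsd_selection` atoms of frame j after
#' rigid superposition of frame j onto frame i using the `fit_selection`
#' atoms.  When the two selections coincide (the default: the substrate
#' heavy atoms) this is plain ligand-conformation RMSD; fitting on e.g.
#' binding-pocket backbone atoms while measuring the ligand gives
#' pocket-referenced binding-mode RMSD.  The matrix is symmetrized as
#' `(M + t(M)) / 2` (the two directions differ only when the selections
#' differ) and has a zero diagonal.  RMSD is mass-unweighted heavy-atom
#' RMSD.
#'
#' @param traj a `lox_trajectory`.
#' @param fit_selection,rmsd_selection atom addresses (default: the
#'   topology's `substrate_heavy_atoms` for both).
#' @return symmetric `n_frames x n_frames` matrix (Angstrom).
#' @export
pairwise_rmsd <- function(traj,
                          fit_selection = NULL,
                          rmsd_selection = NULL) {
  top <- traj$topology
  fit_selection <- fit_selection %||% top$substrate_heavy_atoms
  rmsd_selection <- rmsd_selection %||% fit_selection
  if (length(fit_selection) < 3L)
    stop("need at least 3 fit atoms", call. = FALSE)
  fit_idx <- resolve_addresses(top, fit_selection)
  rms_idx <- resolve_addresses(top, rmsd_selection)
  nf <- n_frames(traj)
  if (nf < 2L)
    stop("pairwise RMSD needs at least 2 frames", call. = FALSE)
  fit_xyz <- lapply(seq_len(nf), frame_coords, traj = traj, atoms = fit_idx)
  rms_xyz <- lapply(seq_len(nf), frame_coords, traj = traj, atoms = rms_idx)
  M <- matrix(0, nf, nf)
  same_sel <- identical(sort(fit_idx), sort(rms_idx))
  for (i in seq_len(nf - 1L)) {
    for (j in (i + 1L):nf) {
      tr <- superpose(fit_xyz[[i]], fit_xyz[[j]])
      M[i, j] <- if (same_sel && identical(fit_idx, rms_idx)) tr$rmsd
      else rmsd_nofit(rms_xyz[[i]], apply_transform(rms_xyz[[j]], tr))
      tr2 <- superpose(fit_xyz[[j]], fit_xyz[[i]])
      M[j, i] <- if (same_sel && identical(fit_idx, rms_idx)) tr2$rmsd
      else rmsd_nofit(rms_xyz[[j]], apply_transform(rms_xyz[[i]], tr2))
    }
  }
  (M + t(M)) / 2
}

#' Cutoff-based conformational clustering (neighbor counting)
#'
#' The Daura/GROMOS procedure, the de facto standard for cutoff-based MD
#' clustering: repeatedly take the unassigned frame with the largest number
#' of unassigned neighbors within `cutoff`, make it and its neighbors a
#' cluster, remove them, and repeat.  Ties on neighbor count are broken by
#' the lowest frame index; final cluster ids are renumbered by decreasing
#' size (id 0 = most populated), size ties by earliest member.
#'
#' @param matrix symmetric pairwise RMSD matrix with zero diagonal
#'   ([pairwise_rmsd()]).
#' @param cutoff neighbor cutoff in Angstrom (default 0.5, the standard
#'   threshold for heavy-atom substrate binding-mode clustering).
#' @return object of class `lox_clusters`: list with `labels` (0-based
#'   per-frame cluster ids), `sizes` (per-cluster counts, non-increasing)
#'   and `n_clusters`.
#' @export
cluster_frames <- function(matrix, cutoff = 0.5) {
  M <- as.matrix(matrix)
  n <- nrow(M)
  if (n != ncol(M) || any(abs(M - t(M)) > 1e-9) || any(M < 0) ||
      any(abs(diag(M)) > 1e-12))
    stop("need a symmetric non-negative matrix with zero diagonal",
         call. = FALSE)
  adj <- M <= cutoff
  remaining <- rep(TRUE, n)
  labels <- integer(n)
  cl <- 0L
  while (any(remaining)) {
    counts <- ifelse(remaining, rowSums(adj[, remaining, drop = FALSE]), -1L)
    center <- which.max(counts)          # which.max takes the lowest index on ties
    members <- which(remaining & adj[center, ])
    labels[members] <- cl
    remaining[members] <- FALSE
    cl <- cl + 1L
  }
  # renumber by size descending; size ties by earliest member
  sizes <- tabulate(labels + 1L, nbins = cl)
  first <- vapply(seq_len(cl) - 1L, function(k) min(which(labels == k)),
                  integer(1L))
  ord <- order(-sizes, first)
  relabel <- integer(cl)
  relabel[ord] <- seq_len(cl) - 1L
  labels <- relabel[labels + 1L]
  structure(list(labels = labels, sizes = sizes[ord], n_clusters = cl),
            class = "lox_clusters")
}

#' @export
print.lox_clusters <- function(x, ...) {
  cat("<lox_clusters> ", x$n_clusters, " cluster(s); sizes: ",
      paste(utils::head(x$sizes, 10L), collapse = ", "),
      if (x$n_clusters > 10L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Centroid frame of the most populated cluster
#'
#' The representative binding mode: the member of cluster 0 minimizing the
#' sum of RMSDs to all other members (ties broken by lowest frame index).
#'
#' @param matrix pairwise RMSD matrix used for the clustering.
#' @param result `lox_clusters` from [cluster_frames()].
#' @param cluster cluster id (default 0, the most populated).
#' @return 1-based frame position of the centroid.
#' @export
extract_centroid <- function(matrix, result, cluster = 0L) {
  stopifnot(inherits(result, "lox_clusters"))
  members <- which(result$labels == cluster)
  if (length(members) == 0L)
    stop("cluster ", cluster, " is empty", call. = FALSE)
  if (length(members) == 1L) return(members)
  tot <- rowSums(as.matrix(matrix)[members, members, drop = FALSE])
  members[which.min(tot)]
}
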