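#' Euclidean distance between two points
#'
#' @param p,q numeric length-3 coordinates (Angstrom).
#' @return distance in Angstrom.
#' @export
dist3 <- function(p, q) {
  if (!all(is.finite(p)) || !all(is.finite(q)))
    stop("non-finite coordinates", call. = FALSE)
  sqrt(sum((p - q)^2))
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation R and translation t minimizing the RMSD between
#' `ref` and `R %*% mov + t` over all rigid motions, via the SVD of the
#' cross-covariance of the centered point sets with the usual determinant
#' correction that excludes reflections.
#'
#' Collinear (or coincident) point sets are rejected rather than answered:
#' with rank < 2 the optimal rotation is not unique and a reflection can
#' masquerade as a rotation.
#'
#' @param ref,mov `n x 3` matrices, `n >= 3`.
#' @return list with `rotation` (3x3, det +1), `translation` (length 3) and
#'   `rmsd` (Angstrom) such that `mov %*% t(rotation) + translation`
#'   superposes onto `ref`.
#' @export
superpose <- function(ref, mov) {
  ref <- as.matrix(ref); mov <- as.matrix(mov)
  if (nrow(ref) != nrow(mov) || ncol(ref) != 3L || ncol(mov) != 3L)
    stop("point sets must be n x 3 with equal n", call. = FALSE)
  n <- nrow(ref)
  if (n < 3L)
    stop("superposition needs at least 3 points", call. = FALSE)
  cr <- colMeans(ref); cm <- colMeans(mov)
  P <- sweep(mov, 2L, cm)   # moving, centered
  Q <- sweep(ref, 2L, cr)
  # rank check: all points collinear => second singular value ~ 0
  if (svd(P, nu = 0, nv = 0)$d[2L] < 1e-8 * max(1, svd(P, nu = 0, nv = 0)$d[1L]) ||
      svd(Q, nu = 0, nv = 0)$d[2L] < 1e-8 * max(1, svd(Q, nu = 0, nv = 0)$d[1L]))
    stop("degenerate (collinear) point set: superposition is ambiguous",
         call. = FALSE)
  s <- svd(crossprod(P, Q))           # 3x3 = t(P) %*% Q
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(rotation = R, translation = as.numeric(cr - R %*% cm), rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#' @param coords `n x 3` matrix.
#' @param transform list with `rotation` and `translation` (as returned by
#'   [superpose()]).
#' @export
apply_transform <- function(coords, transform) {
  sweep(as.matrix(coords) %*% t(transform$rotation), 2L,
        -transform$translation)
}

#' RMSD without fitting
#' @param a,b `n x 3` matrices in the same frame of reference.
#' @export
rmsd_nofit <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(nrow(a) == nrow(b))
  sqrt(mean(rowSums((a - b)^2)))
}

#' Assign the prochiral (proS / proR) hydrogens of the reactive carbon
#'
#' The two hydrogens on the bisallylic carbon are distinguished by which
#' would create an R or S center if promoted in CIP priority above the other
#' hydrogen.  If the topology names `h_proS`/`h_proR` explicitly the call is
#' a passthrough (the recommended route: map force-field atom names once in
#' the config).  With the sentinel `"AUTO"` the labels are derived
#' geometrically: with priorities C_high > C_low > H_promoted > H_other, a
#' hydrogen is pro-R when the scalar triple product of the unit bond vectors
#' C->C_high, C->C_low, C->H_promoted is negative (the 1-2-3 priority sweep
#' appears clockwise with the remaining hydrogen pointing away).
#'
#' @param traj a `lox_trajectory` whose topology resolves `reactive_carbon`
#'   (and, for AUTO, `bonds` + `branch_priority`).
#' @param frame frame position used for the geometric test (labels are a
#'   chemical identity, so any frame of a physical trajectory gives the same
#'   answer; default first frame).
#' @return list with elements `h_proS` and `h_proR` (atom addresses).
#' @export
assign_prochiral_hydrogens <- function(traj, frame = 1L) {
  top <- traj$topology
  if (is.null(top$reactive_carbon))
    stop("topology does not declare a reactive carbon", call. = FALSE)
  if (!identical(top$h_proS, "AUTO") && !is.null(top$h_proS) &&
      !is.null(top$h_proR))
    return(list(h_proS = top$h_proS, h_proR = top$h_proR))
  if (length(top$bonds) == 0L || is.null(top$branch_priority))
    stop("AUTO prochiral assignment needs a bond list and branch_priority",
         call. = FALSE)
  rc <- top$reactive_carbon
  nb <- character()
  for (b in top$bonds) {
    if (b[[1L]] == rc) nb <- c(nb, b[[2L]])
    if (b[[2L]] == rc) nb <- c(nb, b[[1L]])
  }
  if (length(nb) != 4L)
    stop("reactive carbon must be tetra-coordinated (found ",
         length(nb), " bonded neighbours)", call. = FALSE)
  el <- top$atoms$element[resolve_addresses(top, nb)]
  hyd <- nb[toupper(el) == "H"]
  carb <- nb[toupper(el) == "C"]
  if (length(hyd) != 2L || length(carb) != 2L)
    stop("reactive carbon must have two H and two C neighbours",
         call. = FALSE)
  if (!top$branch_priority %in% carb)
    stop("branch_priority '", top$branch_priority,
         "' is not a carbon neighbour of the reactive carbon",
         call. = FALSE)
  c_high <- top$branch_priority
  c_low <- setdiff(carb, c_high)
  co <- frame_coords(traj, frame)
  pos <- function(a) co[resolve_address(top, a), ]
  cc <- pos(rc)
  u <- function(a) { v <- pos(a) - cc; v / sqrt(sum(v^2)) }
  triple <- function(h) det(cbind(u(c_high), u(c_low), u(h)))
  t1 <- triple(hyd[1L]); t2 <- triple(hyd[2L])
  if (t1 == 0 || t2 == 0 || sign(t1) == sign(t2))
    stop("degenerate geometry at the reactive carbon: ",
         "prochiral assignment is ambiguous", call. = FALSE)
  if (t1 < 0) list(h_proS = hyd[2L], h_proR = hyd[1L])
  else        list(h_proS = hyd[1L], h_proR = hyd[2L])
}
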