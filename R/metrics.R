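#' Detect carboxylate anchor hydrogen bonds
#'
#' Geometric hydrogen-bond detection between declared donor (heavy atom,
#' bonded hydrogen) pairs and acceptor atoms: an event is recorded in a
#' frame when d(H...A) <= `d_cutoff` and the D-H...A angle >= `angle_cutoff`.
#' The default cutoffs (3.5 Angstrom, 120 degrees) are deliberately
#' permissive so that long carboxylate contacts near 3.3-3.4 Angstrom are
#' still counted; both are config-exposed.
#'
#' @param traj a `lox_trajectory`.
#' @param donors list of `c(donor_heavy_atom, hydrogen)` address pairs
#'   (default: the topology's `anchor_donors`).
#' @param acceptors acceptor atom addresses (default: the topology's
#'   `anchor_acceptors`).
#' @param d_cutoff H...acceptor distance cutoff, Angstrom.
#' @param angle_cutoff minimum D-H...A angle, degrees.
#' @return list with `events` (data.frame `frame`, `donor`, `hydrogen`,
#'   `acceptor`, `d_H_A`, `angle_DHA`) and `occupancy` (data.frame `donor`,
#'   `acceptor`, `n_events`, `occupancy` = events / frames).
#' @export
detect_anchor_hbonds <- function(traj, donors = NULL, acceptors = NULL,
                                 d_cutoff = 3.5, angle_cutoff = 120) {
  top <- traj$topology
  donors <- donors %||% top$anchor_donors
  acceptors <- acceptors %||% top$anchor_acceptors
  if (length(donors) == 0L || length(acceptors) == 0L)
    stop("no anchor donors/acceptors declared", call. = FALSE)
  don_idx <- lapply(donors, function(p) resolve_addresses(top, p))
  acc_idx <- resolve_addresses(top, acceptors)
  nf <- n_frames(traj)
  ev <- list()
  for (i in seq_len(nf)) {
    co <- frame_coords(traj, i)
    for (di in seq_along(don_idx)) {
      d_at <- co[don_idx[[di]][1L], ]
      h_at <- co[don_idx[[di]][2L], ]
      for (ai in seq_along(acc_idx)) {
        a_at <- co[acc_idx[ai], ]
        d_ha <- dist3(h_at, a_at)
        if (d_ha > d_cutoff) next
        ang <- angle_deg(d_at, h_at, a_at)
        if (ang < angle_cutoff) next
        ev[[length(ev) + 1L]] <- data.frame(
          frame = traj$frame[i],
          donor = donors[[di]][1L], hydrogen = donors[[di]][2L],
          acceptor = acceptors[ai], d_H_A = d_ha, angle_DHA = ang)
      }
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(frame = integer(), donor = character(),
               hydrogen = character(), acceptor = character(),
               d_H_A = numeric(), angle_DHA = numeric())
  pairs <- expand.grid(
    donor = vapply(donors, `[[`, character(1L), 1L),
    acceptor = acceptors, stringsAsFactors = FALSE)
  pairs$n_events <- mapply(function(d, a)
    sum(events$donor == d & events$acceptor == a),
    pairs$donor, pairs$acceptor)
  pairs$occupancy <- pairs$n_events / nf
  list(events = events, occupancy = pairs)
}

# interior angle at b (degrees) of the path a-b-c
angle_deg <- function(a, b, c) {
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

#' Per-residue helical flags for a segment
#'
#' A residue is flagged helical when it lies inside the span of at least one
#' intact alpha-helical i -> i+4 backbone hydrogen bond: bond i is intact
#' when d(O(i) ... H-N(i+4)) <= `d_OH_cutoff` (default 2.7 Angstrom).  When
#' amide hydrogens are absent the test falls back to
#' d(O(i) ... N(i+4)) <= `d_ON_cutoff` (3.5 Angstrom) with a message.  This
#' single-criterion assignment is deliberately simpler than DSSP: it is
#' exactly testable on constructed geometry, and turn counting only needs
#' the longest helical run.
#'
#' @param traj a `lox_trajectory` with backbone atoms (N, C, O and
#'   optionally H) for the segment residues.
#' @param segment either a name in the topology's `helix_segments` or a
#'   list with `monomer`, `from`, `to`.
#' @param d_OH_cutoff,d_ON_cutoff distance cutoffs, Angstrom.
#' @return list with `flags` (`n_frames x n_residues` logical matrix,
#'   columns named by residue number) and `metrics` (data.frame `frame`,
#'   `segment`, `longest_run`, `n_turns`).
#' @export
assign_helix <- function(traj, segment, d_OH_cutoff = 2.7,
                         d_ON_cutoff = 3.5) {
  top <- traj$topology
  if (is.character(segment)) {
    seg_name <- segment
    segment <- top$helix_segments[[segment]]
    if (is.null(segment))
      stop("unknown helix segment '", seg_name, "'", call. = FALSE)
  } else seg_name <- segment$name %||% "segment"
  res <- segment$from:segment$to
  n_res <- length(res)
  if (n_res < 5L)
    stop("helix segment must span at least 5 residues", call. = FALSE)
  idx_of <- function(resnum, name) {
    i <- match(paste(segment$monomer, resnum, name, sep = ":"), top$address)
    i
  }
  O_idx <- vapply(res, idx_of, integer(1L), name = "O")
  N_idx <- vapply(res, idx_of, integer(1L), name = "N")
  H_idx <- vapply(res, idx_of, integer(1L), name = "H")
  if (any(is.na(O_idx)) || any(is.na(N_idx)))
    stop("missing backbone N/O atoms in helix segment", call. = FALSE)
  use_H <- !any(is.na(H_idx))
  if (!use_H)
    message("no amide hydrogens in segment '", seg_name,
            "'; falling back to the O...N distance criterion")
  nf <- n_frames(traj)
  flags <- matrix(FALSE, nf, n_res, dimnames = list(NULL, res))
  metrics <- data.frame(frame = traj$frame, segment = seg_name,
                        longest_run = 0L, n_turns = 0L)
  for (fi in seq_len(nf)) {
    co <- frame_coords(traj, fi)
    bond <- rep(FALSE, n_res)          # bond[i]: O(i) ... N/H(i+4)
    for (i in seq_len(n_res - 4L)) {
      bond[i] <- if (use_H)
        dist3(co[O_idx[i], ], co[H_idx[i + 4L], ]) <= d_OH_cutoff
      else
        dist3(co[O_idx[i], ], co[N_idx[i + 4L], ]) <= d_ON_cutoff
    }
    fl <- rep(FALSE, n_res)
    for (i in which(bond)) fl[i:(i + 4L)] <- TRUE
    flags[fi, ] <- fl
    run <- longest_run(fl)
    metrics$longest_run[fi] <- run
    metrics$n_turns[fi] <- count_turns(fl)
  }
  list(flags = flags, metrics = metrics)
}

longest_run <- function(flags) {
  if (!any(flags)) return(0L)
  r <- rle(flags)
  max(r$lengths[r$values])
}

#' Count helical turns from per-residue flags
#'
#' An alpha helix has 3.6 residues per turn; the turn count is the longest
#' contiguous helical run divided by 3.6, rounded to the nearest integer.
#'
#' @param flags logical per-residue helical flags (or an integer run
#'   length).
#' @return integer number of turns.
#' @export
count_turns <- function(flags) {
  run <- if (is.logical(flags)) longest_run(flags) else as.integer(flags)
  as.integer(round(run / 3.6))
}

#' Inter-monomer contact distance series
#'
#' Per-frame distance between a declared atom pair (e.g. the leucine-zipper
#' CD2 atoms of Leu179(A) and Leu192(B), or Glu181(A) OE1 vs His585(B) NE2).
#' The contact atoms must be named explicitly in the pair; there is no
#' automatic closest-heavy-atom fallback, so reported distances are always
#' attributable to specific atoms.
#'
#' @param traj a `lox_trajectory`.
#' @param pair `c(address, address)`.
#' @return list with `series` (data.frame `frame`, `time_ns`, `distance`),
#'   `mean` and `sd` (Angstrom).
#' @export
contact_distance_series <- function(traj, pair) {
  stopifnot(length(pair) == 2L)
  top <- traj$topology
  ia <- resolve_address(top, pair[[1L]])
  ib <- resolve_address(top, pair[[2L]])
  nf <- n_frames(traj)
  d <- numeric(nf)
  for (i in seq_len(nf)) {
    co <- frame_coords(traj, i)
    d[i] <- dist3(co[ia, ], co[ib, ])
  }
  series <- data.frame(frame = traj$frame, time_ns = traj$time_ns,
                       distance = d)
  list(series = series, mean = mean(d), sd = stats::sd(d))
}
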