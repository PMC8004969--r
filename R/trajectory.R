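#' Construct a trajectory
#'
#' A trajectory is a topology plus an ordered set of coordinate frames.
#' Coordinates are Angstrom throughout the package; nothing downstream ever
#' converts units.  Frames are stored bio3d-style as an `n_frames x 3N`
#' matrix (x1, y1, z1, x2, ...).
#'
#' @param topology a `lox_topology`.
#' @param xyz numeric matrix `n_frames x (3 * n_atoms)`.
#' @param frame integer frame indices (strictly increasing, >= 0).
#' @param time_ns per-frame times in ns (non-decreasing, >= 0).
#' @return an object of class `lox_trajectory`.
#' @export
trajectory <- function(topology, xyz, frame = NULL, time_ns = NULL) {
  stopifnot(inherits(topology, "lox_topology"))
  xyz <- as.matrix(xyz)
  n_at <- nrow(topology$atoms)
  if (ncol(xyz) != 3L * n_at)
    stop("coordinate matrix has ", ncol(xyz) / 3, " atoms but topology has ",
         n_at, call. = FALSE)
  if (nrow(xyz) < 1L)
    stop("trajectory must contain at least one frame", call. = FALSE)
  if (!all(is.finite(xyz)))
    stop("non-finite coordinates in trajectory", call. = FALSE)
  if (is.null(frame)) frame <- seq_len(nrow(xyz)) - 1L
  frame <- as.integer(frame)
  if (is.null(time_ns)) time_ns <- rep(0, nrow(xyz))
  if (length(frame) != nrow(xyz) || length(time_ns) != nrow(xyz))
    stop("frame / time_ns length must match the number of frames",
         call. = FALSE)
  if (any(diff(frame) <= 0L) && nrow(xyz) > 1L)
    stop("frame indices must be strictly increasing", call. = FALSE)
  if (any(diff(time_ns) < 0))
    stop("time_ns must be non-decreasing", call. = FALSE)
  structure(list(topology = topology, xyz = xyz, frame = frame,
                 time_ns = as.numeric(time_ns)),
            class = "lox_trajectory")
}

#' @export
print.lox_trajectory <- function(x, ...) {
  cat("<lox_trajectory> ", n_frames(x), " frame(s), ",
      nrow(x$topology$atoms), " atoms, t = ",
      format(min(x$time_ns)), "-", format(max(x$time_ns)), " ns\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `lox_trajectory`.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Coordinates of one frame
#'
#' @param traj a `lox_trajectory`.
#' @param i frame position (1-based row in the frame matrix).
#' @param atoms optional integer atom indices to subset.
#' @return `n x 3` coordinate matrix (Angstrom).
#' @export
frame_coords <- function(traj, i, atoms = NULL) {
  m <- matrix(traj$xyz[i, ], ncol = 3L, byrow = TRUE)
  if (!is.null(atoms)) m <- m[atoms, , drop = FALSE]
  m
}

#' Read a multi-model PDB file as a trajectory
#'
#' Each `MODEL`/`ENDMDL` block becomes one frame; a single-model file gives
#' a one-frame trajectory at t = 0 ns.  Atom lists must be identical across
#' models.  `ANISOU`/`CONECT` records are ignored (bonds needed for AUTO
#' prochiral assignment come from the config's explicit bond list).
#'
#' @param path path to a PDB file.
#' @param topology_config path to a selection config (see
#'   [read_topology_config()]), or a ready `lox_topology`, or `NULL` to use
#'   the bare atom table with no selections.
#' @param time_step_ns time spacing between frames (the saving stride of the
#'   production run is free here); frame i gets `time_ns = i * time_step_ns`.
#' @return a `lox_trajectory`.
#' @export
read_multimodel_pdb <- function(path, topology_config = NULL,
                                time_step_ns = 0.1) {
  if (!file.exists(path))
    stop("PDB file not found: ", path, call. = FALSE)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- data.frame(
    serial = as.integer(pdb$atom$eleno),
    name = pdb$atom$elety,
    element = ifelse(is.na(pdb$atom$elesy) | pdb$atom$elesy == "",
                     substr(trimws(pdb$atom$elety), 1L, 1L),
                     trimws(pdb$atom$elesy)),
    resname = pdb$atom$resid,
    resnum = as.integer(pdb$atom$resno),
    monomer = pdb$atom$chain,
    stringsAsFactors = FALSE)
  xyz <- if (is.matrix(pdb$xyz)) unclass(pdb$xyz) else
    matrix(unclass(pdb$xyz), nrow = 1L)
  if (ncol(xyz) != 3L * nrow(atoms))
    stop("inconsistent atom count across PDB models in ", path,
         call. = FALSE)
  top <- if (is.null(topology_config)) topology_spec(atoms)
  else if (inherits(topology_config, "lox_topology")) {
    do.call(topology_spec,
            c(list(atoms = atoms),
              topology_config[setdiff(names(topology_config),
                                      c("atoms", "address"))]))
  } else read_topology_config(topology_config, atoms = atoms)
  nf <- nrow(xyz)
  trajectory(top, xyz, frame = seq_len(nf) - 1L,
             time_ns = (seq_len(nf) - 1L) * time_step_ns)
}

#' Read / write the tabular frame format
#'
#' A plain TSV exchange format with header
#' `frame  time_ns  monomer  resnum  atom  x  y  z`, one row per atom per
#' frame.  `read_frame_table(write_frame_table(traj))` reproduces the
#' coordinates bit-for-bit (coordinates are serialized at full double
#' precision).
#'
#' @param path file path.
#' @param topology_config as in [read_multimodel_pdb()]; for reading, if
#'   `NULL` a minimal topology is built from the table itself (elements
#'   guessed from the first letter of the atom name).
#' @return `read_frame_table`: a `lox_trajectory`.
#' @export
read_frame_table <- function(path, topology_config = NULL) {
  if (!file.exists(path))
    stop("frame table not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c("integer", "numeric", "character",
                                          "integer", "character", "numeric",
                                          "numeric", "numeric"))
  need <- c("frame", "time_ns", "monomer", "resnum", "atom", "x", "y", "z")
  if (!identical(names(tab), need))
    stop("frame table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(tab) == 0L)
    stop("empty frame table: ", path, call. = FALSE)
  if (!all(is.finite(tab$x) & is.finite(tab$y) & is.finite(tab$z)))
    stop("non-numeric or non-finite coordinates in frame table",
         call. = FALSE)
  frames <- sort(unique(tab$frame))
  key <- paste(tab$monomer, tab$resnum, tab$atom, sep = ":")
  first <- tab$frame == frames[1L]
  ref_key <- key[first]
  n_at <- length(ref_key)
  xyz <- matrix(NA_real_, nrow = length(frames), ncol = 3L * n_at)
  time_ns <- numeric(length(frames))
  for (fi in seq_along(frames)) {
    sel <- which(tab$frame == frames[fi])
    if (length(sel) != n_at ||
        !identical(key[sel], ref_key))
      stop("ragged frame table: frame ", frames[fi],
           " does not match the atom list of frame ", frames[1L],
           call. = FALSE)
    xyz[fi, ] <- as.vector(t(cbind(tab$x[sel], tab$y[sel], tab$z[sel])))
    time_ns[fi] <- tab$time_ns[sel[1L]]
  }
  atoms <- data.frame(
    serial = seq_len(n_at),
    name = tab$atom[first],
    element = substr(tab$atom[first], 1L, 1L),
    resname = "UNK",
    resnum = tab$resnum[first],
    monomer = tab$monomer[first],
    stringsAsFactors = FALSE)
  top <- if (is.null(topology_config)) topology_spec(atoms)
  else if (inherits(topology_config, "lox_topology")) topology_config
  else read_topology_config(topology_config, atoms = atoms)
  trajectory(top, xyz, frame = frames, time_ns = time_ns)
}

#' @param traj a `lox_trajectory` to serialize.
#' @rdname read_frame_table
#' @export
write_frame_table <- function(traj, path) {
  at <- traj$topology$atoms
  n_at <- nrow(at)
  nf <- n_frames(traj)
  rows <- vector("list", nf)
  for (i in seq_len(nf)) {
    co <- frame_coords(traj, i)
    rows[[i]] <- data.frame(
      frame = traj$frame[i], time_ns = traj$time_ns[i],
      monomer = at$monomer, resnum = at$resnum, atom = at$name,
      x = co[, 1L], y = co[, 2L], z = co[, 3L])
  }
  tab <- do.call(rbind, rows)
  num <- function(v) sprintf("%.17g", v)
  out <- data.frame(frame = tab$frame, time_ns = num(tab$time_ns),
                    monomer = tab$monomer, resnum = tab$resnum,
                    atom = tab$atom, x = num(tab$x), y = num(tab$y),
                    z = num(tab$z))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write one frame as a single-model PDB
#'
#' Used for centroid structures of the most populated binding-mode cluster.
#'
#' @param traj a `lox_trajectory`.
#' @param i frame position (1-based).
#' @param path output path.
#' @export
write_frame_pdb <- function(traj, i, path) {
  at <- traj$topology$atoms
  co <- frame_coords(traj, i)
  bio3d::write.pdb(file = path, xyz = as.vector(t(co)),
                   type = rep("ATOM", nrow(at)), eleno = at$serial,
                   elety = at$name, resid = at$resname, chain = at$monomer,
                   resno = at$resnum, elesy = at$element)
  invisible(path)
}
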