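## Synthetic trajectory / dataset generators.
##
## Each generator is seeded once, leaves the caller's RNG state untouched,
## and attaches analytic ground truth sufficient to verify the downstream
## analysis without re-deriving anything.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Generate frames with a controlled reactive-geometry distribution
#'
#' Builds a minimal cofactor + substrate-fragment system: the hydroxide
#' oxygen at the origin, the bisallylic carbon at a sampled distance d along
#' x (d ~ Normal(`d_mean`, `d_sd`) truncated at d > `b_CH` by rejection),
#' one hydrogen at angle `phi_deg` between the C->H and C->O directions in
#' the xy-plane and the second mirrored out of plane, plus two fixed carbon
#' neighbours.  The sampled distances are kept as ground truth, and the
#' expected well-oriented / pre-catalytic fractions are computed in closed
#' form from the truncated-normal CDF (for phi = 0 the pre-catalytic
#' probability is Phi((cutoff + b_CH - d_mean)/d_sd), renormalized for the
#' truncation).
#'
#' @param n number of frames.
#' @param d_mean,d_sd mean and sd of the C-OH distance, Angstrom.
#' @param phi_deg angle between C->H and C->OH, degrees (0 = H pointing
#'   straight at the hydroxide; 180 = pointing away).
#' @param b_CH C-H bond length, Angstrom.
#' @param cutoff pre-catalytic distance criterion used for the analytic
#'   expectation, Angstrom.
#' @param seed integer seed.
#' @return list with `trajectory` (a `lox_trajectory`), `ground_truth`
#'   (data.frame `frame`, `d`, `d_H`), `expected` (list `well_oriented`,
#'   `precatalytic`, analytic fractions in [0, 1]) and `params`.
#' @export
gen_reactive_frames <- function(n, d_mean, d_sd, phi_deg = 0, b_CH = 1.09,
                                cutoff = 3, seed = NULL) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (d_mean <= b_CH)
    stop("d_mean must exceed the C-H bond length", call. = FALSE)
  if (d_sd < 0 || b_CH <= 0)
    stop("invalid geometry parameters", call. = FALSE)
  phi <- phi_deg * pi / 180
  d <- with_seed(seed, {
    if (d_sd == 0) rep(d_mean, n)
    else {
      out <- numeric(n); have <- 0L
      while (have < n) {
        draw <- stats::rnorm(n, d_mean, d_sd)
        draw <- draw[draw > b_CH]
        take <- min(length(draw), n - have)
        if (take > 0L) out[(have + 1L):(have + take)] <- draw[seq_len(take)]
        have <- have + take
      }
      out
    }
  })

  atoms <- data.frame(
    serial = 1:6,
    name = c("OH", "C12", "C13", "C14", "H3S", "H3R"),
    element = c("O", "C", "C", "C", "H", "H"),
    resname = c("FEO", rep("SUB", 5L)),
    resnum = c(1L, rep(2L, 5L)),
    monomer = c("A", rep("B", 5L)),
    stringsAsFactors = FALSE)
  a <- function(nm) atom_address(atoms$monomer[atoms$name == nm],
                                 atoms$resnum[atoms$name == nm], nm)
  u12 <- c(0.5, 1.0, 0.9); u12 <- 1.5 * u12 / sqrt(sum(u12^2))
  u14 <- c(0.5, -1.0, -0.9); u14 <- 1.5 * u14 / sqrt(sum(u14^2))
  hS_off <- b_CH * c(-cos(phi), sin(phi), 0)
  hR_off <- b_CH * c(-cos(phi), 0, -sin(phi))
  xyz <- matrix(0, nrow = n, ncol = 18L)
  for (i in seq_len(n)) {
    C <- c(d[i], 0, 0)
    xyz[i, ] <- c(c(0, 0, 0), C + u12, C, C + u14, C + hS_off, C + hR_off)
  }
  top <- topology_spec(
    atoms,
    cofactor_oxygen = a("OH"), reactive_carbon = a("C13"),
    h_proS = a("H3S"), h_proR = a("H3R"),
    substrate_heavy_atoms = c(a("C12"), a("C13"), a("C14")),
    bonds = list(c(a("C13"), a("C12")), c(a("C13"), a("C14")),
                 c(a("C13"), a("H3S")), c(a("C13"), a("H3R"))))
  traj <- trajectory(top, xyz, frame = seq_len(n) - 1L,
                     time_ns = (seq_len(n) - 1L) * 0.01)

  d_H <- sqrt((d - b_CH * cos(phi))^2 + (b_CH * sin(phi))^2)
  expected <- reactive_expected_fractions(d_mean, d_sd, phi, b_CH, cutoff)

  list(trajectory = traj,
       ground_truth = data.frame(frame = traj$frame, d = d, d_H = d_H),
       expected = expected,
       params = list(n = n, d_mean = d_mean, d_sd = d_sd,
                     phi_deg = phi_deg, b_CH = b_CH, cutoff = cutoff,
                     seed = seed))
}

# closed-form well-oriented / pre-catalytic fractions for the generator's
# geometry under d ~ N(mu, sd) truncated at d > b
reactive_expected_fractions <- function(mu, sd, phi, b, cutoff) {
  cphi <- cos(phi)
  lo_wo <- if (cphi > 0) max(b, b / (2 * cphi)) else Inf
  d_star <- if (cutoff >= b * abs(sin(phi)))
    b * cphi + sqrt(cutoff^2 - (b * sin(phi))^2) else -Inf
  if (sd == 0) {
    wo <- as.numeric(mu > lo_wo)
    pc <- as.numeric(mu > lo_wo && mu <= d_star)
    return(list(well_oriented = wo, precatalytic = pc))
  }
  Z <- 1 - stats::pnorm((b - mu) / sd)
  P <- function(x) stats::pnorm((x - mu) / sd)
  wo <- if (is.finite(lo_wo)) (1 - P(lo_wo)) / Z else 0
  pc <- if (is.finite(lo_wo) && d_star > lo_wo)
    (P(d_star) - P(max(b, lo_wo))) / Z else 0
  list(well_oriented = wo, precatalytic = max(0, pc))
}

#' Generate frames with planted binding-mode cluster structure
#'
#' Cluster templates are independent random conformers of `n_atoms` pseudo
#' heavy atoms, accepted only when every template pair sits at a fitted
#' (Kabsch) RMSD of at least `separation`; frames are templates plus
#' isotropic Gaussian jitter.  The planted labels are returned as ground
#' truth.  By default the parameters are checked for clean recovery at the
#' clustering `cutoff`: `separation > 6 * jitter_sd + 2 * cutoff`.
#'
#' @param sizes integer vector of cluster sizes (frames are emitted in this
#'   order).
#' @param separation minimum pairwise template RMSD, Angstrom.
#' @param jitter_sd per-coordinate Gaussian jitter, Angstrom.
#' @param n_atoms number of pseudo substrate heavy atoms.
#' @param seed integer seed.
#' @param cutoff clustering cutoff the feasibility check refers to.
#' @param box template coordinates are uniform in `[0, box]^3`.
#' @return list with `trajectory`, `labels` (planted 0-based labels) and
#'   `params`.
#' @export
gen_clustered_frames <- function(sizes, separation = 3, jitter_sd = 0.05,
                                 n_atoms = 10L, seed = NULL, cutoff = 0.5,
                                 box = 10) {
  if (any(sizes < 1L)) stop("cluster sizes must be >= 1", call. = FALSE)
  if (separation <= 6 * jitter_sd + 2 * cutoff)
    stop("infeasible separation: need separation > 6*jitter_sd + 2*cutoff ",
         "for clean recovery", call. = FALSE)
  k <- length(sizes)
  n <- sum(sizes)
  out <- with_seed(seed, {
    templates <- NULL
    for (try in 1:200) {
      cand <- lapply(seq_len(k), function(i)
        matrix(stats::runif(3L * n_atoms, 0, box), ncol = 3L))
      ok <- TRUE
      if (k > 1L)
        for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
          if (superpose(cand[[i]], cand[[j]])$rmsd < separation) ok <- FALSE
      if (ok) { templates <- cand; break }
    }
    if (is.null(templates))
      stop("could not place templates at the requested separation",
           call. = FALSE)
    labels <- rep(seq_len(k) - 1L, times = sizes)
    xyz <- matrix(0, nrow = n, ncol = 3L * n_atoms)
    for (f in seq_len(n)) {
      co <- templates[[labels[f] + 1L]] +
        matrix(stats::rnorm(3L * n_atoms, 0, jitter_sd), ncol = 3L)
      xyz[f, ] <- as.vector(t(co))
    }
    list(xyz = xyz, labels = labels)
  })
  atoms <- data.frame(
    serial = seq_len(n_atoms),
    name = paste0("C", seq_len(n_atoms)),
    element = "C", resname = "SUB", resnum = 1L, monomer = "B",
    stringsAsFactors = FALSE)
  addr <- atom_address("B", 1L, atoms$name)
  top <- topology_spec(atoms, substrate_heavy_atoms = addr)
  traj <- trajectory(top, out$xyz, frame = seq_len(n) - 1L,
                     time_ns = (seq_len(n) - 1L) * 0.1)
  list(trajectory = traj, labels = out$labels,
       params = list(sizes = sizes, separation = separation,
                     jitter_sd = jitter_sd, n_atoms = n_atoms, seed = seed))
}

# NeRF-style internal-coordinate placement: position of d given a-b-c,
# bond |cd|, angle b-c-d (deg) and torsion a-b-c-d (deg)
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  nrm <- c(ab[2] * bc[3] - ab[3] * bc[2],
           ab[3] * bc[1] - ab[1] * bc[3],
           ab[1] * bc[2] - ab[2] * bc[1])
  nrm <- nrm / sqrt(sum(nrm^2))
  m <- c(nrm[2] * bc[3] - nrm[3] * bc[2],
         nrm[3] * bc[1] - nrm[1] * bc[3],
         nrm[1] * bc[2] - nrm[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * nrm
}

#' Generate an ideal (optionally partially unwound) alpha-helix backbone
#'
#' Builds a poly-alanine backbone (N, H, CA, C, O) from ideal internal
#' coordinates.  Helical residues use phi = -57, psi = -47 degrees (the
#' canonical alpha-helix, ~1.5 Angstrom rise and ~100 degree twist per
#' residue); residues in `unwound` get extended (beta-like) torsions
#' phi = -139, psi = +135, which breaks the local i -> i+4 hydrogen bonds.
#' Ground-truth helical flags follow the same span rule as [assign_helix()]:
#' a residue is helical when some intact bond i -> i+4 covers it, and bond i
#' is intact when none of residues i+1..i+4 is unwound (residue i's own
#' torsions rotate its carbonyl and the downstream chain together, so they
#' do not enter the bond geometry).
#'
#' @param n_res number of residues (>= 5).
#' @param unwound integer vector of unwound residue positions (1-based), or
#'   `NULL`.
#' @param phi,psi helical backbone torsions, degrees.
#' @return list with `trajectory` (single frame, monomer "A", residues
#'   1..n_res, segment "helix" preset), `ground_truth` (list `flags`,
#'   `longest_run`, `n_turns`) and `params`.
#' @export
gen_ideal_helix <- function(n_res, unwound = NULL, phi = -57, psi = -47) {
  if (n_res < 5L) stop("need at least 5 residues", call. = FALSE)
  if (!is.null(unwound) && (any(unwound < 1L) || any(unwound > n_res)))
    stop("unwound range outside the segment", call. = FALSE)
  phis <- rep(phi, n_res); psis <- rep(psi, n_res)
  phis[unwound] <- -139; psis[unwound] <- 135

  N <- CA <- C <- O <- H <- matrix(NA_real_, n_res, 3L)
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(1.458, 0, 0)
  C[1L, ] <- CA[1L, ] + 1.525 * c(-cos(111.2 * pi / 180),
                                  sin(111.2 * pi / 180), 0)
  for (i in seq_len(n_res - 1L)) {
    N[i + 1L, ] <- place_atom(N[i, ], CA[i, ], C[i, ], 1.329, 116.2, psis[i])
    CA[i + 1L, ] <- place_atom(CA[i, ], C[i, ], N[i + 1L, ], 1.458, 121.7, 180)
    C[i + 1L, ] <- place_atom(C[i, ], N[i + 1L, ], CA[i + 1L, ],
                              1.525, 111.2, phis[i + 1L])
  }
  for (i in seq_len(n_res)) {
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], 1.231, 120.8,
                         psis[i] + 180)
    if (i == 1L) {
      dir <- N[1L, ] - (CA[1L, ] + C[1L, ]) / 2
      H[i, ] <- N[1L, ] + 1.01 * dir / sqrt(sum(dir^2))
    } else {
      u <- C[i - 1L, ] - N[i, ]; u <- u / sqrt(sum(u^2))
      v <- CA[i, ] - N[i, ]; v <- v / sqrt(sum(v^2))
      dir <- -(u + v); dir <- dir / sqrt(sum(dir^2))
      H[i, ] <- N[i, ] + 1.01 * dir
    }
  }
  atoms <- do.call(rbind, lapply(seq_len(n_res), function(i)
    data.frame(serial = 0L,
               name = c("N", "H", "CA", "C", "O"),
               element = c("N", "H", "C", "C", "O"),
               resname = "ALA", resnum = i, monomer = "A",
               stringsAsFactors = FALSE)))
  atoms$serial <- seq_len(nrow(atoms))
  xyz <- matrix(NA_real_, 1L, 3L * nrow(atoms))
  for (i in seq_len(n_res)) {
    block <- rbind(N[i, ], H[i, ], CA[i, ], C[i, ], O[i, ])
    xyz[1L, (15L * (i - 1L) + 1L):(15L * i)] <- as.vector(t(block))
  }
  top <- topology_spec(
    atoms,
    helix_segments = list(helix = list(monomer = "A", from = 1L,
                                       to = n_res)))
  traj <- trajectory(top, xyz)

  # the O(i) -> H-N(i+4) geometry is set by the torsions of residues
  # i+1..i+4: rotating psi(i) carries O(i) and the downstream chain
  # together, so residue i's own torsions do not enter
  bond_ok <- vapply(seq_len(n_res - 4L), function(i)
    !any(((i + 1L):(i + 4L)) %in% unwound), logical(1L))
  flags <- rep(FALSE, n_res)
  for (i in which(bond_ok)) flags[i:(i + 4L)] <- TRUE
  list(trajectory = traj,
       ground_truth = list(flags = flags,
                           longest_run = longest_run(flags),
                           n_turns = count_turns(flags)),
       params = list(n_res = n_res, unwound = unwound, phi = phi,
                     psi = psi))
}

#' Generate a drifting inter-monomer contact pair
#'
#' Two atoms whose separation drifts linearly from `d_start` to `d_end`
#' (plus optional Gaussian noise); the realized distances are kept as
#' ground truth.
#'
#' @param n number of frames.
#' @param d_start,d_end distances at the first / last frame, Angstrom.
#' @param noise_sd Gaussian noise on the distance, Angstrom.
#' @param seed integer seed.
#' @return list with `trajectory` (interface pair preset:
#'   `A:179:CD2` vs `B:192:CD2`), `ground_truth` (distance vector) and
#'   `params`.
#' @export
gen_contact_pair <- function(n, d_start, d_end, noise_sd = 0, seed = NULL) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  d <- with_seed(seed, {
    base <- if (n == 1L) d_start else seq(d_start, d_end, length.out = n)
    base + if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
  })
  if (any(d <= 0)) stop("generated distances must be positive", call. = FALSE)
  atoms <- data.frame(serial = 1:2, name = c("CD2", "CD2"),
                      element = "C", resname = "LEU",
                      resnum = c(179L, 192L), monomer = c("A", "B"),
                      stringsAsFactors = FALSE)
  pair <- c(atom_address("A", 179L, "CD2"), atom_address("B", 192L, "CD2"))
  xyz <- cbind(0, 0, 0, d, 0, 0)
  top <- topology_spec(atoms, interface_pairs = list(pair))
  traj <- trajectory(top, xyz, frame = seq_len(n) - 1L,
                     time_ns = (seq_len(n) - 1L) * 0.1)
  list(trajectory = traj, pair = pair, ground_truth = d,
       params = list(n = n, d_start = d_start, d_end = d_end,
                     noise_sd = noise_sd, seed = seed))
}

#' Generate Michaelis-Menten rate data
#'
#' v = kcat * S / (KM + S) * (1 + eps), eps ~ N(0, `noise_cv`).  Default
#' parameters are the wild-type/linoleic-acid reference constants
#' (kcat = 47.2 s^-1, KM = 21.4 uM).
#'
#' @param kcat,KM generating parameters (s^-1, uM).
#' @param S_grid substrate concentrations, uM.
#' @param noise_cv multiplicative noise coefficient of variation.
#' @param replicates replicates per concentration.
#' @param seed integer seed.
#' @param substrate label stored in the dataset.
#' @return data.frame (`substrate`, `S_uM`, `v_per_s`, `replicate`) with
#'   attribute `ground_truth` = list(kcat, KM).
#' @export
gen_mm_data <- function(kcat = 47.2, KM = 21.4,
                        S_grid = c(2, 5, 10, 20, 40, 80, 160),
                        noise_cv = 0, replicates = 1L, seed = NULL,
                        substrate = "LA") {
  if (kcat <= 0 || KM <= 0 || any(S_grid <= 0))
    stop("parameters must be positive", call. = FALSE)
  S <- rep(S_grid, each = replicates)
  v0 <- kcat * S / (KM + S)
  v <- with_seed(seed,
                 v0 * (1 + if (noise_cv > 0)
                   stats::rnorm(length(S), 0, noise_cv) else 0))
  out <- data.frame(substrate = substrate, S_uM = S, v_per_s = v,
                    replicate = rep(seq_len(replicates),
                                    times = length(S_grid)))
  attr(out, "ground_truth") <- list(kcat = kcat, KM = KM)
  out
}

#' Generate SEC calibration standards on an exact line
#'
#' Elution volumes are back-computed from the calibration line
#' (-log10 Kav)^(1/2) = intercept + slope * Rh, so
#' [calibrate_sec()] on the output recovers the line with r^2 = 1 and
#' [estimate_rh()] round-trips each standard exactly.  The default radii
#' are the canonical globular standards (chymotrypsinogen A 20.9, bovine
#' serum albumin 35.5, catalase 52.2 Angstrom).
#'
#' @param slope,intercept calibration line (slope must be positive).
#' @param radii hydrodynamic radii of the standards, Angstrom.
#' @param Vo,Vt column void / total volume, mL.
#' @return data.frame (`name`, `Rh_A`, `Ve_mL`) with attribute
#'   `ground_truth` = list(slope, intercept, Vo, Vt).
#' @export
gen_sec_standards <- function(slope, intercept, radii = c(20.9, 35.5, 52.2),
                              Vo = 8, Vt = 24) {
  if (slope <= 0) stop("slope must be positive", call. = FALSE)
  y <- intercept + slope * radii
  if (any(y < 0))
    stop("calibration line gives Kav > 1 for a standard", call. = FALSE)
  K <- 10^(-y^2)
  if (any(K <= 0) || any(K > 1))
    stop("parameters produce Kav outside (0, 1]", call. = FALSE)
  Ve <- Vo + K * (Vt - Vo)
  nm <- if (identical(radii, c(20.9, 35.5, 52.2)))
    c("chymotrypsinogen_A", "BSA", "catalase")
  else paste0("std_", seq_along(radii))
  out <- data.frame(name = nm, Rh_A = radii, Ve_mL = Ve,
                    stringsAsFactors = FALSE)
  attr(out, "ground_truth") <- list(slope = slope, intercept = intercept,
                                    Vo = Vo, Vt = Vt)
  out
}
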