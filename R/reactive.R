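#' Per-frame reactive distances
#'
#' For every frame, the distances from the hydroxide oxygen of the Fe3+-OH
#' cofactor to the reactive (bisallylic) carbon and to each of its two
#' prochiral hydrogens: d(C-OH), d(HproS-OH), d(HproR-OH).  These are the
#' quantities on which the pre-catalytic classification rests.
#'
#' @param traj a `lox_trajectory` whose topology resolves `cofactor_oxygen`,
#'   `reactive_carbon` and the prochiral hydrogens (explicitly or via
#'   `"AUTO"`, see [assign_prochiral_hydrogens()]).
#' @return data.frame with columns `frame`, `time_ns`, `d_C_OH`,
#'   `d_HproS_OH`, `d_HproR_OH` (Angstrom), one row per frame in order.
#' @export
compute_reactive_distances <- function(traj) {
  top <- traj$topology
  for (f in c("cofactor_oxygen", "reactive_carbon"))
    if (is.null(top[[f]]))
      stop("topology does not declare ", f, call. = FALSE)
  pro <- assign_prochiral_hydrogens(traj)
  io <- resolve_address(top, top$cofactor_oxygen)
  ic <- resolve_address(top, top$reactive_carbon)
  is_ <- resolve_address(top, pro$h_proS)
  ir <- resolve_address(top, pro$h_proR)
  nf <- n_frames(traj)
  dC <- dS <- dR <- numeric(nf)
  for (i in seq_len(nf)) {
    co <- frame_coords(traj, i)
    dC[i] <- dist3(co[ic, ], co[io, ])
    dS[i] <- dist3(co[is_, ], co[io, ])
    dR[i] <- dist3(co[ir, ], co[io, ])
  }
  data.frame(frame = traj$frame, time_ns = traj$time_ns,
             d_C_OH = dC, d_HproS_OH = dS, d_HproR_OH = dR)
}

#' Classify frames as well-oriented / pre-catalytic
#'
#' A hydrogen is *well-oriented* in a frame when d(H-OH) < d(C-OH): the C-H
#' bond points toward the abstracting hydroxide.  A frame is *pre-catalytic*
#' for that hydrogen when additionally d(H-OH) <= `cutoff` (default 3
#' Angstrom; the boundary value 3.000 counts).  Per-frame flags are reported
#' per hydrogen and aggregated as at-least-one-hydrogen (`*_any`).
#'
#' @param rd data.frame from [compute_reactive_distances()] (columns
#'   `d_C_OH`, `d_HproS_OH`, `d_HproR_OH`).
#' @param cutoff distance criterion for d(H-OH), Angstrom.
#' @return `rd` with logical columns `wo_S`, `wo_R`, `pc_S`, `pc_R`,
#'   `wo_any`, `pc_any` appended.
#' @export
classify_frames <- function(rd, cutoff = 3) {
  stopifnot(all(c("d_C_OH", "d_HproS_OH", "d_HproR_OH") %in% names(rd)))
  if (!all(is.finite(as.matrix(rd[c("d_C_OH", "d_HproS_OH", "d_HproR_OH")]))))
    stop("non-finite reactive distances", call. = FALSE)
  rd$wo_S <- rd$d_HproS_OH < rd$d_C_OH
  rd$wo_R <- rd$d_HproR_OH < rd$d_C_OH
  rd$pc_S <- rd$wo_S & rd$d_HproS_OH <= cutoff
  rd$pc_R <- rd$wo_R & rd$d_HproR_OH <= cutoff
  rd$wo_any <- rd$wo_S | rd$wo_R
  rd$pc_any <- rd$pc_S | rd$pc_R
  rd
}

#' Summarize reactive geometry over a trajectory
#'
#' Arithmetic means of the three reactive distances plus the percentage of
#' frames that are well-oriented / pre-catalytic with at least one hydrogen
#' (the aggregation used for reported percentages).  Per-hydrogen
#' percentages are included for diagnosis.
#'
#' @param cls classified distances from [classify_frames()].
#' @param system optional system label carried into the summary row.
#' @param discard_ns drop frames with `time_ns < discard_ns` before
#'   summarizing (an equilibration window; default keeps everything).
#' @return one-row data.frame of class `lox_geometry_summary` with columns
#'   `system`, `n_frames`, `mean_d_C_OH`, `mean_d_HproS_OH`,
#'   `mean_d_HproR_OH`, `pct_well_oriented`, `pct_precatalytic`,
#'   `pct_wo_S`, `pct_wo_R`, `pct_pc_S`, `pct_pc_R`.
#' @export
summarize_geometry <- function(cls, system = NA_character_, discard_ns = 0) {
  if (discard_ns > 0) cls <- cls[cls$time_ns >= discard_ns, , drop = FALSE]
  n <- nrow(cls)
  if (n == 0L)
    stop("no frames to summarize (after discard window)", call. = FALSE)
  pct <- function(x) 100 * sum(x) / n
  out <- data.frame(
    system = system, n_frames = n,
    mean_d_C_OH = mean(cls$d_C_OH),
    mean_d_HproS_OH = mean(cls$d_HproS_OH),
    mean_d_HproR_OH = mean(cls$d_HproR_OH),
    pct_well_oriented = pct(cls$wo_any),
    pct_precatalytic = pct(cls$pc_any),
    pct_wo_S = pct(cls$wo_S), pct_wo_R = pct(cls$wo_R),
    pct_pc_S = pct(cls$pc_S), pct_pc_R = pct(cls$pc_R))
  class(out) <- c("lox_geometry_summary", "data.frame")
  out
}

#' Build a geometry summary from already-tabulated values
#'
#' Convenience constructor for comparing against published summary tables
#' (mean distances and percentages) when the underlying trajectories are
#' not available.
#'
#' @param system label; @param mean_d_C_OH,mean_d_HproS_OH,mean_d_HproR_OH
#'   mean distances (Angstrom); @param pct_well_oriented,pct_precatalytic
#'   percentages; @param n_frames frame count if known.
#' @export
geometry_summary <- function(system, mean_d_C_OH, mean_d_HproS_OH,
                             mean_d_HproR_OH, pct_well_oriented,
                             pct_precatalytic, n_frames = NA_integer_) {
  stopifnot(pct_well_oriented >= 0, pct_well_oriented <= 100,
            pct_precatalytic >= 0, pct_precatalytic <= 100)
  out <- data.frame(system = system, n_frames = n_frames,
                    mean_d_C_OH = mean_d_C_OH,
                    mean_d_HproS_OH = mean_d_HproS_OH,
                    mean_d_HproR_OH = mean_d_HproR_OH,
                    pct_well_oriented = pct_well_oriented,
                    pct_precatalytic = pct_precatalytic,
                    pct_wo_S = NA_real_, pct_wo_R = NA_real_,
                    pct_pc_S = NA_real_, pct_pc_R = NA_real_)
  class(out) <- c("lox_geometry_summary", "data.frame")
  out
}

#' Compare two geometry summaries (mutant vs wild type)
#'
#' Fold changes of the pre-catalytic and well-oriented percentages
#' (`a` over `b`) and the shift of the mean C-OH distance (`b` minus `a`,
#' positive when `a` sits closer to the cofactor).  Display values follow
#' reporting conventions: folds >= 10 round to the nearest integer,
#' smaller folds and Angstrom shifts to one decimal.
#'
#' @param a,b `lox_geometry_summary` rows (e.g. mutant and wild type).
#' @return list with raw `fold_precatalytic`, `fold_well_oriented`,
#'   `delta_mean_d_C_OH` and their `display_*` counterparts.
#' @export
compare_summaries <- function(a, b) {
  if (b$pct_precatalytic <= 0)
    stop("fold change undefined: reference pre-catalytic percentage is 0",
         call. = FALSE)
  if (b$pct_well_oriented <= 0)
    stop("fold change undefined: reference well-oriented percentage is 0",
         call. = FALSE)
  disp_fold <- function(x) if (x >= 10) round(x) else round(x, 1)
  fp <- a$pct_precatalytic / b$pct_precatalytic
  fw <- a$pct_well_oriented / b$pct_well_oriented
  dd <- b$mean_d_C_OH - a$mean_d_C_OH
  list(fold_precatalytic = fp,
       fold_well_oriented = fw,
       delta_mean_d_C_OH = dd,
       display_fold_precatalytic = disp_fold(fp),
       display_fold_well_oriented = disp_fold(fw),
       display_delta_mean_d_C_OH = round(dd, 1))
}

#' Write per-frame classification and summary CSVs
#'
#' @param cls classified distances ([classify_frames()]).
#' @param path output CSV path.
#' @export
write_classification_csv <- function(cls, path) {
  out <- data.frame(frame = cls$frame, time_ns = cls$time_ns,
                    dC = cls$d_C_OH, dHS = cls$d_HproS_OH,
                    dHR = cls$d_HproR_OH,
                    wo_S = cls$wo_S, wo_R = cls$wo_R,
                    pc_S = cls$pc_S, pc_R = cls$pc_R,
                    wo_any = cls$wo_any, pc_any = cls$pc_any)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
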