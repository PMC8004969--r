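## End-to-end orchestration: validated run configs, report bundles, and
## rendered tables.  Errors are classed so callers (and the bundled
## command-line wrapper) can map them to stable exit codes:
## lox_config_error -> 2, lox_input_error -> 3, lox_analysis_error -> 4.

lox_abort <- function(class, msg, exit) {
  stop(structure(class = c(class, "lox_error", "error", "condition"),
                 list(message = msg, call = NULL, exit_code = exit)))
}

#' Validate a pipeline run configuration
#'
#' A run config is a named list (or a YAML/JSON file) with keys:
#' `systems` (named list; each entry either `synthetic = list(kind, ...)`
#' or `trajectory` + `topology` file paths), `analyses` (non-empty subset
#' of geometry, cluster, hbonds, helix, contacts), optional `kinetics`
#' (`csv` path or `synthetic` parameter list), optional `sec` (`csv`, `Vo`,
#' `Vt` or `synthetic`), optional `compare = list(a, b)` naming two systems,
#' `parameters` (cutoff overrides, `seed`, `discard_ns`) and `output_dir`.
#' Unknown keys are rejected.
#'
#' @param config list or path.
#' @return the normalized config (invisibly usable by [run_pipeline()]).
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      lox_abort("lox_config_error", paste("config file not found:", config), 2L)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::fromJSON(config, simplifyVector = FALSE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config))
    lox_abort("lox_config_error", "config must be a list or a file path", 2L)
  known <- c("systems", "analyses", "kinetics", "sec", "compare",
             "parameters", "output_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    lox_abort("lox_config_error",
              paste("unknown config key(s):",
                    paste(unknown, collapse = ", ")), 2L)
  traj_analyses <- c("geometry", "cluster", "hbonds", "helix", "contacts")
  all_analyses <- c(traj_analyses, "kinetics", "sec")
  an <- unlist(config$analyses)
  if (length(an) == 0L)
    lox_abort("lox_config_error", "analyses must be a non-empty set", 2L)
  bad <- setdiff(an, all_analyses)
  if (length(bad))
    lox_abort("lox_config_error",
              paste("unknown analysis toggle(s):",
                    paste(bad, collapse = ", ")), 2L)
  if (any(an %in% traj_analyses) &&
      (is.null(config$systems) || length(config$systems) == 0L))
    lox_abort("lox_config_error",
              "trajectory analyses requested but no systems declared", 2L)
  if ("kinetics" %in% an && is.null(config$kinetics))
    lox_abort("lox_config_error", "kinetics analysis needs a kinetics block", 2L)
  if ("sec" %in% an && is.null(config$sec))
    lox_abort("lox_config_error", "sec analysis needs a sec block", 2L)
  p <- config$parameters %||% list()
  defaults <- list(cutoff = 3, cluster_cutoff = 0.5, hbond_d_cutoff = 3.5,
                   hbond_angle_cutoff = 120, discard_ns = 0, seed = 1L)
  for (k in names(defaults)) p[[k]] <- p[[k]] %||% defaults[[k]]
  extra <- setdiff(names(p), names(defaults))
  if (length(extra))
    lox_abort("lox_config_error",
              paste("unknown parameter(s):", paste(extra, collapse = ", ")),
              2L)
  config$parameters <- p
  config$analyses <- an
  config
}

load_system_trajectory <- function(sys, name, params, index) {
  if (!is.null(sys$synthetic)) {
    sp <- sys$synthetic
    seed <- sp$seed %||% (params$seed + index)
    gen <- switch(sp$kind %||% "reactive",
      reactive = gen_reactive_frames(
        n = sp$n %||% 2000L, d_mean = sp$d_mean %||% 4,
        d_sd = sp$d_sd %||% 0.5, phi_deg = sp$phi_deg %||% 0,
        cutoff = params$cutoff, seed = seed),
      clustered = gen_clustered_frames(
        sizes = unlist(sp$sizes) %||% c(50L, 30L, 20L),
        separation = sp$separation %||% 3,
        jitter_sd = sp$jitter_sd %||% 0.05,
        n_atoms = sp$n_atoms %||% 10L, cutoff = params$cluster_cutoff,
        seed = seed),
      helix = gen_ideal_helix(n_res = sp$n_res %||% 18L,
                              unwound = unlist(sp$unwound)),
      contact = gen_contact_pair(n = sp$n %||% 100L,
                                 d_start = sp$d_start %||% 12,
                                 d_end = sp$d_end %||% 12,
                                 noise_sd = sp$noise_sd %||% 0,
                                 seed = seed),
      lox_abort("lox_config_error",
                paste("unknown synthetic kind for system", name), 2L))
    list(trajectory = gen$trajectory, generated = gen)
  } else {
    if (is.null(sys$trajectory))
      lox_abort("lox_config_error",
                paste("system", name, "declares neither synthetic nor",
                      "trajectory input"), 2L)
    if (!file.exists(sys$trajectory))
      lox_abort("lox_input_error",
                paste("trajectory not found:", sys$trajectory), 3L)
    traj <- tryCatch({
      if (grepl("\\.pdb$", sys$trajectory, ignore.case = TRUE))
        read_multimodel_pdb(sys$trajectory, sys$topology)
      else read_frame_table(sys$trajectory, sys$topology)
    }, error = function(e)
      lox_abort("lox_input_error", conditionMessage(e), 3L))
    list(trajectory = traj, generated = NULL)
  }
}

#' Run the full analysis pipeline
#'
#' Executes the configured analyses for every system, writes CSV/JSON
#' outputs plus a manifest into `output_dir`, and returns the report bundle
#' invisibly.  Reruns with identical config and seeds produce byte-identical
#' output files (full precision in the CSVs; rounding only happens in
#' [report_tables()]).
#'
#' @param config see [validate_run_config()].
#' @return a `lox_bundle` list: per-system results, optional `comparison`,
#'   `kinetics`, `sec` and the `manifest`.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  params <- config$parameters
  outdir <- config$output_dir
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  emit <- function(name, writer) {
    if (!is.null(outdir)) writer(file.path(outdir, name))
  }
  wrap <- function(expr)
    tryCatch(expr, lox_error = function(e) stop(e), error = function(e)
      lox_abort("lox_analysis_error", conditionMessage(e), 4L))

  systems <- list()
  for (i in seq_along(config$systems)) {
    name <- names(config$systems)[i]
    loaded <- load_system_trajectory(config$systems[[i]], name, params, i)
    traj <- loaded$trajectory
    res <- list(generated = loaded$generated)
    if ("geometry" %in% config$analyses) {
      res$distances <- wrap(compute_reactive_distances(traj))
      res$classified <- wrap(classify_frames(res$distances,
                                             cutoff = params$cutoff))
      res$summary <- wrap(summarize_geometry(res$classified, system = name,
                                             discard_ns = params$discard_ns))
      emit(paste0(name, "_frames.csv"),
           function(p) write_classification_csv(res$classified, p))
      emit(paste0(name, "_geometry_summary.csv"),
           function(p) utils::write.csv(res$summary, p, row.names = FALSE))
    }
    if ("cluster" %in% config$analyses) {
      res$rmsd_matrix <- wrap(pairwise_rmsd(traj))
      res$clusters <- wrap(cluster_frames(res$rmsd_matrix,
                                          cutoff = params$cluster_cutoff))
      res$centroid <- wrap(extract_centroid(res$rmsd_matrix, res$clusters))
      emit(paste0(name, "_cluster_labels.csv"), function(p)
        utils::write.csv(data.frame(frame = traj$frame,
                                    cluster = res$clusters$labels),
                         p, row.names = FALSE))
      emit(paste0(name, "_clusters.json"), function(p)
        jsonlite::write_json(list(sizes = res$clusters$sizes,
                                  centroid_frame =
                                    traj$frame[res$centroid]),
                             p, auto_unbox = TRUE))
      emit(paste0(name, "_centroid.pdb"), function(p)
        write_frame_pdb(traj, res$centroid, p))
    }
    if ("hbonds" %in% config$analyses) {
      res$hbonds <- wrap(detect_anchor_hbonds(
        traj, d_cutoff = params$hbond_d_cutoff,
        angle_cutoff = params$hbond_angle_cutoff))
      emit(paste0(name, "_hbond_events.csv"), function(p)
        utils::write.csv(res$hbonds$events, p, row.names = FALSE))
      emit(paste0(name, "_hbond_occupancy.csv"), function(p)
        utils::write.csv(res$hbonds$occupancy, p, row.names = FALSE))
    }
    if ("helix" %in% config$analyses) {
      segs <- names(traj$topology$helix_segments)
      res$helix <- lapply(segs, function(s) wrap(assign_helix(traj, s)))
      names(res$helix) <- segs
      for (s in segs)
        emit(paste0(name, "_helix_", s, ".csv"), function(p)
          utils::write.csv(res$helix[[s]]$metrics, p, row.names = FALSE))
    }
    if ("contacts" %in% config$analyses) {
      prs <- traj$topology$interface_pairs
      res$contacts <- lapply(prs, function(pr)
        wrap(contact_distance_series(traj, pr)))
      if (length(prs))
        emit(paste0(name, "_contacts.csv"), function(p) {
          tabs <- lapply(seq_along(prs), function(k)
            cbind(pair = paste(prs[[k]], collapse = "--"),
                  res$contacts[[k]]$series))
          utils::write.csv(do.call(rbind, tabs), p, row.names = FALSE)
        })
    }
    systems[[name]] <- res
  }

  bundle <- list(systems = systems, parameters = params)

  if (!is.null(config$compare) && "geometry" %in% config$analyses) {
    a <- config$compare$a; b <- config$compare$b
    if (is.null(systems[[a]]$summary) || is.null(systems[[b]]$summary))
      lox_abort("lox_config_error",
                "compare names a system without a geometry summary", 2L)
    bundle$comparison <- wrap(compare_summaries(systems[[a]]$summary,
                                                systems[[b]]$summary))
    emit("comparison.json", function(p)
      jsonlite::write_json(bundle$comparison, p, auto_unbox = TRUE,
                           digits = NA))
  }

  if ("kinetics" %in% config$analyses) {
    kin <- config$kinetics
    dat <- if (!is.null(kin$synthetic))
      do.call(gen_mm_data, kin$synthetic)
    else if (!is.null(kin$csv)) {
      if (!file.exists(kin$csv))
        lox_abort("lox_input_error",
                  paste("kinetics CSV not found:", kin$csv), 3L)
      read_kinetics_csv(kin$csv)
    } else lox_abort("lox_config_error",
                     "kinetics block needs csv or synthetic", 2L)
    fits <- lapply(split(dat, dat$substrate), function(d)
      wrap(fit_michaelis_menten(d)))
    bundle$kinetics <- fits
    emit("kinetics_fits.csv", function(p) {
      tab <- do.call(rbind, lapply(names(fits), function(s)
        data.frame(substrate = s, kcat = fits[[s]]$kcat,
                   se_kcat = fits[[s]]$se_kcat, KM = fits[[s]]$KM,
                   se_KM = fits[[s]]$se_KM,
                   efficiency = fits[[s]]$efficiency,
                   rss = fits[[s]]$rss, n = fits[[s]]$n_points)))
      utils::write.csv(tab, p, row.names = FALSE)
    })
  }

  if ("sec" %in% config$analyses) {
    sc <- config$sec
    std <- if (!is.null(sc$synthetic)) do.call(gen_sec_standards,
                                               sc$synthetic)
    else if (!is.null(sc$csv)) {
      if (!file.exists(sc$csv))
        lox_abort("lox_input_error", paste("SEC CSV not found:", sc$csv), 3L)
      read_sec_csv(sc$csv)
    } else lox_abort("lox_config_error", "sec block needs csv or synthetic",
                     2L)
    Vo <- sc$Vo %||% attr(std, "ground_truth")$Vo
    Vt <- sc$Vt %||% attr(std, "ground_truth")$Vt
    cal <- wrap(calibrate_sec(std, Vo = Vo, Vt = Vt))
    bundle$sec <- list(calibration = cal,
                       estimates = if (!is.null(sc$query_Ve))
                         data.frame(Ve_mL = unlist(sc$query_Ve),
                                    Rh_A = estimate_rh(cal,
                                                       unlist(sc$query_Ve))))
    emit("sec_calibration.json", function(p)
      jsonlite::write_json(list(slope = cal$slope,
                                intercept = cal$intercept,
                                r_squared = cal$r_squared,
                                Vo = Vo, Vt = Vt),
                           p, auto_unbox = TRUE, digits = NA))
  }

  hash_inputs <- function() {
    paths <- character()
    for (s in config$systems)
      paths <- c(paths, s$trajectory, s$topology)
    paths <- c(paths, config$kinetics$csv, config$sec$csv)
    paths <- paths[!vapply(paths, is.null, logical(1L))]
    paths <- unlist(paths)
    if (length(paths) == 0L) return(NULL)
    as.list(tools::md5sum(paths))
  }
  bundle$manifest <- list(package_version =
                            as.character(utils::packageVersion("loxtraj")),
                          parameters = params,
                          analyses = config$analyses,
                          input_md5 = hash_inputs())
  emit("manifest.json", function(p)
    jsonlite::write_json(bundle$manifest, p, auto_unbox = TRUE, digits = NA))
  class(bundle) <- "lox_bundle"
  invisible(bundle)
}

fmt <- function(x, digits) {
  if (length(x) == 0L || is.null(x) || all(is.na(x))) return("n/a")
  formatC(x, format = "f", digits = digits)
}

#' Render report tables from a bundle
#'
#' Human-readable tables following the field's reporting conventions:
#' distances and percentages to two decimals, catalytic efficiencies to one
#' decimal, fold changes >= 10 to the nearest integer.  Empty sections
#' render as "n/a" cells rather than zeros.  All rounding happens here; the
#' bundle and its CSVs keep full precision.
#'
#' @param bundle a `lox_bundle` from [run_pipeline()].
#' @return named list of data.frames with formatted character cells.
#' @export
report_tables <- function(bundle) {
  stopifnot(inherits(bundle, "lox_bundle"))
  out <- list()
  summaries <- Filter(Negate(is.null),
                      lapply(bundle$systems, `[[`, "summary"))
  if (length(summaries)) {
    out$geometry <- do.call(rbind, lapply(summaries, function(s)
      data.frame(System = s$system,
                 `d(C-OH)` = fmt(s$mean_d_C_OH, 2),
                 `d(HproS-OH)` = fmt(s$mean_d_HproS_OH, 2),
                 `d(HproR-OH)` = fmt(s$mean_d_HproR_OH, 2),
                 `Well-Oriented (%)` = fmt(s$pct_well_oriented, 2),
                 `Pre-Catalytic (%)` = fmt(s$pct_precatalytic, 2),
                 check.names = FALSE)))
    rownames(out$geometry) <- NULL
  }
  if (!is.null(bundle$comparison)) {
    cp <- bundle$comparison
    out$comparison <- data.frame(
      `Fold pre-catalytic` = as.character(cp$display_fold_precatalytic),
      `Fold well-oriented` = as.character(cp$display_fold_well_oriented),
      `Delta d(C-OH) (A)` = fmt(cp$display_delta_mean_d_C_OH, 1),
      check.names = FALSE)
  }
  if (!is.null(bundle$kinetics)) {
    out$kinetics <- do.call(rbind, lapply(names(bundle$kinetics),
                                          function(s) {
      f <- bundle$kinetics[[s]]
      data.frame(Substrate = s,
                 `kcat (s-1)` = fmt(f$kcat, 1),
                 `KM (uM)` = fmt(f$KM, 1),
                 `kcat/KM (s-1 uM-1)` = fmt(round(f$efficiency, 1), 1),
                 check.names = FALSE)
    }))
  }
  if (!is.null(bundle$sec)) {
    cal <- bundle$sec$calibration
    out$sec <- data.frame(Slope = fmt(cal$slope, 4),
                          Intercept = fmt(cal$intercept, 4),
                          `r^2` = fmt(cal$r_squared, 4),
                          check.names = FALSE)
  }
  if (length(out) == 0L)
    out$empty <- data.frame(Note = "n/a")
  out
}
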