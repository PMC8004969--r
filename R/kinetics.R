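#' Fit Michaelis-Menten kinetics
#'
#' Nonlinear least-squares fit of v = kcat * S / (KM + S) to initial-rate
#' data (rates already normalized per enzyme, s^-1; substrate in uM).
#' Starting values are kcat0 = max(v) and KM0 = the substrate concentration
#' at half-maximal rate, linearly interpolated on the replicate-averaged
#' saturation curve.  The optimizer is Levenberg-Marquardt
#' (minpack.lm), run to tight tolerances (ptol 1e-10, up to 500
#' iterations); standard errors come from the Jacobian at the optimum.
#' Negative parameter estimates are reported as an error, never silently
#' clamped.
#'
#' @param dataset data.frame with columns `S_uM` and `v_per_s` (a
#'   `replicate` column is allowed; replicate points enter the fit
#'   individually and unweighted).  At least 4 distinct substrate
#'   concentrations, all positive.
#' @return object of class `lox_mmfit`: list with `kcat`, `KM`,
#'   `efficiency` (= kcat/KM), `se_kcat`, `se_KM`, `rss`, `n_points` and the
#'   underlying `nls` object as `fit`.
#' @export
fit_michaelis_menten <- function(dataset) {
  if (!all(c("S_uM", "v_per_s") %in% names(dataset)))
    stop("dataset needs columns S_uM and v_per_s", call. = FALSE)
  S <- dataset$S_uM; v <- dataset$v_per_s
  if (any(S <= 0))
    stop("substrate concentrations must be positive", call. = FALSE)
  if (length(unique(S)) < 4L)
    stop("need at least 4 distinct substrate concentrations", call. = FALSE)
  if (all(v == 0) || max(v) <= 0)
    stop("degenerate rate data: no positive rates to fit", call. = FALSE)
  kcat0 <- max(v)
  means <- stats::aggregate(v, list(S = S), mean)
  means <- means[order(means$S), ]
  KM0 <- stats::approx(means$x, means$S, xout = kcat0 / 2, ties = mean,
                       rule = 2)$y
  if (!is.finite(KM0) || KM0 <= 0) KM0 <- stats::median(S)
  df <- data.frame(S = S, v = v)
  fit <- minpack.lm::nlsLM(
    v ~ kcat * S / (KM + S), data = df,
    start = list(kcat = kcat0, KM = KM0),
    control = minpack.lm::nls.lm.control(maxiter = 500, ptol = 1e-10,
                                         ftol = 1e-15))
  co <- withCallingHandlers(
    summary(fit)$coefficients,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  kcat <- co["kcat", "Estimate"]; KM <- co["KM", "Estimate"]
  if (kcat <= 0 || KM <= 0)
    stop("non-positive parameter estimate (kcat = ", signif(kcat, 4),
         ", KM = ", signif(KM, 4), "); data do not support a ",
         "Michaelis-Menten saturation curve", call. = FALSE)
  structure(list(kcat = kcat, KM = KM,
                 efficiency = kcat / KM,
                 se_kcat = co["kcat", "Std. Error"],
                 se_KM = co["KM", "Std. Error"],
                 rss = sum(stats::resid(fit)^2),
                 n_points = length(v), fit = fit),
            class = "lox_mmfit")
}

#' @export
print.lox_mmfit <- function(x, ...) {
  cat("<lox_mmfit> kcat = ", signif(x$kcat, 4), " +/- ",
      signif(x$se_kcat, 3), " s^-1;  KM = ", signif(x$KM, 4), " +/- ",
      signif(x$se_KM, 3), " uM;  kcat/KM = ", round(x$efficiency, 1),
      " s^-1 uM^-1\n", sep = "")
  invisible(x)
}

#' Catalytic efficiency kcat / KM
#'
#' @param kcat turnover number, s^-1.
#' @param KM Michaelis constant, uM (must be positive).
#' @return efficiency in s^-1 uM^-1 (full precision; reports conventionally
#'   round it to one decimal, see [report_tables()]).
#' @export
catalytic_efficiency <- function(kcat, KM) {
  if (KM <= 0) stop("KM must be positive", call. = FALSE)
  kcat / KM
}

#' Fold change of catalytic efficiencies
#'
#' @param a,b efficiencies (s^-1 uM^-1), `b` the reference (must be
#'   positive).
#' @return list with `fold` (= a/b) and `display` (1-decimal rounding).
#' @export
efficiency_fold_change <- function(a, b) {
  if (b <= 0) stop("reference efficiency must be positive", call. = FALSE)
  list(fold = a / b, display = round(a / b, 1))
}

#' Read an initial-rate kinetics CSV
#'
#' Expected columns: `substrate`, `S_uM`, `v_per_s`, `replicate`.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_kinetics_csv <- function(path) {
  if (!file.exists(path))
    stop("kinetics CSV not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("substrate", "S_uM", "v_per_s", "replicate")
  if (!all(need %in% names(tab)))
    stop("kinetics CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  tab
}
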