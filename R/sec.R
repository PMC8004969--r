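#' Size-exclusion partition coefficient
#'
#' Kav = (Ve - Vo) / (Vt - Vo), with Ve the elution volume of the analyte,
#' Vo the column void volume (blue dextran) and Vt the total bed volume.
#'
#' @param Ve,Vo,Vt volumes in mL; requires Vt > Vo and Vo <= Ve <= Vt.
#' @return Kav in [0, 1].
#' @export
kav <- function(Ve, Vo, Vt) {
  if (any(Vt <= Vo))
    stop("total volume Vt must exceed void volume Vo", call. = FALSE)
  if (any(Ve < Vo) || any(Ve > Vt))
    stop("elution volume must satisfy Vo <= Ve <= Vt", call. = FALSE)
  (Ve - Vo) / (Vt - Vo)
}

#' Calibrate a size-exclusion column for hydrodynamic radius
#'
#' Ordinary least squares of y = (-log10 Kav)^(1/2) on the hydrodynamic
#' radius Rh of the standards (the regression direction follows the usual
#' calibration-plot convention: y against Rh, inverted for prediction).
#' Base-10 logarithm by default, switchable via `log_base`.
#'
#' @param standards data.frame with columns `Rh_A` (Angstrom) and `Ve_mL`;
#'   at least 3 standards (fewer is under-determined by policy).
#' @param Vo,Vt column void and total volumes, mL.
#' @param log_base base of the logarithm in (-log Kav)^(1/2).
#' @return object of class `lox_sec_cal`: list with `slope`, `intercept`,
#'   `r_squared`, `Vo`, `Vt`, `log_base`, `standards` and the `lm` fit.
#' @export
calibrate_sec <- function(standards, Vo, Vt, log_base = 10) {
  need <- c("Rh_A", "Ve_mL")
  if (!all(need %in% names(standards)))
    stop("standards need columns Rh_A and Ve_mL", call. = FALSE)
  if (nrow(standards) < 3L)
    stop("need at least 3 SEC standards", call. = FALSE)
  K <- kav(standards$Ve_mL, Vo, Vt)
  if (any(K == 0))
    stop("Kav = 0 for a standard (Ve = Vo): log undefined", call. = FALSE)
  y <- sqrt(-log(K, base = log_base))
  fit <- stats::lm(y ~ Rh_A, data = data.frame(Rh_A = standards$Rh_A, y = y))
  slope <- unname(stats::coef(fit)[2L])
  if (abs(slope) < .Machine$double.eps^0.5)
    stop("zero calibration slope: standards do not separate", call. = FALSE)
  r2 <- withCallingHandlers(
    summary(fit)$r.squared,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2,
                 Vo = Vo, Vt = Vt, log_base = log_base,
                 standards = standards, fit = fit),
            class = "lox_sec_cal")
}

#' @export
print.lox_sec_cal <- function(x, ...) {
  cat("<lox_sec_cal> (-log", x$log_base, " Kav)^1/2 = ",
      signif(x$intercept, 4), " + ", signif(x$slope, 4),
      " * Rh;  r^2 = ", signif(x$r_squared, 6), "\n", sep = "")
  invisible(x)
}

#' Estimate a hydrodynamic radius from an elution volume
#'
#' Inverts the calibration line: Rh = ((-log Kav(Ve))^(1/2) - intercept) /
#' slope.
#'
#' @param cal a `lox_sec_cal` from [calibrate_sec()].
#' @param Ve elution volume, mL (must exceed Vo: Kav = 0 has no log).
#' @return hydrodynamic radius in Angstrom.
#' @export
estimate_rh <- function(cal, Ve) {
  stopifnot(inherits(cal, "lox_sec_cal"))
  K <- kav(Ve, cal$Vo, cal$Vt)
  if (any(K == 0))
    stop("Kav = 0 (Ve = Vo): radius outside the calibrated range",
         call. = FALSE)
  y <- sqrt(-log(K, base = cal$log_base))
  (y - cal$intercept) / cal$slope
}

#' Read a SEC standards CSV
#'
#' Expected columns: `name`, `Rh_A`, `Ve_mL`.
#' @param path CSV path.
#' @export
read_sec_csv <- function(path) {
  if (!file.exists(path))
    stop("SEC CSV not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "Rh_A", "Ve_mL") %in% names(tab)))
    stop("SEC CSV must have columns name, Rh_A, Ve_mL", call. = FALSE)
  tab
}
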