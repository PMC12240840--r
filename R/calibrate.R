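#' Sensor concentration-response calibration curve
#'
#' The sigmoidal (Hill) response
#' `F(C) = f_max C^h / (C^h + EC50^h)` maps transmitter concentration
#' (nM) to percent dF/F0 and is analytically invertible on `(0, f_max)`.
#' The default parameters (`f_max` 5% dF/F0, `EC50` 1010 nM, `hill` 1)
#' are constructed so a quantal amplitude of 0.45% dF/F0 converts to
#' about 100 nM; all are user-overridable.
#'
#' @param f_max Percent dF/F0 at saturation.
#' @param ec50 Half-saturating concentration in nM.
#' @param hill Hill coefficient.
#' @param r_squared Goodness of fit (when fitted from points).
#' @return A `calibration_curve` object.
#' @export
calibration_curve <- function(f_max = 5, ec50 = 1010, hill = 1,
                              r_squared = NA_real_) {
  for (nm in c("f_max", "ec50", "hill")) assert_scalar_pos(get(nm), nm)
  structure(
    list(f_max = f_max, ec50 = ec50, hill = hill, r_squared = r_squared),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> f_max %.3g%%, EC50 %.4g nM, hill %.3g%s\n",
    x$f_max, x$ec50, x$hill,
    if (is.finite(x$r_squared)) sprintf(", R2 %.4f", x$r_squared) else ""
  ))
  invisible(x)
}

#' Fit the sigmoid calibration curve to concentration-response points
#'
#' Least-squares fit of `F = f_max C^h / (C^h + EC50^h)`. Requires at
#' least 4 points spanning at least one decade of concentration;
#' non-monotone data are flagged with a warning (the fit proceeds).
#'
#' @param points Data frame with columns `concentration_nM` and
#'   `dff_pct`.
#' @return A `calibration_curve` with `r_squared` filled in.
#' @export
fit_sigmoid <- function(points) {
  if (!all(c("concentration_nM", "dff_pct") %in% names(points))) {
    abort("`points` needs columns concentration_nM and dff_pct")
  }
  conc <- points$concentration_nM
  dff <- points$dff_pct
  if (length(conc) < 4L) abort("need at least 4 calibration points")
  pos <- conc > 0
  if (sum(pos) < 2L || max(conc[pos]) / min(conc[pos]) < 10) {
    abort("calibration points must span at least one decade of concentration")
  }
  ord <- order(conc)
  if (any(diff(dff[ord]) < -0.05 * max(abs(dff)))) {
    warn("calibration points are not monotone increasing: fit flagged")
  }
  fit <- minpack.lm::nlsLM(
    dff ~ f_max * conc^hill / (conc^hill + ec50^hill),
    start = list(f_max = max(dff) * 1.05,
                 ec50 = stats::median(conc[pos]), hill = 1),
    lower = c(1e-9, 1e-9, 0.1), upper = c(Inf, Inf, 10),
    control = minpack.lm::nls.lm.control(maxiter = 300)
  )
  cf <- as.list(coef(fit))
  rsq <- 1 - sum(residuals(fit)^2) / sum((dff - mean(dff))^2)
  calibration_curve(cf$f_max, cf$ec50, cf$hill, r_squared = rsq)
}

#' Convert dF/F0 amplitudes to transmitter concentration
#'
#' Analytic inverse of the calibration sigmoid:
#' `C = EC50 (F / (f_max - F))^(1/h)`, defined for
#' `0 <= F < f_max`. With the default curve, the quantal size of 0.45%
#' dF/F0 converts to approximately 100 nM.
#'
#' @param curve A [calibration_curve()].
#' @param dff Percent dF/F0 value(s), each in `[0, f_max)`.
#' @return Concentration(s) in nM.
#' @export
dff_to_concentration <- function(curve, dff) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(dff < 0)) abort("dF/F0 must be >= 0")
  if (any(dff >= curve$f_max)) {
    abort(sprintf("dF/F0 must be below saturation f_max = %g%%", curve$f_max))
  }
  curve$ec50 * (dff / (curve$f_max - dff))^(1 / curve$hill)
}

#' @rdname dff_to_concentration
#' @param conc Concentration(s) in nM (>= 0).
#' @export
concentration_to_dff <- function(curve, conc) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(conc < 0)) abort("concentration must be >= 0")
  ch <- conc^curve$hill
  curve$f_max * ch / (ch + curve$ec50^curve$hill)
}
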