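#' Fit the dipole planar offsets to a measured field map
#'
#' Conforms the point-dipole model to a gridded |B| map by nonlinear least
#' squares: starting from the preliminary model (moment magnitude and height
#' above the floor fixed at their preliminary estimates), the planar offsets
#' (dx, dy) of the dipole position are adjusted to minimise the sum of
#' squared differences between predicted and measured |B| over all records.
#' These two offsets are the only unknowns of the standard fit; with
#' `refine_moment = TRUE` the moment magnitude is refined as a third
#' parameter, which is useful for parameter-recovery studies.
#'
#' Adherence of the conformed model to the measures is summarised by the
#' Pearson correlation coefficient of predicted vs measured |B|.
#'
#' @param map A [field_map()] with at least 3 records at >= 2 distinct
#'   heights.
#' @param preliminary A [dipole_model()] holding the preliminary moment,
#'   axis and position (nominal magnet location and height).
#' @param refine_moment Logical; also refine the moment magnitude.
#' @return An object of class `dipole_fit` with fields `delta_x`, `delta_y`
#'   (metres), `moment_estimate` (A m^2), `pearson_r`, `residuals`
#'   (predicted - measured, tesla), `model` (the conformed [dipole_model()])
#'   and `convergence` diagnostics.
#' @seealso [make_field_map()] for synthetic maps, [pearson_correlation()].
#' @export
fit_dipole <- function(map, preliminary, refine_moment = FALSE) {
  stopifnot(inherits(map, "field_map"), inherits(preliminary, "dipole_model"))
  rec <- map$records
  if (nrow(rec) < 3L) stop("fit needs at least 3 field records")
  if (length(unique(rec$z_m)) < 2L)
    stop("fit needs records at >= 2 distinct heights")
  pos <- as.matrix(rec[, c("x_m", "y_m", "z_m")])
  # collinearity of the measurement positions leaves the planar offsets
  # under-determined transverse to the line
  sv <- svd(scale(pos, scale = FALSE))$d
  if (sv[2] < 1e-9 * max(sv))
    warning("measurement positions are (nearly) collinear; fit may be rank-deficient")
  meas <- rec$B_T

  shifted <- function(par) {
    m <- preliminary
    m$position <- preliminary$position + c(par[1], par[2], 0)
    if (refine_moment) m$moment_magnitude <- par[3]
    m
  }
  resid_fun <- function(par) predict_map(shifted(par), pos) - meas

  start <- c(dx = 0, dy = 0)
  lower <- c(-5, -5)
  upper <- c(5, 5)
  if (refine_moment) {
    start <- c(start, m = preliminary$moment_magnitude)
    lower <- c(lower, 1e-3 * preliminary$moment_magnitude)
    upper <- c(upper, 1e3 * preliminary$moment_magnitude)
  }
  ctl <- minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12, maxiter = 500)
  ans <- minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                            fn = resid_fun, control = ctl)
  if (!ans$info %in% 1:4)
    stop("dipole fit failed to converge: ", ans$message)
  par <- ans$par
  final <- shifted(par)
  pred <- predict_map(final, pos)
  structure(
    list(delta_x = unname(par[1]),
         delta_y = unname(par[2]),
         moment_estimate = final$moment_magnitude,
         pearson_r = pearson_correlation(pred, meas),
         residuals = pred - meas,
         model = final,
         convergence = list(info = ans$info, message = ans$message,
                            niter = ans$niter, deviance = ans$deviance)),
    class = "dipole_fit"
  )
}

#' @export
print.dipole_fit <- function(x, ...) {
  cat(sprintf("Dipole fit: dx = %.4f m, dy = %.4f m, m = %.4g A m^2\n",
              x$delta_x, x$delta_y, x$moment_estimate))
  cat(sprintf("  Pearson r (predicted vs measured |B|) = %.4f, RMS residual = %.3g T\n",
              x$pearson_r, sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' Sample Pearson correlation coefficient
#'
#' Thin validated wrapper over [stats::cor()]: equal-length series with
#' nonzero variance in both.
#'
#' @param a,b Numeric vectors of equal length >= 2.
#' @return The sample correlation r in \[-1, 1\].
#' @export
pearson_correlation <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) != length(b)) stop("series must have equal length")
  if (length(a) < 2L) stop("correlation needs length >= 2")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined: a series has zero variance")
  stats::cor(a, b)
}
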