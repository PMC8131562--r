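#' Motion-induced electromotive field |v x B|
#'
#' For a conductor (the body) moving through a static magnetic field, the
#' Lorentz force per unit charge gives the electromotive field v x B; its
#' modulus is the exposure metric tested against the Directive 2013/35/EU
#' exposure limit values. The reaction electrostatic field that builds up
#' inside tissue opposes it, so neglecting it (as done here) is a
#' precautionary overestimate.
#'
#' @param v Velocity 3-vector (m/s) or T x 3 matrix.
#' @param B Magnetic flux density 3-vector (T) or T x 3 matrix.
#' @return |v x B| in V/m (scalar or length-T vector).
#' @export
emf <- function(v, B) {
  if (is.null(dim(v))) v <- matrix(as.numeric(v), nrow = 1L)
  if (is.null(dim(B))) B <- matrix(as.numeric(B), nrow = nrow(v), ncol = 3L,
                                   byrow = TRUE)
  stopifnot(ncol(v) == 3L, ncol(B) == 3L, nrow(v) == nrow(B),
            all(is.finite(v)), all(is.finite(B)))
  cx <- v[, 2] * B[, 3] - v[, 3] * B[, 2]
  cy <- v[, 3] * B[, 1] - v[, 1] * B[, 3]
  cz <- v[, 1] * B[, 2] - v[, 2] * B[, 1]
  out <- sqrt(cx^2 + cy^2 + cz^2)
  if (length(out) == 1L) as.numeric(out) else out
}

#' Exposure limit values of Directive 2013/35/EU
#'
#' The two limit rules printed for movement in static fields: the
#' health-effects ELV of 1.1 V/m on the induced field anywhere in the body,
#' and the sensory-effects ELV of 0.7/f V/m in the head, where f is the
#' motion-related frequency in Hz.
#'
#' @param health_elv Health-effects limit, V/m.
#' @param sensory_coefficient Numerator of the sensory rule, V Hz/m.
#' @return An object of class `elv_spec`.
#' @export
elv_spec <- function(health_elv = 1.1, sensory_coefficient = 0.7) {
  stopifnot(health_elv > 0, sensory_coefficient > 0)
  structure(list(health_elv = health_elv,
                 sensory_coefficient = sensory_coefficient),
            class = "elv_spec")
}

#' Frequency-adjusted sensory-effects ELV
#'
#' @param f Motion-related frequency in Hz (> 0).
#' @param spec An [elv_spec()].
#' @return The sensory ELV 0.7/f in V/m.
#' @export
sensory_elv <- function(f, spec = elv_spec()) {
  stopifnot(inherits(spec, "elv_spec"))
  if (!is.numeric(f) || any(f <= 0)) stop("frequency must be > 0")
  spec$sensory_coefficient / f
}

#' Assess a task: per-point electromotive field and peaks
#'
#' For every frame t and exposure point i, evaluates
#' E\[t, i\] = |v_i(t) x B(p_i(t))| with B taken from the dipole model at the
#' point's instantaneous position (the model is continuous in space, so no
#' static room-map lookup is involved). Also reports the per-frame peak over
#' the requested subset of points and the task peak.
#'
#' @param kin A `point_kinematics` object from [extract_exposure_points()].
#' @param model A [dipole_model()] in the same room frame.
#' @param point_subset `"all"` (the 23 body points) or `"head"` (the 5-point
#'   head subset used for the sensory-effects assessment).
#' @return An object of class `exposure_result`: `E` (T x n matrix, V/m),
#'   `body_peak_series` / `head_peak_series` (per-frame maxima over the 23
#'   points and the head subset), `task_peak`, `peak_frame`, `peak_point`,
#'   `rate`, `subset`, `meta`.
#' @export
assess_task <- function(kin, model, point_subset = c("all", "head")) {
  stopifnot(inherits(kin, "point_kinematics"), inherits(model, "dipole_model"))
  point_subset <- match.arg(point_subset)
  n <- length(kin$position)
  T <- nrow(kin$speed)
  E <- matrix(0, T, n, dimnames = list(NULL, names(kin$position)))
  for (i in seq_len(n)) {
    B <- dipole_field(kin$position[[i]], model)
    E[, i] <- emf(kin$velocity[[i]], B)
  }
  head_idx <- kin$point_set$head_subset
  body_peak <- apply(E, 1L, max)
  head_peak <- apply(E[, head_idx, drop = FALSE], 1L, max)
  used <- if (point_subset == "head") E[, head_idx, drop = FALSE] else E
  pk <- which(used == max(used), arr.ind = TRUE)[1L, ]
  structure(list(E = E,
                 body_peak_series = body_peak,
                 head_peak_series = head_peak,
                 task_peak = if (point_subset == "head") max(head_peak) else max(body_peak),
                 peak_frame = unname(pk["row"]),
                 peak_point = colnames(used)[pk["col"]],
                 rate = kin$rate,
                 subset = point_subset,
                 meta = kin$meta),
            class = "exposure_result")
}

#' @export
print.exposure_result <- function(x, ...) {
  cat(sprintf("Exposure (%s points): task peak %.4f V/m at frame %d (%s)\n",
              x$subset, x$task_peak, x$peak_frame, x$peak_point))
  cat(sprintf("  body peak %.4f V/m, head peak %.4f V/m over %d frames\n",
              max(x$body_peak_series), max(x$head_peak_series),
              length(x$body_peak_series)))
  invisible(x)
}

#' Motion-related frequency by the spectral centroid of the periodogram
#'
#' The signal (by default the head peak-exposure series of the task) is
#' mean-removed, its raw periodogram computed over the full task window with
#' no taper (frequency resolution 1/T_task), and the motion-related
#' frequency estimated as the power-weighted mean frequency
#' f = sum(f_k P_k) / sum(P_k) over the positive frequencies up to Nyquist.
#'
#' @param signal Numeric series of length >= 16.
#' @param rate Sampling rate in Hz.
#' @return An object of class `frequency_estimate`: `f` (Hz) and `method`
#'   metadata (window length, resolution, detrending).
#' @export
spectral_centroid_frequency <- function(signal, rate) {
  x <- as.numeric(signal)
  n <- length(x)
  if (n < 16L) stop("spectral centroid needs at least 16 samples")
  stopifnot(rate > 0, all(is.finite(x)))
  x <- x - mean(x)
  if (all(abs(x) < 1e-300))
    stop("signal has no power after mean removal; frequency undefined")
  P <- Mod(stats::fft(x))^2
  k <- seq(2L, floor(n / 2) + 1L)          # positive frequencies
  f <- (k - 1L) * rate / n
  fc <- sum(f * P[k]) / sum(P[k])
  structure(list(f = fc,
                 method = list(estimator = "spectral centroid of raw periodogram",
                               window = "full task, rectangular",
                               n = n, resolution_hz = rate / n,
                               detrend = "mean removal")),
            class = "frequency_estimate")
}

#' @export
print.frequency_estimate <- function(x, ...) {
  cat(sprintf("Motion-related frequency: %.3f Hz (%s, resolution %.3g Hz)\n",
              x$f, x$method$estimator, x$method$resolution_hz))
  invisible(x)
}

#' Compliance verdict against the Directive ELVs
#'
#' Health effects: the whole-body task peak must stay below 1.1 V/m.
#' Sensory effects: the head task peak must stay below the
#' frequency-adjusted limit 0.7/f V/m. Comparisons are strict ("did not
#' exceed"); margins are reported signed (ELV minus peak, negative on
#' failure).
#'
#' @param result An [assess_task()] result.
#' @param f A `frequency_estimate` (or a plain frequency in Hz).
#' @param spec An [elv_spec()].
#' @return An object of class `compliance_verdict`: `health_pass`,
#'   `sensory_pass`, `body_peak`, `head_peak`, `f_hz`, `health_elv`,
#'   `sensory_elv`, `health_margin`, `sensory_margin`.
#' @export
check_compliance <- function(result, f, spec = elv_spec()) {
  stopifnot(inherits(result, "exposure_result"), inherits(spec, "elv_spec"))
  fhz <- if (inherits(f, "frequency_estimate")) f$f else as.numeric(f)
  body_peak <- max(result$body_peak_series)
  head_peak <- max(result$head_peak_series)
  s_elv <- sensory_elv(fhz, spec)
  structure(list(health_pass = body_peak < spec$health_elv,
                 sensory_pass = head_peak < s_elv,
                 body_peak = body_peak, head_peak = head_peak,
                 f_hz = fhz,
                 health_elv = spec$health_elv, sensory_elv = s_elv,
                 health_margin = spec$health_elv - body_peak,
                 sensory_margin = s_elv - head_peak),
            class = "compliance_verdict")
}

#' @export
print.compliance_verdict <- function(x, ...) {
  cat(sprintf("Health ELV %.2f V/m: body peak %.4f V/m -> %s (margin %+.4f)\n",
              x$health_elv, x$body_peak,
              if (x$health_pass) "PASS" else "FAIL", x$health_margin))
  cat(sprintf("Sensory ELV %.4f V/m (f = %.3f Hz): head peak %.4f V/m -> %s (margin %+.4f)\n",
              x$sensory_elv, x$f_hz, x$head_peak,
              if (x$sensory_pass) "PASS" else "FAIL", x$sensory_margin))
  invisible(x)
}

#' ICNIRP conversion-factor estimator (comparison only)
#'
#' The guideline approximation E_i = C d|B|/dt, with C a "conversion factor"
#' lumping body geometry and tissue properties. It is a coarse approximation
#' of the motion-induced field and is provided only for side-by-side
#' comparison with the |v x B| assessment; no printed value of C exists for
#' this setting, so the default 0.2 m is merely a configurable placeholder
#' magnitude.
#'
#' @param B_series Per-frame |B| at a tracked point, tesla.
#' @param rate Sampling rate in Hz.
#' @param C Conversion factor in metres.
#' @return Per-frame estimate C |d|B|/dt| in V/m (same length as input;
#'   one-sided differences at the ends).
#' @export
icnirp_estimate <- function(B_series, rate, C = 0.2) {
  stopifnot(C > 0)
  x <- as.numeric(B_series)
  if (length(x) < 3L) stop("estimator needs at least 3 frames")
  C * abs(differentiate(x, rate))
}
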