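#' Zero-phase low-pass smoothing of a marker trajectory
#'
#' Marker coordinates are smoothed with a forward-backward (zero phase)
#' Butterworth low-pass filter. To suppress the edge transients of plain
#' forward-backward filtering, the series is first detrended by the straight
#' line through its endpoints, padded by odd reflection about each end, and
#' the trend restored after filtering; a constant series is therefore
#' returned unchanged and a linear ramp is preserved exactly. An optional
#' cross-validated smoothing-spline mode is available for trials whose
#' frequency content is unknown.
#'
#' @param series Numeric vector, or T x 3 position matrix (smoothed per
#'   column). Length must be at least 7 frames.
#' @param rate Sampling rate in Hz.
#' @param cutoff Low-pass cutoff in Hz (default 6, which passes
#'   gait-frequency content untouched and removes marker jitter).
#' @param order Butterworth order (default 4; applied twice, so the
#'   effective roll-off is 8th order).
#' @param method `"butterworth"` (default) or `"spline"`
#'   (generalised cross-validated [stats::smooth.spline()]).
#' @return Smoothed series with the same shape as the input.
#' @export
smooth_series <- function(series, rate, cutoff = 6, order = 4,
                          method = c("butterworth", "spline")) {
  method <- match.arg(method)
  if (is.matrix(series))
    return(apply(series, 2L, smooth_series, rate = rate, cutoff = cutoff,
                 order = order, method = method))
  x <- as.numeric(series)
  n <- length(x)
  if (n < 7L) stop("series too short to smooth (need >= 7 frames)")
  if (any(!is.finite(x))) stop("series contains non-finite values; fill gaps first")
  if (method == "spline") {
    t <- (seq_len(n) - 1) / rate
    return(stats::smooth.spline(t, x)$y)
  }
  if (cutoff >= rate / 2) stop("cutoff must be below the Nyquist frequency")
  line <- x[1] + (x[n] - x[1]) * (seq_len(n) - 1) / (n - 1)
  r <- x - line
  np <- min(n - 1L, max(3L * order, ceiling(3 * rate / cutoff)))
  padded <- c(2 * r[1] - r[seq(np + 1L, 2L)],
              r,
              2 * r[n] - r[seq(n - 1L, n - np)])
  bf <- signal::butter(order, cutoff / (rate / 2))
  sm <- signal::filtfilt(bf, padded)
  sm[(np + 1L):(np + n)] + line
}

#' Differentiate a position series into velocity
#'
#' Central finite differences at interior frames, first-order one-sided
#' differences at the two endpoints. Endpoints of a trial are door-entry and
#' door-exit frames far from the magnet, so the lower-order ends have
#' negligible effect on exposure estimates.
#'
#' @param series Numeric vector or T x 3 matrix of positions (metres).
#' @param rate Sampling rate in Hz.
#' @return Velocity series of the same shape, in m/s.
#' @export
differentiate <- function(series, rate) {
  if (is.matrix(series))
    return(apply(series, 2L, differentiate, rate = rate))
  x <- as.numeric(series)
  n <- length(x)
  if (n < 3L) stop("differentiation needs at least 3 frames")
  v <- numeric(n)
  v[1] <- (x[2] - x[1]) * rate
  v[n] <- (x[n] - x[n - 1]) * rate
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * rate / 2
  v
}

#' Per-frame centroid of a marker cluster
#'
#' Body segments are tracked by clusters of at least three skin markers; the
#' segment's representative point is the per-frame arithmetic mean of the
#' member marker positions.
#'
#' @param rec A [recording()].
#' @param labels Character vector of >= 3 marker labels present in `rec`.
#' @return T x 3 matrix of centroid positions.
#' @export
cluster_centroid <- function(rec, labels) {
  stopifnot(inherits(rec, "recording"))
  if (length(labels) < 3L)
    stop("a segment cluster needs at least 3 markers")
  missing <- setdiff(labels, names(rec$markers))
  if (length(missing))
    stop("cluster labels not in recording: ", paste(missing, collapse = ", "))
  Reduce(`+`, rec$markers[labels]) / length(labels)
}

#' Segment cluster map of the full-body marker protocol
#'
#' The combined full-body protocol tracks 47 reflective markers; six serve
#' only for anatomical calibration in the static trial and are removed
#' before the dynamic trials. Each tracked body segment carries a cluster of
#' at least three markers. This function returns the shipped default map:
#' segment name -> member labels, plus the calibration-only label set.
#'
#' @return A list of class `segment_cluster_map` with elements `clusters`
#'   (named list of label vectors) and `calibration_only` (character).
#' @export
default_cluster_map <- function() {
  clusters <- list(
    head    = c("RTEMP", "LTEMP", "ROCC", "LOCC"),
    trunk   = c("T2", "MAI", "SJN", "SXS"),
    pelvis  = c("RASI", "LASI", "RPSI", "LPSI", "SACR"),
    thigh_r = c("RTH1", "RTH2", "RTH3"),
    thigh_l = c("LTH1", "LTH2", "LTH3"),
    tibia_r = c("RTB1", "RTB2", "RTB3"),
    tibia_l = c("LTB1", "LTB2", "LTB3"),
    foot_r  = c("RHEE", "RFMH", "RVMH"),
    foot_l  = c("LHEE", "LFMH", "LVMH"),
    hand_r  = c("RHD1", "RHD2", "RHD3"),
    hand_l  = c("LHD1", "LHD2", "LHD3")
  )
  calibration_only <- c("RMMA", "LMMA", "RMFE", "LMFE", "RMHE", "LMHE")
  bad <- intersect(unlist(clusters), calibration_only)
  if (length(bad)) stop("calibration-only labels inside dynamic clusters")
  structure(list(clusters = clusters, calibration_only = calibration_only),
            class = "segment_cluster_map")
}

#' The 23 representative exposure points
#'
#' Exposure to the motion-induced electromotive field is assessed at 23
#' representative body points: the 11 segment-cluster centroids (head,
#' trunk, pelvis, right/left thigh, tibia, foot and hand) and 12 individual
#' markers (the four head markers — right/left temple and right/left side of
#' the occipital bone — the second thoracic vertebra, the inter-scapular
#' midpoint, the jugular notch, the xiphoid process, and the four iliac-spine
#' markers). The head subset used for the sensory-effects assessment holds
#' the head centroid plus the four head markers (points 1, 12-15).
#'
#' @return A list of class `exposure_point_set` with elements `points`
#'   (data.frame: `id`, `type` = centroid|marker, `ref` = segment or label)
#'   and `head_subset` (integer indices into `points`).
#' @export
default_exposure_points <- function() {
  points <- data.frame(
    id = 1:23,
    type = c(rep("centroid", 11), rep("marker", 12)),
    ref = c("head", "trunk", "pelvis", "thigh_r", "thigh_l", "tibia_r",
            "tibia_l", "foot_r", "foot_l", "hand_r", "hand_l",
            "RTEMP", "LTEMP", "ROCC", "LOCC", "T2", "MAI", "SJN", "SXS",
            "RASI", "LASI", "RPSI", "LPSI"),
    stringsAsFactors = FALSE
  )
  structure(list(points = points, head_subset = c(1L, 12L, 13L, 14L, 15L)),
            class = "exposure_point_set")
}

#' Positions and velocities at the 23 exposure points
#'
#' Runs the kinematics pipeline on a dynamic trial: fill short occlusion
#' gaps, smooth every marker trajectory, derive the segment-cluster
#' centroids, and differentiate each of the 23 exposure-point trajectories
#' into velocity.
#'
#' @param rec A [recording()] of a dynamic trial.
#' @param clusters A segment cluster map ([default_cluster_map()]).
#' @param point_set An exposure point set ([default_exposure_points()]).
#' @param cutoff,order Smoothing parameters passed to [smooth_series()].
#' @return An object of class `point_kinematics`: list with `rate`,
#'   `position` (list of 23 T x 3 matrices, named `p01`..`p23`),
#'   `velocity` (same shape, m/s), `speed` (T x 23 matrix of |v|),
#'   `point_set`, and `meta` carried over from the recording.
#' @export
extract_exposure_points <- function(rec,
                                    clusters = default_cluster_map(),
                                    point_set = default_exposure_points(),
                                    cutoff = 6, order = 4) {
  stopifnot(inherits(rec, "recording"),
            inherits(clusters, "segment_cluster_map"),
            inherits(point_set, "exposure_point_set"))
  pts <- point_set$points
  needed_markers <- c(unlist(clusters$clusters[pts$ref[pts$type == "centroid"]]),
                      pts$ref[pts$type == "marker"])
  missing <- setdiff(unique(needed_markers), names(rec$markers))
  if (length(missing))
    stop("recording lacks markers required by the point set: ",
         paste(missing, collapse = ", "))

  smoothed <- rec
  smoothed$markers <- lapply(rec$markers, function(m)
    smooth_series(fill_gaps(m), rate = rec$rate, cutoff = cutoff, order = order))

  position <- vector("list", nrow(pts))
  for (i in seq_len(nrow(pts))) {
    position[[i]] <- if (pts$type[i] == "centroid") {
      cluster_centroid(smoothed, clusters$clusters[[pts$ref[i]]])
    } else {
      smoothed$markers[[pts$ref[i]]]
    }
    if (is.null(position[[i]]))
      stop(sprintf("exposure point %d ('%s') cannot be resolved", i, pts$ref[i]))
  }
  names(position) <- sprintf("p%02d", pts$id)
  velocity <- lapply(position, differentiate, rate = rec$rate)
  speed <- vapply(velocity, function(v) sqrt(rowSums(v^2)),
                  numeric(nrow(position[[1]])))
  structure(list(rate = rec$rate, position = position, velocity = velocity,
                 speed = speed, point_set = point_set, meta = rec$meta),
            class = "point_kinematics")
}

#' @export
print.point_kinematics <- function(x, ...) {
  cat(sprintf("Point kinematics: %d points x %d frames @ %g Hz, peak speed %.2f m/s\n",
              length(x$position), nrow(x$speed), x$rate, max(x$speed)))
  invisible(x)
}
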