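#' Point magnetic dipole model of an MRI stray field
#'
#' Constructs the parsimonious source model used for the static field straying
#' from a closed-bore MRI magnet: a single point magnetic dipole of moment
#' `moment_magnitude` (A m^2) directed along the unit vector `moment_axis`,
#' located at `position` (metres, room frame, z up). The room frame has its
#' origin at the field-map corner nearest Door A; the dipole sits at the
#' nominal magnet location plus the fitted planar offsets, at height `h`
#' above the floor.
#'
#' @param moment_magnitude Dipole moment m, in A m^2. Must be positive.
#'   Default is the 3.0 T preliminary, 1.06e6 A m^2.
#' @param position Numeric length-3 position of the dipole (x, y, z) in metres;
#'   z is the height above the floor and must be positive. Default places the
#'   magnet at the nominal isocenter of the reference room at 1.00 m height.
#' @param moment_axis Unit 3-vector giving the moment direction. Defaults to
#'   the bore axis of the reference room (+y, horizontal): a closed full-body
#'   scanner's field is oriented along its bore. Renormalised if within 1e-6
#'   of unit length, rejected otherwise.
#' @return An object of class `dipole_model` with fields `moment_magnitude`,
#'   `moment_axis`, `position` and `mu0`.
#' @seealso [dipole_field()], [fit_dipole()]
#' @examples
#' m <- dipole_model()
#' dipole_field(m$position + c(0, 1, 0), m)
#' @export
dipole_model <- function(moment_magnitude = 1.06e6,
                         position = c(2.0, 5.0, 1.0),
                         moment_axis = c(0, 1, 0)) {
  stopifnot(is.numeric(moment_magnitude), length(moment_magnitude) == 1L,
            is.finite(moment_magnitude),
            is.numeric(position), length(position) == 3L, all(is.finite(position)),
            is.numeric(moment_axis), length(moment_axis) == 3L,
            all(is.finite(moment_axis)))
  if (moment_magnitude <= 0) stop("moment_magnitude must be > 0")
  if (position[3] <= 0) stop("dipole height above the floor must be > 0")
  nrm <- sqrt(sum(moment_axis^2))
  if (abs(nrm - 1) > 1e-6) stop("moment_axis must be a unit vector")
  structure(
    list(moment_magnitude = moment_magnitude,
         moment_axis = moment_axis / nrm,
         position = as.numeric(position),
         mu0 = 4e-7 * pi),
    class = "dipole_model"
  )
}

#' @export
print.dipole_model <- function(x, ...) {
  cat(sprintf("Point dipole: m = %.4g A m^2, axis = (%.3f, %.3f, %.3f),\n",
              x$moment_magnitude, x$moment_axis[1], x$moment_axis[2],
              x$moment_axis[3]))
  cat(sprintf("  position = (%.3f, %.3f, %.3f) m\n",
              x$position[1], x$position[2], x$position[3]))
  invisible(x)
}

#' Magnetic flux density of a point dipole
#'
#' Evaluates B(r) = (mu0 / 4 pi) (3 (m . rhat) rhat - m) / |r|^3 with
#' r the vector from the dipole position to `point` and m the moment vector.
#' On the moment axis this reduces to |B| = mu0 m / (2 pi r^3), and in the
#' equatorial plane to |B| = mu0 m / (4 pi r^3) antiparallel to the moment.
#'
#' @param point Either a numeric length-3 position or an n x 3 matrix of
#'   positions, metres, room frame.
#' @param model A [dipole_model()].
#' @return A length-3 vector (or n x 3 matrix) of B components in tesla.
#' @export
dipole_field <- function(point, model) {
  stopifnot(inherits(model, "dipole_model"))
  single <- is.null(dim(point))
  P <- if (single) matrix(as.numeric(point), nrow = 1L) else as.matrix(point)
  if (ncol(P) != 3L) stop("point must have 3 coordinates")
  R <- sweep(P, 2L, model$position)
  r2 <- rowSums(R^2)
  bad <- which(r2 < 1e-24)
  if (length(bad))
    stop(sprintf("field requested at the dipole position (singularity) at index %d",
                 bad[1]))
  r <- sqrt(r2)
  mvec <- model$moment_magnitude * model$moment_axis
  mdotr <- R %*% mvec            # m . r  (not yet normalised)
  coef <- model$mu0 / (4 * pi)
  # B = coef * (3 (m.r) r / r^5 - m / r^3)
  B <- coef * (3 * as.numeric(mdotr) / r2^2 / r * R -
                 matrix(mvec, nrow(P), 3L, byrow = TRUE) / (r2 * r))
  if (single) as.numeric(B) else B
}

#' Measurement-grid specification for stray-field mapping
#'
#' Describes the planar net of Hall-probe stations and the heights at which
#' |B| is recorded. The default reference layout reproduces the published
#' protocol counts: 70 planar points as close as possible to the bore and
#' couch, with 20 cm (short) steps in the rows nearest the bore and 40 cm
#' (long) steps elsewhere, repeated at heights 72, 119 and 156 cm, for a
#' total of 210 measurement positions.
#'
#' @param planar_points Two-column matrix (or data.frame) of (x, y) station
#'   coordinates in metres; rows must be unique.
#' @param heights Numeric vector of distinct positive probe heights in metres.
#' @param step_short,step_long Nominal short/long net steps in metres,
#'   recorded for provenance (0.20 and 0.40 by default).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(planar_points, heights,
                      step_short = 0.20, step_long = 0.40) {
  pp <- as.matrix(planar_points)
  if (ncol(pp) != 2L || nrow(pp) < 1L)
    stop("planar_points must be an n x 2 matrix with n >= 1")
  if (anyDuplicated(pp)) stop("planar points must be unique")
  heights <- as.numeric(heights)
  if (length(heights) < 1L || any(heights <= 0) || anyDuplicated(heights))
    stop("heights must be distinct and > 0")
  structure(list(planar_points = unname(pp), heights = heights,
                 step_short = step_short, step_long = step_long),
            class = "grid_spec")
}

#' Reference 70-point measurement grid
#'
#' The reference planar net: 10 columns spaced 0.40 m across the room width,
#' and 7 rows approaching the magnet from mid-room, spaced 0.40 m far from
#' the bore and tightening to 0.20 m near it, giving 70 stations. Heights
#' default to 0.72, 1.19 and 1.56 m, so the full map holds 210 measures.
#'
#' @param heights Probe heights in metres.
#' @return A [grid_spec()].
#' @export
default_grid_spec <- function(heights = c(0.72, 1.19, 1.56)) {
  xs <- seq(0.2, 3.8, by = 0.4)                  # 10 columns, long step
  ys <- c(2.4, 2.8, 3.2, 3.6, 3.8, 4.0, 4.2)     # 7 rows, short steps near bore
  pp <- as.matrix(expand.grid(x = xs, y = ys))
  grid_spec(pp, heights)
}

#' Expand a grid specification into 3D measurement positions
#'
#' Cartesian product of the planar stations and the probe heights, in a
#' deterministic order: row-major over planar stations, with heights
#' ascending within each station.
#'
#' @param spec A [grid_spec()].
#' @return An (n_planar * n_heights) x 3 matrix of (x, y, z) positions, metres.
#' @export
generate_grid <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  np <- nrow(spec$planar_points)
  hs <- sort(spec$heights)
  nh <- length(hs)
  idx <- rep(seq_len(np), each = nh)
  cbind(spec$planar_points[idx, 1L],
        spec$planar_points[idx, 2L],
        rep(hs, times = np))
}

#' Predicted |B| over a set of positions
#'
#' Vectorised wrapper over [dipole_field()]: the field modulus at each
#' position, order preserved.
#'
#' @param model A [dipole_model()].
#' @param positions n x 3 matrix of positions, metres.
#' @return Numeric vector of |B| in tesla, one per row of `positions`.
#' @export
predict_map <- function(model, positions) {
  B <- dipole_field(positions, model)
  if (is.null(dim(B))) sqrt(sum(B^2)) else sqrt(rowSums(B^2))
}

#' Gridded stray-field map
#'
#' Container for |B| measurements on a 3D grid, as recorded by a Hall
#' magnetometer or produced by [make_field_map()].
#'
#' @param records Data frame with columns `x_m`, `y_m`, `z_m`, `B_T`.
#'   All `B_T` must be positive.
#' @param scanner_label Free-text scanner identifier (e.g. "Machine 3.0").
#' @return An object of class `field_map`.
#' @export
field_map <- function(records, scanner_label = "unlabelled") {
  records <- as.data.frame(records)
  need <- c("x_m", "y_m", "z_m", "B_T")
  if (!all(need %in% names(records)))
    stop("field map records need columns x_m, y_m, z_m, B_T")
  records <- records[, need]
  if (any(!is.finite(as.matrix(records)))) stop("field map contains non-finite values")
  if (any(records$B_T <= 0)) stop("measured |B| must be > 0 in every record")
  structure(list(records = records, scanner_label = scanner_label),
            class = "field_map")
}

#' @export
print.field_map <- function(x, ...) {
  cat(sprintf("Field map '%s': %d records, |B| in [%.3g, %.3g] T\n",
              x$scanner_label, nrow(x$records),
              min(x$records$B_T), max(x$records$B_T)))
  invisible(x)
}

#' Read / write field-map CSV files
#'
#' The on-disk dialect is a plain CSV with header `x_m,y_m,z_m,B_T`, one
#' measurement per row.
#'
#' @param path File path.
#' @param scanner_label Label attached to the map on read.
#' @return `read_field_map()` returns a [field_map()]; `write_field_map()`
#'   returns `path` invisibly.
#' @export
read_field_map <- function(path, scanner_label = basename(path)) {
  df <- utils::read.csv(path)
  field_map(df, scanner_label = scanner_label)
}

#' @rdname read_field_map
#' @param map A [field_map()] to serialise.
#' @export
write_field_map <- function(map, path) {
  stopifnot(inherits(map, "field_map"))
  utils::write.csv(map$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write grid layouts (YAML)
#'
#' Grid layouts are shipped and exchanged as plain-text YAML with keys
#' `planar_points` (list of `[x, y]` pairs, metres), `heights`,
#' `step_short_m`, `step_long_m`.
#'
#' @param path File path.
#' @return `read_grid_layout()` returns a [grid_spec()].
#' @export
read_grid_layout <- function(path) {
  y <- yaml::read_yaml(path)
  pp <- do.call(rbind, lapply(y$planar_points, as.numeric))
  grid_spec(pp, as.numeric(y$heights),
            step_short = y$step_short_m %||% 0.20,
            step_long  = y$step_long_m  %||% 0.40)
}

#' @rdname read_grid_layout
#' @param spec A [grid_spec()] to serialise.
#' @export
write_grid_layout <- function(spec, path) {
  stopifnot(inherits(spec, "grid_spec"))
  y <- list(planar_points = lapply(seq_len(nrow(spec$planar_points)),
                                   function(i) as.numeric(spec$planar_points[i, ])),
            heights = as.numeric(spec$heights),
            step_short_m = spec$step_short,
            step_long_m = spec$step_long)
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
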