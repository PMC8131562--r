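#' Labelled marker-trajectory recording
#'
#' A motion-capture trial: a set of labelled marker trajectories sampled at a
#' fixed rate (100 Hz for stereophotogrammetric acquisitions), positions in
#' metres in the room frame. Occluded frames may be `NA`; short gaps are
#' filled downstream by [fill_gaps()].
#'
#' @param markers Named list of T x 3 numeric matrices (columns x, y, z in
#'   metres), all with the same number of rows T >= 2; names are the marker
#'   labels and must be unique.
#' @param rate Sampling rate in Hz (> 0).
#' @param meta Optional list of trial metadata (operator id, task code,
#'   trial index, ...).
#' @return An object of class `recording`.
#' @export
recording <- function(markers, rate = 100, meta = list()) {
  if (!is.list(markers) || is.null(names(markers)) ||
      any(!nzchar(names(markers))))
    stop("markers must be a named list of T x 3 matrices")
  if (anyDuplicated(names(markers))) stop("marker labels must be unique")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a positive scalar (Hz)")
  markers <- lapply(markers, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 3L) stop("each marker series must have 3 columns (x, y, z)")
    storage.mode(m) <- "double"
    dimnames(m) <- list(NULL, c("x", "y", "z"))
    m
  })
  lens <- vapply(markers, nrow, 1L)
  if (length(unique(lens)) != 1L)
    stop(sprintf("inconsistent series lengths: %s", paste(unique(lens), collapse = ", ")))
  if (lens[1] < 2L) stop("a recording needs at least 2 frames")
  structure(list(rate = rate, markers = markers, meta = meta),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("Recording: %d markers x %d frames @ %g Hz\n",
              length(x$markers), n_frames(x), x$rate))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of frames in a recording
#' @param rec A [recording()].
#' @return Integer frame count.
#' @export
n_frames <- function(rec) nrow(rec$markers[[1]])

#' Read a marker recording from disk
#'
#' Supported formats: the package CSV dialect (`time_s` column plus
#' `<label>_x`, `<label>_y`, `<label>_z` columns in metres) and TRC
#' (tab-separated Track Row Column files, millimetres, converted to metres
#' on read). C3D is a binary vendor format and is not parsed here; export
#' recordings to TRC or CSV instead.
#'
#' @param path File path.
#' @param format One of `"csv"`, `"trc"`; by default inferred from the file
#'   extension.
#' @return A [recording()].
#' @export
read_recording <- function(path, format = c("auto", "csv", "trc")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", trc = "trc",
                     c3d = stop("C3D is not supported; export the trial to TRC or CSV"),
                     stop(sprintf("cannot infer recording format from extension '%s'", ext)))
  }
  switch(format, csv = read_recording_csv(path), trc = read_recording_trc(path))
}

read_recording_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df)) stop("recording CSV must have a time_s column")
  t <- df$time_s
  if (length(t) < 2L) stop("recording CSV has fewer than 2 frames")
  rate <- 1 / stats::median(diff(t))
  cols <- setdiff(names(df), "time_s")
  labs <- unique(sub("_[xyz]$", "", cols))
  markers <- lapply(labs, function(lb) {
    need <- paste0(lb, "_", c("x", "y", "z"))
    if (!all(need %in% names(df)))
      stop(sprintf("marker '%s' is missing one of its _x/_y/_z columns", lb))
    as.matrix(df[, need])
  })
  names(markers) <- labs
  recording(markers, rate = rate)
}

#' @rdname read_recording
#' @param rec A [recording()] to write.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  T <- n_frames(rec)
  out <- data.frame(time_s = (seq_len(T) - 1L) / rec$rate)
  for (lb in names(rec$markers)) {
    m <- rec$markers[[lb]]
    out[[paste0(lb, "_x")]] <- m[, 1]
    out[[paste0(lb, "_y")]] <- m[, 2]
    out[[paste0(lb, "_z")]] <- m[, 3]
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_recording_trc <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 6L) stop("TRC file too short")
  hdr <- strsplit(lines[3], "\t")[[1]]
  keys <- strsplit(lines[2], "\t")[[1]]
  rate <- as.numeric(hdr[match("DataRate", keys)])
  units <- hdr[match("Units", keys)]
  scale <- if (identical(units, "mm")) 1e-3 else 1
  labrow <- strsplit(lines[4], "\t")[[1]]
  labs <- labrow[labrow != ""][-(1:2)]        # drop Frame#, Time
  dat <- utils::read.table(text = lines[-(1:5)], sep = "\t", header = FALSE,
                           fill = TRUE)
  markers <- lapply(seq_along(labs), function(i) {
    scale * as.matrix(dat[, 2 + (3 * (i - 1) + 1):(3 * i)])
  })
  names(markers) <- labs
  recording(markers, rate = rate)
}

#' @rdname read_recording
#' @export
write_recording_trc <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  T <- n_frames(rec)
  labs <- names(rec$markers)
  nm <- length(labs)
  l1 <- sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path))
  l2 <- paste(c("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
                "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames"),
              collapse = "\t")
  l3 <- paste(c(rec$rate, rec$rate, T, nm, "mm", rec$rate, 1, T), collapse = "\t")
  l4 <- paste(c("Frame#", "Time",
                as.vector(rbind(labs, "", ""))), collapse = "\t")
  l5 <- paste(c("", "", paste0(rep(c("X", "Y", "Z"), nm),
                               rep(seq_len(nm), each = 3))), collapse = "\t")
  body <- cbind(seq_len(T), (seq_len(T) - 1L) / rec$rate,
                do.call(cbind, rec$markers) * 1000)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(l1, l2, l3, l4, l5), con)
  utils::write.table(body, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fill short occlusion gaps in a marker series
#'
#' Linear interpolation over runs of `NA` frames of length up to
#' `max_gap` frames; longer gaps raise an error, as would unflagged
#' occlusions at the boundaries.
#'
#' @param series T x 3 position matrix, possibly with `NA` runs.
#' @param max_gap Longest run of missing frames to bridge (default 10).
#' @return The gap-filled T x 3 matrix.
#' @export
fill_gaps <- function(series, max_gap = 10L) {
  series <- as.matrix(series)
  miss <- rowSums(is.na(series)) > 0
  if (!any(miss)) return(series)
  r <- rle(miss)
  if (miss[1] || miss[length(miss)])
    stop("cannot interpolate a gap at the start or end of a trial")
  if (max(r$lengths[r$values]) > max_gap)
    stop(sprintf("occlusion gap longer than %d frames", max_gap))
  idx <- seq_len(nrow(series))
  for (j in 1:3) {
    ok <- !is.na(series[, j])
    series[, j] <- stats::approx(idx[ok], series[ok, j], xout = idx)$y
  }
  series
}
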