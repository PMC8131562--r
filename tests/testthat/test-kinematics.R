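test_that("recording CSV round-trips bit-identically", {
  set.seed(1)
  rec <- recording(list(M1 = matrix(stats::rnorm(15), 5, 3),
                        M2 = matrix(stats::rnorm(15), 5, 3)), rate = 100)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(rec, p1)
  back <- read_recording(p1)
  expect_equal(back$rate, 100)
  expect_equal(back$markers, rec$markers, tolerance = 1e-12)
  write_recording_csv(back, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("TRC positions in millimetres are converted to metres", {
  lines <- c(
    "PathFileType\t4\t(X/Y/Z)\tfix.trc",
    paste("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
          "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames", sep = "\t"),
    paste(100, 100, 2, 2, "mm", 100, 1, 2, sep = "\t"),
    "Frame#\tTime\tM1\t\t\tM2\t\t",
    "\t\tX1\tY1\tZ1\tX2\tY2\tZ2",
    "1\t0\t1000\t2000\t500\t-250\t0\t1500",
    "2\t0.01\t1010\t2000\t500\t-250\t10\t1500")
  p <- withr::local_tempfile(fileext = ".trc")
  writeLines(lines, p)
  rec <- read_recording(p)
  expect_equal(rec$rate, 100)
  expect_equal(rec$markers$M1[1, ], c(x = 1, y = 2, z = 0.5))
  expect_equal(rec$markers$M2[2, ], c(x = -0.25, y = 0.01, z = 1.5))
})

test_that("TRC export and CSV export of a generated trial agree", {
  rec <- make_task_recording(operator_profiles()[2, ], task_scripts()$N1,
                             seed = 3)
  pt <- withr::local_tempfile(fileext = ".trc")
  pc <- withr::local_tempfile(fileext = ".csv")
  write_recording_trc(rec, pt)
  write_recording_csv(rec, pc)
  a <- read_recording(pt); b <- read_recording(pc)
  expect_equal(names(a$markers), names(b$markers))
  for (lb in names(a$markers))
    expect_equal(a$markers[[lb]], b$markers[[lb]], tolerance = 1e-6)
  expect_error(read_recording("trial.c3d"), "C3D")
})

test_that("format errors name the offending field", {
  p <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(time_s = 0:4 / 100, M1_x = 1:5, M1_y = 1:5),
                   p, row.names = FALSE)
  expect_error(read_recording(p), "M1")
  expect_error(recording(list(A = matrix(0, 5, 3), B = matrix(0, 4, 3))),
               "inconsistent")
})

test_that("smoothing is exact on constants, transparent at gait frequencies", {
  expect_equal(smooth_series(rep(2.5, 100), 100), rep(2.5, 100),
               tolerance = 1e-9)
  t <- seq(0, 20, by = 0.01)
  s <- sin(2 * pi * 1 * t)
  sm <- smooth_series(s, 100, cutoff = 6)
  expect_lt(abs(max(abs(sm)) - 1), 0.01)   # < 1% attenuation at 1 Hz
  # 30 Hz noise on a 1 Hz carrier: residual RMS reduced at least 5x
  noisy <- s + 0.2 * sin(2 * pi * 30 * t)
  sm2 <- smooth_series(noisy, 100)
  rms <- function(x) sqrt(mean(x^2))
  expect_gt(rms(noisy - s) / rms(sm2 - s), 5)
  expect_error(smooth_series(1:5, 100), "short")
})

test_that("smoothing then differentiating a band-limited signal tracks the analytic derivative", {
  t <- seq(0, 10, by = 0.01)
  x <- 0.1 * sin(2 * pi * 2.5 * t) + 0.05 * sin(2 * pi * 1.2 * t)
  vtrue <- 0.1 * 2 * pi * 2.5 * cos(2 * pi * 2.5 * t) +
    0.05 * 2 * pi * 1.2 * cos(2 * pi * 1.2 * t)
  v <- differentiate(smooth_series(x, 100), 100)
  keep <- 10:(length(t) - 10)
  rel <- sqrt(mean((v - vtrue)[keep]^2)) / sqrt(mean(vtrue[keep]^2))
  expect_lt(rel, 0.02)
})

test_that("differentiation matches finite-difference algebra", {
  # static series
  expect_equal(differentiate(rep(3, 10), 100), rep(0, 10))
  # uniform motion is exact at interior frames
  t <- (0:199) / 100
  v <- differentiate(0.5 * t, 100)
  expect_equal(v[2:199], rep(0.5, 198), tolerance = 1e-12)
  # sinusoid vs analytic derivative: interior truncation error of the
  # central difference is amplitude * omega * (1 - sinc(omega dt))
  p <- sin(2 * pi * t)
  vest <- differentiate(p, 100)
  van <- 2 * pi * cos(2 * pi * t)
  w <- 2 * pi
  bound <- w * (1 - sin(w * 0.01) / (w * 0.01))
  expect_lt(max(abs(vest - van)[2:199]), bound * 1.01)
  expect_error(differentiate(1:2, 100), "3 frames")
})

test_that("cluster centroids are per-frame means and behave linearly", {
  set.seed(8)
  T <- 20
  mk <- list(A = matrix(stats::rnorm(T * 3), T, 3),
             B = matrix(stats::rnorm(T * 3), T, 3),
             C = matrix(stats::rnorm(T * 3), T, 3),
             D = matrix(stats::rnorm(T * 3), T, 3))
  rec <- recording(mk, rate = 100)
  cen <- cluster_centroid(rec, c("A", "B", "C", "D"))
  loop <- matrix(0, T, 3)
  for (f in seq_len(T)) for (j in 1:3)
    loop[f, j] <- (mk$A[f, j] + mk$B[f, j] + mk$C[f, j] + mk$D[f, j]) / 4
  expect_equal(unname(cen), loop, tolerance = 1e-12)

  # coincident markers and the simple tetrahedron case
  rec2 <- recording(list(A = matrix(1, 5, 3), B = matrix(1, 5, 3),
                         C = matrix(1, 5, 3)), rate = 100)
  expect_equal(unname(cluster_centroid(rec2, c("A", "B", "C"))),
               matrix(1, 5, 3))
  tet <- recording(list(O = matrix(c(0, 0, 0), 2, 3, byrow = TRUE),
                        X = matrix(c(1, 0, 0), 2, 3, byrow = TRUE),
                        Y = matrix(c(0, 1, 0), 2, 3, byrow = TRUE),
                        Z = matrix(c(0, 0, 1), 2, 3, byrow = TRUE)),
                   rate = 100)
  expect_equal(unname(cluster_centroid(tet, c("O", "X", "Y", "Z"))[1, ]),
               c(0.25, 0.25, 0.25))

  # translation equivariance
  shift <- c(0.3, -1, 2)
  rec3 <- rec
  rec3$markers <- lapply(rec$markers, function(m) sweep(m, 2, -shift))
  expect_equal(cluster_centroid(rec3, names(mk)),
               sweep(cen, 2, -shift), tolerance = 1e-12)
  expect_error(cluster_centroid(rec, c("A", "B")), "3 markers")
})

test_that("gap filling bridges short occlusions only", {
  x <- cbind(1:20 / 10, 0, 1)
  x[8:10, 1] <- NA
  filled <- fill_gaps(x)
  expect_equal(filled[, 1], 1:20 / 10, tolerance = 1e-12)
  x[5:17, 2] <- NA
  expect_error(fill_gaps(x), "gap longer")
})

test_that("the default point set matches the assessment protocol", {
  ps <- default_exposure_points()
  expect_equal(nrow(ps$points), 23L)
  expect_equal(sum(ps$points$type == "centroid"), 11L)
  expect_equal(sum(ps$points$type == "marker"), 12L)
  expect_length(ps$head_subset, 5L)
  cm <- default_cluster_map()
  expect_true(all(lengths(cm$clusters) >= 3))
  expect_length(cm$calibration_only, 6L)
  expect_length(intersect(unlist(cm$clusters), cm$calibration_only), 0L)
})

test_that("exposure-point extraction reproduces rigid-body kinematics", {
  # static posture: all 23 speeds vanish
  prof <- operator_profiles()[1, ]
  static <- make_static_trial(prof, noise_sd = 0, duration = 2)
  kin0 <- extract_exposure_points(static)
  expect_equal(ncol(kin0$speed), 23L)
  expect_lt(max(kin0$speed), 1e-6)

  # rigid translation at 1 m/s: every point moves at 1 m/s
  kin1 <- extract_exposure_points(rigid_translation_recording(c(1, 0, 0)))
  expect_lt(max(abs(kin1$speed - 1)), 0.01)

  # unresolvable point is named
  broken <- static
  broken$markers <- broken$markers[setdiff(names(broken$markers), "RTEMP")]
  expect_error(extract_exposure_points(broken), "RTEMP")
})

test_that("speeds are invariant under room-frame rotation about z", {
  rec <- make_task_recording(operator_profiles()[2, ], task_scripts()$N1,
                             seed = 5)
  kin <- extract_exposure_points(rec)
  rec_rot <- rec
  rec_rot$markers <- lapply(rec$markers, rot_z, a = 0.7)
  kin_rot <- extract_exposure_points(rec_rot)
  expect_lt(max(abs(kin$speed - kin_rot$speed)), 1e-9)
})

test_that("centroid of a rigidly translated cluster is the translated centroid", {
  rec <- make_task_recording(operator_profiles()[1, ], task_scripts()$N4,
                             seed = 2)
  cen <- cluster_centroid(rec, default_cluster_map()$clusters$pelvis)
  shift <- c(1.5, -0.2, 0.05)
  rec2 <- rec
  rec2$markers <- lapply(rec$markers, function(m) sweep(m, 2, -shift))
  cen2 <- cluster_centroid(rec2, default_cluster_map()$clusters$pelvis)
  expect_equal(cen2, sweep(cen, 2, -shift), tolerance = 1e-12)
})
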