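test_that("dipole field matches the on-axis and equatorial closed forms", {
  m <- dipole_model()  # 1.06e6 A m^2, axis +y
  # on-axis: |B| = mu0 m / (2 pi r^3); equatorial: half that, antiparallel
  B_ax <- dipole_field(m$position + c(0, 1, 0), m)
  expect_equal(sqrt(sum(B_ax^2)), 2e-7 * 1.06e6, tolerance = 1e-12)
  expect_equal(B_ax / sqrt(sum(B_ax^2)), c(0, 1, 0), tolerance = 1e-12)

  B_eq <- dipole_field(m$position + c(1, 0, 0), m)
  expect_equal(sqrt(sum(B_eq^2)), 1e-7 * 1.06e6, tolerance = 1e-12)
  expect_equal(B_eq / sqrt(sum(B_eq^2)), c(0, -1, 0), tolerance = 1e-12)
})

test_that("|B| scales as r^-3 in any fixed direction", {
  m <- dipole_model()
  set.seed(42)
  for (i in 1:10) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    r <- stats::runif(1, 0.5, 3)
    B1 <- sqrt(sum(dipole_field(m$position + r * u, m)^2))
    B2 <- sqrt(sum(dipole_field(m$position + 2 * r * u, m)^2))
    expect_equal(B2, B1 / 8, tolerance = 1e-12)
  }
})

test_that("the dipole field is numerically divergence-free", {
  m <- dipole_model()
  h <- 1e-4
  set.seed(7)
  for (i in 1:50) {
    p <- m$position + stats::runif(3, -2, 2)
    if (sqrt(sum((p - m$position)^2)) < 0.3) p <- p + c(0.5, 0.5, 0.5)
    div <- 0; scale <- 0
    for (j in 1:3) {
      e <- numeric(3); e[j] <- h
      d <- (dipole_field(p + e, m)[j] - dipole_field(p - e, m)[j]) / (2 * h)
      div <- div + d
      scale <- max(scale, abs(d))
    }
    expect_lt(abs(div) / scale, 1e-6)
  }
})

test_that("|B| is mirror-symmetric about the plane holding position and axis", {
  m <- dipole_model()  # axis +y: mirror plane is x = x0
  set.seed(11)
  for (i in 1:20) {
    d <- stats::runif(3, -2, 2)
    pa <- m$position + d
    pb <- m$position + c(-d[1], d[2], d[3])
    expect_equal(sqrt(sum(dipole_field(pa, m)^2)),
                 sqrt(sum(dipole_field(pb, m)^2)), tolerance = 1e-12)
  }
})

test_that("field evaluation at the dipole position is a singularity error", {
  m <- dipole_model()
  expect_error(dipole_field(m$position, m), "singularity")
})

test_that("the reference grid yields 70 x 3 = 210 positions in fixed order", {
  spec <- default_grid_spec()
  expect_equal(nrow(spec$planar_points), 70L)
  g <- generate_grid(spec)
  expect_equal(nrow(g), 210L)
  # heights ascend within each planar station
  expect_equal(g[1:3, 3], sort(spec$heights))
  expect_equal(g[1:3, 1], rep(g[1, 1], 3))
})

test_that("grid size is the product of planar and height counts", {
  # brute-force enumeration oracle over small grids
  set.seed(3)
  for (rep in 1:5) {
    n <- sample(1:10, 1); k <- sample(1:10, 1)
    pp <- cbind(stats::runif(n), stats::runif(n))
    hs <- sort(stats::runif(k, 0.1, 2))
    g <- generate_grid(grid_spec(pp, hs))
    enumerated <- 0L
    for (i in seq_len(n)) for (j in seq_len(k)) enumerated <- enumerated + 1L
    expect_equal(nrow(g), enumerated)
  }
  expect_equal(nrow(generate_grid(grid_spec(cbind(0, 0), 1))), 1L)
  expect_error(grid_spec(cbind(numeric(0), numeric(0)), 1), "planar_points")
})

test_that("predict_map equals the per-point field modulus and preserves order", {
  m <- fitted_dipole()
  set.seed(5)
  pos <- cbind(stats::runif(210, 0, 4), stats::runif(210, 0, 4.3),
               stats::runif(210, 0.5, 1.6))
  pred <- predict_map(m, pos)
  loop <- vapply(seq_len(nrow(pos)),
                 function(i) sqrt(sum(dipole_field(pos[i, ], m)^2)),
                 numeric(1))
  expect_equal(pred, loop, tolerance = 1e-12)
  perm <- sample(nrow(pos))
  expect_identical(predict_map(m, pos[perm, ]), pred[perm])
  expect_length(predict_map(m, pos[1, , drop = FALSE]), 1L)
})

test_that("noiseless self-generated maps are refit exactly", {
  pre <- preliminary_dipole()
  spec <- default_grid_spec()
  # zero-offset truth
  fit0 <- fit_dipole(make_field_map(pre, spec, noise_rel = 0), pre)
  expect_lt(abs(fit0$delta_x), 1e-6)
  expect_lt(abs(fit0$delta_y), 1e-6)
  expect_equal(fit0$pearson_r, 1, tolerance = 1e-9)
  # published-offset truth
  truth <- fitted_dipole()
  fit <- fit_dipole(make_field_map(truth, spec, noise_rel = 0), pre)
  expect_lt(abs(fit$delta_x - 0.69), 1e-3)
  expect_lt(abs(fit$delta_y - 0.08), 1e-3)
  expect_equal(fit$pearson_r, 1, tolerance = 1e-9)
})

test_that("random planar offsets are recovered from noiseless maps", {
  pre <- preliminary_dipole()
  spec <- default_grid_spec()
  set.seed(21)
  for (i in 1:20) {
    off <- stats::runif(2, -1, 1)
    truth <- pre; truth$position <- pre$position + c(off, 0)
    fit <- fit_dipole(make_field_map(truth, spec, noise_rel = 0), pre)
    expect_lt(max(abs(c(fit$delta_x, fit$delta_y) - off)), 1e-6)
  }
})

test_that("moment refinement recovers the generating moment under 2% noise", {
  pre <- preliminary_dipole()
  truth <- fitted_dipole()
  for (seed in 1:5) {
    fm <- make_field_map(truth, noise_rel = 0.02, seed = seed)
    fit <- fit_dipole(fm, pre, refine_moment = TRUE)
    expect_lt(abs(fit$moment_estimate - 1.06e6) / 1.06e6, 0.05)
    expect_lt(abs(fit$delta_x - 0.69), 0.02)
    expect_lt(abs(fit$delta_y - 0.08), 0.02)
  }
})

test_that("degenerate geometry and bad maps are reported", {
  pre <- preliminary_dipole()
  # single planar station at several heights: collinear positions
  fm <- make_field_map(pre, grid_spec(cbind(1, 1), c(0.7, 1.2, 1.6)),
                       noise_rel = 0)
  expect_warning(fit_dipole(fm, pre), "collinear")
  expect_error(field_map(data.frame(x_m = 1, y_m = 1, z_m = 1, B_T = -2)),
               "> 0")
  expect_error(fit_dipole(make_field_map(pre, grid_spec(cbind(0:2, 0), 1),
                                         noise_rel = 0), pre),
               "heights")
})

test_that("pearson_correlation matches a two-pass textbook loop", {
  expect_equal(pearson_correlation(1:10, 1:10), 1)
  expect_equal(pearson_correlation(1:10, -(1:10)), -1)
  set.seed(9)
  for (i in 1:100) {
    n <- sample(3:50, 1)
    a <- stats::rnorm(n); b <- stats::rnorm(n)
    ma <- sum(a) / n; mb <- sum(b) / n
    num <- 0; va <- 0; vb <- 0
    for (k in seq_len(n)) {
      num <- num + (a[k] - ma) * (b[k] - mb)
      va <- va + (a[k] - ma)^2
      vb <- vb + (b[k] - mb)^2
    }
    expect_equal(pearson_correlation(a, b), num / sqrt(va * vb),
                 tolerance = 1e-12)
  }
  expect_error(pearson_correlation(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_correlation(1:3, 1:4), "equal length")
})

test_that("field maps and grid layouts round-trip through disk", {
  fm <- make_field_map(fitted_dipole(), noise_rel = 0.02, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_field_map(fm, path)
  back <- read_field_map(path)
  expect_equal(back$records, fm$records, tolerance = 1e-12)

  spec <- default_grid_spec()
  lp <- withr::local_tempfile(fileext = ".yaml")
  write_grid_layout(spec, lp)
  spec2 <- read_grid_layout(lp)
  expect_equal(spec2$planar_points, spec$planar_points, tolerance = 1e-9)
  expect_equal(spec2$heights, spec$heights)
})
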