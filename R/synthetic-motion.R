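#' Reference MRI room geometry for the task simulator
#'
#' A 4 x 6 m room, z up, origin at the field-map corner nearest Door A.
#' Doors A and B open on the near (y = 0) wall, Door C on the east wall;
#' the magnet isocenter sits near the far wall with the bore axis along +y
#' and the couch extending toward the room. The bore entrance lies 0.8 m
#' from the isocenter.
#'
#' @return A list with `width`, `depth` (m), `doors` (named list of (x, y)),
#'   `magnet_xy`, `magnet_height`, `bore_standoff`, `panel_xy` (control
#'   panel on the magnet housing) and `near_bore_xy` (couch end).
#' @export
room_geometry <- function() {
  list(width = 4, depth = 6,
       doors = list(A = c(0.7, 0.05), B = c(3.3, 0.05), C = c(3.95, 1.5)),
       magnet_xy = c(2.0, 5.0), magnet_height = 1.0, bore_standoff = 0.8,
       panel_xy = c(1.25, 4.2), near_bore_xy = c(2.0, 3.9))
}

#' Operator profiles
#'
#' The three reference operators: two radiographers of very different
#' stature and one cleaner. Heights and weights follow the study roster;
#' the per-profile head-speed cap reflects the observed regimes (the head of
#' the small radiographer never exceeds 2 m/s, the tall radiographer's may
#' occasionally, the cleaner's stays below 1 m/s).
#'
#' @return A data.frame with columns `id`, `job`, `height_m`, `weight_kg`,
#'   `max_head_speed`.
#' @export
operator_profiles <- function() {
  data.frame(
    id = c("MRIR1", "MRIR2", "MRIC"),
    job = c("radiographer", "radiographer", "cleaner"),
    height_m = c(1.89, 1.50, 1.72),
    weight_kg = c(115, 49, 61),
    max_head_speed = c(2.2, 2.0, 1.0),
    stringsAsFactors = FALSE
  )
}

#' Speed and standoff constraints for trajectory synthesis
#'
#' Caps enforced by the generator and re-verified through the kinematics
#' pipeline: feet up to 5 m/s, hands up to 3.5 m/s, head below 2 m/s by
#' default (profile overrides apply; 1 m/s for the cleaner), and a minimum
#' 0.7 m standoff of any body point from the dipole position.
#'
#' @param max_foot_speed,max_hand_speed,max_head_speed Caps in m/s.
#' @param min_standoff Minimum body-point distance from the dipole, m.
#' @return A list of class `motion_constraints`.
#' @export
motion_constraints <- function(max_foot_speed = 5, max_hand_speed = 3.5,
                               max_head_speed = 2, min_standoff = 0.7) {
  stopifnot(max_foot_speed > 0, max_hand_speed > 0, max_head_speed > 0,
            min_standoff > 0)
  structure(list(max_foot_speed = max_foot_speed,
                 max_hand_speed = max_hand_speed,
                 max_head_speed = max_head_speed,
                 min_standoff = min_standoff),
            class = "motion_constraints")
}

#' Shipped task scripts
#'
#' The twelve representative job motor tasks: six routine radiographer
#' tasks (N1-N6: entering/leaving by each door, head-coil preparation,
#' patient centering, object recovering), four emergency tasks (E1-E4:
#' emergency entering by each door and emergency patient extraction) and
#' two cleaner tasks (C1 floor sweeping, C2 floor mopping). Each script
#' lists the door used, pelvis waypoints in the room frame, a speed factor
#' on the walking envelope, and timed actions (bend, reach, couch
#' extraction, sweeping) at the near-magnet holds.
#'
#' @param room A [room_geometry()].
#' @return Named list of `task_script` objects with fields `code`, `door`,
#'   `jobs`, `speed_factor`, `segments` (walk/hold sequence) and `sweep`.
#' @export
task_scripts <- function(room = room_geometry()) {
  A <- room$doors$A; B <- room$doors$B; C <- room$doors$C
  P <- room$panel_xy; NB <- room$near_bore_xy
  walk <- walk_segment
  hold <- hold_segment
  script <- task_script
  out <- list(
    N1 = script("N1", "A", "radiographer", A,
                list(walk(c(1.2, 2.5)), walk(P), hold(1.5),
                     walk(c(1.2, 2.5)), walk(A))),
    N2 = script("N2", "B", "radiographer", B,
                list(walk(c(2.8, 2.2)), walk(c(1.6, 3.6)), walk(P), hold(1.5),
                     walk(c(1.6, 3.6)), walk(c(2.8, 2.2)), walk(B))),
    N3 = script("N3", "C", "radiographer", C,
                list(walk(c(3.0, 2.2)), walk(c(1.6, 3.5)), walk(P), hold(1.5),
                     walk(c(1.6, 3.5)), walk(c(3.0, 2.2)), walk(C))),
    N4 = script("N4", "A", "radiographer", A,
                list(walk(c(1.4, 2.5)), walk(NB), hold(2, "bend", 1.30),
                     walk(c(1.4, 2.5)), walk(A))),
    N5 = script("N5", "A", "radiographer", NB,
                list(hold(3, "bend", 1.20), walk(c(1.4, 2.5)), walk(A))),
    N6 = script("N6", "A", "radiographer", A,
                list(walk(c(1.4, 2.5)), walk(NB), hold(2.5, "bend", 0.90),
                     walk(c(1.4, 2.5)), walk(A))),
    E1 = script("E1", "A", "radiographer", A,
                list(walk(c(1.4, 2.6)), walk(NB), hold(1.5, "reach"),
                     walk(c(1.4, 2.6)), walk(A)), speed_factor = 1.15),
    E2 = script("E2", "B", "radiographer", B,
                list(walk(c(2.8, 2.2)), walk(c(2.2, 3.4)), walk(NB),
                     hold(1.5, "reach"), walk(c(2.2, 3.4)), walk(c(2.8, 2.2)),
                     walk(B)), speed_factor = 1.15),
    E3 = script("E3", "C", "radiographer", C,
                list(walk(c(3.0, 2.3)), walk(c(2.3, 3.4)), walk(NB),
                     hold(1.5, "reach"), walk(c(2.3, 3.4)), walk(c(3.0, 2.3)),
                     walk(C)), speed_factor = 1.15),
    E4 = script("E4", "A", "radiographer", A,
                list(walk(c(1.4, 2.6)), walk(NB), hold(1.5, "reach"),
                     hold(3, "extract"), walk(c(2.0, 3.0)), walk(c(1.4, 2.2)),
                     walk(A)), speed_factor = 1.15),
    C1 = script("C1", "A", "cleaner", A,
                list(walk(c(1.0, 1.2)), walk(c(1.0, 3.0)), walk(c(2.0, 3.6)),
                     walk(c(3.0, 3.0)), walk(c(3.0, 1.2)), walk(c(2.0, 1.0)),
                     walk(A)), speed_factor = 0.55, sweep = TRUE),
    C2 = script("C2", "A", "cleaner", A,
                list(walk(c(2.0, 1.0)), walk(c(3.0, 1.4)), walk(c(3.0, 3.2)),
                     walk(c(2.0, 3.7)), walk(c(1.0, 3.0)), walk(c(1.0, 1.2)),
                     walk(A)), speed_factor = 0.55, sweep = TRUE)
  )
  out
}

#' Build a custom task script
#'
#' Scripts are sequences of walk and hold segments starting at `start`
#' (typically a door). Use [walk_segment()] and [hold_segment()] to build
#' the sequence; [task_scripts()] returns the twelve shipped scripts.
#'
#' @param code Task code (e.g. "N1").
#' @param door Door used ("A", "B" or "C").
#' @param jobs Job the task belongs to ("radiographer" or "cleaner").
#' @param start Starting (x, y) position, metres.
#' @param segments List of walk/hold segments.
#' @param speed_factor Multiplier on the walking-speed envelope.
#' @param sweep Logical; hands manipulate a floor tool (sweeping/mopping).
#' @return An object of class `task_script`.
#' @export
task_script <- function(code, door, jobs, start, segments, speed_factor = 1,
                        sweep = FALSE) {
  stopifnot(is.list(segments), length(segments) >= 1L, speed_factor > 0)
  structure(list(code = code, door = door, jobs = jobs,
                 start = as.numeric(start), segments = segments,
                 speed_factor = speed_factor, sweep = sweep),
            class = "task_script")
}

#' @rdname task_script
#' @param to Target (x, y) waypoint of a walk segment.
#' @export
walk_segment <- function(to) list(type = "walk", to = as.numeric(to))

#' @rdname task_script
#' @param duration Hold duration in seconds.
#' @param action One of "none", "bend", "reach", "extract".
#' @param target For "bend": target head height in metres.
#' @export
hold_segment <- function(duration, action = "none", target = NA_real_) {
  stopifnot(duration > 0,
            action %in% c("none", "bend", "reach", "extract"))
  list(type = "hold", duration = duration, action = action, target = target)
}

# ---- full-body marker template -------------------------------------------

# Local body-frame marker offsets for a 1.72 m reference stature:
# x lateral (right +), y anterior, z up from the floor. Scaled linearly by
# stature. The last six labels are anatomical-calibration markers present
# only in the static trial.
marker_template <- function() {
  right <- rbind(
    RTEMP = c(0.08, 0.07, 1.62), ROCC = c(0.07, -0.08, 1.63),
    RSHO = c(0.20, 0.00, 1.42),
    RASI = c(0.12, 0.12, 0.95), RPSI = c(0.05, -0.13, 0.98),
    RELB = c(0.25, 0.00, 1.10),
    RHD1 = c(0.28, 0.06, 0.80), RHD2 = c(0.30, 0.02, 0.78),
    RHD3 = c(0.26, -0.01, 0.77),
    RTH1 = c(0.16, 0.06, 0.70), RTH2 = c(0.17, 0.00, 0.60),
    RTH3 = c(0.15, -0.05, 0.52),
    RTB1 = c(0.09, 0.04, 0.40), RTB2 = c(0.10, 0.00, 0.30),
    RTB3 = c(0.08, -0.04, 0.22),
    RHEE = c(0.09, -0.10, 0.04), RFMH = c(0.10, 0.13, 0.03),
    RVMH = c(0.14, 0.05, 0.03),
    RMMA = c(0.07, 0.00, 0.08), RMFE = c(0.08, 0.00, 0.50),
    RMHE = c(0.22, -0.02, 1.09)
  )
  left <- right
  left[, 1] <- -left[, 1]
  rownames(left) <- sub("^R", "L", rownames(right))
  mid <- rbind(
    T2 = c(0.00, -0.10, 1.45), MAI = c(0.00, -0.11, 1.30),
    SJN = c(0.00, 0.09, 1.40), SXS = c(0.00, 0.10, 1.22),
    SACR = c(0.00, -0.14, 0.97)
  )
  tpl <- rbind(right, left, mid)
  colnames(tpl) <- c("lx", "ly", "lz")
  tpl
}

# Longitudinal (along-heading) gait-oscillation gain per marker label:
# full swing for feet and hands, attenuated up the limb. Sign encodes the
# left/right antiphase.
osc_gain <- function(labels) {
  g <- setNames(numeric(length(labels)), labels)
  set <- function(labs, val) g[intersect(labs, labels)] <<- val
  set(c("RHEE", "RFMH", "RVMH"), 1); set(c("LHEE", "LFMH", "LVMH"), -1)
  set(c("RTB1", "RTB2", "RTB3"), 0.55); set(c("LTB1", "LTB2", "LTB3"), -0.55)
  set(c("RTH1", "RTH2", "RTH3"), 0.25); set(c("LTH1", "LTH2", "LTH3"), -0.25)
  g
}

arm_gain <- function(labels) {
  g <- setNames(numeric(length(labels)), labels)
  set <- function(labs, val) g[intersect(labs, labels)] <<- val
  # arms swing in antiphase with the ipsilateral foot
  set(c("RHD1", "RHD2", "RHD3"), -1); set(c("LHD1", "LHD2", "LHD3"), 1)
  set("RELB", -0.5); set("LELB", 0.5)
  g
}

# half-cosine ramp 0 -> 1 over `up` seconds, plateau, 1 -> 0 over `up`
# seconds, within a hold of `dur` seconds sampled at `rate`
ramp_profile <- function(dur, rate, up = 1) {
  n <- max(2L, round(dur * rate))
  t <- (seq_len(n) - 1) / rate
  up <- min(up, dur / 2)
  p <- numeric(n)
  p[t < up] <- 0.5 * (1 - cos(pi * t[t < up] / up))
  p[t >= up & t <= dur - up] <- 1
  dn <- t > dur - up
  p[dn] <- 0.5 * (1 - cos(pi * (dur - t[dn]) / up))
  p
}

# moving-average smoother with endpoint padding (zero phase)
moving_avg <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w %% 2L == 0L) w <- w + 1L
  if (w == 1L || length(x) < 3L) return(x)
  half <- (w - 1L) %/% 2L
  xx <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xx, rep(1 / w, w), sides = 2))[(half + 1L):(half + length(x))]
}

# ---- pelvis path synthesis ------------------------------------------------

# Resample a waypoint polyline at `ds` arclength, round its corners by a
# moving average, and return x, y, cumulative arclength, tangent angle and
# curvature.
dense_path <- function(waypoints, ds = 0.01, round_m = 0.25) {
  wp <- as.matrix(waypoints)
  if (nrow(wp) < 2L) stop("a walk leg needs at least 2 waypoints")
  segs <- diff(wp)
  len <- sqrt(rowSums(segs^2))
  if (any(len < 1e-9)) stop("degenerate (zero-length) path segment")
  s_wp <- c(0, cumsum(len))
  s <- seq(0, s_wp[length(s_wp)], by = ds)
  x <- stats::approx(s_wp, wp[, 1], xout = s)$y
  y <- stats::approx(s_wp, wp[, 2], xout = s)$y
  w <- round(round_m / ds)
  x <- moving_avg(x, w); y <- moving_avg(y, w)
  dx <- differentiate(x, 1 / ds); dy <- differentiate(y, 1 / ds)
  ddx <- differentiate(dx, 1 / ds); ddy <- differentiate(dy, 1 / ds)
  sp <- pmax(sqrt(dx^2 + dy^2), 1e-9)
  kappa <- abs(dx * ddy - dy * ddx) / sp^3
  s_true <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  list(x = x, y = y, s = s_true, theta = atan2(dy, dx), kappa = kappa)
}

# Walking-speed envelope along a path: fast far from the magnet, slowing to
# v_near close to it, additionally limited by curvature (comfortable lateral
# acceleration 1.5 m/s^2) so turns are taken slowly.
leg_speed <- function(path, magnet_xy, v_far, v_near) {
  d <- sqrt((path$x - magnet_xy[1])^2 + (path$y - magnet_xy[2])^2)
  env <- v_near + (v_far - v_near) * pmin(pmax((d - 1.2) / 1.8, 0), 1)
  v_curv <- pmax(sqrt(1.5 / pmax(path$kappa, 1e-6)), 0.6)
  v <- pmin(env, v_curv)
  moving_avg(v, round(0.4 / max(diff(path$s))))
}

# Sample one walk leg at the capture rate. Returns per-frame root x, y,
# tangent angle and pelvis speed.
sample_leg <- function(waypoints, magnet_xy, v_far, v_near, rate) {
  path <- dense_path(waypoints)
  v <- leg_speed(path, magnet_xy, v_far, v_near)
  t_dense <- c(0, cumsum(diff(path$s) / ((v[-1] + v[-length(v)]) / 2)))
  tt <- seq(0, max(t_dense), by = 1 / rate)
  s_t <- stats::approx(t_dense, path$s, xout = tt)$y
  th <- unwrap_angle(path$theta)
  list(x = stats::approx(path$s, path$x, xout = s_t)$y,
       y = stats::approx(path$s, path$y, xout = s_t)$y,
       theta = stats::approx(path$s, th, xout = s_t)$y,
       v = stats::approx(path$s, v, xout = s_t)$y)
}

unwrap_angle <- function(th) {
  d <- diff(th)
  d <- d - 2 * pi * round(d / (2 * pi))
  th[1] + c(0, cumsum(d))
}

# ---- the task recording generator ----------------------------------------

#' Simulate a full-body marker recording of an operator task
#'
#' Synthesises a 100 Hz stereophotogrammetric trial of the 41 dynamic
#' markers of the full-body protocol (the 6 anatomical-calibration markers
#' appear only in the companion static trial). The pelvis follows the
#' script's waypoints with a walking-speed envelope that is high at the
#' doors and minimal near the magnet (the U-shaped profile), and slows
#' further in turns; limbs oscillate about the pelvis with gait-like phase
#' and amplitudes tied to the walking speed, capped so that foot, hand and
#' head speeds respect the stated constraints even after smoothing and
#' differentiation; anthropometry scales all segment offsets from the
#' operator's stature; every marker coordinate carries seeded Gaussian
#' noise (SD 2 mm).
#'
#' @param profile One row of [operator_profiles()] (or a compatible list
#'   with `id`, `job`, `height_m`, `max_head_speed`).
#' @param script A `task_script` from [task_scripts()].
#' @param constraints A [motion_constraints()].
#' @param seed Integer seed for the marker noise (and any stochastic
#'   amplitude jitter).
#' @param room A [room_geometry()].
#' @param rate Sampling rate, Hz.
#' @param noise_sd Marker noise SD in metres (default 0.002).
#' @return A [recording()] with `meta` fields `operator`, `task`, `seed`.
#' @export
make_task_recording <- function(profile, script,
                                constraints = motion_constraints(),
                                seed = NULL, room = room_geometry(),
                                rate = 100, noise_sd = 0.002) {
  stopifnot(inherits(script, "task_script"),
            inherits(constraints, "motion_constraints"))
  profile <- as.list(profile)
  stature <- profile$height_m / 1.72
  head_cap <- min(profile$max_head_speed %||% constraints$max_head_speed,
                  if (identical(profile$job, "cleaner"))
                    constraints$max_head_speed else Inf)
  validate_script(script, room, constraints)

  # walking envelope: base brisk walk scaled by stature and script pace,
  # limited so that head speed (~= pelvis speed + bob) stays under its cap
  v_far <- min(1.8 * stature * script$speed_factor, head_cap / 1.2)
  v_near <- min(0.35, v_far)
  if (v_near > v_far) stop("infeasible speed envelope: v_near > v_far")

  # assemble the frame-wise timeline: consecutive walk segments form one
  # polyline leg (so corners are rounded and taken slowly), holds freeze the
  # pelvis at the last waypoint, facing the magnet
  pos <- script$start
  xs <- ys <- ths <- vs <- numeric(0)
  bend <- reach <- extract <- numeric(0)
  bend_target <- numeric(0)
  pending <- list()                       # accumulated walk waypoints
  flush_walk <- function() {
    if (!length(pending)) return(invisible())
    wp <- rbind(pos, do.call(rbind, pending))
    leg <- sample_leg(wp, room$magnet_xy, v_far, v_near, rate)
    n <- length(leg$x)
    xs <<- c(xs, leg$x); ys <<- c(ys, leg$y); ths <<- c(ths, leg$theta)
    vs <<- c(vs, leg$v)
    bend <<- c(bend, numeric(n)); reach <<- c(reach, numeric(n))
    extract <<- c(extract, numeric(n))
    bend_target <<- c(bend_target, rep(NA_real_, n))
    pos <<- pending[[length(pending)]]
    pending <<- list()
    invisible()
  }
  for (seg in script$segments) {
    if (seg$type == "walk") {
      pending[[length(pending) + 1L]] <- seg$to
    } else {
      flush_walk()
      n <- max(2L, round(seg$duration * rate))
      th_face <- atan2(room$magnet_xy[2] - pos[2], room$magnet_xy[1] - pos[1])
      xs <- c(xs, rep(pos[1], n)); ys <- c(ys, rep(pos[2], n))
      ths <- c(ths, rep(th_face, n)); vs <- c(vs, numeric(n))
      prof <- ramp_profile(seg$duration, rate)
      bend <- c(bend, if (seg$action == "bend") prof else numeric(n))
      reach <- c(reach, if (seg$action == "reach") prof else numeric(n))
      extract <- c(extract, if (seg$action == "extract") prof else numeric(n))
      bend_target <- c(bend_target,
                       rep(if (seg$action == "bend") seg$target else NA_real_, n))
    }
  }
  flush_walk()
  N <- length(xs)
  tt <- (seq_len(N) - 1) / rate

  # smooth heading and the amplitude-shaping speed so that hold boundaries
  # do not create position discontinuities
  ths <- moving_avg(unwrap_angle(ths), round(0.6 * rate))
  v_amp <- moving_avg(vs, round(0.5 * rate))

  # gait phase and speed-tied oscillation amplitudes, capped to the speed
  # constraints (with a small reserve for smoothing overshoot and noise)
  f_stride <- pmin(0.9 * v_amp + 0.6, 2.2)
  phi <- 2 * pi * cumsum(f_stride * (v_amp > 0.05)) / rate
  omega <- 2 * pi * f_stride
  A_f <- pmin(1.6 * v_amp, 0.95 * constraints$max_foot_speed - v_amp) / omega
  A_f <- pmax(A_f, 0)
  A_h <- pmin(0.8 * v_amp, 0.93 * constraints$max_hand_speed - v_amp) / omega
  A_h <- pmax(A_h, 0)
  if (script$sweep) A_h <- A_h * 0
  A_b <- 0.004 * v_amp                       # vertical pelvis/trunk bob

  tpl <- marker_template() * stature
  cal <- c("RMMA", "LMMA", "RMFE", "LMFE", "RMHE", "LMHE")
  dyn <- setdiff(rownames(tpl), cal)
  gaits <- osc_gain(dyn)
  arms <- arm_gain(dyn)
  z_pelvis <- 0.97 * stature
  z_head <- 1.62 * stature

  u_x <- cos(ths); u_y <- sin(ths)           # anterior unit vector
  l_x <- sin(ths); l_y <- -cos(ths)          # lateral-right unit vector
  long_gait <- sin(phi)
  bob_z <- A_b * sin(2 * phi)
  lift_z <- 0.15 * A_f * (1 + sin(phi))
  sweep_lat <- if (script$sweep) 0.30 * sin(2 * pi * 0.7 * tt) else numeric(N)
  extract_long <- 0.22 * extract * sin(2 * pi * 0.6 * tt)

  markers <- vector("list", length(dyn))
  names(markers) <- dyn
  for (lb in dyn) {
    lx <- tpl[lb, "lx"]; ly <- tpl[lb, "ly"]; lz <- tpl[lb, "lz"]
    long <- A_f * gaits[lb] * long_gait + A_h * arms[lb] * long_gait
    is_hand <- lb %in% c("RHD1", "RHD2", "RHD3", "LHD1", "LHD2", "LHD3")
    is_arm <- is_hand || lb %in% c("RELB", "LELB")
    if (is_arm) long <- long + (if (is_hand) 0.25 else 0.12) * reach +
        (if (is_hand) 1 else 0.5) * extract_long
    lat <- if (is_hand && script$sweep) sweep_lat else numeric(N)
    z <- rep(lz, N)
    if (lz > 0.45) z <- z + bob_z
    if (gaits[lb] != 0 && lz < 0.45)
      z <- z + lift_z * abs(gaits[lb])
    if (is_hand && script$sweep) z <- z - 0.22 * stature
    # bend: markers above the pelvis descend in proportion to their height,
    # the head reaching the scripted target height, with a forward lean
    frac <- max(0, (lz - z_pelvis) / (z_head - z_pelvis))
    if (frac > 0) {
      depth <- ifelse(is.na(bend_target), 0, pmax(0, z_head - bend_target))
      z <- z - bend * depth * frac
      fw <- bend * 0.25 * frac
      long <- long + fw
    }
    markers[[lb]] <- cbind(xs + u_x * (ly + long) + l_x * (lx + lat),
                           ys + u_y * (ly + long) + l_y * (lx + lat),
                           z)
  }
  markers <- with_seed(seed, lapply(markers, function(m)
    m + matrix(stats::rnorm(length(m), 0, noise_sd), nrow(m), 3L)))
  recording(markers, rate = rate,
            meta = list(operator = profile$id, task = script$code,
                        seed = if (is.null(seed)) NA else seed))
}

validate_script <- function(script, room, constraints) {
  pts <- rbind(script$start,
               do.call(rbind, lapply(Filter(function(s) s$type == "walk",
                                            script$segments),
                                     function(s) s$to)))
  if (any(pts[, 1] < 0 | pts[, 1] > room$width |
          pts[, 2] < 0 | pts[, 2] > room$depth))
    stop(sprintf("task %s: waypoint outside the room bounds", script$code))
  d <- sqrt((pts[, 1] - room$magnet_xy[1])^2 + (pts[, 2] - room$magnet_xy[2])^2)
  # waypoints are pelvis targets; leave reach allowance for the arms
  if (any(d < constraints$min_standoff + 0.35))
    stop(sprintf("task %s: waypoint violates the %.2f m standoff",
                 script$code, constraints$min_standoff))
  invisible(TRUE)
}

#' Simulate the static calibration trial
#'
#' A 1 s double-leg-stance acquisition of all 47 markers (including the six
#' anatomical-calibration markers later removed for the dynamic trials),
#' with only seeded measurement noise as motion.
#'
#' @inheritParams make_task_recording
#' @param duration Trial length in seconds.
#' @param stand_xy Standing position in the room frame.
#' @return A [recording()] with all 47 labels.
#' @export
make_static_trial <- function(profile, seed = NULL, rate = 100,
                              duration = 1, noise_sd = 0.002,
                              stand_xy = c(1.0, 1.0)) {
  profile <- as.list(profile)
  stature <- profile$height_m / 1.72
  tpl <- marker_template() * stature
  N <- max(2L, round(duration * rate))
  markers <- lapply(rownames(tpl), function(lb)
    matrix(c(stand_xy[1] + tpl[lb, "lx"], stand_xy[2] + tpl[lb, "ly"],
             tpl[lb, "lz"]), N, 3L, byrow = TRUE))
  names(markers) <- rownames(tpl)
  markers <- with_seed(seed, lapply(markers, function(m)
    m + matrix(stats::rnorm(length(m), 0, noise_sd), N, 3L)))
  recording(markers, rate = rate,
            meta = list(operator = profile$id, task = "static",
                        seed = if (is.null(seed)) NA else seed))
}
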