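# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures are stored.

# the preliminary 3.0 T dipole (nominal magnet position, h = 1.00 m)
preliminary_dipole <- function() dipole_model()

# the conformed 3.0 T dipole at the published planar offsets
fitted_dipole <- function()
  dipole_model(position = c(2.0 + 0.69, 5.0 + 0.08, 1.0))

# a noise-free recording in which the whole static posture translates
# rigidly at constant velocity (m/s)
rigid_translation_recording <- function(velocity = c(1, 0, 0),
                                        duration = 2, rate = 100) {
  prof <- operator_profiles()[1, ]
  rec <- make_static_trial(prof, rate = rate, duration = duration,
                           noise_sd = 0)
  T <- n_frames(rec)
  shift <- outer((seq_len(T) - 1) / rate, as.numeric(velocity))
  rec$markers <- lapply(rec$markers, function(m) m + shift)
  rec
}

# a "stand still" single-waypoint script: one hold, no walking
stand_still_script <- function(duration = 2)
  task_script("S0", "A", "radiographer", c(1.5, 1.5),
              list(hold_segment(duration)))

# hand-rolled point_kinematics for toy exposure tests: a list of T x 3
# position matrices, velocities by the same central differences the
# pipeline uses
toy_kinematics <- function(positions, rate = 100, head_subset = 1L) {
  velocity <- lapply(positions, differentiate, rate = rate)
  speed <- vapply(velocity, function(v) sqrt(rowSums(v^2)),
                  numeric(nrow(positions[[1]])))
  if (is.null(dim(speed))) speed <- matrix(speed, nrow = 1L)
  structure(list(rate = rate, position = positions, velocity = velocity,
                 speed = speed,
                 point_set = structure(list(points = NULL,
                                            head_subset = head_subset),
                                       class = "exposure_point_set"),
                 meta = list()),
            class = "point_kinematics")
}

# rotate an n x 3 matrix about the z axis by angle a
rot_z <- function(m, a) {
  R <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  m %*% t(R)
}

point_speeds <- function(kin, refs) {
  idx <- match(refs, kin$point_set$points$ref)
  kin$speed[, idx, drop = FALSE]
}

foot_refs <- c("foot_r", "foot_l")
head_refs <- c("head", "RTEMP", "LTEMP", "ROCC", "LOCC")
hand_refs <- c("hand_r", "hand_l")
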