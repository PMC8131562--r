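# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched. seed = NULL runs unseeded.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

#' Simulate a gridded stray-field survey
#'
#' Emulates a Hall-magnetometer mapping session: |B| of a known dipole at
#' every grid position, perturbed by multiplicative Gaussian noise
#' (Hall-probe error scales with the reading). The noise factor is clipped
#' below at 0.05 so that simulated readings stay positive.
#'
#' @param model The generating [dipole_model()].
#' @param spec A [grid_spec()]; defaults to the reference 70 x 3 grid.
#' @param noise_rel Relative noise standard deviation (default 0.02).
#' @param seed Integer seed; the same seed reproduces the same map.
#' @param scanner_label Label stored in the map.
#' @return A [field_map()] with one record per grid position.
#' @export
make_field_map <- function(model, spec = default_grid_spec(),
                           noise_rel = 0.02, seed = NULL,
                           scanner_label = "synthetic") {
  stopifnot(inherits(model, "dipole_model"), inherits(spec, "grid_spec"),
            noise_rel >= 0)
  pos <- generate_grid(spec)
  Bmod <- predict_map(model, pos)
  fac <- with_seed(seed, pmax(1 + stats::rnorm(length(Bmod), 0, noise_rel), 0.05))
  field_map(data.frame(x_m = pos[, 1], y_m = pos[, 2], z_m = pos[, 3],
                       B_T = Bmod * fac),
            scanner_label = scanner_label)
}
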