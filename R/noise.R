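#' Measurement and mechanical noise model
#'
#' Two noise sources perturb the closed loop: plate-reader measurement noise
#' on OD and fluorescence, and mechanical (pipetted-volume) noise on the
#' executed exchange volume. Measurement noise is multiplicative lognormal
#' with median equal to the true value and coefficient of variation `od_cv`
#' (strictly positive reads, median-preserving). Mechanical noise is a
#' multiplicative normal factor with mean 1 and CV `vol_cv`, truncated at
#' zero (a pipette cannot move negative volume). Setting both CVs to zero
#' reduces the simulator to the deterministic closed loop exactly; identical
#' seed and configuration give bit-identical time series.
#'
#' @param od_cv Measurement coefficient of variation (>= 0).
#' @param vol_cv Pipetted-volume coefficient of variation (>= 0).
#' @param seed Integer random seed for the run.
#' @return An object of class `noise_model`.
#' @examples
#' noise_model(od_cv = 0.05, vol_cv = 0.02, seed = 1)
#' noise_model(0, 0)  # deterministic loop
#' @export
noise_model <- function(od_cv = 0.05, vol_cv = 0.02, seed = 1L) {
  if (od_cv < 0) abort("od_cv must be >= 0")
  if (vol_cv < 0) abort("vol_cv must be >= 0")
  structure(list(od_cv = od_cv, vol_cv = vol_cv, seed = as.integer(seed)),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat("<noise_model> od_cv =", x$od_cv, " vol_cv =", x$vol_cv,
      " seed =", x$seed, "\n")
  invisible(x)
}

#' Apply measurement noise to a true OD
#'
#' Multiplicative lognormal perturbation with median `od_true` and
#' coefficient of variation `noise$od_cv`; a true OD of 0 maps to 0. Draws
#' come from the session RNG ([run_turbidostat()] seeds it from
#' `noise$seed`), so the same seed yields the same sequence.
#'
#' @param od_true True OD600 values (>= 0), vectorized.
#' @param noise A [noise_model()].
#' @return Perturbed measurements, same length as `od_true`.
#' @export
apply_measurement_noise <- function(od_true, noise) {
  stopifnot(inherits(noise, "noise_model"))
  if (any(od_true < 0)) abort("od_true must be >= 0")
  if (noise$od_cv == 0) return(od_true)
  sdlog <- sqrt(log(1 + noise$od_cv^2))
  od_true * exp(rnorm(length(od_true), 0, sdlog))
}

#' Apply mechanical noise to a commanded volume
#'
#' Multiplies each commanded volume by a normal factor (mean 1, CV
#' `noise$vol_cv`) truncated at zero.
#'
#' @param vol_ul Commanded volumes in microlitres (>= 0), vectorized.
#' @param noise A [noise_model()].
#' @return Executed volumes (>= 0).
#' @export
apply_volume_noise <- function(vol_ul, noise) {
  stopifnot(inherits(noise, "noise_model"))
  if (any(vol_ul < 0)) abort("vol_ul must be >= 0")
  if (noise$vol_cv == 0) return(vol_ul)
  vol_ul * pmax(0, rnorm(length(vol_ul), 1, noise$vol_cv))
}
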