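#' Exponential growth between service cycles
#'
#' Culture density evolves as x = x0 * exp(k * t) between liquid-handling
#' cycles; the closed form is used directly, no integration. An OD of 0 is
#' absorbing. Vectorized over all arguments.
#'
#' @param od0 Starting OD600 (>= 0).
#' @param k Exponential growth constant, 1/hour.
#' @param dt Elapsed time in hours (>= 0).
#' @return OD600 after `dt` hours.
#' @examples
#' grow(0.2, log(2), 1)   # one doubling
#' @seealso [dilute()]
#' @export
grow <- function(od0, k, dt) {
  if (any(od0 < 0)) abort("od0 must be >= 0")
  if (any(dt < 0)) abort("dt must be >= 0")
  od0 * exp(k * dt)
}

#' Instantaneous dilution with fresh media
#'
#' A media replacement exchanging fraction `y` of the working volume mixes
#' the culture instantly and uniformly with transparent media, scaling the
#' OD to x / (1 + y). Physically the exchange is volume-neutral: a volume
#' `V * y / (1 + y)` of mixed culture is removed and replaced with the same
#' volume of fresh media, which gives the identical OD update while keeping
#' the working volume constant.
#'
#' @param od OD600 before dilution (>= 0).
#' @param y Replacement fraction (>= 0), media added as a fraction of the
#'   working volume in the mixing picture.
#' @return OD600 after dilution, `od / (1 + y)`.
#' @examples
#' dilute(0.3, 0.5)  # 100 uL culture at OD 0.3 + 50 uL media -> OD 0.2
#' @export
dilute <- function(od, y) {
  if (any(od < 0)) abort("od must be >= 0")
  if (any(y < 0)) abort("y must be >= 0")
  od / (1 + y)
}

#' Absolute exchanged volume for a replacement fraction
#'
#' Converts a controller command `y` (fraction of working volume) into the
#' absolute volume removed and replaced under the constant-volume exchange
#' convention: `V * y / (1 + y)` microlitres.
#'
#' @param y Replacement fraction (>= 0).
#' @param volume_ul Working volume (uL).
#' @return Exchanged volume in microlitres.
#' @export
exchange_volume <- function(y, volume_ul) {
  if (any(y < 0)) abort("y must be >= 0")
  volume_ul * y / (1 + y)
}

#' Replacement fraction realized by an absolute exchanged volume
#'
#' Inverse of [exchange_volume()]: the effective `y` when `vol_ul` of mixed
#' culture was actually removed and replaced (used to apply mechanical
#' pipetting noise to the dilution actually executed).
#'
#' @param vol_ul Exchanged volume (uL), must be < `volume_ul`.
#' @param volume_ul Working volume (uL).
#' @return Effective replacement fraction.
#' @export
effective_fraction <- function(vol_ul, volume_ul) {
  if (any(vol_ul < 0)) abort("vol_ul must be >= 0")
  if (any(vol_ul >= volume_ul)) abort("exchanged volume must be below the working volume")
  vol_ul / (volume_ul - vol_ul)
}
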