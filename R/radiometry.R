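#' Convert thermal digital numbers to TOA spectral radiance
#'
#' `toa_radiance_oli()` applies the OLI/TIRS linear rescaling
#' `L = ML * Qcal + (AL - Oi)`. `toa_radiance_tm()` applies the TM two-point
#' rescaling `L = gain * (Qcal - QcalMin) + LMin` with
#' `gain = (LMax - LMin) / (QcalMax - QcalMin)`, so that `Qcal = QcalMin`
#' maps to `LMin` and `Qcal = QcalMax` to `LMax`. DNs outside the calibrated
#' range are clamped to it, with the number of clamped cells reported in a
#' warning and in the `n_clamped` attribute.
#'
#' @param qcal [band_grid] of quantized calibrated pixel values (DN).
#' @param meta [scene_meta] for the matching sensor.
#' @param literal_eq2 If `TRUE`, `toa_radiance_tm()` evaluates
#'   `gain * ((Qcal - QcalMin) + LMin)` instead — an alternative
#'   parenthesization some sources print, kept for comparison; it does not
#'   satisfy the endpoint identities.
#'
#' @return [band_grid] of spectral radiance (W m-2 sr-1 um-1); nodata
#'   propagated.
#' @examples
#' m <- default_scene_meta("TM")
#' g <- band_grid(matrix(c(1, 128, 255, NA), 2, 2))
#' as.matrix(toa_radiance_tm(g, m))
#' @export
toa_radiance_oli <- function(qcal, meta) {
  stopifnot(is_band_grid(qcal), inherits(meta, "scene_meta"))
  if (meta$sensor != "OLI_TIRS")
    stop("toa_radiance_oli() requires OLI_TIRS metadata, got sensor=",
         meta$sensor, call. = FALSE)
  cl <- clamp_dn(qcal$values, meta)
  out <- grid_like(qcal, meta$ml * cl$v + (meta$al - meta$oi),
                   band_id = "radiance")
  attr(out, "n_clamped") <- cl$n
  out
}

#' @rdname toa_radiance_oli
#' @export
toa_radiance_tm <- function(qcal, meta, literal_eq2 = FALSE) {
  stopifnot(is_band_grid(qcal), inherits(meta, "scene_meta"))
  if (meta$sensor != "TM")
    stop("toa_radiance_tm() requires TM metadata, got sensor=", meta$sensor,
         call. = FALSE)
  if (meta$qcal_max == meta$qcal_min)
    stop("QcalMax equals QcalMin; gain undefined", call. = FALSE)
  gain <- (meta$lmax - meta$lmin) / (meta$qcal_max - meta$qcal_min)
  cl <- clamp_dn(qcal$values, meta)
  lam <- if (literal_eq2) gain * ((cl$v - meta$qcal_min) + meta$lmin)
         else gain * (cl$v - meta$qcal_min) + meta$lmin
  out <- grid_like(qcal, lam, band_id = "radiance")
  attr(out, "n_clamped") <- cl$n
  out
}

# internal: clamp DNs to the calibrated range when the range is known
clamp_dn <- function(v, meta) {
  n <- 0L
  if (!is.na(meta$qcal_min) && !is.na(meta$qcal_max)) {
    bad <- !is.na(v) & (v < meta$qcal_min | v > meta$qcal_max)
    n <- sum(bad)
    if (n > 0L) {
      v[v < meta$qcal_min & !is.na(v)] <- meta$qcal_min
      v[v > meta$qcal_max & !is.na(v)] <- meta$qcal_max
      warning(n, " DN(s) outside [QcalMin, QcalMax] clamped", call. = FALSE)
    }
  }
  list(v = v, n = n)
}

#' TOA brightness temperature from spectral radiance
#'
#' Inverts the Planck relation with the sensor's thermal constants and
#' converts to Celsius: `BT = K2 / ln(K1 / L + 1) - 273.15`. Cells where the
#' log argument is not positive (non-physical radiance) become nodata; their
#' count is reported in a warning and in the `n_invalid` attribute.
#'
#' @param radiance [band_grid] of TOA spectral radiance (W m-2 sr-1 um-1).
#' @param meta [scene_meta] supplying `k1` and `k2`.
#'
#' @return [band_grid] of brightness temperature in degrees Celsius.
#' @examples
#' m <- default_scene_meta("TM")
#' bt <- brightness_temperature(band_grid(matrix(10)), m)
#' as.matrix(bt)  # ~32.55 C
#' @export
brightness_temperature <- function(radiance, meta) {
  stopifnot(is_band_grid(radiance), inherits(meta, "scene_meta"))
  v <- radiance$values
  arg <- meta$k1 / v + 1
  bad <- !is.na(v) & (!is.finite(arg) | arg <= 0 | arg == 1)
  n_bad <- sum(bad)
  if (n_bad > 0L) {
    warning(n_bad, " cell(s) with non-positive Planck log argument set to ",
            "nodata", call. = FALSE)
    arg[bad] <- NA_real_
  }
  bt <- meta$k2 / log(arg) - 273.15
  out <- grid_like(radiance, bt, band_id = "BT_C")
  attr(out, "n_invalid") <- n_bad
  out
}
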