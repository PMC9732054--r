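#' Normalized difference vegetation index
#'
#' `NDVI = (NIR - RED) / (NIR + RED)` computed cell-wise. Values lie in
#' \[-1, 1\] for non-negative band values; dense healthy vegetation typically
#' falls in 0.1-0.75, rock and bare soil near zero, and water is negative.
#' Cells where `NIR + RED = 0` (no signal) become nodata.
#'
#' By convention the bands are raw digital numbers, matching the rest of the
#' DN-based chain; reflectance grids are accepted unchanged since the index
#' is scale-invariant per band pair.
#'
#' @param red,nir [band_grid]s of the red and near-infrared bands (same
#'   shape).
#'
#' @return [band_grid] of NDVI values.
#' @examples
#' r <- band_grid(matrix(c(0.3, 1), 1, 2))
#' n <- band_grid(matrix(c(0.5, 1), 1, 2))
#' as.matrix(ndvi(r, n))  # 0.25, 0
#' @export
ndvi <- function(red, nir) {
  stopifnot(is_band_grid(red), is_band_grid(nir))
  check_same_shape(red, nir)
  den <- nir$values + red$values
  num <- nir$values - red$values
  v <- ifelse(!is.na(den) & den == 0, NA_real_, num / den)
  grid_like(red, v, band_id = "NDVI")
}

#' Proportion of vegetation from NDVI
#'
#' Squared min-max scaling of NDVI:
#' `PV = ((NDVI - NDVImin) / (NDVImax - NDVImin))^2`, with the ratio clipped
#' to \[0, 1\] before squaring so PV always lies in \[0, 1\]. By default the
#' scaling endpoints are the observed minimum and maximum of the (non-nodata)
#' NDVI grid, i.e. they are read from the NDVI image itself; both can be
#' overridden.
#'
#' @param ndvi [band_grid] of NDVI values.
#' @param ndvi_min,ndvi_max Scaling endpoints; `ndvi_max` must exceed
#'   `ndvi_min`. Default: observed grid minimum / maximum.
#'
#' @return [band_grid] of PV values in \[0, 1\].
#' @export
proportion_vegetation <- function(ndvi, ndvi_min = NULL, ndvi_max = NULL) {
  stopifnot(is_band_grid(ndvi))
  v <- ndvi$values
  if (is.null(ndvi_min)) ndvi_min <- min(v, na.rm = TRUE)
  if (is.null(ndvi_max)) ndvi_max <- max(v, na.rm = TRUE)
  if (!is.finite(ndvi_min) || !is.finite(ndvi_max) || ndvi_max <= ndvi_min)
    stop("ndvi_max must exceed ndvi_min (got ", ndvi_min, ", ", ndvi_max, ")",
         call. = FALSE)
  ratio <- (v - ndvi_min) / (ndvi_max - ndvi_min)
  ratio <- pmin(pmax(ratio, 0), 1)
  grid_like(ndvi, ratio^2, band_id = "PV")
}

#' Land surface emissivity from proportion of vegetation
#'
#' Linear NDVI-threshold emissivity `E = 0.004 * PV + 0.986`, ranging from
#' 0.986 over fully non-vegetated cells to 0.990 over full vegetation cover.
#'
#' @param pv [band_grid] of proportion-of-vegetation values in \[0, 1\].
#'
#' @return [band_grid] of emissivity values; the PV grid is attached as the
#'   `pv` attribute.
#' @export
emissivity <- function(pv) {
  stopifnot(is_band_grid(pv))
  v <- pv$values
  if (any(!is.na(v) & (v < 0 | v > 1)))
    stop("PV values must lie in [0, 1]", call. = FALSE)
  out <- grid_like(pv, 0.004 * v + 0.986, band_id = "E")
  attr(out, "pv") <- pv
  out
}

#' Single-channel land surface temperature
#'
#' Emissivity-corrected brightness temperature
#' `LST = BT / (1 + (lambda * BT / c2) * ln(E))`, with `lambda` the
#' emitted-radiance wavelength in micrometres and `c2 = 14388` um K the
#' second radiation constant.
#'
#' Two evaluation modes are provided. `"celsius_literal"` (default) feeds the
#' Celsius brightness temperature straight into the formula — the common
#' applied-remote-sensing usage this package reproduces, despite mixing
#' Celsius with the Kelvin-based constant. `"kelvin_physical"` evaluates the
#' formula on the Kelvin scale and converts the result back to Celsius, which
#' is the dimensionally consistent form; the mode used is recorded in the
#' result's `lst_mode` attribute.
#'
#' @param bt [band_grid] of brightness temperature in degrees Celsius.
#' @param emis [band_grid] of emissivity values in (0, 1\].
#' @param meta [scene_meta] supplying the wavelength.
#' @param mode `"celsius_literal"` or `"kelvin_physical"`.
#' @param c2 Second radiation constant in um K (default 14388).
#'
#' @return [band_grid] of LST in degrees Celsius; cells with a non-positive
#'   denominator become nodata (count in the `n_invalid` attribute).
#' @examples
#' m <- default_scene_meta("TM")
#' bt <- band_grid(matrix(32.55))
#' e <- band_grid(matrix(0.986))
#' as.matrix(land_surface_temperature(bt, e, m))  # ~32.56 C
#' @export
land_surface_temperature <- function(bt, emis, meta,
                                     mode = c("celsius_literal",
                                              "kelvin_physical"),
                                     c2 = 14388) {
  stopifnot(is_band_grid(bt), is_band_grid(emis), inherits(meta, "scene_meta"))
  mode <- match.arg(mode)
  check_same_shape(bt, emis)
  e <- emis$values
  if (any(!is.na(e) & (e <= 0 | e > 1)))
    stop("emissivity values must lie in (0, 1]", call. = FALSE)
  lam <- meta$wavelength_um
  t_in <- if (mode == "celsius_literal") bt$values else bt$values + 273.15
  den <- 1 + (lam * t_in / c2) * log(e)
  bad <- !is.na(den) & den <= 0
  n_bad <- sum(bad)
  if (n_bad > 0L) {
    warning(n_bad, " cell(s) with non-positive LST denominator set to nodata",
            call. = FALSE)
    den[bad] <- NA_real_
  }
  lst <- t_in / den
  if (mode == "kelvin_physical") lst <- lst - 273.15
  out <- grid_like(bt, lst, band_id = "LST_C")
  attr(out, "n_invalid") <- n_bad
  attr(out, "lst_mode") <- mode
  attr(out, "c2") <- c2
  attr(out, "wavelength_um") <- lam
  out
}
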