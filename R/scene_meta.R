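#' Scene calibration metadata
#'
#' Radiometric and thermal calibration constants for one Landsat-style scene:
#' the linear DN-to-radiance rescaling (gain/offset form `ml`/`al` plus band
#' correction `oi` for OLI/TIRS; endpoint form `lmax`/`lmin` over
#' `qcal_min..qcal_max` for TM), the inverted-Planck thermal constants
#' `k1` (W m-2 sr-1 um-1) and `k2` (K), and the emitted-radiance wavelength
#' in micrometres used by the single-channel LST formula.
#'
#' @param sensor `"TM"` or `"OLI_TIRS"`.
#' @param k1,k2 Thermal conversion constants; both must be positive.
#' @param wavelength_um Wavelength of emitted radiance in um (11.5 for TM
#'   band 6, 10.8 for OLI/TIRS band 10).
#' @param ml,al Radiance multiplicative / additive rescaling factors
#'   (OLI_TIRS; `ml` must be non-zero).
#' @param oi Band correction value subtracted from `al` (OLI_TIRS only).
#' @param lmax,lmin Spectral radiance at `qcal_max` / `qcal_min` (TM; must
#'   satisfy `lmax > lmin`).
#' @param qcal_max,qcal_min Calibrated pixel-value range (`qcal_max >
#'   qcal_min`).
#'
#' @return An object of class `scene_meta`.
#' @examples
#' scene_meta("TM", k1 = 607.76, k2 = 1260.56, wavelength_um = 11.5,
#'            lmax = 15.303, lmin = 1.238, qcal_max = 255, qcal_min = 1)
#' @export
scene_meta <- function(sensor = c("TM", "OLI_TIRS"),
                       k1, k2, wavelength_um,
                       ml = NA_real_, al = NA_real_, oi = 0,
                       lmax = NA_real_, lmin = NA_real_,
                       qcal_max = NA_real_, qcal_min = NA_real_) {
  sensor <- match.arg(sensor)
  num1 <- function(x) {
    x <- as.numeric(x)
    stopifnot(length(x) == 1L)
    x
  }
  m <- structure(
    list(sensor = sensor, k1 = num1(k1), k2 = num1(k2),
         wavelength_um = num1(wavelength_um),
         ml = num1(ml), al = num1(al), oi = num1(oi),
         lmax = num1(lmax), lmin = num1(lmin),
         qcal_max = num1(qcal_max), qcal_min = num1(qcal_min)),
    class = "scene_meta"
  )
  if (!is.finite(m$k1) || m$k1 <= 0) stop("K1 must be > 0", call. = FALSE)
  if (!is.finite(m$k2) || m$k2 <= 0) stop("K2 must be > 0", call. = FALSE)
  if (!is.finite(m$wavelength_um) || m$wavelength_um <= 0)
    stop("wavelength_um must be > 0", call. = FALSE)
  if (!is.na(m$qcal_max) && !is.na(m$qcal_min) && m$qcal_max <= m$qcal_min)
    stop("qcal_max must exceed qcal_min", call. = FALSE)
  if (sensor == "TM") {
    if (is.na(m$lmax) || is.na(m$lmin) || m$lmax <= m$lmin)
      stop("TM metadata requires lmax > lmin", call. = FALSE)
    if (is.na(m$qcal_max) || is.na(m$qcal_min))
      stop("TM metadata requires qcal_max and qcal_min", call. = FALSE)
  } else {
    if (is.na(m$ml) || m$ml == 0)
      stop("OLI_TIRS metadata requires a non-zero ML", call. = FALSE)
    if (is.na(m$al)) stop("OLI_TIRS metadata requires AL", call. = FALSE)
  }
  m
}

#' @export
print.scene_meta <- function(x, ...) {
  cat(sprintf("<scene_meta> sensor=%s  K1=%g  K2=%g  lambda=%g um\n",
              x$sensor, x$k1, x$k2, x$wavelength_um))
  if (x$sensor == "TM") {
    cat(sprintf("  LMax=%g LMin=%g  Qcal=[%g, %g]\n",
                x$lmax, x$lmin, x$qcal_min, x$qcal_max))
  } else {
    cat(sprintf("  ML=%g AL=%g Oi=%g\n", x$ml, x$al, x$oi))
  }
  invisible(x)
}

#' Default calibration constants per sensor
#'
#' TM defaults are the Landsat 5 band-6 constants (K1 = 607.76, K2 = 1260.56,
#' lambda = 11.5 um, radiance endpoints 1.238-15.303 over DN 1-255).
#' OLI_TIRS defaults are the standard Landsat 8 band-10 metadata constants
#' (K1 = 774.8853, K2 = 1321.0789, lambda = 10.8 um, ML = 3.342e-4,
#' AL = 0.1, Oi = 0.29, DN 1-65535).
#'
#' @param sensor `"TM"` or `"OLI_TIRS"`.
#' @return A [scene_meta].
#' @export
default_scene_meta <- function(sensor = c("TM", "OLI_TIRS")) {
  sensor <- match.arg(sensor)
  if (sensor == "TM") {
    scene_meta("TM", k1 = 607.76, k2 = 1260.56, wavelength_um = 11.5,
               lmax = 15.303, lmin = 1.238, qcal_max = 255, qcal_min = 1)
  } else {
    scene_meta("OLI_TIRS", k1 = 774.8853, k2 = 1321.0789,
               wavelength_um = 10.8, ml = 3.342e-4, al = 0.1, oi = 0.29,
               qcal_max = 65535, qcal_min = 1)
  }
}

# keys accepted in metadata files, mapped to scene_meta arguments
.meta_keys <- c(SENSOR = "sensor", K1 = "k1", K2 = "k2",
                WAVELENGTH_UM = "wavelength_um", ML = "ml", AL = "al",
                OI = "oi", LMAX = "lmax", LMIN = "lmin",
                QCALMAX = "qcal_max", QCALMIN = "qcal_min")

#' Read or write scene calibration metadata
#'
#' Metadata files are flat `KEY = value` text (an MTL-style subset), one key
#' per line; `#` starts a comment. Required keys are `SENSOR`, `K1`, `K2`,
#' `WAVELENGTH_UM`, plus `LMAX`, `LMIN`, `QCALMAX`, `QCALMIN` for TM and
#' `ML`, `AL` for OLI_TIRS (`OI` defaults to 0).
#'
#' @param path Path to the metadata text file.
#' @return `read_scene_meta()` returns a [scene_meta];
#'   `write_scene_meta()` returns `path` invisibly.
#' @export
read_scene_meta <- function(path) {
  if (!file.exists(path))
    stop("metadata file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(parts) != 2L)
      stop("malformed metadata line (expected KEY = value): '", ln, "'",
           call. = FALSE)
    kv[[toupper(trimws(parts[1L]))]] <- trimws(parts[2L])
  }
  need <- function(key) {
    if (is.null(kv[[key]]))
      stop("metadata file is missing required key '", key, "'", call. = FALSE)
    kv[[key]]
  }
  sensor <- toupper(need("SENSOR"))
  if (!sensor %in% c("TM", "OLI_TIRS"))
    stop("SENSOR must be TM or OLI_TIRS, got '", sensor, "'", call. = FALSE)
  args <- list(sensor = sensor,
               k1 = as.numeric(need("K1")),
               k2 = as.numeric(need("K2")),
               wavelength_um = as.numeric(need("WAVELENGTH_UM")))
  if (sensor == "TM") {
    for (key in c("LMAX", "LMIN", "QCALMAX", "QCALMIN"))
      args[[.meta_keys[[key]]]] <- as.numeric(need(key))
  } else {
    for (key in c("ML", "AL"))
      args[[.meta_keys[[key]]]] <- as.numeric(need(key))
    if (!is.null(kv[["OI"]])) args$oi <- as.numeric(kv[["OI"]])
  }
  # optional extras accepted for either sensor (e.g. Qcal range for OLI)
  for (key in names(.meta_keys)) {
    arg <- .meta_keys[[key]]
    if (is.null(args[[arg]]) && !is.null(kv[[key]]) && key != "SENSOR")
      args[[arg]] <- as.numeric(kv[[key]])
  }
  do.call(scene_meta, args)
}

#' @rdname read_scene_meta
#' @param meta A [scene_meta].
#' @export
write_scene_meta <- function(meta, path) {
  stopifnot(inherits(meta, "scene_meta"))
  lines <- c(paste("SENSOR =", meta$sensor))
  for (key in setdiff(names(.meta_keys), "SENSOR")) {
    val <- meta[[.meta_keys[[key]]]]
    if (!is.na(val)) lines <- c(lines, sprintf("%s = %.10g", key, val))
  }
  writeLines(lines, path)
  invisible(path)
}
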