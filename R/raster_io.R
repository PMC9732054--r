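#' Read a raster band from an ESRI ASCII Grid file
#'
#' Rasters are stored in the ESRI ASCII Grid plain-text format (`ncols`,
#' `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value` header
#' followed by row-major values, north row first). Multi-band files written by
#' [write_band_stack()] carry an additional `nbands` header line and
#' concatenate the band blocks; standard single-band files are read unchanged.
#'
#' @param path Path to an `.asc` file.
#' @param band_index 1-based band to extract (files without an `nbands` header
#'   hold exactly one band).
#'
#' @return A [band_grid]; file nodata cells are `NA`, pixel size is taken from
#'   the `cellsize` header.
#' @seealso [write_band()], [write_band_stack()]
#' @export
read_band <- function(path, band_index = 1L) {
  if (!file.exists(path))
    stop("raster file not found: ", path, call. = FALSE)
  band_index <- as.integer(band_index)
  if (length(band_index) != 1L || is.na(band_index) || band_index < 1L)
    stop("`band_index` must be a positive integer", call. = FALSE)

  lines <- readLines(path, warn = FALSE)
  hdr <- list(ncols = NA, nrows = NA, cellsize = NA, nodata_value = NA,
              nbands = 1)
  n_hdr <- 0L
  for (ln in lines) {
    toks <- strsplit(trimws(ln), "\\s+")[[1L]]
    key <- tolower(toks[1L])
    if (length(toks) == 2L &&
        key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
                   "nodata_value", "nbands")) {
      hdr[[key]] <- as.numeric(toks[2L])
      n_hdr <- n_hdr + 1L
    } else {
      break
    }
  }
  for (k in c("ncols", "nrows", "cellsize")) {
    if (is.na(hdr[[k]]))
      stop("ASCII grid header is missing '", k, "': ", path, call. = FALSE)
  }
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  nb <- as.integer(hdr$nbands)
  if (band_index > nb)
    stop("band_index ", band_index, " out of range: file has ", nb,
         " band(s)", call. = FALSE)

  vals <- scan(text = paste(lines[-seq_len(n_hdr)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nc * nr * nb)
    stop("ASCII grid body has ", length(vals), " values; expected ",
         nc * nr * nb, call. = FALSE)
  block <- vals[seq.int((band_index - 1L) * nc * nr + 1L,
                        band_index * nc * nr)]
  m <- matrix(block, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.na(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  band_grid(m, pixel_size_m = hdr$cellsize,
            band_id = if (nb > 1L) paste0("band", band_index) else
              tools::file_path_sans_ext(basename(path)))
}

#' Write raster bands to ESRI ASCII Grid files
#'
#' `write_band()` writes one [band_grid] as a standard single-band ASCII grid;
#' `write_band_stack()` writes several same-shape grids into one file with an
#' `nbands` header (a documented package extension of the format).
#'
#' @param grid A [band_grid].
#' @param path Output file path.
#' @param nodata Numeric value written for nodata cells (default -9999).
#'
#' @return `path`, invisibly.
#' @export
write_band <- function(grid, path, nodata = -9999) {
  stopifnot(is_band_grid(grid))
  write_band_stack(list(grid), path, nodata = nodata)
}

#' @rdname write_band
#' @param grids List of [band_grid]s sharing one shape and pixel size.
#' @export
write_band_stack <- function(grids, path, nodata = -9999) {
  stopifnot(length(grids) >= 1L, all(vapply(grids, is_band_grid, logical(1))))
  do.call(check_same_shape, grids)
  d <- dim(grids[[1L]])
  hdr <- c(
    sprintf("ncols %d", d[2L]),
    sprintf("nrows %d", d[1L]),
    "xllcorner 0",
    "yllcorner 0",
    sprintf("cellsize %.10g", grids[[1L]]$pixel_size_m),
    sprintf("NODATA_value %.10g", nodata)
  )
  if (length(grids) > 1L) hdr <- c(hdr, sprintf("nbands %d", length(grids)))
  body <- unlist(lapply(grids, function(g) {
    v <- g$values
    v[is.na(v)] <- nodata
    apply(v, 1L, function(row) paste(format(row, trim = TRUE, digits = 15,
                                            scientific = FALSE),
                                     collapse = " "))
  }), use.names = FALSE)
  writeLines(c(hdr, body), path)
  invisible(path)
}
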