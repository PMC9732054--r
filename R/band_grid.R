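#' Single-band raster grid
#'
#' Lightweight in-memory container for one raster band: a numeric matrix of
#' per-pixel values in which `NA` marks nodata cells, plus the pixel edge
#' length in metres and a band label. All raster algebra in the package
#' propagates `NA` (any operation on a nodata cell yields nodata).
#'
#' @param values Numeric matrix (or object coercible to one). `NA` = nodata.
#' @param pixel_size_m Pixel edge length in metres; must be > 0.
#' @param band_id Short text label for the band (e.g. `"B3"`, `"thermal"`).
#'
#' @return An object of class `band_grid`.
#' @examples
#' g <- band_grid(matrix(1:12, 3, 4), pixel_size_m = 30, band_id = "B3")
#' dim(g)
#' @export
band_grid <- function(values, pixel_size_m = 30, band_id = "band") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  pixel_size_m <- as.numeric(pixel_size_m)
  if (length(pixel_size_m) != 1L || !is.finite(pixel_size_m) || pixel_size_m <= 0)
    stop("`pixel_size_m` must be a single positive number", call. = FALSE)
  structure(
    list(values = values, pixel_size_m = pixel_size_m,
         band_id = as.character(band_id)[1L]),
    class = "band_grid"
  )
}

#' @rdname band_grid
#' @param x Object to test or coerce.
#' @export
is_band_grid <- function(x) inherits(x, "band_grid")

#' @export
dim.band_grid <- function(x) dim(x$values)

#' @rdname band_grid
#' @param ... Unused.
#' @export
as.matrix.band_grid <- function(x, ...) x$values

#' @export
print.band_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<band_grid '%s'> %d x %d, pixel %g m, %d nodata cell(s)\n",
              x$band_id, nrow(v), ncol(v), x$pixel_size_m, sum(is.na(v))))
  if (all(is.na(v))) {
    cat("  all nodata\n")
  } else {
    cat(sprintf("  range: [%g, %g]\n", min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  }
  invisible(x)
}

# internal: new grid sharing geometry with a template
grid_like <- function(template, values, band_id = template$band_id) {
  band_grid(values, pixel_size_m = template$pixel_size_m, band_id = band_id)
}

# internal: stop unless all grids share one shape
check_same_shape <- function(...) {
  grids <- list(...)
  d <- dim(grids[[1L]])
  for (g in grids[-1L]) {
    if (!identical(dim(g), d))
      stop("grids must share one shape (", paste(d, collapse = "x"),
           " vs ", paste(dim(g), collapse = "x"), ")", call. = FALSE)
  }
  invisible(d)
}

#' Clip a grid to a study-area mask
#'
#' Cells outside the mask become nodata; in-mask values are unchanged. This is
#' the raster analogue of extracting a study area with a boundary polygon.
#'
#' @param grid A [band_grid].
#' @param mask Logical (or 0/1 numeric) matrix with the same shape as `grid`;
#'   `TRUE`/1 marks cells to keep.
#'
#' @return A [band_grid] with out-of-mask cells set to nodata.
#' @examples
#' g <- band_grid(matrix(1, 2, 2))
#' m <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
#' sum(is.na(as.matrix(clip_to_mask(g, m))))
#' @export
clip_to_mask <- function(grid, mask) {
  stopifnot(is_band_grid(grid))
  mask <- as.matrix(mask)
  if (!identical(dim(mask), dim(grid$values)))
    stop("mask shape (", paste(dim(mask), collapse = "x"),
         ") does not match grid shape (",
         paste(dim(grid$values), collapse = "x"), ")", call. = FALSE)
  keep <- mask
  storage.mode(keep) <- "logical"
  if (anyNA(keep)) keep[is.na(keep)] <- FALSE
  v <- grid$values
  v[!keep] <- NA_real_
  grid_like(grid, v)
}
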