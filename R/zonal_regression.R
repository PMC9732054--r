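#' Per-class LST and NDVI means
#'
#' Arithmetic mean of LST and NDVI over each class's pixels, skipping cells
#' that are nodata in either grid. Classes with no usable pixels are omitted
#' with a warning.
#'
#' @param lst [band_grid] of LST (degrees Celsius).
#' @param ndvi [band_grid] of NDVI.
#' @param labels A [label_map] sharing the grids' shape.
#'
#' @return Data frame with columns `class`, `mean_lst_c`, `mean_ndvi`,
#'   `n_pixels`.
#' @export
class_means <- function(lst, ndvi, labels) {
  stopifnot(is_band_grid(lst), is_band_grid(ndvi),
            inherits(labels, "label_map"))
  check_same_shape(lst, ndvi)
  if (!identical(dim(labels$labels), dim(lst$values)))
    stop("label map shape does not match the grids", call. = FALSE)
  ok <- !is.na(lst$values) & !is.na(ndvi$values) & !is.na(labels$labels)
  cls <- labels$class_names
  rows <- lapply(seq_along(cls), function(k) {
    idx <- ok & labels$labels == k
    n <- sum(idx)
    if (n == 0L) return(NULL)
    data.frame(class = cls[k],
               mean_lst_c = mean(lst$values[idx]),
               mean_ndvi = mean(ndvi$values[idx]),
               n_pixels = n, stringsAsFactors = FALSE)
  })
  empty <- cls[vapply(rows, is.null, logical(1))]
  if (length(empty) > 0L)
    warning("class(es) with no usable pixels omitted: ",
            paste(empty, collapse = ", "), call. = FALSE)
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Random per-class pixel sample
#'
#' Draws `n_per_class` distinct pixel coordinates per class uniformly
#' without replacement, deterministically for a fixed seed.
#'
#' @param labels A [label_map].
#' @param n_per_class Points per class; every sampled class must have at
#'   least this many pixels.
#' @param seed Integer random seed.
#' @param classes Classes to sample (default: all classes present).
#'
#' @return Data frame with columns `row`, `col`, `label`.
#' @export
sample_class_points <- function(labels, n_per_class, seed, classes = NULL) {
  stopifnot(inherits(labels, "label_map"))
  n_per_class <- as.integer(n_per_class)
  if (is.na(n_per_class) || n_per_class < 1L)
    stop("n_per_class must be a positive integer", call. = FALSE)
  if (is.null(classes)) {
    present <- sort(unique(labels$labels[!is.na(labels$labels)]))
    classes <- labels$class_names[present]
  }
  out <- withr_seed(seed, {
    do.call(rbind, lapply(classes, function(cl) {
      k <- match(cl, labels$class_names)
      if (is.na(k)) stop("unknown class '", cl, "'", call. = FALSE)
      cells <- which(labels$labels == k)
      if (length(cells) < n_per_class)
        stop("class '", cl, "' has only ", length(cells),
             " pixels; need ", n_per_class, call. = FALSE)
      pick <- sample(cells, n_per_class)
      data.frame(row = row(labels$labels)[pick],
                 col = col(labels$labels)[pick],
                 label = cl, stringsAsFactors = FALSE)
    }))
  })
  rownames(out) <- NULL
  out
}

# internal: evaluate expr under a local RNG seed, restoring RNG state after
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# internal: derive an independent substream seed from a base seed
substream_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 10007) %% 2147483629)
}

#' Bivariate LST-on-NDVI regression
#'
#' Ordinary least squares of LST (response, degrees Celsius) on NDVI
#' (predictor): `LST = slope * NDVI + intercept`, with the coefficient of
#' determination equal to the squared Pearson correlation of the two value
#' lists.
#'
#' @param lst_values Numeric vector of LST values (degrees Celsius).
#' @param ndvi_values Numeric vector of NDVI values, same length; at least
#'   3 pairs with non-zero NDVI variance.
#'
#' @return An object of class `lst_ndvi_fit`: list with `slope`,
#'   `intercept`, `r_squared`, `n_points` and the underlying `lm` fit.
#' @examples
#' f <- fit_lst_ndvi(c(30, 29, 28), c(0.1, 0.2, 0.3))
#' c(f$slope, f$intercept, f$r_squared)  # -10, 31, 1
#' @export
fit_lst_ndvi <- function(lst_values, ndvi_values) {
  lst_values <- as.numeric(lst_values)
  ndvi_values <- as.numeric(ndvi_values)
  ok <- !is.na(lst_values) & !is.na(ndvi_values)
  lst_values <- lst_values[ok]
  ndvi_values <- ndvi_values[ok]
  if (length(lst_values) != length(ndvi_values))
    stop("lst_values and ndvi_values must have equal length", call. = FALSE)
  if (length(lst_values) < 3L)
    stop("need at least 3 point pairs", call. = FALSE)
  if (stats::var(ndvi_values) == 0)
    stop("NDVI values are all identical; regression undefined", call. = FALSE)
  fit <- stats::lm(lst_values ~ ndvi_values)
  structure(
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r_squared = summary(fit)$r.squared,
         n_points = length(lst_values),
         fit = fit),
    class = "lst_ndvi_fit"
  )
}

#' @export
print.lst_ndvi_fit <- function(x, ...) {
  cat(sprintf("LST = %.4g NDVI + %.4g  (R2 = %.3f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Per-class LST-NDVI regression at sampled points
#'
#' Samples `n_per_class` pixels per class (see [sample_class_points()]),
#' reads LST and NDVI at those pixels and fits [fit_lst_ndvi()] per class.
#' Classes whose sampled NDVI values have zero variance or fewer than 3
#' usable pairs are reported with `NA` coefficients.
#'
#' @inheritParams class_means
#' @inheritParams sample_class_points
#' @return Data frame with columns `class`, `slope`, `intercept`,
#'   `r_squared`, `n_points`.
#' @export
fit_lst_ndvi_by_class <- function(lst, ndvi, labels, n_per_class = 20,
                                  seed = 1L) {
  pts <- sample_class_points(labels, n_per_class, seed)
  do.call(rbind, lapply(split(pts, pts$label), function(p) {
    lv <- lst$values[cbind(p$row, p$col)]
    nv <- ndvi$values[cbind(p$row, p$col)]
    f <- tryCatch(fit_lst_ndvi(lv, nv), error = function(e) NULL)
    if (is.null(f))
      data.frame(class = p$label[1L], slope = NA_real_,
                 intercept = NA_real_, r_squared = NA_real_,
                 n_points = sum(!is.na(lv) & !is.na(nv)),
                 stringsAsFactors = FALSE)
    else
      data.frame(class = p$label[1L], slope = f$slope,
                 intercept = f$intercept, r_squared = f$r_squared,
                 n_points = f$n_points, stringsAsFactors = FALSE)
  }))
}
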