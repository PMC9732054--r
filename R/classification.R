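#' Per-pixel class label raster
#'
#' Integer matrix of 1-based class indices (`NA` = nodata) with the ordered
#' class-name vector and pixel size attached.
#'
#' @param labels Integer matrix of class indices in `1..length(class_names)`,
#'   `NA` for nodata.
#' @param class_names Ordered character vector of class names.
#' @param pixel_size_m Pixel edge length in metres.
#'
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, class_names, pixel_size_m = 30) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  class_names <- as.character(class_names)
  if (anyDuplicated(class_names))
    stop("class_names must be unique", call. = FALSE)
  if (any(!is.na(labels))) {
    rng <- range(labels, na.rm = TRUE)
    if (rng[1L] < 1L || rng[2L] > length(class_names))
      stop("labels must be indices into class_names", call. = FALSE)
  }
  if (pixel_size_m <= 0) stop("pixel_size_m must be > 0", call. = FALSE)
  structure(list(labels = labels, class_names = class_names,
                 pixel_size_m = as.numeric(pixel_size_m)),
            class = "label_map")
}

#' @export
dim.label_map <- function(x) dim(x$labels)

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %d x %d, pixel %g m, %d classes\n",
              nrow(x$labels), ncol(x$labels), x$pixel_size_m,
              length(x$class_names)))
  tab <- tabulate(x$labels, nbins = length(x$class_names))
  for (k in seq_along(x$class_names))
    cat(sprintf("  %-14s %d px\n", x$class_names[k], tab[k]))
  invisible(x)
}

#' Gaussian class signatures from labeled training points
#'
#' For each class, the sample mean vector and sample covariance matrix
#' (denominator n - 1) of the band values at the class's training pixels.
#' Covariances whose smallest eigenvalue falls below a small ridge
#' `eps = epsilon_scale * mean(diag(cov))` (or `epsilon_scale` itself when
#' the diagonal is all zero) are regularized by adding `eps` to the diagonal,
#' so degenerate training sets still yield usable signatures.
#'
#' Training points falling on nodata pixels in any band are skipped, with
#' the skipped count reported in a warning.
#'
#' @param bands List of [band_grid]s sharing one shape (e.g. the three-band
#'   false-colour composite used for classification).
#' @param training Data frame with columns `row`, `col` (1-based pixel
#'   coordinates) and `label` (class name).
#' @param epsilon_scale Ridge scale for covariance regularization.
#'
#' @return A list of class `class_signatures`; each element has `label`,
#'   `mean`, `cov` and `n_train`.
#' @export
extract_signatures <- function(bands, training, epsilon_scale = 1e-6) {
  stopifnot(is.list(bands), length(bands) >= 1L,
            all(vapply(bands, is_band_grid, logical(1))))
  do.call(check_same_shape, bands)
  training <- as.data.frame(training)
  if (!all(c("row", "col", "label") %in% names(training)))
    stop("training must have columns row, col, label", call. = FALSE)
  nb <- length(bands)
  X <- vapply(bands, function(b) b$values[cbind(training$row, training$col)],
              numeric(nrow(training)))
  X <- matrix(X, ncol = nb)
  ok <- stats::complete.cases(X)
  if (any(!ok))
    warning(sum(!ok), " training point(s) on nodata pixels skipped",
            call. = FALSE)
  labels <- as.character(training$label)[ok]
  X <- X[ok, , drop = FALSE]
  classes <- unique(as.character(training$label))
  sigs <- lapply(classes, function(cl) {
    Xi <- X[labels == cl, , drop = FALSE]
    if (nrow(Xi) < nb + 1L)
      stop("class '", cl, "' has ", nrow(Xi), " usable training points; ",
           "need at least ", nb + 1L, call. = FALSE)
    mu <- colMeans(Xi)
    S <- stats::cov(Xi)
    eps <- epsilon_scale * mean(diag(S))
    if (!is.finite(eps) || eps <= 0) eps <- epsilon_scale
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < eps)
      S <- S + diag(eps, nb)
    list(label = cl, mean = mu, cov = S, n_train = nrow(Xi))
  })
  names(sigs) <- classes
  structure(sigs, class = "class_signatures")
}

#' Maximum likelihood classification
#'
#' Assigns each pixel to the class maximizing the Gaussian discriminant
#' `g_i(x) = ln p_i - 1/2 ln|S_i| - 1/2 (x - m_i)' S_i^-1 (x - m_i)`,
#' i.e. the class with the highest multivariate-normal likelihood given the
#' class signatures. Priors default to equal; ties go to the lowest class
#' index; pixels with nodata in any band stay nodata.
#'
#' @param bands List of [band_grid]s sharing one shape.
#' @param signatures [class_signatures][extract_signatures] covering at
#'   least two classes.
#' @param priors Optional per-class prior probabilities (same order as
#'   `signatures`); must sum to 1.
#'
#' @return A [label_map] whose class names follow the signature order.
#' @export
classify_mlc <- function(bands, signatures, priors = NULL) {
  stopifnot(is.list(bands), all(vapply(bands, is_band_grid, logical(1))),
            inherits(signatures, "class_signatures"))
  if (length(signatures) < 2L)
    stop("need signatures for at least 2 classes", call. = FALSE)
  do.call(check_same_shape, bands)
  nb <- length(bands)
  K <- length(signatures)
  if (is.null(priors)) priors <- rep(1 / K, K)
  if (length(priors) != K || abs(sum(priors) - 1) > 1e-8 || any(priors <= 0))
    stop("priors must be ", K, " positive values summing to 1", call. = FALSE)

  d <- dim(bands[[1L]])
  X <- vapply(bands, function(b) as.vector(b$values), numeric(prod(d)))
  X <- matrix(X, ncol = nb)
  ok <- stats::complete.cases(X)
  G <- matrix(NA_real_, nrow = sum(ok), ncol = K)
  Xo <- X[ok, , drop = FALSE]
  for (k in seq_len(K)) {
    sig <- signatures[[k]]
    R <- tryCatch(chol(sig$cov), error = function(e)
      stop("covariance for class '", sig$label,
           "' is singular after regularization", call. = FALSE))
    logdet <- 2 * sum(log(diag(R)))
    Z <- backsolve(R, t(Xo) - sig$mean, transpose = TRUE)
    G[, k] <- log(priors[k]) - 0.5 * logdet - 0.5 * colSums(Z^2)
  }
  lab <- rep(NA_integer_, prod(d))
  lab[ok] <- max.col(G, ties.method = "first")
  label_map(matrix(lab, d[1L], d[2L]),
            class_names = vapply(signatures, `[[`, character(1), "label"),
            pixel_size_m = bands[[1L]]$pixel_size_m)
}
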