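#' Synthetic LULC class specification
#'
#' Describes one land-cover class for scene synthesis: the multivariate
#' normal distribution of its optical-band digital numbers, the univariate
#' normal of its thermal-band DNs, and its target share of the scene.
#'
#' @param label Class name (e.g. `"forests"`).
#' @param band_means Numeric vector of per-optical-band mean DNs.
#' @param band_cov Covariance matrix of the optical-band DNs (symmetric
#'   positive semi-definite; a scalar is expanded to `scalar^2 * I`).
#' @param thermal_dn_mean,thermal_dn_sd Thermal-band DN mean and standard
#'   deviation (`sd >= 0`).
#' @param area_fraction Target fraction of the scene in \[0, 1\].
#'
#' @return An object of class `class_spec`.
#' @export
class_spec <- function(label, band_means, band_cov, thermal_dn_mean,
                       thermal_dn_sd, area_fraction) {
  band_means <- as.numeric(band_means)
  nb <- length(band_means)
  if (length(band_cov) == 1L) band_cov <- diag(as.numeric(band_cov)^2, nb)
  band_cov <- as.matrix(band_cov)
  if (!identical(dim(band_cov), c(nb, nb)))
    stop("band_cov must be ", nb, "x", nb, call. = FALSE)
  if (max(abs(band_cov - t(band_cov))) > 1e-8)
    stop("band_cov must be symmetric", call. = FALSE)
  ev <- eigen(band_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("band_cov must be positive semi-definite", call. = FALSE)
  if (thermal_dn_sd < 0) stop("thermal_dn_sd must be >= 0", call. = FALSE)
  if (area_fraction < 0 || area_fraction > 1)
    stop("area_fraction must be in [0, 1]", call. = FALSE)
  structure(list(label = as.character(label), band_means = band_means,
                 band_cov = band_cov,
                 thermal_dn_mean = as.numeric(thermal_dn_mean),
                 thermal_dn_sd = as.numeric(thermal_dn_sd),
                 area_fraction = as.numeric(area_fraction)),
            class = "class_spec")
}

#' Default six-class spectral library
#'
#' Hand-chosen three-band (green, red, near-infrared) DN means and thermal
#' DN means for the six LULC classes urbanized, forests, agricultural, bare,
#' rocks and water. The means are picked so the class-mean NDVI ordering is
#' forests (~0.55) > agricultural (~0.40) > urbanized (~0.05) > bare (~0.02)
#' > rocks (~0) > water (~-0.40), and the thermal ordering (hence LST)
#' is urbanized > bare > rocks > agricultural > forests ~ water — the
#' qualitative structure of a tropical urbanizing coastal scene. Default
#' area fractions are the published Penang Island class shares for the
#' chosen year.
#'
#' @param year `"2010"` or `"2021"`: which published area-share vector to
#'   use as the target fractions.
#' @param band_sd Per-band DN standard deviation (spherical covariance);
#'   controls class separability.
#' @param thermal_sd Thermal-band DN standard deviation.
#' @param area_fractions Optional named numeric vector overriding the
#'   fractions (names must be the six class labels).
#'
#' @return Named list of six [class_spec]s.
#' @export
default_class_specs <- function(year = c("2010", "2021"), band_sd = 3,
                                thermal_sd = 2, area_fractions = NULL) {
  year <- match.arg(year)
  lib <- list(
    urbanized    = list(means = c(90, 95, 105),  thermal = 160),
    forests      = list(means = c(35, 40, 138),  thermal = 138),
    agricultural = list(means = c(50, 60, 140),  thermal = 144),
    bare         = list(means = c(110, 120, 125), thermal = 156),
    rocks        = list(means = c(80, 90, 90),   thermal = 150),
    water        = list(means = c(30, 35, 15),   thermal = 137)
  )
  if (is.null(area_fractions)) {
    pct <- if (year == "2010")
      c(urbanized = 19.90, forests = 39.17, agricultural = 34.06,
        bare = 1.39, rocks = 4.87, water = 0.62)
    else
      c(urbanized = 29.01, forests = 39.78, agricultural = 22.65,
        bare = 4.95, rocks = 2.35, water = 1.25)
    area_fractions <- pct / sum(pct)
  }
  if (!setequal(names(area_fractions), names(lib)))
    stop("area_fractions must be named with the six class labels",
         call. = FALSE)
  out <- lapply(names(lib), function(cl) {
    class_spec(cl, lib[[cl]]$means, band_sd, lib[[cl]]$thermal,
               thermal_sd, area_fractions[[cl]])
  })
  names(out) <- names(lib)
  out
}

# internal: validate a spec set's fractions; renormalize small rounding slack
spec_fractions <- function(specs) {
  fr <- vapply(specs, `[[`, numeric(1), "area_fraction")
  if (abs(sum(fr) - 1) > 0.02)
    stop("class area fractions sum to ", round(sum(fr), 4),
         "; expected 1", call. = FALSE)
  fr / sum(fr)
}

#' Generate a blocky truth map with target class fractions
#'
#' Partitions the grid into `region_scale x region_scale` rectangular tiles,
#' shuffles the tile order (seeded) and fills tiles sequentially with the
#' classes in spec order until each class's target pixel count is met. The
#' result is a contiguous, blocky class mosaic whose realized per-class
#' fractions match the targets to within one pixel, deterministically for a
#' fixed seed.
#'
#' @param shape Integer vector `c(nrow, ncol)`.
#' @param specs List of [class_spec]s whose `area_fraction`s sum to 1 (small
#'   rounding slack is renormalized).
#' @param region_scale Tile edge in pixels; must not exceed `min(shape)`.
#' @param seed Integer random seed.
#' @param pixel_size_m Pixel edge length in metres.
#'
#' @return A [label_map] with the spec labels as class names.
#' @export
generate_truth_map <- function(shape, specs, region_scale = 16L, seed = 1L,
                               pixel_size_m = 30) {
  stopifnot(length(shape) == 2L, all(shape >= 1L))
  region_scale <- as.integer(region_scale)
  if (region_scale < 1L || region_scale > min(shape))
    stop("region_scale must be in [1, min(shape)]", call. = FALSE)
  fr <- spec_fractions(specs)
  nr <- as.integer(shape[1L]); nc <- as.integer(shape[2L])
  N <- nr * nc

  # integer class targets: floor + largest remainders
  tgt <- floor(fr * N)
  rem <- fr * N - tgt
  short <- N - sum(tgt)
  if (short > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(short)]
    tgt[add] <- tgt[add] + 1L
  }

  ri <- row(matrix(0, nr, nc)); ci <- col(matrix(0, nr, nc))
  tile <- ((ri - 1L) %/% region_scale) * (((nc - 1L) %/% region_scale) + 1L) +
    ((ci - 1L) %/% region_scale) + 1L
  ntiles <- max(tile)
  tile_rank <- withr_seed(substream_seed(seed, 1L), sample(ntiles))
  ord <- order(tile_rank[tile], ri, ci)

  lab <- integer(N)
  lab[ord] <- rep.int(seq_along(specs), times = tgt)
  label_map(matrix(lab, nr, nc),
            class_names = vapply(specs, `[[`, character(1), "label"),
            pixel_size_m = pixel_size_m)
}

#' Synthesize a multispectral scene over a truth map
#'
#' Draws each pixel's optical DN vector from its class's multivariate normal
#' and its thermal DN from the class's univariate normal, then clips all DNs
#' to the calibrated range `[qcal_min, qcal_max]` of `meta`. Deterministic
#' for a fixed seed.
#'
#' @param truth_map A [label_map]; every class present must have a spec.
#' @param specs Named list of [class_spec]s (names = class labels).
#' @param meta [scene_meta] providing the DN range and thermal constants.
#' @param seed Integer random seed.
#'
#' @return An object of class `synthetic_scene`: list with `optical` (list
#'   of [band_grid]s, ids `B1..Bk`), `thermal` ([band_grid]), `truth`
#'   (the truth [label_map]), `meta`, `seed`, and a `roles` attribute naming
#'   the red and NIR optical band indices.
#' @export
generate_scene <- function(truth_map, specs, meta = default_scene_meta("TM"),
                           seed = 1L) {
  stopifnot(inherits(truth_map, "label_map"), inherits(meta, "scene_meta"))
  present <- truth_map$class_names[sort(unique(
    truth_map$labels[!is.na(truth_map$labels)]))]
  spec_labels <- vapply(specs, `[[`, character(1), "label")
  names(specs) <- spec_labels
  missing_cls <- setdiff(present, spec_labels)
  if (length(missing_cls) > 0L)
    stop("no class_spec for truth-map class(es): ",
         paste(missing_cls, collapse = ", "), call. = FALSE)
  nb <- length(specs[[1L]]$band_means)
  d <- dim(truth_map$labels)
  opt <- lapply(seq_len(nb), function(b) matrix(NA_real_, d[1L], d[2L]))
  thm <- matrix(NA_real_, d[1L], d[2L])

  withr_seed(substream_seed(seed, 2L), {
    for (cl in present) {
      sp <- specs[[cl]]
      idx <- which(truth_map$labels == match(cl, truth_map$class_names))
      n <- length(idx)
      draws <- MASS::mvrnorm(n, mu = sp$band_means, Sigma = sp$band_cov)
      draws <- matrix(draws, nrow = n)
      for (b in seq_len(nb)) opt[[b]][idx] <- draws[, b]
      thm[idx] <- stats::rnorm(n, sp$thermal_dn_mean, sp$thermal_dn_sd)
    }
  })

  clip <- function(v) {
    if (!is.na(meta$qcal_min)) v <- pmax(v, meta$qcal_min)
    if (!is.na(meta$qcal_max)) v <- pmin(v, meta$qcal_max)
    v
  }
  optical <- lapply(seq_len(nb), function(b)
    band_grid(clip(opt[[b]]), pixel_size_m = truth_map$pixel_size_m,
              band_id = paste0("B", b)))
  thermal <- band_grid(clip(thm), pixel_size_m = truth_map$pixel_size_m,
                       band_id = "thermal")
  structure(
    list(optical = optical, thermal = thermal, truth = truth_map,
         meta = meta, seed = as.integer(seed)),
    roles = list(red = nb - 1L, nir = nb),
    class = "synthetic_scene"
  )
}

#' @export
print.synthetic_scene <- function(x, ...) {
  d <- dim(x$truth$labels)
  cat(sprintf("<synthetic_scene> %d x %d, %d optical band(s) + thermal, %s\n",
              d[1L], d[2L], length(x$optical), x$meta$sensor))
  invisible(x)
}

#' Sample labeled truth points from a truth map
#'
#' Uniform without-replacement draw of `n_per_class` pixels per class,
#' labeled from the truth map — the synthetic stand-in for field-collected
#' training/ground-truth points.
#'
#' @param truth_map A [label_map].
#' @param n_per_class Points per class (paper practice: at least 40 training
#'   points per class, 20 for the LST-NDVI relation).
#' @param seed Integer random seed.
#'
#' @return Data frame with columns `row`, `col`, `label`.
#' @export
sample_truth_points <- function(truth_map, n_per_class = 40L, seed = 1L) {
  sample_class_points(truth_map, n_per_class, seed)
}
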