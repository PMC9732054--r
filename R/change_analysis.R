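#' Per-class area tabulation
#'
#' Converts a classified map into per-class areas: pixel count times the
#' pixel area (`pixel_size_m^2 / 10000` hectares per pixel) and the
#' percentage of the non-nodata total.
#'
#' @param labels A [label_map]; must contain at least one non-nodata pixel.
#'
#' @return An `area_table`: data frame with columns `class`, `n_pixels`,
#'   `area_ha`, `area_pct` and attribute `total_area_ha`.
#' @examples
#' lm <- label_map(matrix(1L, 100, 100), "forests", pixel_size_m = 30)
#' class_areas(lm)  # 900 ha, 100%
#' @export
class_areas <- function(labels) {
  stopifnot(inherits(labels, "label_map"))
  counts <- tabulate(labels$labels, nbins = length(labels$class_names))
  if (sum(counts) == 0L)
    stop("label map is entirely nodata", call. = FALSE)
  px_ha <- labels$pixel_size_m^2 / 1e4
  area_table(labels$class_names, counts * px_ha, n_pixels = counts)
}

#' Area table from known per-class areas
#'
#' Builds the same structure as [class_areas()] directly from areas in
#' hectares, e.g. for published area tables.
#'
#' @param class Character vector of class names.
#' @param area_ha Numeric vector of areas in hectares.
#' @param n_pixels Optional pixel counts.
#' @return An `area_table`.
#' @export
area_table <- function(class, area_ha, n_pixels = NA_integer_) {
  stopifnot(length(class) == length(area_ha), all(area_ha >= 0))
  total <- sum(area_ha)
  out <- data.frame(class = as.character(class),
                    n_pixels = n_pixels,
                    area_ha = as.numeric(area_ha),
                    area_pct = if (total > 0) 100 * area_ha / total
                               else NA_real_,
                    stringsAsFactors = FALSE)
  attr(out, "total_area_ha") <- total
  class(out) <- c("area_table", "data.frame")
  out
}

#' Two-date per-class change statistics
#'
#' For each class, the changed area `Ca = area(t2) - area(t1)` in hectares,
#' the changed extent `Ce = Ca / area(t1)` (dimensionless), the percentage
#' change `100 * Ce`, and the annual rate of change. The default annual rate
#' is the linear `pct_change / interval_years`; `rate = "compound"` uses the
#' geometric `((A2/A1)^(1/interval) - 1) * 100` instead.
#'
#' Classes with zero first-date area get `NA` extent, percentage and annual
#' rate while `Ca` is still reported.
#'
#' @param t1,t2 [area_table]s for the first and second date; must cover the
#'   same class set.
#' @param interval_years Positive number of years between the dates.
#' @param rate `"linear"` (default) or `"compound"`.
#'
#' @return A `change_table`: data frame with columns `class`, `area_t1_ha`,
#'   `area_t2_ha`, `change_area_ha`, `changed_extent`, `pct_change`,
#'   `annual_rate_pct`; `interval_years` is attached as an attribute.
#' @examples
#' t1 <- area_table(c("urbanized", "forests"), c(6111.62, 12025.44))
#' t2 <- area_table(c("urbanized", "forests"), c(8905.43, 12213.70))
#' change_table(t1, t2, interval_years = 11)
#' @export
change_table <- function(t1, t2, interval_years,
                         rate = c("linear", "compound")) {
  stopifnot(inherits(t1, "area_table"), inherits(t2, "area_table"))
  rate <- match.arg(rate)
  if (!is.numeric(interval_years) || length(interval_years) != 1L ||
      interval_years <= 0)
    stop("interval_years must be a positive number", call. = FALSE)
  if (!setequal(t1$class, t2$class))
    stop("the two area tables must cover the same class set", call. = FALSE)
  a1 <- t1$area_ha
  a2 <- t2$area_ha[match(t1$class, t2$class)]
  ca <- a2 - a1
  ce <- ifelse(a1 > 0, ca / a1, NA_real_)
  pct <- 100 * ce
  annual <- if (rate == "linear") pct / interval_years
            else ifelse(a1 > 0, ((a2 / a1)^(1 / interval_years) - 1) * 100,
                        NA_real_)
  out <- data.frame(class = t1$class,
                    area_t1_ha = a1, area_t2_ha = a2,
                    change_area_ha = ca, changed_extent = ce,
                    pct_change = pct, annual_rate_pct = annual,
                    stringsAsFactors = FALSE)
  attr(out, "interval_years") <- interval_years
  attr(out, "rate") <- rate
  class(out) <- c("change_table", "data.frame")
  out
}

#' Published Penang Island LULC areas, 2010 and 2021
#'
#' The per-class LULC areas of Penang Island (hectares) for 2010 and 2021 as
#' published for the six classes urbanized, forests, agricultural, bare,
#' rocks and water (total 30,703.01 ha each year), shipped as a plain-text
#' fixture. Useful as a worked input for [change_table()].
#'
#' @return A list with elements `t1` and `t2`, each an [area_table], plus
#'   `interval_years = 11`.
#' @export
penang_lulc_areas <- function() {
  path <- system.file("extdata", "penang_lulc_areas_2010_2021.csv",
                      package = "lulcst", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  list(t1 = area_table(df$class, df$area_ha_2010),
       t2 = area_table(df$class, df$area_ha_2021),
       interval_years = 11)
}
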