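#' Configuration for a two-date LULC/LST pipeline run
#'
#' Collects every knob of the end-to-end analysis in one validated list: the
#' synthetic-scene parameters (or paths to ingested scenes), sampling sizes,
#' classifier and LST options, the observation interval and the output
#' directory. A config plus a seed fully determines a run.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Integer master seed; per-stage substreams are derived from it.
#' @param shape Synthetic scene shape `c(nrow, ncol)`.
#' @param region_scale Truth-map tile edge in pixels.
#' @param interval_years Years between the two dates (default 11, a
#'   2010-2021 run).
#' @param year_t1,year_t2 Date labels; also select the default area-share
#'   vectors for the synthetic truth maps.
#' @param band_sd,thermal_sd Synthetic class spectral spread (DN).
#' @param n_train Training points per class (>= number of bands + 1;
#'   default 40).
#' @param n_test Held-out accuracy points per class.
#' @param n_relate Points per class for the LST-NDVI regression (default 20).
#' @param lst_mode `"celsius_literal"` or `"kelvin_physical"` (see
#'   [land_surface_temperature()]).
#' @param priors Optional classifier priors.
#' @param write_rasters Write LULC/LST/NDVI rasters as ASCII grids?
#' @param scenes Optional list for ingesting real scenes instead of
#'   synthesizing: per date (`t1`, `t2`) a list with `bands` (multi-band
#'   ASCII stack path), `thermal` (path), `meta` (metadata path), `training`
#'   (CSV path) and optionally `reference` (CSV path for accuracy).
#'
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, shape = c(120L, 120L),
                       region_scale = 16L, interval_years = 11,
                       year_t1 = "2010", year_t2 = "2021",
                       band_sd = 3, thermal_sd = 2,
                       n_train = 40L, n_test = 40L, n_relate = 20L,
                       lst_mode = c("celsius_literal", "kelvin_physical"),
                       priors = NULL, write_rasters = TRUE, scenes = NULL) {
  lst_mode <- match.arg(lst_mode)
  stopifnot(interval_years > 0, n_train >= 1L, n_test >= 1L, n_relate >= 1L)
  if (!is.null(scenes)) {
    for (dt in c("t1", "t2")) {
      sc <- scenes[[dt]]
      if (is.null(sc)) stop("scenes must have entries t1 and t2", call. = FALSE)
      for (p in c("bands", "thermal", "meta", "training")) {
        if (is.null(sc[[p]]) || !file.exists(sc[[p]]))
          stop("scenes$", dt, "$", p, " missing or not found", call. = FALSE)
      }
    }
  }
  structure(
    list(out_dir = out_dir, seed = as.integer(seed),
         shape = as.integer(shape), region_scale = as.integer(region_scale),
         interval_years = interval_years,
         year_t1 = year_t1, year_t2 = year_t2,
         band_sd = band_sd, thermal_sd = thermal_sd,
         n_train = as.integer(n_train), n_test = as.integer(n_test),
         n_relate = as.integer(n_relate), lst_mode = lst_mode,
         priors = priors, write_rasters = isTRUE(write_rasters),
         scenes = scenes),
    class = "run_config"
  )
}

# internal: run one named stage; on failure leave a FAILED marker and abort
run_stage <- function(name, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(paste0("stage: ", name, "\nerror: ", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

# internal: full single-date analysis; returns grids, maps and tables
analyse_date <- function(cfg, which_date) {
  yr <- if (which_date == 1L) cfg$year_t1 else cfg$year_t2
  seed_d <- substream_seed(cfg$seed, 100L * which_date)

  if (is.null(cfg$scenes)) {
    specs <- default_class_specs(year = yr, band_sd = cfg$band_sd,
                                 thermal_sd = cfg$thermal_sd)
    truth <- generate_truth_map(cfg$shape, specs,
                                region_scale = cfg$region_scale,
                                seed = substream_seed(seed_d, 1L))
    scene <- generate_scene(truth, specs, seed = substream_seed(seed_d, 2L))
    bands <- scene$optical
    thermal <- scene$thermal
    meta <- scene$meta
    roles <- attr(scene, "roles")
    training <- sample_truth_points(truth, cfg$n_train,
                                    seed = substream_seed(seed_d, 3L))
    # held-out reference points: mask training pixels, then redraw
    masked <- truth
    masked$labels[cbind(training$row, training$col)] <- NA_integer_
    reference <- sample_class_points(masked, cfg$n_test,
                                     seed = substream_seed(seed_d, 4L))
  } else {
    sc <- cfg$scenes[[paste0("t", which_date)]]
    meta <- read_scene_meta(sc$meta)
    first <- read_band(sc$bands, 1L)
    nb <- 1L
    bands <- list(first)
    repeat {
      nxt <- tryCatch(read_band(sc$bands, nb + 1L), error = function(e) NULL)
      if (is.null(nxt)) break
      nb <- nb + 1L
      bands[[nb]] <- nxt
    }
    thermal <- read_band(sc$thermal)
    roles <- list(red = nb - 1L, nir = nb)
    truth <- NULL
    training <- utils::read.csv(sc$training, stringsAsFactors = FALSE)
    reference <- if (!is.null(sc$reference))
      utils::read.csv(sc$reference, stringsAsFactors = FALSE) else NULL
  }

  radiance <- if (meta$sensor == "TM") toa_radiance_tm(thermal, meta)
              else toa_radiance_oli(thermal, meta)
  bt <- brightness_temperature(radiance, meta)
  nd <- ndvi(red = bands[[roles$red]], nir = bands[[roles$nir]])
  pv <- proportion_vegetation(nd)
  e <- emissivity(pv)
  lst <- land_surface_temperature(bt, e, meta, mode = cfg$lst_mode)

  sigs <- extract_signatures(bands, training)
  lulc <- classify_mlc(bands, sigs, priors = cfg$priors)

  em <- NULL; acc <- NULL
  if (!is.null(reference)) {
    em <- build_error_matrix(lulc, reference)
    acc <- accuracy_summary(em)
  }
  areas <- class_areas(lulc)
  zonal <- class_means(lst, nd, lulc)
  fits <- fit_lst_ndvi_by_class(lst, nd, lulc, n_per_class = cfg$n_relate,
                                seed = substream_seed(seed_d, 5L))
  list(year = yr, truth = truth, bands = bands, thermal = thermal,
       meta = meta, radiance = radiance, bt = bt, ndvi = nd, pv = pv,
       emissivity = e, lst = lst, training = training,
       reference = reference, signatures = sigs, lulc = lulc,
       error_matrix = em, accuracy = acc, areas = areas, zonal = zonal,
       fits = fits)
}

#' Run the full two-date LULC/LST analysis
#'
#' Orchestrates, for each date: scene synthesis (or ingestion), the thermal
#' chain (radiance, brightness temperature), the surface products (NDVI,
#' proportion of vegetation, emissivity, LST), maximum-likelihood
#' classification from sampled training points, held-out accuracy
#' assessment, and per-class area, zonal-mean and LST-NDVI regression
#' tables; then the cross-date change table. All tables are written as CSV
#' into `config$out_dir` along with a JSON manifest; optionally the LULC,
#' LST and NDVI rasters are written as ASCII grids. Identical config and
#' seed give bit-identical outputs. Any stage failure aborts with the stage
#' name and leaves a `FAILED` marker in the output directory.
#'
#' @param config A [run_config].
#'
#' @return Invisibly, a list with the per-date results (`t1`, `t2`), the
#'   `change` table and the `manifest` (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(out_dir, "FAILED"))

  dates <- list()
  for (i in 1:2) {
    nm <- paste0("t", i)
    dates[[nm]] <- run_stage(paste0("analyse_", nm), out_dir,
                             analyse_date(config, i))
  }
  change <- run_stage("change_table", out_dir,
                      change_table(dates$t1$areas, dates$t2$areas,
                                   interval_years = config$interval_years))

  files <- character(0)
  emit_csv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  run_stage("write_outputs", out_dir, {
    for (nm in names(dates)) {
      d <- dates[[nm]]
      yr <- d$year
      emit_csv(d$areas, sprintf("areas_%s.csv", yr))
      emit_csv(d$zonal, sprintf("zonal_means_%s.csv", yr))
      emit_csv(d$fits, sprintf("lst_ndvi_regression_%s.csv", yr))
      if (!is.null(d$accuracy)) {
        acc <- d$accuracy
        acc$overall_accuracy_pct <- attr(acc, "overall_accuracy_pct")
        acc$kappa <- attr(acc, "kappa")
        emit_csv(acc, sprintf("accuracy_%s.csv", yr))
        emit_csv(as.data.frame.matrix(unclass(d$error_matrix)),
                 sprintf("error_matrix_%s.csv", yr))
      }
      if (config$write_rasters) {
        for (ras in c("lulc", "lst", "ndvi")) {
          p <- file.path(out_dir, sprintf("%s_%s.asc", ras, yr))
          g <- switch(ras,
                      lulc = band_grid(d$lulc$labels,
                                       pixel_size_m = d$lulc$pixel_size_m,
                                       band_id = "lulc"),
                      lst = d$lst, ndvi = d$ndvi)
          write_band(g, p)
          files <- c(files, p)
          if (ras == "lulc") {
            cp <- file.path(out_dir, sprintf("lulc_classes_%s.json", yr))
            jsonlite::write_json(as.list(stats::setNames(
              d$lulc$class_names, seq_along(d$lulc$class_names))), cp,
              auto_unbox = TRUE)
            files <- c(files, cp)
          }
        }
      }
    }
    emit_csv(change, "change_table.csv")
  })

  cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "scenes")],
                               auto_unbox = TRUE, null = "null", digits = NA)
  cfg_path <- file.path(out_dir, "config.json")
  writeLines(cfg_json, cfg_path)
  manifest <- list(
    package = "lulcst",
    version = as.character(utils::packageVersion("lulcst")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    files = basename(c(files, cfg_path))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(t1 = dates$t1, t2 = dates$t2, change = change,
                 manifest = manifest))
}
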