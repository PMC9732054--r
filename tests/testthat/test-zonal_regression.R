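test_that("class means average only usable pixels per class", {
  lab <- label_map(matrix(c(1L, 1L, 2L, 2L), 2, 2), c("c1", "c2"))
  lst <- band_grid(matrix(c(30, 30, 20, 40), 2, 2))
  nd <- band_grid(matrix(c(0.5, 0.7, -0.1, 0.1), 2, 2))
  cm <- class_means(lst, nd, lab)
  expect_equal(cm$mean_lst_c, c(30, 30))
  expect_equal(cm$mean_ndvi, c(0.6, 0))
  expect_equal(cm$n_pixels, c(2L, 2L))

  # constant field: every class mean equals the constant
  const <- band_grid(matrix(7, 2, 2))
  expect_equal(class_means(const, nd, lab)$mean_lst_c, c(7, 7))

  # nodata excluded from numerator and denominator
  lst$values[1, 1] <- NA
  cm2 <- class_means(lst, nd, lab)
  expect_equal(cm2$mean_lst_c[1], 30)
  expect_equal(cm2$n_pixels[1], 1L)

  # class entirely nodata is omitted with a warning
  lst$values[, 1] <- NA
  expect_warning(cm3 <- class_means(lst, nd, lab), "omitted")
  expect_identical(cm3$class, "c2")
})

test_that("per-class point sampling is seeded, distinct and label-true", {
  specs <- default_class_specs("2010")
  truth <- generate_truth_map(c(80, 80), specs, region_scale = 10, seed = 3)
  pts <- sample_class_points(truth, 20, seed = 5)
  expect_identical(nrow(pts), 120L)
  expect_identical(as.integer(table(pts$label)), rep(20L, 6))
  got <- truth$class_names[truth$labels[cbind(pts$row, pts$col)]]
  expect_identical(got, pts$label)
  expect_false(anyDuplicated(pts[c("row", "col")]) > 0)
  expect_identical(sample_class_points(truth, 20, seed = 5), pts)
  expect_false(identical(sample_class_points(truth, 20, seed = 6), pts))

  one <- sample_class_points(truth, 1, seed = 1)
  expect_identical(nrow(one), 6L)
  expect_error(sample_class_points(truth, 10000, seed = 1),
               "has only .* pixels")
})

test_that("OLS fit matches closed-form slope, intercept and R-squared", {
  # exactly collinear input; summary.lm warns about the perfect fit
  f <- suppressWarnings(fit_lst_ndvi(c(30, 29, 28), c(0.1, 0.2, 0.3)))
  expect_equal(f$slope, -10, tolerance = 1e-12)
  expect_equal(f$intercept, 31, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)

  f2 <- fit_lst_ndvi(c(30, 20, 25), c(0, 1, 2))
  expect_equal(f2$slope, -2.5, tolerance = 1e-12)
  expect_equal(f2$intercept, 27.5, tolerance = 1e-12)
  expect_equal(f2$r_squared, 0.25, tolerance = 1e-12)

  # duplicating every point changes nothing
  f3 <- fit_lst_ndvi(rep(c(30, 20, 25), 2), rep(c(0, 1, 2), 2))
  expect_equal(f3$slope, f2$slope)
  expect_equal(f3$intercept, f2$intercept)
  expect_equal(f3$r_squared, f2$r_squared)

  expect_error(fit_lst_ndvi(c(1, 2), c(0, 1)), "3 point")
  expect_error(fit_lst_ndvi(c(1, 2, 3), c(0.5, 0.5, 0.5)), "identical")
})

test_that("the fit passes through the centroid and R2 = 1 - SSE/SST", {
  set.seed(40)
  for (i in 1:20) {
    x <- rnorm(20)
    y <- 3 * x + rnorm(20)
    f <- fit_lst_ndvi(y, x)
    expect_equal(f$slope * mean(x) + f$intercept, mean(y), tolerance = 1e-9)
    sse <- sum((y - (f$slope * x + f$intercept))^2)
    sst <- sum((y - mean(y))^2)
    expect_equal(f$r_squared, 1 - sse / sst, tolerance = 1e-9)
    # R2 equals the squared Pearson correlation
    expect_equal(f$r_squared, cor(x, y)^2, tolerance = 1e-9)
  }
})

test_that("per-class regression table covers each sampled class", {
  ts <- make_test_scene(shape = c(60, 60), seed = 10)
  nd <- ndvi(ts$scene$optical[[2]], ts$scene$optical[[3]])
  rad <- toa_radiance_tm(ts$scene$thermal, ts$scene$meta)
  bt <- brightness_temperature(rad, ts$scene$meta)
  lst <- land_surface_temperature(bt, emissivity(proportion_vegetation(nd)),
                                  ts$scene$meta)
  fits <- fit_lst_ndvi_by_class(lst, nd, ts$truth, n_per_class = 20,
                                seed = 4)
  expect_setequal(fits$class, ts$truth$class_names)
  expect_true(all(fits$n_points == 20))
  expect_true(all(fits$r_squared >= 0 & fits$r_squared <= 1, na.rm = TRUE))
})
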