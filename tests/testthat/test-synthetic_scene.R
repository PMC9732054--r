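test_that("truth maps hit target fractions and are seed-deterministic", {
  fr2010 <- c(urbanized = 0.199, forests = 0.392, agricultural = 0.341,
              bare = 0.014, rocks = 0.049, water = 0.006)
  specs <- default_class_specs("2010", area_fractions = fr2010 / sum(fr2010))
  tm <- generate_truth_map(c(200, 200), specs, region_scale = 20, seed = 17)
  got <- tabulate(tm$labels, 6) / (200 * 200)
  want <- fr2010 / sum(fr2010)
  expect_true(all(abs(got - want) < 0.05))
  # the tile fill is actually exact to within one pixel per class
  expect_true(all(abs(got - want) < 1.5 / (200 * 200) + 1e-12))

  expect_identical(generate_truth_map(c(200, 200), specs, 20, seed = 17)$labels,
                   tm$labels)
  expect_false(identical(
    generate_truth_map(c(200, 200), specs, 20, seed = 18)$labels, tm$labels))
})

test_that("degenerate and invalid fraction sets are handled", {
  solo <- list(class_spec("all", c(10, 20, 30), 1, 100, 1, 1))
  tm <- generate_truth_map(c(15, 15), solo, region_scale = 5, seed = 1)
  expect_true(all(tm$labels == 1L))

  bad <- list(class_spec("a", 1, 1, 10, 1, 0.5),
              class_spec("b", 2, 1, 20, 1, 0.3))
  expect_error(generate_truth_map(c(10, 10), bad, 5, seed = 1), "sum")
  specs <- default_class_specs("2010")
  expect_error(generate_truth_map(c(10, 10), specs, region_scale = 11,
                                  seed = 1), "region_scale")
})

test_that("class_spec validates covariance and fractions", {
  expect_error(class_spec("a", c(1, 2), matrix(c(1, 2, 3, 1), 2, 2), 10, 1,
                          0.5), "symmetric")
  expect_error(class_spec("a", c(1, 2), matrix(c(1, 2, 2, 1), 2, 2), 10, 1,
                          0.5), "semi-definite")
  expect_error(class_spec("a", 1, 1, 10, -1, 0.5), "thermal_dn_sd")
  expect_error(class_spec("a", 1, 1, 10, 1, 1.5), "area_fraction")
})

test_that("scenes are seed-deterministic with DNs in the calibrated range", {
  ts <- make_test_scene(shape = c(40, 40), seed = 23)
  again <- generate_scene(ts$truth, ts$specs, seed = 23)
  for (b in 1:3)
    expect_identical(ts$scene$optical[[b]]$values, again$optical[[b]]$values)
  expect_identical(ts$scene$thermal$values, again$thermal$values)

  m <- ts$scene$meta
  for (g in c(ts$scene$optical, list(ts$scene$thermal))) {
    expect_true(all(g$values >= m$qcal_min))
    expect_true(all(g$values <= m$qcal_max))
  }
})

test_that("noise-free scenes reproduce the class mean vectors exactly", {
  specs <- default_class_specs("2010", band_sd = 0, thermal_sd = 0)
  truth <- generate_truth_map(c(30, 30), specs, region_scale = 6, seed = 2)
  sc <- generate_scene(truth, specs, seed = 2)
  for (cl in names(specs)) {
    idx <- truth$labels == match(cl, truth$class_names)
    if (!any(idx)) next
    for (b in 1:3)
      expect_true(all(sc$optical[[b]]$values[idx] ==
                        specs[[cl]]$band_means[b]))
    expect_true(all(sc$thermal$values[idx] == specs[[cl]]$thermal_dn_mean))
  }
  # a truth-map class without a spec is rejected
  expect_error(generate_scene(truth, specs[-1], seed = 2), "urbanized")
})

test_that("default spectra order class-mean NDVI like the real classes", {
  ts <- make_test_scene(shape = c(80, 80), seed = 31)
  nd <- ndvi(ts$scene$optical[[2]], ts$scene$optical[[3]])
  mean_ndvi <- vapply(seq_along(ts$truth$class_names), function(k)
    mean(nd$values[ts$truth$labels == k]), numeric(1))
  names(mean_ndvi) <- ts$truth$class_names
  expect_true(mean_ndvi[["forests"]] > mean_ndvi[["agricultural"]])
  expect_true(mean_ndvi[["agricultural"]] > mean_ndvi[["urbanized"]])
  expect_true(mean_ndvi[["urbanized"]] > mean_ndvi[["bare"]])
  expect_true(mean_ndvi[["bare"]] > mean_ndvi[["rocks"]])
  expect_true(mean_ndvi[["rocks"]] >= mean_ndvi[["water"]])
})

test_that("truth points are exact per-class draws matching the map", {
  specs <- default_class_specs("2010")
  truth <- generate_truth_map(c(100, 100), specs, region_scale = 10,
                              seed = 11)
  pts <- sample_truth_points(truth, 40, seed = 7)
  expect_identical(nrow(pts), 240L)
  expect_identical(as.integer(table(pts$label)), rep(40L, 6))
  expect_identical(truth$class_names[truth$labels[cbind(pts$row, pts$col)]],
                   pts$label)
  expect_identical(sample_truth_points(truth, 1, seed = 1)$label,
                   truth$class_names)
  expect_error(sample_truth_points(truth, 100000, seed = 1),
               "has only .* pixels")
})
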