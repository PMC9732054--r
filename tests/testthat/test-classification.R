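test_that("signatures match hand-computed mean and covariance", {
  X <- rbind(c(10, 20), c(12, 24), c(9, 21), c(11, 19), c(13, 26))
  # two classes laid out on the two rows of a 2 x 5 grid
  v1 <- matrix(0, 2, 5); v1[1, ] <- X[, 1]; v1[2, ] <- c(50, 52, 51, 49, 50)
  v2 <- matrix(0, 2, 5); v2[1, ] <- X[, 2]; v2[2, ] <- c(80, 81, 79, 80, 82)
  bands <- list(band_grid(v1), band_grid(v2))
  train <- data.frame(row = c(rep(1, 5), rep(2, 5)),
                      col = rep(1:5, 2),
                      label = rep(c("a", "b"), each = 5))
  sigs <- extract_signatures(bands, train)
  expect_equal(sigs[["a"]]$mean, colMeans(X), ignore_attr = TRUE)
  expect_equal(sigs[["a"]]$cov, cov(X), ignore_attr = TRUE)
  expect_identical(sigs[["a"]]$n_train, 5L)
})

test_that("degenerate training samples get a ridge covariance", {
  v <- matrix(7, 2, 2)
  train <- data.frame(row = c(1, 2), col = c(1, 1), label = "a")
  sigs <- extract_signatures(list(band_grid(v)), train)
  expect_equal(sigs[["a"]]$mean, 7, ignore_attr = TRUE)
  expect_equal(sigs[["a"]]$cov, matrix(1e-6), ignore_attr = TRUE)
})

test_that("training points on nodata pixels are skipped with a warning", {
  v <- matrix(c(NA, 1, 2, 3, 4, 5), 2, 3)
  train <- data.frame(row = c(1, 2, 1, 2, 1, 2), col = c(1, 1, 2, 2, 3, 3),
                      label = "a")
  expect_warning(sigs <- extract_signatures(list(band_grid(v)), train),
                 "skipped")
  expect_identical(sigs[["a"]]$n_train, 5L)
  # too few usable points names the class
  small <- data.frame(row = 1, col = 1, label = "empty")
  expect_error(
    suppressWarnings(extract_signatures(list(band_grid(v)), small)),
    "empty")
})

test_that("one-band MLC picks the nearer mean and breaks ties low", {
  v1 <- matrix(c(rep(10, 4), rep(100, 4)), 2, 4)
  bands <- list(band_grid(v1))
  train <- data.frame(row = rep(1:2, each = 4), col = rep(1:4, 2),
                      label = rep(c("lo", "hi"), each = 4))
  # give both classes identical unit variance via hand-built signatures
  sigs <- structure(list(
    lo = list(label = "lo", mean = 10, cov = matrix(1), n_train = 4),
    hi = list(label = "hi", mean = 100, cov = matrix(1), n_train = 4)),
    class = "class_signatures")
  got <- classify_mlc(list(band_grid(matrix(12))), sigs)
  expect_identical(got$class_names[got$labels[1, 1]], "lo")
  # exact midpoint: tie goes to the lowest class index
  mid <- classify_mlc(list(band_grid(matrix(55))), sigs)
  expect_identical(mid$labels[1, 1], 1L)
  # nodata propagates
  nd <- classify_mlc(list(band_grid(matrix(c(12, NA), 1, 2))), sigs)
  expect_true(is.na(nd$labels[1, 2]))
})

test_that("MLC equals the brute-force Gaussian density oracle", {
  ts <- make_test_scene(shape = c(30, 30), seed = 3)
  train <- sample_truth_points(ts$truth, 12, seed = 9)
  sigs <- extract_signatures(ts$scene$optical, train)
  pred <- classify_mlc(ts$scene$optical, sigs)
  X <- sapply(ts$scene$optical, function(b) as.vector(b$values))
  want <- oracle_mlc(X, sigs)
  expect_identical(as.vector(pred$labels), as.integer(want))
})

test_that("decisions are invariant to common band scaling", {
  ts <- make_test_scene(shape = c(20, 20), seed = 4)
  train <- sample_truth_points(ts$truth, 10, seed = 2)
  sigs <- extract_signatures(ts$scene$optical, train)
  pred <- classify_mlc(ts$scene$optical, sigs)

  cc <- 2.5
  scaled_bands <- lapply(ts$scene$optical, function(b)
    band_grid(b$values * cc, b$pixel_size_m, b$band_id))
  scaled_sigs <- structure(lapply(sigs, function(s)
    list(label = s$label, mean = s$mean * cc, cov = s$cov * cc^2,
         n_train = s$n_train)), class = "class_signatures")
  names(scaled_sigs) <- names(sigs)
  pred2 <- classify_mlc(scaled_bands, scaled_sigs)
  expect_identical(pred$labels, pred2$labels)
})

test_that("equal priors + shared covariance reduce to minimum Mahalanobis", {
  set.seed(8)
  S <- matrix(c(4, 1, 1, 3), 2, 2)
  mus <- list(c(0, 0), c(6, 1), c(2, 7))
  sigs <- structure(lapply(seq_along(mus), function(k)
    list(label = paste0("c", k), mean = mus[[k]], cov = S, n_train = 10)),
    class = "class_signatures")
  names(sigs) <- paste0("c", 1:3)
  X <- matrix(rnorm(400, sd = 4), 200, 2)
  bands <- list(band_grid(matrix(X[, 1], 20, 10)),
                band_grid(matrix(X[, 2], 20, 10)))
  pred <- classify_mlc(bands, sigs)
  Sinv <- solve(S)
  maha <- sapply(mus, function(mu) {
    d <- sweep(X, 2, mu)
    rowSums((d %*% Sinv) * d)
  })
  expect_identical(as.vector(pred$labels),
                   as.integer(apply(maha, 1, which.min)))
})

test_that("noise-free scenes are recovered exactly", {
  specs <- default_class_specs("2010", band_sd = 0, thermal_sd = 0)
  truth <- generate_truth_map(c(40, 40), specs, region_scale = 8, seed = 6)
  scene <- generate_scene(truth, specs, seed = 6)
  train <- sample_truth_points(truth, 5, seed = 1)
  sigs <- extract_signatures(scene$optical, train)
  pred <- classify_mlc(scene$optical, sigs)
  expect_identical(pred$labels, truth$labels)
})

test_that("priors are validated and can shift decisions", {
  sigs <- structure(list(
    a = list(label = "a", mean = 0, cov = matrix(1), n_train = 5),
    b = list(label = "b", mean = 2, cov = matrix(1), n_train = 5)),
    class = "class_signatures")
  g <- list(band_grid(matrix(1)))  # exact midpoint
  expect_error(classify_mlc(g, sigs, priors = c(0.6, 0.6)), "summing to 1")
  expect_identical(classify_mlc(g, sigs, priors = c(0.9, 0.1))$labels[1, 1], 1L)
  expect_identical(classify_mlc(g, sigs, priors = c(0.1, 0.9))$labels[1, 1], 2L)
})
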