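# shared fixtures: all built in code at test time

tm_meta <- function() default_scene_meta("TM")

# a small well-separated six-class scene with known truth; fractions are
# balanced so even small scenes can supply per-class samples
make_test_scene <- function(shape = c(60, 60), seed = 1L, year = "2010",
                            band_sd = 3, thermal_sd = 2,
                            region_scale = 10L,
                            area_fractions = c(urbanized = 0.22,
                                               forests = 0.22,
                                               agricultural = 0.20,
                                               bare = 0.12, rocks = 0.12,
                                               water = 0.12)) {
  specs <- default_class_specs(year = year, band_sd = band_sd,
                               thermal_sd = thermal_sd,
                               area_fractions = area_fractions)
  truth <- generate_truth_map(shape, specs, region_scale = region_scale,
                              seed = seed)
  scene <- generate_scene(truth, specs, seed = seed)
  list(specs = specs, truth = truth, scene = scene)
}

# straight-line independent oracle for the thermal chain (kept free of
# package functions on purpose)
oracle_radiance_tm <- function(q, lmax, lmin, qmax, qmin) {
  (lmax - lmin) / (qmax - qmin) * (q - qmin) + lmin
}
oracle_bt <- function(l, k1, k2) k2 / log(k1 / l + 1) - 273.15
oracle_ndvi <- function(red, nir) (nir - red) / (nir + red)
oracle_pv <- function(nd, lo, hi) pmin(pmax((nd - lo) / (hi - lo), 0), 1)^2
oracle_emis <- function(pv) 0.004 * pv + 0.986
oracle_lst <- function(bt, e, lam, c2 = 14388) {
  bt / (1 + (lam * bt / c2) * log(e))
}

# brute-force Gaussian density classifier (solve-based, independent of the
# cholesky path used by classify_mlc)
oracle_mlc <- function(X, sigs, priors = NULL) {
  K <- length(sigs)
  if (is.null(priors)) priors <- rep(1 / K, K)
  G <- sapply(seq_len(K), function(k) {
    mu <- sigs[[k]]$mean
    S <- sigs[[k]]$cov
    diff <- sweep(X, 2, mu)
    quad <- rowSums((diff %*% solve(S)) * diff)
    log(priors[k]) - 0.5 * determinant(S, logarithm = TRUE)$modulus - 0.5 * quad
  })
  apply(G, 1, which.max)
}
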