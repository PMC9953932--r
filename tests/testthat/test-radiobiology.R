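test_that("colony surviving fraction handles ratios, clipping and zeros", {
  expect_equal(colony_sf(50, 50), 1.0)
  expect_equal(colony_sf(5, 50), 0.1)
  expect_warning(sf <- colony_sf(60, 50), "clipping")
  expect_equal(sf, 1.0)
  expect_error(colony_sf(5, 0), "control")
  expect_error(colony_sf(0, 50), "log-transformed")
  expect_equal(colony_sf(0, 50, zero_policy = "floor"), 0.5 / 50)
})

test_that("LQ fit recovers parameters exactly on noiseless curves", {
  d <- c(0, 1, 2, 4, 6, 8)
  for (true in list(c(0.2, 0.02), c(0.05, 0.05), c(0.4, 0))) {
    sf <- exp(-true[1] * d - true[2] * d^2)
    fit <- fit_lq(d, sf)
    expect_equal(fit$alpha, true[1], tolerance = 1e-6)
    expect_equal(fit$beta, true[2], tolerance = 1e-6)
  }
  # no kill: all SF 1 at positive doses -> alpha = beta = 0
  flat <- fit_lq(c(1, 2, 3), c(1, 1, 1))
  expect_equal(flat$alpha, 0)
  expect_equal(flat$beta, 0)
  # non-negativity active: pure-quadratic data stay on the boundary
  sfq <- exp(-0.03 * d^2)
  fitq <- fit_lq(d, sfq)
  expect_gte(fitq$alpha, 0)
  expect_equal(fitq$beta, 0.03, tolerance = 1e-6)
  expect_error(fit_lq(c(2, 2, 2), c(0.5, 0.5, 0.5)), "distinct")
})

test_that("LQ fit recovers parameters from Poisson-noised counts", {
  set.seed(101)
  d <- c(1, 2, 3, 4, 6, 8)
  control <- 200
  sf_true <- exp(-0.2 * d - 0.02 * d^2)
  counts <- rpois(length(d), control * sf_true)
  fit <- fit_lq(d, colony_sf(counts, control, zero_policy = "floor"))
  iso_true <- oracle_lq_iso_bisect(0.2, 0.02, 0.1)
  expect_equal(dose_at_sf(fit, 0.1), iso_true, tolerance = 0.1)
})

test_that("iso-effect dose inversion matches a bisection oracle", {
  p <- list(alpha = 0.2, beta = 0.02)
  expect_equal(dose_at_sf(p, 0.1), 6.83762, tolerance = 1e-5)
  expect_equal(dose_at_sf(p, 0.1), oracle_lq_iso_bisect(0.2, 0.02, 0.1),
               tolerance = 1e-9)
  # beta = 0 closed form: SF = e^-alpha at D = 1
  expect_equal(dose_at_sf(list(alpha = 0.7, beta = 0), exp(-0.7)), 1.0,
               tolerance = 1e-12)
  # round trip over a parameter sweep
  set.seed(102)
  for (i in 1:30) {
    q <- list(alpha = runif(1, 0.01, 0.6), beta = runif(1, 0, 0.08))
    s <- runif(1, 0.01, 0.9)
    expect_equal(lq_sf(q, dose_at_sf(q, s)), s, tolerance = 1e-9)
  }
  expect_error(dose_at_sf(list(alpha = 0, beta = 0), 0.1), "not both zero")
  expect_error(dose_at_sf(p, 1.2), "sf_level")
})

test_that("iso-effect dose is decreasing in sf_level, alpha and beta", {
  base <- list(alpha = 0.2, beta = 0.02)
  expect_gt(dose_at_sf(base, 0.05), dose_at_sf(base, 0.1))
  expect_gt(dose_at_sf(base, 0.1), dose_at_sf(base, 0.5))
  expect_gt(dose_at_sf(base, 0.1),
            dose_at_sf(list(alpha = 0.3, beta = 0.02), 0.1))
  expect_gt(dose_at_sf(base, 0.1),
            dose_at_sf(list(alpha = 0.2, beta = 0.04), 0.1))
})

test_that("curve iso-dose supports LQ inversion and log-linear interpolation", {
  d <- c(0.5, 1, 2, 3, 5, 7)
  sf <- exp(-0.25 * d - 0.015 * d^2)
  expect_equal(curve_iso_dose(d, sf, 0.1, strategy = "lq"),
               dose_at_sf(fit_lq(d, sf), 0.1), tolerance = 1e-12)
  # two-point log-linear interpolation, frozen from an approx() oracle
  expect_equal(curve_iso_dose(c(1, 3), c(0.5, 0.05), 0.1,
                              strategy = "loglinear"),
               2.39794, tolerance = 1e-5)
  expect_error(curve_iso_dose(c(1, 3), c(0.9, 0.5), 0.1,
                              strategy = "loglinear"),
               "outside the observed")
  expect_warning(curve_iso_dose(c(1, 2, 3), c(0.5, 0.6, 0.05), 0.1,
                                strategy = "loglinear"),
                 "monotone")
})

test_that("beam RBE excludes boron and credits gamma at weight 1", {
  comps <- dose_components(d_b = 0, d_n = 0.8, d_h = 1.19, d_gamma = 0.48)
  expect_equal(estimate_rbe_beam(6.45, comps), 3.0, tolerance = 1e-9)
  nog <- dose_components(d_b = 0, d_n = 0.8, d_h = 1.19, d_gamma = 0)
  expect_equal(estimate_rbe_beam(6.45, nog), 6.45 / 1.99, tolerance = 1e-12)
  expect_error(estimate_rbe_beam(6.45, dose_components(d_b = 1, d_n = 1)),
               "d_b = 0")
  expect_error(estimate_rbe_beam(6.45, dose_components(d_gamma = 1)),
               "d_n \\+ d_h")
  # scaling invariance: scaling components and the photon-equivalent
  # requirement by k leaves the RBE unchanged
  for (k in c(0.5, 2, 3.7)) {
    sc <- dose_components(0, 0.8 * k, 1.19 * k, 0.48 * k)
    lq_eq <- 3.0 * (0.8 + 1.19) * k + 0.48 * k
    expect_equal(estimate_rbe_beam(lq_eq, sc), 3.0, tolerance = 1e-12)
  }
})

test_that("CBE estimation is the exact inverse of the photon-equivalent dose", {
  set.seed(103)
  for (i in 1:40) {
    comp <- dose_components(d_b = runif(1, 0.1, 3), d_n = runif(1, 0, 1),
                            d_h = runif(1, 0, 1), d_gamma = runif(1, 0, 1))
    cbe <- runif(1, 0.5, 10); rbe <- runif(1, 1, 4)
    lq_iso <- photon_equivalent(comp, rbe_weights(cbe, rbe))
    expect_equal(estimate_cbe(lq_iso, comp, rbe), cbe, tolerance = 1e-9)
  }
  # planted published-scale fixture
  comp <- dose_components(d_b = 0.5, d_n = 0.12, d_h = 0.18, d_gamma = 0.3)
  lq_iso <- photon_equivalent(comp, rbe_weights(8.43, 3.0))
  expect_equal(estimate_cbe(lq_iso, comp, 3.0), 8.43, tolerance = 1e-9)
  # limit: no beam components
  only_b <- dose_components(d_b = 2)
  expect_equal(estimate_cbe(6.45, only_b, 3.0), 6.45 / 2, tolerance = 1e-12)
  expect_error(estimate_cbe(6.45, dose_components(d_gamma = 1), 3), "d_b > 0")
  expect_error(estimate_cbe(0.1, dose_components(d_b = 1, d_gamma = 1), 3),
               "negative numerator")
})

test_that("effectiveness chain recovers planted values on noiseless data", {
  cfg <- study_config()
  dat <- gen_clonogenic(cfg, seed = 7, noise = "none")
  est <- estimate_effectiveness(dat)
  expect_equal(est$lq$alpha, cfg$clonogenic$alpha, tolerance = 1e-6)
  expect_equal(est$lq$beta, cfg$clonogenic$beta, tolerance = 1e-6)
  expect_equal(est$rbe_beam, cfg$clonogenic$rbe_beam, tolerance = 1e-6)
  expect_equal(unname(est$cbe[c("dpa_bstpg", "bpa", "bsh")]),
               c(8.43, 3.80, 2.41), tolerance = 1e-6)
  expect_equal(unname(est$iso_doses["dpa_bstpg"]), 0.88, tolerance = 1e-6)
})
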