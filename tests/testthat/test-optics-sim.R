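test_that("emission spectrum sampling honours the contract", {
  expect_length(sample_emission_spectrum(0), 0)
  e <- sample_emission_spectrum(100000, emission_spectrum(2.58, 0.15), seed = 1)
  expect_true(all(e > 0))
  expect_lt(abs(mean(e) - 2.58), 0.01)
  mono <- sample_emission_spectrum(50, emission_spectrum(2.58, 0), seed = 1)
  expect_identical(mono, rep(2.58, 50))
  expect_error(sample_emission_spectrum(-1), "non-negative")
})

test_that("isotropic directions are unit vectors with no preferred axis", {
  one <- isotropic_directions(1, seed = 3)
  expect_equal(sqrt(sum(one^2)), 1, tolerance = 1e-12)
  d <- isotropic_directions(100000, seed = 4)
  expect_equal(max(abs(sqrt(rowSums(d^2)) - 1)), 0, tolerance = 1e-12)
  expect_true(all(abs(colMeans(d)) < 0.01))
  expect_lt(abs(mean(d[, 3] < 0) - 0.5), 0.01)
})

test_that("Fresnel reflectance matches closed forms and conserves energy", {
  # normal incidence off an n = 2.15 / 1.56 interface
  expect_equal(fresnel_reflectance(1, 2.15, 1.56),
               ((2.15 - 1.56) / (2.15 + 1.56))^2, tolerance = 1e-12)
  # index match: no reflection at any angle
  cosines <- seq(0.05, 1, by = 0.05)
  expect_equal(fresnel_reflectance(cosines, 1.5, 1.5), rep(0, length(cosines)))
  # 60 degrees is beyond the ~46.5 degree critical angle
  expect_identical(fresnel_reflectance(0.5, 2.15, 1.56), 1)
  # R stays a probability over a fuzzed grid
  r <- fresnel_reflectance(runif(500, 1e-6, 1), 2.15, 1.56)
  expect_true(all(r >= 0 & r <= 1))
  expect_error(fresnel_reflectance(0, 2.15, 1.56), "cos_incidence")
  expect_error(fresnel_reflectance(1.1, 2.15, 1.56), "cos_incidence")
})

test_that("refraction follows Snell's law in vector form", {
  n_hat <- c(0, 0, -1)
  # normal incidence: direction unchanged
  expect_equal(refract(c(0, 0, -1), n_hat, 2.15, 1.56), c(0, 0, -1),
               tolerance = 1e-12)
  # 30 degrees in -> sin(theta_out) = 2.15 * 0.5 / 1.56
  d_in <- c(sin(pi / 6), 0, -cos(pi / 6))
  t <- refract(d_in, n_hat, 2.15, 1.56)
  expect_equal(sqrt(sum(t^2)), 1, tolerance = 1e-12)
  sin_out <- sqrt(t[1]^2 + t[2]^2)
  expect_equal(sin_out, 2.15 * 0.5 / 1.56, tolerance = 1e-9)
  expect_equal(t[2], 0, tolerance = 1e-12) # tangential plane preserved
  # beyond the critical angle: total-internal-reflection signal, no error
  d60 <- c(sin(pi / 3), 0, -cos(pi / 3))
  expect_null(refract(d60, n_hat, 2.15, 1.56))
  expect_error(refract(c(0, 0, 1), n_hat, 2.15, 1.56), "into the surface")
})

test_that("single-photon tracing handles ballistic and absorbing cases", {
  clear <- crystal_geometry(attenuation_length = Inf, n_coupling = 2.15)
  res <- trace_photon(c(0, 0, 1), c(0, 0, -1), geometry = clear, seed = 1)
  expect_identical(res$outcome, "exit")
  expect_equal(res$record$X, 0)
  expect_equal(res$record$Y, 0)
  expect_equal(unlist(res$record[, c("dX", "dY", "dZ")]),
               c(dX = 0, dY = 0, dZ = -1), tolerance = 1e-12)

  black <- crystal_geometry(reflector_reflectivity = 0, attenuation_length = Inf)
  res2 <- trace_photon(c(0, 0, 5), c(1, 0, 0), geometry = black, seed = 1)
  expect_identical(res2$outcome, "absorbed")

  expect_error(trace_photon(c(5, 0, 1), c(0, 0, -1)), "inside the crystal")
})

test_that("every photon terminates and outcomes partition the bundle", {
  geom <- crystal_geometry(max_bounces = 50)
  set.seed(9)
  n <- 5000
  res <- scintigan:::trace_bundle(
    matrix(rep(c(0.5, 0.5, 1.0), each = n), n, 3),
    isotropic_directions(n),
    rep(2.58, n), geom
  )
  expect_true(all(res$status %in% 1:3))
  expect_identical(sum(res$status == 1L) + sum(res$status == 2L) +
                     sum(res$status == 3L), as.integer(n))
  expect_identical(nrow(res$exits), sum(res$status == 1L))
})

test_that("lossless geometry lets essentially every photon escape", {
  lossless <- crystal_geometry(
    reflector_reflectivity = 1, attenuation_length = Inf,
    n_coupling = 2.15, max_bounces = 10000
  )
  ps <- simulate_point(c(0, 0, 5), 10000, lossless, seed = 2)
  expect_gte(nrow(ps) / 10000, 0.999)
})

test_that("simulate_point returns a valid, reproducible phase-space table", {
  empty <- simulate_point(c(0, 0, 5), 0, seed = 1)
  expect_identical(names(empty), scintigan:::phase_space_columns)
  expect_identical(nrow(empty), 0L)

  ps <- simulate_point(c(0.5, 0.5, 1.0), 30000, seed = 7)
  expect_lte(nrow(ps), 30000)
  expect_gt(nrow(ps), 1000)
  # unit directions pointing out of the crystal, positive energies
  expect_lt(max(abs(sqrt(ps$dX^2 + ps$dY^2 + ps$dZ^2) - 1)), 1e-6)
  expect_true(all(ps$dZ < 0))
  expect_true(all(ps$EKine > 0))
  expect_true(all(abs(ps$X) <= 1.5 & abs(ps$Y) <= 1.5))
  # emission from the (+, +) quadrant biases the detected positions
  expect_gt(mean(ps$X), 0.05)
  expect_gt(mean(ps$Y), 0.05)
  expect_identical(unique(ps$emX), 0.5)

  again <- simulate_point(c(0.5, 0.5, 1.0), 30000, seed = 7)
  expect_identical(ps, again)
  expect_error(simulate_point(c(2, 0, 5), 10), "outside")
})

test_that("detection efficiency falls with wall losses and bulk absorption", {
  eff <- function(reflectivity, attenuation) {
    g <- crystal_geometry(reflector_reflectivity = reflectivity,
                          attenuation_length = attenuation)
    nrow(simulate_point(c(0, 0, 5), 20000, g, seed = 5)) / 20000
  }
  by_refl <- c(eff(1, Inf), eff(0.9, Inf), eff(0.5, Inf))
  expect_true(all(diff(by_refl) < 0))
  by_att <- c(eff(0.95, Inf), eff(0.95, 100), eff(0.95, 10))
  expect_true(all(diff(by_att) < 0))
})

test_that("mirroring the emission point mirrors the X and dX marginals", {
  a <- simulate_point(c(0.5, 0.5, 1.0), 20000, seed = 21)
  b <- simulate_point(c(-0.5, 0.5, 1.0), 20000, seed = 22)
  ks_x <- suppressWarnings(stats::ks.test(a$X, -b$X))$statistic
  ks_dx <- suppressWarnings(stats::ks.test(a$dX, -b$dX))$statistic
  expect_lt(ks_x, 0.02)
  expect_lt(ks_dx, 0.02)
})

test_that("event sampling reproduces the expected photon totals", {
  ev <- sample_events(1000, 1, yield_model(2500), c(0.5, 0.5, 1), seed = 1)
  total <- sum(ev$n_op)
  # compound Poisson: var = lambda * (mean^2 + mean)
  sd_total <- sqrt(1000 * (2500^2 + 2500))
  expect_lt(abs(total - 2.5e6), 3 * sd_total)
  expect_true(all(ev$n_op >= 0))

  none <- sample_events(1e-9, 1e-9, seed = 2)
  expect_identical(nrow(none), 0L)
  expect_identical(sum(none$n_op), 0L)

  zero_yield <- sample_events(100, 1, yield_model(0), seed = 3)
  expect_true(all(zero_yield$n_op == 0L))
  expect_error(sample_events(-1, 1), "positive")
  expect_error(sample_events(1, 0), "positive")
})

test_that("configuration files round-trip the simulator settings", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "geometry:",
    "  reflector_reflectivity: 0.8",
    "  attenuation_length: 150",
    "spectrum:",
    "  mean_energy: 3.1"
  ), path)
  cfg <- read_sim_config(path)
  expect_equal(cfg$geometry$reflector_reflectivity, 0.8)
  expect_equal(cfg$geometry$attenuation_length, 150)
  expect_equal(cfg$geometry$length_z, 10)
  expect_equal(cfg$spectrum$mean_energy, 3.1)
  expect_equal(cfg$yield$mean_photons_per_event, 2400)

  writeLines("geometry:\n  bogus: 1", path)
  expect_error(read_sim_config(path), "bogus")
})
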