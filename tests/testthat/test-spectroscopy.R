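test_that("the lineshape matches the static and Kubo closed forms", {
  d2 <- 4e-4                                   # rad^2/fs^2
  lag <- seq(0, 3000, by = 1)
  ls_static <- lineshape(data.frame(lag_fs = lag, value = rep(d2, 3001)),
                         units = "rad2fs2")
  ref <- static_g(ls_static$t_grid, d2)
  expect_lt(max(abs(ls_static$g - ref)[-1] / ref[-1]), 1e-10)

  tauc <- 100
  ls_kubo <- lineshape(data.frame(lag_fs = lag, value = d2 * exp(-lag / tauc)),
                       units = "rad2fs2")
  refk <- kubo_g(ls_kubo$t_grid, d2, tauc)
  expect_lt(max(abs(ls_kubo$g - refk)[-1] / refk[-1]), 1e-4)

  ls0 <- lineshape(data.frame(lag_fs = lag, value = numeric(3001)),
                   units = "rad2fs2")
  expect_equal(max(abs(ls0$g)), 0)
  expect_equal(ls_kubo$g[1], 0)
  expect_true(all(diff(ls_kubo$g) >= 0))       # non-decreasing
})

test_that("wavenumber input is converted to angular units", {
  lag <- seq(0, 100, by = 1)
  delta_cm <- 100
  ls <- lineshape(data.frame(lag_fs = lag, value = rep(delta_cm^2, 101)))
  d2 <- (2 * pi * speed_of_light_cm_fs() * delta_cm)^2
  expect_equal(ls$delta2, d2, tolerance = 1e-12)
  expect_equal(ls$g[51], static_g(50, d2), tolerance = 1e-6)
})

test_that("non-uniform lag grids are rejected", {
  expect_error(lineshape(data.frame(lag_fs = c(0, 1, 3), value = c(1, 1, 1)),
                         units = "rad2fs2"), "non-uniform")
})

test_that("the static-limit echo rephases at t3 = t1", {
  d2 <- 2e-3
  lag <- seq(0, 1200, by = 1)
  ls <- lineshape(data.frame(lag_fs = lag, value = rep(d2, 1201)),
                  units = "rad2fs2")
  g <- stats::approxfun(ls$t_grid, ls$g)
  t1 <- 60; t2 <- 100
  t3 <- seq(0, 400, by = 1)
  env <- exp(-g(t1) + g(t2) - g(t3) - g(t1 + t2) - g(t2 + t3) +
               g(t1 + t2 + t3))
  ## integrand peaks at t3 = t1 and is symmetric about it
  expect_equal(t3[which.max(env)], t1, tolerance = 1)
  lhs <- env[t3 %in% (t1 - 30:1)]
  rhs <- env[t3 %in% (t1 + 1:30)]
  expect_equal(lhs, rev(rhs), tolerance = 1e-6)
})

test_that("a vanishing lineshape gives a t1-independent intensity", {
  lag <- seq(0, 1500, by = 1)
  ls <- lineshape(data.frame(lag_fs = lag, value = numeric(1501)),
                  units = "rad2fs2")
  surf <- echo_intensity(ls, t1_grid = c(0, 20, 40), t2_grid = c(0, 200),
                         t3_max = 800)
  expect_lt(max(abs(surf$I - surf$I[1, 1])) / surf$I[1, 1], 1e-12)
  expect_false(surf$truncation_ok)     # constant integrand never decays
})

test_that("motional narrowing yields exponential free-induction decay", {
  ## fast modulation: g(t) ~ Gamma t with Gamma = Delta^2 tauc,
  ## so I(t1) ~ exp(-2 Gamma t1) and no echo forms
  d2 <- 0.01; tauc <- 2                        # Delta * tauc = 0.2
  lag <- seq(0, 4000, by = 1)
  ls <- lineshape(data.frame(lag_fs = lag, value = d2 * exp(-lag / tauc)),
                  units = "rad2fs2")
  t1g <- seq(0, 120, by = 20)
  surf <- echo_intensity(ls, t1g, t2_grid = c(500), t3_max = 2000)
  expect_true(all(surf$I >= 0))
  gamma <- d2 * tauc
  ratio <- surf$I[, 1] / surf$I[1, 1]
  ## exact fast-modulation form ln I(t1)/I(0) = -2 [g(t1)] with the Kubo g,
  ## i.e. -2 Gamma (t1 - tauc (1 - exp(-t1/tauc))); the pure -2 Gamma t1
  ## law is its asymptote
  ref <- -2 * gamma * (t1g - tauc * (1 - exp(-t1g / tauc)))
  expect_equal(log(ratio), ref, tolerance = 0.02)
  expect_equal(log(ratio[-(1:2)]), (-2 * gamma * t1g)[-(1:2)],
               tolerance = 0.06)
})

test_that("truncation is self-consistent when no warning is recorded", {
  om <- gen_frequency_process(16, 2000, 5, a0 = 1, tau0_ps = 0.3,
                              tau1_ps = 0.3, delta_cm = 100, seed = 41)
  ftcf <- tcf(om, dt = 5, max_lag = 5000)
  ls <- lineshape(ftcf)
  t1g <- c(0, 2, 4)
  s1 <- echo_intensity(ls, t1g, t2_grid = c(0, 500), t3_max = 1500)
  s2 <- echo_intensity(ls, t1g, t2_grid = c(0, 500), t3_max = 3000)
  expect_true(s1$truncation_ok)
  expect_lt(max(abs(s2$I - s1$I) / s1$I), 1e-3)
})

test_that("S3PE stays flat in the inhomogeneous limit", {
  delta_cm <- 100
  lag <- seq(0, 3000, by = 2)
  static <- data.frame(lag_fs = lag, value = rep(delta_cm^2, length(lag)))
  res <- s3pe_from_ftcf(static, t2_max = 800, t3_max = 2000, fit = FALSE)
  expect_equal(res$curve$C[1], 1)
  expect_true(all(res$curve$C > 0.95))
})

test_that("S3PE decays on the modulation timescale in the Kubo model", {
  ## intermediate modulation, Delta * tauc ~ 1
  tauc_fs <- 1000
  delta_rad <- 1 / tauc_fs                     # rad/fs
  lag <- seq(0, 7000, by = 5)
  kubo <- data.frame(lag_fs = lag, value = delta_rad^2 * exp(-lag / tauc_fs))
  res <- s3pe_from_ftcf(kubo, units_in = "rad2fs2", t2_max = 4000,
                        t3_max = 2500)
  fit <- attr(res$curve, "fit")
  expect_lt(abs(biexp_long_time(fit) - 1) / 1, 0.15)
  ## fast modulation: decay toward the homogeneous plateau on ~tauc
  tauc2 <- 100
  d2 <- (0.1 / tauc2)^2 * 100^2                # Delta * tauc = 0.1... scaled
  kubo2 <- data.frame(lag_fs = seq(0, 5000, by = 5),
                      value = 1e-6 * exp(-seq(0, 5000, by = 5) / tauc2))
  res2 <- s3pe_from_ftcf(kubo2, units_in = "rad2fs2", t2_max = 1500,
                         t3_max = 2500, fit = FALSE)
  expect_lt(res2$curve$C[res2$curve$t2_fs >= 500][1], 0.5)
})

test_that("observable TCFs rescale to frequency units through the map slope", {
  om <- gen_frequency_process(8, 1500, 5, a0 = 1, tau0_ps = 0.4,
                              tau1_ps = 0.4, delta_cm = 100, seed = 43)
  y <- -150 + 0.0392 * om                      # noise-free linear coupling
  c_om <- tcf(om, dt = 5, max_lag = 2000)
  c_y <- tcf(y, dt = 5, max_lag = 2000)
  map <- fit_linear(as.vector(om), as.vector(y), "dE")
  resc <- rescale_tcf_to_frequency(c_y, map, denoise = FALSE)
  expect_equal(resc$value, c_om$value, tolerance = 1e-6)
  expect_error(rescale_tcf_to_frequency(
    tcf(y, dt = 5, max_lag = 500, normalize = TRUE), map), "unnormalized")
})

test_that("the closed-loop S3PE recovers a planted long timescale", {
  ## planted bi-exponential FTCF -> full cumulant pipeline -> fitted tau1
  ## within 15% of the plant, for two long constants spanning the band
  for (tau1 in c(0.7, 1.5)) {
    om <- gen_frequency_process(96, 4800, 5, a0 = 0.6, tau0_ps = 0.1,
                                tau1_ps = tau1, delta_cm = 100,
                                seed = 50 + round(10 * tau1))
    ftcf <- tcf(om, dt = 5, max_lag = 6200)
    res <- s3pe_from_ftcf(ftcf, t2_max = 4000, t3_max = 2000)
    est <- biexp_long_time(attr(res$curve, "fit"))
    expect_lt(abs(est - tau1) / tau1, 0.15)
  }
})
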