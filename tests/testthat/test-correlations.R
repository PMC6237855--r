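test_that("the FFT correlation engine matches brute-force double loops", {
  set.seed(21)
  for (n in c(50, 137, 200)) {
    x <- rnorm(n)
    ct <- tcf(x, dt = 1, max_lag = min(40, n - 1), center = "ensemble")
    expect_lt(max(abs(ct$value - brute_tcf(x, min(40, n - 1)))), 1e-10)
  }
  ## uncentred form
  x <- rnorm(120) + 3
  ct <- tcf(x, dt = 1, max_lag = 30, center = "none")
  expect_lt(max(abs(ct$value - brute_tcf(x, 30, center = FALSE))), 1e-10)
})

test_that("gapped series contribute only contiguous segments", {
  set.seed(22)
  x <- rnorm(100)
  xg <- x
  xg[41:45] <- NA
  ct <- tcf(matrix(xg), dt = 1, max_lag = 20, center = "none")
  seg1 <- x[1:40]; seg2 <- x[46:100]
  manual <- vapply(0:20, function(k) {
    s <- sum(seg1[seq_len(40 - k)] * seg1[seq_len(40 - k) + k]) +
         sum(seg2[seq_len(55 - k)] * seg2[seq_len(55 - k) + k])
    s / ((40 - k) + (55 - k))
  }, numeric(1))
  expect_lt(max(abs(ct$value - manual)), 1e-10)
})

test_that("lag-0 equals the variance and normalization pins it to 1", {
  set.seed(23)
  x <- matrix(rnorm(400, sd = 2.5), 100, 4)
  ct <- tcf(x, dt = 1, max_lag = 10)
  xc <- x - mean(x)
  expect_equal(ct$value[1], mean(xc^2), tolerance = 1e-12)
  ctn <- tcf(x, dt = 1, max_lag = 10, normalize = TRUE)
  expect_equal(ctn$value[1], 1, tolerance = 1e-12)
  expect_error(tcf(x, dt = 1, max_lag = 100), "max_lag")
})

test_that("closed-form autocorrelations are reproduced", {
  ## cosine: C(k) -> cos(W k)/2 under time-origin averaging
  W <- 0.37
  n <- 20000
  x <- cos(W * (0:(n - 1)))
  ct <- tcf(x, dt = 1, max_lag = 40, center = "none")
  expect_lt(max(abs(ct$value - cos(W * (0:40)) / 2)), 5e-3)
  ## white noise decorrelates beyond lag 0
  set.seed(24)
  w <- matrix(rnorm(3e4), ncol = 10)
  cw <- tcf(w, dt = 1, max_lag = 20)
  expect_lt(max(abs(cw$value[-1])), 4 / sqrt(3e4))
  ## OU process: exponential decay of the normalized TCF (64 modes x 20 ps
  ## gives ~2.5e3 effective samples per lag, so ~4 sigma is ~0.08)
  om <- gen_frequency_process(64, 4000, 5, a0 = 1, tau0_ps = 0.5,
                              tau1_ps = 0.5, seed = 25)
  co <- tcf(om, dt = 5, max_lag = 1500, normalize = TRUE)
  expect_lt(max(abs(co$value - exp(-co$lag_fs / 500))), 0.08)
})

test_that("continuous HB survival behaves as a probability", {
  rec <- data.frame(frame = 1:50, donor_mol = 1, donor_H = 1,
                    acceptor_mol = 2)
  attr(rec, "n_frames") <- 50
  s <- s_hb(rec, dt = 1, max_lag = 20)
  expect_true(all(s$value == 1))              # never-broken bond

  expect_error(s_hb(rec[0, ], dt = 1, max_lag = 10), "no HBs")

  set.seed(26)
  rec2 <- gen_markov_hbonds(20, 400, 5, k_break = 2, k_form = 1, seed = 26)
  s2 <- s_hb(rec2, dt = 5, max_lag = 600)
  expect_true(all(diff(s2$value) <= 1e-12))
  expect_true(all(s2$value >= 0 & s2$value <= 1))
  expect_equal(s2$value[1], 1)
})

test_that("Markov bonds decay with the planted continuous lifetime", {
  tau_c <- 1.2   # ps
  rec <- gen_markov_hbonds(400, 4000, 5, k_break = 1 / tau_c, k_form = 0.5,
                           seed = 27)
  s <- s_hb(rec, dt = 5, max_lag = 4000)
  theory <- exp(-s$lag_fs / 1000 / tau_c)
  expect_lt(max(abs(s$value - theory)[s$lag_fs <= 2500]), 0.03)
})

test_that("HB-number correlation is normalized and needs variance", {
  rec <- data.frame(frame = rep(1:30, 2),
                    donor_mol = rep(1:2, each = 30), donor_H = 1,
                    acceptor_mol = rep(3:4, each = 30))
  attr(rec, "n_frames") <- 30
  expect_error(n_hb(rec, dt = 1, max_lag = 10), "zero variance")

  rec2 <- gen_markov_hbonds(300, 3000, 5, k_break = 1, k_form = 1, seed = 28)
  ct <- n_hb(rec2, dt = 5, max_lag = 2000)
  expect_equal(ct$value[1], 1, tolerance = 1e-12)
  ## independent two-state bonds relax with 1/(k_break + k_form) = 0.5 ps
  expect_lt(max(abs(ct$value - exp(-ct$lag_fs / 500))[ct$lag_fs <= 1500]),
            0.05)
})

test_that("noiseless bi-exponential curves are recovered to 1e-6", {
  t <- seq(0, 8000, by = 5)
  set.seed(29)
  for (i in 1:20) {
    a0 <- runif(1, 0.1, 0.9)
    tau0 <- runif(1, 0.02, 0.3)
    tau1 <- runif(1, 0.5, 2.5)
    curve <- data.frame(lag_fs = t,
                        value = biexp_decay(t, a0, tau0, tau1))
    fit <- fit_biexp(curve, t_max = 8000)
    expect_lt(abs(fit$a0 - a0) / a0, 1e-5)
    expect_lt(abs(fit$tau0_ps - tau0) / tau0, 1e-6)
    expect_lt(abs(fit$tau1_ps - tau1) / tau1, 1e-6)
    expect_lte(fit$tau0_ps, fit$tau1_ps)
  }
})

test_that("a single exponential lands on one active branch", {
  t <- seq(0, 8000, by = 5)
  curve <- data.frame(lag_fs = t, value = exp(-t / 1200))
  fit <- fit_biexp(curve, t_max = 8000)
  expect_equal(biexp_long_time(fit), 1.2, tolerance = 1e-4)
})

test_that("tau1 survives moderate noise within 5 percent", {
  t <- seq(0, 8000, by = 5)
  set.seed(30)
  curve <- data.frame(lag_fs = t,
                      value = biexp_decay(t, 0.6, 0.1, 1.02) +
                        rnorm(length(t), 0, 0.01))
  fit <- fit_biexp(curve)
  expect_lt(abs(fit$tau1_ps - 1.02) / 1.02, 0.05)
})

test_that("fit windows shorter than 3 points are rejected", {
  curve <- data.frame(lag_fs = seq(0, 1000, by = 5),
                      value = exp(-seq(0, 1000, by = 5) / 500))
  expect_error(fit_biexp(curve, t_min = 0, t_max = 6), "3 points")
})

test_that("block errors vanish for identical blocks and count correctly", {
  x <- rep(c(1, 2, 3), 30)
  be <- block_errors(x, function(b) mean(b), n_blocks = 3)
  expect_equal(be$stderr, 0)
  expect_length(be$estimates, 3)
  expect_error(block_errors(x, mean, n_blocks = 1), "n_blocks")

  ## a 24 ps record split into 3 blocks of 8 ps
  m <- matrix(rnorm(4800 * 2), 4800, 2)
  be2 <- block_errors(m, function(b) nrow(b) * 5, n_blocks = 3)
  expect_equal(be2$estimates, rep(8000, 3))
})

test_that("planted OU timescale lies within 2 block stderr in most replicates", {
  hits <- 0
  n_rep <- 50
  tau <- 0.5   # ps
  for (r in seq_len(n_rep)) {
    om <- gen_frequency_process(16, 1600, 5, a0 = 1, tau0_ps = tau,
                                tau1_ps = tau, delta_cm = 100,
                                seed = 1000 + r)
    est <- function(x) {
      ct <- tcf(x, dt = 5, max_lag = 2000, normalize = TRUE)
      biexp_long_time(fit_biexp(ct, t_max = 2000))
    }
    be <- block_errors(om, est, n_blocks = 3)
    full <- est(om)
    if (abs(full - tau) <= 2 * be$stderr) hits <- hits + 1
  }
  ## with only 3 blocks the 2-stderr band has ~82% nominal coverage
  ## (Student t with 2 dof, P(|t| < 2) = 0.816), not the Gaussian 95%;
  ## threshold is that minus 3 binomial sigma
  expect_gte(hits, round(0.816 * n_rep - 3 * sqrt(n_rep * 0.816 * 0.184)))
})

test_that("the lag-0 nugget of white measurement scatter is removed", {
  set.seed(31)
  om <- gen_frequency_process(16, 4000, 5, a0 = 1, tau0_ps = 0.8,
                              tau1_ps = 0.8, delta_cm = 100, seed = 31)
  y <- 0.04 * om + matrix(rnorm(length(om), 0, 7.27), nrow(om))
  raw <- tcf(y, dt = 5, max_lag = 3000)
  den <- denoise_lag0(raw)
  ## nugget close to the planted scatter variance, corrected lag-0 close to
  ## the dynamical variance slope^2 * Delta^2 (16 modes x 20 ps puts the
  ## sampling sd of the dynamical variance itself near 10%)
  expect_equal(attr(den, "nugget"), 7.27^2, tolerance = 0.15)
  expect_equal(den$value[1], 0.04^2 * 100^2, tolerance = 0.15)
  ## a 16-mode x 20 ps ensemble resolves the timescale only coarsely; the
  ## sharp assertions above are the point of the nugget correction
  fitn <- fit_biexp(normalize_tcf(den), t_max = 3000)
  expect_equal(biexp_long_time(fitn), 0.8, tolerance = 0.2)
})
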