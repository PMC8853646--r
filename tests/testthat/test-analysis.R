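test_that("LFP weights give the unit-converted point-source potential", {
  # 100 pA at 100 um with sigma = 1/300 (Ohm cm)^-1 -> about 0.239 uV
  w <- lfp_weights(matrix(c(100, 0, 0), 1), c(0, 0, 0))
  expect_equal(100 * w, 0.2387, tolerance = 1e-3)
  # linearity and inverse distance
  cur <- matrix(c(50, 100), 2, 1)
  pos <- matrix(c(100, 0, 0), 1)
  phi <- compute_lfp(cur, pos, c(0, 0, 0))
  expect_equal(phi[2], 2 * phi[1])
  w2 <- lfp_weights(matrix(c(200, 0, 0), 1), c(0, 0, 0))
  expect_equal(as.numeric(w / w2), 2, tolerance = 1e-12)
  # minimum-distance clamp at the electrode
  w0 <- lfp_weights(matrix(0, 1, 3), c(0, 0, 0))
  expect_true(is.finite(w0))
})

test_that("the spectrum estimator recovers a pure tone", {
  dt <- 0.1
  t <- seq(0, 2000 - dt, by = dt)
  x <- sin(2 * pi * 15 * t / 1000)
  sp <- lfp_spectrum(x, dt = dt)
  expect_equal(sp$freq[which.max(sp$power)], 15, tolerance = 0.1)
  expect_error(lfp_spectrum(x[1:1000], dt = dt), "too short")
})

test_that("white-noise spectra are flat and the filter rolls off", {
  set.seed(15)
  dt <- 0.1
  x <- stats::rnorm(30000)
  sp <- lfp_spectrum(x, dt = dt, filter = FALSE)
  inband <- sp$power[sp$freq >= 20 & sp$freq <= 150]
  expect_lt(stats::sd(inband) / mean(inband), 0.5)
  spf <- lfp_spectrum(x, dt = dt, filter = TRUE)
  # 6th-order Butterworth: an octave above cutoff attenuated >= 30 dB
  p200 <- mean(spf$power[abs(spf$freq - 190) < 10]) /
    mean(sp$power[abs(sp$freq - 190) < 10])
  p400 <- mean(spf$power[abs(spf$freq - 400) < 10]) /
    mean(sp$power[abs(sp$freq - 400) < 10])
  expect_lt(p400, p200 / 1000)
})

test_that("windowed rates count and conserve spikes", {
  sp <- data.frame(id = 1L, t = seq(1000 / 70, 1000, by = 1000 / 70))
  m <- windowed_rates(sp, 1L, window = 100, overlap = 0.5, duration = 1000)
  expect_true(all(abs(m - 70) <= 10))
  # empty train
  m0 <- windowed_rates(sp[0, ], 1:3, window = 50, overlap = 0.5,
                       duration = 500)
  expect_true(all(m0 == 0))
  # non-overlapping tiling conserves the total count
  set.seed(16)
  tr <- data.frame(id = sample(1:4, 200, TRUE),
                   t = stats::runif(200, 0, 1000))
  mt <- windowed_rates(tr, 1:4, window = 100, overlap = 0, duration = 1000)
  expect_equal(sum(mt) * 0.1, 200)
})

test_that("correlation time course matches brute force and handles edge cases", {
  set.seed(17)
  a <- matrix(stats::rnorm(50 * 20), 50)
  b <- matrix(stats::rnorm(50 * 20), 50)
  attr(a, "t_start") <- attr(b, "t_start") <- seq(0, by = 50, length.out = 20)
  ct <- correlation_timecourse(a, b, first_sniff_ms = 0)
  for (wdx in c(1, 7, 20)) {
    va <- a[, wdx]; vb <- b[, wdx]
    brute <- sum((va - mean(va)) * (vb - mean(vb))) /
      sqrt(sum((va - mean(va))^2) * sum((vb - mean(vb))^2))
    expect_equal(ct$correlation[wdx], brute, tolerance = 1e-12)
  }
  # identical matrices correlate at 1 everywhere
  ci <- correlation_timecourse(a, a, first_sniff_ms = 0)
  expect_true(all(abs(ci$correlation - 1) < 1e-12))
  # independent matrices have near-zero mean correlation
  expect_lt(abs(ct$mean), 0.1)
  # zero-variance windows are skipped, not scored
  az <- a; az[, 3] <- 5
  attr(az, "t_start") <- attr(a, "t_start")
  cz <- correlation_timecourse(az, b, first_sniff_ms = 0)
  expect_true(is.na(cz$correlation[3]))
  expect_equal(cz$n_skipped, 1)
})

test_that("stretched-exponential fits recover known parameters", {
  x <- seq(50, 1150, by = 100)
  y <- 229.2 * exp(-1.721e-4 * x^1.545)
  f <- fit_stretched_exp(x, y)
  expect_equal(f$a, 229.2, tolerance = 1e-4)
  expect_equal(f$b, 1.721e-4, tolerance = 1e-3)
  expect_equal(f$n, 1.545, tolerance = 1e-3)
  # fixed exponent reduces to an ordinary exponential fit
  y2 <- 50 * exp(-0.004 * x)
  f2 <- fit_stretched_exp(x, y2, fix_n = 1)
  expect_equal(f2$n, 1)
  expect_equal(f2$b, 0.004, tolerance = 1e-6)
})

test_that("skew-normal fitting recovers simulated parameters", {
  set.seed(18)
  # sample via the additive representation
  n <- 4000
  d <- 5 / sqrt(1 + 25)
  z <- d * abs(stats::rnorm(n)) + sqrt(1 - d^2) * stats::rnorm(n)
  x <- 10 + 40 * z
  fit <- fit_skew_normal(x)
  expect_equal(fit$xi, 10, tolerance = 0.3)
  expect_equal(fit$omega, 40, tolerance = 0.15)
  expect_gt(fit$shape, 2)
})
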