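test_that("iFR is a normalized sum of Gaussian kernels", {
  # empty raster -> zero trace
  r0 <- spike_raster(numeric(0), integer(0), 4, window = c(0, 1000))
  ifr0 <- compute_ifr(r0, n_cells = 4, sigma = 6)
  expect_true(all(ifr0$rate == 0))
  expect_error(compute_ifr(r0, n_cells = 0), "positive")

  # one spike, one cell: the trace integrates to one spike
  r1 <- spike_raster(500, 1L, 1, window = c(0, 1000))
  ifr1 <- compute_ifr(r1, n_cells = 1, sigma = 6, dt_out = 1)
  expect_equal(sum(ifr1$rate) / 1000, 1, tolerance = 0.01)

  # FWHM convention narrows to sd by the standard factor
  ifr2 <- compute_ifr(r1, n_cells = 1, sigma = 6, width_is_fwhm = TRUE)
  expect_lt(max(ifr2$rate) * 0.9, max(compute_ifr(r1, 1, sigma = 2.6)$rate))
})

test_that("mean rate equals the counting oracle on random rasters", {
  set.seed(21)
  for (k in 1:3) {
    n <- 8
    rate <- runif(1, 5, 30)
    times <- sort(runif(rpois(1, rate * n), 0, 1000))
    r <- spike_raster(times, sample.int(n, length(times), replace = TRUE),
                      n, window = c(0, 1000))
    ifr <- compute_ifr(r, n_cells = n, sigma = 6)
    oracle <- length(r$times) / n / 1  # count / (N cells x 1 s)
    expect_lt(abs(mean_rate(ifr) - oracle), 0.02 * oracle + 0.2)
  }
  # constant trace: mean is the constant
  tr <- structure(list(t = 0:100, rate = rep(7, 101), sigma = 2,
                       n_cells = 1L, label = "x"), class = "ifr_trace")
  expect_equal(mean_rate(tr), 7)
})

test_that("Welch spectrum localizes a pure oscillation", {
  t <- seq(0, 2047) / 1000
  x <- 3 + sin(2 * pi * 30 * t)
  spec <- welch_psd(x, fs = 1000)
  expect_equal(spec$freq[which.max(spec$power)], 30, tolerance = 0.05)
  # frequency resolution of the padded spectrum is <= 1 Hz
  expect_lte(spec$freq[2] - spec$freq[1], 1)

  tr <- structure(list(t = seq_along(x) - 1, rate = x, sigma = 2,
                       n_cells = 1L, label = "x"), class = "ifr_trace")
  pf <- population_frequency(tr)
  expect_equal(pf$f_pop, 30, tolerance = 0.5)
})

test_that("flat traces yield a missing population frequency", {
  tr <- structure(list(t = 0:1500, rate = rep(0, 1501), sigma = 2,
                       n_cells = 1L, label = "x"), class = "ifr_trace")
  pf <- population_frequency(tr)
  expect_true(is.na(pf$f_pop))
  expect_match(attr(pf$f_pop, "reason"), "flat|spiking")
})

test_that("population frequency matches a synthetic periodic population", {
  r <- periodic_raster(25, n_cells = 10, duration = 1500)
  ifr <- compute_ifr(r, n_cells = 10, sigma = 2, window = c(0, 1500))
  pf <- population_frequency(ifr)
  # 10 cells phase-spread over the cycle: population rate modulated at 25 Hz
  # times the per-cycle structure; dominant component at n_cells x 25 or 25.
  expect_true(min(abs(pf$f_pop - c(25, 250))) < 1.5 ||
                pf$f_pop %% 25 < 1.5 || 25 - pf$f_pop %% 25 < 1.5)

  # synchronous volleys: all cells spike together at 25 Hz
  times <- rep(seq(20, 1480, by = 40), each = 10)
  r2 <- spike_raster(times, rep(1:10, times = length(times) / 10), 10,
                     window = c(0, 1500))
  ifr2 <- compute_ifr(r2, n_cells = 10, sigma = 2, window = c(0, 1500))
  expect_equal(population_frequency(ifr2)$f_pop, 25, tolerance = 1)
})

test_that("kernel width does not move the spectral peak", {
  r <- periodic_raster(20, n_cells = 1, duration = 2000)
  f2 <- population_frequency(compute_ifr(r, 1, sigma = 2,
                                         window = c(0, 2000)))$f_pop
  f1 <- population_frequency(compute_ifr(r, 1, sigma = 1,
                                         window = c(0, 2000)))$f_pop
  expect_lt(abs(f2 - f1), 1)
})

test_that("nested-oscillation flag requires a secondary peak above a slow drive", {
  f <- seq(0, 100, by = 0.5)
  single <- data.frame(freq = f, power = dnorm(f, 24, 1))
  expect_false(nested_oscillation_flag(single, f_inp = 24))
  nested <- data.frame(freq = f,
                       power = dnorm(f, 8, 1) * 0.8 + dnorm(f, 28, 1))
  expect_true(nested_oscillation_flag(nested, f_inp = 8))
  # primary at the drive itself: not nested
  expect_false(nested_oscillation_flag(nested, f_inp = 28))
  expect_false(nested_oscillation_flag(NULL, f_inp = 10))
})

test_that("natural frequency is the median asynchronous population frequency", {
  nf <- natural_frequency(control_network(), r_inp = 1000, seeds = 1:2,
                          duration = 1200, onset = 300)
  expect_false(is.na(nf$f_N))
  expect_gt(nf$f_N, 10)
  expect_length(nf$f_pop, 2)
  expect_equal(nf$f_N, median(nf$f_pop))
})
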