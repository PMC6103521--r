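test_that("fixed-mean square pulses have the closed-form amplitude", {
  # amplitude = r_inp / (f_inp * delta_inp), delta in seconds
  cases <- list(
    list(r = 1000, f = 25, d = 10, amp = 4000),
    list(r = 1000, f = 20, d = 10, amp = 5000),
    list(r = 500, f = 10, d = 5, amp = 10000)
  )
  for (cs in cases) {
    rp <- rate_program("square_fixed_mean", r_inp = cs$r, f_inp = cs$f,
                       delta_inp = cs$d, duration = 400)
    expect_equal(pulse_amplitude(rp), cs$amp, tolerance = 1e-12)
    expect_equal(mean_lambda(rp), cs$r, tolerance = 1e-6)
  }
})

test_that("duty cycle one degenerates to a constant asynchronous rate", {
  rp <- rate_program("square_fixed_mean", r_inp = 1000, f_inp = 50,
                     delta_inp = 20, duration = 200)
  expect_true(all(abs(rp$lambda - 1000) < 1e-9))
  expect_error(rate_program("square_fixed_mean", r_inp = 1000, f_inp = 50,
                            delta_inp = 25, duration = 200),
               "duty cycle")
})

test_that("sine programs honor both normalization conventions", {
  # as-printed: lambda = r (1 + sin) / 2, extremes r and 0, mean r/2
  rp <- rate_program("sine", r_inp = 1000, f_inp = 10, duration = 1000,
                     sine_mean = "half")
  expect_equal(max(rp$lambda), 1000, tolerance = 1e-3)
  expect_equal(min(rp$lambda), 0, tolerance = 1e-3)
  expect_equal(mean_lambda(rp), 500, tolerance = 1e-3)
  expect_true(all(rp$lambda >= 0))
  # matched-mean: time-average r_inp
  rp2 <- rate_program("sine", r_inp = 1000, f_inp = 10, duration = 1000,
                      sine_mean = "matched")
  expect_equal(mean_lambda(rp2), 1000, tolerance = 1e-3)
  expect_equal(max(rp2$lambda), 2000, tolerance = 1e-3)
})

test_that("rate is zero before onset and parameters are validated", {
  rp <- rate_program("sine", r_inp = 500, f_inp = 5, onset = 100,
                     duration = 300)
  t <- (seq_along(rp$lambda) - 1) * rp$dt
  expect_true(all(rp$lambda[t < 100] == 0))
  expect_error(rate_program("sine", r_inp = -1, f_inp = 5, duration = 100))
  expect_error(rate_program("sine", r_inp = 100, duration = 100),
               "f_inp")
  expect_error(rate_program("asynchronous", duration = 100), "r_inp")
})

test_that("fixed-amplitude square mean rate grows with f_inp", {
  means <- sapply(c(10, 20, 40), function(f) {
    rp <- rate_program("square_fixed_amplitude", r_p = 4000, f_inp = f,
                       delta_inp = 10, duration = 1000)
    mean_lambda(rp)
  })
  # mean = r_p * f * delta: 400, 800, 1600 sp/s
  expect_equal(means, c(400, 800, 1600), tolerance = 1e-6)
})

test_that("Poisson sampling is seeded, reproducible, and has Poisson counts", {
  rp <- rate_program("asynchronous", r_inp = 1000, duration = 1000)
  r1 <- draw_poisson_spikes(rp, n_sources = 3, seed = 42)
  r2 <- draw_poisson_spikes(rp, n_sources = 3, seed = 42)
  expect_identical(r1$times, r2$times)
  expect_identical(r1$sources, r2$sources)
  r3 <- draw_poisson_spikes(rp, n_sources = 3, seed = 43)
  expect_false(identical(r1$times, r3$times))
  # nested sources: first k sources identical across raster sizes
  r4 <- draw_poisson_spikes(rp, n_sources = 5, seed = 42)
  expect_identical(r1$times, r4$times[r4$sources <= 3])
  expect_error(draw_poisson_spikes(rp, n_sources = 1), "seed")

  # count statistics against the Poisson count oracle: expected 1000,
  # each count must lie within 1000 +- 3 sqrt(1000), and the mean over
  # many seeds within 3 standard errors
  counts <- sapply(1:60, function(s)
    length(draw_poisson_spikes(rp, 1, seed = s)$times))
  expect_true(all(abs(counts - 1000) < 3 * sqrt(1000) + 10))
  expect_lt(abs(mean(counts) - 1000), 3 * sqrt(1000 / 60))

  # zero rate -> empty raster
  rp0 <- rate_program("asynchronous", r_inp = 0, duration = 500)
  expect_length(draw_poisson_spikes(rp0, 2, seed = 1)$times, 0)
})

test_that("generated rasters match the mean of lambda(t)", {
  # relative error < 5% once >= 1e4 spikes are expected
  for (kind in c("sine", "square_fixed_mean")) {
    rp <- rate_program(kind, r_inp = 2000, f_inp = 8, delta_inp = 20,
                       duration = 1000)
    r <- draw_poisson_spikes(rp, n_sources = 6, seed = 7)  # ~12000 spikes
    emp <- length(r$times) / 6 / (rp$duration / 1000)
    expect_lt(abs(emp - mean_lambda(rp)) / mean_lambda(rp), 0.05)
  }
  # fixed-mean square: total count independent of f_inp
  counts <- sapply(c(5, 20, 40), function(f) {
    rp <- rate_program("square_fixed_mean", r_inp = 2000, f_inp = f,
                       delta_inp = 10, duration = 1000)
    length(draw_poisson_spikes(rp, 5, seed = 11)$times)
  })
  expect_true(max(abs(counts - mean(counts))) / mean(counts) < 0.06)
})

test_that("background drive is a thin asynchronous preset", {
  bg <- background_drive(n_cells = 100, rate = 1, duration = 1000, seed = 5)
  expect_equal(bg$n_sources, 100)
  # Poisson sum: expected 100 spikes total
  expect_lt(abs(length(bg$times) - 100), 3 * 10 + 5)
  expect_length(background_drive(n_cells = 0, duration = 100, seed = 1)$times,
                0)
  # superposition: 100 cells at 1 sp/s ~ one source at 100 sp/s in counts
  agg <- draw_poisson_spikes(
    rate_program("asynchronous", r_inp = 100, duration = 1000), 1, seed = 5)
  expect_lt(abs(length(bg$times) - length(agg$times)), 6 * 10)
})

test_that("rasters validate geometry and serialize as CSV", {
  expect_error(spike_raster(c(5, 1), c(1, 1), 1, window = c(0, 2)),
               "outside")
  expect_error(spike_raster(c(1, 1), c(1, 1), 1, window = c(0, 2)),
               "strictly increasing")
  r <- spike_raster(c(0.5, 1.2, 0.8), c(2, 1, 2), 3, window = c(0, 2))
  path <- tempfile(fileext = ".csv")
  write_raster_csv(r, path)
  r2 <- read_raster_csv(path, n_sources = 3, window = c(0, 2))
  expect_equal(r$times, r2$times)
  expect_equal(r$sources, r2$sources)
  unlink(path)
})

test_that("rate programs round-trip through JSON", {
  rp <- rate_program("square_fixed_mean", r_inp = 1000, f_inp = 25,
                     delta_inp = 10, onset = 50, duration = 400)
  path <- tempfile(fileext = ".json")
  write_rate_program(rp, path)
  rp2 <- read_rate_program(path)
  expect_equal(rp$lambda, rp2$lambda)
  expect_equal(rp$kind, rp2$kind)
  unlink(path)
})
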