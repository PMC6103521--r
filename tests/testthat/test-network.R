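test_that("all-to-all synapse counts match the architecture", {
  expect_equal(build_network(control_network())$synapse_count, 200)
  # two 20-PC populations sharing 5 INs, reciprocal
  expect_equal(build_network(competition_network())$synapse_count,
               2 * 20 * 5 + 2 * 5 * 20)
  expect_equal(build_network(lif_network())$synapse_count, 25 * 5 + 5 * 25)
  expect_equal(build_network(minimal_network())$synapse_count, 2)
})

test_that("invalid specifications are rejected", {
  bad <- control_network()
  bad$populations$PC$model <- "izhikevich"
  expect_error(build_network(bad), "unknown cell model")
  bad2 <- control_network()
  bad2$signal_pops <- "PC_X"
  expect_error(build_network(bad2), "unknown population")
  bad3 <- control_network()
  bad3$connections[[1]]$g <- -1
  expect_error(build_network(bad3), "negative")
  # dangling signal: raster with wrong source count
  r <- spike_raster(c(1, 2), c(1, 1), n_sources = 1, window = c(0, 100))
  expect_error(run_trial(control_network(), signal = r, seed = 1,
                         duration = 100, onset = 0),
               "sources")
})

test_that("trials are bit-reproducible from (spec, seed)", {
  rp <- rate_program("sine", r_inp = 1000, f_inp = 20, onset = 200,
                     duration = 700)
  a <- run_trial(control_network(), rp, seed = 9, duration = 700,
                 onset = 200)
  b <- run_trial(control_network(), rp, seed = 9, duration = 700,
                 onset = 200)
  expect_identical(a$rasters$PC$times, b$rasters$PC$times)
  expect_identical(a$rasters$IN$times, b$rasters$IN$times)
  expect_identical(a$v, b$v)
  c <- run_trial(control_network(), rp, seed = 10, duration = 700,
                 onset = 200)
  expect_false(identical(a$rasters$PC$times, c$rasters$PC$times))
})

test_that("no signal-driven spikes arrive before onset", {
  # noise-free single PC: the only input starts at onset
  spec <- single_pc_network()
  rp <- rate_program("asynchronous", r_inp = 2000, onset = 400,
                     duration = 900)
  tr <- run_trial(spec, rp, seed = 2, duration = 900, onset = 400)
  expect_true(all(tr$rasters$PC$times >= 400))
  expect_equal(tr$analysis_start, 900)
})

test_that("a quiescent network stays at rest", {
  spec <- control_network(background_rate = 0)
  spec$init_jitter <- 0
  tr <- run_trial(spec, signal = NULL, seed = 1, duration = 300, onset = 0)
  expect_length(tr$rasters$PC$times, 0)
  expect_length(tr$rasters$IN$times, 0)
  # PC voltages settle near rest, far from threshold
  expect_lt(max(tr$v[nrow(tr$v), 1:20]), -40)
})

test_that("raster events coincide with somatic threshold crossings", {
  tr <- run_async_trial(seed = 4, duration = 900, onset = 200)
  v <- tr$v
  t <- tr$v_time
  spk <- tr$rasters$PC
  for (k in seq_len(min(20, length(spk$times)))) {
    near <- abs(t - spk$times[k]) <= 1
    expect_gt(max(v[near, spk$sources[k]]), -10)
  }
})

test_that("oscillation requires feedback inhibition", {
  # with inhibition: rhythmic volleys; without: no inhibition-paced rhythm
  tr1 <- run_async_trial(control_network(), seed = 1)
  m1 <- trial_measures(tr1)
  expect_false(is.na(m1$f_pop))
  expect_gt(m1$rates[["IN"]], 5)
  tr0 <- run_async_trial(control_network(g_gaba = 0), seed = 1)
  m0 <- trial_measures(tr0)
  # without the IN->PC synapse PCs fire more (disinhibition)
  expect_gt(m0$rates[["PC"]], m1$rates[["PC"]])
})

test_that("LIF network responds to pulse-packet drive", {
  spec <- lif_network()
  rp <- rate_program("square_fixed_mean", r_inp = 1000, f_inp = 24,
                     delta_inp = 1, onset = 300, duration = 1300)
  tr <- run_trial(spec, rp, seed = 3, duration = 1300, onset = 300)
  m <- trial_measures(tr)
  expect_gt(m$rates[["PC"]], 5)
  expect_gt(m$rates[["IN"]], 1)
  # refractory hold: no PC fires twice within 3 ms
  by_cell <- split(tr$rasters$PC$times, tr$rasters$PC$sources)
  gaps <- unlist(lapply(by_cell, function(x) diff(x)))
  if (length(gaps)) expect_gte(min(gaps), 3)
})

test_that("network size scaling at fixed synaptic strength preserves rates", {
  # per-source normalization: 40 PC / 10 IN behaves like 20 PC / 5 IN
  m1 <- trial_measures(run_async_trial(control_network(), seed = 6,
                                       duration = 1200, onset = 300))
  m2 <- trial_measures(run_async_trial(control_network(n_pc = 40, n_in = 10),
                                       seed = 6, duration = 1200,
                                       onset = 300))
  expect_lt(abs(m1$rates[["PC"]] - m2$rates[["PC"]]),
            0.5 * m1$rates[["PC"]] + 1)
  expect_lt(abs(m1$f_pop - m2$f_pop), 6)
})

test_that("network specs round-trip through a JSON config file", {
  spec <- control_network()
  path <- tempfile(fileext = ".json")
  write_network_spec(spec, path)
  spec2 <- read_network_spec(path)
  expect_equal(spec2$populations$PC$params, spec$populations$PC$params)
  expect_equal(build_network(spec2)$synapse_count, 200)
  tr1 <- run_async_trial(spec, seed = 3, duration = 700, onset = 200)
  tr2 <- run_async_trial(spec2, seed = 3, duration = 700, onset = 200)
  expect_identical(tr1$rasters$PC$times, tr2$rasters$PC$times)
  unlink(path)
})
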