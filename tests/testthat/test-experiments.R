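test_that("sweep specs carry the protocol and scaled preset", {
  sw <- sweep_spec()
  expect_equal(sw$grid, 1:50)
  expect_equal(sw$n_realizations, 10)
  expect_equal(sw$duration, 2500)
  sc <- scaled_sweep_spec()
  expect_equal(sc$grid, seq(16, 32, 2))
  expect_equal(sc$n_realizations, 3)
  expect_equal(sc$duration, 1500)
  sc2 <- scaled_sweep_spec(grid = c(10, 20), kind = "sine")
  expect_equal(sc2$grid, c(10, 20))
  expect_equal(sc2$kind, "sine")
})

test_that("resonance extraction takes lower-tie argmaxes and excludes nested points", {
  grid <- c(10, 20, 30, 40)
  fake <- data.frame(
    f_inp = grid,
    rate_PC = c(1, 5, 5, 2), rate_PC_sd = 0,
    rate_IN = c(1, 2, 6, 3), rate_IN_sd = 0,
    f_pop = c(50, 20, 30, 25), f_pop_sd = 0,
    nested_frac = c(1, 0, 0, 0))   # the 10 Hz point is a nested regime
  attr(fake, "per_real") <- list(
    rate_PC = cbind(c(1, 5, 5, 2), c(1, 5, 5, 2)),
    rate_IN = cbind(c(1, 2, 6, 3), c(1, 2, 6, 3)),
    f_pop = cbind(c(50, 20, 30, 25), c(50, 20, 28, 25)))
  attr(fake, "f_N") <- 18
  class(fake) <- c("response_profile", "data.frame")
  res <- extract_resonances(fake)
  expect_equal(res$f_R_PC, 20)    # tie between 20 and 30 -> lower
  expect_equal(res$f_R_IN, 30)
  expect_equal(res$f_R_pop, 30)   # 50 at 10 Hz excluded as nested
  expect_equal(res$f_N, 18)
  expect_equal(res$f_R_PC_sd, 0)
})

test_that("frequency sweep aggregates over realizations with a reference", {
  sw <- scaled_sweep_spec(grid = c(18, 26), n_realizations = 2,
                          duration = 1100, network = lif_network())
  prof <- frequency_sweep(sw)
  expect_s3_class(prof, "response_profile")
  expect_equal(nrow(prof), 2)
  expect_true(all(is.finite(prof$rate_PC)))
  expect_true(all(prof$rate_PC_sd >= 0))
  expect_false(is.null(attr(prof, "ref_rates")))
  res <- extract_resonances(prof)
  expect_true(res$f_R_PC %in% sw$grid)
  path <- tempfile(fileext = ".csv")
  write_profile_csv(prof, path)
  expect_equal(nrow(utils::read.csv(path)), 2)
  unlink(path)
  path2 <- tempfile(fileext = ".json")
  write_resonance_summary(res, path2)
  expect_equal(jsonlite::read_json(path2)$f_R_PC, res$f_R_PC)
  unlink(path2)
})

test_that("filter regimes are classified from cartoon profiles", {
  grid <- seq(4, 40, by = 4)
  mk <- function(r) data.frame(f_inp = grid, rate_PC = r)
  band <- mk(ifelse(grid >= 16 & grid <= 28, 10, 0.2))
  expect_equal(classify_filter_regime(band), "band-pass")
  low <- mk(ifelse(grid <= 24, 10 + (grid == 20) * 5, 0.2))
  expect_match(classify_filter_regime(low), "^low-pass")
  high <- mk(ifelse(grid >= 20, 2 + grid / 10, 0.2))
  expect_equal(classify_filter_regime(high), "high-pass")
  all_flat <- mk(rep(8, length(grid)))
  expect_equal(classify_filter_regime(all_flat), "all-pass")
  all_peak <- mk(8 + 8 * exp(-(grid - 24)^2 / 32))
  expect_equal(classify_filter_regime(all_peak), "all-pass+peak")
})

test_that("rate programs concatenate into two-period schedules", {
  a <- rate_program("asynchronous", r_inp = 1000, duration = 500, dt = 0.05)
  b <- rate_program("square_fixed_mean", r_inp = 1000, f_inp = 25,
                    delta_inp = 10, duration = 500, dt = 0.05)
  ab <- concat_rate_programs(a, b)
  expect_equal(ab$duration, 1000)
  expect_length(ab$lambda, length(a$lambda) + length(b$lambda))
  expect_equal(ab$lambda[seq_along(a$lambda)], a$lambda)
  expect_error(concat_rate_programs(a, rate_program("asynchronous",
                                                    r_inp = 1, duration = 10,
                                                    dt = 0.01)))
})

test_that("competition bookkeeping produces the suppression index", {
  # LIF-sized surrogate via tiny HH competition net for speed
  net <- competition_network(n_pc = 4, n_in = 2)
  tg <- rate_program("square_fixed_mean", r_inp = 1000, f_inp = 24,
                     delta_inp = 1, onset = 200, duration = 800)
  ds <- rate_program("asynchronous", r_inp = 1000, onset = 200,
                     duration = 800)
  cr <- competition_experiment(tg, ds, network = net, seeds = 1,
                               duration = 800, onset = 200)
  expect_s3_class(cr, "competition_result")
  expect_true(is.finite(cr$suppression_index))
  expect_lte(cr$suppression_index, 1)
  expect_equal(cr$suppression_index, 1 - cr$rate_D / cr$rate_D_alone)
})
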