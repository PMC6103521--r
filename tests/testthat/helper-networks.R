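# Small shared fixtures; everything is generated in code at test time.

# short control-network trial settings used across files
short_trial <- list(duration = 1200, onset = 300)

# run one control trial with an asynchronous drive
run_async_trial <- function(spec = control_network(), r_inp = 1000, seed = 1,
                            duration = 1500, onset = 400) {
  rp <- rate_program("asynchronous", r_inp = r_inp, onset = onset,
                     duration = duration)
  run_trial(spec, rp, seed = seed, duration = duration, onset = onset)
}

# deterministic synthetic raster: n_cells cells firing periodically with
# per-cell phase offsets
periodic_raster <- function(rate_hz, n_cells, duration, jitter = 0) {
  period <- 1000 / rate_hz
  times <- c()
  cells <- c()
  for (i in seq_len(n_cells)) {
    t <- seq(period * i / n_cells, duration - 1e-9, by = period)
    times <- c(times, t)
    cells <- c(cells, rep(i, length(t)))
  }
  spike_raster(times, cells, n_sources = n_cells, window = c(0, duration))
}
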