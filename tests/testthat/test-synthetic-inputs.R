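# Presynaptic drive generators: 1/f modulators, rhythms, Poisson sampling,
# functional groups, clustered trains.

test_that("pink modulator spans exactly [0.5, 1.5] and is seed-deterministic", {
  m1 <- gen_pink_modulator(5000, seed = 7)
  m2 <- gen_pink_modulator(5000, seed = 7)
  expect_identical(m1$values, m2$values)
  expect_equal(min(m1$values), 0.5)
  expect_equal(max(m1$values), 1.5)
  expect_error(gen_pink_modulator(500), "1000")
  expect_error(gen_pink_modulator(-10), "positive")
})

test_that("pink modulator has an approximately 1/f power spectrum", {
  m <- gen_pink_modulator(60000, seed = 11)
  x <- m$values - mean(m$values)
  n <- length(x)
  p <- Mod(stats::fft(x)[2:(n / 2)])^2
  f <- (1:(n / 2 - 1)) / (n / 1000) # Hz
  keep <- f >= 0.2 & f <= 100
  slope <- unname(stats::coef(stats::lm(log10(p[keep]) ~ log10(f[keep])))[2])
  expect_gt(slope, -1.4)
  expect_lt(slope, -0.6)
})

test_that("rhythm amplitude follows A = off * d / (1 - d)", {
  expect_equal(rhythm_spec(16, 0.5, off = 10)$amplitude, 10)
  expect_equal(rhythm_spec(16, 0.2, off = 10)$amplitude, 2.5)
  beta <- rhythm_spec(16, 0.2, off = 3.9)
  gamma <- rhythm_spec(64, 0.4, off = 16.9)
  expect_equal(beta$amplitude, 3.9 * 0.25)
  expect_equal(gamma$amplitude, 16.9 * 2 / 3)
  expect_error(rhythm_spec(16, 1.2, off = 10), "depth")
  expect_error(rhythm_spec(-4, 0.2, off = 10), "positive")
})

test_that("sine_rate realises the parameterised sinusoid", {
  spec <- rhythm_spec(10, 0.2, off = 8)
  r <- sine_rate(spec, duration = 1000, dt = 0.5)
  expect_true(all(r$values >= 0))
  # mean over an integer number of cycles equals the offset
  expect_equal(mean(r$values), 8, tolerance = 1e-10)
  expect_equal(max(r$values), 8 + spec$amplitude, tolerance = 1e-3)
  # phase convention: rate maximum maps to phase 0, minimum to +/- pi
  tmax <- trace_times(r)[which.max(r$values)]
  tmin <- trace_times(r)[which.min(r$values)]
  expect_lt(abs(phase_of(tmax, spec)), 0.05)
  expect_gt(abs(phase_of(tmin, spec)), pi - 0.05)
})

test_that("burst envelope is a unit-peak Gaussian with sigma = 2 cycles", {
  env <- burst_envelope(16, center = 1000, duration = 2000, dt = 1)
  expect_equal(max(env$values), 1, tolerance = 1e-6)
  # sigma = 2 * (1000/16) = 125 ms: value at one sigma is exp(-1/2)
  at <- function(t) env$values[which.min(abs(trace_times(env) - t))]
  expect_equal(at(1125), exp(-0.5), tolerance = 1e-3)
  expect_equal(at(1000 + 80), at(1000 - 80), tolerance = 1e-9)
})

test_that("sharpen_modulator preserves the mean and inflates variance", {
  const <- rate_trace(rep(2, 1000))
  expect_equal(sharpen_modulator(const, 4)$values, const$values)
  m <- gen_pink_modulator(5000, seed = 3)
  s <- sharpen_modulator(m, 4)
  expect_equal(mean(s$values), mean(m$values), tolerance = 1e-9)
  expect_gt(stats::var(s$values), stats::var(m$values))
})

test_that("inhibitory modulator is a lagged rescaled copy of excitation", {
  m <- gen_pink_modulator(10000, seed = 5)
  inh <- derive_inhibitory_modulator(m, lag = 4)
  cc <- stats::ccf(m$values, inh$values, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], -4) # output trails input by 4 ms
  expect_equal(mean(inh$values), mean(m$values), tolerance = 1e-9)
  ident <- derive_inhibitory_modulator(m, lag = 0, target_mean = mean(m$values))
  expect_equal(ident$values, m$values, tolerance = 1e-12)
  long <- derive_inhibitory_modulator(m, lag = 500)
  expect_equal(length(long), length(m))
  expect_error(derive_inhibitory_modulator(m, lag = 20000), "duration")
})

test_that("node-rate modulation is exact multiplicative scaling", {
  const <- rate_trace(rep(1, 1000))
  out <- modulate_node_rates(c(4.43, 0), const)
  expect_equal(out[[1]]$values, rep(4.43, 1000))
  expect_equal(out[[2]]$values, rep(0, 1000))
  m <- gen_pink_modulator(2000, seed = 2)
  out <- modulate_node_rates(10, m)
  expect_equal(mean(out[[1]]$values), 10 * mean(m$values), tolerance = 1e-12)
  expect_error(modulate_node_rates(-1, m), "non-negative")
})

test_that("functional-group bookkeeping reproduces the budget arithmetic", {
  g <- build_functional_groups(26112, 5, 100)
  expect_length(g, 52)
  ids <- unlist(lapply(g, `[[`, "node_ids"))
  expect_length(ids, 5200)
  expect_false(any(duplicated(ids)))
  expect_length(build_functional_groups(200, 1, 100), 2)
  expect_error(build_functional_groups(50, 1, 100), "group_size")
})

test_that("Poisson sampling matches the Bernoulli-per-bin law", {
  empty <- sample_poisson(rate_trace(rep(0, 1000)), seed = 1)
  expect_length(empty$times, 0)
  # constant 10 Hz for 100 s: n bins = 1e5, p = 0.01 per bin
  counts <- vapply(1:20, function(s) {
    length(sample_poisson(rate_trace(rep(10, 1e5)), seed = s)$times)
  }, numeric(1))
  sigma <- sqrt(1e5 * 0.01 * 0.99)
  expect_true(all(abs(counts - 1000) < 3 * sigma + 1e-9 * 0))
  expect_error(sample_poisson(rate_trace(rep(1100, 100))), "finer")
})

test_that("sampled trains are sorted and duplicate-free across seeds", {
  for (s in 1:5) {
    tr <- sample_poisson(rate_trace(rep(50, 5000)), seed = s)
    expect_false(is.unsorted(tr$times, strictly = TRUE))
  }
  grp <- sample_poisson_group(c(4, 8, 2), gen_pink_modulator(3000, seed = 1),
                              seed = 2)
  for (tr in grp) expect_false(is.unsorted(tr$times, strictly = TRUE))
})

test_that("clustered trains are jittered copies with preserved counts", {
  base <- sample_poisson(rate_trace(rep(10, 5000)), seed = 4)
  same <- gen_cluster_trains(base, 3, jitter = 0, seed = 1)
  for (tr in same) expect_equal(tr$times, base$times)
  jit <- gen_cluster_trains(base, 40, jitter = 2, seed = 1,
                            window = c(0, 5000))
  for (tr in jit) {
    expect_length(tr$times, length(base$times))
    expect_true(all(abs(sort(tr$times) - base$times) <= 2 + 1e-9))
  }
})

test_that("spike trains and rate traces survive text round trips", {
  tmp <- tempfile(fileext = ".tsv")
  trains <- list(spike_train(1L, c(1.5, 7.25, 90)), spike_train(5L, 2.125))
  write_spike_trains(trains, tmp)
  back <- read_spike_trains(tmp)
  expect_equal(back[[1]]$times, trains[[1]]$times)
  expect_equal(back[[2]]$node_id, 5L)
  tr <- rate_trace(c(0.5, 1.25, 3), dt = 0.5, t0 = 10)
  tmp2 <- tempfile(fileext = ".txt")
  write_rate_trace(tr, tmp2)
  back2 <- read_rate_trace(tmp2)
  expect_equal(back2$values, tr$values)
  expect_equal(back2$dt, 0.5)
  expect_equal(back2$t0, 10)
})
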