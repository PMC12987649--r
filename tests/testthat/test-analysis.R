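# Phase assignment, histograms, pairwise phase consistency, STA,
# corrected cross-correlograms, f-I summaries, thresholds, fluctuations.

test_that("phase convention: inhibition maximum at 0, minimum at +/- pi", {
  spec <- rhythm_spec(16, 0.2, off = 10)
  r <- sine_rate(spec, 1000, dt = 0.1)
  t <- trace_times(r)
  expect_lt(abs(phase_of(t[which.max(r$values)], spec)), 0.02)
  expect_gt(abs(phase_of(t[which.min(r$values)], spec)), pi - 0.02)
  # periodicity: one full period leaves the phase unchanged
  times <- c(13.2, 401.77, 995)
  expect_equal(phase_of(times + 1000 / 16, spec), phase_of(times, spec),
               tolerance = 1e-9)
  # peak/trough split: phase 0 is peak, +/- pi is trough, half/half overall
  expect_equal(peak_trough_masks(spec, t[which.max(r$values)]), "peak")
  expect_equal(peak_trough_masks(spec, t[which.min(r$values)]), "trough")
  dense <- seq(0, 10000 - 0.5, by = 0.5)
  frac <- mean(peak_trough_masks(spec, dense) == "peak")
  expect_equal(frac, 0.5, tolerance = 0.01)
})

test_that("phase histogram has 8 bins and exact percent-change arithmetic", {
  spec <- rhythm_spec(10, 0.2, off = 5)
  set.seed(1)
  unif <- stats::runif(20000, 0, 10000)
  ph <- phase_histogram(unif, spec)
  expect_equal(nrow(ph), 8)
  expect_true(all(abs(ph$pct_change) < 10))
  # all events in one bin: +700% there, -100% elsewhere
  period <- 1000 / 10
  one_bin <- seq(0, 9000, by = period) + period * 5 / 16 # phase pi/8, a bin centre
  ph1 <- phase_histogram(one_bin, spec)
  hit <- which.max(ph1$value)
  expect_equal(ph1$pct_change[hit], 700)
  expect_true(all(ph1$pct_change[-hit] == -100))
  # presence-series mode: occupancy-weighted bin means recover the global mean
  x <- as.numeric(stats::runif(5000) < 0.3)
  phb <- phase_histogram(x, spec, bin_dt = 2)
  t <- 2 + (seq_along(x) - 1) * 2
  idx <- pmin(8, pmax(1, ceiling((phase_of(t, spec) + pi) / (pi / 4))))
  w <- tabulate(idx, 8)
  expect_equal(sum(phb$value * w) / sum(w), mean(x), tolerance = 1e-12)
})

test_that("PPC matches its algebraic form and is unbiased on uniform phases", {
  expect_equal(ppc(rep(1.3, 50)), 1)
  expect_equal(ppc(c(0, pi)), -1)
  # brute-force pairwise mean cosine on small n
  set.seed(2)
  phs <- stats::runif(40, -pi, pi)
  brute <- mean(cos(outer(phs, phs, `-`)[lower.tri(matrix(0, 40, 40))]))
  expect_equal(ppc(phs), brute, tolerance = 1e-12)
  # resultant identity (n R^2 - 1)/(n - 1)
  n <- length(phs)
  Rbar <- Mod(sum(complex(argument = phs))) / n
  expect_equal(ppc(phs), (n * Rbar^2 - 1) / (n - 1), tolerance = 1e-12)
  # near zero for uniform phases at n = 1000 (3 sigma ~ sqrt(2)/n)
  vals <- vapply(1:10, function(s) {
    set.seed(s)
    ppc(stats::runif(1000, -pi, pi))
  }, numeric(1))
  expect_true(all(abs(vals) < 0.01))
  expect_error(ppc(0.5), "two")
})

test_that("STA percent change localises event-AP coupling", {
  # constant presence: zero percent change at every lag
  const <- rep(1, 5000)
  sta <- sta_percent_change(const, ap_times = c(1000, 3000, 5000),
                            bin = 2, max_lag = 50)
  expect_true(all(sta$pct == 0))
  # events exactly at AP bins: peak at lag 0 equals 100 (1/mean - 1)
  x <- numeric(5000)
  ap <- seq(500, 9000, by = 500)
  x[floor(ap / 2) + 1] <- 1
  sta2 <- sta_percent_change(x, ap, bin = 2, max_lag = 40)
  expect_equal(sta2$pct[sta2$lag_ms == 0], 100 * (1 / mean(x) - 1))
  expect_equal(which.max(sta2$pct), which(sta2$lag_ms == 0))
  # independent events: no structure beyond noise
  set.seed(3)
  y <- as.numeric(stats::runif(5000) < 0.2)
  sta3 <- sta_percent_change(y, sort(stats::runif(150, 200, 9800)),
                             bin = 2, max_lag = 40)
  sigma_pct <- 100 * sqrt(0.2 * 0.8 / 150) / 0.2
  expect_true(all(abs(sta3$pct) < 4 * sigma_pct))
  expect_error(sta_percent_change(numeric(100) , 10), "zero global mean")
})

test_that("grouped STA aggregates by class and decile medians", {
  x <- rep(list(as.numeric(stats::runif(2000) < 0.3)), 4)
  names(x) <- c("10", "11", "20", "21")
  groups <- data.frame(comp = c(10, 11, 20, 21),
                       class = c("apical", "apical", "basal", "basal"),
                       decile = c(1, 1, 2, 2))
  out <- sta_percent_change(x, ap_times = seq(200, 3800, by = 100),
                            bin = 2, max_lag = 20, groups = groups)
  expect_setequal(unique(out$class), c("apical", "basal"))
  expect_equal(nrow(out), 2 * length(seq(-20, 20, by = 2)))
})

test_that("delta-coupled trains give a CC peak at the implanted lag", {
  fx <- fixture_suite(seed = 6)
  cc <- phase_stratified_cc(fx$delta_coupled$pre, fx$delta_coupled$post,
                            duration = fx$delta_coupled$duration,
                            max_lag = 30, correct = FALSE)
  expect_equal(cc$lags[which.max(cc$cc)], fx$delta_coupled$truth)
  expect_equal(cc$peak_lag, fx$delta_coupled$truth)
})

test_that("peak area integrates the near-zero positive lobe exactly", {
  # construct a triangular cross-correlogram directly through the raw path:
  # pre spikes regularly spaced, each followed by post spikes fanned over
  # lags 1..9 with triangular multiplicity
  pre <- seq(100, 59900, by = 100)
  weights <- c(1, 2, 3, 4, 5, 4, 3, 2, 1)
  post <- sort(unlist(lapply(seq_along(weights), function(k) {
    rep(pre + k + 0.5, weights[k]) # bin centres, away from bin edges
  })))
  cc <- phase_stratified_cc(pre, post, duration = 60000, max_lag = 50,
                            correct = FALSE)
  # area = sum of counts x 1 ms bin; edges at the zero counts flanking it
  lobe <- cc$cc[cc$lags >= 1 & cc$lags <= 9]
  expect_equal(cc$peak_area, sum(lobe) * 1, tolerance = 1e-6)
  expect_equal(sum(lobe), length(pre) * sum(weights), tolerance = 0.01)
})

test_that("the spectral correction flattens co-modulated independent trains", {
  spec <- rhythm_spec(16, 0.3, off = 20)
  r <- sine_rate(spec, 60000, dt = 1)
  a <- sample_poisson(r, seed = 11)$times
  b <- sample_poisson(r, seed = 22)$times
  cc <- phase_stratified_cc(a, b, duration = 60000, rhythm = spec,
                            max_lag = 100, correct = TRUE)
  raw <- phase_stratified_cc(a, b, duration = 60000, rhythm = spec,
                             max_lag = 100, correct = FALSE)
  # jittered surrogates break the co-modulation: null band for the
  # corrected CC
  sur <- vapply(1:20, function(s) {
    set.seed(s)
    aj <- sort(a + stats::runif(length(a), -40, 40))
    cs <- phase_stratified_cc(aj, b, duration = 60000, rhythm = spec,
                              max_lag = 100, correct = TRUE)
    max(abs(cs$cc))
  }, numeric(1))
  expect_lt(max(abs(cc$cc)), max(sur) * 1.5)
  # spectral power at the modulation frequency: corrected far below raw
  pow_at <- function(x) {
    M <- length(x)
    k <- round(16 * M / 1000)
    Mod(stats::fft(x))[k + 1]
  }
  expect_lt(pow_at(cc$cc - mean(cc$cc)), 0.05 * pow_at(raw$cc - mean(raw$cc)))
})

test_that("f-I summary flags all-subthreshold and sorts amplitudes", {
  cell <- passive_cell()
  fi <- fi_curve(cell, amplitudes = c(0.1, 0.3), step_dur = 300, t_on = 100)
  expect_true(fi$all_subthreshold)
  expect_true(is.na(fi$threshold_nA))
  expect_true(is.na(fi$slope_hz_per_nA))
  expect_error(fi_curve(cell, amplitudes = c(1, 0.5)), "sorted")
})

test_that("AP threshold reads the voltage 1 ms before the peak", {
  dt <- 0.1
  n <- 3000
  v <- rep(-70, n)
  # linear ramp into a spike peak at 200 ms: ramp slope 2 mV/ms
  t <- (seq_len(n)) * dt
  ramp <- t >= 190 & t <= 200
  v[ramp] <- -70 + 2 * (t[ramp] - 190)
  thr <- ap_threshold(v, dt, peak_times = 200, t0 = dt)
  expect_equal(thr, -70 + 2 * 9, tolerance = 0.21)
  # a trace-wide constant offset shifts thresholds by exactly that offset
  thr2 <- ap_threshold(v + 7.5, dt, peak_times = 200, t0 = dt)
  expect_equal(thr2, thr + 7.5)
  expect_warning(ap_threshold(v, dt, peak_times = c(0.5, 200), t0 = dt),
                 "skipped")
  expect_length(suppressWarnings(
    ap_threshold(v, dt, peak_times = c(0.5, 200), t0 = dt)), 1)
})

test_that("fluctuation bias tracks the discrete derivative by phase", {
  spec <- rhythm_spec(8, 0.2, off = 5)
  dt <- 0.5
  n <- 20000
  t <- dt * seq_len(n)
  expect_true(all(fluctuation_bias(rep(-65, n), dt, spec)$dv == 0))
  ramp <- fluctuation_bias(0.3 * t, dt, spec)
  expect_equal(ramp$dv, rep(0.3, 8), tolerance = 1e-9)
  # V oscillating at the rhythm frequency: bias follows the discrete
  # difference of the sinusoid, i.e. proportional to cos(phase + w/2)
  w <- 2 * pi * 8 / 1000
  v <- sin(w * t) # peaks at rate phase 0 under the package convention
  fb <- fluctuation_bias(v, dt, spec, delay = 1)
  # wt = phase + pi/2 under the package convention, so
  # dV = 2 sin(w/2) cos(wt + w/2) = -2 sin(w/2) sin(phase + w/2)
  pred <- vapply(fb$phase_mid, function(ph) {
    -2 * sin(w * 1 / 2) * sin(ph + w * 1 / 2)
  }, numeric(1))
  expect_gt(stats::cor(fb$dv, pred), 0.999)
})
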