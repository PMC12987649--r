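# Statistics over events, phases, and traces: spike-triggered averages,
# rhythm phase assignment and histograms, pairwise phase consistency,
# phase-stratified corrected cross-correlograms, f-I curves, AP thresholds,
# and membrane-fluctuation bias.

# internal: wrap angles to (-pi, pi]
.wrap_pi <- function(x) {
  w <- x %% (2 * pi)
  ifelse(w > pi, w - 2 * pi, w)
}

#' Instantaneous rhythm phase of event times
#'
#' Phase convention: 0 marks the *maximum* of the modulated inhibitory rate
#' and +/- pi its minimum (inhibition weakest). For the sine parameterisation
#' used here the raw oscillator angle is shifted by -pi/2 so that the rate
#' maximum falls at phase 0.
#'
#' @param times Event times, ms.
#' @param rhythm A `rhythm_spec`.
#' @return Phases in (-pi, pi].
#' @export
phase_of <- function(times, rhythm) {
  stopifnot(inherits(rhythm, "rhythm_spec"))
  .wrap_pi(2 * pi * rhythm$f * times / 1000 + rhythm$phase - pi / 2)
}

#' Phase lag of the synaptic conductance behind the presynaptic rate
#'
#' A sinusoidally modulated presynaptic rate drives a postsynaptic
#' conductance through the dual-exponential synaptic kernel, which delays
#' the conductance oscillation by `atan(w tau_r) + atan(w tau_d)` radians at
#' angular frequency `w`. Analyses that probe *shunting* (e.g. the AP
#' threshold against the gamma cycle) should stratify by the phase of the
#' conductance the membrane actually feels, i.e. shift event times back by
#' this lag; at 64 Hz the GABA_A kernel lag is ~3.5 ms, close to a quarter
#' cycle.
#'
#' @param f Modulation frequency, Hz.
#' @param kin A `kinetic_params` (default GABA_A).
#' @return Lag in ms.
#' @export
synaptic_phase_lag <- function(f, kin = default_kinetics()$GABA_A) {
  w <- 2 * pi * f / 1000
  (atan(w * kin$tau_rise) + atan(w * kin$tau_decay)) / w
}

#' Peak/trough stratum of event times
#'
#' `"peak"` when the instantaneous inhibitory rate exceeds its offset
#' (inhibition above its mean), `"trough"` otherwise. Equivalent to
#' cos(phase) > 0 under the package phase convention.
#'
#' @param rhythm A `rhythm_spec`.
#' @param times Event times, ms.
#' @return Character vector, `"peak"` or `"trough"`.
#' @export
peak_trough_masks <- function(rhythm, times) {
  ifelse(cos(phase_of(times, rhythm)) > 0, "peak", "trough")
}

#' Phase histogram of events relative to an inhibitory rhythm
#'
#' Eight bins of width pi/4 over (-pi, pi]. For event *times*, the per-bin
#' value is the mean event count per unit time spent in that bin (all bins
#' are visited equally for a tonic rhythm, so raw counts are used); for a
#' binary *presence series*, the value is the mean of the series over
#' samples falling in the bin. Values are also expressed as percent change
#' from the across-bin mean.
#'
#' @param x Either a numeric vector of event times (ms), or a logical/0-1
#'   vector of presence values (when `bin_dt` is given).
#' @param rhythm A `rhythm_spec`.
#' @param bin_dt Sample interval of a presence series, ms; `NULL` means `x`
#'   holds event times.
#' @param t0 Time of the first presence sample, ms.
#' @param n_bins Number of phase bins (default 8).
#' @return Data frame: `bin`, `phase_lo`, `phase_hi`, `phase_mid`, `value`,
#'   `pct_change`.
#' @export
phase_histogram <- function(x, rhythm, bin_dt = NULL, t0 = bin_dt,
                            n_bins = 8) {
  stopifnot(inherits(rhythm, "rhythm_spec"))
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  if (is.null(bin_dt)) {
    if (!length(x)) stop("need at least one event")
    ph <- phase_of(x, rhythm)
    idx <- pmin(n_bins, pmax(1L, ceiling((ph + pi) / (2 * pi / n_bins))))
    value <- as.numeric(tabulate(idx, nbins = n_bins))
  } else {
    t <- t0 + (seq_along(x) - 1) * bin_dt
    ph <- phase_of(t, rhythm)
    idx <- pmin(n_bins, pmax(1L, ceiling((ph + pi) / (2 * pi / n_bins))))
    value <- vapply(seq_len(n_bins), function(b) {
      sel <- idx == b
      if (!any(sel)) return(NA_real_)
      mean(as.numeric(x[sel]))
    }, numeric(1))
  }
  m <- mean(value, na.rm = TRUE)
  pct <- if (m > 0) 100 * (value / m - 1) else rep(NA_real_, n_bins)
  data.frame(
    bin = seq_len(n_bins),
    phase_lo = edges[-(n_bins + 1)], phase_hi = edges[-1],
    phase_mid = (edges[-1] + edges[-(n_bins + 1)]) / 2,
    value = value, pct_change = pct
  )
}

#' Pairwise phase consistency
#'
#' The mean cosine of all unordered pairwise phase differences, an unbiased
#' estimator of phase-locking strength (zero-mean for uniform phases,
#' regardless of n). Computed via the resultant identity
#' \eqn{(|\sum e^{i\phi}|^2 - n) / (n (n - 1))}.
#'
#' @param phases Numeric vector of phases, radians (length >= 2).
#' @return Scalar in \[-1, 1\].
#' @export
ppc <- function(phases) {
  n <- length(phases)
  if (n < 2) stop("PPC needs at least two phases")
  s <- sum(complex(argument = phases))
  (Mod(s)^2 - n) / (n * (n - 1))
}

#' Spike-triggered average of event presence, as percent change from mean
#'
#' For each time lag around somatic action potentials, the mean of a binary
#' dendritic-spike presence series across AP-aligned windows, expressed as
#' `100 * (value / global mean - 1)`. With a named list of series and a
#' decile table, per-compartment STAs are aggregated by the median within
#' dendrite class x electrotonic decile.
#'
#' @param binary A logical/0-1 vector (single compartment) or a named list
#'   of such vectors keyed by compartment id.
#' @param ap_times Somatic AP times, ms (>= 1 required).
#' @param bin Bin width of the series, ms (default 2).
#' @param max_lag Maximum lag, ms.
#' @param groups Optional decile table (`comp`, `class`, `decile`) for
#'   aggregation.
#' @return Single series: data frame `lag_ms`, `pct`. Grouped: data frame
#'   `class`, `decile`, `lag_ms`, `pct` (median across member compartments;
#'   compartments with zero global mean are excluded with a warning).
#' @export
sta_percent_change <- function(binary, ap_times, bin = 2, max_lag = 100,
                               groups = NULL) {
  if (!length(ap_times)) stop("need at least one action potential")
  one <- function(x) {
    x <- as.numeric(x)
    g <- mean(x)
    if (g == 0) return(NULL)
    L <- as.integer(round(max_lag / bin))
    ap_bin <- floor(ap_times / bin) + 1L
    ap_bin <- ap_bin[ap_bin - L >= 1 & ap_bin + L <= length(x)]
    if (!length(ap_bin)) return(NULL)
    lags <- (-L):L
    val <- vapply(lags, function(l) mean(x[ap_bin + l]), numeric(1))
    data.frame(lag_ms = lags * bin, pct = 100 * (val / g - 1))
  }
  if (!is.list(binary)) {
    out <- one(binary)
    if (is.null(out)) stop("series has zero global mean; STA undefined")
    return(out)
  }
  stas <- lapply(binary, one)
  dropped <- names(binary)[vapply(stas, is.null, logical(1))]
  if (length(dropped)) {
    warning("excluded ", length(dropped),
            " compartment(s) with zero event rate or no usable APs")
  }
  keep <- !vapply(stas, is.null, logical(1))
  stas <- stas[keep]
  if (!length(stas)) stop("no compartment has a defined STA")
  if (is.null(groups)) {
    lag_ms <- stas[[1]]$lag_ms
    pct <- apply(vapply(stas, `[[`, numeric(length(lag_ms)), "pct"), 1,
                 stats::median)
    return(data.frame(lag_ms = lag_ms, pct = pct))
  }
  comp_ids <- as.integer(names(stas))
  gi <- groups[match(comp_ids, groups$comp), ]
  out <- list()
  for (cls in unique(gi$class)) {
    for (dec in sort(unique(gi$decile[gi$class == cls]))) {
      sel <- which(gi$class == cls & gi$decile == dec)
      if (!length(sel)) next
      lag_ms <- stas[[sel[1]]]$lag_ms
      pct <- apply(vapply(stas[sel], `[[`, numeric(length(lag_ms)), "pct"),
                   1, stats::median)
      out[[length(out) + 1L]] <- data.frame(class = cls, decile = dec,
                                            lag_ms = lag_ms, pct = pct)
    }
  }
  do.call(rbind, out)
}

# internal: circular cross-correlogram of two binned 0/1 vectors at lags
# -L..L, ordered lag 0, 1, .., L, -L, .., -1 ("fft order") or centred
.binned_cc <- function(a, b, L) {
  n <- length(a)
  fa <- stats::fft(a)
  fb <- stats::fft(b)
  cc <- Re(stats::fft(Conj(fa) * fb, inverse = TRUE)) / n
  # cc[1 + l] is sum_t a[t] b[t + l] for circular lag l
  c(cc[1:(L + 1)], cc[(n - L + 1):n]) # fft order: 0..L, -L..-1
}

.fft_to_centred <- function(x, L) c(x[(L + 2):(2 * L + 1)], x[1:(L + 1)])
.centred_to_fft <- function(x, L) c(x[(L + 1):(2 * L + 1)], x[1:L])

#' Phase-stratified corrected cross-correlogram
#'
#' Cross-correlogram (1 ms bins) between presynaptic spikes restricted to
#' one rhythm stratum (peak or trough) and all somatic APs. Both trains
#' inherit periodicity from the rhythm (and the stratification itself
#' introduces it), so the correlogram is corrected in the frequency domain:
#' the transform coefficients at the modulation frequency (nearest bin plus
#' `zero_width` neighbours on each side, and their conjugates) are zeroed in
#' the CC and in both autocorrelograms, the CC transform is divided
#' element-wise by the square root of the product of the two
#' autocorrelogram transforms, and the result inverse-transformed. The
#' near-zero-lag positive peak is integrated between its flanking
#' zero crossings (`peak_area`).
#'
#' @param presyn_times Presynaptic spike times, ms.
#' @param ap_times Somatic AP times, ms.
#' @param duration Total time, ms.
#' @param rhythm A `rhythm_spec`, or `NULL` for no stratification
#'   (stratum `"all"`).
#' @param stratum `"peak"`, `"trough"`, or `"all"`.
#' @param max_lag Maximum lag, ms (default 100).
#' @param bin Bin width, ms (default 1).
#' @param zero_width Neighbouring bins zeroed on each side of the rhythm
#'   bin (default 1).
#' @param correct Apply the spectral correction (default TRUE when a rhythm
#'   is given).
#' @param peak_search Length-2 lag window (ms) within which the near-zero
#'   positive peak is sought (default the full lag range; use e.g.
#'   `c(0, 30)` when the coupling is known to be causal).
#' @param stratum_lag Shift (ms) subtracted from presynaptic times *for
#'   stratification only*, so that peak/trough refer to the inhibitory
#'   conductance cycle rather than the presynaptic rate cycle (see
#'   [synaptic_phase_lag()]); the correlogram itself uses the raw times.
#' @return List of class `cc_result`: `lags` (ms), `cc` (corrected),
#'   `raw` (counts), `peak_area`, `peak_lag`, `stratum`, `n_pre`, `n_post`.
#' @export
phase_stratified_cc <- function(presyn_times, ap_times, duration,
                                rhythm = NULL,
                                stratum = c("all", "peak", "trough"),
                                max_lag = 100, bin = 1, zero_width = 1,
                                correct = !is.null(rhythm),
                                peak_search = c(-max_lag, max_lag),
                                stratum_lag = 0) {
  stratum <- match.arg(stratum)
  if (!length(presyn_times) || !length(ap_times)) {
    stop("both spike trains must be non-empty")
  }
  if (stratum != "all") {
    if (is.null(rhythm)) stop("stratification requires a rhythm")
    keep <- peak_trough_masks(rhythm, presyn_times - stratum_lag) == stratum
    presyn_times <- presyn_times[keep]
    if (!length(presyn_times)) {
      warning("empty stratum '", stratum, "'")
      return(structure(list(lags = numeric(), cc = numeric(),
                            raw = numeric(), peak_area = NA_real_,
                            peak_lag = NA_real_, stratum = stratum,
                            n_pre = 0L, n_post = length(ap_times)),
                       class = "cc_result"))
    }
  }
  n <- as.integer(ceiling(duration / bin))
  L <- as.integer(round(max_lag / bin))
  tovec <- function(t) {
    v <- numeric(n)
    idx <- pmin(n, pmax(1L, floor(t / bin) + 1L))
    tb <- tabulate(idx, nbins = n)
    as.numeric(tb)
  }
  a <- tovec(presyn_times)
  b <- tovec(ap_times)
  cc <- .binned_cc(a, b, L)        # fft order
  if (correct) {
    aa <- .binned_cc(a, a, L)
    bb <- .binned_cc(b, b, L)
    M <- 2L * L + 1L
    fs <- 1000 / bin
    fcc <- stats::fft(cc)
    faa <- stats::fft(aa)
    fbb <- stats::fft(bb)
    if (!is.null(rhythm)) {
      k0 <- round(rhythm$f * M / fs)
      kill <- unique(pmax(1, pmin(M - 1, k0 + (-zero_width):zero_width)))
      kill <- unique(c(kill, M - kill)) # conjugate bins
      kill <- kill[kill >= 1 & kill <= M - 1]
      fcc[kill + 1] <- 0
      faa[kill + 1] <- 0
      fbb[kill + 1] <- 0
    }
    den <- sqrt(pmax(Re(faa) * Re(fbb), 0))
    den[den < 1e-12] <- Inf
    cc <- Re(stats::fft(fcc / den, inverse = TRUE)) / M
  }
  lags <- (-L):L * bin
  cc_c <- .fft_to_centred(cc, L)
  raw_c <- .fft_to_centred(.binned_cc(a, b, L), L)
  # positive peak nearest zero lag, integrated between zero crossings
  pos <- which(cc_c > 0 & lags >= peak_search[1] & lags <= peak_search[2])
  peak_area <- 0
  peak_lag <- NA_real_
  if (length(pos)) {
    # candidate local maxima among positive samples
    iz <- L + 1L
    cand <- pos[order(abs(pos - iz))]
    p0 <- cand[1]
    lo <- p0
    while (lo > 1 && cc_c[lo - 1] > 0) lo <- lo - 1
    hi <- p0
    while (hi < length(cc_c) && cc_c[hi + 1] > 0) hi <- hi + 1
    peak_area <- sum(cc_c[lo:hi]) * bin
    peak_lag <- lags[lo:hi][which.max(cc_c[lo:hi])]
  }
  structure(list(lags = lags, cc = cc_c, raw = raw_c,
                 peak_area = peak_area, peak_lag = peak_lag,
                 stratum = stratum, n_pre = length(presyn_times),
                 n_post = length(ap_times)),
            class = "cc_result")
}

#' f-I curve under a given inhibition state
#'
#' Firing rate versus injected somatic current. For each amplitude a square
#' step of `step_dur` ms is injected (on top of optional background
#' synaptic drive) and the AP count within the step window divided by its
#' duration gives the rate. The threshold (rheobase) is the lowest amplitude
#' with a non-zero rate; the gain is the least-squares slope over the
#' suprathreshold amplitudes.
#'
#' @param cell A `cell`.
#' @param amplitudes Sorted injected amplitudes, nA (default -1 to 2.4 nA
#'   in 0.2 nA steps).
#' @param step_dur Step duration, ms.
#' @param background Optional list with `synapses` and `deliveries` for
#'   ongoing drive.
#' @param t_on Step onset, ms (settling time before the step).
#' @param dt Integration step, ms.
#' @param v_init Initial potential, mV.
#' @return List of class `fi_curve`: data frame `curve` (`amp_nA`,
#'   `rate_hz`), `threshold_nA`, `slope_hz_per_nA` (NA, flagged by
#'   `all_subthreshold`, when nothing fires; NA slope when fewer than two
#'   suprathreshold points).
#' @export
fi_curve <- function(cell, amplitudes = seq(-1, 2.4, by = 0.2),
                     step_dur = 2000, background = NULL, t_on = 200,
                     dt = 0.1, v_init = -80) {
  if (is.unsorted(amplitudes)) stop("amplitudes must be sorted")
  rates <- vapply(amplitudes, function(a) {
    ts <- integrate_cell(
      cell, duration = t_on + step_dur + 50,
      synapses = background$synapses, deliveries = background$deliveries,
      inj = data.frame(comp = cell$soma, amp = a, t_on = t_on,
                       t_off = t_on + step_dur),
      dt = dt, record = "v", rec_comps = cell$soma, rec_dt = max(dt, 0.5),
      v_init = v_init
    )
    ap <- detect_aps(trace_of(ts, cell$soma, "v"), ts$dt, t0 = ts$t0)
    sum(ap$onsets >= t_on & ap$onsets < t_on + step_dur) / step_dur * 1000
  }, numeric(1))
  supra <- which(rates > 0)
  threshold <- if (length(supra)) amplitudes[supra[1]] else NA_real_
  slope <- if (length(supra) >= 2) {
    unname(stats::coef(stats::lm(rates[supra] ~ amplitudes[supra]))[2])
  } else {
    NA_real_
  }
  structure(list(curve = data.frame(amp_nA = amplitudes, rate_hz = rates),
                 threshold_nA = threshold, slope_hz_per_nA = slope,
                 all_subthreshold = !length(supra)),
            class = "fi_curve")
}

#' Action potential voltage threshold
#'
#' The membrane potential 1 ms before each AP peak (nearest sample). Peaks
#' within the first millisecond of the trace are skipped with a warning.
#'
#' @param v Somatic voltage trace, mV.
#' @param dt Sample interval, ms.
#' @param peak_times AP peak times, ms.
#' @param t0 Time of the first sample, ms.
#' @param lead Lead time before the peak, ms (default 1).
#' @return Numeric vector, one threshold (mV) per usable AP.
#' @export
ap_threshold <- function(v, dt, peak_times, t0 = dt, lead = 1) {
  idx <- round((peak_times - lead - t0) / dt) + 1L
  ok <- idx >= 1L & idx <= length(v)
  if (any(!ok)) warning(sum(!ok), " AP(s) too close to the trace edge; skipped")
  v[idx[ok]]
}

#' Phase-binned bias of short-timescale membrane fluctuations
#'
#' The mean of `V(t + delay) - V(t)` (default 1 ms delay) within each rhythm
#' phase bin of `t`. Positive values mean momentary fluctuations are biased
#' depolarising in that phase.
#'
#' @param v Somatic voltage trace, mV.
#' @param dt Sample interval, ms (must divide `delay`).
#' @param rhythm A `rhythm_spec`.
#' @param delay Delay, ms (default 1).
#' @param t0 Time of the first sample, ms.
#' @param n_bins Number of phase bins (default 8).
#' @return Data frame `bin`, `phase_mid`, `dv` (mV per delay).
#' @export
fluctuation_bias <- function(v, dt, rhythm, delay = 1, t0 = dt, n_bins = 8) {
  k <- as.integer(round(delay / dt))
  if (abs(k * dt - delay) > 1e-9 || k < 1) stop("delay must be a multiple of dt")
  n <- length(v)
  dv <- v[(1 + k):n] - v[1:(n - k)]
  t <- t0 + (seq_len(n - k) - 1) * dt
  ph <- phase_of(t, rhythm)
  idx <- pmin(n_bins, pmax(1L, ceiling((ph + pi) / (2 * pi / n_bins))))
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  data.frame(
    bin = seq_len(n_bins),
    phase_mid = (edges[-1] + edges[-(n_bins + 1)]) / 2,
    dv = vapply(seq_len(n_bins), function(b) {
      s <- idx == b
      if (!any(s)) NA_real_ else mean(dv[s])
    }, numeric(1))
  )
}
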