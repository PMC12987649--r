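#' Discretised firing-rate trace
#'
#' A `rate_trace` holds an instantaneous firing rate (Hz) -- or a unitless
#' rate multiplier -- sampled on a regular grid. It is the common currency
#' between the modulator generators and the inhomogeneous-Poisson sampler.
#'
#' @param values Numeric vector of rates (Hz) or multipliers; must be
#'   non-negative and non-empty.
#' @param dt Sample interval in ms (> 0).
#' @param t0 Time of the first sample in ms.
#' @return An object of class `rate_trace`: a list with fields `t0`, `dt`,
#'   `values`.
#' @examples
#' r <- rate_trace(rep(10, 1000), dt = 1)
#' mean(r$values)
#' @export
rate_trace <- function(values, dt = 1, t0 = 0) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("rate_trace needs at least one sample")
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  if (anyNA(values) || any(values < 0)) stop("rate values must be non-negative")
  structure(list(t0 = t0, dt = dt, values = values), class = "rate_trace")
}

#' @export
print.rate_trace <- function(x, ...) {
  cat(sprintf(
    "<rate_trace> %d samples, dt = %g ms, t0 = %g ms, mean = %.4g\n",
    length(x$values), x$dt, x$t0, mean(x$values)
  ))
  invisible(x)
}

#' @export
length.rate_trace <- function(x) length(x$values)

#' Sample times of a rate trace
#' @param x A `rate_trace`.
#' @return Numeric vector of sample times (ms), one per value.
#' @export
trace_times <- function(x) {
  stopifnot(inherits(x, "rate_trace"))
  x$t0 + (seq_along(x$values) - 1) * x$dt
}

#' Duration covered by a rate trace (ms)
#' @param x A `rate_trace`.
#' @export
trace_duration <- function(x) length(x$values) * x$dt

#' Sinusoidal rhythm specification
#'
#' Parameterises a sinusoidal rate modulation
#' \deqn{r(t) = A \sin(2\pi f t + \phi) + \mathrm{off}}
#' where the amplitude is tied to the modulation depth \eqn{d} by
#' \eqn{A = \mathrm{off} / (1/d - 1) = \mathrm{off}\, d / (1 - d)}. Depth is
#' the amplitude of the modulation relative to the offset rate; the study's
#' beta regime is 16 Hz at 20% depth and the gamma regime 64 Hz at 40%.
#'
#' The phase convention used throughout the package maps the *maximum* of the
#' modulated (inhibitory) rate to phase 0 and its minimum to +/- pi; see
#' [phase_of()].
#'
#' @param f Frequency in Hz (> 0).
#' @param depth Modulation depth `d`, strictly inside (0, 1).
#' @param phase Phase offset phi in radians (inside the sine argument).
#' @param off Offset rate in Hz (> 0).
#' @param envelope Optional `rate_trace` of unitless 0-1 values multiplying
#'   the oscillatory term (burst envelope); `NULL` for a tonic rhythm.
#' @return Object of class `rhythm_spec` with fields `f`, `depth`, `phase`,
#'   `off`, `amplitude`, `envelope`.
#' @examples
#' beta <- rhythm_spec(16, 0.2, off = 10)
#' beta$amplitude # 10 * 0.2 / 0.8 = 2.5 Hz
#' @export
rhythm_spec <- function(f, depth, phase = 0, off = 1, envelope = NULL) {
  if (!is.finite(f) || f <= 0) stop("frequency must be positive")
  if (!is.finite(depth) || depth <= 0 || depth >= 1) {
    stop("depth must lie strictly between 0 and 1")
  }
  if (!is.finite(off) || off <= 0) stop("offset rate must be positive")
  if (!is.null(envelope)) stopifnot(inherits(envelope, "rate_trace"))
  structure(
    list(
      f = f, depth = depth, phase = phase, off = off,
      amplitude = off * depth / (1 - depth), envelope = envelope
    ),
    class = "rhythm_spec"
  )
}

#' Generate a 1/f ("pink") rate modulator normalised to [0.5, 1.5]
#'
#' Builds the slow multiplicative rate modulator shared by the members of a
#' functional group. Seeded white noise is filtered in the frequency domain
#' with a 1/sqrt(f) amplitude mask (so the power spectrum falls off as 1/f),
#' transformed back, and min-max normalised so the trace spans exactly
#' \[0.5, 1.5\].
#'
#' @param duration Trace duration in ms (>= 1000 so the spectrum is resolved).
#' @param dt Sample interval in ms (default 1 ms, the spike-generation grid).
#' @param seed Optional integer seed (sets the RNG).
#' @return A `rate_trace` of unitless multipliers with min 0.5 and max 1.5.
#' @examples
#' m <- gen_pink_modulator(2000, seed = 1)
#' range(m$values)
#' @export
gen_pink_modulator <- function(duration, dt = 1, seed = NULL) {
  if (!is.finite(duration) || duration <= 0 || !is.finite(dt) || dt <= 0) {
    stop("duration and dt must be positive")
  }
  if (duration < 1000) stop("duration must be at least 1000 ms")
  if (!is.null(seed)) set.seed(seed)
  n <- max(2L, as.integer(round(duration / dt)))
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  # frequency of each DFT bin; DC carries no modulation
  freq <- c(0, seq_len(n - 1))
  freq <- pmin(freq, n - freq) # fold to the Nyquist range
  mask <- c(0, 1 / sqrt(freq[-1]))
  pink <- Re(stats::fft(spec * mask, inverse = TRUE)) / n
  lo <- min(pink)
  hi <- max(pink)
  if (hi <= lo) stop("degenerate noise trace; cannot normalise")
  rate_trace(0.5 + (pink - lo) / (hi - lo), dt = dt)
}

#' Multiply per-node base rates by a shared modulator
#'
#' Applies a functional group's common rate modulator to each member node's
#' mean firing rate. The per-node mean of the result is the base rate times
#' the modulator mean (exactly 1 for an ideal \[0.5, 1.5\] modulator only if
#' its mean is 1).
#'
#' @param base_rates Numeric vector of non-negative mean rates (Hz), one per
#'   node.
#' @param modulator A `rate_trace` of unitless multipliers.
#' @return A list of `rate_trace` objects, one per node.
#' @export
modulate_node_rates <- function(base_rates, modulator) {
  stopifnot(inherits(modulator, "rate_trace"))
  if (anyNA(base_rates) || any(base_rates < 0)) {
    stop("base rates must be non-negative")
  }
  lapply(base_rates, function(b) {
    rate_trace(b * modulator$values, dt = modulator$dt, t0 = modulator$t0)
  })
}

#' Derive the feedforward inhibitory modulator from the excitatory one
#'
#' Feedforward inhibition tracks excitation with a short delay: the
#' excitatory modulator is shifted forward in time by `lag` (nominally 4 ms)
#' and rescaled to a target mean, and the result modulates the inhibitory
#' spike trains. The leading edge is padded by holding the first sample.
#'
#' @param exc_modulator A `rate_trace` (unitless multiplier).
#' @param lag Forward shift in ms (>= 0, less than the trace duration).
#'   The study sweeps 4, 125, 250, and 500 ms.
#' @param target_mean Desired mean of the output (default: preserve the
#'   input mean, so scaling to the inhibitory node base rates is done by the
#'   caller).
#' @return A `rate_trace` whose cross-correlation with the input peaks at
#'   +`lag`.
#' @export
derive_inhibitory_modulator <- function(exc_modulator, lag = 4,
                                        target_mean = NULL) {
  stopifnot(inherits(exc_modulator, "rate_trace"))
  if (!is.finite(lag) || lag < 0) stop("lag must be non-negative")
  if (lag >= trace_duration(exc_modulator)) {
    stop("lag exceeds the modulator duration")
  }
  v <- exc_modulator$values
  k <- as.integer(round(lag / exc_modulator$dt))
  shifted <- if (k == 0L) v else c(rep(v[1], k), v[seq_len(length(v) - k)])
  if (is.null(target_mean)) target_mean <- mean(v)
  m <- mean(shifted)
  if (m > 0) shifted <- shifted * (target_mean / m)
  rate_trace(shifted, dt = exc_modulator$dt, t0 = exc_modulator$t0)
}

#' Exaggerate deviations of a modulator from its mean
#'
#' Raises the modulatory trace to a power (the study uses 4) and renormalises
#' so the mean rate is unchanged. Large excursions are amplified, increasing
#' the variance of the drive without altering its mean -- used when probing
#' the sensitivity of integration to the E/I lag.
#'
#' @param modulator A `rate_trace`.
#' @param power Exponent >= 1.
#' @return A `rate_trace` with identical mean and variance >= the input's.
#' @export
sharpen_modulator <- function(modulator, power = 4) {
  stopifnot(inherits(modulator, "rate_trace"))
  if (!is.finite(power) || power < 1) stop("power must be >= 1")
  v <- modulator$values^power
  m <- mean(v)
  if (m > 0) v <- v * (mean(modulator$values) / m)
  rate_trace(v, dt = modulator$dt, t0 = modulator$t0)
}

#' Evaluate a sinusoidal rate modulation on a time grid
#'
#' Materialises `r(t) = A sin(2 pi f t + phi) + off` (with `A` tied to the
#' modulation depth, see [rhythm_spec()]) as a `rate_trace`. If the spec
#' carries a burst envelope, the oscillatory term is multiplied by it,
#' leaving the offset untouched. For depths <= 0.5 all values are
#' non-negative and the mean over an integer number of cycles equals `off`.
#'
#' @param spec A `rhythm_spec`.
#' @param duration Duration in ms.
#' @param dt Sample interval in ms.
#' @return A `rate_trace` in Hz.
#' @export
sine_rate <- function(spec, duration, dt = 1) {
  stopifnot(inherits(spec, "rhythm_spec"))
  if (!is.finite(duration) || duration <= 0 || !is.finite(dt) || dt <= 0) {
    stop("duration and dt must be positive")
  }
  t <- seq(0, duration - dt, by = dt)
  osc <- spec$amplitude * sin(2 * pi * spec$f * t / 1000 + spec$phase)
  if (!is.null(spec$envelope)) {
    env <- spec$envelope
    idx <- pmin(length(env$values), pmax(1L, 1L + as.integer(round((t - env$t0) / env$dt))))
    osc <- osc * env$values[idx]
  }
  r <- osc + spec$off
  if (any(r < 0)) {
    # depths above 0.5 push the trough below zero; a rate cannot be negative
    r <- pmax(r, 0)
  }
  rate_trace(r, dt = dt)
}

#' Gaussian burst envelope for oscillatory bursts
#'
#' In vivo, beta and gamma occur as brief bursts. The envelope is a Gaussian
#' kernel in time whose standard deviation equals two oscillatory cycles of
#' the carrier frequency, peaking at 1 at the burst centre.
#'
#' @param f Carrier frequency in Hz (> 0); sigma = 2 * 1000 / f ms.
#' @param center Burst centre in ms.
#' @param duration Envelope duration in ms.
#' @param dt Sample interval in ms.
#' @return A unitless `rate_trace` in \[0, 1\].
#' @export
burst_envelope <- function(f, center, duration, dt = 1) {
  if (!is.finite(f) || f <= 0) stop("frequency must be positive")
  sigma <- 2 * 1000 / f
  t <- seq(0, duration - dt, by = dt)
  rate_trace(exp(-((t - center)^2) / (2 * sigma^2)), dt = dt)
}
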