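#' Receptor kinetic parameters
#'
#' Dual-exponential synaptic kinetics expressed through the two-state
#' transmitter-gating scheme
#' \deqn{r' = \alpha T_{max}\, ON\, (1 - r) - \beta r,}
#' where `ON = 1` during a transmitter pulse and 0 otherwise. The printed
#' rise/decay constants (AMPA 0.6/6.9 ms, NMDA 3.7/125 ms, GABA_A
#' 0.5/6.8 ms) are converted by `beta = 1/tau_decay` and
#' `alpha + beta = 1/tau_rise`; the pulse duration `t_on` defaults to the
#' dual-exponential time-to-peak
#' \deqn{t_{peak} = \frac{\tau_r \tau_d}{\tau_d - \tau_r}
#'   \ln(\tau_d/\tau_r),}
#' so a single activation peaks at the closed-form time. Reversal potentials
#' are 0 mV (AMPA/NMDA) and -75 mV (GABA_A).
#'
#' @param tau_rise,tau_decay Rise/decay time constants, ms (decay > rise > 0).
#' @param E Reversal potential, mV.
#' @param t_on Transmitter pulse duration, ms; `NULL` selects the
#'   dual-exponential time-to-peak.
#' @return Object of class `kinetic_params` with fields `tau_rise`,
#'   `tau_decay`, `E`, `alpha`, `beta`, `t_on`.
#' @examples
#' kinetic_params(0.6, 6.9, 0) # AMPA
#' @export
kinetic_params <- function(tau_rise, tau_decay, E, t_on = NULL) {
  if (!(tau_decay > tau_rise && tau_rise > 0)) {
    stop("need tau_decay > tau_rise > 0")
  }
  beta <- 1 / tau_decay
  alpha <- 1 / tau_rise - beta
  if (is.null(t_on)) {
    t_on <- tau_rise * tau_decay / (tau_decay - tau_rise) *
      log(tau_decay / tau_rise)
  }
  structure(list(tau_rise = tau_rise, tau_decay = tau_decay, E = E,
                 alpha = alpha, beta = beta, t_on = t_on),
            class = "kinetic_params")
}

#' Default receptor kinetics (AMPA, NMDA, GABA_A)
#' @return Named list of `kinetic_params`.
#' @export
default_kinetics <- function() {
  list(
    AMPA = kinetic_params(0.6, 6.9, 0),
    NMDA = kinetic_params(3.7, 125, 0),
    GABA_A = kinetic_params(0.5, 6.8, -75)
  )
}

#' Closed-form time-to-peak of a dual-exponential conductance
#' @param tau_rise,tau_decay Time constants in ms.
#' @return Peak time in ms after activation onset.
#' @export
dual_exp_peak_time <- function(tau_rise, tau_decay) {
  tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
}

#' Voltage-dependent magnesium block of the NMDA receptor
#'
#' \deqn{s(V) = [1 + 0.33\, e^{-0.06 V}]^{-1}}
#' Strictly increasing in V with limit 1 as V grows; at 0 mV,
#' s = 1/1.33 ~= 0.752.
#'
#' @param V Membrane potential, mV (vectorised).
#' @param conc_factor,slope Block constants (defaults 0.33 and 0.06/mV).
#' @return Unblocked fraction in (0, 1].
#' @export
mg_block <- function(V, conc_factor = 0.33, slope = 0.06) {
  1 / (1 + conc_factor * exp(-slope * V))
}

#' Short-term depression parameters (two-factor model)
#'
#' Each factor obeys \eqn{\tau_D dD/dt = 1 - D} between stimuli and is
#' multiplied by its constant `d` (<= 1) at each presynaptic event; the
#' effective depression is the product `D1 * D2`. Named presets carry the
#' tuned values: excitatory (35 ms/0.95, 250 ms/0.8), perisomatic
#' inhibition (40 ms/0.7, 500 ms/0.7), and dendritic inhibition
#' (200 ms/0.8 with the slow factor disabled, i.e. `d2 = 1`).
#'
#' @param tau_d1,d1 Fast factor: recovery time constant (ms) and per-event
#'   multiplier.
#' @param tau_d2,d2 Slow factor.
#' @return Object of class `stp_params`.
#' @export
stp_params <- function(tau_d1, d1, tau_d2, d2) {
  if (tau_d1 <= 0 || tau_d2 <= 0) stop("recovery time constants must be > 0")
  if (d1 <= 0 || d1 > 1 || d2 <= 0 || d2 > 1) {
    stop("depression multipliers must lie in (0, 1]")
  }
  structure(list(tau_d1 = tau_d1, d1 = d1, tau_d2 = tau_d2, d2 = d2),
            class = "stp_params")
}

#' @rdname stp_params
#' @param name One of `"excitatory"`, `"perisomatic_inh"`, `"dendritic_inh"`,
#'   or `"none"` (depression disabled).
#' @export
stp_preset <- function(name = c("excitatory", "perisomatic_inh",
                                "dendritic_inh", "none")) {
  name <- match.arg(name)
  switch(name,
    excitatory = stp_params(35, 0.95, 250, 0.8),
    perisomatic_inh = stp_params(40, 0.7, 500, 0.7),
    dendritic_inh = stp_params(200, 0.8, 1, 1),
    none = stp_params(1, 1, 1, 1)
  )
}

#' Fresh short-term depression state
#' @param t0 Time of the (virtual) last update, ms.
#' @return Object of class `stp_state` with `D1 = D2 = 1`.
#' @export
stp_state <- function(t0 = -Inf) {
  structure(list(D1 = 1, D2 = 1, t_last = t0), class = "stp_state")
}

#' Advance a depression state across one presynaptic event
#'
#' Each factor first recovers exponentially toward 1 over the elapsed time,
#' `D <- 1 - (1 - D) exp(-dt/tau)`, then is multiplied by its constant `d`.
#' The effective depression returned (and intended to scale the evoked
#' conductance) is the recovered product *before* the multiplicative step,
#' so the first event of a rested synapse sees D = 1.
#'
#' @param state An `stp_state`.
#' @param params An `stp_params`.
#' @param t_event Event time, ms (>= `state$t_last`).
#' @return List with `state` (updated) and `D` (effective depression,
#'   clamped to <= 1).
#' @export
stp_step <- function(state, params, t_event) {
  stopifnot(inherits(state, "stp_state"), inherits(params, "stp_params"))
  if (t_event < state$t_last) stop("events must be processed in time order")
  dt <- t_event - state$t_last
  D1 <- 1 - (1 - state$D1) * exp(-dt / params$tau_d1)
  D2 <- 1 - (1 - state$D2) * exp(-dt / params$tau_d2)
  D <- min(1, D1 * D2)
  state$D1 <- D1 * params$d1
  state$D2 <- D2 * params$d2
  state$t_last <- t_event
  list(state = state, D = D)
}

#' Effective depression for a whole event train (vectorised recursion)
#'
#' Runs [stp_step()] over a sorted vector of event times and returns the
#' effective `D` seen by each event.
#'
#' @param times Sorted event times, ms.
#' @param params An `stp_params`.
#' @return Numeric vector of per-event depression factors in (0, 1].
#' @export
stp_train <- function(times, params) {
  if (is.unsorted(times)) stop("event times must be sorted")
  drop(stp_train_cpp(as.numeric(times), params$tau_d1, params$d1,
                     params$tau_d2, params$d2))
}

#' Synaptic current for given gating, voltage, and depression
#'
#' Implements `I = w * G * (V - E)` with `G = g_max * D * r`, multiplied by
#' the magnesium block `s(V)` for NMDA. Units: `g_max` in uS, V in mV,
#' I in nA.
#'
#' @param r Gating variable in \[0, 1\].
#' @param V Membrane potential, mV.
#' @param w Unitless synaptic weight.
#' @param g_max Maximal conductance, uS.
#' @param params A `kinetic_params`.
#' @param D Effective depression factor.
#' @param nmda Logical; apply the Mg2+ block.
#' @return List with `I` (nA) and `G` (uS).
#' @export
syn_current <- function(r, V, w, g_max, params, D = 1, nmda = FALSE) {
  if (any(r < 0 | r > 1)) stop("gating variable must lie in [0, 1]")
  G <- g_max * D * r
  if (nmda) G <- G * mg_block(V)
  list(I = w * G * (V - params$E), G = w * G)
}

#' Integrate the transmitter-gating variable over one step
#'
#' Exact update of `r' = alpha ON (1 - r) - beta r` over `dt` with `ON`
#' constant: exponential relaxation toward `alpha/(alpha+beta)` during a
#' pulse and pure decay otherwise.
#'
#' @param r Current gating value.
#' @param dt Step, ms.
#' @param params A `kinetic_params`.
#' @param on Logical: transmitter pulse active.
#' @return Updated gating value.
#' @export
gating_step <- function(r, dt, params, on) {
  if (on) {
    rinf <- params$alpha / (params$alpha + params$beta)
    rinf + (r - rinf) * exp(-(params$alpha + params$beta) * dt)
  } else {
    r * exp(-params$beta * dt)
  }
}

#' Simulated conductance time course of one synaptic activation
#'
#' Convenience wrapper used for calibration: integrates [gating_step()] on a
#' fine grid for a single release at t = 0 and returns the conductance
#' trace (unit weight and depression).
#'
#' @param params A `kinetic_params`.
#' @param g_max Maximal conductance, uS.
#' @param duration Trace length, ms.
#' @param dt Step, ms.
#' @return Data frame with `t` (ms) and `G` (uS).
#' @export
psc_waveform <- function(params, g_max = 1, duration = 50, dt = 0.1) {
  n <- as.integer(round(duration / dt))
  r <- numeric(n + 1)
  for (i in seq_len(n)) {
    t_now <- (i - 1) * dt
    r[i + 1] <- gating_step(r[i], dt, params, on = t_now < params$t_on)
  }
  data.frame(t = seq(0, n) * dt, G = g_max * r)
}

#' Draw maximal conductances for a synapse table
#'
#' Excitatory conductances follow a log-normal whose *distribution* mean and
#' standard deviation are 0.2 nS and 0.345 nS (moment-matched to the
#' underlying normal); inhibitory conductances are fixed at 1 nS.
#'
#' @param specs Synapse table (data frame with a `class` column,
#'   `"exc"`/`"inh"`).
#' @param seed Optional integer seed.
#' @param mean_nS,sd_nS Log-normal moments for excitatory synapses, nS.
#' @param inh_nS Fixed inhibitory conductance, nS.
#' @return The table with a `g_max_uS` column filled in (uS).
#' @export
draw_weights <- function(specs, seed = NULL, mean_nS = 0.2, sd_nS = 0.345,
                         inh_nS = 1) {
  if (!nrow(specs)) stop("specs must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  sigma2 <- log(1 + (sd_nS / mean_nS)^2)
  mu <- log(mean_nS) - sigma2 / 2
  g <- numeric(nrow(specs))
  exc <- specs$class == "exc"
  g[exc] <- stats::rlnorm(sum(exc), mu, sqrt(sigma2))
  g[!exc] <- inh_nS
  specs$g_max_uS <- g * 1e-3 # nS -> uS
  specs
}

#' Bernoulli release gate
#'
#' Independent release decision per presynaptic event and contact with
#' probability `p`.
#'
#' @param n Number of events.
#' @param p Release probability in (0, 1].
#' @param seed Optional integer seed.
#' @return Logical vector: event transmitted.
#' @export
release_gate <- function(n, p, seed = NULL) {
  if (any(p <= 0 | p > 1)) stop("release probability must lie in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  stats::runif(n) <= p
}

#' Short-term plasticity train-induction value
#'
#' Reference protocol: `n_pulses` (>= 8) presynaptic pulses at `f` Hz under
#' voltage clamp at `hold` mV; the per-pulse PSC peaks P_k are measured and
#' the induction value is `(mean(P6, P7, P8) - P1) / max(P)`. A depressing
#' synapse gives a negative value. With `amplitude_only = TRUE` the kinetic
#' waveform (and any summation) is ignored and the per-pulse effective
#' depression factors stand in for the peaks -- the calibration reference
#' used when comparing the Table-style presets (-0.60 perisomatic, -0.34
#' excitatory, -0.10 dendritic ordering).
#'
#' @param kin A `kinetic_params`.
#' @param stp An `stp_params`.
#' @param n_pulses Number of pulses (>= 8).
#' @param f Pulse rate, Hz (default 50).
#' @param hold Holding potential, mV.
#' @param g_max Maximal conductance, uS.
#' @param nmda Apply Mg2+ block at the holding potential.
#' @param amplitude_only Use the depression-only amplitude model.
#' @param dt Integration step, ms.
#' @return List with `induction`, per-pulse `peaks`, and pulse `times`.
#' @export
stp_train_induction <- function(kin, stp, n_pulses = 8, f = 50, hold = -70,
                                g_max = 1e-3, nmda = FALSE,
                                amplitude_only = FALSE, dt = 0.05) {
  if (n_pulses < 8) stop("the induction protocol needs at least 8 pulses")
  isi <- 1000 / f
  times <- (seq_len(n_pulses) - 1) * isi
  D <- stp_train(times, stp)
  if (amplitude_only) {
    peaks <- D
  } else {
    dur <- times[n_pulses] + 4 * kin$tau_decay
    n <- as.integer(round(dur / dt))
    r <- 0
    G <- numeric(n)
    pulse_end <- -Inf
    amp <- 0
    k <- 1L
    for (i in seq_len(n)) {
      t_now <- (i - 1) * dt
      if (k <= n_pulses && t_now >= times[k]) {
        pulse_end <- times[k] + kin$t_on
        amp <- D[k]
        k <- k + 1L
      }
      r <- gating_step(r, dt, kin, on = t_now < pulse_end)
      s <- if (nmda) mg_block(hold) else 1
      # under clamp the PSC is proportional to the conductance; D scales the
      # increment of the pulse that is currently (or was last) active
      G[i] <- g_max * amp * r * s
    }
    peaks <- vapply(seq_len(n_pulses), function(j) {
      i0 <- as.integer(times[j] / dt) + 1L
      i1 <- if (j < n_pulses) as.integer(times[j + 1] / dt) else n
      max(G[i0:i1])
    }, numeric(1))
    if (length(unique(round(peaks, 12))) < 1 || any(peaks <= 0)) {
      stop("invalid protocol: fewer than 8 detectable PSC peaks")
    }
  }
  list(
    induction = (mean(peaks[6:8]) - peaks[1]) / max(peaks),
    peaks = peaks, times = times
  )
}
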