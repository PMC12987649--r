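# Config-driven orchestration of the in-silico experiments at reduced
# scale: synapse-budget arithmetic, network assembly (morphology + synapse
# placement + presynaptic drive), the tonic / E-I-lag / rhythmic / burst /
# clustered regimes, and the ground-truth fixture suite for the detectors.

#' Synapse-budget arithmetic
#'
#' Deterministic reproduction of the synapse-count bookkeeping: per-zone
#' cable length times density, rounded, plus a fixed somatic inhibitory
#' contingent. With the printed lengths (7440 um apical, 4649 um basal,
#' 483 um of proximal dendrite) and densities (2.16 excitatory, 0.22
#' inhibitory per um) this gives 16070/10042 excitatory and 1637/1023
#' dendritic inhibitory contacts, and 106 + 150 = 256 perisomatic.
#'
#' @param lengths Named cable lengths, um: `apical`, `basal`,
#'   `perisomatic_dend`.
#' @param densities Named densities per um: `exc`, `inh`.
#' @param n_somatic Somatic inhibitory contacts (default 150).
#' @return Data frame (`zone`, `class`, `length_um`, `density_per_um`,
#'   `count`) with attribute `totals`: named vector with `exc`,
#'   `perisomatic_inh` (somatic + proximal dendritic), `dendritic_inh`.
#' @examples
#' synapse_budget()
#' @export
synapse_budget <- function(lengths = c(apical = 7440, basal = 4649,
                                       perisomatic_dend = 483),
                           densities = c(exc = 2.16, inh = 0.22),
                           n_somatic = 150) {
  if (any(lengths < 0) || any(densities < 0)) {
    stop("lengths and densities must be non-negative")
  }
  rows <- data.frame(
    zone = c("apical", "basal", "apical", "basal", "perisomatic_dend",
             "soma"),
    class = c("exc", "exc", "inh", "inh", "inh", "inh"),
    length_um = c(lengths[["apical"]], lengths[["basal"]],
                  lengths[["apical"]], lengths[["basal"]],
                  lengths[["perisomatic_dend"]], NA),
    density_per_um = c(densities[["exc"]], densities[["exc"]],
                       densities[["inh"]], densities[["inh"]],
                       densities[["inh"]], NA)
  )
  rows$count <- ifelse(is.na(rows$length_um), n_somatic,
                       round(rows$length_um * rows$density_per_um))
  attr(rows, "totals") <- c(
    exc = sum(rows$count[rows$class == "exc"]),
    perisomatic_inh = rows$count[rows$zone == "perisomatic_dend"] +
      n_somatic,
    dendritic_inh = sum(rows$count[rows$class == "inh" &
                                     rows$zone %in% c("apical", "basal")])
  )
  rows
}

#' Scenario configuration
#'
#' Bundles everything one simulated condition needs. Regimes: `baseline`
#' (naturalistic 1/f-modulated drive with E/I balance), `tonic_2x_perisomatic`
#' / `tonic_2x_distal` (doubled inhibitory drive to one zone), `ei_lag`
#' (sharpened excitatory modulator, independent perisomatic/distal lags),
#' `rhythm` (sinusoidal inhibitory modulation of one zone, homogeneous
#' Poisson excitation), `rhythm_swapped`, `freq_sweep`, `burst` (enveloped
#' rhythm), `clustered` (rhythm plus a patch of jitter-synchronised
#' excitatory input).
#'
#' @param regime Regime name (see above).
#' @param duration Simulated time, ms.
#' @param seed Integer seed governing every random stage.
#' @param scale Morphology scale factor (see [morphology_params()]).
#' @param rhythm_f,rhythm_depth Rhythm frequency (Hz) and depth.
#' @param rhythm_zone `"distal"` or `"perisomatic"`.
#' @param lag_perisomatic,lag_distal E/I lags, ms.
#' @param sweep_freqs Frequencies for `freq_sweep`, Hz.
#' @param burst Logical: apply the Gaussian burst envelope.
#' @param cluster_site `"nexus"` or `"basal"`.
#' @param cluster_rate Mean rate (Hz) of the Poisson process behind the
#'   jitter-synchronised cluster trains.
#' @param rec_dt Recording interval, ms.
#' @param dt Integration step, ms.
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(regime = "baseline", duration = 10000, seed = 1,
                            scale = 0.5, rhythm_f = 16, rhythm_depth = 0.2,
                            rhythm_zone = "distal",
                            lag_perisomatic = 4, lag_distal = 4,
                            sweep_freqs = c(0.5, 2, 5, 10, 16, 20, 30, 40,
                                            50, 60, 80),
                            burst = FALSE, cluster_site = "nexus",
                            cluster_rate = 10, rec_dt = 0.5, dt = 0.1) {
  regimes <- c("baseline", "tonic_2x_perisomatic", "tonic_2x_distal",
               "ei_lag", "rhythm", "rhythm_swapped", "freq_sweep", "burst",
               "clustered")
  regime <- match.arg(regime, regimes)
  if (duration <= 0) stop("duration must be positive")
  structure(as.list(environment()), class = "scenario_config")
}

#' Assemble the reduced-scale network (cell + synapses + node statistics)
#'
#' Builds the synthetic morphology at the configured scale, places
#' excitatory and inhibitory synapses at the full densities (the somatic
#' inhibitory contingent scales with the cell), draws conductances and
#' per-node mean rates, and groups excitatory nodes into functional groups.
#'
#' @param config A `scenario_config`.
#' @return List of class `network`: `morph`, `cell`, `specs` (combined
#'   synapse table), `exc_nodes`, `inh_nodes` (per-node data frames with
#'   rates and zones), `groups` (node ids per functional group).
#' @export
setup_network <- function(config) {
  set.seed(config$seed)
  morph <- build_synthetic_morphology(morphology_params(scale = config$scale))
  cell <- assemble_cell(morph)
  # the soma itself does not shrink with `scale`, so its fixed contingent
  # of inhibitory contacts stays at full strength
  n_som <- 150L
  # group size shrinks with the cell so several groups still form
  gsz <- max(20L, round(100 * config$scale))
  exc <- place_excitatory_synapses(morph, group_size = gsz)
  inh <- place_inhibitory_synapses(morph, n_somatic = n_som)
  inh$node_id <- inh$node_id + max(exc$node_id)
  inh$synapse_id <- inh$synapse_id + nrow(exc)
  specs <- rbind(exc, inh)
  specs <- draw_weights(specs)
  exc_nodes <- data.frame(node_id = sort(unique(exc$node_id)))
  exc_nodes$group_id <- exc$group_id[match(exc_nodes$node_id, exc$node_id)]
  exc_nodes$rate <- draw_node_rates(nrow(exc_nodes), 4.43, 2.9)
  inh_nodes <- data.frame(node_id = sort(unique(inh$node_id)))
  inh_nodes$zone <- inh$zone[match(inh_nodes$node_id, inh$node_id)]
  peri <- inh_nodes$zone == "perisomatic"
  inh_nodes$rate <- NA_real_
  inh_nodes$rate[peri] <- draw_node_rates(sum(peri), 16.9, 14.3)
  inh_nodes$rate[!peri] <- draw_node_rates(sum(!peri), 3.9, 4.9)
  groups <- split(exc_nodes$node_id, exc_nodes$group_id)
  structure(list(morph = morph, cell = cell, specs = specs,
                 exc_nodes = exc_nodes, inh_nodes = inh_nodes,
                 groups = groups),
            class = "network")
}

# internal: flat-modulator constant trace
.flat_mod <- function(duration, dt = 1) rate_trace(rep(1, round(duration / dt)), dt = dt)

# internal: unit-mean sinusoidal modulator for a rhythm (optionally bursty)
.rhythm_modulator <- function(f, depth, duration, dt = 1, burst = FALSE,
                              phase = 0) {
  amp <- depth / (1 - depth)
  t <- seq(0, duration - dt, by = dt)
  osc <- sin(2 * pi * f * t / 1000 + phase)
  if (burst) {
    # regular bursts: one burst every 8 cycles, sd of two cycles
    cyc <- 1000 / f
    centres <- seq(4 * cyc, duration, by = 8 * cyc)
    env <- rep(0, length(t))
    for (cen in centres) {
      env <- pmax(env, exp(-((t - cen)^2) / (2 * (2 * cyc)^2)))
    }
    osc <- osc * env
  }
  rate_trace(pmax(1 + amp * osc, 0), dt = dt)
}

#' Generate all presynaptic spike trains for one scenario
#'
#' Implements the drive regimes. Under naturalistic (tonic / lag) regimes
#' each functional group gets its own 1/f modulator; their average, shifted
#' by the E/I lag, modulates the inhibitory nodes of each zone. Under
#' rhythm regimes, excitation is homogeneous Poisson and the target zone's
#' inhibitory nodes follow the sinusoidal (optionally bursty) modulator
#' while the other zone stays Poisson.
#'
#' @param network A `network`.
#' @param config A `scenario_config`.
#' @param inh_gain Named multipliers on inhibitory node rates,
#'   `c(perisomatic = , distal = )` (tonic doubling).
#' @param rhythm_f,rhythm_zone Overrides of the config rhythm (for sweeps).
#' @return List: `trains` (all spike trains), `rhythm` (the `rhythm_spec`
#'   applied, or NULL), `exc_avg_mod` (average excitatory modulator).
#' @export
gen_drive <- function(network, config,
                      inh_gain = c(perisomatic = 1, distal = 1),
                      rhythm_f = NULL, rhythm_zone = NULL) {
  set.seed(config$seed + 1000L)
  dur <- config$duration
  regime <- config$regime
  rhythmic <- regime %in% c("rhythm", "rhythm_swapped", "freq_sweep",
                            "burst", "clustered")
  if (is.null(rhythm_f)) rhythm_f <- config$rhythm_f
  if (is.null(rhythm_zone)) rhythm_zone <- config$rhythm_zone
  en <- network$exc_nodes
  inh <- network$inh_nodes

  trains <- list()
  if (rhythmic) {
    flat <- .flat_mod(dur)
    trains <- c(trains, sample_poisson_group(en$rate, flat,
                                             node_ids = en$node_id))
    exc_avg <- flat
  } else {
    mods <- list()
    for (g in seq_along(network$groups)) {
      mods[[g]] <- gen_pink_modulator(dur)
      if (regime == "ei_lag") mods[[g]] <- sharpen_modulator(mods[[g]], 4)
      ids <- network$groups[[g]]
      trains <- c(trains, sample_poisson_group(
        en$rate[match(ids, en$node_id)], mods[[g]], node_ids = ids))
    }
    avg <- Reduce(`+`, lapply(mods, `[[`, "values")) / length(mods)
    exc_avg <- rate_trace(avg, dt = mods[[1]]$dt)
  }

  rhythm <- NULL
  for (zone in c("perisomatic", "distal")) {
    sel <- inh$zone == zone
    if (!any(sel)) next
    gain <- inh_gain[[zone]]
    if (rhythmic && zone == rhythm_zone) {
      depth <- config$rhythm_depth
      rhythm <- rhythm_spec(rhythm_f, depth, phase = 0, off = 1)
      mod <- .rhythm_modulator(rhythm_f, depth, dur,
                               burst = (regime == "burst" || config$burst))
    } else if (rhythmic) {
      mod <- .flat_mod(dur)
    } else {
      lag <- if (zone == "perisomatic") config$lag_perisomatic else config$lag_distal
      mod <- derive_inhibitory_modulator(exc_avg, lag = lag, target_mean = 1)
    }
    trains <- c(trains, sample_poisson_group(
      inh$rate[sel] * gain, mod, node_ids = inh$node_id[sel]))
  }
  list(trains = trains, rhythm = rhythm, exc_avg_mod = exc_avg)
}

#' Summarise event rates per kind and dendrite class
#'
#' @param events Result of [detect_all_events()].
#' @param morph The `morphology`.
#' @param duration Simulated time, ms.
#' @return Data frame `kind`, `class`, `rate_hz` (pooled event rate across
#'   compartments) plus the somatic AP rate as kind `"AP"`.
#' @export
event_rate_summary <- function(events, morph, duration) {
  apical <- dendritic_ids(morph, "apical")
  rows <- list(data.frame(kind = "AP", class = "soma",
                          rate_hz = length(events$ap$onsets) / duration * 1000))
  for (kind in c("Na", "NMDA", "Ca")) {
    for (cls in c("apical", "basal")) {
      ids <- dendritic_ids(morph, cls)
      n <- sum(vapply(events$dend, function(e) {
        if (e[[kind]]$comp %in% ids) length(e[[kind]]$onsets) else 0L
      }, numeric(1)))
      rows[[length(rows) + 1L]] <- data.frame(kind = kind, class = cls,
                                              rate_hz = n / duration * 1000)
    }
  }
  do.call(rbind, rows)
}

# internal: pooled onset times of one event kind across compartments
.pooled_onsets <- function(events, kind, ids = NULL) {
  sort(unlist(lapply(events$dend, function(e) {
    if (!is.null(ids) && !(e[[kind]]$comp %in% ids)) return(numeric())
    e[[kind]]$onsets
  })))
}

#' Run one scenario end to end
#'
#' Wires the modules per the configured regime: network assembly,
#' presynaptic drive, release/depression, cable integration, event
#' detection, and a manifest. Regime-specific analyses are performed by the
#' dedicated experiment helpers ([run_tonic_experiment()],
#' [run_rhythm_experiment()], [run_cluster_experiment()], [fi_curve()]).
#'
#' @param config A `scenario_config`.
#' @param record Quantities to record.
#' @return List of class `scenario_result`: `config`, `network`, `drive`,
#'   `traces`, `events`, `rates`, `manifest`.
#' @export
run_scenario <- function(config, record = c("v", "gna", "inmda", "ica")) {
  stopifnot(inherits(config, "scenario_config"))
  t_start <- Sys.time()
  network <- setup_network(config)
  gain <- c(perisomatic = 1, distal = 1)
  if (config$regime == "tonic_2x_perisomatic") gain[["perisomatic"]] <- 2
  if (config$regime == "tonic_2x_distal") gain[["distal"]] <- 2
  drive <- gen_drive(network, config, inh_gain = gain)
  specs <- network$specs
  cluster <- NULL
  if (config$regime == "clustered") {
    set.seed(config$seed + 2000L)
    # the patch is a fixed experimental manipulation (187 contacts over
    # 140 um, 1.3/um); it does not shrink with the morphology scale
    cl <- place_clustered_synapses(network$morph, config$cluster_site,
                                   n_synapses = 187, span_um = 140)
    base <- sample_poisson(
      rate_trace(rep(config$cluster_rate, config$duration), dt = 1),
      node_id = max(network$inh_nodes$node_id) + 1L)
    ctr <- gen_cluster_trains(base, 40, jitter = 2,
                              window = c(0, config$duration))
    cl$specs$node_id <- sample(vapply(ctr, `[[`, integer(1), "node_id"),
                               nrow(cl$specs), replace = TRUE)
    cl$specs$synapse_id <- cl$specs$synapse_id + max(specs$synapse_id)
    cl$specs <- draw_weights(cl$specs)
    specs <- rbind(specs, cl$specs)
    drive$trains <- c(drive$trains, list(base), ctr)
    cluster <- list(specs = cl$specs, trains = ctr,
                    density = cl$density)
  }
  deliveries <- build_deliveries(specs, drive$trains,
                                 seed = config$seed + 3000L)
  traces <- integrate_cell(network$cell, duration = config$duration,
                           synapses = specs, deliveries = deliveries,
                           dt = config$dt, record = record,
                           rec_dt = config$rec_dt)
  events <- if (all(c("v", "gna", "inmda", "ica") %in% record)) {
    detect_all_events(traces, network$morph)
  } else {
    list(ap = detect_aps(trace_of(traces, traces$soma, "v"), traces$dt,
                         t0 = traces$t0, comp = traces$soma),
         dend = list())
  }
  manifest <- list(
    regime = config$regime, seed = config$seed, scale = config$scale,
    duration_ms = config$duration,
    n_synapses = nrow(specs), n_deliveries = nrow(deliveries),
    package_version = as.character(utils::packageVersion("dendrhythm")),
    wall_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  )
  structure(list(config = config, network = network, drive = drive,
                 traces = traces, events = events, cluster = cluster,
                 rates = event_rate_summary(events, network$morph,
                                            config$duration),
                 manifest = manifest),
            class = "scenario_result")
}

#' Tonic-inhibition experiment (baseline vs doubled drive to one zone)
#'
#' @param seed Integer seed.
#' @param duration Simulated time per condition, ms.
#' @param scale Morphology scale.
#' @param conditions Regimes to run.
#' @param keep_traces Keep the full `trace_set` of each run (default FALSE:
#'   only events, rates, and the manifest are retained, which keeps long
#'   multi-condition sweeps within ordinary memory budgets).
#' @return Named list of `scenario_result`s (one per condition).
#' @export
run_tonic_experiment <- function(seed = 1, duration = 10000, scale = 0.5,
                                 conditions = c("baseline",
                                                "tonic_2x_distal",
                                                "tonic_2x_perisomatic"),
                                 keep_traces = FALSE) {
  out <- lapply(conditions, function(cond) {
    sc <- run_scenario(scenario_config(cond, duration = duration,
                                       seed = seed, scale = scale))
    if (!keep_traces) sc$traces <- NULL
    sc
  })
  names(out) <- conditions
  out
}

#' Rhythmic-inhibition experiment with phase analytics
#'
#' Runs a rhythm scenario and computes the phase-resolved summaries: phase
#' histograms of pooled dendritic-spike presence per kind, pairwise phase
#' consistency of event onsets, AP-threshold and membrane statistics split
#' by rhythm peak/trough, and the fluctuation bias.
#'
#' @param seed,duration,scale As elsewhere.
#' @param f Rhythm frequency, Hz.
#' @param depth Modulation depth.
#' @param zone `"distal"` or `"perisomatic"`.
#' @param burst Use the burst envelope.
#' @param keep_traces Keep the full `trace_set` (default FALSE).
#' @return List: `scenario`, `rhythm`, `phase` (per-kind phase histograms of
#'   presence), `ppc` (per-kind onset PPC), `threshold` (median AP threshold
#'   by stratum), `vm` (mean somatic V by stratum), `fluct` (fluctuation
#'   bias per phase bin), `mod_depth` (per-kind modulation range of the
#'   presence histogram, percent).
#' @export
run_rhythm_experiment <- function(seed = 1, duration = 10000, scale = 0.5,
                                  f = 16, depth = 0.2, zone = "distal",
                                  burst = FALSE, keep_traces = FALSE) {
  cfg <- scenario_config(if (burst) "burst" else "rhythm",
                         duration = duration, seed = seed, scale = scale,
                         rhythm_f = f, rhythm_depth = depth,
                         rhythm_zone = zone, burst = burst)
  sc <- run_scenario(cfg)
  rhythm <- sc$drive$rhythm
  phase <- list()
  ppcs <- c(Na = NA_real_, NMDA = NA_real_, Ca = NA_real_)
  mod_depth <- c(Na = NA_real_, NMDA = NA_real_, Ca = NA_real_)
  for (kind in c("Na", "NMDA", "Ca")) {
    onsets <- .pooled_onsets(sc$events, kind)
    if (length(onsets) >= 10) {
      ph <- phase_histogram(onsets, rhythm)
      phase[[kind]] <- ph
      mod_depth[[kind]] <- max(ph$pct_change) - min(ph$pct_change)
      ppcs[[kind]] <- ppc(phase_of(onsets, rhythm))
    }
  }
  v <- trace_of(sc$traces, sc$traces$soma, "v")
  aps <- sc$events$ap
  thr <- ap_threshold(v, sc$traces$dt, aps$peaks, t0 = sc$traces$t0)
  # somatic excitability reads on the inhibitory *conductance* cycle, which
  # lags the presynaptic rate by the synaptic kernel phase
  lag <- synaptic_phase_lag(rhythm$f)
  strat <- peak_trough_masks(rhythm, aps$peaks[seq_along(thr)] - lag)
  t_grid <- sc$traces$t0 + (seq_along(v) - 1) * sc$traces$dt
  vm_strat <- peak_trough_masks(rhythm, t_grid - lag)
  threshold <- c(
    peak = stats::median(thr[strat == "peak"]),
    trough = stats::median(thr[strat == "trough"])
  )
  vm <- c(peak = mean(v[vm_strat == "peak"]),
          trough = mean(v[vm_strat == "trough"]))
  ap_ph <- if (length(aps$onsets) >= 10) {
    phase_histogram(aps$onsets, rhythm)
  } else {
    NULL
  }
  fluct <- fluctuation_bias(v, sc$traces$dt, rhythm, t0 = sc$traces$t0)
  if (!keep_traces) sc$traces <- NULL
  list(scenario = sc, rhythm = rhythm, phase = phase, ap_phase = ap_ph,
       ppc = ppcs, threshold = threshold, vm = vm, fluct = fluct,
       mod_depth = mod_depth)
}

#' Clustered-input experiment: phase-stratified transmission
#'
#' Adds a patch of jitter-synchronised excitatory synapses (nexus or basal)
#' under rhythmic inhibition and measures the corrected cross-correlogram
#' between the pooled cluster drive and somatic APs separately for
#' presynaptic spikes arriving at the rhythm peak and trough.
#'
#' @param seed,duration,scale As elsewhere.
#' @param f,depth Rhythm parameters.
#' @param zone Inhibitory rhythm zone.
#' @param site Cluster placement, `"nexus"` or `"basal"`.
#' @param keep_traces Keep the full `trace_set` (default FALSE).
#' @return List: `scenario`, `cc` (list with `peak`, `trough` `cc_result`s),
#'   `peak_area` (named numeric).
#' @export
run_cluster_experiment <- function(seed = 1, duration = 15000, scale = 0.5,
                                   f = 16, depth = 0.2, zone = "distal",
                                   site = "nexus", keep_traces = FALSE) {
  cfg <- scenario_config("clustered", duration = duration, seed = seed,
                         scale = scale, rhythm_f = f, rhythm_depth = depth,
                         rhythm_zone = zone, cluster_site = site)
  sc <- run_scenario(cfg)
  pre <- sort(unlist(lapply(sc$cluster$trains, `[[`, "times")))
  aps <- sc$events$ap$onsets
  cc <- list()
  area <- c(peak = NA_real_, trough = NA_real_)
  if (length(aps) >= 5 && length(pre)) {
    for (st in c("peak", "trough")) {
      cc[[st]] <- phase_stratified_cc(pre, aps, duration = duration,
                                      rhythm = sc$drive$rhythm,
                                      stratum = st, max_lag = 100,
                                      peak_search = c(0, 30),
                                      stratum_lag = synaptic_phase_lag(f))
      area[[st]] <- cc[[st]]$peak_area
    }
  }
  if (!keep_traces) sc$traces <- NULL
  list(scenario = sc, cc = cc, peak_area = area)
}

#' Ground-truth fixture suite for the detectors and analytics
#'
#' Constructs synthetic traces with implanted events whose times are known
#' by construction: an AP trace, an Na+ conductance trace with a
#' bAP-confounded pulse, NMDA-like and Ca-like plateau fixtures in which
#' only the matching current satisfies the plateau criterion, a
#' phase-locked event train, and a delta-coupled pre/post train pair.
#'
#' @param seed Integer seed.
#' @return List with elements `ap`, `na`, `nmda`, `ca`, `phase_locked`,
#'   `delta_coupled`; each carries its traces/times, metadata, and a
#'   `truth` entry.
#' @export
fixture_suite <- function(seed = 1) {
  set.seed(seed)
  dt <- 0.1
  dur <- 2000
  n <- dur / dt
  t <- (seq_len(n)) * dt

  bump <- function(centre, width, height, base, tt) {
    base + height * exp(-((tt - centre)^2) / (2 * width^2))
  }
  # --- AP fixture: 5 spikes crossing -10 mV
  ap_times <- c(200, 500, 900, 1300, 1750)
  v <- rep(-70, n)
  for (a in ap_times) v <- pmax(v, bump(a, 0.4, 95, -70, t))
  ap_fix <- list(v = v, dt = dt, t0 = dt, truth = ap_times)

  # --- Na fixture: 4 free pulses + 1 pulse 1 ms after an AP (excluded)
  na_free <- c(150, 600, 1100, 1600)
  ap_for_na <- 1000
  gna <- rep(0.05, n)
  for (a in c(na_free, ap_for_na + 1)) gna <- pmax(gna, bump(a, 0.3, 0.55, 0.05, t))
  na_fix <- list(gna = gna, dt = dt, t0 = dt, ap_times = ap_for_na,
                 truth = na_free)

  # --- plateau fixtures: 40 ms V excursion above -40 mV; the driving
  # current doubles shortly after the crossing and decays linearly through
  # the 1.15x reference level inside the excursion.
  plat_on <- 800
  plat_len <- 40
  v_p <- rep(-70, n)
  v_p[t >= plat_on & t < plat_on + plat_len] <- -30
  i_ref <- 0.05
  i_drive <- rep(i_ref, n)
  ramp_up_end <- plat_on + 4
  decay_start <- plat_on + 20
  decay_end <- plat_on + 36
  seg <- t >= plat_on & t < ramp_up_end
  i_drive[seg] <- i_ref * (1 + (t[seg] - plat_on) / 4) # rises to 2x
  i_drive[t >= ramp_up_end & t < decay_start] <- 2 * i_ref
  seg <- t >= decay_start & t < decay_end
  i_drive[seg] <- i_ref * (2 - 1.2 * (t[seg] - decay_start) / 16) # to 0.8x
  i_drive[t >= decay_end] <- 0.8 * i_ref
  # truth: onset where i first reaches 1.3x ref; offset where it falls
  # back to 1.15x (computed from the ramp geometry, not the detector)
  truth_on <- plat_on + 4 * 0.3            # 1 + x/4 = 1.3
  truth_off <- decay_start + 16 * (0.85 / 1.2) # 2 - 1.2 x/16 = 1.15
  flat <- rep(i_ref, n)
  nmda_fix <- list(v = v_p, i_nmda = -i_drive, i_ca = -flat, dt = dt,
                   t0 = dt, truth = list(onset = truth_on, offset = truth_off))
  ca_fix <- list(v = v_p, i_nmda = -flat, i_ca = -i_drive, dt = dt,
                 t0 = dt, truth = list(onset = truth_on, offset = truth_off))

  # --- phase-locked events: wrapped-normal phases around 0 for a 16 Hz
  # rhythm (concentration high enough that PPC > 0.9 by construction)
  rhythm <- rhythm_spec(16, 0.2, off = 10)
  cyc <- 1000 / 16
  centres <- seq(cyc, 20000 - cyc, by = cyc)
  # phase 0 (rate maximum) sits a quarter period into each cycle
  locked <- sort(centres + cyc / 4 + stats::rnorm(length(centres), 0, 0.02 * cyc))
  phase_fix <- list(times = locked, rhythm = rhythm, truth = 0)

  # --- delta-coupled trains: post = pre + 3 ms
  pre <- sample_poisson(rate_trace(rep(20, 20000), dt = 1), node_id = 1L)
  post <- spike_train(2L, pre$times + 3)
  delta_fix <- list(pre = pre$times, post = post$times, duration = 20010,
                    truth = 3)

  list(ap = ap_fix, na = na_fix, nmda = nmda_fix, ca = ca_fix,
       phase_locked = phase_fix, delta_coupled = delta_fix)
}
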