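#' Channel density map
#'
#' Peak conductance densities (S/cm2) per region for the ten
#' Hodgkin-Huxley-style conductances: fast-inactivating Na+ (NaT),
#' persistent Na+ (NaP), h-current (Ih), muscarinic K+ (Im), slow- and
#' fast-inactivating K+ (KPst, KTst), fast non-inactivating K+ (Kv31),
#' high- and low-voltage-activated Ca2+ (CaHVA, CaLVA), and
#' Ca2+-activated K+ (SK). The soma carries every channel except Im;
#' dendritic regions carry exactly \{CaLVA, CaHVA, SK, Kv31, NaT, Im, Ih\}.
#' The nexus gets a Ca2+ "hot zone" (elevated CaHVA/CaLVA) so that strong
#' apical input evokes a calcium plateau there. Defaults are tuned for the
#' synthetic morphology and are configuration, not measurements.
#'
#' @param overrides Named list `list(region = c(channel = value))` applied on
#'   top of the defaults.
#' @return Data frame, regions x 10 channels, class `density_map`.
#' @export
channel_density_map <- function(overrides = NULL) {
  chan <- c("NaT", "NaP", "Ih", "Im", "KPst", "KTst", "Kv31",
            "CaHVA", "CaLVA", "SK")
  m <- rbind(
    soma         = c(2.20, 0.0017, 0.0002, 0,       0.0022, 0.081, 0.70, 0.00099, 0.0034, 0.044),
    axon         = c(3.10, 0.0068, 0,      0,       0.97,   0.089, 1.87, 0.00099, 0.0081, 0.007),
    basal        = c(0.035, 0,     0.0002, 0.00007, 0,      0,     0.0003, 0.0006, 0.0002, 0.0012),
    apical_trunk = c(0.028, 0,     0.002,  0.00007, 0,      0,     0.0003, 0.0006, 0.0002, 0.0012),
    nexus        = c(0.028, 0,     0.002,  0.00007, 0,      0,     0.0003, 0.0120, 0.0080, 0.0012),
    tuft         = c(0.028, 0,     0.002,  0.001,   0,      0,     0.02,   0.0006, 0.0010, 0.0240)
  )
  colnames(m) <- chan
  df <- as.data.frame(m)
  if (!is.null(overrides)) {
    for (reg in names(overrides)) {
      vals <- overrides[[reg]]
      df[reg, names(vals)] <- vals
    }
  }
  class(df) <- c("density_map", "data.frame")
  df
}

#' Passive membrane parameters
#'
#' Membrane capacitance is 1 uF/cm2 for soma and axon and 2 uF/cm2 for
#' dendrites (correcting for spine area), axial resistivity 100 Ohm cm, and
#' the leak reverses at -90 mV. Leak conductance is per-region
#' configuration.
#'
#' @param cm Named vector, uF/cm2 for `soma`, `axon`, `dend`.
#' @param ra Axial resistivity, Ohm cm.
#' @param e_leak Leak reversal, mV.
#' @param g_leak Named per-region leak densities, S/cm2.
#' @return List of class `passive_params`.
#' @export
passive_params <- function(cm = c(soma = 1, axon = 1, dend = 2),
                           ra = 100, e_leak = -90,
                           g_leak = c(soma = 3.38e-5, axon = 3.38e-5,
                                      basal = 4.67e-5, apical_trunk = 5.89e-5,
                                      nexus = 5.89e-5, tuft = 1.77e-4)) {
  if (any(c(cm, ra, g_leak) <= 0)) stop("passive parameters must be positive")
  structure(list(cm = cm, ra = ra, e_leak = e_leak, g_leak = g_leak),
            class = "passive_params")
}

#' Calcium-pool parameters for the SK current
#'
#' Single-pool first-order model: influx from the (HVA + LVA) calcium
#' current into a thin submembrane shell, exponential return to the resting
#' level.
#'
#' @param gamma Fraction of the calcium current reaching the pool (named per
#'   region or scalar).
#' @param decay Removal time constant, ms (named per region or scalar).
#' @param depth Shell depth, um.
#' @param min_ca Resting calcium, mM.
#' @param cao Extracellular calcium, mM (sets the Nernst potential).
#' @return List of class `ca_params`.
#' @export
ca_params <- function(gamma = 0.0005, decay = c(soma = 460, axon = 80,
                                                basal = 120, apical_trunk = 120,
                                                nexus = 120, tuft = 120),
                      depth = 0.1, min_ca = 1e-4, cao = 2) {
  structure(list(gamma = gamma, decay = decay, depth = depth,
                 min_ca = min_ca, cao = cao), class = "ca_params")
}

#' Assemble a simulatable cell from morphology, densities, and passives
#'
#' Validates the channel roster (no Im at the soma; dendrites restricted to
#' their seven channels, i.e. zero NaP/KPst/KTst density) and flattens all
#' per-region parameters into per-compartment arrays for the solver.
#'
#' @param morph A `morphology`.
#' @param densities A `density_map` (see [channel_density_map()]).
#' @param passive A `passive_params`.
#' @param ca A `ca_params`.
#' @return Object of class `cell`.
#' @export
assemble_cell <- function(morph, densities = channel_density_map(),
                          passive = passive_params(), ca = ca_params()) {
  stopifnot(inherits(morph, "morphology"))
  df <- morph$df
  regions <- unique(df$region)
  missing <- setdiff(regions, rownames(densities))
  if (length(missing)) stop("no densities for region(s): ",
                            paste(missing, collapse = ", "))
  if (densities["soma", "Im"] > 0) {
    stop("invalid config: the soma must not carry Im")
  }
  dend_regions <- intersect(c("basal", "apical_trunk", "nexus", "tuft"), regions)
  for (reg in dend_regions) {
    bad <- c("NaP", "KPst", "KTst")[unlist(densities[reg, c("NaP", "KPst", "KTst")]) > 0]
    if (length(bad)) {
      stop("invalid config: dendritic region '", reg,
           "' may not carry ", paste(bad, collapse = ", "))
    }
  }
  region_of <- df$region
  cm <- ifelse(region_of == "soma", passive$cm[["soma"]],
               ifelse(region_of == "axon", passive$cm[["axon"]],
                      passive$cm[["dend"]]))
  gl <- unname(unlist(passive$g_leak[region_of]))
  chan <- as.matrix(densities[region_of, , drop = FALSE])
  rownames(chan) <- NULL
  expand <- function(x) {
    if (length(x) == 1) rep(unname(x), nrow(df)) else unname(unlist(x[region_of]))
  }
  structure(list(
    morph = morph,
    densities = densities, passive = passive, ca = ca,
    n_comp = nrow(df),
    parent0 = as.integer(df$parent - 1L), # -1 root in 0-based indexing
    length = df$length, diam = df$diam,
    cm = cm, gl = gl, chan = chan,
    ca_gamma = expand(ca$gamma), ca_decay = expand(ca$decay),
    soma = df$id[df$region == "soma"][1]
  ), class = "cell")
}

#' @export
print.cell <- function(x, ...) {
  cat(sprintf("<cell> %d compartments, soma id %d\n", x$n_comp, x$soma))
  invisible(x)
}

# engine ordering of synapse kinds
.KIND_CODE <- c(AMPA = 0L, NMDA = 1L, GABA = 2L)

# internal: expand a synapse spec table into engine-level entries.
# An excitatory contact contributes an AMPA and an NMDA entry sharing its
# deliveries; an inhibitory contact contributes one GABA_A entry.
.engine_synapses <- function(specs, nmda_ratio) {
  if (is.null(specs) || !nrow(specs)) {
    return(list(comp0 = integer(), kind = integer(),
                map = list(), gmult = list()))
  }
  exc <- specs$class == "exc"
  n_entry <- sum(exc) * 2L + sum(!exc)
  comp0 <- integer(n_entry)
  kind <- integer(n_entry)
  map <- vector("list", nrow(specs))
  gmult <- vector("list", nrow(specs))
  k <- 0L
  for (j in seq_len(nrow(specs))) {
    if (exc[j]) {
      comp0[k + 1:2] <- specs$comp[j] - 1L
      kind[k + 1L] <- .KIND_CODE[["AMPA"]]
      kind[k + 2L] <- .KIND_CODE[["NMDA"]]
      map[[j]] <- c(k, k + 1L)
      gmult[[j]] <- c(specs$g_max_uS[j], specs$g_max_uS[j] * nmda_ratio)
      k <- k + 2L
    } else {
      comp0[k + 1L] <- specs$comp[j] - 1L
      kind[k + 1L] <- .KIND_CODE[["GABA"]]
      map[[j]] <- k
      gmult[[j]] <- specs$g_max_uS[j]
      k <- k + 1L
    }
  }
  list(comp0 = comp0, kind = kind, map = map, gmult = gmult)
}

#' Integrate the cell under synaptic drive and/or current injection
#'
#' Solves the branched cable equation with the ten-channel membrane model by
#' a Hines-ordered semi-implicit backward-Euler scheme at `dt` (default
#' 0.1 ms). Synaptic input arrives as *deliveries* -- released presynaptic
#' events with their effective depression, see [build_deliveries()] --
#' mapped onto the synapse table.
#'
#' @param cell A `cell`.
#' @param duration Simulated time, ms.
#' @param synapses Synapse spec table (rows with `comp`, `class`,
#'   `g_max_uS`), or `NULL`.
#' @param deliveries Data frame (`synapse_id`, `time`, `D`), or `NULL`.
#' @param inj Data frame of current injections: columns `comp`, `amp`
#'   (nA), `t_on`, `t_off` (ms), optional `sine_amp` (nA), `sine_freq` (Hz).
#' @param dt Integration step, ms (default 0.1).
#' @param record Character subset of `c("v", "gna", "inmda", "ica", "cai")`.
#' @param rec_comps Compartment ids to record (default: soma + all
#'   dendritic compartments).
#' @param rec_dt Recording interval, ms (multiple of `dt`).
#' @param v_init Initial potential, mV.
#' @param nmda_ratio NMDA:AMPA maximal-conductance ratio (default 0.8).
#' @return A `trace_set`: list with `dt`, `t0`, `comps`, and one matrix per
#'   recorded quantity (samples x compartments; `gna` is the within-interval
#'   peak in mS/cm2, `inmda`/`ica` are currents in nA).
#' @export
integrate_cell <- function(cell, duration, synapses = NULL, deliveries = NULL,
                           inj = NULL, dt = 0.1,
                           record = c("v", "gna", "inmda", "ica"),
                           rec_comps = NULL, rec_dt = dt, v_init = -80,
                           nmda_ratio = 0.8) {
  stopifnot(inherits(cell, "cell"))
  if (duration <= 0) stop("duration must be positive")
  rec_every <- as.integer(round(rec_dt / dt))
  if (abs(rec_every * dt - rec_dt) > 1e-9) {
    stop("rec_dt must be a multiple of dt")
  }
  n_steps <- as.integer(round(duration / dt))
  if (is.null(rec_comps)) {
    rec_comps <- c(cell$soma, dendritic_ids(cell$morph))
  }
  bad <- setdiff(rec_comps, seq_len(cell$n_comp))
  if (length(bad)) stop("unknown recording compartment(s)")
  kin <- default_kinetics()
  kv <- function(field) vapply(kin[c("AMPA", "NMDA", "GABA_A")], `[[`,
                               numeric(1), field)
  es <- .engine_synapses(synapses, nmda_ratio)
  # expand deliveries onto engine entries
  if (!is.null(deliveries) && nrow(deliveries)) {
    if (is.null(synapses)) stop("deliveries given without a synapse table")
    row_of <- match(deliveries$synapse_id, synapses$synapse_id)
    if (anyNA(row_of)) stop("delivery refers to an unknown synapse")
    reps <- lengths(es$map[row_of])
    didx <- rep(seq_len(nrow(deliveries)), reps)
    dsyn <- unlist(es$map[row_of])
    dmult <- unlist(es$gmult[row_of])
    step <- pmax(0L, as.integer(round(deliveries$time[didx] / dt)))
    ord <- order(step)
    del_step <- step[ord]
    del_syn <- as.integer(dsyn[ord])
    del_c <- (dmult * deliveries$D[didx])[ord]
  } else {
    del_step <- integer()
    del_syn <- integer()
    del_c <- numeric()
  }
  if (is.null(inj) || !nrow(inj)) {
    inj <- data.frame(comp = integer(), amp = numeric(), t_on = numeric(),
                      t_off = numeric())
  }
  if (is.null(inj$sine_amp)) inj$sine_amp <- rep(0, nrow(inj))
  if (is.null(inj$sine_freq)) inj$sine_freq <- rep(0, nrow(inj))
  if (nrow(inj) && any(!inj$comp %in% seq_len(cell$n_comp))) {
    stop("injection into unknown compartment")
  }
  res <- simulate_cpp(
    cell$parent0, cell$length, cell$diam, cell$cm, cell$passive$ra,
    cell$gl, cell$passive$e_leak, cell$chan,
    50, -85, -45, cell$ca$cao,
    cell$ca_gamma, cell$ca_decay, cell$ca$depth, cell$ca$min_ca,
    as.integer(es$comp0), as.integer(es$kind),
    kv("alpha"), kv("beta"), kv("t_on"), kv("E"),
    as.integer(del_step), del_syn, del_c,
    as.integer(inj$comp - 1L), inj$amp,
    as.integer(round(inj$t_on / dt)), as.integer(round(inj$t_off / dt)),
    inj$sine_amp, inj$sine_freq,
    dt, n_steps, v_init,
    as.integer(rec_comps - 1L), rec_every,
    "v" %in% record, "gna" %in% record, "inmda" %in% record,
    "ica" %in% record, "cai" %in% record
  )
  out <- list(dt = rec_dt, t0 = rec_dt, duration = duration,
              comps = rec_comps, soma = cell$soma, v_final = res$v_final)
  for (nm in c("v", "gna", "inmda", "ica", "cai")) {
    if (nm %in% record ||
        (nm == "v" && "v" %in% record)) {
      m <- res[[nm]]
      if (nrow(m)) colnames(m) <- rec_comps
      out[[nm]] <- m
    }
  }
  structure(out, class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set> %g ms at %g ms resolution, %d compartments\n",
              x$duration, x$dt, length(x$comps)))
  invisible(x)
}

#' Extract one recorded series from a trace set
#' @param ts A `trace_set`.
#' @param comp Compartment id.
#' @param what One of `"v"`, `"gna"`, `"inmda"`, `"ica"`, `"cai"`.
#' @return Numeric vector.
#' @export
trace_of <- function(ts, comp, what = "v") {
  stopifnot(inherits(ts, "trace_set"))
  m <- ts[[what]]
  if (is.null(m)) stop("'", what, "' was not recorded")
  j <- match(comp, ts$comps)
  if (is.na(j)) stop("compartment ", comp, " was not recorded")
  m[, j]
}

#' Inject a square current step
#'
#' Convenience wrapper around [integrate_cell()] adding a square pulse at
#' one compartment (soma by default), on top of any synaptic drive.
#'
#' @param cell A `cell`.
#' @param amplitude Step amplitude, nA (negative allowed).
#' @param duration Step length, ms.
#' @param compartment Target compartment id (default soma).
#' @param t_on Step onset, ms.
#' @param total Total simulated time, ms (default pad of 100 ms after the
#'   step).
#' @param ... Passed to [integrate_cell()].
#' @return A `trace_set`.
#' @export
inject_step <- function(cell, amplitude, duration, compartment = NULL,
                        t_on = 100, total = NULL, ...) {
  if (is.null(compartment)) compartment <- cell$soma
  if (is.null(total)) total <- t_on + duration + 100
  inj <- data.frame(comp = compartment, amp = amplitude,
                    t_on = t_on, t_off = t_on + duration)
  integrate_cell(cell, duration = total, inj = inj, ...)
}

# internal: complex admittance matrix of the passive-linearised cell at
# angular frequency omega (rad/ms); units uS / nF
.passive_admittance <- function(cell, omega) {
  n <- cell$n_comp
  area <- pi * cell$diam * cell$length
  gl <- cell$gl * area * 1e-2      # uS
  cap <- cell$cm * area * 1e-5     # nF
  A <- matrix(0 + 0i, n, n)
  diag(A) <- gl + 1i * omega * cap
  ra_rel <- cell$passive$ra / 100
  rhalf <- ra_rel * (cell$length / 2) / (pi * cell$diam^2 / 4) # MOhm
  for (i in seq_len(n)) {
    p <- cell$parent0[i] + 1L
    if (p < 1) next
    g <- 1 / (rhalf[i] + rhalf[p])
    A[i, i] <- A[i, i] + g
    A[p, p] <- A[p, p] + g
    A[i, p] <- A[i, p] - g
    A[p, i] <- A[p, i] - g
  }
  A
}

#' Electrotonic attenuation toward the soma
#'
#' Measures, on the passive-linearised cell, the ratio of the somatic
#' voltage response to the local response for a subthreshold sinusoidal
#' current injected at each compartment (default 20 Hz, a timescale
#' comparable to the membrane time constant). Computed in the frequency
#' domain from the complex impedance matrix.
#'
#' @param cell A `cell`.
#' @param comps Compartment ids (default all).
#' @param f Frequency, Hz.
#' @return Data frame with `comp` and `ratio` (soma amplitude / local
#'   amplitude, in (0, 1]; 1 at the soma itself).
#' @export
measure_attenuation <- function(cell, comps = NULL, f = 20) {
  stopifnot(inherits(cell, "cell"))
  if (f < 0) stop("frequency must be non-negative")
  if (is.null(comps)) comps <- seq_len(cell$n_comp)
  omega <- 2 * pi * f / 1000 # rad/ms
  A <- .passive_admittance(cell, omega)
  Z <- solve(A)
  soma <- cell$soma
  ratio <- Mod(Z[soma, comps]) / Mod(Z[cbind(comps, comps)])
  data.frame(comp = comps, ratio = as.numeric(ratio))
}

#' Group dendritic compartments into electrotonic-distance deciles
#'
#' Within each dendrite class (apical, basal), compartments are ranked by
#' their attenuation ratio (1 = electrotonically closest to the soma) and
#' split into `n_bins` equal-count groups; decile 1 is closest. Ties are
#' broken by compartment id. Classes with fewer compartments than bins fall
#' back to one compartment per bin with a warning.
#'
#' @param morph A `morphology`.
#' @param ratios Data frame `comp`/`ratio` as from [measure_attenuation()];
#'   must cover every dendritic compartment.
#' @param n_bins Number of groups (default 10).
#' @return Data frame `comp`, `class` (apical/basal), `ratio`, `decile`.
#' @export
electrotonic_deciles <- function(morph, ratios, n_bins = 10) {
  stopifnot(inherits(morph, "morphology"))
  out <- list()
  for (cls in c("apical", "basal")) {
    ids <- dendritic_ids(morph, cls)
    if (!length(ids)) next
    r <- ratios$ratio[match(ids, ratios$comp)]
    if (anyNA(r)) stop("ratios must cover every dendritic compartment")
    nb <- n_bins
    if (length(ids) < n_bins) {
      warning("fewer ", cls, " compartments than bins; using ", length(ids))
      nb <- length(ids)
    }
    ord <- order(-r, ids)
    decile <- integer(length(ids))
    decile[ord] <- ceiling(seq_along(ids) / (length(ids) / nb))
    decile <- pmin(decile, nb)
    out[[cls]] <- data.frame(comp = ids, class = cls, ratio = r,
                             decile = decile)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Turn presynaptic spike trains into synaptic deliveries
#'
#' For every contact of every presynaptic node: short-term depression is
#' advanced across all node events (each presynaptic stimulus depresses,
#' whether or not it releases), a Bernoulli release gate with the contact's
#' probability selects the transmitted events, and each transmitted event
#' becomes a delivery carrying the effective depression at that moment.
#'
#' @param specs Synapse table with `node_id`, `p_release`, `stp` columns.
#' @param trains List of `spike_train` objects (node ids must cover the
#'   table's nodes that should fire).
#' @param seed Optional integer seed.
#' @return Data frame `synapse_id`, `time`, `D`, sorted by time.
#' @export
build_deliveries <- function(specs, trains, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- vapply(trains, `[[`, integer(1), "node_id")
  out_id <- vector("list", nrow(specs))
  out_t <- vector("list", nrow(specs))
  out_d <- vector("list", nrow(specs))
  # cache per node x stp preset: the D sequence is shared by its contacts
  d_cache <- new.env(parent = emptyenv())
  for (j in seq_len(nrow(specs))) {
    tr <- match(specs$node_id[j], ids)
    if (is.na(tr)) next
    times <- trains[[tr]]$times
    if (!length(times)) next
    key <- paste0(specs$node_id[j], ":", specs$stp[j])
    D <- get0(key, envir = d_cache)
    if (is.null(D)) {
      D <- stp_train(times, stp_preset(specs$stp[j]))
      assign(key, D, envir = d_cache)
    }
    keep <- stats::runif(length(times)) <= specs$p_release[j]
    if (!any(keep)) next
    out_id[[j]] <- rep(specs$synapse_id[j], sum(keep))
    out_t[[j]] <- times[keep]
    out_d[[j]] <- D[keep]
  }
  df <- data.frame(
    synapse_id = unlist(out_id), time = unlist(out_t), D = unlist(out_d)
  )
  if (!nrow(df)) return(df)
  df[order(df$time), , drop = FALSE]
}

#' Draw per-node mean firing rates
#'
#' Samples node rates from a gamma distribution moment-matched to the given
#' mean and standard deviation, truncated below at `min_rate`. Used with
#' 4.43 +/- 2.9 Hz for excitatory nodes and the zone-specific inhibitory
#' values (16.9 +/- 14.3 Hz perisomatic, 3.9 +/- 4.9 Hz dendritic).
#'
#' @param n Number of nodes.
#' @param mean,sd Target moments, Hz.
#' @param min_rate Lower truncation, Hz.
#' @param seed Optional integer seed.
#' @return Numeric vector of rates (Hz).
#' @export
draw_node_rates <- function(n, mean = 4.43, sd = 2.9, min_rate = 0.1,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  shape <- (mean / sd)^2
  rate <- mean / sd^2
  pmax(stats::rgamma(n, shape = shape, rate = rate), min_rate)
}
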