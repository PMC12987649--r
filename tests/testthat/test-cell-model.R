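# Cable solver and membrane model: passive correctness against analytic
# oracles, channel-roster validation, attenuation, deciles, and the
# regenerative-event competence of the default cell.

test_that("channel roster constraints are enforced", {
  m <- small_morph()
  expect_error(assemble_cell(m, channel_density_map(
    overrides = list(soma = c(Im = 0.001)))), "soma")
  expect_error(assemble_cell(m, channel_density_map(
    overrides = list(tuft = c(KPst = 0.01)))), "KPst")
  expect_error(assemble_cell(m, channel_density_map(
    overrides = list(basal = c(NaP = 0.001)))), "NaP")
  # default dendritic rows carry exactly the seven allowed channels
  d <- channel_density_map()
  for (reg in c("basal", "apical_trunk", "nexus", "tuft")) {
    expect_true(all(d[reg, c("NaP", "KPst", "KTst")] == 0))
    expect_true(all(d[reg, c("NaT", "Ih", "Im", "Kv31", "CaHVA", "CaLVA",
                             "SK")] > 0))
  }
  expect_equal(d["soma", "Im"], 0)
})

test_that("a passive cell settles to the leak reversal", {
  cell <- passive_cell()
  ts <- integrate_cell(cell, 600, record = "v", rec_comps = cell$soma,
                       rec_dt = 1, v_init = -70)
  expect_equal(tail(trace_of(ts, cell$soma, "v"), 1), -90, tolerance = 1e-3)
})

test_that("membrane charge decays with tau = Cm/g_leak in isolation", {
  # single isolated compartment: relaxation from -70 toward -90 must be a
  # pure exponential with the analytic time constant
  df <- data.frame(id = 1L, parent = -1L, length = 25, diam = 25,
                   region = "soma", branch = 0L, x = 0, y = 0, z = 0,
                   path_dist = 0)
  morph <- structure(list(df = df, params = NULL), class = "morphology")
  cell <- assemble_cell(morph, zero_densities())
  tau_an <- 1e-6 / 3.38e-5 * 1000 # Cm/gl in ms
  ts <- integrate_cell(cell, 100, record = "v", rec_comps = 1L, rec_dt = 0.1,
                       v_init = -70)
  v <- trace_of(ts, 1L, "v")
  t <- ts$t0 + (seq_along(v) - 1) * ts$dt
  fit <- stats::lm(log(v + 90) ~ t)
  tau_fit <- -1 / unname(stats::coef(fit)[2])
  expect_equal(tau_fit, tau_an, tolerance = 0.01)
})

test_that("steady-state response matches the analytic branched-cable solve", {
  cell <- passive_cell()
  ts <- inject_step(cell, 0.1, 1200, t_on = 400, total = 1700,
                    record = "v", rec_comps = cell$soma, rec_dt = 1,
                    v_init = -90)
  v <- trace_of(ts, cell$soma, "v")
  dV_sim <- v[1590] - v[390]
  A <- dendrhythm:::.passive_admittance(cell, 0)
  rhs <- numeric(cell$n_comp)
  rhs[cell$soma] <- 0.1
  dV_an <- Re(solve(A, rhs))[cell$soma]
  expect_equal(dV_sim, dV_an, tolerance = 0.01)
})

test_that("attenuation agrees with a time-domain sinusoid measurement", {
  cell <- passive_cell()
  att <- measure_attenuation(cell, f = 20)
  expect_equal(att$ratio[att$comp == cell$soma], 1, tolerance = 1e-9)
  # independent oracle: inject the sinusoid and measure response amplitudes
  trunk <- cell$morph$df$id[cell$morph$df$region == "apical_trunk"]
  probe <- trunk[length(trunk) %/% 2]
  inj <- data.frame(comp = probe, amp = 0, t_on = 0, t_off = 2000,
                    sine_amp = 0.02, sine_freq = 20)
  ts <- integrate_cell(cell, 2000, inj = inj, record = "v",
                       rec_comps = c(cell$soma, probe), rec_dt = 0.5,
                       v_init = -90)
  amp_of <- function(comp) {
    v <- trace_of(ts, comp, "v")
    late <- v[(length(v) / 2):length(v)] # settled cycles
    (max(late) - min(late)) / 2
  }
  ratio_td <- amp_of(cell$soma) / amp_of(probe)
  expect_equal(ratio_td, att$ratio[att$comp == probe], tolerance = 0.01)
})

test_that("attenuation decreases monotonically along an unbranched path and
           is qualitatively stable between 10 and 20 Hz", {
  cell <- passive_cell()
  trunk <- cell$morph$df$id[cell$morph$df$region == "apical_trunk"]
  a20 <- measure_attenuation(cell, f = 20)
  a10 <- measure_attenuation(cell, f = 10)
  r20 <- a20$ratio[match(trunk, a20$comp)]
  r10 <- a10$ratio[match(trunk, a10$comp)]
  expect_true(all(diff(r20) < 0))
  # same ordering of compartments at either probe frequency
  expect_equal(order(r20), order(r10))
})

test_that("electrotonic deciles rank by ratio with stable tie-breaks", {
  m <- small_morph()
  ids <- dendritic_ids(m)
  ratios <- data.frame(comp = ids,
                       ratio = seq(1, 0.01, length.out = length(ids)))
  dec <- electrotonic_deciles(m, ratios)
  expect_true(all(dec$decile %in% 1:10))
  # boundaries monotone: higher ratio implies lower-or-equal decile
  for (cls in c("apical", "basal")) {
    d <- dec[dec$class == cls, ]
    d <- d[order(-d$ratio), ]
    expect_false(is.unsorted(d$decile))
    expect_lt(max(table(d$decile)) - min(table(d$decile)), 2)
  }
  # ties broken by compartment id: brute-force comparison
  tied <- data.frame(comp = ids, ratio = 0.5)
  dec_t <- electrotonic_deciles(m, tied)
  for (cls in c("apical", "basal")) {
    d <- dec_t[dec_t$class == cls, ]
    expect_equal(d$decile, dec_t$decile[dec_t$class == cls][order(d$comp)])
    expect_false(is.unsorted(d$decile[order(d$comp)]))
  }
  few <- data.frame(comp = ids[1:5], ratio = 1:5 / 5)
  expect_warning(
    electrotonic_deciles(
      structure(list(df = m$df[m$df$id %in% c(1, ids[1:5]), ],
                     params = NULL), class = "morphology"),
      few
    ),
    "fewer"
  )
})

test_that("current steps behave physically", {
  cell <- passive_cell()
  base <- integrate_cell(cell, 400, record = "v", rec_comps = cell$soma,
                         rec_dt = 1, v_init = -90)
  zero <- inject_step(cell, 0, 200, t_on = 100, total = 400, record = "v",
                      rec_comps = cell$soma, rec_dt = 1, v_init = -90)
  expect_equal(trace_of(zero, cell$soma, "v"), trace_of(base, cell$soma, "v"))
  hyp <- inject_step(cell, -1, 200, t_on = 100, total = 400, record = "v",
                     rec_comps = cell$soma, rec_dt = 1, v_init = -90)
  v <- trace_of(hyp, cell$soma, "v")
  expect_lt(min(v[100:300]), -95)
  # the printed f-I grid spans 18 amplitudes
  expect_length(seq(-1, 2.4, by = 0.2), 18)
})

test_that("halving the time step barely changes an active simulation", {
  m <- small_morph()
  cell <- assemble_cell(m)
  specs <- draw_weights(place_excitatory_synapses(m, seed = 5), seed = 5)
  n_nodes <- max(specs$node_id)
  # drive kept subthreshold so the comparison is not dominated by O(dt)
  # spike-time shifts
  trains <- sample_poisson_group(rep(0.5, n_nodes),
                                 gen_pink_modulator(1000, seed = 5), seed = 6)
  del <- build_deliveries(specs, trains, seed = 7)
  run <- function(dt) {
    integrate_cell(cell, 1000, synapses = specs, deliveries = del, dt = dt,
                   record = "v", rec_comps = cell$soma, rec_dt = 1)
  }
  v1 <- trace_of(run(0.1), cell$soma, "v")
  v2 <- trace_of(run(0.05), cell$soma, "v")
  expect_lt(max(v1), -15) # subthreshold: a smooth-trace comparison
  expect_lt(sqrt(mean((v1 - v2)^2)), 0.5)
})

test_that("somatic APs overshoot and backpropagate decrementally", {
  m <- build_synthetic_morphology()
  cell <- assemble_cell(m)
  df <- m$df
  trunk <- df$id[df$region == "apical_trunk"]
  prox <- trunk[2]
  tuft_tip <- df$id[df$region == "tuft"]
  tuft_tip <- tuft_tip[which.max(df$path_dist[match(tuft_tip, df$id)])]
  ts <- inject_step(cell, 2, 5, t_on = 150, total = 300,
                    record = "v", rec_comps = c(cell$soma, prox, tuft_tip),
                    rec_dt = 0.5, v_init = -78)
  vs <- trace_of(ts, cell$soma, "v")
  ap <- detect_aps(vs, ts$dt, t0 = ts$t0)
  expect_gte(length(ap$onsets), 1)
  expect_gt(max(vs), -10) # overshoots the AP criterion
  depol <- function(comp) {
    v <- trace_of(ts, comp, "v")
    max(v[300:400]) - v[295] # deflection around the evoked spike
  }
  expect_gt(depol(prox), depol(tuft_tip))
})

test_that("clustered excitation evokes the full roster of dendritic events", {
  m <- build_synthetic_morphology()
  cell <- assemble_cell(m)
  df <- m$df
  # --- basal branch: NMDA plateau with a local Na+ transient
  bas <- df[df$region == "basal" & df$path_dist > 150, ]
  target <- df$id[df$branch == bas$branch[1] & !is.na(df$branch)][5:9]
  nsyn <- 40
  specs <- one_synapse(target[1])[rep(1, nsyn), ]
  specs$synapse_id <- seq_len(nsyn)
  specs$comp <- rep(target, length.out = nsyn)
  del <- expand.grid(synapse_id = seq_len(nsyn), time = c(200, 205, 210))
  del$D <- 1
  ts <- integrate_cell(cell, 500, synapses = specs, deliveries = del,
                       record = c("v", "gna", "inmda", "ica"),
                       rec_comps = c(cell$soma, target), rec_dt = 0.5,
                       v_init = -80)
  v <- trace_of(ts, target[3], "v")
  ev <- detect_plateau(v, trace_of(ts, target[3], "inmda"), ts$dt,
                       t0 = ts$t0, kind = "NMDA")
  expect_gte(length(ev$onsets), 1)
  expect_gte(sum(v > -40) * ts$dt, 26) # plateau holds above -40 mV
  expect_gt(max(trace_of(ts, target[3], "gna")), 0.3)

  # --- tuft volley: nexus Ca2+ plateau converting a spike into a burst
  nexus <- df$id[df$region == "nexus"]
  tp <- df$id[df$region == "tuft" & df$path_dist < 900]
  nsyn <- 250
  specs <- one_synapse(tp[1])[rep(1, nsyn), ]
  specs$synapse_id <- seq_len(nsyn)
  specs$comp <- rep(tp, length.out = nsyn)
  del <- expand.grid(synapse_id = seq_len(nsyn),
                     time = c(200, 204, 208, 212))
  del$D <- 1
  ts <- integrate_cell(cell, 600, synapses = specs, deliveries = del,
                       record = c("v", "gna", "inmda", "ica"),
                       rec_comps = c(cell$soma, nexus), rec_dt = 0.5,
                       v_init = -80)
  ca <- detect_plateau(trace_of(ts, nexus[1], "v"),
                       trace_of(ts, nexus[1], "ica"), ts$dt, t0 = ts$t0,
                       kind = "Ca")
  expect_gte(length(ca$onsets), 1)
  ap <- detect_aps(trace_of(ts, cell$soma, "v"), ts$dt, t0 = ts$t0)
  expect_gte(length(ap$onsets), 2)
  expect_lt(min(diff(ap$onsets)), 25) # burst
})
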