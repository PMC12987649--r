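# Synaptic kinetics, magnesium block, short-term depression, weights,
# release gating, placement, and the train-induction protocol.

test_that("magnesium block follows the printed closed form", {
  expect_equal(mg_block(0), 1 / 1.33)
  v <- seq(-90, 40, by = 10)
  expect_true(all(diff(mg_block(v)) > 0))
  expect_gt(mg_block(1000), 1 - 1e-6)
  # strong suppression at rest relative to depolarised levels
  expect_lt(mg_block(-70) / mg_block(-20), 0.15)
})

test_that("stp_step implements recovery-then-depress with product clamp", {
  none <- stp_preset("none")
  st <- stp_state()
  for (t in c(0, 10, 20)) {
    r <- stp_step(st, none, t)
    st <- r$state
    expect_equal(r$D, 1)
  }
  exc <- stp_preset("excitatory")
  st <- stp_state()
  st <- stp_step(st, exc, 0)$state
  r <- stp_step(st, exc, 1e7) # essentially full recovery
  expect_equal(r$D, 1, tolerance = 1e-9)
  expect_error(stp_step(st, exc, -5), "order")
})

test_that("two-factor depression matches an independent recursion oracle", {
  # closed-form recursion computed step by step, separate from the
  # implementation path (stp_train_cpp)
  oracle <- function(times, tau1, d1, tau2, d2) {
    D1 <- 1; D2 <- 1; tl <- -Inf
    out <- numeric(length(times))
    for (i in seq_along(times)) {
      a <- 1 - (1 - D1) * exp(-(times[i] - tl) / tau1)
      b <- 1 - (1 - D2) * exp(-(times[i] - tl) / tau2)
      out[i] <- min(1, a * b)
      D1 <- a * d1; D2 <- b * d2; tl <- times[i]
    }
    out
  }
  times <- (0:7) * 20 # 8 pulses at 50 Hz
  for (preset in c("excitatory", "perisomatic_inh", "dendritic_inh")) {
    p <- stp_preset(preset)
    expect_equal(stp_train(times, p),
                 oracle(times, p$tau_d1, p$d1, p$tau_d2, p$d2),
                 tolerance = 1e-12)
  }
  # irregular event times too
  irregular <- cumsum(c(0, 3, 50, 7, 300, 12))
  p <- stp_preset("excitatory")
  expect_equal(stp_train(irregular, p),
               oracle(irregular, p$tau_d1, p$d1, p$tau_d2, p$d2),
               tolerance = 1e-12)
  # the dendritic preset is effectively single-factor (slow factor disabled)
  dend <- stp_preset("dendritic_inh")
  expect_equal(dend$d2, 1)
})

test_that("depression factors stay in (0, 1] and recover monotonically", {
  p <- stp_preset("perisomatic_inh")
  times <- sort(stats::runif(200, 0, 2000))
  D <- stp_train(times, p)
  expect_true(all(D > 0 & D <= 1))
  # between two events, longer gaps give larger effective D
  st <- stp_step(stp_state(), p, 0)$state
  gaps <- c(5, 20, 100, 400)
  Ds <- vapply(gaps, function(g) stp_step(st, p, g)$D, numeric(1))
  expect_true(all(diff(Ds) > 0))
})

test_that("conductance weights: log-normal excitatory, fixed inhibitory", {
  specs <- data.frame(class = c(rep("exc", 1e5), rep("inh", 10)))
  specs <- draw_weights(specs, seed = 1)
  g_nS <- specs$g_max_uS * 1e3
  expect_true(all(g_nS[specs$class == "inh"] == 1))
  expect_true(all(g_nS > 0))
  exc <- g_nS[specs$class == "exc"]
  expect_lt(abs(mean(exc) - 0.2), 3 * 0.345 / sqrt(1e5))
  expect_equal(stats::sd(exc), 0.345, tolerance = 0.05)
  expect_error(draw_weights(specs[0, , drop = FALSE]), "non-empty")
})

test_that("release gate is Bernoulli per event-contact", {
  expect_true(all(release_gate(100, 1, seed = 1)))
  acc <- sum(release_gate(1e4, 0.5, seed = 2))
  expect_lt(abs(acc - 5000), 3 * sqrt(1e4 * 0.25))
  expect_error(release_gate(10, 1.2), "probability")
  # the study's release probabilities are representable
  expect_silent(release_gate(10, 0.53, seed = 1))
  expect_silent(release_gate(10, 0.88, seed = 1))
})

test_that("synaptic current follows I = w G (V - E) with Mg block on NMDA", {
  kin <- default_kinetics()
  expect_equal(syn_current(0, -60, 1, 1e-3, kin$AMPA)$I, 0)
  expect_equal(syn_current(0.5, 0, 1, 1e-3, kin$AMPA)$I, 0) # V = E
  out <- syn_current(0.5, -75, 1, 1e-3, kin$GABA_A)$I
  expect_equal(out, 0) # at the GABA reversal
  blocked <- syn_current(1, -70, 1, 1e-3, kin$NMDA, nmda = TRUE)$G
  open <- syn_current(1, -70, 1, 1e-3, kin$NMDA, nmda = FALSE)$G
  expect_equal(blocked / open, mg_block(-70))
  expect_error(syn_current(1.5, 0, 1, 1e-3, kin$AMPA), "0, 1")
})

test_that("single-activation conductance peaks at the dual-exponential time", {
  for (nm in c("AMPA", "NMDA", "GABA_A")) {
    kin <- default_kinetics()[[nm]]
    t_pk <- dual_exp_peak_time(kin$tau_rise, kin$tau_decay)
    wave <- psc_waveform(kin, duration = max(50, 5 * kin$tau_decay), dt = 0.1)
    expect_equal(wave$t[which.max(wave$G)], t_pk, tolerance = 0.11)
    expect_true(all(wave$G >= 0))
  }
})

test_that("train induction: zero without depression, ordered with presets", {
  kin <- default_kinetics()$AMPA
  none <- stp_train_induction(kin, stp_preset("none"), amplitude_only = TRUE)
  expect_equal(none$induction, 0)
  # D-only amplitude model equals the recursion arithmetic directly
  vals <- vapply(c("excitatory", "perisomatic_inh", "dendritic_inh"),
                 function(p) {
    r <- stp_train_induction(kin, stp_preset(p), amplitude_only = TRUE)
    D <- stp_train((0:7) * 20, stp_preset(p))
    expect_equal(r$induction, (mean(D[6:8]) - D[1]) / max(D),
                 tolerance = 1e-12)
    r$induction
  }, numeric(1))
  expect_true(all(vals < 0)) # all three synapse classes depress
  expect_gt(abs(vals[["perisomatic_inh"]]), abs(vals[["excitatory"]]))
  expect_gt(abs(vals[["excitatory"]]), abs(vals[["dendritic_inh"]]))
  expect_error(stp_train_induction(kin, stp_preset("none"), n_pulses = 5),
               "8 pulses")
  # kinetic (voltage-clamp) variant also reports depression for a
  # depressing synapse
  full <- stp_train_induction(kin, stp_preset("perisomatic_inh"))
  expect_lt(full$induction, 0)
  expect_length(full$peaks, 8)
})

test_that("excitatory placement honours density budgets and clustering", {
  morph <- build_synthetic_morphology()
  specs <- place_excitatory_synapses(morph, seed = 1)
  lens <- cable_lengths(morph)
  expect_equal(sum(specs$subtree == "apical"), round(2.16 * lens[["apical"]]))
  expect_equal(sum(specs$subtree == "basal"), round(2.16 * lens[["basal"]]))
  expect_true(all(specs$p_release >= 0.16 & specs$p_release <= 0.9))
  # one release probability and one branch per node; divergence 2..8
  by_node <- split(specs, specs$node_id)
  sizes <- lengths(lapply(by_node, `[[`, "synapse_id"))
  expect_true(all(sizes >= 1 & sizes <= 8)) # trailing node may be truncated
  full <- by_node[sizes >= 2]
  some <- full[sample.int(length(full), 200)]
  df <- morph$df
  for (nd in some) {
    expect_length(unique(nd$p_release), 1)
    expect_length(unique(df$branch[match(nd$comp, df$id)]), 1)
  }
  # zone tags consistent with recomputed path distance
  pd <- df$path_dist[match(specs$comp, df$id)]
  expect_equal(specs$zone == "perisomatic", pd <= 100)
})

test_that("inhibitory placement separates perisomatic and distal pools", {
  morph <- build_synthetic_morphology()
  specs <- place_inhibitory_synapses(morph, seed = 2)
  lens <- cable_lengths(morph)
  df <- morph$df
  expect_equal(sum(df$region[match(specs$comp, df$id)] == "soma"), 150)
  dend <- specs[df$region[match(specs$comp, df$id)] != "soma", ]
  expect_equal(nrow(dend),
               round(0.22 * lens[["apical"]]) + round(0.22 * lens[["basal"]]))
  pd <- df$path_dist[match(specs$comp, df$id)]
  expect_equal(specs$zone == "perisomatic",
               df$region[match(specs$comp, df$id)] == "soma" | pd <= 100)
  expect_true(all(specs$stp[specs$zone == "perisomatic"] == "perisomatic_inh"))
  expect_true(all(specs$stp[specs$zone == "distal"] == "dendritic_inh"))
  expect_true(all(specs$p_release > 0 & specs$p_release <= 1))
})

test_that("synapse tables survive a text round trip", {
  morph <- build_synthetic_morphology(morphology_params(scale = 0.25))
  specs <- draw_weights(place_excitatory_synapses(morph, seed = 3), seed = 3)
  tmp <- tempfile(fileext = ".tsv")
  write_synapses(specs, tmp)
  back <- read_synapses(tmp)
  expect_equal(back$comp, specs$comp)
  expect_equal(back$g_max_uS, specs$g_max_uS, tolerance = 1e-12)
  expect_equal(back$zone, specs$zone)
})
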