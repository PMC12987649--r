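# shared helpers: passive density maps and small cells for solver tests

zero_densities <- function() {
  all_off <- stats::setNames(rep(0, 10),
                             c("NaT", "NaP", "Ih", "Im", "KPst", "KTst",
                               "Kv31", "CaHVA", "CaLVA", "SK"))
  channel_density_map(overrides = list(
    soma = all_off, axon = all_off, basal = all_off,
    apical_trunk = all_off, nexus = all_off, tuft = all_off
  ))
}

small_morph <- function(scale = 0.25, seed = NULL) {
  build_synthetic_morphology(morphology_params(scale = scale), seed = seed)
}

passive_cell <- function(scale = 0.25) {
  assemble_cell(small_morph(scale), zero_densities())
}

# minimal one-synapse spec table on a given compartment
one_synapse <- function(comp, class = "exc", g = 2e-4, p = 1,
                        stp = "excitatory") {
  data.frame(synapse_id = 1L, comp = comp, pos = 0.5, class = class,
             subtree = "basal", zone = "distal", node_id = 1L,
             group_id = 1L, p_release = p, stp = stp, g_max_uS = g)
}
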