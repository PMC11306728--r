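# shared fixtures: a representative mid-range compound and modified variants

base_compound_params <- function() {
  list(Vmax_uptake = 100, Km_uptake = 1, Vmax_met = 250, Km_met = 10,
       PSdif_inf = 30, Vmax_targetUptake = 0.192, Km_targetUptake = 1,
       PSdiff_target = 0.115, Vmax_targetMet = 0.192, Km_targetMet = 10,
       Kd = 0.00134, koff = 1, X_TotalR = 0.01, fub = 0.5, CLr = 3,
       Kp_scaling = 4, id = "test-base")
}

make_compound <- function(...) {
  do.call(itm_compound, utils::modifyList(base_compound_params(), list(...)))
}

# physiology with all tissue perfusion switched off (reduced-model oracles)
no_flow_physiology <- function(keep_qt = FALSE) {
  phys <- itm_physiology()
  for (q in c("Qa", "Qh", "Qm", "Qs", if (!keep_qt) "Qt")) phys[[q]] <- 0
  phys
}

# n sampled compounds as itm_compound objects under the default config
sampled_compounds <- function(n, seed) {
  population_compounds(sample_compounds(n, seed))
}
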