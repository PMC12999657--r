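# Shared fixtures: compounds, a deterministic reference individual and a
# cheap simulation wrapper used across test files.

dox_fix <- load_compound("doxepin")
nor_fix <- load_compound("nordoxepin")
ref_ind <- reference_individual()

sim_genotype <- function(phenotype, duration_h = 96, dose_mg = 75) {
  m <- build_model(dox_fix, nor_fix, ref_ind,
                   genotype_profile(phenotype = phenotype),
                   dose_regimen(dose_mg))
  simulate_model(m, duration_h = duration_h)
}

# One-compartment Bateman configuration with non-vanishing concentrations
# over the whole grid (terminal half-life ~2.3 h, 24 h horizon).
bateman_case <- function() {
  list(V = 40, CL = 0.2, ka = 0.05, D = 1e5,
       grid_h = seq(0.25, 24, by = 0.25))
}

bateman_closed_form <- function(case) {
  ke <- case$CL / case$V
  t_min <- case$grid_h * 60
  case$D * case$ka / (case$V * (case$ka - ke)) *
    (exp(-ke * t_min) - exp(-case$ka * t_min))
}
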