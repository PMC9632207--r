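# Canonical synthetic-study fixtures shared across test files.
# Truth values mirror the study conditions the package is built around.

canonical_solvation_truth <- function(q_max = 50)
  solvation_parameters(p = 1.2, q_max = q_max,
                       delta_A = -0.23, delta_B = -0.17)

# mild quadratic dilution-heat profile; free parameters (no dilution
# series is published for this system)
default_dilution_coef <- c(-20, 40, -30)

canonical_titration <- function(noise_sd = 0, seed = NULL,
                                truth = canonical_solvation_truth()) {
  simulate_titration(titration_design(), truth,
                     dilution_coef = default_dilution_coef,
                     noise_sd = noise_sd, seed = seed)
}

# 15-point log grid bracketing the dissociation constant 1/Ka
hill_grid_uM <- function(Ka, span = 20, n = 15) {
  Kd_uM <- 1e6 / Ka
  exp(seq(log(Kd_uM / span), log(Kd_uM * span), length.out = n))
}

hill_truth_low <- list(n = 1.37, Ka = 5.65e7, dH = 4.52, dG = -44.62,
                   TdS = 49.15)
hill_truth_high <- list(n = 3.25, Ka = 2.46e8, dH = 4.15, dG = -48.31)

noncomp_dataset <- function(Ki = 6.06, Vmax = 1, Km = 3, noise_sd = 0,
                            seed = NULL, replicates = 1) {
  simulate_kinetics(kinetics_design(replicates = replicates),
                    "noncompetitive", Vmax = Vmax, Km = Km, Ki = Ki,
                    noise_sd = noise_sd, seed = seed)
}

ic50_grid <- function(n = 10) exp(seq(log(0.5), log(50), length.out = n))

rel_err <- function(est, truth) abs(est - truth) / abs(truth)

# bare titration series with placeholder heats, for estimator algebra tests
new_series_for_test <- function(ligand_uM, enzyme_uM = 0) {
  solvbind:::new_titration_series(
    data.frame(injection = seq_along(ligand_uM), ligand_uM = ligand_uM,
               heat = seq_along(ligand_uM)),
    design = list(cell_enzyme_conc = enzyme_uM, temperature = 300))
}
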