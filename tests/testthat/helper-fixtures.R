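# Shared fixtures: the reference particle/field settings used across tests.

# Study-like particle: 18 nm core, 10 nm coating, x ~ 0.3 saturation
# magnetization, physiological temperature, water.
ref_particle <- function(eta = 1e-3, brown_disabled = FALSE) {
  particle_model(D = 18e-9, shell = 10e-9, Ms_vol = 93.4 * 5180,
                 K = 1.6e4, tau0 = 1e-9, T = 310, eta = eta,
                 brown_disabled = brown_disabled)
}

ref_sar_params <- function(eta = 1e-3, brown_disabled = FALSE, ...) {
  sar_model_params(ref_particle(eta, brown_disabled), density = 5180,
                   tau_N0 = 3e-5, A = 2, C = 3, Gamma = NULL, ...)
}

# Gamma at the 65 kA/m reference amplitude implied by the eq9 prefactor.
ref_gamma_true <- function() {
  gamma_coefficient(driving_field(355e3, 65e3), 93.4 * 5180, 5180)
}
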