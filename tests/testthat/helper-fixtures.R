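# Shared fixtures; heavier objects are memoized so several test files can
# reuse one noiseless simulation.

fx <- new.env(parent = emptyenv())

fx_ligands <- function() nk1_reference_ligands()

fx_noiseless <- noise_model(cv = 0, additive_sd = 0)

# Noiseless SP agonist-only concentration-response (8 concentrations over
# ~5 log units around KD), cAMP-like calibration.
fx_sp_concs <- function() kd(fx_ligands()$SP) * 10^seq(-2, 3, length.out = 8)

fx_sp_dataset <- function() {
  if (is.null(fx$sp_dataset)) {
    prot <- build_concentration_response_protocol(
      fx_ligands()$SP, fx_sp_concs(), n_replicates = 1, noise = fx_noiseless)
    fx$sp_dataset <- generate_dataset(prot, seed = 1)
  }
  fx$sp_dataset
}

fx_sp_fit <- function() {
  if (is.null(fx$sp_fit)) {
    fx$sp_fit <- fit_concentration_response(peak_response(fx_sp_dataset()))
  }
  fx$sp_fit
}

# Noiseless single time-course at a saturating SP concentration.
fx_saturating_trace <- function() {
  if (is.null(fx$sat_trace)) {
    sp <- fx_ligands()$SP
    prot <- build_single_timecourse_protocol(
      sp, 200 * kd(sp), n_replicates = 1, noise = fx_noiseless,
      preincubation_min = 0)
    fx$sat_trace <- generate_dataset(prot, seed = 1)
  }
  fx$sat_trace
}

# Peak of the noiseless simulator output for one condition, as a vector.
fx_condition_values <- function(ds, id = unique(ds$condition_id)[1]) {
  d <- ds[ds$condition_id == id & ds$replicate == 1, ]
  d[order(d$time_min), ]
}
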