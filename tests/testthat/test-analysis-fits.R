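test_that("peak analysis subtracts the baseline it estimates", {
  mk <- function(values, id = "c1") {
    data.frame(time_min = seq_along(values) - 1, condition_id = id,
               agonist = "a", agonist_conc_nM = 1, antagonist = "",
               antagonist_conc_nM = 0, replicate = 1, readout = "camp",
               value = values)
  }
  rising <- mk(seq(10, 100, by = 10))
  pk <- peak_response(rising)
  expect_equal(pk$peak, 90) # last sample minus first-sample baseline
  flat <- mk(rep(20, 10))
  expect_equal(peak_response(flat)$peak, 0)
  # explicit pre-stimulation window
  with_pre <- mk(c(5, 5, seq(5, 45, by = 10)))
  with_pre$time_min <- c(-2, -1, 0:4)
  expect_equal(peak_response(with_pre)$peak, 40)
  broken <- mk(rep(NA_real_, 5))
  expect_error(peak_response(broken), "no non-missing")
})

test_that("simulated saturating trace peaks where the noiseless generator does", {
  ds <- fx_saturating_trace()
  pk <- peak_response(ds)
  d <- fx_condition_values(ds)
  expect_equal(pk$peak, max(d$value) - d$value[1], tolerance = 1e-12)
  t_peak <- d$time_min[which.max(d$value)]
  expect_gte(t_peak, 20)
  expect_lte(t_peak, 30)
})

test_that("the variable-slope fit recovers exact logistic parameters", {
  concs <- 10^seq(-1.5, 2.5, length.out = 9)
  resp <- 100 / (1 + (2.2 / concs)^1) # EC50 2.2 nM, hill 1, top 100
  fit <- fit_concentration_response(data.frame(conc_nM = concs, peak = resp))
  expect_true(fit$converged)
  expect_equal(fit$ec50, 2.2, tolerance = 1e-6)
  expect_equal(fit$emax, 100, tolerance = 1e-6)
  expect_equal(fit$hill, 1, tolerance = 1e-6)
  expect_equal(fit$pec50, 9 - log10(2.2), tolerance = 1e-6)

  resp2 <- 5 + 80 / (1 + (0.5 / concs)^1.7)
  fit2 <- fit_concentration_response(data.frame(conc_nM = concs, peak = resp2))
  expect_equal(fit2$hill, 1.7, tolerance = 1e-5)
  expect_equal(fit2$baseline, 5, tolerance = 1e-4)
})

test_that("degenerate inputs come back flagged, not as errors", {
  concs <- 10^seq(-1, 3, length.out = 8)
  flat <- fit_concentration_response(data.frame(conc_nM = concs,
                                                peak = rep(7, 8)))
  expect_false(flat$converged)
  expect_match(flat$reason, "degenerate")
  expect_error(
    fit_concentration_response(data.frame(conc_nM = concs[1:4], peak = 1:4)),
    "at least 5")
})

test_that("a free hill slope stays at 1 for hill-1 synthetic data", {
  concs <- 10^seq(-2, 2, length.out = 11)
  resp <- 50 / (1 + 1.3 / concs)
  fit <- fit_concentration_response(data.frame(conc_nM = concs, peak = resp))
  expect_lt(abs(fit$hill - 1), 0.01)
})

test_that("normalization pins the control at 100% and scales linearly", {
  concs <- 10^seq(-1.5, 2.5, length.out = 9)
  mkfit <- function(top) {
    fit_concentration_response(
      data.frame(conc_nM = concs, peak = top / (1 + 2 / concs)))
  }
  fits <- list(control = mkfit(400), half = mkfit(200))
  nf <- normalize_to_control(fits, "control")
  expect_equal(nf$control$emax, 100, tolerance = 1e-8)
  expect_equal(nf$half$emax, 50, tolerance = 1e-6)
  expect_true(nf$control$normalized)
  # affine invariance: rescaling raw readout units changes nothing
  fits7 <- list(control = mkfit(7 * 400), half = mkfit(7 * 200))
  nf7 <- normalize_to_control(fits7, "control")
  expect_equal(nf7$half$emax, nf$half$emax, tolerance = 1e-8)
  expect_error(normalize_to_control(fits, "missing"), "not found")
})

test_that("inhibition fits recover the generating IC50", {
  concs <- 10^seq(-2, 2, length.out = 9)
  resp <- 20 + 80 / (1 + (concs / 0.37)^1.2) # IC50 0.37, descending
  d <- data.frame(antagonist_conc_nM = c(0, concs), peak = c(100, resp))
  fit <- fit_inhibition(d)
  expect_true(fit$converged)
  expect_equal(fit$direction, "descending")
  expect_lt(abs(fit$ec50 - 0.37) / 0.37, 1e-4)
  expect_lt(fit$hill, 0)

  flat <- data.frame(antagonist_conc_nM = c(0, concs), peak = rep(55, 10))
  expect_false(fit_inhibition(flat)$converged)
})

test_that("simulated IC50 rises with the agonist challenge concentration", {
  ligs <- fx_ligands()
  fast_ant <- ligand_kinetics("fastAnt", 1, 1, "antagonist") # KD 1 nM
  agF <- ligand_kinetics("fastAg", 0.5, 0.5, "agonist")
  ic50_at <- function(challenge) {
    prot <- build_ic50_protocol(
      fast_ant, 10^seq(-1.5, 2, length.out = 8), agF, challenge,
      n_replicates = 1, noise = fx_noiseless)
    fit_inhibition(peak_response(generate_dataset(prot, seed = 1)))$ec50
  }
  ics <- vapply(kd(agF) * c(1, 4, 16), ic50_at, numeric(1))
  expect_true(all(diff(ics) > 0))
})

test_that("EC80 algebra and definition agree with the fitted curve", {
  concs <- 10^seq(-1.5, 2.5, length.out = 9)
  fit1 <- fit_concentration_response(
    data.frame(conc_nM = concs, peak = 100 / (1 + 2 / concs)))
  expect_equal(compute_ec80(fit1), 4 * fit1$ec50, tolerance = 1e-6)
  fit2 <- fit_concentration_response(
    data.frame(conc_nM = concs, peak = 100 / (1 + (2 / concs)^2)))
  expect_equal(compute_ec80(fit2), 2 * fit2$ec50, tolerance = 1e-4)
  # definition check on the pipeline: response at EC80 is 80% of fitted top
  fit <- fx_sp_fit()
  ec80 <- compute_ec80(fit)
  prot <- build_single_timecourse_protocol(fx_ligands()$SP, ec80,
                                           n_replicates = 1,
                                           noise = fx_noiseless)
  pk <- peak_response(generate_dataset(prot, seed = 1))$peak
  expect_equal(pk / fit$emax, 0.8, tolerance = 0.05)
  bad <- fit1; bad$hill <- -1
  expect_error(compute_ec80(bad), "hill")
})
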