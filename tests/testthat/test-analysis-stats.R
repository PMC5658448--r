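test_that("KRI is the plain binding ratio with its interpretation", {
  expect_equal(compute_kri(100, 100)$kri, 1.0)
  r <- compute_kri(90, 50)
  expect_equal(r$kri, 1.8)
  expect_match(r$interpretation, "slower")
  r2 <- compute_kri(35, 50)
  expect_equal(r2$kri, 0.7)
  expect_match(r2$interpretation, "faster")
  expect_error(compute_kri(10, 0), "b_t2")
  expect_error(compute_kri(-1, 10), "b_t1")
})

test_that("onset slope reproduces exact lines and rejects thin windows", {
  mk <- function(vals, times = seq_along(vals)) {
    data.frame(time_min = times, condition_id = "c", agonist = "a",
               agonist_conc_nM = 1, antagonist = "", antagonist_conc_nM = 0,
               replicate = 1, readout = "camp", value = vals)
  }
  line <- mk(5 * (1:8))
  on <- compute_onset(line, "c")
  expect_equal(on$slope, 5, tolerance = 1e-12)
  expect_equal(on$r_squared, 1)
  expect_equal(on$n_points, 8)
  flat <- mk(rep(3, 8))
  expect_equal(compute_onset(flat, "c")$slope, 0, tolerance = 1e-12)
  # window is (0, window]: t = 0 and t > window are excluded
  wide <- mk(c(99, 1:8, 99), times = c(0, 1:8, 9))
  expect_equal(compute_onset(wide, "c")$slope, 1, tolerance = 1e-12)
  thin <- mk(1:2, times = 1:2)
  expect_error(compute_onset(thin, "c"), ">= 3 samples")
})

test_that("onset of a noiseless EC80 trace matches a finite-difference oracle", {
  fit <- fx_sp_fit()
  ec80 <- compute_ec80(fit)
  prot <- build_single_timecourse_protocol(fx_ligands()$SP, ec80,
                                           n_replicates = 1,
                                           noise = fx_noiseless)
  ds <- generate_dataset(prot, seed = 1)
  on <- compute_onset(ds, unique(ds$condition_id), window_min = 8)
  # independent route: direct fine-grid simulation (bypassing the dataset
  # generator) and the closed-form least-squares slope over the same window
  sys <- receptor_system(list(fx_ligands()$SP))
  sch <- addition_schedule(
    data.frame(time = 0, ligand = "SP", conc = ec80), horizon = 45)
  tr <- simulate_binding(sys, sch, grid_step = 0.05)
  r <- simulate_readout(tr, transduction_calibration("camp"), "SP")
  y <- stats::approx(r$times, r$response, xout = 1:8)$y
  tt <- 1:8
  oracle <- sum((tt - mean(tt)) * (y - mean(y))) / sum((tt - mean(tt))^2)
  expect_equal(on$slope, oracle, tolerance = 0.01)
})

test_that("Dunnett comparisons are calibrated against a Monte-Carlo oracle", {
  set.seed(123)
  groups <- paste0("g", 1:5)
  d <- data.frame(
    group = rep(c("control", groups), each = 5),
    value = rnorm(30)
  )
  d$value[d$group == "g3"] <- d$value[d$group == "g3"] + 2.5
  res <- dunnett_anova(d, "control", seed = 42)
  expect_equal(res$n_comparisons, 5)
  expect_true(all(res$comparisons$p_adj >= 0 & res$comparisons$p_adj <= 1))

  # Monte-Carlo max-|t| oracle under the pooled-variance null
  n <- 5; k <- 5
  df <- 30 - 6
  s2 <- sum(tapply(d$value, d$group, function(v) sum((v - mean(v))^2))) / df
  means <- tapply(d$value, d$group, mean)
  t_obs <- (means[groups] - means["control"]) / sqrt(2 * s2 / n)
  set.seed(99)
  nmc <- 20000
  tmax <- replicate(nmc, {
    m <- rnorm(k + 1, 0, 1 / sqrt(n))
    s <- sqrt(rchisq(1, df) / df)
    max(abs(m[-1] - m[1]) / (s * sqrt(2 / n)))
  })
  p_mc <- vapply(abs(t_obs), function(tt) mean(tmax >= tt), numeric(1))
  expect_equal(unname(res$comparisons$p_adj[match(groups, res$comparisons$label)]),
               unname(p_mc), tolerance = 0.03)
  expect_lt(res$comparisons$p_adj[res$comparisons$label == "g3"], 0.05)
})

test_that("a ten-sigma group separation is flagged at p < 0.001", {
  set.seed(17)
  d <- data.frame(group = rep(c("control", "far"), each = 6),
                  value = c(rnorm(6, 0, 1), rnorm(6, 10, 1)))
  res <- dunnett_anova(d, "control", seed = 3)
  expect_lt(res$comparisons$p_adj, 0.001)
})

test_that("Dunnett adjustment inflates p-values and is seed-deterministic", {
  set.seed(5)
  d <- data.frame(group = rep(c("control", "a", "b"), each = 6),
                  value = rnorm(18))
  # push one group to sit near single-test p = 0.04
  tcrit <- qt(0.98, df = 15)
  d$value[d$group == "a"] <- d$value[d$group == "a"] +
    tcrit * sqrt(2 / 6) * sd(d$value)
  res <- dunnett_anova(d, "control", seed = 7)
  fit <- stats::lm(value ~ relevel(factor(group), "control"), data = d)
  p_single <- summary(fit)$coefficients[2:3, 4]
  idx <- match(c("a", "b"), res$comparisons$label)
  expect_true(all(res$comparisons$p_adj[idx] > p_single))
  expect_identical(res$comparisons$p_adj,
                   dunnett_anova(d, "control", seed = 7)$comparisons$p_adj)
})

test_that("identical groups give near-unity adjusted p-values", {
  set.seed(11)
  base <- rnorm(6)
  d <- data.frame(group = rep(c("control", "a", "b"), each = 6),
                  value = rep(base, 3) + rnorm(18, 0, 1e-3))
  res <- dunnett_anova(d, "control", seed = 1)
  expect_true(all(res$comparisons$p_adj > 0.9))
  d0 <- data.frame(group = rep(c("control", "a"), each = 3),
                   value = rep(c(1, 1, 1), 2))
  expect_error(dunnett_anova(d0, "control"), "variance")
})

test_that("surmountability labels follow the significance + Emax rule", {
  concs <- 10^seq(-1.5, 2.5, length.out = 9)
  mkfit <- function(top) {
    fit_concentration_response(
      data.frame(conc_nM = concs, peak = top / (1 + 2 / concs)))
  }
  fits <- list(control = mkfit(100), ns97 = mkfit(97), sig82 = mkfit(82),
               sig8 = mkfit(7.8))
  nf <- normalize_to_control(fits, "control")
  dn <- structure(
    list(comparisons = data.frame(
      label = c("ns97", "sig82", "sig8"),
      diff = c(-3, -18, -92.2), se = 1, t = 0,
      p_adj = c(0.6, 0.004, 1e-6),
      significant = c(FALSE, TRUE, TRUE)),
      alpha = 0.05, n_comparisons = 3, f_statistic = 10, f_p_value = 1e-4),
    class = "dunnett_result")
  cls <- classify_surmountability(nf$control, nf[c("ns97", "sig82", "sig8")], dn)
  expect_equal(cls$classification,
               c("surmountable", "partially insurmountable", "insurmountable"))
  expect_error(classify_surmountability(fits$control,
                                        nf[c("ns97")], dn), "normalized")
})
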