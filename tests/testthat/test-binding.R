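test_that("single-ligand binding reaches Langmuir occupancy at L = KD", {
  sp <- ligand_kinetics("SP", 0.24, 0.027, "agonist")
  sys <- receptor_system(list(sp))
  sch <- addition_schedule(
    data.frame(time = 0, ligand = "SP", conc = kd(sp)), horizon = 600)
  traj <- simulate_binding(sys, sch, grid_step = 2)
  expect_equal(tail(traj$bound[, "SP"], 1), 0.5, tolerance = 1e-6)
})

test_that("an empty schedule leaves the receptor pool untouched", {
  sp <- ligand_kinetics("SP", 0.24, 0.027, "agonist")
  sys <- receptor_system(list(sp), r_tot = 3)
  sch <- addition_schedule(
    data.frame(time = numeric(0), ligand = character(0), conc = numeric(0)),
    horizon = 60)
  traj <- simulate_binding(sys, sch)
  expect_true(all(traj$bound == 0))
  expect_true(all(traj$free_receptor == 3))
})

test_that("unknown ligand names and bad grids are rejected", {
  sp <- ligand_kinetics("SP", 0.24, 0.027, "agonist")
  sys <- receptor_system(list(sp))
  sch <- addition_schedule(
    data.frame(time = 0, ligand = "ghost", conc = 1), horizon = 10)
  expect_error(simulate_binding(sys, sch), "unknown ligand")
  sch2 <- addition_schedule(
    data.frame(time = 0, ligand = "SP", conc = 1), horizon = 10)
  expect_error(simulate_binding(sys, sch2, grid_step = 0), "positive")
})

test_that("receptor mass is conserved across random multi-ligand schedules", {
  set.seed(42)
  for (rep in 1:8) {
    n <- sample(1:3, 1)
    ligs <- lapply(seq_len(n), function(i) {
      ligand_kinetics(paste0("L", i), kon = 10^runif(1, -3, 0),
                      koff = 10^runif(1, -3, 0), role = "agonist")
    })
    sys <- receptor_system(ligs, r_tot = runif(1, 0.5, 5))
    ev <- data.frame(
      time = sort(runif(n, 0, 40)),
      ligand = paste0("L", seq_len(n)),
      conc = 10^runif(n, -1, 2))
    traj <- simulate_binding(sys, addition_schedule(ev, horizon = 90),
                             grid_step = 1)
    total <- traj$free_receptor + rowSums(traj$bound)
    expect_lt(max(abs(total - sys$r_tot)) / sys$r_tot, 1e-9)
    expect_true(all(traj$bound >= 0))
  }
})

test_that("Motulsky-Mahan reduces to one-ligand association at I = 0", {
  rad <- ligand_kinetics("rad", 0.24, 0.027, "radioligand")
  cmp <- ligand_kinetics("cmp", 0.01, 0.1, "antagonist")
  t <- c(1, 5, 30, 120)
  L <- 2.5
  kobs <- rad$kon * L + rad$koff
  expected <- (L / (L + kd(rad))) * (1 - exp(-kobs * t))
  expect_equal(motulsky_mahan_binding(rad, cmp, L, 0, 1, t), expected,
               tolerance = 1e-12)
})

test_that("Motulsky-Mahan approaches the Gaddum equilibrium at long times", {
  rad <- ligand_kinetics("rad", 0.24, 0.027, "radioligand")
  cmp <- ligand_kinetics("cmp", 0.05, 0.02, "antagonist")
  eq <- gaddum_occupancy(rad, 2.5, list(list(ligand = cmp, conc = 1)))
  expect_equal(motulsky_mahan_binding(rad, cmp, 2.5, 1, 1, 1e5), eq,
               tolerance = 1e-8)
})

test_that("the degenerate equal-rate limit is continuous", {
  # KF == KS requires equal relaxation rates and vanishing cross term
  rad <- ligand_kinetics("rad", 0.1, 0.05, "radioligand")
  cmp <- ligand_kinetics("cmp", 0.2, 0.15, "antagonist")
  t <- c(5, 30, 120)
  # I = 0 makes the cross term vanish; pick L so KA == KB exactly
  L <- (cmp$koff - rad$koff) / rad$kon
  exact <- motulsky_mahan_binding(rad, cmp, L, 0, 1, t)
  nudged <- motulsky_mahan_binding(
    rad, ligand_kinetics("cmp", 0.2, 0.15 + 1e-9, "antagonist"), L, 0, 1, t)
  expect_equal(exact, nudged, tolerance = 1e-6)
  expect_true(all(is.finite(exact)))
})

test_that("ODE simulation matches the closed-form oracle on a wide grid", {
  rad <- ligand_kinetics("rad", 0.24, 0.027, "radioligand")
  t_read <- c(5, 30, 120)
  for (L in c(0.25, 2.5, 25)) {
    for (koff_c in c(1e-3, 1e-2, 1e-1, 1)) {
      cmp <- ligand_kinetics("cmp", koff_c / 0.5, koff_c, "antagonist")
      for (I in c(0.05, 5)) {
        sys <- receptor_system(list(rad, cmp))
        sch <- addition_schedule(
          data.frame(time = c(0, 0), ligand = c("rad", "cmp"),
                     conc = c(L, I)), horizon = 121)
        traj <- simulate_binding(sys, sch, grid_step = 1)
        idx <- match(t_read, traj$times)
        ode <- traj$bound[idx, "rad"]
        mm <- motulsky_mahan_binding(rad, cmp, L, I, 1, t_read)
        expect_lt(max(abs(ode - mm) / pmax(mm, 1e-10)), 1e-4)
      }
    }
  }
})

test_that("long-horizon occupancy matches Gaddum for 1-3 ligands", {
  set.seed(7)
  for (n in 1:3) {
    ligs <- lapply(seq_len(n), function(i) {
      ligand_kinetics(paste0("L", i), kon = 10^runif(1, -2, 0),
                      koff = 10^runif(1, -2, 0), role = "agonist")
    })
    concs <- 10^runif(n, -1, 1) * vapply(ligs, kd, numeric(1))
    sys <- receptor_system(ligs)
    sch <- addition_schedule(
      data.frame(time = 0, ligand = paste0("L", seq_len(n)), conc = concs),
      horizon = 5e4)
    traj <- simulate_binding(sys, sch, grid_step = 5e3)
    for (i in seq_len(n)) {
      comp <- lapply(setdiff(seq_len(n), i), function(j) {
        list(ligand = ligs[[j]], conc = concs[j])
      })
      expect_equal(tail(traj$bound[, i], 1),
                   gaddum_occupancy(ligs[[i]], concs[i], comp),
                   tolerance = 1e-3)
    }
  }
})

test_that("Gaddum occupancy follows the competitive-binding algebra", {
  ag <- ligand_kinetics("ag", 0.2, 0.1, "agonist")
  ant <- ligand_kinetics("ant", 0.5, 0.25, "antagonist")
  expect_equal(gaddum_occupancy(ag, kd(ag)), 0.5)
  expect_equal(
    gaddum_occupancy(ag, kd(ag), list(list(ligand = ant, conc = kd(ant)))),
    1 / 3)
  expect_equal(gaddum_occupancy(ag, 0), 0)
})

test_that("Schild dose ratios are linear in antagonist concentration", {
  ant <- ligand_kinetics("ant", 0.5, 0.25, "antagonist")
  expect_equal(schild_shift(ant, 0), 1)
  expect_equal(schild_shift(ant, kd(ant)), 2)
  expect_equal(schild_shift(ant, 9 * kd(ant)), 10)
})

test_that("dual-point design concentration halves binding at the late read", {
  rad <- ligand_kinetics("rad", 0.24, 0.027, "radioligand")
  cmp <- ligand_kinetics("cmp", 0.001, 1e-3, "antagonist") # slow equilibrator
  I <- dual_point_design_conc(rad, cmp, L = 2.5, t = 120)
  b0 <- motulsky_mahan_binding(rad, cmp, 2.5, 0, 1, 120)
  bI <- motulsky_mahan_binding(rad, cmp, 2.5, I, 1, 120)
  expect_equal(bI / b0, 0.5, tolerance = 1e-6)
  # well above the equilibrium IC50 for a slow equilibrator
  expect_gt(I, gaddum_ic50(rad, cmp, 2.5))
})

test_that("agonist occupancy falls with antagonist residence time", {
  # fixed KD_B and concentration; koff range restricted to antagonists that
  # (near-)equilibrate within the 30-min pre-incubation, the regime the
  # assay design assumes -- at fixed KD an ultra-slow koff implies an
  # ultra-slow kon and the antagonist never binds in the first place
  sp <- ligand_kinetics("SP", 0.24, 0.027, "agonist")
  occ_at <- function(koff_b) {
    ant <- ligand_kinetics("ant", koff_b / 0.05, koff_b, "antagonist")
    sys <- receptor_system(list(sp, ant))
    sch <- addition_schedule(
      data.frame(time = c(0, 30), ligand = c("ant", "SP"),
                 conc = c(0.5, 4 * kd(sp))), horizon = 45)
    traj <- simulate_binding(sys, sch, grid_step = 0.5)
    traj$bound[match(40, traj$times), "SP"]
  }
  occ <- vapply(c(3, 1, 0.3, 0.1, 0.03), occ_at, numeric(1)) # rising residence
  expect_true(all(diff(occ) < 0))
})
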