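#' Simulate competitive receptor binding kinetics
#'
#' Integrates the mass-action competition system
#' \deqn{dRL_i/dt = kon_i L_i(t) R(t) - koff_i RL_i(t)}
#' with \eqn{R(t) = R_{tot} - \sum_i RL_i(t)}, for up to a handful of
#' ligands whose free concentrations \eqn{L_i(t)} are piecewise constant
#' between addition events. Event times are hard breakpoints: integration
#' restarts at each event so that the per-segment right-hand side is smooth.
#' All receptor species start empty at t = 0 unless concentrations are set
#' by a t = 0 event.
#'
#' @param system A [receptor_system()].
#' @param schedule An [addition_schedule()] referencing only ligands present
#'   in `system`.
#' @param grid_step Output grid spacing in min (> 0); event times are always
#'   included in the grid.
#' @return An object of class `occupancy_trajectory`: a list with `times`
#'   (min), `bound` (matrix, one column per ligand, receptor-ligand complex
#'   concentration), `free_receptor` and `r_tot`. At every grid point
#'   `free_receptor + rowSums(bound) == r_tot` by construction.
#' @examples
#' sp <- ligand_kinetics("SP", 0.24, 0.027, "agonist")
#' sys <- receptor_system(list(sp))
#' sch <- addition_schedule(
#'   data.frame(time = 0, ligand = "SP", conc = kd(sp)), horizon = 600)
#' traj <- simulate_binding(sys, sch, grid_step = 1)
#' tail(traj$bound[, "SP"], 1) # ~0.5: half occupancy at L = KD
#' @export
simulate_binding <- function(system, schedule, grid_step = 0.5) {
  stopifnot(inherits(system, "receptor_system"),
            inherits(schedule, "addition_schedule"))
  if (!is.numeric(grid_step) || length(grid_step) != 1L || grid_step <= 0) {
    stop("`grid_step` must be a single positive number", call. = FALSE)
  }
  ev <- schedule$events
  lig_names <- names(system$ligands)
  unknown <- setdiff(unique(ev$ligand), lig_names)
  if (length(unknown)) {
    stop("schedule references unknown ligand(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  n <- length(lig_names)
  horizon <- schedule$horizon
  grid <- sort(unique(c(seq(0, horizon, by = grid_step), ev$time, horizon)))

  if (n == 0L) {
    return(new_occupancy_trajectory(
      grid, matrix(0, length(grid), 0), system$r_tot))
  }

  kon <- vapply(system$ligands, `[[`, numeric(1), "kon")
  koff <- vapply(system$ligands, `[[`, numeric(1), "koff")
  r_tot <- system$r_tot

  seg_bounds <- sort(unique(c(0, ev$time, horizon)))
  conc <- stats::setNames(numeric(n), lig_names)
  state <- stats::setNames(numeric(n), lig_names)
  times_out <- numeric(0)
  bound_out <- NULL

  rhs <- function(t, y, parms) {
    r_free <- r_tot - sum(y)
    list(parms$kon * parms$conc * r_free - parms$koff * y)
  }

  for (s in seq_len(length(seg_bounds) - 1L)) {
    t0 <- seg_bounds[s]
    t1 <- seg_bounds[s + 1L]
    hit <- ev$time == t0
    if (any(hit)) conc[ev$ligand[hit]] <- ev$conc[hit]
    seg_times <- grid[grid >= t0 & grid <= t1]
    if (length(seg_times) < 2L) seg_times <- c(t0, t1)
    sol <- deSolve::lsoda(
      y = state, times = seg_times, func = rhs,
      parms = list(kon = kon, koff = koff, conc = conc),
      rtol = 1e-8, atol = 1e-10
    )
    istate <- attr(sol, "istate")[1L]
    if (is.null(istate) || istate < 0) {
      stop("ODE integrator failed to meet tolerance (istate = ", istate, ")",
           call. = FALSE)
    }
    keep <- if (is.null(bound_out)) seq_len(nrow(sol)) else -1L
    times_out <- c(times_out, sol[keep, 1L])
    seg_b <- sol[keep, -1L, drop = FALSE]
    bound_out <- rbind(bound_out, seg_b)
    state <- sol[nrow(sol), -1L]
  }

  colnames(bound_out) <- lig_names
  # clip tiny negative round-off
  bound_out[bound_out < 0 & bound_out > -1e-12] <- 0
  new_occupancy_trajectory(times_out, bound_out, r_tot)
}

new_occupancy_trajectory <- function(times, bound, r_tot) {
  free <- r_tot - if (ncol(bound)) rowSums(bound) else 0
  structure(
    list(times = times, bound = bound, free_receptor = free, r_tot = r_tot),
    class = "occupancy_trajectory"
  )
}

#' @export
print.occupancy_trajectory <- function(x, ...) {
  cat(sprintf(
    "<occupancy_trajectory> %d time points over [%g, %g] min, ligands: %s\n",
    length(x$times), min(x$times), max(x$times),
    if (ncol(x$bound)) paste(colnames(x$bound), collapse = ", ") else "(none)"
  ))
  invisible(x)
}

#' Tidy export of an occupancy trajectory
#'
#' @param x An `occupancy_trajectory`.
#' @param ... Unused.
#' @return Data frame with columns `time_min`, `species`, `value`, suitable
#'   for CSV export; `species` is `free_receptor` or a ligand name.
#' @export
as.data.frame.occupancy_trajectory <- function(x, ...) {
  species <- c("free_receptor", colnames(x$bound))
  vals <- cbind(free_receptor = x$free_receptor, x$bound)
  data.frame(
    time_min = rep(x$times, times = length(species)),
    species = rep(species, each = length(x$times)),
    value = as.vector(vals),
    stringsAsFactors = FALSE
  )
}

#' Motulsky-Mahan closed-form competition association binding
#'
#' Analytic solution for the amount of radioligand-receptor complex when a
#' radioligand (concentration `L`) and one unlabelled competitor
#' (concentration `I`) are co-added at t = 0 to an empty receptor pool.
#' This is the textbook biexponential used to analyse (dual-point)
#' competition association assays; here it serves as the independent oracle
#' for [simulate_binding()].
#'
#' @param radio,competitor [ligand_kinetics()] objects.
#' @param L,I Free concentrations in nM (held constant); `I = 0` reduces to
#'   one-ligand association kinetics.
#' @param r_tot Total receptor concentration.
#' @param t Time(s) in min (vectorised).
#' @return Bound radioligand concentration at each `t`; as `t -> Inf` this
#'   approaches `gaddum_occupancy(radio, L, ...) * r_tot`.
#' @export
motulsky_mahan_binding <- function(radio, competitor, L, I, r_tot = 1.0, t) {
  stopifnot(inherits(radio, "ligand_kinetics"),
            inherits(competitor, "ligand_kinetics"))
  if (L < 0 || I < 0) stop("`L` and `I` must be >= 0", call. = FALSE)
  k1 <- radio$kon; k2 <- radio$koff
  k3 <- competitor$kon; k4 <- competitor$koff
  KA <- k1 * L + k2
  KB <- k3 * I + k4
  S <- sqrt((KA - KB)^2 + 4 * k1 * k3 * L * I)
  KF <- 0.5 * (KA + KB + S)
  KS <- 0.5 * (KA + KB - S)
  if (S <= 1e-10 * KF) {
    # degenerate KF == KS: analytic limit of the biexponential
    K <- 0.5 * (KA + KB)
    return(r_tot * k1 * L *
             (k4 / K^2 + (-k4 / K^2 - t * (k4 - K) / K) * exp(-K * t)))
  }
  q <- r_tot * k1 * L / (KF - KS)
  q * (k4 * (KF - KS) / (KF * KS) +
         (k4 - KF) / KF * exp(-KF * t) -
         (k4 - KS) / KS * exp(-KS * t))
}

#' Gaddum equilibrium occupancy under competitive inhibition
#'
#' Fractional receptor occupancy of a ligand at concentration `L` in the
#' presence of competitive inhibitors at equilibrium:
#' \deqn{o = (L/K_D) / (1 + L/K_D + \sum_j I_j/K_{D,j})}
#'
#' @param agonist A [ligand_kinetics()] object (any role).
#' @param L Its free concentration, nM (>= 0).
#' @param competitors Optional list of `list(ligand = <ligand_kinetics>,
#'   conc = <nM>)` entries.
#' @return Fractional occupancy in `[0, 1)`.
#' @export
gaddum_occupancy <- function(agonist, L, competitors = list()) {
  stopifnot(inherits(agonist, "ligand_kinetics"))
  if (L < 0) stop("`L` must be >= 0", call. = FALSE)
  x <- L / kd(agonist)
  i <- 0
  for (cmp in competitors) {
    stopifnot(inherits(cmp$ligand, "ligand_kinetics"))
    if (cmp$conc < 0) stop("competitor concentrations must be >= 0", call. = FALSE)
    i <- i + cmp$conc / kd(cmp$ligand)
  }
  x / (1 + x + i)
}

#' Competitor concentration giving 50% inhibition of radioligand binding
#'
#' Helper for dual-point assay design: the Cheng-Prusoff-style equilibrium
#' IC50 of a competitor against a radioligand at concentration `L`,
#' `IC50 = KD_competitor * (1 + L/KD_radio)`.
#'
#' @param radio,competitor [ligand_kinetics()] objects.
#' @param L Radioligand concentration, nM.
#' @return Concentration in nM.
#' @export
gaddum_ic50 <- function(radio, competitor, L) {
  stopifnot(inherits(radio, "ligand_kinetics"),
            inherits(competitor, "ligand_kinetics"))
  kd(competitor) * (1 + L / kd(radio))
}

#' Competitor concentration for a dual-point screen
#'
#' The dual-point assay design rule calls for the competitor concentration
#' at which approximately 50% (30-70%) of radioligand binding is achieved
#' at the read. For slowly equilibrating competitors the *apparent* IC50 at
#' the late read time t2 can sit far above the equilibrium Gaddum IC50, so
#' the design concentration is found by root-solving the Motulsky-Mahan
#' model at t2 rather than from the equilibrium expression.
#'
#' @param radio,competitor [ligand_kinetics()] objects.
#' @param L Radioligand concentration, nM.
#' @param t Read time at which 50% inhibition is targeted, min (default
#'   the 120-min equilibration read).
#' @return Concentration in nM.
#' @seealso [gaddum_ic50()] for the equilibrium limit.
#' @export
dual_point_design_conc <- function(radio, competitor, L = 2.5, t = 120) {
  stopifnot(inherits(radio, "ligand_kinetics"),
            inherits(competitor, "ligand_kinetics"))
  ctrl <- motulsky_mahan_binding(radio, competitor, L, 0, 1, t)
  f <- function(logI) {
    motulsky_mahan_binding(radio, competitor, L, 10^logI, 1, t) - 0.5 * ctrl
  }
  10^stats::uniroot(f, c(-6, 8), tol = 1e-10)$root
}

#' Schild dose ratio of a surmountable competitive antagonist
#'
#' In the fast-equilibrating limit a competitive antagonist at
#' concentration `I` shifts the agonist concentration-response curve
#' rightwards by the dose ratio `1 + I/KD_B` without depressing its
#' maximum. Slowly dissociating antagonists depart from this limit
#' (insurmountable behaviour) on the assay timescale.
#'
#' @param antagonist A [ligand_kinetics()] object.
#' @param I Antagonist concentration, nM (>= 0).
#' @return The dimensionless dose ratio (>= 1).
#' @export
schild_shift <- function(antagonist, I) {
  stopifnot(inherits(antagonist, "ligand_kinetics"))
  if (I < 0) stop("`I` must be >= 0", call. = FALSE)
  1 + I / kd(antagonist)
}
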