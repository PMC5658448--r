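#' Transduction parameters for the occupancy-to-response stage
#'
#' The functional readout is produced in two first-order steps downstream of
#' receptor occupancy. Newly formed agonist-receptor complex enters an
#' "active" state A that desensitizes with rate `k_des`:
#' \deqn{dA/dt = dB/dt - k_{des} A}
#' where B(t) is the agonist-bound receptor fraction. The readout r(t)
#' (relative light units for the cAMP-like calibration, normalized cell
#' index for the impedance-like calibration) follows operational-model
#' style hyperbolic coupling with gain:
#' \deqn{dr/dt = k_{syn} \frac{g e A}{1 + g e A} - k_{deg} (r - basal)}
#' Desensitization of the occupied receptor is what makes the response
#' transient and its peak time concentration-dependent: a saturating
#' agonist drives A high immediately and the readout peaks tens of minutes
#' later as synthesis wanes against first-order decay.
#'
#' @param efficacy Intrinsic efficacy of the agonist in `[0, 1]`.
#' @param gain Transduction amplification (dimensionless, > 0). Large values
#'   emulate receptor reserve: the response saturates at occupancies well
#'   below 100%, compressing the EC50 below the agonist KD.
#' @param k_syn Maximal response synthesis rate, readout units min^-1.
#' @param k_deg First-order response decay rate, min^-1.
#' @param k_des Desensitization rate of the agonist-occupied receptor, min^-1.
#' @param basal Baseline readout, readout units.
#' @return An object of class `transduction_params`.
#' @seealso [transduction_calibration()] for the named default profiles.
#' @export
transduction_params <- function(efficacy = 1, gain = 3, k_syn = 100,
                                k_deg = 0.06, k_des = 0.06, basal = 20) {
  if (!is.numeric(efficacy) || efficacy < 0 || efficacy > 1) {
    stop("`efficacy` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(gain) || gain <= 0) stop("`gain` must be > 0", call. = FALSE)
  for (v in c("k_syn", "k_deg", "k_des", "basal")) {
    x <- get(v)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
      stop(sprintf("`%s` must be a single finite number >= 0", v), call. = FALSE)
    }
  }
  structure(
    list(efficacy = efficacy, gain = gain, k_syn = k_syn,
         k_deg = k_deg, k_des = k_des, basal = basal),
    class = "transduction_params"
  )
}

#' Named transduction calibrations
#'
#' Two default profiles are shipped. `"camp"` (cAMP-like, GloSensor-type
#' readout in relative light units) uses a modest gain so that depressed
#' maxima under slowly dissociating antagonists are readily visible, and is
#' calibrated so that a saturating agonist peaks 20-30 min after
#' stimulation. `"impedance"` (cell-morphology readout in normalized cell
#' index units) uses a much higher gain, emulating the receptor reserve
#' that left-shifts potencies in label-free whole-cell assays, with a
#' smaller absolute signal scale.
#'
#' @param name `"camp"` or `"impedance"`.
#' @param ... Overrides passed to [transduction_params()] fields.
#' @return A `transduction_params` object.
#' @export
transduction_calibration <- function(name = c("camp", "impedance"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    camp = list(efficacy = 1, gain = 3, k_syn = 100, k_deg = 0.06,
                k_des = 0.06, basal = 20),
    impedance = list(efficacy = 1, gain = 30, k_syn = 0.05, k_deg = 0.08,
                     k_des = 0.09, basal = 0.1)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(base))
  if (length(bad)) stop("unknown calibration override(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  base[names(over)] <- over
  do.call(transduction_params, base)
}

#' Multiplicative-plus-additive Gaussian noise model
#'
#' Replicate scatter of plate-reader signals scales with the signal, so the
#' default noise is multiplicative (`value * (1 + eps_m)`) with an optional
#' additive floor. Defaults mirror typical replicate variability of
#' real-time cAMP/impedance experiments (CV around 5-15%).
#'
#' @param cv Coefficient of variation of the multiplicative term (>= 0).
#' @param additive_sd SD of the additive term, readout units (>= 0).
#' @param seed Optional integer seed recorded with the model; generation
#'   functions may override it.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(cv = 0.10, additive_sd = 0, seed = NULL) {
  if (cv < 0 || additive_sd < 0) {
    stop("`cv` and `additive_sd` must be >= 0", call. = FALSE)
  }
  structure(list(cv = cv, additive_sd = additive_sd, seed = seed),
            class = "noise_model")
}

#' Convert an occupancy trajectory into a functional readout
#'
#' Runs the transduction cascade described in [transduction_params()] on
#' the bound-receptor series of the named agonist. The active state A is
#' propagated with an exact exponential update assuming piecewise-linear
#' occupancy between grid points; the readout ODE is then integrated on the
#' same grid.
#'
#' @param occupancy An `occupancy_trajectory` from [simulate_binding()].
#' @param params A `transduction_params` object.
#' @param agonist Name of the agonist whose bound series drives the response.
#' @return An object of class `response_trajectory`: list with `times`,
#'   `response` (readout units) and `active` (active receptor fraction).
#' @export
simulate_readout <- function(occupancy, params, agonist) {
  stopifnot(inherits(occupancy, "occupancy_trajectory"),
            inherits(params, "transduction_params"))
  if (!agonist %in% colnames(occupancy$bound)) {
    stop("occupancy trajectory has no bound series for agonist '",
         agonist, "'", call. = FALSE)
  }
  times <- occupancy$times
  b <- occupancy$bound[, agonist] / occupancy$r_tot # fractional occupancy

  a <- numeric(length(times))
  a[1] <- b[1]
  kdes <- params$k_des
  for (i in seq_len(length(times) - 1L)) {
    dt <- times[i + 1L] - times[i]
    slope <- (b[i + 1L] - b[i]) / dt
    if (kdes > 0) {
      a[i + 1L] <- a[i] * exp(-kdes * dt) + (slope / kdes) * (1 - exp(-kdes * dt))
    } else {
      a[i + 1L] <- a[i] + slope * dt
    }
  }
  a[a < 0] <- 0

  afun <- stats::approxfun(times, a, rule = 2)
  g <- params$gain * params$efficacy
  rhs <- function(t, y, p) {
    drive <- g * afun(t)
    list(params$k_syn * drive / (1 + drive) - params$k_deg * (y - params$basal))
  }
  sol <- deSolve::lsoda(c(r = params$basal), times, rhs, parms = NULL,
                        rtol = 1e-8, atol = 1e-10)
  istate <- attr(sol, "istate")[1L]
  if (is.null(istate) || istate < 0) {
    stop("readout integrator failed to meet tolerance", call. = FALSE)
  }
  structure(list(times = times, response = sol[, "r"], active = a),
            class = "response_trajectory")
}

#' @export
print.response_trajectory <- function(x, ...) {
  pk <- which.max(x$response)
  cat(sprintf(
    "<response_trajectory> %d points over [%g, %g] min; peak %.4g at %g min\n",
    length(x$times), min(x$times), max(x$times), x$response[pk], x$times[pk]))
  invisible(x)
}

#' Add replicate noise to a response trajectory
#'
#' Each replicate observation is `value * (1 + eps_m) + eps_a` with
#' `eps_m ~ N(0, cv)` and `eps_a ~ N(0, additive_sd)`, drawn independently
#' per time point and replicate. Reproducible given `seed`.
#'
#' @param traj A `response_trajectory`, or a numeric vector of values.
#' @param noise A [noise_model()].
#' @param n_replicates Number of replicates (>= 1).
#' @param seed Integer seed; defaults to the seed stored in `noise`.
#' @return Data frame with columns `time_min` (absent for bare vectors),
#'   `replicate`, `value`.
#' @export
apply_noise <- function(traj, noise, n_replicates = 3, seed = noise$seed) {
  stopifnot(inherits(noise, "noise_model"))
  if (n_replicates < 1) stop("`n_replicates` must be >= 1", call. = FALSE)
  if (inherits(traj, "response_trajectory")) {
    values <- traj$response
    times <- traj$times
  } else {
    values <- as.numeric(traj)
    times <- NULL
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
  }
  n <- length(values)
  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    eps_m <- if (noise$cv > 0) stats::rnorm(n, 0, noise$cv) else numeric(n)
    eps_a <- if (noise$additive_sd > 0) stats::rnorm(n, 0, noise$additive_sd) else numeric(n)
    v <- values * (1 + eps_m) + eps_a
    out[[r]] <- if (is.null(times)) {
      data.frame(replicate = r, value = v)
    } else {
      data.frame(time_min = times, replicate = r, value = v)
    }
  }
  do.call(rbind, out)
}
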