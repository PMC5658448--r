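new_assay_protocol <- function(kind, agonist = NULL, agonist_concs = numeric(0),
                               antagonist = NULL, antagonist_concs = numeric(0),
                               radioligand = NULL, radioligand_conc = NA_real_,
                               preincubation_min = 30, read_horizon_min = 45,
                               read_times = NULL, calibration = "camp",
                               n_replicates = 3, noise = noise_model()) {
  structure(
    list(kind = kind, agonist = agonist, agonist_concs = agonist_concs,
         antagonist = antagonist, antagonist_concs = antagonist_concs,
         radioligand = radioligand, radioligand_conc = radioligand_conc,
         preincubation_min = preincubation_min,
         read_horizon_min = read_horizon_min, read_times = read_times,
         calibration = calibration, n_replicates = n_replicates,
         noise = noise),
    class = "assay_protocol"
  )
}

#' @export
print.assay_protocol <- function(x, ...) {
  cat(sprintf("<assay_protocol> kind = %s\n", x$kind))
  if (!is.null(x$agonist)) {
    cat(sprintf("  agonist    %s at %s nM\n", x$agonist$name,
                paste(signif(x$agonist_concs, 3), collapse = ", ")))
  }
  if (!is.null(x$antagonist)) {
    cat(sprintf("  antagonist %s at %s nM (%g min pre-incubation)\n",
                x$antagonist$name,
                paste(signif(x$antagonist_concs, 3), collapse = ", "),
                x$preincubation_min))
  }
  if (!is.null(x$radioligand)) {
    cat(sprintf("  radioligand %s at %g nM, reads at %s min\n",
                x$radioligand$name, x$radioligand_conc,
                paste(x$read_times, collapse = " and ")))
  }
  cat(sprintf("  readout %s, %d replicate(s), noise cv %g\n",
              x$calibration, x$n_replicates, x$noise$cv))
  invisible(x)
}

check_conc_series <- function(concs, what = "concentration series") {
  if (!length(concs)) stop(what, " must be non-empty", call. = FALSE)
  if (any(!is.finite(concs)) || any(concs <= 0)) {
    stop(what, " must be strictly positive and finite", call. = FALSE)
  }
  if (is.unsorted(concs, strictly = TRUE)) {
    stop(what, " must be strictly increasing", call. = FALSE)
  }
  invisible(concs)
}

#' Build an agonist concentration-response protocol
#'
#' Emulates the functional assay design: optional antagonist addition at
#' the start of a pre-incubation window (default 30 min, matching the
#' 0.07/0.21/0.7 nM antagonist pre-treatment design) followed by agonist
#' challenge at a series of concentrations. One condition per agonist
#' concentration; time is exported relative to agonist addition.
#'
#' @param agonist [ligand_kinetics()] of the challenging agonist.
#' @param concs Strictly increasing agonist concentrations, nM. A warning
#'   is issued if fewer than 6 points or a span below 3 log units.
#' @param antagonist Optional [ligand_kinetics()] pre-incubated antagonist.
#' @param antagonist_conc Its concentration, nM (one value; 0 with no
#'   antagonist supplied is allowed, > 0 requires `antagonist`).
#' @param preincubation_min Minutes of antagonist-only binding before
#'   agonist addition; 0 means co-addition.
#' @param read_horizon_min Readout duration after agonist addition (min).
#' @param calibration Name passed to [transduction_calibration()].
#' @param n_replicates,noise Replicate structure and [noise_model()].
#' @return An `assay_protocol` of kind `"conc_response"`.
#' @export
build_concentration_response_protocol <- function(
    agonist, concs, antagonist = NULL, antagonist_conc = 0,
    preincubation_min = 30, read_horizon_min = 45, calibration = "camp",
    n_replicates = 3, noise = noise_model()) {
  stopifnot(inherits(agonist, "ligand_kinetics"))
  check_conc_series(concs, "agonist concentration series")
  if (length(concs) < 6 || log10(max(concs) / min(concs)) < 3) {
    warning("agonist series should span >= 3 log units with >= 6 points",
            call. = FALSE)
  }
  if (is.null(antagonist) && antagonist_conc > 0) {
    stop("`antagonist_conc` > 0 requires an antagonist", call. = FALSE)
  }
  if (!is.null(antagonist)) stopifnot(inherits(antagonist, "ligand_kinetics"))
  if (preincubation_min < 0) stop("`preincubation_min` must be >= 0", call. = FALSE)
  if (read_horizon_min < 45) read_horizon_min <- 45
  new_assay_protocol(
    "conc_response", agonist = agonist, agonist_concs = concs,
    antagonist = antagonist,
    antagonist_concs = if (is.null(antagonist)) numeric(0) else antagonist_conc,
    preincubation_min = preincubation_min,
    read_horizon_min = read_horizon_min, calibration = calibration,
    n_replicates = n_replicates, noise = noise
  )
}

#' Build an IC50-at-EC80 inhibition protocol
#'
#' Increasing antagonist concentrations are pre-incubated before challenge
#' with a fixed EC80 concentration of agonist; an antagonist-free control
#' condition is always included. The EC80 should come from a prior fit of
#' the agonist-only concentration-response (see [compute_ec80()]), not from
#' generating parameters, mirroring experimental practice.
#'
#' @param antagonist [ligand_kinetics()] titrated antagonist.
#' @param concs Strictly increasing antagonist concentrations, nM. A zero
#'   member is deduplicated against the built-in control.
#' @param agonist [ligand_kinetics()] challenging agonist.
#' @param agonist_ec80 Challenge concentration, nM (> 0).
#' @inheritParams build_concentration_response_protocol
#' @return An `assay_protocol` of kind `"ic50_at_ec80"`.
#' @export
build_ic50_protocol <- function(antagonist, concs, agonist, agonist_ec80,
                                preincubation_min = 30, read_horizon_min = 45,
                                calibration = "camp", n_replicates = 3,
                                noise = noise_model()) {
  stopifnot(inherits(antagonist, "ligand_kinetics"),
            inherits(agonist, "ligand_kinetics"))
  if (!length(concs)) stop("antagonist concentration series is empty", call. = FALSE)
  concs <- sort(unique(concs))
  concs <- concs[concs > 0] # control handled explicitly
  if (!length(concs)) stop("antagonist concentration series is empty", call. = FALSE)
  if (!is.numeric(agonist_ec80) || agonist_ec80 <= 0) {
    stop("`agonist_ec80` must be > 0", call. = FALSE)
  }
  new_assay_protocol(
    "ic50_at_ec80", agonist = agonist, agonist_concs = agonist_ec80,
    antagonist = antagonist, antagonist_concs = concs,
    preincubation_min = preincubation_min,
    read_horizon_min = read_horizon_min, calibration = calibration,
    n_replicates = n_replicates, noise = noise
  )
}

#' Build a dual-point competition association protocol
#'
#' Radioligand and competitor are co-added at t = 0 to an empty membrane
#' receptor pool; specific bound radioligand is read at two time points,
#' by default t1 = 30 min (radioligand equilibration) and t2 = 120 min
#' (competitor equilibration). The assay design rule is to use a
#' competitor concentration giving roughly 50% (30-70%) inhibition of
#' radioligand binding at equilibrium; [gaddum_ic50()] computes it, and a
#' warning (not an error) is raised when `I` falls outside that window.
#'
#' @param radio [ligand_kinetics()] radioligand; default tracer
#'   concentration is 2.5 nM.
#' @param L Radioligand concentration, nM.
#' @param competitor [ligand_kinetics()] competing (unlabelled) ligand.
#' @param I Competitor concentration, nM. Defaults to the Gaddum-derived
#'   equilibrium IC50.
#' @param t1,t2 Read times in min, `t1 < t2`.
#' @param n_replicates,noise Optional replicate structure; the default is
#'   a single noiseless read, matching the use of the assay as a
#'   deterministic screening statistic.
#' @return An `assay_protocol` of kind `"dual_point"`.
#' @export
build_dual_point_protocol <- function(radio, L = 2.5, competitor,
                                      I = gaddum_ic50(radio, competitor, L),
                                      t1 = 30, t2 = 120, n_replicates = 1,
                                      noise = noise_model(cv = 0, additive_sd = 0)) {
  stopifnot(inherits(radio, "ligand_kinetics"),
            inherits(competitor, "ligand_kinetics"))
  if (L <= 0 || I < 0) stop("`L` must be > 0 and `I` >= 0", call. = FALSE)
  if (!(t1 > 0 && t2 > t1)) stop("read times must satisfy 0 < t1 < t2", call. = FALSE)
  ctrl <- gaddum_occupancy(radio, L)
  inhib <- 1 - gaddum_occupancy(radio, L, list(list(ligand = competitor, conc = I))) / ctrl
  if (I > 0 && (inhib < 0.3 || inhib > 0.7)) {
    warning(sprintf(
      "competitor concentration gives %.0f%% equilibrium inhibition; the assay design rule targets 30-70%%",
      100 * inhib), call. = FALSE)
  }
  new_assay_protocol(
    "dual_point", radioligand = radio, radioligand_conc = L,
    antagonist = competitor, antagonist_concs = I,
    preincubation_min = 0, read_horizon_min = t2, read_times = c(t1, t2),
    calibration = "binding", n_replicates = n_replicates, noise = noise
  )
}

#' Build a single time-course protocol
#'
#' One agonist concentration (optionally after antagonist pre-incubation),
#' read on the functional time grid. Used for onset-of-activation analysis
#' at EC80 challenge.
#'
#' @inheritParams build_concentration_response_protocol
#' @param conc Single agonist concentration, nM.
#' @return An `assay_protocol` of kind `"single_timecourse"`.
#' @export
build_single_timecourse_protocol <- function(
    agonist, conc, antagonist = NULL, antagonist_conc = 0,
    preincubation_min = 30, read_horizon_min = 45, calibration = "camp",
    n_replicates = 3, noise = noise_model()) {
  stopifnot(inherits(agonist, "ligand_kinetics"))
  if (length(conc) != 1L || conc <= 0) stop("`conc` must be a single positive number", call. = FALSE)
  if (is.null(antagonist) && antagonist_conc > 0) {
    stop("`antagonist_conc` > 0 requires an antagonist", call. = FALSE)
  }
  p <- build_concentration_response_protocol(
    agonist, concs = conc, antagonist = antagonist,
    antagonist_conc = antagonist_conc, preincubation_min = preincubation_min,
    read_horizon_min = read_horizon_min, calibration = calibration,
    n_replicates = n_replicates, noise = noise
  ) |> suppressWarnings()
  p$kind <- "single_timecourse"
  p
}
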