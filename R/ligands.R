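#' Define a ligand by its binding kinetics
#'
#' A ligand is characterised by its association rate constant `kon`
#' (nM^-1 min^-1), dissociation rate constant `koff` (min^-1) and its
#' pharmacological role. The equilibrium dissociation constant follows as
#' `KD = koff/kon` (nM) and the residence time as `1/koff` (min).
#'
#' @param name Label used to identify the ligand in schedules and datasets.
#' @param kon Association rate constant, nM^-1 min^-1. Must be > 0.
#' @param koff Dissociation rate constant, min^-1. Must be > 0.
#' @param role One of `"agonist"`, `"antagonist"`, `"radioligand"`.
#' @return An object of class `ligand_kinetics`.
#' @examples
#' sp <- ligand_kinetics("SP", kon = 0.24, koff = 0.027, role = "agonist")
#' kd(sp) # 0.1125 nM
#' @export
ligand_kinetics <- function(name, kon, koff,
                            role = c("agonist", "antagonist", "radioligand")) {
  role <- match.arg(role)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("`name` must be a non-empty string", call. = FALSE)
  }
  for (v in c("kon", "koff")) {
    x <- get(v)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      stop(sprintf("`%s` must be a single finite positive number", v),
           call. = FALSE)
    }
  }
  structure(
    list(name = name, kon = kon, koff = koff, role = role),
    class = "ligand_kinetics"
  )
}

#' Equilibrium dissociation constant of a ligand
#'
#' @param ligand A [ligand_kinetics()] object.
#' @return `koff/kon` in nM.
#' @export
kd <- function(ligand) {
  stopifnot(inherits(ligand, "ligand_kinetics"))
  ligand$koff / ligand$kon
}

#' Residence time of a ligand-receptor complex
#'
#' @param ligand A [ligand_kinetics()] object.
#' @return `1/koff` in min.
#' @export
residence_time <- function(ligand) {
  stopifnot(inherits(ligand, "ligand_kinetics"))
  1 / ligand$koff
}

#' @export
print.ligand_kinetics <- function(x, ...) {
  cat(sprintf(
    "<ligand_kinetics> %s (%s)\n  kon  %.4g nM^-1 min^-1\n  koff %.4g min^-1\n  KD   %.4g nM (residence time %.4g min)\n",
    x$name, x$role, x$kon, x$koff, kd(x), residence_time(x)
  ))
  invisible(x)
}

#' A receptor pool with its competing ligands
#'
#' Receptor density is expressed in arbitrary concentration units; the
#' default `r_tot = 1` makes all bound series fractional occupancies.
#' Receptor reserve is modelled downstream through the transduction gain,
#' not through `r_tot`.
#'
#' @param ligands List of [ligand_kinetics()] objects with unique names.
#' @param r_tot Total receptor concentration (> 0).
#' @return An object of class `receptor_system`.
#' @export
receptor_system <- function(ligands = list(), r_tot = 1.0) {
  if (inherits(ligands, "ligand_kinetics")) ligands <- list(ligands)
  if (!is.numeric(r_tot) || length(r_tot) != 1L || !is.finite(r_tot) || r_tot <= 0) {
    stop("`r_tot` must be a single positive number", call. = FALSE)
  }
  ok <- vapply(ligands, inherits, logical(1), what = "ligand_kinetics")
  if (!all(ok)) stop("all `ligands` must be ligand_kinetics objects", call. = FALSE)
  nm <- vapply(ligands, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop("ligand names must be unique: ", paste(nm[duplicated(nm)], collapse = ", "),
         call. = FALSE)
  }
  names(ligands) <- nm
  structure(list(r_tot = r_tot, ligands = ligands), class = "receptor_system")
}

#' @export
print.receptor_system <- function(x, ...) {
  cat(sprintf("<receptor_system> r_tot = %g, %d ligand(s): %s\n",
              x$r_tot, length(x$ligands), paste(names(x$ligands), collapse = ", ")))
  invisible(x)
}

#' Piecewise-constant ligand addition schedule
#'
#' Each event sets the free concentration of one ligand from that time
#' onwards (free concentrations are held constant between events; ligand
#' depletion is neglected). Pre-incubation is expressed by adding the
#' antagonist at t = 0 and the agonist at t = preincubation time.
#'
#' @param events Data frame with columns `time` (min), `ligand` (name) and
#'   `conc` (free concentration, nM). Times must be non-decreasing, >= 0 and
#'   < `horizon`; concentrations must be >= 0.
#' @param horizon Total simulated time (min).
#' @return An object of class `addition_schedule`.
#' @examples
#' addition_schedule(
#'   data.frame(time = c(0, 30), ligand = c("aprepitant", "SP"),
#'              conc = c(0.7, 10)),
#'   horizon = 75
#' )
#' @export
addition_schedule <- function(events, horizon) {
  if (!is.data.frame(events) || !all(c("time", "ligand", "conc") %in% names(events))) {
    stop("`events` must be a data frame with columns time, ligand, conc",
         call. = FALSE)
  }
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= 0) {
    stop("`horizon` must be a single positive number", call. = FALSE)
  }
  events <- events[, c("time", "ligand", "conc")]
  events$ligand <- as.character(events$ligand)
  if (nrow(events)) {
    if (is.unsorted(events$time)) stop("event times must be non-decreasing", call. = FALSE)
    if (any(events$time < 0) || any(events$time >= horizon)) {
      stop("event times must lie in [0, horizon)", call. = FALSE)
    }
    if (any(!is.finite(events$conc)) || any(events$conc < 0)) {
      stop("event concentrations must be finite and >= 0", call. = FALSE)
    }
  }
  structure(list(events = events, horizon = horizon), class = "addition_schedule")
}

#' Reference NK1 receptor ligand kinetics
#'
#' Fixture parameter sets for the neurokinin-1 receptor system. SP and NKA
#' use published kinetic rate constants (SP kon 0.24 nM^-1 min^-1, koff
#' 0.027 min^-1; NKA kon 0.0010, koff 0.19: NKA associates 240-fold more
#' slowly but dissociates 7-fold faster). The antagonist entries are
#' synthetic reconstructions: their rate constants are not published, so
#' `koff` is taken as 0.0054 min^-1 for aprepitant (reported at room
#' temperature) and as the radioligand's koff for DFA (its kinetic rate
#' index of 1.0 implies radioligand-like dissociation), with KD derived from
#' pKi (9.5 and 9.3) and kon = koff/KD. The radioligand defaults to SP's
#' rate constants, the standard assumption for this labelled SP analogue.
#'
#' @return Named list of [ligand_kinetics()] objects:
#'   `SP`, `NKA`, `radioligand`, `aprepitant`, `DFA`.
#' @export
nk1_reference_ligands <- function() {
  kd_aprep <- 10^(-9.5) * 1e9 # pKi 9.5 -> nM
  kd_dfa <- 10^(-9.3) * 1e9
  list(
    SP = ligand_kinetics("SP", kon = 0.24, koff = 0.027, role = "agonist"),
    NKA = ligand_kinetics("NKA", kon = 0.0010, koff = 0.19, role = "agonist"),
    radioligand = ligand_kinetics("radioligand", kon = 0.24, koff = 0.027,
                                  role = "radioligand"),
    aprepitant = ligand_kinetics("aprepitant", kon = 0.0054 / kd_aprep,
                                 koff = 0.0054, role = "antagonist"),
    DFA = ligand_kinetics("DFA", kon = 0.027 / kd_dfa, koff = 0.027,
                          role = "antagonist")
  )
}
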