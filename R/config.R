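run_config_schema <- function() {
  list(
    top = c("ligands", "protocol", "transduction", "noise", "seed",
            "output_dir", "analysis"),
    ligand = c("name", "kon_per_nM_per_min", "koff_per_min", "role"),
    protocol = c("kind", "agonist", "agonist_concs_nM", "antagonist",
                 "antagonist_conc_nM", "antagonist_concs_nM",
                 "preincubation_min", "read_horizon_min", "radioligand",
                 "radioligand_conc_nM", "competitor", "competitor_conc_nM",
                 "t1_min", "t2_min", "n_replicates", "agonist_ec80_nM"),
    transduction = c("calibration", "efficacy", "gain", "k_syn", "k_deg",
                     "k_des", "basal"),
    noise = c("cv", "additive_sd"),
    analysis = c("window_min", "alpha", "normalize_to", "baseline_window_min")
  )
}

#' Load and validate a run configuration
#'
#' Reads a JSON or YAML configuration describing ligands, one protocol
#' block, transduction calibration, noise and analysis options. The schema
#' is validated before any computation: unknown keys are rejected and all
#' problems are reported in a single error. Defaults (30-min
#' pre-incubation, 8-min onset window, dual-point reads at 30/120 min,
#' radioligand at 2.5 nM, camp calibration, cv 0.10, seed 1, alpha 0.05)
#' are applied for omitted keys.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A validated `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("config must be JSON or YAML (got .", ext, ")", call. = FALSE)
  )
  validate_config(raw)
}

#' Validate a configuration list
#'
#' @param raw A list with the structure documented in [load_config()].
#' @return A `run_config` with defaults applied.
#' @export
validate_config <- function(raw) {
  sch <- run_config_schema()
  errs <- character(0)
  note <- function(...) errs <<- c(errs, sprintf(...))

  unknown <- setdiff(names(raw), sch$top)
  if (length(unknown)) note("unknown top-level key(s): %s", paste(unknown, collapse = ", "))

  ligands <- list()
  if (is.null(raw$ligands) || !length(raw$ligands)) {
    note("`ligands` must define at least one ligand")
  } else {
    for (i in seq_along(raw$ligands)) {
      lg <- raw$ligands[[i]]
      bad <- setdiff(names(lg), sch$ligand)
      if (length(bad)) note("ligand %d: unknown key(s): %s", i, paste(bad, collapse = ", "))
      miss <- setdiff(sch$ligand, names(lg))
      if (length(miss)) {
        note("ligand %d: missing key(s): %s", i, paste(miss, collapse = ", "))
      } else {
        lk <- tryCatch(
          ligand_kinetics(lg$name, lg$kon_per_nM_per_min, lg$koff_per_min, lg$role),
          error = function(e) {note("ligand %d: %s", i, conditionMessage(e)); NULL})
        if (!is.null(lk)) ligands[[lk$name]] <- lk
      }
    }
  }

  pr <- raw$protocol
  if (is.null(pr)) {
    note("`protocol` block is required")
    pr <- list()
  } else {
    bad <- setdiff(names(pr), sch$protocol)
    if (length(bad)) note("protocol: unknown key(s): %s", paste(bad, collapse = ", "))
    kinds <- c("conc_response", "ic50_at_ec80", "dual_point", "single_timecourse")
    if (is.null(pr$kind) || !pr$kind %in% kinds) {
      note("protocol$kind must be one of %s", paste(kinds, collapse = ", "))
    }
    for (ref in c("agonist", "antagonist", "radioligand", "competitor")) {
      if (!is.null(pr[[ref]]) && length(ligands) && !pr[[ref]] %in% names(ligands)) {
        note("protocol$%s references undefined ligand '%s'", ref, pr[[ref]])
      }
    }
  }
  pr$preincubation_min <- pr$preincubation_min %||% 30
  pr$read_horizon_min <- pr$read_horizon_min %||% 45
  pr$t1_min <- pr$t1_min %||% 30
  pr$t2_min <- pr$t2_min %||% 120
  pr$radioligand_conc_nM <- pr$radioligand_conc_nM %||% 2.5
  pr$n_replicates <- pr$n_replicates %||% 3

  tr <- raw$transduction %||% list()
  bad <- setdiff(names(tr), sch$transduction)
  if (length(bad)) note("transduction: unknown key(s): %s", paste(bad, collapse = ", "))
  tr$calibration <- tr$calibration %||% "camp"
  if (!tr$calibration %in% c("camp", "impedance")) {
    note("transduction$calibration must be 'camp' or 'impedance'")
  }

  nz <- raw$noise %||% list()
  bad <- setdiff(names(nz), sch$noise)
  if (length(bad)) note("noise: unknown key(s): %s", paste(bad, collapse = ", "))
  nz$cv <- nz$cv %||% 0.10
  nz$additive_sd <- nz$additive_sd %||% 0

  an <- raw$analysis %||% list()
  bad <- setdiff(names(an), sch$analysis)
  if (length(bad)) note("analysis: unknown key(s): %s", paste(bad, collapse = ", "))
  an$window_min <- an$window_min %||% 8
  an$alpha <- an$alpha %||% 0.05
  an$normalize_to <- an$normalize_to %||% "control"
  an$baseline_window_min <- an$baseline_window_min %||% 5

  if (length(errs)) {
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  structure(
    list(ligands = ligands, protocol = pr, transduction = tr, noise = nz,
         seed = as.integer(raw$seed %||% 1L),
         output_dir = raw$output_dir %||% ".", analysis = an),
    class = "run_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a run configuration
#'
#' Writes the configuration back as JSON or YAML (by extension) such that
#' [load_config()] reproduces it.
#'
#' @param config A `run_config`.
#' @param path Output path (`.json`, `.yaml` or `.yml`).
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  raw <- list(
    ligands = unname(lapply(config$ligands, function(l) {
      list(name = l$name, kon_per_nM_per_min = l$kon,
           koff_per_min = l$koff, role = l$role)
    })),
    protocol = config$protocol,
    transduction = config$transduction,
    noise = config$noise,
    seed = config$seed,
    output_dir = config$output_dir,
    analysis = config$analysis
  )
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = I(17), null = "null")
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(raw, path)
  } else {
    stop("config must be saved as JSON or YAML", call. = FALSE)
  }
  invisible(path)
}

#' Build an assay protocol from a run configuration
#'
#' @param config A `run_config` from [load_config()].
#' @return An `assay_protocol` ready for [generate_dataset()].
#' @export
config_to_protocol <- function(config) {
  stopifnot(inherits(config, "run_config"))
  pr <- config$protocol
  nz <- noise_model(cv = config$noise$cv, additive_sd = config$noise$additive_sd)
  get_lig <- function(nm) {
    if (is.null(nm)) return(NULL)
    config$ligands[[nm]]
  }
  switch(pr$kind,
    conc_response = build_concentration_response_protocol(
      agonist = get_lig(pr$agonist),
      concs = as.numeric(unlist(pr$agonist_concs_nM)),
      antagonist = get_lig(pr$antagonist),
      antagonist_conc = pr$antagonist_conc_nM %||% 0,
      preincubation_min = pr$preincubation_min,
      read_horizon_min = pr$read_horizon_min,
      calibration = config$transduction$calibration,
      n_replicates = pr$n_replicates, noise = nz),
    single_timecourse = build_single_timecourse_protocol(
      agonist = get_lig(pr$agonist),
      conc = as.numeric(unlist(pr$agonist_concs_nM))[1],
      antagonist = get_lig(pr$antagonist),
      antagonist_conc = pr$antagonist_conc_nM %||% 0,
      preincubation_min = pr$preincubation_min,
      read_horizon_min = pr$read_horizon_min,
      calibration = config$transduction$calibration,
      n_replicates = pr$n_replicates, noise = nz),
    ic50_at_ec80 = build_ic50_protocol(
      antagonist = get_lig(pr$antagonist),
      concs = as.numeric(unlist(pr$antagonist_concs_nM)),
      agonist = get_lig(pr$agonist),
      agonist_ec80 = pr$agonist_ec80_nM,
      preincubation_min = pr$preincubation_min,
      read_horizon_min = pr$read_horizon_min,
      calibration = config$transduction$calibration,
      n_replicates = pr$n_replicates, noise = nz),
    dual_point = build_dual_point_protocol(
      radio = get_lig(pr$radioligand), L = pr$radioligand_conc_nM,
      competitor = get_lig(pr$competitor),
      I = pr$competitor_conc_nM %||%
        gaddum_ic50(get_lig(pr$radioligand), get_lig(pr$competitor),
                    pr$radioligand_conc_nM),
      t1 = pr$t1_min, t2 = pr$t2_min,
      n_replicates = pr$n_replicates, noise = nz),
    stop("unsupported protocol kind: ", pr$kind, call. = FALSE)
  )
}
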