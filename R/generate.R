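#' @importFrom utils packageVersion read.csv write.csv
NULL

# Deterministic 31-bit seed for a condition/replicate substream. Based on a
# string hash of the condition id so that streams are stable under
# condition reordering.
condition_seed <- function(seed, condition_id, replicate = 0L) {
  h <- 0
  for (ch in utf8ToInt(as.character(condition_id))) {
    h <- (h * 31 + ch) %% 2147483L
  }
  as.integer((as.numeric(seed) * 7919 + h * 1000 + replicate) %% 2147483647)
}

protocol_conditions <- function(protocol) {
  p <- protocol
  ant_name <- if (is.null(p$antagonist)) "" else p$antagonist$name
  if (p$kind %in% c("conc_response", "single_timecourse")) {
    ant_conc <- if (length(p$antagonist_concs)) p$antagonist_concs[1] else 0
    data.frame(
      condition_id = sprintf("%s_%.6gnM%s", p$agonist$name, p$agonist_concs,
                             if (ant_conc > 0) sprintf("_%s_%.6gnM", ant_name, ant_conc) else ""),
      agonist = p$agonist$name, agonist_conc_nM = p$agonist_concs,
      antagonist = if (ant_conc > 0) ant_name else "",
      antagonist_conc_nM = ant_conc,
      stringsAsFactors = FALSE
    )
  } else if (p$kind == "ic50_at_ec80") {
    concs <- c(0, p$antagonist_concs)
    data.frame(
      condition_id = c("control",
                       sprintf("%s_%.6gnM", ant_name, p$antagonist_concs)),
      agonist = p$agonist$name, agonist_conc_nM = p$agonist_concs[1],
      antagonist = ifelse(concs > 0, ant_name, ""),
      antagonist_conc_nM = concs,
      stringsAsFactors = FALSE
    )
  } else if (p$kind == "dual_point") {
    data.frame(
      condition_id = sprintf("dualpoint_%s_%.6gnM", ant_name, p$antagonist_concs),
      agonist = p$radioligand$name, agonist_conc_nM = p$radioligand_conc,
      antagonist = if (p$antagonist_concs > 0) ant_name else "",
      antagonist_conc_nM = p$antagonist_concs,
      stringsAsFactors = FALSE
    )
  } else {
    stop("unknown protocol kind: ", p$kind, call. = FALSE)
  }
}

#' Generate a tidy synthetic time-course dataset from a protocol
#'
#' Runs the full forward model -- competitive binding ODE, transduction
#' (except for dual-point binding protocols, which read bound radioligand
#' directly), then replicate noise -- for every condition of the protocol.
#' Functional time courses are exported on a 1-min grid with t = 0 at
#' agonist addition (the pre-incubation occupies negative time internally
#' and is shifted out before export). Deterministic given `seed`; noise
#' streams are keyed per condition and replicate, so adding or reordering
#' conditions does not perturb the others.
#'
#' @param protocol An `assay_protocol`.
#' @param r_tot Total receptor concentration (fractional occupancy scale by
#'   default).
#' @param seed Integer seed governing all noise.
#' @param grid_step Internal binding integration grid, min.
#' @return A `timecourse_dataset`: a data frame with columns `time_min`,
#'   `condition_id`, `agonist`, `agonist_conc_nM`, `antagonist`,
#'   `antagonist_conc_nM`, `replicate`, `readout`, `value`, carrying a
#'   `metadata` attribute (protocol echo, seed, generator version)
#'   sufficient to regenerate it exactly.
#' @export
generate_dataset <- function(protocol, r_tot = 1.0, seed = 1L,
                             grid_step = 0.25) {
  stopifnot(inherits(protocol, "assay_protocol"))
  p <- protocol
  conds <- protocol_conditions(p)
  rows <- vector("list", nrow(conds))

  if (p$kind == "dual_point") {
    ligs <- list(p$radioligand)
    if (p$antagonist_concs > 0) ligs <- c(ligs, list(p$antagonist))
    sys <- receptor_system(ligs, r_tot = r_tot)
    ev <- data.frame(time = 0, ligand = p$radioligand$name,
                     conc = p$radioligand_conc)
    if (p$antagonist_concs > 0) {
      ev <- rbind(ev, data.frame(time = 0, ligand = p$antagonist$name,
                                 conc = p$antagonist_concs))
    }
    sch <- addition_schedule(ev, horizon = p$read_horizon_min)
    traj <- simulate_binding(sys, sch, grid_step = min(grid_step, 0.5))
    idx <- vapply(p$read_times, function(tt) which.min(abs(traj$times - tt)),
                  integer(1))
    vals <- traj$bound[idx, p$radioligand$name]
    reps <- lapply(seq_len(p$n_replicates), function(r) {
      nz <- apply_noise(vals, p$noise, n_replicates = 1,
                        seed = condition_seed(seed, conds$condition_id[1], r))
      data.frame(time_min = p$read_times, replicate = r, value = nz$value)
    })
    base <- do.call(rbind, reps)
    rows[[1]] <- data.frame(
      time_min = base$time_min, condition_id = conds$condition_id[1],
      agonist = conds$agonist[1], agonist_conc_nM = conds$agonist_conc_nM[1],
      antagonist = conds$antagonist[1],
      antagonist_conc_nM = conds$antagonist_conc_nM[1],
      replicate = base$replicate, readout = "bound", value = base$value,
      stringsAsFactors = FALSE
    )
  } else {
    params <- transduction_calibration(p$calibration)
    out_times <- seq(0, p$read_horizon_min, by = 1)
    for (i in seq_len(nrow(conds))) {
      ci <- conds[i, ]
      ligs <- list(p$agonist)
      has_ant <- ci$antagonist_conc_nM > 0
      if (has_ant) ligs <- c(ligs, list(p$antagonist))
      sys <- receptor_system(ligs, r_tot = r_tot)
      pre <- p$preincubation_min
      ev <- data.frame(time = pre, ligand = p$agonist$name,
                       conc = ci$agonist_conc_nM)
      if (has_ant) {
        ev <- rbind(data.frame(time = 0, ligand = p$antagonist$name,
                               conc = ci$antagonist_conc_nM), ev)
      } else if (pre > 0) {
        ev$time <- 0
        pre <- 0
      }
      sch <- addition_schedule(ev, horizon = pre + p$read_horizon_min)
      traj <- simulate_binding(sys, sch, grid_step = grid_step)
      resp <- simulate_readout(traj, params, p$agonist$name)
      shifted <- resp$times - pre
      vals <- stats::approx(shifted, resp$response, xout = out_times)$y
      reps <- lapply(seq_len(p$n_replicates), function(r) {
        nz <- apply_noise(vals, p$noise, n_replicates = 1,
                          seed = condition_seed(seed, ci$condition_id, r))
        data.frame(time_min = out_times, replicate = r, value = nz$value)
      })
      base <- do.call(rbind, reps)
      rows[[i]] <- data.frame(
        time_min = base$time_min, condition_id = ci$condition_id,
        agonist = ci$agonist, agonist_conc_nM = ci$agonist_conc_nM,
        antagonist = ci$antagonist, antagonist_conc_nM = ci$antagonist_conc_nM,
        replicate = base$replicate, readout = p$calibration,
        value = base$value, stringsAsFactors = FALSE
      )
    }
  }

  ds <- do.call(rbind, rows)
  rownames(ds) <- NULL
  attr(ds, "metadata") <- list(
    protocol = protocol_echo(p), seed = as.integer(seed), r_tot = r_tot,
    grid_step = grid_step,
    generator = paste0("kinsig ", as.character(utils::packageVersion("kinsig")))
  )
  class(ds) <- c("timecourse_dataset", "data.frame")
  ds
}

ligand_echo <- function(l) {
  if (is.null(l)) NULL else
    list(name = l$name, kon_per_nM_per_min = l$kon, koff_per_min = l$koff,
         role = l$role)
}

protocol_echo <- function(p) {
  list(
    kind = p$kind, agonist = ligand_echo(p$agonist),
    agonist_concs_nM = p$agonist_concs,
    antagonist = ligand_echo(p$antagonist),
    antagonist_concs_nM = p$antagonist_concs,
    radioligand = ligand_echo(p$radioligand),
    radioligand_conc_nM = p$radioligand_conc,
    preincubation_min = p$preincubation_min,
    read_horizon_min = p$read_horizon_min, read_times = p$read_times,
    calibration = p$calibration, n_replicates = p$n_replicates,
    noise = list(cv = p$noise$cv, additive_sd = p$noise$additive_sd)
  )
}

ligand_from_echo <- function(e) {
  if (is.null(e)) NULL else
    ligand_kinetics(e$name, e$kon_per_nM_per_min, e$koff_per_min, e$role)
}

#' Rebuild an assay protocol from a metadata echo
#'
#' Inverse of the metadata block written by [generate_dataset()]; together
#' with the recorded seed this regenerates a dataset exactly.
#'
#' @param echo The `protocol` element of a dataset's metadata.
#' @return An `assay_protocol`.
#' @export
protocol_from_echo <- function(echo) {
  e <- echo
  noise <- noise_model(cv = e$noise$cv, additive_sd = e$noise$additive_sd)
  p <- new_assay_protocol(
    e$kind, agonist = ligand_from_echo(e$agonist),
    agonist_concs = as.numeric(unlist(e$agonist_concs_nM)),
    antagonist = ligand_from_echo(e$antagonist),
    antagonist_concs = as.numeric(unlist(e$antagonist_concs_nM)),
    radioligand = ligand_from_echo(e$radioligand),
    radioligand_conc = if (is.null(e$radioligand_conc_nM)) NA_real_ else e$radioligand_conc_nM,
    preincubation_min = e$preincubation_min,
    read_horizon_min = e$read_horizon_min,
    read_times = if (is.null(e$read_times)) NULL else as.numeric(unlist(e$read_times)),
    calibration = e$calibration, n_replicates = e$n_replicates, noise = noise
  )
  p
}

#' Write a time-course dataset as tidy CSV with a JSON metadata sidecar
#'
#' @param dataset A `timecourse_dataset`.
#' @param path Output CSV path; metadata is written to `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_timecourse_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "timecourse_dataset"))
  df <- as.data.frame(dataset)
  attr(df, "metadata") <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  meta <- attr(dataset, "metadata")
  if (!is.null(meta)) {
    # I(17) significant digits round-trips IEEE doubles exactly, so the
    # sidecar alone suffices to regenerate the dataset bit-for-bit
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = I(17), null = "null")
  }
  invisible(path)
}

#' Read a time-course dataset written by [write_timecourse_csv()]
#'
#' @param path CSV path; the `<path>.meta.json` sidecar is attached as
#'   metadata when present.
#' @return A `timecourse_dataset`.
#' @export
read_timecourse_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_min", "condition_id", "agonist", "agonist_conc_nM",
            "antagonist", "antagonist_conc_nM", "replicate", "readout", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("not a timecourse CSV; missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df$antagonist[is.na(df$antagonist)] <- ""
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    attr(df, "metadata") <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  }
  class(df) <- c("timecourse_dataset", "data.frame")
  df
}

#' Run a dual-point protocol and compute its kinetic rate index
#'
#' Convenience wrapper: generates the dual-point dataset, averages bound
#' radioligand over replicates at each read time, and forms the KRI.
#'
#' @param protocol An `assay_protocol` of kind `"dual_point"`.
#' @inheritParams generate_dataset
#' @return A `kri_result` (see [compute_kri()]).
#' @export
run_dual_point <- function(protocol, r_tot = 1.0, seed = 1L) {
  stopifnot(inherits(protocol, "assay_protocol"))
  if (protocol$kind != "dual_point") {
    stop("`protocol` must be of kind 'dual_point'", call. = FALSE)
  }
  ds <- generate_dataset(protocol, r_tot = r_tot, seed = seed)
  b <- tapply(ds$value, ds$time_min, mean)
  tt <- as.numeric(names(b))
  o <- order(tt)
  compute_kri(b_t1 = unname(b[o][1]), b_t2 = unname(b[o][2]),
              t1 = tt[o][1], t2 = tt[o][2])
}
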