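#' Peak analysis of real-time traces
#'
#' For every condition and replicate, the peak response is the maximum of
#' (value - baseline) over the trace, with the baseline taken as the mean
#' over a pre-stimulation window (`time_min <= 0` within `baseline_window`
#' minutes before stimulation) or the first sample when no pre-stimulation
#' samples exist. No smoothing is applied; replicate structure is relied on
#' to average out noise.
#'
#' @param dataset A `timecourse_dataset` (functional readout).
#' @param baseline_window Width of the pre-stimulation baseline window, min.
#' @param aggregate_replicates Average the replicate wells of each condition
#'   into one trace before taking the peak. This is the within-experiment
#'   convention of plate assays run in duplicate/triplicate (the replicate
#'   wells of one experiment are averaged; independent experiments carry
#'   the statistics) and reduces the upward bias of a max taken over a
#'   noisy trace. Default `FALSE`: one peak per replicate, as needed for
#'   replicate-level statistics.
#' @return Data frame with one row per (condition, replicate): columns
#'   `condition_id`, `agonist`, `agonist_conc_nM`, `antagonist`,
#'   `antagonist_conc_nM`, `replicate`, `baseline`, `peak`. With
#'   `aggregate_replicates = TRUE` the replicate column is 1 throughout.
#' @export
peak_response <- function(dataset, baseline_window = 5,
                          aggregate_replicates = FALSE) {
  stopifnot(is.data.frame(dataset))
  if (!nrow(dataset)) stop("dataset is empty", call. = FALSE)
  if (aggregate_replicates) {
    dataset <- stats::aggregate(
      value ~ time_min + condition_id + agonist + agonist_conc_nM +
        antagonist + antagonist_conc_nM + readout,
      data = as.data.frame(dataset), FUN = mean)
    dataset$replicate <- 1L
  }
  key <- interaction(dataset$condition_id, dataset$replicate, drop = TRUE)
  parts <- split(as.data.frame(dataset), key)
  out <- lapply(parts, function(d) {
    d <- d[order(d$time_min), ]
    if (all(is.na(d$value))) {
      stop("condition '", d$condition_id[1], "' has no non-missing values",
           call. = FALSE)
    }
    pre <- d$value[d$time_min <= 0 & d$time_min >= -baseline_window]
    baseline <- if (length(pre)) mean(pre, na.rm = TRUE) else d$value[1]
    data.frame(
      condition_id = d$condition_id[1], agonist = d$agonist[1],
      agonist_conc_nM = d$agonist_conc_nM[1], antagonist = d$antagonist[1],
      antagonist_conc_nM = d$antagonist_conc_nM[1],
      replicate = d$replicate[1], baseline = baseline,
      peak = max(d$value - baseline, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$condition_id, res$replicate), ]
}

logistic4 <- function(logL, bottom, top, logec50, hill) {
  bottom + (top - bottom) / (1 + 10^((logec50 - logL) * hill))
}

#' Variable-slope (four-parameter logistic) concentration-response fit
#'
#' Least-squares fit of the log(agonist) vs response model with variable
#' slope:
#' \deqn{r = bottom + (top - bottom) / (1 + 10^{(\log EC_{50} - \log L) \cdot hill})}
#' Initialisation is multi-start from 5 deterministic points spanning the
#' fitted concentration range; fits that fail to converge from every start,
#' or degenerate inputs (no spread in response), return a flagged result
#' rather than an error. Standard errors come from the converged
#' least-squares fit.
#'
#' @param peaks Data frame with columns `agonist_conc_nM` (or `conc_nM`)
#'   and `peak` (or `response`/`value`); replicate rows per concentration
#'   are fitted together. At least 5 distinct concentrations are required.
#' @param direction `"ascending"` fits an agonist curve (hill constrained
#'   positive); `"descending"` an inhibition curve (hill negative, reported
#'   with `ic50` semantics by [fit_inhibition()]).
#' @param fix_bottom Optional fixed lower asymptote (e.g. 0 for
#'   baseline-corrected peaks); `NULL` fits it freely.
#' @return An object of class `conc_response_fit`: list with `ec50` (nM),
#'   `pec50` (-log10 M), `emax` (fitted top), `baseline` (fitted bottom),
#'   `hill`, `se` (named vector), `converged`, `extrapolated` (EC50 outside
#'   the fitted range +/- 1 log), `normalized` flag, `direction`, `n`,
#'   residual standard error `sigma`, and the `data` used.
#' @export
fit_concentration_response <- function(peaks,
                                       direction = c("ascending", "descending"),
                                       fix_bottom = NULL) {
  direction <- match.arg(direction)
  d <- normalize_fit_input(peaks)
  if (length(unique(d$conc)) < 5) {
    stop("at least 5 distinct concentrations are required", call. = FALSE)
  }
  d <- d[d$conc > 0 & is.finite(d$resp), ]
  logL <- log10(d$conc)
  resp <- d$resp

  spread <- diff(range(resp))
  scale <- max(abs(resp), 1e-12)
  if (spread < 1e-8 * scale) {
    return(flagged_fit(d, direction, reason = "degenerate: no response spread"))
  }

  sgn <- if (direction == "ascending") 1 else -1
  starts <- seq(min(logL), max(logL), length.out = 5)
  lo_resp <- min(resp); hi_resp <- max(resp)
  best <- NULL
  for (s in starts) {
    st <- list(logec50 = s, hill = sgn * 1)
    if (is.null(fix_bottom)) {
      st <- c(list(bottom = lo_resp, top = hi_resp), st)
      fml <- resp ~ logistic4(logL, bottom, top, logec50, hill)
    } else {
      st <- c(list(top = hi_resp), st)
      fml <- resp ~ logistic4(logL, fix_bottom, top, logec50, hill)
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(fml, data = data.frame(logL = logL, resp = resp),
                        start = st,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(flagged_fit(d, direction, reason = "non-convergent from all starts"))
  }
  fit <- best$fit
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, length(cf)), names(cf)))
  bottom <- if (is.null(fix_bottom)) cf[["bottom"]] else fix_bottom
  top <- cf[["top"]]
  hill <- cf[["hill"]]
  logec50 <- cf[["logec50"]]
  ec50 <- 10^logec50
  ok_dir <- if (direction == "ascending") hill > 0 else hill < 0
  extrapolated <- logec50 < min(logL) - 1 || logec50 > max(logL) + 1
  structure(
    list(
      ec50 = ec50, pec50 = 9 - logec50, emax = top, baseline = bottom,
      hill = hill, se = se, converged = ok_dir,
      extrapolated = extrapolated, normalized = FALSE, direction = direction,
      n = nrow(d), sigma = tryCatch(summary(fit)$sigma, error = function(e) NA_real_),
      data = d
    ),
    class = "conc_response_fit"
  )
}

normalize_fit_input <- function(peaks) {
  stopifnot(is.data.frame(peaks))
  conc_col <- intersect(c("agonist_conc_nM", "antagonist_conc_nM", "conc_nM", "conc"),
                        names(peaks))[1]
  resp_col <- intersect(c("peak", "response", "value"), names(peaks))[1]
  if (is.na(conc_col) || is.na(resp_col)) {
    stop("`peaks` must contain a concentration and a response column",
         call. = FALSE)
  }
  data.frame(conc = peaks[[conc_col]], resp = peaks[[resp_col]])
}

flagged_fit <- function(d, direction, reason) {
  structure(
    list(ec50 = NA_real_, pec50 = NA_real_, emax = NA_real_,
         baseline = NA_real_, hill = NA_real_,
         se = c(bottom = NA_real_, top = NA_real_, logec50 = NA_real_, hill = NA_real_),
         converged = FALSE, extrapolated = NA, normalized = FALSE,
         direction = direction, n = nrow(d), sigma = NA_real_,
         reason = reason, data = d),
    class = "conc_response_fit"
  )
}

#' @export
print.conc_response_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<conc_response_fit> NOT converged",
        if (!is.null(x$reason)) paste0(" (", x$reason, ")"), "\n", sep = "")
    return(invisible(x))
  }
  lab <- if (x$direction == "ascending") "EC50" else "IC50"
  unit <- if (isTRUE(x$normalized)) "% of control" else "readout units"
  cat(sprintf(
    "<conc_response_fit> %s %.4g nM (p%s %.3f), Emax %.4g %s, hill %.3f, n = %d\n",
    lab, x$ec50, lab, x$pec50, x$emax, unit, x$hill, x$n))
  invisible(x)
}

#' Normalize fits or peaks to the agonist-only control maximum
#'
#' Expresses responses as percent of the maximal response induced by the
#' agonist without antagonist. The scale factor is `100 / top` of the
#' control *fit* (less noise-sensitive than the single largest observed
#' value); the same factor is applied to every condition, so the control's
#' normalized Emax is 100% by construction and the transformation is
#' invariant to the readout units.
#'
#' @param x Either a named list of `conc_response_fit` objects or a peaks
#'   data frame (from [peak_response()]) with a `condition_id` column.
#' @param control_label Name/condition id of the agonist-only control.
#' @return Same shape as `x`, with responses (and for fits: `emax`,
#'   `baseline`, `sigma`, asymptote SEs) rescaled to percent-of-control and
#'   `normalized = TRUE`.
#' @export
normalize_to_control <- function(x, control_label = "control") {
  if (is.data.frame(x)) {
    ctrl <- x[x$condition_id == control_label, ]
    if (!nrow(ctrl)) stop("control '", control_label, "' not found", call. = FALSE)
    top <- max(ctrl$peak)
    if (!is.finite(top) || top <= 0) {
      stop("control maximum must be positive", call. = FALSE)
    }
    x$peak <- 100 * x$peak / top
    attr(x, "normalized") <- TRUE
    return(x)
  }
  stopifnot(is.list(x))
  if (!control_label %in% names(x)) {
    stop("control '", control_label, "' not found", call. = FALSE)
  }
  ctrl <- x[[control_label]]
  stopifnot(inherits(ctrl, "conc_response_fit"))
  if (!isTRUE(ctrl$converged)) {
    stop("control fit did not converge; cannot normalize", call. = FALSE)
  }
  top <- ctrl$emax
  if (!is.finite(top) || top <= 0) stop("control maximum must be positive", call. = FALSE)
  f <- 100 / top
  lapply(x, function(ft) {
    if (!inherits(ft, "conc_response_fit")) return(ft)
    ft$emax <- ft$emax * f
    ft$baseline <- ft$baseline * f
    ft$sigma <- ft$sigma * f
    for (nm in intersect(c("bottom", "top"), names(ft$se))) ft$se[nm] <- ft$se[nm] * f
    ft$data$resp <- ft$data$resp * f
    ft$normalized <- TRUE
    ft
  })
}

#' Fit antagonist inhibition of a fixed agonist challenge (IC50)
#'
#' Descending variable-slope logistic of peak response against antagonist
#' concentration (EC80 agonist challenge design). The IC50 is the
#' antagonist concentration halving the response between the fitted
#' asymptotes.
#'
#' @param peaks Data frame with antagonist concentrations
#'   (`antagonist_conc_nM` or `conc_nM`) and responses (`peak`); the
#'   zero-antagonist control rows anchor the upper asymptote. At least 5
#'   positive antagonist concentrations plus a control are required.
#' @return A `conc_response_fit` with `direction = "descending"`; `ec50`
#'   holds the IC50 (nM) and `hill` the (negative) slope factor.
#' @export
fit_inhibition <- function(peaks) {
  # the titrated variable here is the antagonist, not the (fixed) agonist
  if ("antagonist_conc_nM" %in% names(peaks)) {
    keep <- setdiff(names(peaks), c("agonist_conc_nM", "conc_nM", "conc"))
    peaks <- peaks[, keep, drop = FALSE]
  }
  d <- normalize_fit_input(peaks)
  pos <- unique(d$conc[d$conc > 0])
  if (length(pos) < 5) {
    stop("at least 5 positive antagonist concentrations are required",
         call. = FALSE)
  }
  ctrl <- d$resp[d$conc == 0]
  if (length(ctrl)) {
    # represent the control as a concentration 3 logs below the lowest dose
    d$conc[d$conc == 0] <- min(pos) * 1e-3
  }
  fit_concentration_response(
    data.frame(conc_nM = d$conc, peak = d$resp), direction = "descending")
}

#' EC80 from a fitted concentration-response curve
#'
#' The concentration producing 80% of the fitted maximum:
#' `EC80 = EC50 * (80/20)^(1/hill)`. With hill = 1 this is 4 x EC50.
#'
#' @param fit A converged ascending `conc_response_fit`.
#' @return Concentration in nM.
#' @export
compute_ec80 <- function(fit) {
  stopifnot(inherits(fit, "conc_response_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  if (fit$direction != "ascending") stop("EC80 requires an ascending fit", call. = FALSE)
  if (!is.finite(fit$hill) || fit$hill <= 0) {
    stop("`hill` must be > 0", call. = FALSE)
  }
  fit$ec50 * (80 / 20)^(1 / fit$hill)
}
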