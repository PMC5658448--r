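#' Kinetic rate index (KRI) from dual-point specific binding
#'
#' The KRI is the ratio of competitor-inhibited radioligand specific
#' binding at two read times, `KRI = B_t1 / B_t2`. A KRI above 1 indicates
#' the competitor dissociates more slowly than the radioligand (its
#' inhibition deepens between t1 and t2); below 1, faster; a competitor
#' with radioligand-identical kinetics gives KRI = 1.
#'
#' @param b_t1,b_t2 Specific binding at t1 and t2 (`b_t2 > 0`, `b_t1 >= 0`).
#' @param t1,t2 Read times, min (informational; defaults 30 and 120).
#' @return An object of class `kri_result`: list with `b_t1`, `b_t2`,
#'   `t1`, `t2`, `kri` and an `interpretation` string.
#' @examples
#' compute_kri(90, 50)$kri # 1.8
#' @export
compute_kri <- function(b_t1, b_t2, t1 = 30, t2 = 120) {
  if (!is.numeric(b_t2) || b_t2 <= 0) stop("`b_t2` must be > 0", call. = FALSE)
  if (!is.numeric(b_t1) || b_t1 < 0) stop("`b_t1` must be >= 0", call. = FALSE)
  kri <- b_t1 / b_t2
  interp <- if (kri > 1.02) {
    "slower dissociation than the radioligand"
  } else if (kri < 0.98) {
    "faster dissociation than the radioligand"
  } else {
    "dissociation comparable to the radioligand"
  }
  structure(list(b_t1 = b_t1, b_t2 = b_t2, t1 = t1, t2 = t2, kri = kri,
                 interpretation = interp),
            class = "kri_result")
}

#' @export
print.kri_result <- function(x, ...) {
  cat(sprintf("<kri_result> KRI = %.3f (B_t%g = %.4g / B_t%g = %.4g): %s\n",
              x$kri, x$t1, x$b_t1, x$t2, x$b_t2, x$interpretation))
  invisible(x)
}

#' Onset of receptor activation
#'
#' Ordinary least-squares slope of the readout against time over the first
#' `window_min` minutes after agonist addition (samples strictly after
#' t = 0, including the window endpoint), computed per replicate and then
#' averaged. The slope has units of readout min^-1 (RLU min^-1 for the
#' cAMP-like calibration, NCI min^-1 for the impedance-like one).
#'
#' @param dataset A `timecourse_dataset`.
#' @param condition_id Condition to analyse; `NULL` analyses every
#'   condition.
#' @param window_min Regression window length, min (default 8).
#' @return For a single condition, an `onset_result`: list with `slope`
#'   (mean across replicates), `se`, `intercept`, `window_min`,
#'   `r_squared` (mean), `n_points` (per replicate) and `replicates` (the
#'   per-replicate slopes). For `condition_id = NULL`, a data frame with
#'   one row per condition.
#' @export
compute_onset <- function(dataset, condition_id = NULL, window_min = 8) {
  stopifnot(is.data.frame(dataset))
  if (is.null(condition_id)) {
    ids <- unique(dataset$condition_id)
    rows <- lapply(ids, function(id) {
      r <- compute_onset(dataset, id, window_min)
      data.frame(condition_id = id, slope = r$slope, se = r$se,
                 r_squared = r$r_squared, n_points = r$n_points,
                 stringsAsFactors = FALSE)
    })
    return(do.call(rbind, rows))
  }
  d <- dataset[dataset$condition_id == condition_id &
                 dataset$time_min > 0 & dataset$time_min <= window_min, ]
  if (!nrow(d)) stop("condition '", condition_id, "' has no samples in the onset window",
                     call. = FALSE)
  parts <- split(as.data.frame(d), d$replicate)
  npts <- unique(vapply(parts, nrow, integer(1)))
  if (any(npts < 3)) {
    stop("need >= 3 samples in (0, ", window_min, "] per replicate", call. = FALSE)
  }
  fits <- lapply(parts, function(p) stats::lm(value ~ time_min, data = p))
  slopes <- vapply(fits, function(f) stats::coef(f)[["time_min"]], numeric(1))
  intercepts <- vapply(fits, function(f) stats::coef(f)[["(Intercept)"]], numeric(1))
  # noiseless traces fit exactly; the perfect-fit warning is expected
  r2 <- vapply(fits, function(f) suppressWarnings(summary(f)$r.squared),
               numeric(1))
  structure(
    list(slope = mean(slopes),
         se = if (length(slopes) > 1) stats::sd(slopes) / sqrt(length(slopes)) else NA_real_,
         intercept = mean(intercepts), window_min = window_min,
         r_squared = mean(r2), n_points = max(npts), replicates = slopes),
    class = "onset_result"
  )
}

#' @export
print.onset_result <- function(x, ...) {
  cat(sprintf(
    "<onset_result> slope %.4g readout/min (SEM %.3g, %d replicate(s), first %g min, R2 %.3f)\n",
    x$slope, x$se, length(x$replicates), x$window_min, x$r_squared))
  invisible(x)
}

#' One-way ANOVA with Dunnett's many-to-one post-test
#'
#' Compares every treatment group against a control with family-wise error
#' control, as used for antagonist-vs-agonist-only comparisons of Emax,
#' EC50 and onset values. The omnibus test is a one-way ANOVA; adjusted
#' p-values come from the multivariate-t distribution of the Dunnett
#' contrasts (via \pkg{multcomp}). The multivariate-t integration is
#' randomized quasi-Monte Carlo, so a seed argument makes the result
#' deterministic.
#'
#' @param data Data frame with columns `group` and `value` (replicate-level
#'   observations, e.g. per-replicate peaks or onset slopes).
#' @param control_label Level of `group` serving as control.
#' @param alpha Family-wise error rate (default 0.05).
#' @param seed Integer seed for the multivariate-t integration.
#' @return An object of class `dunnett_result`: list with `comparisons`
#'   (data frame: `label`, `diff`, `se`, `t`, `p_adj`, `significant`),
#'   `alpha`, `n_comparisons`, `f_statistic`, `f_p_value`.
#' @export
dunnett_anova <- function(data, control_label, alpha = 0.05, seed = 1L) {
  stopifnot(is.data.frame(data), all(c("group", "value") %in% names(data)))
  data$group <- as.character(data$group)
  if (!control_label %in% data$group) {
    stop("control '", control_label, "' not found in `group`", call. = FALSE)
  }
  lv <- unique(data$group)
  if (length(lv) < 2) stop("need >= 2 groups including the control", call. = FALSE)
  cnt <- table(data$group)
  if (any(cnt < 2)) stop("need >= 2 replicates per group", call. = FALSE)
  wvar <- tapply(data$value, data$group, stats::var)
  if (all(wvar < .Machine$double.eps)) {
    stop("zero within-group variance in every group", call. = FALSE)
  }
  data$group <- factor(data$group, levels = c(control_label, setdiff(lv, control_label)))
  fit <- stats::aov(value ~ group, data = data)
  fsum <- summary(fit)[[1]]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  glht <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
  sm <- summary(glht)
  labels <- sub(paste0(" - ", control_label, "$"), "", names(sm$test$coefficients))
  comparisons <- data.frame(
    label = labels,
    diff = as.numeric(sm$test$coefficients),
    se = as.numeric(sm$test$sigma),
    t = as.numeric(sm$test$tstat),
    p_adj = pmin(pmax(as.numeric(sm$test$pvalues), 0), 1),
    stringsAsFactors = FALSE
  )
  comparisons$significant <- comparisons$p_adj < alpha
  structure(
    list(comparisons = comparisons, alpha = alpha,
         n_comparisons = nrow(comparisons),
         f_statistic = fsum[["F value"]][1], f_p_value = fsum[["Pr(>F)"]][1]),
    class = "dunnett_result"
  )
}

#' @export
print.dunnett_result <- function(x, ...) {
  cat(sprintf("<dunnett_result> %d comparison(s) vs control, alpha = %g, F = %.3g (p = %.3g)\n",
              x$n_comparisons, x$alpha, x$f_statistic, x$f_p_value))
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}

#' Classify antagonism as surmountable or (partially) insurmountable
#'
#' Rule applied to normalized concentration-response fits: an antagonist
#' condition is *surmountable* when its Emax reduction versus the control
#' is not statistically significant; *partially insurmountable* when the
#' reduction is significant but the normalized Emax remains >= 50% of
#' control; and *insurmountable* when significant with normalized
#' Emax < 50%. Significance comes from a [dunnett_anova()] on
#' per-replicate peak values.
#'
#' @param control_fit The agonist-only `conc_response_fit` (normalized).
#' @param antagonist_fits Named list of normalized `conc_response_fit`
#'   objects, names matching Dunnett comparison labels.
#' @param dunnett A `dunnett_result` with one comparison per antagonist
#'   condition.
#' @return Data frame with columns `label`, `emax_pct`, `p_adj`,
#'   `classification`.
#' @export
classify_surmountability <- function(control_fit, antagonist_fits, dunnett) {
  stopifnot(inherits(control_fit, "conc_response_fit"),
            inherits(dunnett, "dunnett_result"))
  if (!isTRUE(control_fit$normalized)) {
    stop("fits must be normalized to the control maximum", call. = FALSE)
  }
  labels <- names(antagonist_fits)
  if (is.null(labels) || !all(labels %in% dunnett$comparisons$label)) {
    stop("every antagonist fit needs a matching Dunnett comparison", call. = FALSE)
  }
  rows <- lapply(labels, function(lb) {
    ft <- antagonist_fits[[lb]]
    stopifnot(inherits(ft, "conc_response_fit"))
    p <- dunnett$comparisons$p_adj[dunnett$comparisons$label == lb][1]
    sig <- p < dunnett$alpha
    cls <- if (!sig) {
      "surmountable"
    } else if (ft$emax >= 50) {
      "partially insurmountable"
    } else {
      "insurmountable"
    }
    data.frame(label = lb, emax_pct = ft$emax, p_adj = p,
               classification = cls, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
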