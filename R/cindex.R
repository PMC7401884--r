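# Fixed-horizon concordance index for competing risks. A pair (i, j) is
# comparable at horizon tau if subject i died of the cause of interest at
# T_i <= tau and subject j is known to have been event-free for that cause at
# T_i: either j's time exceeds T_i, or j had a competing event at or before
# T_i (a competing event precludes the cause of interest at every later
# time). Subjects censored at or before T_i are not comparable with i. The
# pair is concordant when the predicted risk of i exceeds that of j; tied
# risks count one half. No inverse-probability-of-censoring weighting is
# applied.

#' Competing-risks concordance index at a fixed horizon
#'
#' @param risk per-subject predicted absolute risk of the cause of interest
#'   at `tau` (any scale: only the ranking matters).
#' @param time follow-up times (years).
#' @param event event factor as in [event_levels()].
#' @param tau horizon (years, positive).
#' @param cause cause of interest.
#' @return object of class `cindex_result` with the C-index, the horizon and
#'   the counts of comparable / concordant / tied pairs.
#' @export
cr_cindex <- function(risk, time, event, tau,
                      cause = "metastatic_death") {
  stopifnot(length(risk) == length(time), length(time) == length(event),
            tau > 0)
  cause <- match.arg(cause, event_levels()[2:3])
  competing <- setdiff(event_levels()[2:3], cause)
  is_case <- event == cause & time <= tau
  is_comp <- event == competing
  conc <- tied <- comp <- 0
  for (i in which(is_case)) {
    ok <- (time > time[i]) | (is_comp & time <= time[i])
    ok[i] <- FALSE
    comp <- comp + sum(ok)
    conc <- conc + sum(risk[i] > risk[ok])
    tied <- tied + sum(risk[i] == risk[ok])
  }
  if (comp == 0) stop("no comparable pairs at tau = ", tau)
  structure(list(tau = tau, cindex = (conc + tied / 2) / comp,
                 comparable = comp, concordant = conc, tied = tied,
                 cause = cause, lower = NA_real_, upper = NA_real_),
            class = "cindex_result")
}

#' @export
print.cindex_result <- function(x, ...) {
  cat(sprintf("C-index (%s) at %g y: %.3f", x$cause, x$tau, x$cindex))
  if (is.finite(x$lower))
    cat(sprintf(" (95%% CI %.3f, %.3f)", x$lower, x$upper))
  cat("\n  pairs: ", x$comparable, " comparable, ", x$concordant,
      " concordant, ", x$tied, " tied\n", sep = "")
  invisible(x)
}

# model-based risk scores: each subject's predicted absolute risk at tau is
# the metastatic CIF of their group (LBTD bin, optionally x C3S) evaluated on
# `fit_cohort`; subjects whose group is empty in the fitting data get risk 0
.group_risks <- function(eval_bin, eval_c3s, fit_time, fit_status, fit_bin,
                         fit_c3s, tau, by_c3s) {
  if (by_c3s) {
    gf <- .group_index(fit_bin, fit_c3s)
    ge <- .group_index(eval_bin, eval_c3s)
  } else {
    gf <- .group_index(fit_bin)
    ge <- .group_index(eval_bin)
  }
  cif <- .group_cif_at(fit_time, fit_status, gf$idx, gf$n, tau)
  cif[ge$idx, 1]
}

#' Bootstrap C-index for the group-based prognostic models
#'
#' Risk scores are the pooled group cumulative incidences at each horizon
#' (LBTD-only groups, or LBTD x C3S groups with missing C3S completed by
#' multiple imputation). Point estimates pool the per-dataset C-indices;
#' percentile confidence intervals pool all `M * B` subject-level bootstrap
#' replicates, re-estimating the group risks within each resample. Resamples
#' with no comparable pairs are skipped and counted.
#'
#' @param cohort a `cohort`.
#' @param taus horizons (years).
#' @param config an [mi_config()].
#' @param by_c3s use the LBTD x C3S model (`TRUE`) or LBTD-only (`FALSE`).
#' @param ensemble optional precomputed `mi_ensemble`.
#' @param cause cause of interest.
#' @return data.frame with one row per horizon: `tau`, `cindex`, `lower`,
#'   `upper`; attribute `n_skipped` counts degenerate resamples.
#' @export
bootstrap_cindex <- function(cohort, taus = c(2, 5, 10),
                             config = mi_config(), by_c3s = TRUE,
                             ensemble = NULL, cause = "metastatic_death") {
  stopifnot(inherits(cohort, "cohort"))
  time <- cohort$time
  status <- .status_code(cohort$event)
  bin <- cohort$lbtd_bin
  need_mi <- by_c3s && any(cohort$c3s == "missing")
  if (need_mi && is.null(ensemble))
    ensemble <- impute_c3s(cohort, config = config)
  M <- if (need_mi) ensemble$M else 1L
  c3s_col <- function(i) if (need_mi) ensemble$c3s[, i] else
    as.character(cohort$c3s)

  n <- nrow(cohort)
  skipped <- 0L
  out <- NULL
  for (tau in taus) {
    pts <- numeric(M)
    boot_vals <- rep(NA_real_, M * config$B)
    set.seed(config$seed + 7L + round(tau))
    for (i in seq_len(M)) {
      c3s <- c3s_col(i)
      risks <- .group_risks(bin, c3s, time, status, bin, c3s, tau, by_c3s)
      pts[i] <- cr_cindex(risks, time, cohort$event, tau, cause)$cindex
      for (b in seq_len(config$B)) {
        idx <- sample.int(n, n, replace = TRUE)
        rb <- .group_risks(bin[idx], c3s[idx], time[idx], status[idx],
                           bin[idx], c3s[idx], tau, by_c3s)
        cb <- tryCatch(
          cr_cindex(rb, time[idx], cohort$event[idx], tau, cause)$cindex,
          error = function(e) NA_real_)
        if (is.na(cb)) skipped <- skipped + 1L
        boot_vals[(i - 1L) * config$B + b] <- cb
      }
    }
    alpha <- (1 - config$ci_level) / 2
    qs <- quantile(boot_vals, c(alpha, 1 - alpha), na.rm = TRUE,
                   names = FALSE)
    out <- rbind(out, data.frame(tau = tau, cindex = mean(pts),
                                 lower = qs[1], upper = qs[2]))
  }
  attr(out, "n_skipped") <- skipped
  out
}
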