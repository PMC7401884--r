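# Nonparametric estimation core. The group-wise absolute risk of metastatic
# death is the Aalen-Johansen estimator
#
#   F_k(t) = sum_{u <= t} S_k(u-) * dN_k(u) / Y_k(u)
#
# where S_k is the group's own all-cause Kaplan-Meier survival (left limit),
# Y_k the at-risk count and dN_k the metastatic death count at u. No
# independence assumption is made about the competing other-cause risk.
# Ties: deaths of both causes at the same time share the same at-risk set and
# left-limit survival; censorings at a death time are processed after the
# deaths (at-risk counts include every subject with time >= u).

# counting-process summary on one group: unique times with at-risk counts and
# per-cause death counts; status is 0 censored / 1 metastatic / 2 other
.cr_counts <- function(time, status) {
  n <- length(time)
  o <- order(time)
  t_s <- time[o]; s_s <- status[o]
  ut <- unique(t_s)
  idx <- findInterval(t_s, ut)
  n_at <- tabulate(idx, length(ut))
  Y <- n - c(0, cumsum(n_at))[seq_along(ut)]
  d1 <- tabulate(idx[s_s == 1L], length(ut))
  d2 <- tabulate(idx[s_s == 2L], length(ut))
  keep <- (d1 + d2) > 0
  list(times = ut[keep], Y = Y[keep], d1 = d1[keep], d2 = d2[keep], n = n)
}

# full Aalen-Johansen solution for one group: KM survival plus both CIFs on
# the death-time grid
.aj_core <- function(time, status) {
  cc <- .cr_counts(time, status)
  dany <- cc$d1 + cc$d2
  surv <- cumprod(1 - dany / cc$Y)
  s_left <- c(1, surv[-length(surv)])
  if (!length(cc$times)) s_left <- numeric(0)
  list(times = cc$times, Y = cc$Y, d1 = cc$d1, d2 = cc$d2,
       surv = surv, s_left = s_left,
       F1 = cumsum(s_left * cc$d1 / cc$Y),
       F2 = cumsum(s_left * cc$d2 / cc$Y), n = cc$n)
}

# right-continuous step lookup: value of a step function with jumps at
# `times` to `values`, 0 (or `init`) before the first jump
.step_at <- function(times, values, t, init = 0) {
  i <- findInterval(t, times)
  c(init, values)[i + 1L]
}

#' All-cause Kaplan-Meier survival for a group
#'
#' Product-limit estimate treating any-cause death as the event. The returned
#' object carries the jump times, survival values and at-risk counts; use
#' [eval_surv()] for right-continuous lookup and its `left = TRUE` form for
#' the left limit S(t-).
#'
#' @param time follow-up times (years), or a `cohort`.
#' @param event event factor as in [event_levels()] (ignored when `time` is a
#'   cohort).
#' @param group optional group key stored on the curve.
#' @return object of class `survival_curve`.
#' @export
km_all_cause <- function(time, event = NULL, group = NULL) {
  if (inherits(time, "cohort")) { event <- time$event; time <- time$time }
  if (!length(time)) stop("empty group")
  core <- .aj_core(time, .status_code(event))
  structure(list(times = core$times, surv = core$surv, n_risk = core$Y,
                 n = core$n, group = group),
            class = "survival_curve")
}

#' Evaluate a survival curve
#'
#' @param curve a `survival_curve`.
#' @param t time(s).
#' @param left if `TRUE`, return the left limit S(t-).
#' @return survival probabilities.
#' @export
eval_surv <- function(curve, t, left = FALSE) {
  if (left) {
    i <- findInterval(t, curve$times, left.open = TRUE)
    return(c(1, curve$surv)[i + 1L])
  }
  .step_at(curve$times, curve$surv, t, init = 1)
}

#' Aalen-Johansen cumulative incidence for one cause in one group
#'
#' @param time follow-up times (years), or a `cohort` (then `event` is taken
#'   from it).
#' @param event event factor as in [event_levels()].
#' @param cause `"metastatic_death"` or `"other_death"`.
#' @param group optional group key stored on the curve.
#' @return object of class `cif_curve` with fields `times`, `cif`, `cause`,
#'   `group`, plus the companion all-cause survival values.
#' @export
aalen_cif <- function(time, event = NULL, cause = "metastatic_death",
                      group = NULL) {
  if (inherits(time, "cohort")) { event <- time$event; time <- time$time }
  if (!length(time)) stop("empty group")
  cause <- match.arg(cause, event_levels()[2:3])
  core <- .aj_core(time, .status_code(event))
  cif <- if (cause == "metastatic_death") core$F1 else core$F2
  structure(list(times = core$times, cif = cif, surv = core$surv,
                 cause = cause, group = group, n = core$n),
            class = "cif_curve")
}

#' Evaluate a cumulative incidence curve
#'
#' Right-continuous step lookup; 0 before the first event time, last value
#' beyond the last.
#'
#' @param curve a `cif_curve`.
#' @param t nonnegative time(s).
#' @return probabilities.
#' @export
eval_cif <- function(curve, t) {
  if (any(t < 0)) stop("t must be nonnegative")
  .step_at(curve$times, curve$cif, t)
}

#' @export
print.cif_curve <- function(x, ...) {
  cat("Cumulative incidence of ", x$cause,
      if (!is.null(x$group)) paste0(" [group ", x$group, "]"), ": n = ", x$n,
      ", ", length(x$times), " event times",
      if (length(x$times)) sprintf(", F(last) = %.4f", max(x$cif)), "\n",
      sep = "")
  invisible(x)
}

#' @export
print.survival_curve <- function(x, ...) {
  cat("All-cause Kaplan-Meier", if (!is.null(x$group))
    paste0(" [group ", x$group, "]"), ": n = ", x$n, ", ",
    length(x$times), " death times\n", sep = "")
  invisible(x)
}

#' Cause-specific Nelson-Aalen hazard increments
#'
#' Increments dL(u) = dN(u)/Y(u) at the observed death times of the given
#' cause; the building block combined with the Cox other-cause model.
#'
#' @inheritParams aalen_cif
#' @return data.frame with columns `time` and `dhaz`.
#' @export
nelson_aalen_cause_specific <- function(time, event = NULL,
                                        cause = "metastatic_death") {
  if (inherits(time, "cohort")) { event <- time$event; time <- time$time }
  if (!length(time)) stop("empty group")
  cause <- match.arg(cause, event_levels()[2:3])
  cc <- .cr_counts(time, .status_code(event))
  d <- if (cause == "metastatic_death") cc$d1 else cc$d2
  keep <- d > 0
  data.frame(time = cc$times[keep], dhaz = (d / cc$Y)[keep])
}

#' Cox model for the competing risk of other-cause death
#'
#' Partial-likelihood fit of the other-cause death hazard on binary age at
#' treatment (over 80 vs not), treating metastatic deaths as censored, with
#' the Breslow baseline cumulative hazard. A monotone likelihood (no
#' other-cause events in one age stratum) is flagged and the coefficient
#' capped.
#'
#' @param cohort a `cohort`.
#' @param cap absolute bound applied to the log hazard ratio when the partial
#'   likelihood is monotone.
#' @return object of class `cox_other` with the log hazard ratio `beta`, the
#'   Breslow baseline increments (`times`, `dhaz0`) and fit diagnostics.
#' @export
fit_cox_other_cause <- function(cohort, cap = 10) {
  stopifnot(inherits(cohort, "cohort"))
  d <- as.integer(cohort$event == "other_death")
  if (!any(d == 1)) stop("no other-cause deaths: Cox model unidentifiable")
  z <- as.integer(cohort$age_bin == "gt80")
  monotone <- length(unique(z[d == 1])) < 2 || length(unique(z)) < 2
  if (monotone || all(z == z[1])) {
    warning("monotone partial likelihood: no other-cause events in one age ",
            "stratum; coefficient capped", call. = FALSE)
    beta <- if (all(z == z[1])) 0 else
      sign(mean(z[d == 1]) - mean(z)) * cap
    ll <- c(NA_real_, NA_real_)
  } else {
    fit <- survival::coxph(survival::Surv(cohort$time, d) ~ z, ties = "breslow")
    beta <- unname(coef(fit)[1])
    if (!is.finite(beta) || abs(beta) > cap) {
      warning("coefficient capped at +/-", cap, call. = FALSE)
      beta <- sign(beta) * cap
    }
    ll <- fit$loglik
  }
  # Breslow baseline: dL0(u) = d_oth(u) / sum_{time >= u} exp(beta z),
  # via suffix sums over the time-sorted risk scores
  o <- order(cohort$time)
  ts <- cohort$time[o]
  rs <- exp(beta * z[o])
  ds <- d[o]
  suffix <- rev(cumsum(rev(rs)))
  ev_times <- unique(ts[ds == 1])
  first_ge <- findInterval(ev_times, ts, left.open = TRUE) + 1L
  denom <- suffix[first_ge]
  dN <- as.vector(tapply(ds, factor(ts, levels = ev_times), sum))
  dN <- dN[!is.na(dN)]
  structure(list(beta = beta, times = ev_times, dhaz0 = dN / denom,
                 loglik = ll, df = 1L, n = nrow(cohort),
                 n_events = sum(d)),
            class = "cox_other")
}

#' @export
print.cox_other <- function(x, ...) {
  cat("Cox other-cause model: log HR (age >80 vs <=80) = ",
      sprintf("%.4f", x$beta), " (HR ", sprintf("%.3f", exp(x$beta)),
      "), ", x$n_events, "/", x$n, " other-cause deaths\n", sep = "")
  invisible(x)
}

#' Age-specific absolute risk from a group's metastatic hazard and the Cox
#' other-cause model
#'
#' Composes the group's cause-specific metastatic hazard increments with the
#' semiparametric other-cause hazard (Breslow baseline scaled by the age
#' hazard ratio) through the product-integral: at each event time u,
#' S(u) = prod_{v <= u} (1 - dLm(v) - dLo(v | age)), and
#' F(t) = sum_{u <= t} S(u-) dLm(u). Increments are clipped so every survival
#' factor stays within [0, 1].
#'
#' @param met_hazard data.frame of metastatic hazard increments for the group
#'   (from [nelson_aalen_cause_specific()]).
#' @param cox a `cox_other` fit.
#' @param age_bin `"le80"` or `"gt80"`.
#' @return a `cif_curve` for metastatic death at the given age.
#' @export
combine_cif_with_cox <- function(met_hazard, cox, age_bin = "le80") {
  stopifnot(inherits(cox, "cox_other"), age_bin %in% c("le80", "gt80"))
  z <- as.integer(age_bin == "gt80")
  times <- sort(unique(c(met_hazard$time, cox$times)))
  dLm <- numeric(length(times))
  dLm[match(met_hazard$time, times)] <- met_hazard$dhaz
  dLo <- numeric(length(times))
  dLo[match(cox$times, times)] <- cox$dhaz0 * exp(cox$beta * z)
  f <- 1 - dLm - dLo
  f <- pmin(pmax(f, 0), 1)
  if (any(f < 0)) stop("negative survival factor")  # unreachable post-clip
  surv <- cumprod(f)
  s_left <- c(1, surv[-length(surv)])
  if (!length(times)) s_left <- numeric(0)
  structure(list(times = times, cif = cumsum(s_left * dLm), surv = surv,
                 cause = "metastatic_death",
                 group = paste0("age=", age_bin), n = cox$n),
            class = "cif_curve")
}

# --- fast internal evaluators used by the bootstrap machinery ---------------

# CIF of `cause` (1 or 2) at the horizons, for one group given as raw vectors;
# returns 0s when the group is empty (a degenerate bootstrap resample)
.cif_at <- function(time, status, horizons, cause = 1L) {
  if (!length(time)) return(rep(0, length(horizons)))
  core <- .aj_core(time, status)
  Fv <- if (cause == 1L) core$F1 else core$F2
  .step_at(core$times, Fv, horizons)
}

# group x horizon matrix of metastatic CIFs; `grp` is an integer vector in
# 1..n_groups (NA allowed -> subject ignored)
.group_cif_at <- function(time, status, grp, n_groups, horizons) {
  out <- matrix(0, n_groups, length(horizons))
  for (g in seq_len(n_groups)) {
    sel <- which(grp == g)
    out[g, ] <- .cif_at(time[sel], status[sel], horizons)
  }
  out
}

#' Export a set of curves as a tidy table
#'
#' @param curves list of `cif_curve` or `survival_curve` objects.
#' @return data.frame with columns `time`, `value`, `group`, `cause`,
#'   suitable for step-plotting cumulative incidence by group.
#' @export
curves_to_frame <- function(curves) {
  do.call(rbind, lapply(curves, function(cv) {
    if (inherits(cv, "cif_curve"))
      data.frame(time = c(0, cv$times), value = c(0, cv$cif),
                 group = cv$group %||% NA, cause = cv$cause)
    else
      data.frame(time = c(0, cv$times), value = c(1, cv$surv),
                 group = cv$group %||% NA, cause = "all")
  }))
}
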