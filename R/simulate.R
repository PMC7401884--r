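# Synthetic cohort generator. Constant (exponential) cause-specific hazards
# per LBTD bin x C3S cell for metastatic death and per age bin for other-cause
# death, so the true cumulative incidence has a closed form that serves as an
# exact oracle in recovery tests. C3S missingness depends only on the LBTD
# bin (missing at random given observed covariates), emulating cohorts where
# small tumors are less likely to be genetically typed.

#' Simulation configuration
#'
#' Defaults describe a realistic referral cohort: LBTD lognormal with median
#' 12 mm and interquartile range about 9.6-14.8 mm, truncated to 2.4-28 mm;
#' monosomy-3 prevalence rising with LBTD bin; probability that C3S is
#' untyped falling with LBTD bin (about three quarters missing overall);
#' metastatic hazard increasing with LBTD and about an order of magnitude
#' higher under monosomy 3; other-cause hazard markedly elevated over age 80;
#' independent exponential censoring plus an administrative horizon.
#'
#' @param n_subjects number of patients.
#' @param lbtd_meanlog,lbtd_sdlog,lbtd_range lognormal parameters and
#'   truncation range (mm) for largest basal tumor diameter.
#' @param age_mean,age_sd,age_range truncated-normal age distribution (years).
#' @param p_m3_by_bin probability of monosomy 3 per LBTD bin (length 6,
#'   nondecreasing).
#' @param p_missing_c3s_by_bin probability that C3S is untyped per LBTD bin
#'   (length 6, nonincreasing).
#' @param lambda_met 6 x 2 matrix of metastatic-death hazards per year,
#'   rows = LBTD bins, columns = `c("D3", "M3")`.
#' @param lambda_oth other-cause death hazards per year, named
#'   `c(le80 = , gt80 = )`.
#' @param censor_rate exponential censoring hazard per year.
#' @param admin_horizon administrative censoring time (years).
#' @param missing_outcome_shift optional logit shift applied to the C3S
#'   missingness probability of patients who died (0 = missing at random);
#'   provided for sensitivity analyses only.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_subjects = 5000,
                       lbtd_meanlog = log(12), lbtd_sdlog = 0.32,
                       lbtd_range = c(2.4, 28),
                       age_mean = 63, age_sd = 14, age_range = c(20, 100),
                       p_m3_by_bin = c(0.22, 0.29, 0.45, 0.57, 0.64, 0.79),
                       p_missing_c3s_by_bin =
                         c(0.85, 0.80, 0.77, 0.71, 0.66, 0.64),
                       lambda_met = cbind(
                         D3 = c(0.002, 0.004, 0.007, 0.012, 0.020, 0.022),
                         M3 = c(0.033, 0.050, 0.085, 0.125, 0.185, 0.230)),
                       lambda_oth = c(le80 = 0.02, gt80 = 0.09),
                       censor_rate = 0.08,
                       admin_horizon = 25,
                       missing_outcome_shift = 0) {
  cfg <- list(n_subjects = n_subjects, lbtd_meanlog = lbtd_meanlog,
              lbtd_sdlog = lbtd_sdlog, lbtd_range = lbtd_range,
              age_mean = age_mean, age_sd = age_sd, age_range = age_range,
              p_m3_by_bin = p_m3_by_bin,
              p_missing_c3s_by_bin = p_missing_c3s_by_bin,
              lambda_met = lambda_met, lambda_oth = lambda_oth,
              censor_rate = censor_rate, admin_horizon = admin_horizon,
              missing_outcome_shift = missing_outcome_shift)
  chk <- function(ok, field, msg)
    if (!ok) stop("invalid config field `", field, "`: ", msg, call. = FALSE)
  chk(is.numeric(n_subjects) && length(n_subjects) == 1 && n_subjects >= 1,
      "n_subjects", "must be a positive integer")
  chk(length(p_m3_by_bin) == 6 && all(p_m3_by_bin >= 0 & p_m3_by_bin <= 1),
      "p_m3_by_bin", "6 probabilities in [0,1]")
  chk(length(p_missing_c3s_by_bin) == 6 &&
        all(p_missing_c3s_by_bin >= 0 & p_missing_c3s_by_bin <= 1),
      "p_missing_c3s_by_bin", "6 probabilities in [0,1]")
  chk(is.matrix(lambda_met) && all(dim(lambda_met) == c(6, 2)) &&
        all(lambda_met >= 0), "lambda_met",
      "6 x 2 nonnegative hazard matrix (D3, M3)")
  chk(length(lambda_oth) == 2 && all(lambda_oth >= 0) &&
        all(c("le80", "gt80") %in% names(lambda_oth)),
      "lambda_oth", "named nonnegative hazards for le80 and gt80")
  chk(censor_rate >= 0, "censor_rate", "must be >= 0")
  chk(admin_horizon > 0, "admin_horizon", "must be positive")
  structure(cfg, class = "sim_config")
}

# truncated draws by inverse-cdf so the configured range is respected exactly
.rtrunc <- function(n, q, p, lo, hi, ...) {
  u <- runif(n, p(lo, ...), p(hi, ...))
  q(u, ...)
}

#' Probability of age over 80 under a simulation configuration
#'
#' @param config a `sim_config`.
#' @return scalar probability, used to weight the closed-form cumulative
#'   incidence when marginalizing over age.
#' @export
prob_gt80 <- function(config) {
  lo <- pnorm(config$age_range[1], config$age_mean, config$age_sd)
  hi <- pnorm(config$age_range[2], config$age_mean, config$age_sd)
  p80 <- pnorm(80, config$age_mean, config$age_sd)
  (hi - p80) / (hi - lo)
}

#' Simulate a choroidal melanoma cohort
#'
#' Each patient draws LBTD, age and true C3S; latent metastatic and
#' other-cause death times are competing exponentials with the configured
#' cause-specific hazards; the observed time is the minimum of the event
#' time, an independent exponential censoring time and the administrative
#' horizon. C3S is then masked according to the per-bin missingness
#' probabilities (true status retained in column `c3s_true`). Additional
#' covariates (sex, ciliary body involvement, extraocular spread, thickness,
#' chromosome 8q, histology) are generated as realistic correlates that do
#' not enter the hazards, for use as noise factors in selection experiments.
#' The same seed yields a bit-identical cohort.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return a `cohort` with the extra ground-truth column `c3s_true`.
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- as.integer(config$n_subjects)

  lbtd <- .rtrunc(n, qlnorm, plnorm, config$lbtd_range[1],
                  config$lbtd_range[2], meanlog = config$lbtd_meanlog,
                  sdlog = config$lbtd_sdlog)
  age <- .rtrunc(n, qnorm, pnorm, config$age_range[1], config$age_range[2],
                 mean = config$age_mean, sd = config$age_sd)
  bin <- as.integer(bin_lbtd(lbtd))
  m3 <- rbinom(n, 1, config$p_m3_by_bin[bin])
  agebin <- ifelse(age > 80, "gt80", "le80")

  lam_m <- config$lambda_met[cbind(bin, m3 + 1L)]
  lam_o <- config$lambda_oth[agebin]
  t_met <- ifelse(lam_m > 0, rexp(n, pmax(lam_m, 1e-300)), Inf)
  t_oth <- ifelse(lam_o > 0, rexp(n, pmax(lam_o, 1e-300)), Inf)
  t_cen <- if (config$censor_rate > 0) rexp(n, config$censor_rate) else
    rep(Inf, n)
  t_cen <- pmin(t_cen, config$admin_horizon)
  t_ev <- pmin(t_met, t_oth)
  time <- pmin(t_ev, t_cen)
  event <- ifelse(t_ev > t_cen, "alive",
           ifelse(t_met <= t_oth, "definite_metastatic", "non_cancerous"))

  p_miss <- config$p_missing_c3s_by_bin[bin]
  if (config$missing_outcome_shift != 0) {
    dead <- event != "alive"
    p_miss[dead] <- plogis(qlogis(pmin(pmax(p_miss[dead], 1e-6), 1 - 1e-6)) +
                             config$missing_outcome_shift)
  }
  miss <- rbinom(n, 1, p_miss) == 1
  c3s_true <- ifelse(m3 == 1, "M3", "D3")
  c3s <- ifelse(miss, NA, c3s_true)

  # correlates that never enter the hazards
  sex <- ifelse(runif(n) < 0.5, "female", "male")
  ciliary <- runif(n) < 0.12
  extra <- runif(n) < 0.03
  thick <- pmin(pmax(0.3 * lbtd * exp(rnorm(n, 0, 0.3)), 0.5), 16)
  chr8q <- ifelse(runif(n) < ifelse(m3 == 1, 0.65, 0.20), "gain", "normal")
  chr8q[runif(n) < 0.5] <- NA  # genetic typing incomplete
  histo_known <- runif(n) < 0.4
  closed_loops <- ifelse(histo_known, runif(n) < (0.25 + 0.2 * m3), NA)
  epithelioid <- ifelse(histo_known, runif(n) < (0.2 + 0.25 * m3), NA)
  mitotic <- ifelse(histo_known, rpois(n, 2 + 2 * m3), NA)

  df <- data.frame(
    id = sprintf("sim%06d", seq_len(n)),
    lbtd_mm = round(lbtd, 1), age_years = round(age, 1), sex = sex,
    c3s = c3s, chr8q = chr8q, ciliary_body = ciliary, extraocular = extra,
    thickness_mm = round(thick, 1), closed_loops = closed_loops,
    epithelioid = epithelioid, mitotic_count = mitotic,
    followup_years = pmax(round(time, 4), 1e-4),
    outcome = event, c3s_true = c3s_true, stringsAsFactors = FALSE)
  suppressWarnings(as_cohort(df, source = sprintf("simulate(seed=%d)", seed)))
}

#' Closed-form true cumulative incidence under a simulation configuration
#'
#' With constant cause-specific hazards lambda_met (by LBTD bin and C3S) and
#' lambda_oth (by age bin), the cumulative incidence of cause 1 is
#' `F1(t) = lm/(lm+lo) * (1 - exp(-(lm+lo) t))`, independent of the
#' (non-informative) censoring. `age_bin = "marginal"` mixes the two age
#' strata with weight [prob_gt80()].
#'
#' @param config a [sim_config()].
#' @param lbtd_bin bin index 1-6 or a label from [lbtd_levels()].
#' @param c3s `"D3"` or `"M3"`.
#' @param age_bin `"le80"`, `"gt80"` or `"marginal"`.
#' @param t nonnegative time(s), years.
#' @param cause `"metastatic_death"` or `"other_death"`.
#' @return vector of probabilities.
#' @export
true_cif <- function(config, lbtd_bin, c3s = "D3", age_bin = "marginal",
                     t = c(2, 5, 10), cause = "metastatic_death") {
  stopifnot(inherits(config, "sim_config"))
  if (any(t < 0)) stop("t must be nonnegative")
  if (is.character(lbtd_bin)) lbtd_bin <- match(lbtd_bin, lbtd_levels())
  stopifnot(lbtd_bin %in% 1:6, c3s %in% c("D3", "M3"))
  lm <- unname(config$lambda_met[lbtd_bin, c3s])
  one_age <- function(ab) {
    lo <- config$lambda_oth[[ab]]
    tot <- lm + lo
    lam <- if (cause == "metastatic_death") lm else lo
    if (tot == 0) rep(0, length(t)) else lam / tot * (1 - exp(-tot * t))
  }
  switch(age_bin,
         le80 = one_age("le80"),
         gt80 = one_age("gt80"),
         marginal = {
           w <- prob_gt80(config)
           (1 - w) * one_age("le80") + w * one_age("gt80")
         },
         stop("age_bin must be 'le80', 'gt80' or 'marginal'"))
}
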