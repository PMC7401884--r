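test_that("all-cause Kaplan-Meier matches the hand product-limit", {
  ch <- toy_cohort(c(1, 2, 3, 4),
                   c("metastatic_death", "other_death", "censored",
                     "metastatic_death"))
  km <- km_all_cause(ch)
  expect_equal(km$times, c(1, 2, 4))
  expect_equal(km$surv, c(3 / 4, 1 / 2, 0))
  expect_equal(eval_surv(km, 3), 1 / 2)
  expect_equal(eval_surv(km, 2, left = TRUE), 3 / 4)  # S(t-)
  expect_equal(eval_surv(km, 0.5), 1)
  # no deaths at all
  km0 <- km_all_cause(toy_cohort(c(1, 2), c("censored", "censored")))
  expect_equal(eval_surv(km0, 100), 1)
  expect_error(km_all_cause(numeric(0), factor(character())), "empty")
})

test_that("Aalen-Johansen reproduces the worked four-subject example", {
  ch <- toy_cohort(c(1, 2, 3, 4),
                   c("metastatic_death", "other_death", "censored",
                     "metastatic_death"))
  f1 <- aalen_cif(ch, cause = "metastatic_death")
  f2 <- aalen_cif(ch, cause = "other_death")
  expect_equal(eval_cif(f1, 1), 0.25)
  expect_equal(eval_cif(f1, 3), 0.25)
  expect_equal(eval_cif(f1, 4), 0.75)
  expect_equal(eval_cif(f2, 2), 0.25)
  expect_equal(eval_cif(f1, 0), 0)
  expect_equal(eval_cif(f1, 99), 0.75)  # flat beyond last event
  inc <- nelson_aalen_cause_specific(ch, cause = "metastatic_death")
  expect_equal(inc$time, c(1, 4))
  expect_equal(inc$dhaz, c(1 / 4, 1))
})

test_that("with no competing events the CIF is one minus the single-cause KM", {
  ch <- toy_cohort(c(1, 2, 3, 5, 6),
                   c("metastatic_death", "censored", "metastatic_death",
                     "censored", "metastatic_death"))
  f1 <- aalen_cif(ch)
  km <- km_all_cause(ch)
  expect_equal(eval_cif(f1, km$times), 1 - km$surv)
  # zero events of a cause gives an all-zero curve
  f2 <- aalen_cif(ch, cause = "other_death")
  expect_equal(eval_cif(f2, c(1, 10)), c(0, 0))
})

test_that("estimator equals the event-loop oracle on random small cohorts", {
  set.seed(11)
  for (rep in 1:60) {
    n <- sample(2:8, 1)
    time <- sample(1:5, n, replace = TRUE)  # ties included
    status <- sample(0:2, n, replace = TRUE)
    ev <- status_to_event(status)
    for (cause in 1:2) {
      est <- aalen_cif(time, ev, event_levels()[cause + 1])
      orc <- aj_oracle(time, status, cause)
      expect_equal(eval_cif(est, 0:6), orc$at(0:6), tolerance = 1e-14)
    }
  }
})

test_that("conservation: sum of CIFs plus KM survival is exactly one", {
  set.seed(12)
  time <- round(rexp(300, 0.2), 2)
  status <- sample(0:2, 300, replace = TRUE, prob = c(0.3, 0.4, 0.3))
  ev <- status_to_event(status)
  f1 <- aalen_cif(time, ev, "metastatic_death")
  f2 <- aalen_cif(time, ev, "other_death")
  km <- km_all_cause(time, ev)
  at <- km$times
  tot <- eval_cif(f1, at) + eval_cif(f2, at) + eval_surv(km, at)
  expect_equal(tot, rep(1, length(at)), tolerance = 1e-12)
  expect_true(all(diff(eval_cif(f1, sort(at))) >= 0))
  expect_true(all(eval_cif(f1, at) <= 1 - eval_surv(km, at) + 1e-12))
})

test_that("estimator agrees with cmprsk::cuminc on a simulated cohort", {
  ch <- simulate_cohort(sim_config(n_subjects = 800), seed = 21)
  cu <- cmprsk::cuminc(ch$time, ifelse(ch$event == "metastatic_death", 1,
                                       ifelse(ch$event == "other_death", 2,
                                              0)), cencode = 0)
  f1 <- aalen_cif(ch)
  ts <- c(2, 5, 10)
  ours <- eval_cif(f1, ts)
  theirs <- cmprsk::timepoints(cu["1 1"], ts)$est[1, ]
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-8)
})

test_that("Cox other-cause fit recovers null and twofold age hazards", {
  cfg0 <- sim_config(n_subjects = 2000,
                     lambda_oth = c(le80 = 0.04, gt80 = 0.04))
  ch0 <- simulate_cohort(cfg0, seed = 31)
  fit0 <- fit_cox_other_cause(ch0)
  se0 <- 1 / sqrt(sum(ch0$event == "other_death") *
                    mean(ch0$age_bin == "gt80"))
  expect_lt(abs(fit0$beta), 3 * se0)

  cfg2 <- sim_config(n_subjects = 5000,
                     lambda_oth = c(le80 = 0.04, gt80 = 0.08))
  ch2 <- simulate_cohort(cfg2, seed = 32)
  fit2 <- fit_cox_other_cause(ch2)
  d_gt <- sum(ch2$event == "other_death" & ch2$age_bin == "gt80")
  expect_lt(abs(fit2$beta - log(2)), 3 / sqrt(d_gt))
  expect_true(all(diff(cumsum(fit2$dhaz0)) >= 0))
  # no metastatic deaths: identical to the all-deaths Cox fit
  cfg1 <- sim_config(n_subjects = 1000, lambda_met = matrix(0, 6, 2,
    dimnames = list(NULL, c("D3", "M3"))))
  ch1 <- simulate_cohort(cfg1, seed = 33)
  ref <- survival::coxph(
    survival::Surv(time, event != "censored") ~ I(age_bin == "gt80"),
    data = as.data.frame(ch1), ties = "breslow")
  expect_equal(fit_cox_other_cause(ch1)$beta, unname(coef(ref)),
               tolerance = 1e-8)
  expect_error(fit_cox_other_cause(ch1[ch1$event == "censored", ]),
               "no other-cause")
})

test_that("composing a group's hazard with a null Cox model reduces to its own CIF", {
  ch <- simulate_cohort(sim_config(n_subjects = 600,
                                   lambda_oth = c(le80 = 0.05, gt80 = 0.05)),
                        seed = 41)
  grp <- ch[ch$lbtd_bin == "12.1-14.0", ]
  # all ages pooled, beta forced to 0: baseline is the group's own hazard
  cox <- fit_cox_other_cause(grp)
  cox0 <- cox
  cox0$beta <- 0
  cc <- crprog:::.cr_counts(grp$time, crprog:::.status_code(grp$event))
  cox0$times <- cc$times[cc$d2 > 0]
  cox0$dhaz0 <- (cc$d2 / cc$Y)[cc$d2 > 0]
  mh <- nelson_aalen_cause_specific(grp)
  comb <- combine_cif_with_cox(mh, cox0, "le80")
  own <- aalen_cif(grp)
  ts <- c(1, 2, 5, 10, 20)
  expect_equal(eval_cif(comb, ts), eval_cif(own, ts), tolerance = 1e-12)
})

test_that("a higher other-cause hazard lowers the metastatic risk pointwise", {
  ch <- simulate_cohort(sim_config(n_subjects = 3000), seed = 42)
  cox <- fit_cox_other_cause(ch)
  expect_gt(cox$beta, 0)  # over-80 other-cause hazard is elevated
  grp <- ch[ch$lbtd_bin == "14.1-16.0" & ch$c3s_true == "M3", ]
  mh <- nelson_aalen_cause_specific(grp)
  young <- combine_cif_with_cox(mh, cox, "le80")
  old <- combine_cif_with_cox(mh, cox, "gt80")
  ts <- c(2, 5, 10)
  expect_true(all(eval_cif(old, ts) <= eval_cif(young, ts)))
  expect_true(all(diff(eval_cif(young, sort(c(ts, 15)))) >= 0))
})

test_that("two-event toy composition matches the hand product-integral", {
  # group hazard: metastatic jump 1/2 at t=1; other-cause baseline jump 1/4
  # at t=2 with log HR log(2) for the old
  mh <- data.frame(time = c(1, 3), dhaz = c(0.5, 0.25))
  cox <- structure(list(beta = log(2), times = 2, dhaz0 = 0.25,
                        loglik = c(NA, NA), df = 1L, n = 10, n_events = 1),
                   class = "cox_other")
  f_young <- combine_cif_with_cox(mh, cox, "le80")
  # S(1-)=1, F(1)=0.5; S(2-)=0.5; S(3-)=0.5*(1-0.25); F(3)=0.5+0.375*0.25
  expect_equal(eval_cif(f_young, c(1, 2, 3)),
               c(0.5, 0.5, 0.5 + 0.375 * 0.25))
  f_old <- combine_cif_with_cox(mh, cox, "gt80")
  expect_equal(eval_cif(f_old, 3), 0.5 + 0.5 * (1 - 0.5) * 0.25)
})

test_that("tidy export mirrors curve contents", {
  ch <- toy_cohort(c(1, 2), c("metastatic_death", "censored"))
  df <- curves_to_frame(list(aalen_cif(ch, group = "g1"), km_all_cause(ch)))
  expect_equal(df$value[df$cause == "metastatic_death"], c(0, 0.5))
  expect_equal(df$value[df$cause == "all"], c(1, 0.5))
})
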