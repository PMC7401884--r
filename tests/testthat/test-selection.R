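test_that("rescaled AIC is the LR chi-square minus twice the df cost", {
  full <- structure(list(loglik = -100, df = 3L, factors = c("a", "b"),
                         n = 500), class = "csc_fit")
  red <- structure(list(loglik = -105, df = 2L, factors = "a", n = 500),
                   class = "csc_fit")
  expect_equal(rescaled_aic(full, red), 10 - 2)
  red$loglik <- -100.5
  expect_equal(rescaled_aic(full, red), 1 - 2)  # overfitting signal
  bad <- red; bad$factors <- "z"
  expect_error(rescaled_aic(full, bad), "not nested")
  bad2 <- red; bad2$n <- 400
  expect_error(rescaled_aic(full, bad2), "different rows")
})

test_that("cause-specific Cox recovers a simulated hazard ratio", {
  # strong C3S effect; other-cause deaths treated as censoring
  ch <- simulate_cohort(sim_config(n_subjects = 3000), seed = 61)
  fit <- fit_cause_specific_cox(ch, "c3s_true", "metastatic_death")
  # generating model: M3 multiplies the metastatic hazard ~10-16x per bin;
  # the marginal coefficient must at least be large and positive
  expect_gt(unname(fit$coef[1]), 1)
  null <- fit_cause_specific_cox(ch, character(), "metastatic_death",
                                 use_rows = fit$rows)
  expect_equal(null$df, 0L)
  expect_gt(rescaled_aic(fit, null), 50)
  expect_error(fit_cause_specific_cox(ch, "nonexistent"), "nonexistent")
  expect_error(fit_cause_specific_cox(
    ch[ch$event != "metastatic_death", ], "sex"), "no events")
})

test_that("constant and duplicated factors are dropped with a warning", {
  ch <- simulate_cohort(sim_config(n_subjects = 800), seed = 62)
  ch$const <- 1
  expect_warning(fit <- fit_cause_specific_cox(ch, c("sex", "const")),
                 "constant")
  expect_equal(fit$factors, "sex")
  ch$sex2 <- ch$sex
  expect_warning(fit2 <- fit_cause_specific_cox(ch, c("sex", "sex2")),
                 "collinear")
  expect_equal(fit2$df, 1L)
})

test_that("a pure noise factor has rescaled AIC near its chi-square mean of -1", {
  set.seed(63)
  cfg <- sim_config(n_subjects = 2000)
  vals <- vapply(1:60, function(r) {
    ch <- simulate_cohort(cfg, seed = 6300 + r)
    full <- fit_cause_specific_cox(ch, "sex", "metastatic_death")
    null <- fit_cause_specific_cox(ch, character(), use_rows = full$rows)
    rescaled_aic(full, null)
  }, 0)
  # E[chi2_1] - 2 = -1; MC error of the mean of 60 chi2 draws ~ sqrt(2/60)
  expect_lt(abs(mean(vals) + 1), 4 * sqrt(2 / 60))
})

test_that("backward selection keeps the informative factors and ranks them first", {
  cfg <- sim_config(n_subjects = 5000, p_missing_c3s_by_bin = rep(0, 6))
  ch <- simulate_cohort(cfg, seed = 64)
  factors <- c("lbtd_bin", "c3s", "sex", "ciliary_body", "extraocular")
  rk <- backward_select(ch, factors)
  expect_s3_class(rk, "factor_ranking")
  expect_setequal(rk$factor, factors)
  expect_true(all(diff(rk$aic) <= 0))  # sorted descending
  expect_setequal(rk$factor[1:2], c("lbtd_bin", "c3s"))
  expect_true(all(rk$retained[1:2]))
  # single-deletion mode ranks the same two first here
  rk1 <- backward_select(ch, factors, method = "single")
  expect_setequal(rk1$factor[1:2], c("lbtd_bin", "c3s"))
  # determinism: no randomness in selection
  expect_identical(as.data.frame(backward_select(ch, factors)),
                   as.data.frame(rk))
})

test_that("all-noise candidate sets are (almost always) emptied out", {
  # each noise factor survives a deletion step only when its LR chi-square
  # exceeds twice its df, which happens with probability ~0.16 under the
  # null; across replicates the retained fraction must stay near that rate
  cfg <- sim_config(n_subjects = 2000)
  retained <- vapply(1:10, function(r) {
    ch <- simulate_cohort(cfg, seed = 6500 + r)
    rk <- backward_select(ch, c("sex", "ciliary_body", "extraocular"))
    sum(rk$retained)
  }, 0)
  expect_lt(mean(retained) / 3, 0.3)
  expect_true(any(retained == 0))
})

test_that("selection under missing C3S averages rankings over imputations", {
  ch <- simulate_cohort(sim_config(n_subjects = 2500), seed = 66)
  ens <- impute_c3s(ch, config = mi_config(M = 3, B = 1, seed = 2))
  rk <- backward_select(ch, c("lbtd_bin", "c3s", "sex"), ensemble = ens)
  expect_setequal(rk$factor[1:2], c("lbtd_bin", "c3s"))
  expect_equal(attr(rk, "averaged"), 3)
})
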