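test_that("imputation never alters observed C3S and is seed-reproducible", {
  ch <- simulate_cohort(sim_config(n_subjects = 1500), seed = 51)
  cfg <- mi_config(M = 7, B = 10, seed = 3)
  ens <- impute_c3s(ch, config = cfg)
  obs <- ch$c3s != "missing"
  for (i in seq_len(ens$M)) {
    comp <- completed_cohort(ens, i)
    expect_equal(as.character(comp$c3s[obs]), as.character(ch$c3s[obs]))
    expect_false(any(comp$c3s == "missing"))
  }
  ens2 <- impute_c3s(ch, config = cfg)
  expect_identical(ens$c3s, ens2$c3s)
  # different seeds differ somewhere among the imputed values
  ens3 <- impute_c3s(ch, config = mi_config(M = 7, B = 10, seed = 4))
  expect_false(identical(ens$c3s, ens3$c3s))
})

test_that("a fully observed cohort imputes to M identical copies", {
  cfg <- sim_config(n_subjects = 300, p_missing_c3s_by_bin = rep(0, 6))
  ch <- simulate_cohort(cfg, seed = 52)
  ens <- impute_c3s(ch, config = mi_config(M = 4, B = 10, seed = 1))
  for (i in 2:4) expect_identical(ens$c3s[, i], ens$c3s[, 1])
  expect_identical(ens$c3s[, 1], as.character(ch$c3s))
})

test_that("the imputation model recovers a rising monosomy gradient", {
  ch <- simulate_cohort(sim_config(n_subjects = 5000), seed = 53)
  m <- fit_imputation_model(ch)
  # fitted P(M3) per bin (averaged over outcome/time covariates of complete
  # cases) should increase from the smallest to the largest tumors
  obs <- ch$c3s != "missing"
  X <- crprog:::.imp_design(ch)[obs, m$keep, drop = FALSE]
  p <- plogis(drop(X %*% m$beta))
  p_bin <- tapply(p, ch$lbtd_bin[obs], mean)
  expect_gt(p_bin[[6]], p_bin[[1]] + 0.2)
  expect_error(fit_imputation_model(
    toy_cohort(c(1, 2), c("censored", "censored"), c3s = NA)),
    "complete cases")
})

test_that("intercept-only degenerate designs still fit", {
  # single bin, single event type, constant time: everything but the
  # intercept is dropped
  ch <- toy_cohort(rep(2, 30), rep("censored", 30),
                   c3s = rep(c("D3", "M3", NA), 10))
  m <- fit_imputation_model(ch)
  expect_equal(length(m$beta), 1L)
  ens <- impute_c3s(ch, m, mi_config(M = 3, B = 5, seed = 1))
  expect_false(any(ens$c3s == "missing"))
})

test_that("pooling is the arithmetic mean and permutation-invariant", {
  expect_equal(pool_cif(c(0.2, 0.4)), 0.3)
  expect_equal(pool_cif(rep(0.37, 101)), 0.37)
  v <- runif(101)
  expect_equal(pool_cif(v), sum(v) / 101)
  expect_equal(pool_cif(v), pool_cif(rev(v)))
  m <- matrix(runif(20), 4, 5)
  expect_equal(pool_cif(m), colMeans(m))
  expect_error(pool_cif(numeric(0)), "no values")
})

test_that("MAR imputation recovers complete-data group risks", {
  base <- sim_config(n_subjects = 4000,
                     p_missing_c3s_by_bin = rep(0.4, 6))
  ch <- simulate_cohort(base, seed = 54)
  full <- ch
  full$c3s <- factor(ch$c3s_true, levels = c("D3", "M3", "missing"))
  ens <- impute_c3s(ch, config = mi_config(M = 11, B = 10, seed = 5))
  for (b in c(2, 4)) {
    for (cs in c("D3", "M3")) {
      sel_full <- full$lbtd_bin == lbtd_levels()[b] & full$c3s == cs
      f_full <- eval_cif(aalen_cif(full[sel_full, ]), 5)
      per <- vapply(seq_len(ens$M), function(i) {
        comp <- completed_cohort(ens, i)
        sel <- comp$lbtd_bin == lbtd_levels()[b] & comp$c3s == cs
        eval_cif(aalen_cif(comp[sel, ]), 5)
      }, 0)
      se <- sqrt(f_full * (1 - f_full) / sum(sel_full))
      expect_lt(abs(pool_cif(per) - f_full), 3 * se)
    }
  }
})

test_that("with no missing data the pooled CI reduces to a plain bootstrap", {
  cfg <- sim_config(n_subjects = 500, p_missing_c3s_by_bin = rep(0, 6))
  ch <- simulate_cohort(cfg, seed = 55)
  ci <- mi_bootstrap_ci(ch, mi_config(M = 1, B = 150, seed = 6),
                        horizons = 5, by_c3s = TRUE)
  expect_true(all(ci$lower >= 0 & ci$upper <= 1))
  expect_true(all(ci$lower <= ci$upper))
  # point estimates match direct estimation (no imputation involved)
  for (b in c(1, 3)) {
    sel <- ch$lbtd_bin == lbtd_levels()[b] & ch$c3s == "M3"
    direct <- eval_cif(aalen_cif(ch[sel, ]), 5)
    got <- ci$estimate[ci$group == paste0("M3:", lbtd_levels()[b])]
    expect_equal(got, direct)
  }
})

test_that("CI bounds bracket the pooled point estimate in nearly all cells", {
  ch <- simulate_cohort(sim_config(n_subjects = 1200), seed = 56)
  ci <- mi_bootstrap_ci(ch, mi_config(M = 5, B = 80, seed = 7),
                        horizons = c(2, 5, 10), by_c3s = TRUE)
  inside <- ci$estimate >= ci$lower & ci$estimate <= ci$upper
  expect_gte(mean(inside), 0.95)
  expect_true(all(ci$lower >= 0 & ci$upper <= 1))
})
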