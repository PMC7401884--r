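# Approximate Bayesian multiple imputation of missing chromosome 3 status.
# A logistic model for P(monosomy 3) given LBTD bin, event-type indicators
# and log follow-up time is fitted on complete cases; each of the M completed
# datasets draws fresh coefficients from the normal approximation to their
# posterior (mean = estimate, covariance = estimated covariance) and then
# draws each missing C3S as Bernoulli. Point estimates pool across datasets
# by the arithmetic mean; confidence intervals come from the pooled-sample
# bootstrap: B resamples within each completed dataset, all M*B estimates
# pooled into one empirical distribution whose 2.5 and 97.5 percentiles are
# the limits.

#' Multiple-imputation / bootstrap configuration
#'
#' Analysis-scale defaults are `M = 101` imputed datasets and `B = 2000`
#' bootstrap resamples per dataset; smaller profiles (e.g. `M = 11`,
#' `B = 200`) are appropriate for interactive work.
#'
#' @param M number of imputed datasets (>= 2 for genuine imputation; `M = 1`
#'   reduces the pooled bootstrap to an ordinary percentile bootstrap).
#' @param B bootstrap resamples per imputed dataset.
#' @param ci_level confidence level for percentile intervals.
#' @param seed integer seed for imputation and resampling.
#' @return object of class `mi_config`.
#' @export
mi_config <- function(M = 101, B = 2000, ci_level = 0.95, seed = 1L) {
  if (!(is.numeric(M) && M >= 1)) stop("invalid config field `M`: must be >= 1")
  if (!(is.numeric(B) && B >= 1)) stop("invalid config field `B`: must be >= 1")
  if (!(ci_level > 0 && ci_level < 1))
    stop("invalid config field `ci_level`")
  structure(list(M = as.integer(M), B = as.integer(B), ci_level = ci_level,
                 seed = as.integer(seed)), class = "mi_config")
}

# design matrix of the imputation model
.imp_design <- function(cohort) {
  df <- data.frame(
    lbtd_bin = factor(cohort$lbtd_bin, levels = lbtd_levels()),
    met = as.integer(cohort$event == "metastatic_death"),
    oth = as.integer(cohort$event == "other_death"),
    logt = log(cohort$time))
  model.matrix(~ lbtd_bin + met + oth + logt, df)
}

# minimal ridge-penalised logistic IRLS, fallback under separation
.ridge_logit <- function(X, y, lambda = 0.5, iter = 50) {
  beta <- rep(0, ncol(X))
  P <- diag(lambda, ncol(X)); P[1, 1] <- 0
  for (i in seq_len(iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-8)
    H <- crossprod(X, X * w) + P
    g <- crossprod(X, y - mu) - P %*% beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < 1e-8) break
  }
  list(beta = drop(beta), vcov = solve(H))
}

#' Fit the C3S imputation model
#'
#' Logistic regression of monosomy 3 (vs disomy 3) on LBTD bin, event-type
#' indicators and log follow-up time, fitted on patients with observed C3S.
#' Outcome information is included so that imputation is compatible with the
#' downstream survival analyses. The coefficient covariance is retained for
#' posterior draws. On separation or non-convergence a lightly
#' ridge-penalised fit is substituted with a warning.
#'
#' @param cohort a `cohort` with at least some observed C3S.
#' @return object of class `imputation_model` (coefficients, covariance,
#'   kept design columns, number of complete cases).
#' @export
fit_imputation_model <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  obs <- cohort$c3s != "missing"
  if (!any(obs)) stop("no complete cases: cannot fit imputation model")
  X <- .imp_design(cohort)[obs, , drop = FALSE]
  y <- as.integer(cohort$c3s[obs] == "M3")
  # drop constant columns (e.g. unobserved bins) to keep the fit full-rank
  keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2, function(v) var(v) > 0))
  qrX <- qr(X[, keep, drop = FALSE])
  keep[keep] <- seq_len(sum(keep)) %in% qrX$pivot[seq_len(qrX$rank)]
  Xk <- X[, keep, drop = FALSE]
  fit <- suppressWarnings(glm.fit(Xk, y, family = binomial()))
  beta <- fit$coefficients
  separated <- !fit$converged || any(!is.finite(beta)) || any(abs(beta) > 15)
  if (separated) {
    warning("separation in imputation model; using ridge-penalised fit",
            call. = FALSE)
    rf <- .ridge_logit(Xk, y)
    beta <- rf$beta; V <- rf$vcov
  } else {
    w <- fit$weights
    V <- solve(crossprod(Xk, Xk * w))
  }
  structure(list(beta = beta, vcov = V, keep = keep,
                 columns = colnames(Xk), n_complete = sum(obs)),
            class = "imputation_model")
}

#' @export
print.imputation_model <- function(x, ...) {
  cat("C3S imputation model (logistic, ", x$n_complete,
      " complete cases):\n", sep = "")
  print(round(setNames(x$beta, x$columns), 3))
  invisible(x)
}

#' Multiply impute missing chromosome 3 status
#'
#' For each of `M` datasets: coefficients are drawn from the normal
#' approximation to the posterior of the imputation model, each missing C3S
#' is drawn Bernoulli with the implied probability of monosomy 3, and
#' observed values are left untouched. Reproducible given the config seed.
#'
#' @param cohort a `cohort`.
#' @param model an `imputation_model`; fitted from `cohort` if `NULL`.
#' @param config an [mi_config()].
#' @return object of class `mi_ensemble`: the source cohort plus an
#'   `n x M` character matrix of completed C3S values.
#' @export
impute_c3s <- function(cohort, model = NULL, config = mi_config()) {
  stopifnot(inherits(cohort, "cohort"), inherits(config, "mi_config"))
  miss <- cohort$c3s == "missing"
  if (any(miss) && is.null(model)) model <- fit_imputation_model(cohort)
  M <- config$M
  c3s_mat <- matrix(as.character(cohort$c3s), nrow(cohort), M)
  if (any(miss)) {
    set.seed(config$seed)
    Xm <- .imp_design(cohort)[miss, model$keep, drop = FALSE]
    for (i in seq_len(M)) {
      b <- MASS::mvrnorm(1, model$beta, model$vcov)
      p <- plogis(drop(Xm %*% b))
      c3s_mat[miss, i] <- ifelse(rbinom(sum(miss), 1, p) == 1, "M3", "D3")
    }
  }
  structure(list(cohort = cohort, c3s = c3s_mat, M = M, model = model,
                 config = config), class = "mi_ensemble")
}

#' Extract the i-th completed cohort from an ensemble
#'
#' @param ensemble an `mi_ensemble`.
#' @param i dataset index in `1..M`.
#' @return a `cohort` with no missing C3S (unless the source itself had
#'   missing values and `M` trivially copied them, which cannot happen after
#'   [impute_c3s()]).
#' @export
completed_cohort <- function(ensemble, i) {
  stopifnot(inherits(ensemble, "mi_ensemble"), i >= 1, i <= ensemble$M)
  ch <- ensemble$cohort
  ch$c3s <- factor(ensemble$c3s[, i], levels = c("D3", "M3", "missing"))
  ch
}

#' @export
print.mi_ensemble <- function(x, ...) {
  cat("MI ensemble: M = ", x$M, " completed cohorts of ", nrow(x$cohort),
      " patients (", sum(x$cohort$c3s == "missing"),
      " originally missing C3S)\n", sep = "")
  invisible(x)
}

#' Pool per-dataset estimates
#'
#' Point estimates under multiple imputation are the arithmetic mean of the
#' per-dataset estimates.
#'
#' @param per_dataset_values numeric vector (or matrix with one row per
#'   dataset, pooled column-wise).
#' @return pooled estimate(s).
#' @export
pool_cif <- function(per_dataset_values) {
  if (!length(per_dataset_values)) stop("no values to pool")
  if (is.matrix(per_dataset_values)) colMeans(per_dataset_values)
  else mean(per_dataset_values)
}

# integer group index for each subject: by LBTD bin alone (6 groups) or by
# LBTD bin x C3S (12 groups: D3 bins 1-6, M3 bins 7-12); c3s may come from an
# imputed column
.group_index <- function(lbtd_bin, c3s = NULL) {
  b <- as.integer(lbtd_bin)
  if (is.null(c3s)) return(list(idx = b, n = 6L,
                                labels = lbtd_levels()))
  m3 <- as.character(c3s) == "M3"
  list(idx = b + 6L * as.integer(m3), n = 12L,
       labels = c(paste0("D3:", lbtd_levels()), paste0("M3:", lbtd_levels())))
}

#' Pooled-sample MI bootstrap confidence intervals for group absolute risks
#'
#' For every completed dataset, `B` bootstrap resamples of subjects (with
#' replacement) are drawn and the group-wise metastatic cumulative incidence
#' at each horizon is re-estimated; all `M * B` bootstrap values per cell are
#' pooled into one empirical distribution whose 2.5 and 97.5 percentiles (at
#' the default level) are the confidence limits. Point estimates are the
#' pooled (unresampled) per-dataset estimates. A resample in which a group is
#' empty contributes 0 (no events observable) and is counted in
#' `n_degenerate`.
#'
#' @param cohort a `cohort`.
#' @param config an [mi_config()].
#' @param horizons evaluation times (years).
#' @param by_c3s if `TRUE`, the 12 LBTD x C3S groups (missing C3S completed
#'   by imputation); otherwise the 6 LBTD-only groups, C3S ignored.
#' @param ensemble optionally a precomputed `mi_ensemble` (ignored when
#'   `by_c3s = FALSE`).
#' @return data.frame with columns `group`, `horizon`, `estimate`, `lower`,
#'   `upper` and attribute `n_degenerate`.
#' @export
mi_bootstrap_ci <- function(cohort, config = mi_config(),
                            horizons = c(2, 5, 10), by_c3s = TRUE,
                            ensemble = NULL) {
  stopifnot(inherits(cohort, "cohort"), inherits(config, "mi_config"))
  status <- .status_code(cohort$event)
  time <- cohort$time
  n <- nrow(cohort)
  alpha <- (1 - config$ci_level) / 2

  if (by_c3s) {
    if (is.null(ensemble)) ensemble <- impute_c3s(cohort, config = config)
    M <- ensemble$M
    grp_i <- lapply(seq_len(M), function(i)
      .group_index(cohort$lbtd_bin, ensemble$c3s[, i]))
  } else {
    M <- 1L
    grp_i <- list(.group_index(cohort$lbtd_bin))
  }
  ng <- grp_i[[1]]$n
  labels <- grp_i[[1]]$labels

  point <- matrix(0, ng, length(horizons))
  boots <- array(NA_real_, c(ng, length(horizons), M * config$B))
  degenerate <- 0L
  set.seed(config$seed + 1L)
  for (i in seq_len(M)) {
    gi <- grp_i[[i]]$idx
    point <- point + .group_cif_at(time, status, gi, ng, horizons) / M
    for (b in seq_len(config$B)) {
      idx <- sample.int(n, n, replace = TRUE)
      gb <- gi[idx]
      if (any(tabulate(gb, ng) == 0)) degenerate <- degenerate + 1L
      boots[, , (i - 1L) * config$B + b] <-
        .group_cif_at(time[idx], status[idx], gb, ng, horizons)
    }
  }
  lo <- apply(boots, c(1, 2), quantile, probs = alpha, names = FALSE)
  hi <- apply(boots, c(1, 2), quantile, probs = 1 - alpha, names = FALSE)
  out <- data.frame(
    group = rep(labels, times = length(horizons)),
    horizon = rep(horizons, each = ng),
    estimate = as.vector(point), lower = as.vector(lo),
    upper = as.vector(hi))
  attr(out, "n_degenerate") <- degenerate
  out
}
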