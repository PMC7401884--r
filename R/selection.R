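# Backward selection of risk factors by rescaled AIC. For a factor, the
# rescaled AIC is the likelihood-ratio chi-square for dropping it minus twice
# the degrees of freedom it costs: positive values mean the factor carries
# more information than its complexity, negative values signal overfitting
# risk. Under the null the LR statistic is chi-square(df), so a pure noise
# factor has expected rescaled AIC df - 2*df = -df.

# analysis frame in which untyped C3S is a true NA (two-level factor), so
# complete-case filtering treats it like any other missing covariate
.factor_frame <- function(cohort) {
  df <- as.data.frame(cohort)
  df$c3s <- factor(ifelse(as.character(df$c3s) == "missing", NA,
                          as.character(df$c3s)), levels = c("D3", "M3"))
  df
}

#' Cause-specific Cox fit over a list of factors
#'
#' Partial-likelihood fit for the hazard of the given cause, treating deaths
#' from the competing cause as censored. Rows with missing values in any of
#' the listed factors are dropped (so nested fits share the same data);
#' constant factors are dropped with a warning.
#'
#' @param cohort a `cohort`.
#' @param factors character vector of covariate column names; may be empty
#'   for the null model. Factor-valued columns contribute one coefficient per
#'   non-reference level.
#' @param cause `"metastatic_death"` or `"other_death"`.
#' @param use_rows optional logical row filter (used internally to keep
#'   nested fits on identical rows).
#' @return object of class `csc_fit` with `loglik`, `df`, `coef`, `factors`,
#'   `n`, `n_events`.
#' @export
fit_cause_specific_cox <- function(cohort, factors = character(),
                                   cause = "metastatic_death",
                                   use_rows = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  cause <- match.arg(cause, event_levels()[2:3])
  missing_cols <- setdiff(factors, names(cohort))
  if (length(missing_cols))
    stop("factor(s) not in cohort: ", paste(missing_cols, collapse = ", "))
  df <- .factor_frame(cohort)
  if (is.null(use_rows))
    use_rows <- if (length(factors))
      complete.cases(df[, factors, drop = FALSE]) else rep(TRUE, nrow(df))
  df <- df[use_rows, , drop = FALSE]
  status <- as.integer(df$event == cause)
  if (!any(status == 1)) stop("no events of cause ", cause)

  constant <- vapply(factors, function(f)
    length(unique(df[[f]][!is.na(df[[f]])])) < 2, TRUE)
  if (any(constant)) {
    warning("dropping constant factor(s): ",
            paste(factors[constant], collapse = ", "), call. = FALSE)
    factors <- factors[!constant]
  }
  if (!length(factors)) {
    fit <- survival::coxph(survival::Surv(df$time, status) ~ 1)
    ll <- fit$loglik[1]
    return(structure(list(loglik = ll, df = 0L, coef = numeric(0),
                          factors = character(0), n = nrow(df),
                          n_events = sum(status), rows = use_rows),
                     class = "csc_fit"))
  }
  fml <- as.formula(paste("survival::Surv(time, ..status..) ~",
                          paste(factors, collapse = " + ")))
  df$..status.. <- status
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "breslow"),
    warning = function(w) {
      if (grepl("Loglik converged|Ran out of iterations",
                conditionMessage(w))) {
        flagged <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (flagged)
    warning("monotone/ill-conditioned partial likelihood for {",
            paste(factors, collapse = ", "), "}; some coefficients may be ",
            "unstable", call. = FALSE)
  cf <- coef(fit)
  dropped <- is.na(cf)
  if (any(dropped))
    warning("collinear term(s) dropped: ",
            paste(names(cf)[dropped], collapse = ", "), call. = FALSE)
  structure(list(loglik = fit$loglik[2], df = sum(!dropped),
                 coef = cf[!dropped], factors = factors, n = nrow(df),
                 n_events = sum(status), rows = use_rows),
            class = "csc_fit")
}

#' @export
print.csc_fit <- function(x, ...) {
  cat("Cause-specific Cox fit: ", length(x$factors), " factor(s), df = ",
      x$df, ", loglik = ", sprintf("%.2f", x$loglik), ", ", x$n_events,
      " events / ", x$n, " subjects\n", sep = "")
  invisible(x)
}

#' Rescaled AIC of a nested model comparison
#'
#' `LR - 2 * ddf`, where `LR = 2 (loglik_full - loglik_reduced)` and `ddf`
#' is the difference in model degrees of freedom. Positive values indicate
#' an informative factor; negative values an increased chance of
#' overfitting.
#'
#' @param full_fit,reduced_fit `csc_fit` objects with the reduced model's
#'   factors a subset of the full model's, fitted on the same rows.
#' @return numeric scalar.
#' @export
rescaled_aic <- function(full_fit, reduced_fit) {
  stopifnot(inherits(full_fit, "csc_fit"), inherits(reduced_fit, "csc_fit"))
  if (!all(reduced_fit$factors %in% full_fit$factors))
    stop("fits are not nested")
  if (full_fit$n != reduced_fit$n)
    stop("fits use different rows; refit on a common subset")
  lr <- 2 * (full_fit$loglik - reduced_fit$loglik)
  ddf <- full_fit$df - reduced_fit$df
  lr - 2 * ddf
}

#' Backward selection and rescaled-AIC ranking of risk factors
#'
#' Sequential mode repeatedly drops the factor whose removal most improves
#' model quality (most negative rescaled AIC) until every remaining factor
#' has a positive value; dropped factors are ranked by the value at their
#' removal, retained factors by single deletion from the final model.
#' Single-deletion mode ranks every factor by deleting it once from the full
#' model. With an `mi_ensemble`, the ranking values are averaged over the
#' completed datasets.
#'
#' @param cohort a `cohort`.
#' @param factors character vector of candidate covariate columns.
#' @param cause target cause, see [fit_cause_specific_cox()].
#' @param method `"sequential"` (default) or `"single"`.
#' @param ensemble optional `mi_ensemble` used when `c3s` is among the
#'   factors and has missing values.
#' @return object of class `factor_ranking`: data.frame with columns
#'   `factor`, `aic`, `df`, `retained`, sorted by decreasing `aic`.
#' @export
backward_select <- function(cohort, factors, cause = "metastatic_death",
                            method = c("sequential", "single"),
                            ensemble = NULL) {
  method <- match.arg(method)
  if (!length(factors)) stop("need at least one candidate factor")
  if (!is.null(ensemble)) {
    ranks <- lapply(seq_len(ensemble$M), function(i)
      backward_select(completed_cohort(ensemble, i), factors, cause, method))
    avg <- Reduce(`+`, lapply(ranks, function(r)
      r$aic[match(factors, r$factor)])) / length(ranks)
    ret <- Reduce(`+`, lapply(ranks, function(r)
      as.numeric(r$retained[match(factors, r$factor)]))) / length(ranks)
    out <- data.frame(factor = factors, aic = avg,
                      df = ranks[[1]]$df[match(factors, ranks[[1]]$factor)],
                      retained = ret >= 0.5)
    out <- out[order(-out$aic), ]
    rownames(out) <- NULL
    return(structure(out, class = c("factor_ranking", "data.frame"),
                     cause = cause, method = method, averaged = ensemble$M))
  }

  rows <- complete.cases(.factor_frame(cohort)[, factors, drop = FALSE])
  refit <- function(fs) fit_cause_specific_cox(cohort, fs, cause,
                                               use_rows = rows)
  deletion_values <- function(fs) {
    full <- refit(fs)
    vapply(fs, function(f) {
      red <- refit(setdiff(fs, f))
      c(aic = rescaled_aic(full, red), df = full$df - red$df)
    }, c(aic = 0, df = 0))
  }

  if (method == "single") {
    vals <- deletion_values(factors)
    out <- data.frame(factor = factors, aic = vals["aic", ],
                      df = as.integer(vals["df", ]),
                      retained = vals["aic", ] > 0)
  } else {
    current <- factors
    removed <- list()
    while (length(current)) {
      vals <- deletion_values(current)
      worst <- which.min(vals["aic", ])
      if (vals["aic", worst] >= 0) break
      removed[[current[worst]]] <- vals[, worst]
      current <- current[-worst]
    }
    final_vals <- if (length(current)) deletion_values(current) else
      matrix(numeric(0), 2, 0, dimnames = list(c("aic", "df"), NULL))
    out <- rbind(
      if (length(current))
        data.frame(factor = current, aic = final_vals["aic", ],
                   df = as.integer(final_vals["df", ]), retained = TRUE),
      if (length(removed))
        data.frame(factor = names(removed),
                   aic = vapply(removed, `[[`, 0, "aic"),
                   df = as.integer(vapply(removed, `[[`, 0, "df")),
                   retained = FALSE))
  }
  out <- out[order(-out$aic), ]
  rownames(out) <- NULL
  structure(out, class = c("factor_ranking", "data.frame"),
            cause = cause, method = method)
}

#' @export
print.factor_ranking <- function(x, ...) {
  cat("Risk-factor ranking for ", attr(x, "cause"),
      " (rescaled AIC, method = ", attr(x, "method"), ")\n", sep = "")
  print.data.frame(x, digits = 4)
  invisible(x)
}
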