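# Independent oracles used across the suite. These deliberately avoid the
# package's vectorised counting-process code paths: the Aalen-Johansen
# oracle walks event times one by one, and the concordance oracle enumerates
# every ordered pair.

# Aalen-Johansen by explicit event-time loop; status: 0 cens, 1 met, 2 other.
# Returns a function of t for the requested cause (1 or 2), plus the KM
# survival at each event time for conservation checks.
aj_oracle <- function(time, status, cause = 1L) {
  ut <- sort(unique(time[status > 0]))
  S <- 1
  Fv <- numeric(length(ut))
  Sv <- numeric(length(ut))
  acc <- 0
  for (j in seq_along(ut)) {
    u <- ut[j]
    Y <- sum(time >= u)
    d_any <- sum(time == u & status > 0)
    d_c <- sum(time == u & status == cause)
    acc <- acc + S * d_c / Y
    S <- S * (1 - d_any / Y)
    Fv[j] <- acc
    Sv[j] <- S
  }
  list(times = ut, F = Fv, S = Sv,
       at = function(t) if (!length(ut)) rep(0, length(t)) else
         vapply(t, function(tt) {
           i <- which(ut <= tt)
           if (length(i)) Fv[max(i)] else 0
         }, 0))
}

# all-pairs concordance oracle at a fixed horizon
cindex_oracle <- function(risk, time, event, tau,
                          cause = "metastatic_death") {
  competing <- setdiff(c("metastatic_death", "other_death"), cause)
  n <- length(risk)
  conc <- tied <- comp <- 0
  for (i in seq_len(n)) {
    if (!(event[i] == cause && time[i] <= tau)) next
    for (j in seq_len(n)) {
      if (j == i) next
      eligible <- time[j] > time[i] ||
        (event[j] == competing && time[j] <= time[i])
      if (!eligible) next
      comp <- comp + 1
      if (risk[i] > risk[j]) conc <- conc + 1
      else if (risk[i] == risk[j]) tied <- tied + 1
    }
  }
  (conc + tied / 2) / comp
}

# small hand-built coded cohort from parallel vectors
toy_cohort <- function(time, event, lbtd = 13, age = 60, c3s = "D3") {
  n <- length(time)
  rec <- function(x) rep_len(x, n)
  df <- data.frame(
    id = paste0("t", seq_len(n)), lbtd_mm = rec(lbtd),
    age_years = rec(age), sex = "female", c3s = rec(c3s),
    followup_years = time,
    outcome = c(censored = "alive", metastatic_death = "definite_metastatic",
                other_death = "non_cancerous")[event],
    stringsAsFactors = FALSE)
  suppressWarnings(as_cohort(df, source = "toy"))
}

# event factor from integer status codes
status_to_event <- function(status) {
  factor(c("censored", "metastatic_death", "other_death")[status + 1L],
         levels = c("censored", "metastatic_death", "other_death"))
}
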