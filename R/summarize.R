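# Crude cohort summary: per LBTD bin, N and metastatic deaths by C3S level,
# and N and non-metastatic deaths by age bin, with crude percentages.

#' Round half away from zero
#'
#' Display rounding for crude percentages: 26.25 prints as 26.3, not 26.2
#' (base R's `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Crude cohort summary by LBTD bin, C3S and age
#'
#' For each LBTD bin and each C3S level (unknown, D3, M3): the number of
#' patients and the number of metastatic deaths with crude percentage
#' 100 n/N. For each LBTD bin and age bin: the number of patients and the
#' number of non-metastatic (other-cause) deaths with crude percentage.
#' Percentages are rounded half-up to one decimal; column totals are
#' appended.
#'
#' @param cohort a `cohort`.
#' @return object of class `cohort_summary`: a list with data.frames `c3s`
#'   and `age` (columns `lbtd_bin`, `stratum`, `n`, `deaths`, `pct`) and a
#'   named vector `totals`.
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  if (!nrow(cohort)) stop("empty cohort")
  bins <- lbtd_levels()

  cell <- function(keep, death_event) {
    n <- sum(keep)
    d <- sum(keep & cohort$event == death_event)
    c(n = n, deaths = d,
      pct = if (n > 0) round_half_up(100 * d / n, 1) else NA_real_)
  }
  c3s_levels <- c(unknown = "missing", D3 = "D3", M3 = "M3")
  c3s_tab <- do.call(rbind, lapply(names(c3s_levels), function(s) {
    do.call(rbind, lapply(bins, function(b) {
      data.frame(lbtd_bin = b, stratum = s, t(cell(
        cohort$lbtd_bin == b & cohort$c3s == c3s_levels[[s]],
        "metastatic_death")))
    }))
  }))
  age_tab <- do.call(rbind, lapply(c("le80", "gt80"), function(a) {
    do.call(rbind, lapply(bins, function(b) {
      data.frame(lbtd_bin = b, stratum = a, t(cell(
        cohort$lbtd_bin == b & cohort$age_bin == a, "other_death")))
    }))
  }))
  totals <- c(
    tapply(c3s_tab$n, c3s_tab$stratum, sum)[names(c3s_levels)],
    tapply(age_tab$n, age_tab$stratum, sum)[c("le80", "gt80")],
    total = nrow(cohort))
  structure(list(c3s = c3s_tab, age = age_tab, totals = totals),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(render_summary(x, format = "text"), sep = "\n")
  invisible(x)
}

#' Render a crude cohort summary
#'
#' @param summary a `cohort_summary` from [summarize_cohort()].
#' @param format `"text"`, `"markdown"` or `"csv"` (long-format table).
#' @return character vector of lines.
#' @export
render_summary <- function(summary, format = c("text", "markdown", "csv")) {
  format <- match.arg(format)
  long <- rbind(
    cbind(summary$c3s, deaths_of = "metastatic"),
    cbind(summary$age, deaths_of = "non-metastatic"))
  if (format == "csv") {
    con <- textConnection("out", "w", local = TRUE)
    utils::write.csv(long, con, row.names = FALSE)
    close(con)
    return(out)
  }
  wide <- function(tab, strata) {
    rows <- lapply(lbtd_levels(), function(b) {
      cells <- vapply(strata, function(s) {
        r <- tab[tab$lbtd_bin == b & tab$stratum == s, ]
        sprintf("%d %d (%.1f)", r$n, r$deaths, r$pct)
      }, "")
      c(b, cells)
    })
    tot <- c("Total", vapply(strata, function(s)
      as.character(sum(tab$n[tab$stratum == s])), ""))
    do.call(rbind, c(rows, list(tot)))
  }
  m1 <- wide(summary$c3s, c("unknown", "D3", "M3"))
  m2 <- wide(summary$age, c("le80", "gt80"))
  m <- cbind(m1, m2[, -1, drop = FALSE])
  hdr <- c("LBTD (mm)", "Unknown C3S", "Disomy 3", "Monosomy 3",
           age_levels()[["le80"]], age_levels()[["gt80"]])
  m <- rbind(hdr, m)
  if (format == "markdown") {
    sep <- paste0("|", paste(rep("---", ncol(m)), collapse = "|"), "|")
    lines <- apply(m, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                            " |"))
    return(c(lines[1], sep, lines[-1]))
  }
  w <- apply(nchar(m), 2, max)
  apply(m, 1, function(r)
    paste(vapply(seq_along(r), function(i)
      sprintf(paste0("%-", w[i], "s"), r[i]), ""), collapse = "  "))
}
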