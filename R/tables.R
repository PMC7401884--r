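# Prognostic tables: absolute risk (%) of metastatic death at 2, 5 and
# 10 years for each LBTD bin, in three panels (disomy 3, monosomy 3, unknown
# C3S) and two age columns (<=80 / >80 at treatment). D3/M3 panels come from
# the 12 LBTD x C3S groups with missing C3S multiply imputed; the unknown
# panel is the LBTD-only model's marginal estimate over C3S, not an average
# of the other two panels. Age-specific risks compose each group's
# metastatic hazard with the cohort-wide Cox other-cause hazard.

.panels <- c("D3", "M3", "unknown")
.ages <- c("le80", "gt80")

# left-justified padding, element-wise widths
.pad <- function(s, w) {
  vapply(seq_along(s), function(i)
    sprintf(paste0("%-", w[i], "s"), s[i]), "")
}

# risks (proportions) for all panels/ages/horizons of one completed dataset
.table_point <- function(time, status, bin, c3s, cox, horizons) {
  out <- array(NA_real_, c(6, 3, length(horizons), 2),
               dimnames = list(lbtd_levels(), .panels, horizons, .ages))
  fill <- function(sel, row, panel) {
    if (!any(sel)) return()
    cc <- .cr_counts(time[sel], status[sel])
    keep <- cc$d1 > 0
    mh <- data.frame(time = cc$times[keep], dhaz = (cc$d1 / cc$Y)[keep])
    for (a in .ages)
      out[row, panel, , a] <<- eval_cif(combine_cif_with_cox(mh, cox, a),
                                        horizons)
  }
  for (b in 1:6) {
    fill(bin == b & c3s == "D3", b, "D3")
    fill(bin == b & c3s == "M3", b, "M3")
    fill(bin == b, b, "unknown")
  }
  out
}

#' Build the prognostic table of absolute metastatic risk
#'
#' @param cohort a `cohort`.
#' @param config an [mi_config()] controlling imputations, bootstrap
#'   resamples and the seed.
#' @param horizons prediction horizons in years.
#' @param ci if `FALSE`, skip the bootstrap and return point estimates only.
#' @return object of class `prognostic_table`: arrays `estimate`, `lower`,
#'   `upper` of dimension 6 bins x 3 panels x horizons x 2 ages, on the
#'   percent scale, with empty cells `NA`.
#' @export
build_prognostic_table <- function(cohort, config = mi_config(),
                                   horizons = c(2, 5, 10), ci = TRUE) {
  stopifnot(inherits(cohort, "cohort"), inherits(config, "mi_config"))
  time <- cohort$time
  status <- .status_code(cohort$event)
  bin <- as.integer(cohort$lbtd_bin)
  any_missing <- any(cohort$c3s == "missing")
  ensemble <- if (any_missing) impute_c3s(cohort, config = config)
  M <- if (any_missing) config$M else 1L
  c3s_col <- function(i) if (any_missing) ensemble$c3s[, i] else
    as.character(cohort$c3s)

  cox <- fit_cox_other_cause(cohort)
  point <- NULL
  for (i in seq_len(M)) {
    pi <- .table_point(time, status, bin, c3s_col(i), cox, horizons)
    point <- if (is.null(point)) pi / M else point + pi / M
  }

  lower <- upper <- array(NA_real_, dim(point), dimnames(point))
  if (ci) {
    n <- nrow(cohort)
    boots <- array(NA_real_, c(length(point), M * config$B))
    set.seed(config$seed + 2L)
    for (i in seq_len(M)) {
      c3s <- c3s_col(i)
      for (b in seq_len(config$B)) {
        idx <- sample.int(n, n, replace = TRUE)
        cox_b <- suppressWarnings(
          tryCatch(fit_cox_other_cause(cohort[idx, ]),
                   error = function(e) cox))
        boots[, (i - 1L) * config$B + b] <-
          as.vector(.table_point(time[idx], status[idx], bin[idx],
                                 c3s[idx], cox_b, horizons))
      }
    }
    alpha <- (1 - config$ci_level) / 2
    qs <- apply(boots, 1, quantile, probs = c(alpha, 1 - alpha),
                na.rm = TRUE, names = FALSE)
    lower[] <- qs[1, ]
    upper[] <- qs[2, ]
  }
  structure(list(estimate = 100 * point, lower = 100 * lower,
                 upper = 100 * upper, horizons = horizons,
                 M = M, B = if (ci) config$B else 0L, n = nrow(cohort)),
            class = "prognostic_table")
}

#' Format an absolute risk the way prognostic tables print it
#'
#' Risks below 10% are shown to one decimal (half-up); risks of 10% or more
#' to two significant figures.
#'
#' @param x risks in percent.
#' @return character vector.
#' @export
format_risk <- function(x) {
  ifelse(is.na(x), "—",
         ifelse(x < 10, sprintf("%.1f", round_half_up(x, 1)),
                formatC(signif(x, 2), format = "fg")))
}

#' Render a prognostic table
#'
#' @param table a `prognostic_table`.
#' @param format `"text"`, `"markdown"` or `"csv"` (long format, one row per
#'   cell, numeric columns unrounded).
#' @return character vector of lines.
#' @export
render_table <- function(table, format = c("text", "markdown", "csv")) {
  stopifnot(inherits(table, "prognostic_table"))
  format <- match.arg(format)
  long <- table_to_frame(table)
  if (format == "csv") {
    con <- textConnection("out", "w", local = TRUE)
    utils::write.csv(long, con, row.names = FALSE)
    close(con)
    return(out)
  }
  cell_txt <- function(e, l, u) {
    if (is.na(e)) return("—")
    if (is.na(l)) return(format_risk(e))
    sprintf("%s (%s, %s)", format_risk(e), format_risk(l), format_risk(u))
  }
  lines <- character(0)
  hdr <- c("LBTD (mm)",
           as.vector(outer(table$horizons, .ages,
                           function(h, a) sprintf("%g y, %s", h,
                                                  age_levels()[a]))))
  panel_name <- c(D3 = "Disomy-3 melanoma", M3 = "Monosomy-3 melanoma",
                  unknown = "Unknown chromosome 3 status")
  for (p in .panels) {
    m <- rbind(hdr, t(vapply(1:6, function(b) {
      c(lbtd_levels()[b],
        as.vector(outer(seq_along(table$horizons), seq_along(.ages),
                        Vectorize(function(h, a)
                          cell_txt(table$estimate[b, p, h, a],
                                   table$lower[b, p, h, a],
                                   table$upper[b, p, h, a])))))
    }, character(1 + 2 * length(table$horizons)))))
    if (format == "markdown") {
      sep <- paste0("|", paste(rep("---", ncol(m)), collapse = "|"), "|")
      body <- apply(m, 1, function(r)
        paste0("| ", paste(r, collapse = " | "), " |"))
      lines <- c(lines, paste0("**", panel_name[[p]], "**"), "",
                 body[1], sep, body[-1], "")
    } else {
      w <- apply(nchar(m), 2, max)
      lines <- c(lines, panel_name[[p]],
                 apply(m, 1, function(r) paste(.pad(r, w), collapse = "  ")),
                 "")
    }
  }
  lines
}

#' Long-format view of a prognostic table
#'
#' @param table a `prognostic_table`.
#' @return data.frame with columns `lbtd_bin`, `panel`, `horizon`,
#'   `age_bin`, `estimate`, `lower`, `upper` (percent).
#' @export
table_to_frame <- function(table) {
  g <- expand.grid(lbtd_bin = lbtd_levels(), panel = .panels,
                   horizon = table$horizons, age_bin = .ages,
                   stringsAsFactors = FALSE)
  g$estimate <- as.vector(table$estimate)
  g$lower <- as.vector(table$lower)
  g$upper <- as.vector(table$upper)
  g
}

#' @export
print.prognostic_table <- function(x, ...) {
  cat("Absolute risk of metastatic death, % (n = ", x$n, ", M = ", x$M,
      ", B = ", x$B, ")\n\n", sep = "")
  cat(render_table(x, "text"), sep = "\n")
  invisible(x)
}
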