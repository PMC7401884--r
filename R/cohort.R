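# Cohort container and CSV I/O. A `cohort` is a data.frame of one row per
# patient carrying the raw measurements plus the coded analysis columns
# (lbtd_bin, age_bin, event, time).

.required_cols <- c("id", "lbtd_mm", "age_years", "sex", "c3s",
                    "followup_years", "outcome")
.optional_cols <- c("chr8q", "ciliary_body", "extraocular", "thickness_mm",
                    "closed_loops", "epithelioid", "mitotic_count",
                    "c3s_true")

#' Build a coded cohort from a raw per-patient table
#'
#' Validates the raw columns, codes LBTD bin, age bin and the competing-risks
#' event, and rejects (with a warning) rows with non-positive follow-up or
#' unparseable LBTD / follow-up time. Rejected rows are recorded in the
#' `"rejected"` attribute.
#'
#' @param df data.frame with at least the columns `id`, `lbtd_mm`,
#'   `age_years`, `sex`, `c3s` (`"D3"`, `"M3"` or missing), `followup_years`
#'   and `outcome` (`"alive"` or a cause-of-death category, see
#'   [code_cause_of_death()]). Optional columns: `chr8q`, `ciliary_body`,
#'   `extraocular`, `thickness_mm`, `closed_loops`, `epithelioid`,
#'   `mitotic_count`.
#' @param source character tag stored as provenance metadata.
#' @return an object of class `cohort` (a data.frame).
#' @export
as_cohort <- function(df, source = "in-memory") {
  stopifnot(is.data.frame(df))
  miss <- setdiff(.required_cols, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  extra <- setdiff(names(df),
                   c(.required_cols, .optional_cols,
                     c("lbtd_bin", "age_bin", "event", "time")))
  if (length(extra))
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
  df$lbtd_mm <- suppressWarnings(as.numeric(df$lbtd_mm))
  df$followup_years <- suppressWarnings(as.numeric(df$followup_years))
  df$age_years <- suppressWarnings(as.numeric(df$age_years))

  bad <- is.na(df$lbtd_mm) | df$lbtd_mm <= 0 |
    is.na(df$followup_years) | df$followup_years <= 0 |
    !is.finite(df$followup_years) |
    is.na(df$age_years) | df$age_years <= 0
  rejected <- df[bad, , drop = FALSE]
  if (nrow(rejected))
    warning("rejected ", nrow(rejected), " row(s) with invalid LBTD, age or ",
            "follow-up time (row index: ",
            paste(utils::head(which(bad), 10), collapse = ", "), ")",
            call. = FALSE)
  df <- df[!bad, , drop = FALSE]
  if (!nrow(df)) stop("cohort is empty after validation")

  c3s <- as.character(df$c3s)
  c3s[is.na(c3s) | c3s == "" | c3s == "NA"] <- "missing"
  if (!all(c3s %in% c("D3", "M3", "missing")))
    stop("c3s must be 'D3', 'M3' or missing")
  df$c3s <- factor(c3s, levels = c("D3", "M3", "missing"))

  df$sex <- factor(as.character(df$sex), levels = c("male", "female"))
  df$lbtd_bin <- bin_lbtd(df$lbtd_mm)
  df$age_bin <- bin_age(df$age_years)
  df$event <- code_cause_of_death(df$outcome)
  df$time <- df$followup_years
  rownames(df) <- NULL

  structure(df, class = c("cohort", "data.frame"),
            source = source, coding_version = "lbtd6-age80-v1",
            rejected = rejected)
}

#' Read a cohort CSV
#'
#' Comma-separated, header row required, UTF-8; missing values as empty string
#' or `"NA"`. See [as_cohort()] for the schema and validation rules.
#'
#' @param path path to the CSV file.
#' @return a `cohort`.
#' @export
load_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), fileEncoding = "UTF-8")
  as_cohort(df, source = path)
}

#' Write a cohort back to CSV
#'
#' Writes the raw (uncoded) columns so that [load_cohort()] round-trips to an
#' identical cohort.
#'
#' @param cohort a `cohort`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  keep <- intersect(c(.required_cols, .optional_cols), names(cohort))
  utils::write.csv(as.data.frame(cohort)[, keep], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' @export
print.cohort <- function(x, ...) {
  cat("Choroidal melanoma cohort: ", nrow(x), " patients (",
      sum(x$event == "metastatic_death"), " metastatic deaths, ",
      sum(x$event == "other_death"), " other-cause deaths, ",
      sum(x$c3s == "missing"), " with unknown C3S)\n", sep = "")
  cat("source:", attr(x, "source") %||% "?", "\n")
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' Reconstruct a coded cohort from published crude counts
#'
#' Given a crude cross-tabulation -- per LBTD bin: the number of patients with
#' unknown C3S, disomy 3 and monosomy 3 together with metastatic deaths in
#' each, and the number of patients aged <=80 / >80 with non-metastatic deaths
#' in each -- builds a coded cohort whose crude margins reproduce the counts
#' exactly. Within each bin, metastatic deaths are placed on distinct subjects
#' from non-metastatic deaths (possible whenever the two death totals fit in
#' the bin). Follow-up times are arbitrary constants: the cohort is intended
#' for crude summaries, not time-to-event estimation.
#'
#' @param counts data.frame with columns `lbtd_bin`, `stratum` (one of
#'   `"unknown"`, `"D3"`, `"M3"`, `"le80"`, `"gt80"`), `n` and `deaths`;
#'   `deaths` are metastatic for the C3S strata and non-metastatic for the
#'   age strata. The two stratifications must agree on bin totals.
#' @return a `cohort`.
#' @seealso [reference_counts()] for a published example table.
#' @export
cohort_from_counts <- function(counts) {
  stopifnot(all(c("lbtd_bin", "stratum", "n", "deaths") %in% names(counts)))
  bins <- lbtd_levels()
  mids <- c(8, 11, 13, 15, 17, 20)  # representative diameters per bin
  rows <- list()
  for (b in seq_along(bins)) {
    cb <- counts[counts$lbtd_bin == bins[b], , drop = FALSE]
    getn <- function(s) {
      r <- cb[cb$stratum == s, , drop = FALSE]
      if (nrow(r) != 1) stop("counts must have one row per bin x stratum; ",
                             "missing ", bins[b], " / ", s)
      c(r$n, r$deaths)
    }
    un <- getn("unknown"); d3 <- getn("D3"); m3 <- getn("M3")
    le <- getn("le80"); gt <- getn("gt80")
    N <- un[1] + d3[1] + m3[1]
    if (N != le[1] + gt[1])
      stop("bin ", bins[b], ": C3S and age stratifications disagree on N")
    met <- un[2] + d3[2] + m3[2]
    oth <- le[2] + gt[2]
    if (met + oth > N)
      stop("bin ", bins[b], ": more deaths than patients")
    # metastatic deaths occupy the head of the bin block, non-metastatic the
    # tail, so the two never collide
    c3s <- c(rep("missing", un[2]), rep("D3", d3[2]), rep("M3", m3[2]),
             rep("missing", un[1] - un[2]), rep("D3", d3[1] - d3[2]),
             rep("M3", m3[1] - m3[2]))
    age <- c(rep(70, le[1] - le[2]), rep(85, gt[1] - gt[2]),
             rep(70, le[2]), rep(85, gt[2]))
    outcome <- rep("alive", N)
    if (met) outcome[seq_len(met)] <- "definite_metastatic"
    if (oth) outcome[N - seq_len(oth) + 1] <- "non_cancerous"
    rows[[b]] <- data.frame(
      id = sprintf("b%d_%04d", b, seq_len(N)),
      lbtd_mm = mids[b], age_years = age, sex = "female",
      c3s = ifelse(c3s == "missing", NA, c3s),
      followup_years = 5, outcome = outcome,
      stringsAsFactors = FALSE)
  }
  as_cohort(do.call(rbind, rows), source = "crude-counts")
}

#' Published crude counts for a large choroidal-melanoma series
#'
#' Crude cross-tabulation of a published 4174-patient choroidal melanoma
#' series: per LBTD bin, patient counts and metastatic deaths by chromosome 3
#' status (unknown / disomy 3 / monosomy 3) and patient counts and
#' non-metastatic deaths by age at treatment (up to 80 / over 80 years).
#' Shipped as a plain-text fixture; used as a worked numeric example and as an
#' arithmetic check of [summarize_cohort()].
#'
#' @return data.frame with columns `lbtd_bin`, `stratum`, `n`, `deaths`.
#' @export
reference_counts <- function() {
  path <- system.file("extdata", "reference_crude_counts.csv",
                      package = "crprog")
  if (path == "") stop("fixture reference_crude_counts.csv not installed")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
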