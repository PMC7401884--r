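# Covariate and outcome codings: six-level LBTD factor, binary age at 80,
# and the cause-of-death rule (metastatic death = "definite" or "probable"
# metastatic uveal melanoma only).

#' Six-level LBTD bins
#'
#' Largest basal tumor diameter (mm) is recoded into six ordered levels with
#' edges at 10, 12, 14, 16 and 18 mm. Intervals are left-open/right-closed,
#' matching labels printed at 0.1 mm resolution: a tumor of exactly 12.0 mm
#' falls in "10.1-12.0". Raw diameters are binned unrounded.
#'
#' @param lbtd_mm numeric vector of largest basal tumor diameters in mm;
#'   must be positive.
#' @return an ordered factor with levels `lbtd_levels()`.
#' @examples
#' bin_lbtd(c(2.4, 12, 28))
#' @export
bin_lbtd <- function(lbtd_mm) {
  if (!is.numeric(lbtd_mm)) stop("`lbtd_mm` must be numeric")
  bad <- !is.na(lbtd_mm) & lbtd_mm <= 0
  if (any(bad)) stop("LBTD must be positive; offending value(s): ",
                     paste(lbtd_mm[bad], collapse = ", "))
  out <- range_warn(lbtd_mm, 2.4, 28, "lbtd_mm")
  cut(lbtd_mm, breaks = c(-Inf, 10, 12, 14, 16, 18, Inf),
      labels = lbtd_levels(), right = TRUE, ordered_result = TRUE)
}

#' @rdname bin_lbtd
#' @export
lbtd_levels <- function() {
  c("<10.1", "10.1-12.0", "12.1-14.0", "14.1-16.0", "16.1-18.0", "18.1-28.0")
}

range_warn <- function(x, lo, hi, what) {
  out <- !is.na(x) & (x < lo | x > hi)
  if (any(out))
    warning(sum(out), " ", what, " value(s) outside [", lo, ", ", hi,
            "], the usual range for this tumor", call. = FALSE)
  invisible(x)
}

#' Binary age at treatment
#'
#' Age at treatment is dichotomized at 80 years: `le80` ("<81 yr") for ages
#' up to and including 80, `gt80` (">80 yr") above. The threshold maximizes
#' the separation between the absolute risks of metastatic and non-metastatic
#' death in this disease.
#'
#' @param age_years numeric vector of ages at treatment, in years (positive).
#' @return factor with levels `c("le80", "gt80")`.
#' @examples
#' bin_age(c(80, 81))
#' @export
bin_age <- function(age_years) {
  if (!is.numeric(age_years)) stop("`age_years` must be numeric")
  bad <- !is.na(age_years) & age_years <= 0
  if (any(bad)) stop("age must be positive")
  factor(ifelse(age_years > 80, "gt80", "le80"), levels = c("le80", "gt80"))
}

#' @rdname bin_age
#' @export
age_levels <- function() c(le80 = "<81 yr", gt80 = ">80 yr")

# Registry cause-of-death categories.
cause_categories <- c("definite_metastatic", "probable_metastatic",
                      "possible_metastatic", "other_malignancy",
                      "non_cancerous", "unknown")

#' Code cause of death into the competing-risks event
#'
#' Death is attributed to the uveal melanoma only when metastatic disease is
#' "definite" (category 1) or "probable" (category 2), i.e. when no other
#' cause of death and no other source of metastases was specified. "Possible"
#' metastatic disease, other malignancies, non-cancerous causes and unknown
#' causes (categories 3-6) count as death from other causes. Patients alive
#' at last follow-up are censored.
#'
#' @param category vector of outcome codes: `"alive"`, an integer 1-6, or one
#'   of `"definite_metastatic"`, `"probable_metastatic"`,
#'   `"possible_metastatic"`, `"other_malignancy"`, `"non_cancerous"`,
#'   `"unknown"`.
#' @return factor with levels
#'   `c("censored", "metastatic_death", "other_death")`.
#' @export
code_cause_of_death <- function(category) {
  x <- as.character(category)
  num <- suppressWarnings(as.integer(x))
  use_num <- !is.na(num) & x == as.character(num)
  x[use_num] <- ifelse(num[use_num] >= 1 & num[use_num] <= 6,
                       cause_categories[pmin(pmax(num[use_num], 1L), 6L)],
                       x[use_num])
  ok <- x %in% c("alive", cause_categories)
  if (any(!ok)) stop("unknown cause-of-death category: ",
                     paste(unique(x[!ok]), collapse = ", "))
  ev <- ifelse(x == "alive", "censored",
        ifelse(x %in% cause_categories[1:2], "metastatic_death",
               "other_death"))
  factor(ev, levels = event_levels())
}

#' @rdname code_cause_of_death
#' @export
event_levels <- function() c("censored", "metastatic_death", "other_death")

# integer status codes used by the estimation core: 0 censored, 1 metastatic,
# 2 other-cause
.status_code <- function(event) {
  match(as.character(event), event_levels()) - 1L
}
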