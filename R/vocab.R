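# Controlled vocabularies shared across the pipeline.

#' Canonical adverse-event group labels
#'
#' The 19 otolaryngologic adverse-event-following-immunization (AEFI) group
#' names used by the default preferred-term mapping and the replay fixture.
#' Labels are canonicalized with ASCII apostrophes.
#'
#' @return Character vector of 19 group names.
#' @export
#' @examples
#' aefi_group_names()
aefi_group_names <- function() {
  c(
    "Hearing loss",
    "Tinnitus (Ringing in the ears)",
    "Ear infections (Otitis Media)",
    "Meniere's disease",
    "Vestibular neuronitis",
    "Dizziness or vertigo",
    "Sinusitis",
    "Rhinitis (Allergic and Non-allergic)",
    "Epistaxis",
    "Anosmia",
    "Nasal polyps",
    "Snoring or difficulty breathing through the nose and sleep apnea",
    "Allergies",
    "Tonsillitis",
    "Laryngitis",
    "Vocal cord polyps and nodules",
    "Laryngopharyngeal reflux (Acid Reflux)",
    "Epiglottitis",
    "Pharyngitis"
  )
}

# Dose-series populations: completed primary series, updated bivalent
# booster, at-least-one-dose (the CDC Data Tracker's three denominators).
dose_series_levels <- function() c("CPS", "UBB", "ALOD", "UNKNOWN")

manufacturer_levels <- function() {
  c("PFIZER_BIONTECH", "MODERNA", "JANSSEN", "OTHER", "UNKNOWN")
}

sex_levels <- function() c("M", "F", "UNKNOWN")

stratum_axes <- function() c("TOTAL", "SEX", "AGE", "MANUFACTURER")

#' Age-band labels used for the AGE stratum axis
#'
#' Bands are half-open on integer years: [0,18), [18,50), [50,65), [65,Inf).
#'
#' @return Character vector of band labels.
#' @export
age_band_labels <- function() c("0-17", "18-49", "50-64", "65+")

#' Assign ages to age bands
#'
#' @param age_years Numeric vector of ages in years; `NA` allowed.
#' @return Character vector of band labels (see [age_band_labels()]),
#'   `"UNKNOWN"` where the age is missing.
#' @export
#' @examples
#' age_band(c(0, 17, 18, 49.9, 50, 64, 65, 90, NA))
age_band <- function(age_years) {
  dplyr::case_when(
    is.na(age_years) ~ "UNKNOWN",
    age_years < 18 ~ "0-17",
    age_years < 50 ~ "18-49",
    age_years < 65 ~ "50-64",
    TRUE ~ "65+"
  )
}

# Pseudo-group counting reports with >= 1 mapped group (the "Any IR" row).
ANY_GROUP <- "ANY"
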