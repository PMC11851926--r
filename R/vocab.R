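#' Treatment and outcome vocabulary
#'
#' The pipeline recognizes six treatment categories plus the distinguished
#' amputation outcome event. Event codes arriving from file are matched
#' case-insensitively against these names. The order of
#' `treatment_codes()` is the canonical order used to break same-date ties
#' during sequence extraction, so extraction is deterministic even when two
#' different treatments share a calendar date.
#'
#' @return `treatment_codes()`: character vector of the six category codes,
#'   in canonical order. `treatment_labels()`: named vector of display
#'   labels. `outcome_levels()`: the two outcome labels.
#' @examples
#' treatment_codes()
#' outcome_levels()
#' @export
treatment_codes <- function() {
  c(
    "ANTIPLATELET",
    "LIPID_LOWERING",
    "SMOKING_CESSATION",
    "EXERCISE_THERAPY",
    "ENDOVASCULAR_REVASCULARIZATION",
    "REVASCULARIZATION_SURGERY"
  )
}

#' @rdname treatment_codes
#' @export
treatment_labels <- function() {
  c(
    ANTIPLATELET = "Antiplatelet",
    LIPID_LOWERING = "Lipid lowering",
    SMOKING_CESSATION = "Smoking cessation",
    EXERCISE_THERAPY = "Exercise therapy",
    ENDOVASCULAR_REVASCULARIZATION = "Endovascular revascularization",
    REVASCULARIZATION_SURGERY = "Revascularization surgery"
  )
}

# the distinguished outcome event code
amputation_code <- function() "AMPUTATION"

#' @rdname treatment_codes
#' @export
outcome_levels <- function() c("AMPUTATION", "NON_AMPUTATION")

event_codes <- function() c(treatment_codes(), amputation_code())

#' Comorbidity flags recognized in person tables
#'
#' Boolean per-patient flags for the six comorbidities used in
#' confounder-stratified analyses. The flags are resolved upstream of this
#' package (their defining diagnosis-code lists are data-source specific);
#' here they are plain logical columns of the person table, named in lower
#' case.
#'
#' @return Character vector of flag names (upper case; the matching person
#'   table columns are lower case).
#' @export
comorbidity_flags <- function() {
  c(
    "DIABETES",
    "HYPERTENSION",
    "HEART_FAILURE",
    "CEREBROVASCULAR_DISEASE",
    "CORONARY_ARTERY_DISEASE",
    "HYPERLIPIDEMIA"
  )
}

# canonical rank of a treatment code; used for same-date tie-breaks
treatment_rank <- function(code) match(code, treatment_codes())

# normalize raw code strings (case/whitespace) to vocabulary form; returns
# NA for unknown codes
normalize_code <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x <- gsub("[ -]+", "_", x)
  ifelse(x %in% event_codes(), x, NA_character_)
}

#' Collapse a step vector to a pathway key, and back
#'
#' Pathway keys are the canonical single-string representation of an
#' ordered treatment sequence, with stages joined by `" -> "`. Tables and
#' JSON exports use the key; list-columns of step vectors are used inside
#' the package.
#'
#' @param steps Character vector of treatment codes (one pathway), or a
#'   list of such vectors.
#' @param key A pathway key string.
#' @return `pathway_key()`: a character scalar (or vector, for a list
#'   input). `pathway_steps()`: a character vector of codes.
#' @examples
#' pathway_key(c("ANTIPLATELET", "LIPID_LOWERING"))
#' pathway_steps("ANTIPLATELET -> LIPID_LOWERING")
#' @export
pathway_key <- function(steps) {
  if (is.list(steps)) {
    return(vapply(steps, function(s) paste(s, collapse = " -> "), character(1)))
  }
  paste(steps, collapse = " -> ")
}

#' @rdname pathway_key
#' @export
pathway_steps <- function(key) {
  strsplit(key, " -> ", fixed = TRUE)[[1]]
}

# validate one ordered step vector against the sequence invariants
check_steps <- function(steps, what = "steps") {
  steps <- as.character(steps)
  if (length(steps) == 0) {
    stop(what, " must contain at least one treatment", call. = FALSE)
  }
  bad <- setdiff(steps, treatment_codes())
  if (length(bad) > 0) {
    stop(what, " contains unknown treatment code(s): ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(steps)) {
    stop(what, " must not repeat a treatment category", call. = FALSE)
  }
  steps
}

# round half away from zero (R's round() is half-to-even); a tiny epsilon
# absorbs binary representation error in values like 100*k/n
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}
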