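#' Assign the outcome label for one patient's events
#'
#' A patient belongs to the amputation cohort if and only if any of their
#' events carries the `AMPUTATION` code; otherwise to the non-amputation
#' cohort.
#'
#' @param events Event tibble for a single patient (`person_id`, `code`,
#'   `date`).
#' @return `"AMPUTATION"` or `"NON_AMPUTATION"`.
#' @export
assign_outcome <- function(events) {
  if (nrow(events) == 0) stop("no events supplied", call. = FALSE)
  if (length(unique(events$person_id)) > 1) {
    stop("events mix multiple person_ids", call. = FALSE)
  }
  if (any(events$code == amputation_code())) "AMPUTATION" else "NON_AMPUTATION"
}

#' Extract one patient's first-occurrence treatment sequence
#'
#' Implements the sequence-construction rule of the pipeline: events are
#' ordered by date, with same-date ties between different treatments
#' broken by the canonical category order ([treatment_codes()]); for
#' amputation patients only treatment events dated strictly before the
#' first amputation date count; each treatment category contributes at
#' most once, at its first qualifying occurrence; patients whose step list
#' comes out empty (no treatment before the outcome) are excluded from the
#' cohort.
#'
#' @param events Event tibble for a single patient.
#' @return A one-row tibble (`person_id`, `outcome`, `steps` list-column),
#'   or `NULL` when the patient is excluded.
#' @export
extract_sequence <- function(events) {
  if (length(unique(events$person_id)) > 1) {
    stop("events mix multiple person_ids", call. = FALSE)
  }
  if (any(is.na(events$date))) stop("event with missing date", call. = FALSE)
  outcome <- assign_outcome(events)
  tr <- events[events$code %in% treatment_codes(), , drop = FALSE]
  if (outcome == "AMPUTATION") {
    amp_date <- min(events$date[events$code == amputation_code()])
    tr <- tr[tr$date < amp_date, , drop = FALSE]
  }
  if (nrow(tr) == 0) return(NULL)
  tr <- tr[order(tr$date, treatment_rank(tr$code)), , drop = FALSE]
  steps <- unique(tr$code)
  tibble(
    person_id = events$person_id[1],
    outcome = outcome,
    steps = list(steps)
  )
}

#' Reduce an event log to one treatment sequence per eligible patient
#'
#' Applies [extract_sequence()] to every patient in the event log and
#' assembles the included sequences together with an extraction report.
#' Patients present in the event log but absent from the person table are
#' retained for pathway statistics and flagged via the `has_attributes`
#' column (they drop out only of confounder stratification).
#'
#' @param events Event tibble for the whole cohort.
#' @param persons Optional person attribute tibble.
#' @return A list with elements
#'   * `sequences`: tibble (`person_id`, `outcome`, `steps`,
#'     `has_attributes`), and
#'   * `report`: tibble with `n_input_patients`,
#'     `n_excluded_no_treatment`, `n_amputation`, `n_non_amputation`.
#' @examples
#' ev <- tibble::tibble(
#'   person_id = c("p1", "p1", "p2"),
#'   code = c("ANTIPLATELET", "AMPUTATION", "LIPID_LOWERING"),
#'   date = as.Date(c("2020-01-01", "2020-02-01", "2020-01-15"))
#' )
#' build_cohort(ev)$report
#' @export
build_cohort <- function(events, persons = NULL) {
  if (nrow(events) == 0) {
    return(list(
      sequences = tibble(
        person_id = character(), outcome = character(),
        steps = list(), has_attributes = logical()
      ),
      report = tibble(
        n_input_patients = 0L, n_excluded_no_treatment = 0L,
        n_amputation = 0L, n_non_amputation = 0L
      )
    ))
  }
  if (any(is.na(events$date))) stop("event with missing date", call. = FALSE)

  # vectorized equivalent of per-patient extract_sequence()
  ev <- events |>
    dplyr::group_by(.data$person_id) |>
    dplyr::mutate(
      outcome = ifelse(any(.data$code == amputation_code()),
        "AMPUTATION", "NON_AMPUTATION"
      ),
      amp_date = if (any(.data$code == amputation_code())) {
        min(.data$date[.data$code == amputation_code()])
      } else {
        as.Date(NA)
      }
    ) |>
    dplyr::ungroup()

  tr <- ev |>
    dplyr::filter(
      .data$code %in% treatment_codes(),
      is.na(.data$amp_date) | .data$date < .data$amp_date
    ) |>
    dplyr::arrange(.data$person_id, .data$date, treatment_rank(.data$code)) |>
    dplyr::distinct(.data$person_id, .data$code, .keep_all = TRUE)

  seqs <- tr |>
    dplyr::group_by(.data$person_id, .data$outcome) |>
    dplyr::summarise(steps = list(.data$code), .groups = "drop")

  all_ids <- unique(events$person_id)
  n_input <- length(all_ids)
  known <- if (is.null(persons)) character() else persons$person_id
  seqs$has_attributes <- seqs$person_id %in% known
  seqs <- seqs[, c("person_id", "outcome", "steps", "has_attributes")]

  n_amp <- sum(seqs$outcome == "AMPUTATION")
  n_non <- sum(seqs$outcome == "NON_AMPUTATION")
  report <- tibble(
    n_input_patients = n_input,
    n_excluded_no_treatment = n_input - nrow(seqs),
    n_amputation = n_amp,
    n_non_amputation = n_non
  )
  list(sequences = seqs, report = report)
}
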