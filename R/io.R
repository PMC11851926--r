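#' Read a clinical event table
#'
#' Reads a delimited text file of dated, categorized clinical events: one
#' row per event, with a person identifier, an event code (one of the six
#' treatment categories or `AMPUTATION`), and an ISO-8601 date. Column
#' names are mapped via `columns`, defaulting to
#' `person_id` / `event_code` / `event_date`. Row order is preserved.
#'
#' In strict mode (the default) an unknown event code or unparseable date
#' aborts with the offending line number; in lenient mode such rows are
#' dropped with a warning naming how many were skipped. Silent data loss
#' is never the default.
#'
#' @param path Path to the file.
#' @param delim Field delimiter; `NULL` (default) picks tab when the
#'   header contains a tab, else comma.
#' @param columns Named character vector mapping the roles
#'   `person_id`, `code`, `date` to column names in the file.
#' @param strict Logical; abort on bad rows (`TRUE`) or skip them with a
#'   warning (`FALSE`).
#' @return A tibble with columns `person_id` (character), `code`
#'   (character, vocabulary form) and `date` (`Date`), in file order.
#' @seealso [read_persons()], [treatment_codes()]
#' @export
read_events <- function(path, delim = NULL,
                        columns = c(
                          person_id = "person_id",
                          code = "event_code",
                          date = "event_date"
                        ),
                        strict = TRUE) {
  raw <- read_delim_quiet(path, delim)
  need <- unname(columns[c("person_id", "code", "date")])
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop(
      "event table ", path, " lacks required column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  out <- tibble(
    person_id = as.character(raw[[columns[["person_id"]]]]),
    code = normalize_code(raw[[columns[["code"]]]]),
    date = suppressWarnings(as.Date(as.character(raw[[columns[["date"]]]]),
      format = "%Y-%m-%d"
    ))
  )
  bad_code <- which(is.na(out$code))
  bad_date <- which(is.na(out$date) & !is.na(raw[[columns[["date"]]]]))
  bad <- sort(union(bad_code, bad_date))
  if (length(bad) > 0) {
    # +1: line numbers are reported relative to the file, whose first line
    # is the header
    if (strict) {
      first <- bad[1]
      what <- if (first %in% bad_code) {
        paste0("unknown event code ", sQuote(raw[[columns[["code"]]]][first]))
      } else {
        paste0("unparseable date ", sQuote(raw[[columns[["date"]]]][first]))
      }
      stop("line ", first + 1, " of ", path, ": ", what, call. = FALSE)
    }
    warning(
      "skipped ", length(bad), " row(s) with unknown codes or bad dates ",
      "(lines ", paste(head(bad + 1, 5), collapse = ", "),
      if (length(bad) > 5) ", ..." else "", ")",
      call. = FALSE
    )
    out <- out[-bad, ]
  }
  out
}

#' Read a person attribute table
#'
#' Reads a delimited table of per-patient attributes: `person_id`, `age`
#' (integer years), `gender`, `race`, `smoker` (logical), and one logical
#' column per comorbidity flag (`diabetes`, `hypertension`,
#' `heart_failure`, `cerebrovascular_disease`, `coronary_artery_disease`,
#' `hyperlipidemia`). Duplicate person ids and negative ages are errors.
#'
#' @inheritParams read_events
#' @return A tibble, one row per person.
#' @export
read_persons <- function(path, delim = NULL) {
  raw <- read_delim_quiet(path, delim)
  need <- c("person_id", "age", "gender", "race", "smoker",
            tolower(comorbidity_flags()))
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop(
      "person table ", path, " lacks required column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  out <- tibble(
    person_id = as.character(raw$person_id),
    age = as.integer(raw$age),
    gender = as.character(raw$gender),
    race = as.character(raw$race),
    smoker = as_flag(raw$smoker)
  )
  for (flag in tolower(comorbidity_flags())) {
    out[[flag]] <- as_flag(raw[[flag]])
  }
  dup <- unique(out$person_id[duplicated(out$person_id)])
  if (length(dup) > 0) {
    stop("duplicate person_id in ", path, ": ",
      paste(head(dup, 5), collapse = ", "),
      call. = FALSE
    )
  }
  if (any(!is.na(out$age) & out$age < 0)) {
    stop("negative age in ", path, call. = FALSE)
  }
  out
}

as_flag <- function(x) {
  if (is.logical(x)) return(x)
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[x %in% c("false", "f", "0", "no", "n")] <- FALSE
  as.logical(out)
}

read_delim_quiet <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  readr::read_delim(path,
    delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
}

#' Write and re-read pathway tables
#'
#' `write_pathway_table()` serializes a (normalized) pathway table to
#' delimited text with columns `stage1..stage6` (empty beyond the pathway
#' length), `outcome`, `count` and `rate_percent`, in deterministic order:
#' descending rate, ties broken lexicographically by pathway key.
#' `read_pathway_table()` reads such a file back into a [pathway_table]
#' object; the round trip is the identity on counts and rates.
#'
#' @param table A [pathway_table] object.
#' @param path Output (input) file path.
#' @param delim Field delimiter (default tab).
#' @return `write_pathway_table()` returns `path` invisibly;
#'   `read_pathway_table()` returns a [pathway_table].
#' @export
write_pathway_table <- function(table, path, delim = "\t") {
  stopifnot(inherits(table, "pathway_table"))
  rows <- table$rows
  if (!"rate_percent" %in% names(rows)) rows$rate_percent <- NA_real_
  stages <- t(vapply(
    rows$steps,
    function(s) c(s, rep("", 6L - length(s))),
    character(6)
  ))
  out <- as_tibble(stages, .name_repair = ~ paste0("stage", 1:6))
  out$outcome <- rows$outcome
  out$count <- rows$count
  out$rate_percent <- rows$rate_percent
  out <- out[order(-replace(out$rate_percent, is.na(out$rate_percent), -Inf),
                   pathway_key(rows$steps)), ]
  header <- sprintf(
    "# dataset=%s amputation=%d non_amputation=%d",
    table$dataset_label,
    table$cohort_sizes[["AMPUTATION"]],
    table$cohort_sizes[["NON_AMPUTATION"]]
  )
  writeLines(header, path)
  readr::write_delim(out, path, delim = delim, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_pathway_table
#' @export
read_pathway_table <- function(path, delim = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  meta <- regmatches(
    header,
    regexec("# dataset=(.*) amputation=(\\d+) non_amputation=(\\d+)", header)
  )[[1]]
  if (length(meta) != 4) stop("not a pathway table file: ", path, call. = FALSE)
  raw <- readr::read_delim(path,
    delim = delim, skip = 1, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  stage_cols <- paste0("stage", 1:6)
  steps <- lapply(seq_len(nrow(raw)), function(i) {
    s <- as.character(raw[i, stage_cols])
    s[!is.na(s) & nzchar(s)]
  })
  rows <- tibble(
    steps = steps,
    pathway = pathway_key(steps),
    outcome = raw$outcome,
    count = as.integer(raw$count),
    rate_percent = suppressWarnings(as.numeric(raw$rate_percent))
  )
  new_pathway_table(
    rows = rows,
    cohort_sizes = c(
      AMPUTATION = as.integer(meta[3]),
      NON_AMPUTATION = as.integer(meta[4])
    ),
    dataset_label = meta[2]
  )
}

#' Write and read extracted treatment sequences
#'
#' One row per patient: `person_id`, `outcome`, `step1..step6` (empty
#' beyond the sequence length).
#'
#' @param sequences A sequence tibble from [build_cohort()].
#' @param path File path.
#' @param delim Field delimiter (default tab).
#' @return `write_sequences()` returns `path` invisibly;
#'   `read_sequences()` a sequence tibble.
#' @export
write_sequences <- function(sequences, path, delim = "\t") {
  stages <- t(vapply(
    sequences$steps,
    function(s) c(s, rep("", 6L - length(s))),
    character(6)
  ))
  out <- tibble(
    person_id = sequences$person_id,
    outcome = sequences$outcome
  )
  out <- dplyr::bind_cols(out, as_tibble(stages, .name_repair = ~ paste0("step", 1:6)))
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

#' @rdname write_sequences
#' @export
read_sequences <- function(path, delim = "\t") {
  raw <- read_delim_quiet(path, delim)
  step_cols <- paste0("step", 1:6)
  steps <- lapply(seq_len(nrow(raw)), function(i) {
    s <- as.character(raw[i, step_cols])
    s[!is.na(s) & nzchar(s)]
  })
  tibble(
    person_id = as.character(raw$person_id),
    outcome = as.character(raw$outcome),
    steps = steps
  )
}

#' Write a person attribute table
#'
#' Inverse of [read_persons()]; logical flags are written as
#' `true`/`false`.
#'
#' @param persons Person tibble.
#' @param path File path.
#' @param delim Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_persons <- function(persons, path, delim = "\t") {
  out <- persons
  for (col in names(out)) {
    if (is.logical(out[[col]])) out[[col]] <- tolower(as.character(out[[col]]))
  }
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

#' Write a clinical event table
#'
#' Inverse of [read_events()] under the default column mapping.
#'
#' @param events Event tibble (`person_id`, `code`, `date`).
#' @param path File path.
#' @param delim Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, delim = "\t") {
  out <- tibble(
    person_id = events$person_id,
    event_code = events$code,
    event_date = format(events$date, "%Y-%m-%d")
  )
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}
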