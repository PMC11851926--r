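#' Define a confounder filter
#'
#' A predicate over the person attribute table used to carve the cohort
#' into strata: age cuts (`AGE_GT`, `AGE_LE` — the published strata use
#' thresholds 50, 65 and 80, but any value is accepted), gender and race
#' equality (case-insensitive), smoking status, and comorbidity flags.
#'
#' @param kind One of `"AGE_GT"`, `"AGE_LE"`, `"GENDER_EQ"`, `"RACE_EQ"`,
#'   `"SMOKER"`, `"COMORBIDITY"`.
#' @param value Threshold (age kinds), string (gender/race), comorbidity
#'   flag name from [comorbidity_flags()], or ignored for `SMOKER`.
#' @return A `confounder_filter` object with a human-readable `label`.
#' @examples
#' confounder_filter("AGE_LE", 50)
#' confounder_filter("COMORBIDITY", "HYPERTENSION")
#' @export
confounder_filter <- function(kind, value = NULL) {
  kind <- match.arg(
    kind,
    c("AGE_GT", "AGE_LE", "GENDER_EQ", "RACE_EQ", "SMOKER", "COMORBIDITY")
  )
  label <- switch(kind,
    AGE_GT = paste0("age > ", value),
    AGE_LE = paste0("age <= ", value),
    GENDER_EQ = paste0("gender = ", tolower(value)),
    RACE_EQ = paste0("race = ", tolower(value)),
    SMOKER = "smoker",
    COMORBIDITY = tolower(value)
  )
  if (kind %in% c("AGE_GT", "AGE_LE")) {
    stopifnot(is.numeric(value), length(value) == 1)
  }
  if (kind == "COMORBIDITY" &&
      !toupper(value) %in% comorbidity_flags()) {
    stop(
      "unknown comorbidity flag ", sQuote(value), "; known: ",
      paste(comorbidity_flags(), collapse = ", "),
      call. = FALSE
    )
  }
  structure(list(kind = kind, value = value, label = label),
    class = "confounder_filter"
  )
}

#' @export
print.confounder_filter <- function(x, ...) {
  cat("<confounder_filter> ", x$label, "\n", sep = "")
  invisible(x)
}

# evaluate a filter as a logical vector over the person table
filter_mask <- function(persons, filter) {
  switch(filter$kind,
    AGE_GT = !is.na(persons$age) & persons$age > filter$value,
    AGE_LE = !is.na(persons$age) & persons$age <= filter$value,
    GENDER_EQ = !is.na(persons$gender) &
      tolower(persons$gender) == tolower(filter$value),
    RACE_EQ = !is.na(persons$race) &
      tolower(persons$race) == tolower(filter$value),
    SMOKER = !is.na(persons$smoker) & persons$smoker,
    COMORBIDITY = {
      col <- tolower(filter$value)
      !is.na(persons[[col]]) & persons[[col]]
    }
  )
}

#' Select the sequences of patients satisfying a confounder predicate
#'
#' Filters never mutate sequences — they only select them. Patients whose
#' sequences lack a person-table record (or whose needed attribute is
#' missing) are dropped, with a message stating how many.
#'
#' @param sequences Sequence tibble from [build_cohort()].
#' @param persons Person attribute tibble.
#' @param filter A [confounder_filter()].
#' @return The subset of `sequences` in the stratum.
#' @export
apply_filter <- function(sequences, persons, filter) {
  stopifnot(inherits(filter, "confounder_filter"))
  keep_ids <- persons$person_id[filter_mask(persons, filter)]
  n_unknown <- sum(!sequences$person_id %in% persons$person_id)
  if (n_unknown > 0) {
    message(
      n_unknown, " patient(s) without person-table attributes dropped ",
      "from stratum ", sQuote(filter$label)
    )
  }
  sequences[sequences$person_id %in% keep_ids, , drop = FALSE]
}

#' The published stratification scheme
#'
#' The 19 strata analyzed per dataset: six age cuts, two genders, three
#' races, smoking, six comorbidities, plus the full cohort is *not*
#' included (it is the unstratified analysis).
#'
#' @return List of [confounder_filter()]s.
#' @export
standard_strata <- function() {
  c(
    lapply(comorbidity_flags(), function(f) confounder_filter("COMORBIDITY", f)),
    lapply(c(50, 65, 80), function(a) confounder_filter("AGE_GT", a)),
    lapply(c(50, 65, 80), function(a) confounder_filter("AGE_LE", a)),
    lapply(c("male", "female"), function(g) confounder_filter("GENDER_EQ", g)),
    lapply(c("white", "black", "asian"), function(r) confounder_filter("RACE_EQ", r)),
    list(confounder_filter("SMOKER"))
  )
}

#' Re-run the pathway pipeline within each confounder stratum
#'
#' For every filter: select the stratum's sequences, tabulate and
#' normalize its pathway table, and build its normalized Sankey graph.
#' Per-stratum statistics are identical to running the unstratified
#' pipeline on the pre-filtered cohort. When `out_dir` is given, each
#' stratum's pathway table and Sankey JSON are written under a
#' subdirectory, plus a master `summary.tsv`.
#'
#' @param events Event tibble for the whole cohort.
#' @param persons Person attribute tibble.
#' @param filters List of [confounder_filter()]s (default
#'   [standard_strata()]).
#' @param dataset_label Cohort label.
#' @param out_dir Optional output directory.
#' @return A `stratified_run` object: list of per-stratum summaries
#'   (`filter`, `n_amputation`, `n_non_amputation`, `pathway_table`,
#'   `sankey`) plus the master `summary` tibble.
#' @export
stratified_run <- function(events, persons, filters = standard_strata(),
                           dataset_label = "dataset", out_dir = NULL) {
  cohort <- build_cohort(events, persons)
  summaries <- lapply(filters, function(f) {
    seqs <- apply_filter(cohort$sequences, persons, f)
    tab <- cohort_normalize(count_pathways(seqs, dataset_label))
    graph <- if (nrow(seqs) > 0) {
      normalize_sankey(build_sankey(seqs, dataset_label))
    } else {
      NULL
    }
    list(
      filter = f,
      n_amputation = sum(seqs$outcome == "AMPUTATION"),
      n_non_amputation = sum(seqs$outcome == "NON_AMPUTATION"),
      pathway_table = tab,
      sankey = graph
    )
  })
  summary <- tibble(
    dataset = dataset_label,
    stratum = vapply(summaries, function(s) s$filter$label, character(1)),
    n_amputation = vapply(summaries, function(s) s$n_amputation, integer(1)),
    n_non_amputation = vapply(
      summaries, function(s) s$n_non_amputation, integer(1)
    )
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (s in summaries) {
      slug <- gsub("[^a-z0-9]+", "_", tolower(s$filter$label))
      sub <- file.path(out_dir, slug)
      dir.create(sub, showWarnings = FALSE)
      write_pathway_table(s$pathway_table, file.path(sub, "pathways.tsv"))
      if (!is.null(s$sankey)) {
        export_sankey(s$sankey, file.path(sub, "sankey.json"))
      }
    }
    readr::write_tsv(summary, file.path(out_dir, "summary.tsv"))
  }
  structure(
    list(summaries = summaries, summary = summary),
    class = "stratified_run"
  )
}

#' @export
print.stratified_run <- function(x, ...) {
  cat("<stratified_run> ", nrow(x$summary), " strata\n", sep = "")
  print(x$summary, ...)
  invisible(x)
}

#' Long-format stratum counts, with derived age bands
#'
#' Reshapes a stratified run's master summary into a long table
#' (`dataset`, `stratum`, `outcome`, `count`) suitable for grouped bar
#' plots. When the cumulative age strata `age <= 50`, `age <= 65` and
#' `age <= 80` are present, the interior bands `age 51-65` and
#' `age 66-80` are derived by differencing the cumulative counts; a
#' decreasing cumulative count is an inconsistency and errors.
#'
#' @param run A `stratified_run` (or its `summary` tibble).
#' @return Long-format tibble of counts.
#' @export
summary_counts <- function(run) {
  summary <- if (inherits(run, "stratified_run")) run$summary else run
  long <- tidyr::pivot_longer(summary,
    cols = c("n_amputation", "n_non_amputation"),
    names_to = "outcome", values_to = "count"
  )
  long$outcome <- ifelse(long$outcome == "n_amputation",
    "AMPUTATION", "NON_AMPUTATION"
  )
  cuts <- c(50, 65, 80)
  cum_labels <- paste0("age <= ", cuts)
  if (all(cum_labels %in% summary$stratum)) {
    bands <- purrr::map_dfr(c("AMPUTATION", "NON_AMPUTATION"), function(oc) {
      n_cum <- vapply(cum_labels, function(lb) {
        long$count[long$stratum == lb & long$outcome == oc][1]
      }, numeric(1))
      if (any(diff(n_cum) < 0)) {
        stop(
          "inconsistent cumulative age strata for ", oc,
          ": counts must be nondecreasing in the threshold",
          call. = FALSE
        )
      }
      tibble(
        dataset = summary$dataset[1],
        stratum = c("age 51-65", "age 66-80"),
        outcome = oc,
        count = unname(diff(n_cum))
      )
    })
    long <- dplyr::bind_rows(long, bands)
  }
  long
}
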