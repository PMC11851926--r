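new_pathway_table <- function(rows, cohort_sizes, dataset_label) {
  structure(
    list(
      dataset_label = dataset_label,
      rows = rows,
      cohort_sizes = cohort_sizes
    ),
    class = "pathway_table"
  )
}

#' Count distinct treatment pathways per outcome cohort
#'
#' Tabulates the extracted sequences into one row per distinct
#' (ordered pathway, outcome) pair with its exact patient count. Cohort
#' sizes (the denominators for [cohort_normalize()]) are the numbers of
#' included patients per outcome — one sequence per patient.
#'
#' @param sequences Sequence tibble from [build_cohort()].
#' @param dataset_label Label naming the data source (used by
#'   [compare_datasets()] and in exports).
#' @return A `pathway_table`: a list with `dataset_label`, `rows` (tibble
#'   with `steps` list-column, `pathway` key, `outcome`, `count`, and —
#'   after normalization — `rate_percent`) and `cohort_sizes` (named
#'   integer vector over the two outcomes).
#' @export
count_pathways <- function(sequences, dataset_label = "dataset") {
  sizes <- c(
    AMPUTATION = sum(sequences$outcome == "AMPUTATION"),
    NON_AMPUTATION = sum(sequences$outcome == "NON_AMPUTATION")
  )
  if (nrow(sequences) == 0) {
    rows <- tibble(
      steps = list(), pathway = character(), outcome = character(),
      count = integer()
    )
    return(new_pathway_table(rows, sizes, dataset_label))
  }
  rows <- tibble(
    pathway = pathway_key(sequences$steps),
    outcome = sequences$outcome
  ) |>
    dplyr::count(.data$pathway, .data$outcome, name = "count") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$pathway, .data$outcome)
  rows$steps <- lapply(rows$pathway, pathway_steps)
  rows <- rows[, c("steps", "pathway", "outcome", "count")]
  new_pathway_table(rows, sizes, dataset_label)
}

#' Cohort-level normalization of pathway counts to percentage rates
#'
#' Divides each pathway's count by the total number of sequences in its
#' outcome cohort and scales to percent, rounded to two decimals (half
#' away from zero). Because amputations are rare, this normalization is
#' what makes pathway prevalences comparable across the two outcome
#' cohorts.
#'
#' @param table A `pathway_table` from [count_pathways()].
#' @return The table with `rate_percent` filled in.
#' @examples
#' seqs <- tibble::tibble(
#'   person_id = as.character(1:4),
#'   outcome = c("AMPUTATION", "AMPUTATION", "NON_AMPUTATION", "NON_AMPUTATION"),
#'   steps = list("ANTIPLATELET", "ANTIPLATELET", "LIPID_LOWERING", "ANTIPLATELET")
#' )
#' cohort_normalize(count_pathways(seqs))$rows
#' @export
cohort_normalize <- function(table) {
  stopifnot(inherits(table, "pathway_table"))
  rows <- table$rows
  denom <- table$cohort_sizes[rows$outcome]
  if (any(denom == 0 & rows$count > 0)) {
    stop("outcome cohort of size 0 has pathway rows", call. = FALSE)
  }
  rows$rate_percent <- round_half_away(100 * rows$count / as.numeric(denom), 2)
  table$rows <- rows
  table
}

#' Pathways more prevalent in one outcome cohort than in the other
#'
#' Selects the rows of a normalized pathway table whose rate in the
#' favored cohort strictly exceeds the same pathway's rate in the other
#' cohort (a pathway absent from a cohort has rate 0 there), sorted by
#' favored-cohort rate descending with lexicographic pathway tie-breaks,
#' truncated to `top_k`. This reproduces the shape of the dominance
#' tables: the pathways characteristic of amputation or of non-amputation.
#'
#' @param table Normalized `pathway_table`.
#' @param favored `"AMPUTATION"` or `"NON_AMPUTATION"`.
#' @param top_k Maximum number of rows returned (default `Inf`).
#' @return Tibble of dominant rows (`pathway`, `steps`, `count`,
#'   `rate_percent`, `other_rate_percent`).
#' @export
dominant_pathways <- function(table, favored = "AMPUTATION", top_k = Inf) {
  stopifnot(inherits(table, "pathway_table"))
  favored <- match.arg(favored, outcome_levels())
  other <- setdiff(outcome_levels(), favored)
  rows <- table$rows
  if (!"rate_percent" %in% names(rows)) {
    stop("table must be normalized first (cohort_normalize)", call. = FALSE)
  }
  fav <- rows[rows$outcome == favored, ]
  oth <- rows[rows$outcome == other, c("pathway", "rate_percent")]
  names(oth)[2] <- "other_rate_percent"
  out <- dplyr::left_join(fav, oth, by = "pathway")
  out$other_rate_percent[is.na(out$other_rate_percent)] <- 0
  out <- out[out$rate_percent > out$other_rate_percent, , drop = FALSE]
  out <- out[order(-out$rate_percent, out$pathway), , drop = FALSE]
  head(out[, c("pathway", "steps", "count", "rate_percent", "other_rate_percent")],
       if (is.finite(top_k)) top_k else nrow(out))
}

#' Compare one pathway's rate across datasets
#'
#' One row per dataset with the rate of the given pathway in the given
#' outcome cohort (0 when the pathway is absent), preserving dataset
#' order.
#'
#' @param tables List of normalized `pathway_table`s with distinct
#'   `dataset_label`s.
#' @param steps Pathway as a character vector of treatment codes.
#' @param outcome Outcome cohort to compare within.
#' @param strict Require at least two datasets (default `TRUE`).
#' @return Tibble (`dataset`, `pathway`, `outcome`, `rate_percent`).
#' @export
compare_datasets <- function(tables, steps, outcome = "NON_AMPUTATION",
                             strict = TRUE) {
  outcome <- match.arg(outcome, outcome_levels())
  labels <- vapply(tables, function(t) t$dataset_label, character(1))
  if (anyDuplicated(labels)) {
    stop("dataset labels must be distinct", call. = FALSE)
  }
  if (strict && length(tables) < 2) {
    stop("need at least two datasets to compare", call. = FALSE)
  }
  key <- pathway_key(check_steps(steps))
  rate <- vapply(tables, function(t) {
    hit <- t$rows$pathway == key & t$rows$outcome == outcome
    if (any(hit)) t$rows$rate_percent[hit][1] else 0
  }, numeric(1))
  tibble(
    dataset = labels, pathway = key, outcome = outcome,
    rate_percent = rate
  )
}

#' Look up one pathway's rate in a normalized table
#'
#' Convenience accessor used throughout examples and reporting.
#'
#' @param table Normalized `pathway_table`.
#' @param steps Pathway as character vector of codes.
#' @param outcome Outcome cohort.
#' @return The rate in percent (0 if the pathway is absent).
#' @export
pathway_rate <- function(table, steps, outcome = "AMPUTATION") {
  outcome <- match.arg(outcome, outcome_levels())
  key <- pathway_key(check_steps(steps))
  hit <- table$rows$pathway == key & table$rows$outcome == outcome
  if (!any(hit)) return(0)
  table$rows$rate_percent[hit][1]
}

#' @export
print.pathway_table <- function(x, ...) {
  cat(
    "<pathway_table> ", x$dataset_label,
    ": ", x$cohort_sizes[["AMPUTATION"]], " amputation / ",
    x$cohort_sizes[["NON_AMPUTATION"]], " non-amputation patients, ",
    nrow(x$rows), " distinct (pathway, outcome) rows\n",
    sep = ""
  )
  print(x$rows, ...)
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.pathway_table <- function(x, ...) x$rows
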