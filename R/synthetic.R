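#' Declare a pathway allocation for the synthetic generator
#'
#' An allocation pins down a block of patients who all share one intended
#' first-occurrence treatment sequence and outcome. The generator
#' guarantees that extraction over its (noisy) output recovers exactly
#' `n_patients` sequences equal to `steps` for each allocation.
#'
#' @param steps Ordered character vector of treatment codes (no repeats,
#'   length 1..6).
#' @param outcome `"AMPUTATION"` or `"NON_AMPUTATION"`.
#' @param n_patients Number of patients in the block.
#' @param attributes Optional named list of person attributes forced for
#'   every patient in the block (e.g. `list(age = 45)` or
#'   `list(age = c(25, 50), hypertension = TRUE)`; a length-2 numeric is
#'   sampled as an integer uniform on that range). Unlisted attributes are
#'   sampled from the spec's distributions.
#' @return A one-row allocation tibble.
#' @export
pathway_allocation <- function(steps, outcome, n_patients, attributes = NULL) {
  steps <- check_steps(steps, "allocation steps")
  outcome <- match.arg(outcome, outcome_levels())
  stopifnot(is.numeric(n_patients), n_patients >= 0)
  tibble(
    steps = list(steps),
    outcome = outcome,
    n_patients = as.integer(n_patients),
    attributes = list(attributes)
  )
}

#' Specify a synthetic cohort
#'
#' Bundles everything [generate_cohort()] needs: the pathway allocation
#' table, the noise model, confounder prevalences, demographic sampling
#' parameters, the date model and the seed. Identical specs and seeds
#' produce byte-identical cohorts.
#'
#' The noise model has three knobs, all of which extraction must survive
#' without any change to the recovered sequences:
#' * `p_duplicate_event`: per emitted treatment, the probability of
#'   re-emitting that category at a later date (before the amputation,
#'   for amputation patients);
#' * `p_post_outcome_event`: drives extra events of any category dated
#'   after the amputation date (amputation patients only — a
#'   non-amputation patient has no outcome date, and a genuinely new
#'   late category would alter their sequence);
#' * `max_extra_events`: cap per patient on each kind of noise event.
#'
#' @param allocations Allocation tibble ([pathway_allocation()] rows bound
#'   together).
#' @param dataset_label Cohort label.
#' @param noise Named list with `p_duplicate_event`,
#'   `p_post_outcome_event`, `max_extra_events`.
#' @param confounder_prevalence Named probabilities for `smoker` and the
#'   lower-cased [comorbidity_flags()].
#' @param demographics Named list: `p_male`, `race_probs` (named,
#'   including an `other` mass), `age_mean`, `age_sd`.
#' @param date_start First possible event date.
#' @param gap_days Mean inter-event gap in days (gaps are
#'   `1 + Poisson(gap_days - 1)`, hence at least one day: event order is
#'   never tie-dependent in generated data).
#' @param seed Integer seed used by [generate_cohort()].
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(allocations,
                           dataset_label = "synthetic",
                           noise = list(
                             p_duplicate_event = 0.25,
                             p_post_outcome_event = 0.25,
                             max_extra_events = 3
                           ),
                           confounder_prevalence = c(
                             smoker = 0.45,
                             diabetes = 0.35,
                             hypertension = 0.65,
                             heart_failure = 0.2,
                             cerebrovascular_disease = 0.25,
                             coronary_artery_disease = 0.4,
                             hyperlipidemia = 0.75
                           ),
                           demographics = list(
                             p_male = 0.55,
                             race_probs = c(
                               white = 0.6, black = 0.12,
                               asian = 0.13, other = 0.15
                             ),
                             age_mean = 69, age_sd = 11
                           ),
                           date_start = as.Date("2015-01-01"),
                           gap_days = 30,
                           seed = 1L) {
  stopifnot(nrow(allocations) > 0)
  for (s in allocations$steps) check_steps(s, "allocation steps")
  probs <- c(
    noise$p_duplicate_event, noise$p_post_outcome_event,
    confounder_prevalence
  )
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (noise$max_extra_events < 0) {
    stop("max_extra_events must be nonnegative", call. = FALSE)
  }
  if (gap_days < 1) stop("gap_days must be at least 1", call. = FALSE)
  structure(
    list(
      dataset_label = dataset_label,
      allocations = allocations,
      noise = noise,
      confounder_prevalence = confounder_prevalence,
      demographics = demographics,
      date_start = as.Date(date_start),
      gap_days = gap_days,
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

#' Cohort sizes implied by a spec's allocations
#'
#' @param spec A `synthetic_spec`.
#' @return Named integer vector over the two outcomes.
#' @export
allocation_sizes <- function(spec) {
  c(
    AMPUTATION = sum(spec$allocations$n_patients[
      spec$allocations$outcome == "AMPUTATION"
    ]),
    NON_AMPUTATION = sum(spec$allocations$n_patients[
      spec$allocations$outcome == "NON_AMPUTATION"
    ])
  )
}

#' Generate a synthetic event log and person table
#'
#' Materializes a [synthetic_spec()] into patient-level clinical event and
#' attribute tables. For every allocation, exactly `n_patients` patients
#' are emitted whose first-occurrence, outcome-truncated sequence equals
#' the allocated steps; amputation patients get exactly one `AMPUTATION`
#' event dated after their last intended treatment; noise events never
#' change the extracted sequence (duplicates re-emit an already-present
#' category no earlier than its first occurrence and, for amputation
#' patients, strictly before the amputation; post-outcome events of any
#' category are dated after the amputation).
#'
#' @param spec A `synthetic_spec`.
#' @param seed Seed override; defaults to `spec$seed`.
#' @return List with `events` (tibble: `person_id`, `code`, `date`) and
#'   `persons` (attribute tibble).
#' @examples
#' spec <- synthetic_spec(
#'   pathway_allocation(c("ANTIPLATELET", "LIPID_LOWERING"), "AMPUTATION", 5),
#'   noise = list(
#'     p_duplicate_event = 0, p_post_outcome_event = 0,
#'     max_extra_events = 0
#'   )
#' )
#' generate_cohort(spec)$events
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(as.integer(seed), generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  lambda <- spec$gap_days - 1
  max_extra <- spec$noise$max_extra_events
  events_list <- list()
  persons_list <- list()
  id_offset <- 0L
  prefix <- gsub("[^A-Za-z0-9]+", "_", spec$dataset_label)

  for (k in seq_len(nrow(spec$allocations))) {
    steps <- spec$allocations$steps[[k]]
    outcome <- spec$allocations$outcome[k]
    n <- spec$allocations$n_patients[k]
    attrs <- spec$allocations$attributes[[k]]
    if (n == 0) next
    L <- length(steps)
    ids <- sprintf("%s-%06d", prefix, id_offset + seq_len(n))
    id_offset <- id_offset + n

    # strictly increasing per-patient dates: gaps of at least one day
    gaps <- matrix(1 + rpois(n * L, lambda), nrow = n, ncol = L)
    offsets <- matrix(0L, n, L)
    acc <- rep(0L, n)
    for (j in seq_len(L)) {
      acc <- acc + gaps[, j]
      offsets[, j] <- acc
    }
    ev <- tibble(
      person_id = rep(ids, each = L),
      code = rep(steps, times = n),
      date = spec$date_start + as.vector(t(offsets))
    )

    amp_date <- NULL
    if (outcome == "AMPUTATION") {
      amp_date <- spec$date_start + acc + 1 + rpois(n, lambda)
      ev <- dplyr::bind_rows(ev, tibble(
        person_id = ids, code = amputation_code(), date = amp_date
      ))
    }

    # duplicate-treatment noise: re-emit an already-present category at a
    # date in [first occurrence, horizon]; never changes first occurrences
    if (spec$noise$p_duplicate_event > 0 && max_extra > 0) {
      pick <- matrix(
        runif(n * L) < spec$noise$p_duplicate_event,
        nrow = n, ncol = L
      )
      if (max_extra < L) {
        # cap per patient: keep only the first max_extra selected steps
        pick <- t(apply(pick, 1, function(r) {
          over <- which(r)
          if (length(over) > max_extra) r[over[-seq_len(max_extra)]] <- FALSE
          r
        }))
      }
      if (any(pick)) {
        idx <- which(pick, arr.ind = TRUE)
        first <- as.numeric(spec$date_start) + offsets[idx]
        horizon <- if (outcome == "AMPUTATION") {
          as.numeric(amp_date)[idx[, 1]] - 1
        } else {
          as.numeric(spec$date_start) + acc[idx[, 1]] + spec$gap_days
        }
        dup_date <- first + floor(runif(nrow(idx)) * (horizon - first + 1))
        ev <- dplyr::bind_rows(ev, tibble(
          person_id = ids[idx[, 1]],
          code = steps[idx[, 2]],
          date = as.Date(dup_date, origin = "1970-01-01")
        ))
      }
    }

    # post-outcome noise: any category, strictly after the amputation date
    if (outcome == "AMPUTATION" && spec$noise$p_post_outcome_event > 0 &&
        max_extra > 0) {
      n_post <- rbinom(n, max_extra, spec$noise$p_post_outcome_event)
      if (sum(n_post) > 0) {
        who <- rep(seq_len(n), n_post)
        ev <- dplyr::bind_rows(ev, tibble(
          person_id = ids[who],
          code = sample(treatment_codes(), sum(n_post), replace = TRUE),
          date = amp_date[who] + sample.int(60, sum(n_post), replace = TRUE)
        ))
      }
    }

    ev <- ev[order(ev$person_id, ev$date, ev$code), ]
    events_list[[k]] <- ev
    persons_list[[k]] <- sample_persons(ids, attrs, spec)
  }

  list(
    events = dplyr::bind_rows(events_list),
    persons = dplyr::bind_rows(persons_list)
  )
}

# sample person attributes, honoring per-allocation explicit assignments
sample_persons <- function(ids, attrs, spec) {
  n <- length(ids)
  dem <- spec$demographics
  prev <- spec$confounder_prevalence
  out <- tibble(
    person_id = ids,
    age = pmin(pmax(as.integer(round(rnorm(n, dem$age_mean, dem$age_sd))), 18L), 100L),
    gender = sample(c("male", "female"), n, replace = TRUE,
      prob = c(dem$p_male, 1 - dem$p_male)
    ),
    race = sample(names(dem$race_probs), n, replace = TRUE,
      prob = dem$race_probs
    ),
    smoker = runif(n) < prev[["smoker"]]
  )
  for (flag in tolower(comorbidity_flags())) {
    out[[flag]] <- runif(n) < prev[[flag]]
  }
  for (nm in names(attrs)) {
    val <- attrs[[nm]]
    if (!nm %in% names(out)) {
      stop("unknown person attribute in allocation: ", nm, call. = FALSE)
    }
    if (is.numeric(val) && length(val) == 2) {
      out[[nm]] <- as.integer(floor(runif(n, val[1], val[2] + 1)))
    } else {
      out[[nm]] <- rep(val, n)
    }
  }
  out
}

#' @export
print.synthetic_spec <- function(x, ...) {
  sizes <- allocation_sizes(x)
  cat(
    "<synthetic_spec> ", x$dataset_label, ": ",
    nrow(x$allocations), " allocations, ",
    sizes[["AMPUTATION"]], " amputation / ",
    sizes[["NON_AMPUTATION"]], " non-amputation patients, seed ",
    x$seed, "\n",
    sep = ""
  )
  invisible(x)
}
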