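# terse builders shared across test files

AP <- "ANTIPLATELET"
LL <- "LIPID_LOWERING"
SC <- "SMOKING_CESSATION"
ET <- "EXERCISE_THERAPY"
ER <- "ENDOVASCULAR_REVASCULARIZATION"
RS <- "REVASCULARIZATION_SURGERY"
AMP <- "AMPUTATION"

# event tibble from parallel vectors; dates given as day offsets
ev <- function(person_id, code, day) {
  tibble::tibble(
    person_id = as.character(person_id),
    code = code,
    date = as.Date("2020-01-01") + day
  )
}

no_noise <- list(
  p_duplicate_event = 0, p_post_outcome_event = 0, max_extra_events = 0
)

heavy_noise <- list(
  p_duplicate_event = 0.9, p_post_outcome_event = 0.9, max_extra_events = 3
)

# sequence tibble straight from a list of (steps, outcome) pairs
seqs_of <- function(...) {
  pairs <- list(...)
  tibble::tibble(
    person_id = sprintf("p%03d", seq_along(pairs)),
    outcome = vapply(pairs, `[[`, character(1), 2),
    steps = lapply(pairs, `[[`, 1)
  )
}

# independent quadratic recount: for each distinct (pathway, outcome),
# count matching patients one by one
naive_pathway_counts <- function(sequences) {
  keys <- vapply(sequences$steps, paste, character(1), collapse = "|")
  combos <- unique(data.frame(
    key = keys, outcome = sequences$outcome,
    stringsAsFactors = FALSE
  ))
  combos$count <- vapply(seq_len(nrow(combos)), function(i) {
    sum(vapply(seq_len(nrow(sequences)), function(j) {
      keys[j] == combos$key[i] && sequences$outcome[j] == combos$outcome[i]
    }, logical(1)))
  }, integer(1))
  combos[order(combos$key, combos$outcome), ]
}

# independent re-statement of the stratum predicates, used as an oracle
filter_mask_for_test <- function(persons, f) {
  switch(f$kind,
    AGE_GT = persons$age > f$value,
    AGE_LE = persons$age <= f$value,
    GENDER_EQ = tolower(persons$gender) == tolower(f$value),
    RACE_EQ = tolower(persons$race) == tolower(f$value),
    SMOKER = persons$smoker,
    COMORBIDITY = persons[[tolower(f$value)]]
  ) & !is.na(persons$age)
}

# a small mixed synthetic spec used by several property tests
small_mixed_spec <- function(noise = no_noise, seed = 42) {
  synthetic_spec(
    dplyr::bind_rows(
      pathway_allocation(c(AP, LL), "AMPUTATION", 3),
      pathway_allocation(c(LL, AP, ER), "AMPUTATION", 2),
      pathway_allocation(AP, "NON_AMPUTATION", 4),
      pathway_allocation(c(AP, LL), "NON_AMPUTATION", 5),
      pathway_allocation(c(SC, ET), "NON_AMPUTATION", 2)
    ),
    noise = noise, seed = seed
  )
}
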