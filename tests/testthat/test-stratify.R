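persons_of <- function(ids, age = 70, gender = "male", race = "white",
                       smoker = FALSE, ...) {
  p <- tibble::tibble(
    person_id = ids, age = as.integer(age), gender = gender, race = race,
    smoker = smoker
  )
  flags <- list(...)
  for (f in tolower(comorbidity_flags())) {
    p[[f]] <- if (f %in% names(flags)) flags[[f]] else FALSE
  }
  p
}

test_that("age filters keep exactly the patients past the threshold", {
  seqs <- seqs_of(
    list(AP, "NON_AMPUTATION"),
    list(AP, "NON_AMPUTATION"),
    list(AP, "NON_AMPUTATION")
  )
  persons <- persons_of(seqs$person_id, age = c(49, 51, 80))
  kept <- apply_filter(seqs, persons, confounder_filter("AGE_GT", 50))
  expect_equal(nrow(kept), 2)
  kept_le <- apply_filter(seqs, persons, confounder_filter("AGE_LE", 50))
  expect_equal(nrow(kept_le), 1)
  # complementarity: > t and <= t partition the patients with known age
  expect_equal(nrow(kept) + nrow(kept_le), nrow(seqs))
})

test_that("gender and race match case-insensitively; unknown values match nothing", {
  seqs <- seqs_of(list(AP, "NON_AMPUTATION"), list(LL, "NON_AMPUTATION"))
  persons <- persons_of(seqs$person_id,
    gender = c("Male", "female"),
    race = c("White", "declined")
  )
  expect_equal(
    nrow(apply_filter(seqs, persons, confounder_filter("GENDER_EQ", "male"))), 1
  )
  expect_equal(
    nrow(apply_filter(seqs, persons, confounder_filter("RACE_EQ", "white"))), 1
  )
  expect_equal(
    nrow(apply_filter(seqs, persons, confounder_filter("RACE_EQ", "asian"))), 0
  )
})

test_that("comorbidity filters select on the boolean flag", {
  seqs <- seqs_of(
    list(AP, "AMPUTATION"), list(AP, "NON_AMPUTATION"),
    list(LL, "NON_AMPUTATION")
  )
  persons <- persons_of(seqs$person_id, hypertension = c(TRUE, TRUE, FALSE))
  kept <- apply_filter(
    seqs, persons, confounder_filter("COMORBIDITY", "HYPERTENSION")
  )
  expect_equal(nrow(kept), 2)
  expect_error(confounder_filter("COMORBIDITY", "GOUT"), "unknown comorbidity")
})

test_that("sequentially applied filters equal a single conjunctive pass", {
  g <- generate_cohort(small_mixed_spec(seed = 8))
  seqs <- build_cohort(g$events, g$persons)$sequences
  f1 <- confounder_filter("AGE_GT", 65)
  f2 <- confounder_filter("SMOKER")
  seq_then <- apply_filter(apply_filter(seqs, g$persons, f1), g$persons, f2)
  both <- g$persons$person_id[
    filter_mask_for_test(g$persons, f1) & filter_mask_for_test(g$persons, f2)
  ]
  expect_setequal(seq_then$person_id, intersect(seqs$person_id, both))
})

test_that("patients missing from the person table drop out of strata with a message", {
  seqs <- seqs_of(list(AP, "NON_AMPUTATION"), list(LL, "NON_AMPUTATION"))
  persons <- persons_of(seqs$person_id[1], age = 70)
  expect_message(
    kept <- apply_filter(seqs, persons, confounder_filter("AGE_GT", 50)),
    "without person-table attributes"
  )
  expect_equal(kept$person_id, seqs$person_id[1])
})

test_that("stratified statistics equal the unstratified pipeline on the filtered input", {
  g <- generate_cohort(paper_fixture("starr_amputation_table2", seed = 19))
  run <- stratified_run(g$events, g$persons,
    filters = list(
      confounder_filter("AGE_GT", 65),
      confounder_filter("GENDER_EQ", "female")
    ),
    dataset_label = "STARR"
  )
  for (s in run$summaries) {
    keep <- g$persons$person_id[filter_mask_for_test(g$persons, s$filter)]
    direct <- build_cohort(
      g$events[g$events$person_id %in% keep, ], g$persons
    )
    direct_tab <- cohort_normalize(count_pathways(direct$sequences, "STARR"))
    ord <- function(t) t$rows[order(t$rows$pathway, t$rows$outcome), ]
    expect_equal(ord(s$pathway_table)$count, ord(direct_tab)$count)
    expect_equal(ord(s$pathway_table)$rate_percent, ord(direct_tab)$rate_percent)
    expect_equal(
      s$n_amputation + s$n_non_amputation,
      sum(direct_tab$cohort_sizes)
    )
  }
})

test_that("one summary row per filter, zeros for empty strata, outputs on disk", {
  g <- generate_cohort(small_mixed_spec(seed = 4))
  out_dir <- withr::local_tempdir()
  run <- stratified_run(g$events, g$persons,
    filters = list(
      confounder_filter("AGE_GT", 50),
      confounder_filter("RACE_EQ", "martian") # matches nobody
    ),
    out_dir = out_dir
  )
  expect_equal(nrow(run$summary), 2)
  empty <- run$summary[run$summary$stratum == "race = martian", ]
  expect_equal(empty$n_amputation + empty$n_non_amputation, 0)
  expect_null(run$summaries[[2]]$sankey)
  expect_true(file.exists(file.path(out_dir, "summary.tsv")))
  expect_true(file.exists(file.path(out_dir, "age_50", "pathways.tsv")))
})

test_that("summary counts derive interior age bands by cumulative differencing", {
  summary <- tibble::tibble(
    dataset = "STARR",
    stratum = c("age <= 50", "age <= 65", "age <= 80"),
    n_amputation = c(3L, 26L, 58L),
    n_non_amputation = c(265L, 1855L, 4555L)
  )
  long <- summary_counts(summary)
  band <- long[long$stratum == "age 51-65" & long$outcome == "AMPUTATION", ]
  expect_equal(band$count, 23)
  band2 <- long[long$stratum == "age 66-80" & long$outcome == "AMPUTATION", ]
  expect_equal(band2$count, 32)
  # single stratum: plain long format, no bands
  single <- summary_counts(summary[1, ])
  expect_equal(nrow(single), 2)
  # inconsistent cumulative counts error
  bad <- summary
  bad$n_amputation <- c(26L, 3L, 58L)
  expect_error(summary_counts(bad), "nondecreasing")
})
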