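test_that("pathway counts are exact multiset counts", {
  tab <- count_pathways(seqs_of(
    list(c(AP, LL), "AMPUTATION"),
    list(c(AP, LL), "AMPUTATION"),
    list(c(AP, LL), "AMPUTATION")
  ))
  expect_equal(nrow(tab$rows), 1)
  expect_equal(tab$rows$count, 3)

  empty <- count_pathways(seqs_of())
  expect_equal(nrow(empty$rows), 0)
})

test_that("counts match a naive quadratic recount on small cohorts", {
  g <- generate_cohort(small_mixed_spec(noise = heavy_noise, seed = 5))
  seqs <- build_cohort(g$events)$sequences
  expect_lte(nrow(seqs), 20)
  tab <- count_pathways(seqs)
  naive <- naive_pathway_counts(seqs)
  got <- tab$rows[order(
    vapply(tab$rows$steps, paste, character(1), collapse = "|"),
    tab$rows$outcome
  ), ]
  expect_equal(got$count, naive$count)
})

test_that("cohort normalization divides by the outcome cohort size", {
  seqs <- seqs_of(
    list(c(AP, LL), "AMPUTATION"),
    list(LL, "AMPUTATION"),
    list(LL, "AMPUTATION"),
    list(AP, "NON_AMPUTATION")
  )
  tab <- cohort_normalize(count_pathways(seqs))
  expect_equal(pathway_rate(tab, c(AP, LL), "AMPUTATION"), 33.33)
  expect_equal(pathway_rate(tab, LL, "AMPUTATION"), 66.67)
  expect_equal(pathway_rate(tab, AP, "NON_AMPUTATION"), 100)
  # absent pathway has rate 0
  expect_equal(pathway_rate(tab, SC, "AMPUTATION"), 0)
})

test_that("rounding is half away from zero at two decimals", {
  # 6 of 77 prints as 7.79, 20 of 77 as 25.97
  seqs <- dplyr::bind_rows(
    do.call(seqs_of, rep(list(list(c(AP, LL, ER), "AMPUTATION")), 6)),
    do.call(seqs_of, rep(list(list(c(AP, LL), "AMPUTATION")), 20)),
    do.call(seqs_of, rep(list(list(LL, "AMPUTATION")), 51))
  )
  seqs$person_id <- sprintf("q%03d", seq_len(nrow(seqs)))
  tab <- cohort_normalize(count_pathways(seqs))
  expect_equal(pathway_rate(tab, c(AP, LL, ER), "AMPUTATION"), 7.79)
  expect_equal(pathway_rate(tab, c(AP, LL), "AMPUTATION"), 25.97)
})

test_that("rates sum to 100 per outcome within rounding tolerance", {
  g <- generate_cohort(paper_fixture("starr_amputation_table2", seed = 31))
  tab <- cohort_normalize(count_pathways(build_cohort(g$events)$sequences))
  for (oc in outcome_levels()) {
    rows <- tab$rows[tab$rows$outcome == oc, ]
    if (nrow(rows) == 0) next
    expect_equal(sum(rows$count), unname(tab$cohort_sizes[oc]))
    expect_lt(abs(sum(rows$rate_percent) - 100), 0.05 * nrow(rows) + 1e-9)
  }
})

test_that("rates are invariant under k-fold patient duplication", {
  seqs <- seqs_of(
    list(c(AP, LL), "AMPUTATION"),
    list(LL, "AMPUTATION"),
    list(AP, "NON_AMPUTATION"),
    list(c(SC, ET), "NON_AMPUTATION")
  )
  tripled <- dplyr::bind_rows(seqs, seqs, seqs)
  tripled$person_id <- sprintf("d%03d", seq_len(nrow(tripled)))
  t1 <- cohort_normalize(count_pathways(seqs))
  t3 <- cohort_normalize(count_pathways(tripled))
  ord <- function(t) t$rows[order(t$rows$pathway, t$rows$outcome), ]
  expect_equal(ord(t1)$rate_percent, ord(t3)$rate_percent)
})

test_that("zero-size cohort with rows errors on normalization", {
  tab <- count_pathways(seqs_of(list(AP, "AMPUTATION")))
  tab$cohort_sizes["AMPUTATION"] <- 0L
  expect_error(cohort_normalize(tab), "size 0")
})

test_that("dominant pathways require a strict rate advantage", {
  seqs <- dplyr::bind_rows(
    seqs_of(
      list(c(AP, LL, ER), "AMPUTATION"), # only in amputation cohort
      list(c(AP, LL), "AMPUTATION"),
      list(SC, "AMPUTATION"),
      list(SC, "AMPUTATION")
    ),
    seqs_of(
      list(SC, "NON_AMPUTATION"),
      list(SC, "NON_AMPUTATION"),
      list(LL, "NON_AMPUTATION"),
      list(LL, "NON_AMPUTATION")
    )
  )
  seqs$person_id <- sprintf("s%03d", seq_len(nrow(seqs)))
  tab <- cohort_normalize(count_pathways(seqs))
  dom <- dominant_pathways(tab, "AMPUTATION")
  # brute-force comparison over all amputation rows
  amp <- tab$rows[tab$rows$outcome == "AMPUTATION", ]
  want <- vapply(amp$pathway, function(p) {
    other <- tab$rows$rate_percent[
      tab$rows$pathway == p & tab$rows$outcome == "NON_AMPUTATION"
    ]
    amp$rate_percent[amp$pathway == p] > ifelse(length(other), other, 0)
  }, logical(1))
  expect_setequal(dom$pathway, amp$pathway[want])
  # SC has equal rates (50 vs 50): excluded by strictness
  expect_false(pathway_key(SC) %in% dom$pathway)
  # sorted by favored rate descending; top_k truncates
  expect_equal(dom$rate_percent, sort(dom$rate_percent, decreasing = TRUE))
  expect_equal(nrow(dominant_pathways(tab, "AMPUTATION", top_k = 1)), 1)
})

test_that("cross-dataset comparison reports one rate per dataset, zeros when absent", {
  t_a <- cohort_normalize(count_pathways(
    seqs_of(
      list(c(AP, LL), "NON_AMPUTATION"),
      list(LL, "NON_AMPUTATION")
    ),
    dataset_label = "A"
  ))
  t_b <- cohort_normalize(count_pathways(
    seqs_of(list(LL, "NON_AMPUTATION")),
    dataset_label = "B"
  ))
  cmp <- compare_datasets(list(t_a, t_b), c(AP, LL), "NON_AMPUTATION")
  expect_equal(cmp$dataset, c("A", "B"))
  expect_equal(cmp$rate_percent, c(50, 0))
  expect_error(compare_datasets(list(t_a), c(AP, LL)), "two datasets")
  expect_equal(
    nrow(compare_datasets(list(t_a), c(AP, LL), strict = FALSE)), 1
  )
  t_b$dataset_label <- "A"
  expect_error(compare_datasets(list(t_a, t_b), c(AP, LL)), "distinct")
})
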