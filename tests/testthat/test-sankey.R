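test_that("one sequence builds a chain of stage-indexed links to its outcome", {
  g <- build_sankey(seqs_of(list(c(AP, LL), "AMPUTATION")))
  expect_equal(nrow(g$nodes), 3)
  expect_equal(nrow(g$links), 2)
  expect_equal(g$links$raw_count, c(1L, 1L))
  expect_equal(g$nodes$stage, c(1L, 2L, 3L))
  # both links colored by the amputation outcome
  expect_equal(unique(g$links$color), unname(outcome_colors()["AMPUTATION"]))
})

test_that("same treatment at different stages yields distinct nodes", {
  g <- build_sankey(seqs_of(
    list(c(AP, LL), "NON_AMPUTATION"),
    list(c(LL, AP), "NON_AMPUTATION")
  ))
  labels <- paste(g$nodes$stage, g$nodes$label)
  expect_true(all(c("1 ANTIPLATELET", "2 ANTIPLATELET") %in% labels))
  expect_equal(anyDuplicated(labels), 0)
})

test_that("links connect adjacent stages or go to the terminal outcome", {
  g <- build_sankey(seqs_of(
    list(c(AP, LL, ER), "AMPUTATION"),
    list(AP, "NON_AMPUTATION")
  ))
  stage_of <- setNames(g$nodes$stage, g$nodes$node_id)
  terminal <- max(g$nodes$stage)
  for (i in seq_len(nrow(g$links))) {
    s <- stage_of[g$links$source[i]]
    t <- stage_of[g$links$target[i]]
    expect_true(t == s + 1 || t == terminal)
  }
  # terminal stage holds exactly the outcome labels present
  expect_setequal(
    g$nodes$label[g$nodes$stage == terminal],
    c("AMPUTATION", "NON_AMPUTATION")
  )
})

test_that("raw link counts equal brute-force adjacent-pair counting", {
  g <- generate_cohort(small_mixed_spec(noise = heavy_noise, seed = 21))
  seqs <- build_cohort(g$events)$sequences
  graph <- build_sankey(seqs)
  # oracle: enumerate every patient's chain and count pairs by hand
  pair_count <- list()
  for (i in seq_len(nrow(seqs))) {
    s <- seqs$steps[[i]]
    chain <- c(
      paste0("s", seq_along(s), ":", s),
      paste0("s", max(lengths(seqs$steps)) + 1, ":", seqs$outcome[i])
    )
    for (j in seq_len(length(chain) - 1)) {
      k <- paste(chain[j], chain[j + 1], seqs$outcome[i])
      prev <- pair_count[[k]]
      pair_count[[k]] <- (if (is.null(prev)) 0L else prev) + 1L
    }
  }
  for (i in seq_len(nrow(graph$links))) {
    k <- paste(
      graph$links$source[i], graph$links$target[i], graph$links$outcome[i]
    )
    expect_equal(graph$links$raw_count[i], pair_count[[k]])
  }
})

test_that("raw counts conserve flow at internal nodes and cohort sizes at terminals", {
  g <- generate_cohort(paper_fixture("allofus_table4", seed = 17))
  seqs <- build_cohort(g$events)$sequences
  graph <- build_sankey(seqs)
  terminal <- max(graph$nodes$stage)
  for (i in seq_len(nrow(graph$nodes))) {
    nid <- graph$nodes$node_id[i]
    if (graph$nodes$stage[i] == terminal) next
    incoming <- sum(graph$links$raw_count[graph$links$target == nid])
    outgoing <- sum(graph$links$raw_count[graph$links$source == nid])
    if (graph$nodes$stage[i] > 1) {
      expect_equal(incoming, outgoing)
    }
  }
  for (oc in outcome_levels()) {
    tid <- paste0("s", terminal, ":", oc)
    expect_equal(
      sum(graph$links$raw_count[graph$links$target == tid]),
      sum(seqs$outcome == oc)
    )
  }
})

test_that("node normalization makes outgoing flows sum to one everywhere", {
  seqs <- seqs_of(
    list(c(AP, LL), "AMPUTATION"),
    list(c(AP, ER), "NON_AMPUTATION"),
    list(c(AP, LL), "NON_AMPUTATION"),
    list(AP, "NON_AMPUTATION")
  )
  graph <- normalize_sankey(build_sankey(seqs))
  sums <- tapply(graph$links$node_value, graph$links$source, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # cohort_value uses the outcome cohort of each link
  l <- graph$links
  amp_l <- l[l$outcome == "AMPUTATION" & grepl("AMPUTATION$", l$target), ]
  expect_equal(amp_l$cohort_value, amp_l$raw_count / 1)
  # mixed-outcome node: stage-1 AP fans out across both colors, still sums to 1
  ap1 <- l[l$source == "s1:ANTIPLATELET", ]
  expect_gt(length(unique(ap1$outcome)), 1)
  expect_equal(sum(ap1$node_value), 1)
  # single outgoing link gets node_value 1
  lone <- normalize_sankey(build_sankey(seqs_of(list(c(SC, ET), "AMPUTATION"))))
  expect_true(all(lone$links$node_value == 1))
})

test_that("hand-checked node normalization on a three-patient example", {
  # 1 amputation (AP -> outcome), 2 non-amputation (AP -> outcome):
  # cohort values at s1:AP are 1/1 = 1 and 2/2 = 1; node values 0.5, 0.5
  seqs <- seqs_of(
    list(AP, "AMPUTATION"),
    list(AP, "NON_AMPUTATION"),
    list(AP, "NON_AMPUTATION")
  )
  graph <- normalize_sankey(build_sankey(seqs))
  expect_equal(sort(graph$links$node_value), c(0.5, 0.5))
})

test_that("JSON export round-trips and is byte-deterministic", {
  g <- generate_cohort(small_mixed_spec(seed = 3))
  graph <- normalize_sankey(build_sankey(
    build_cohort(g$events)$sequences, "toy"
  ))
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  export_sankey(graph, p1)
  export_sankey(graph, p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- read_sankey(p1)
  expect_equal(back$dataset_label, "toy")
  ord_n <- function(n) n[order(n$node_id), ]
  expect_equal(ord_n(back$nodes), ord_n(graph$nodes), ignore_attr = TRUE)
  ord_l <- function(l) l[order(l$source, l$target, l$outcome), ]
  expect_equal(
    ord_l(back$links), ord_l(graph$links),
    ignore_attr = TRUE
  )
  # empty graph still exports valid JSON with empty arrays
  p3 <- withr::local_tempfile(fileext = ".json")
  export_sankey(normalize_sankey(build_sankey(seqs_of())), p3)
  parsed <- jsonlite::fromJSON(p3)
  expect_equal(length(parsed$nodes), 0)
  expect_equal(length(parsed$links), 0)
})
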