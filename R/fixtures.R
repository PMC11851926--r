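#' Back-solve a patient count from a printed percentage rate
#'
#' Published pathway tables report cohort-normalized rates, not counts.
#' Given the printed rate, the cohort size and the printed precision,
#' this recovers the integer count `k` with
#' `round(100 * k / n, digits) == rate` (rounding half away from zero).
#' When several counts round to the same printed rate the smallest is
#' returned with a warning; when none does, it is an error (the printed
#' rate is inconsistent with the stated cohort size).
#'
#' @param rate Printed percentage (0-100 scale).
#' @param n Cohort size.
#' @param digits Decimal places of the printed rate.
#' @return Integer count.
#' @examples
#' back_solve_count(7.79, 77) # 6
#' back_solve_count(6.25, 176) # 11
#' @export
back_solve_count <- function(rate, n, digits = 2) {
  k <- 0:n
  hits <- k[round_half_away(100 * k / n, digits) == rate]
  if (length(hits) == 0) {
    stop(
      "no count in 0..", n, " rounds to ", rate, "% at ", digits,
      " decimals",
      call. = FALSE
    )
  }
  if (length(hits) > 1) {
    warning(
      "ambiguous back-solve: counts ", paste(hits, collapse = ", "),
      " all print as ", rate, "% of ", n, "; using the smallest",
      call. = FALSE
    )
  }
  hits[1]
}

# shorthand used only inside fixture definitions
.tc <- c(
  AP = "ANTIPLATELET", LL = "LIPID_LOWERING", SC = "SMOKING_CESSATION",
  ET = "EXERCISE_THERAPY", ER = "ENDOVASCULAR_REVASCULARIZATION",
  RS = "REVASCULARIZATION_SURGERY"
)

#' Synthetic cohort specs reconstructing the published worked examples
#'
#' Returns a ready-made [synthetic_spec()] whose documented allocation
#' counts are back-solved from the published cohort sizes and printed
#' percentage rates ([back_solve_count()]); remaining patients are filler
#' allocations that only pad the cohort to its published size (they use
#' pathways disjoint from the documented ones, and no
#' revascularization-only pathway where the source reports none). The
#' provenance of every documented allocation — printed rate, precision,
#' cohort size, solved count — is attached as the `"provenance"`
#' attribute of the returned spec.
#'
#' Available fixtures:
#' * `"starr_amputation_table2"` — the 77-patient STARR-like amputation
#'   cohort (documented pathways: rates 7.79, 5.19, 2.6, 1.3, 25.97 and
#'   15.58).
#' * `"allofus_table4"` — the 176-patient All-of-Us-like amputation
#'   cohort (rates 13.6, 6.25, 3.98, 2.84).
#' * `"starr_nonamputation_table6"` — the 5504-patient STARR-like
#'   non-amputation cohort (rates 32.29, 24.1, 16.8, 10.2).
#' * `"starr_hypertension"` — full STARR-like mixed cohort (77 + 5504)
#'   whose hypertensive stratum holds 56 amputation and 3812
#'   non-amputation patients; within the stratum, documented amputation
#'   pathway rates 1.79, 7.14 and 7.14.
#' * `"starr_age_le50"` — full STARR-like mixed cohort whose age <= 50
#'   stratum holds 3 amputation (rates 66.67 and 33.33) and 265
#'   non-amputation patients (rates 18.49, 17.36, 5.28).
#'
#' @param name Fixture id (see above).
#' @param seed Seed stored in the returned spec (default 20250121).
#' @return A `synthetic_spec` with a `"provenance"` attribute.
#' @export
paper_fixture <- function(name, seed = 20250121L) {
  builders <- list(
    starr_amputation_table2 = fixture_starr_amputation,
    allofus_table4 = fixture_allofus_amputation,
    starr_nonamputation_table6 = fixture_starr_nonamputation,
    starr_hypertension = fixture_starr_hypertension,
    starr_age_le50 = fixture_starr_age_le50
  )
  if (!name %in% names(builders)) {
    stop(
      "unknown fixture ", sQuote(name), "; available: ",
      paste(names(builders), collapse = ", "),
      call. = FALSE
    )
  }
  builders[[name]](seed)
}

# build documented allocations + provenance rows from (pathway, rate,
# digits) triples against one cohort size
solve_block <- function(triples, n, outcome, attributes = NULL) {
  alloc <- list()
  prov <- list()
  for (i in seq_along(triples)) {
    tr <- triples[[i]]
    k <- back_solve_count(tr$rate, n, tr$digits)
    alloc[[i]] <- pathway_allocation(tr$steps, outcome, k, attributes)
    prov[[i]] <- tibble(
      pathway = pathway_key(tr$steps), outcome = outcome,
      printed_rate = tr$rate, digits = tr$digits,
      cohort_n = n, solved_count = k
    )
  }
  list(alloc = dplyr::bind_rows(alloc), prov = dplyr::bind_rows(prov))
}

# filler allocations padding a cohort to size n_total
fillers <- function(n_fill, outcome, pathways, attributes = NULL) {
  if (n_fill < 0) stop("documented allocations exceed cohort size")
  if (n_fill == 0) {
    return(NULL)
  }
  sizes <- rep(n_fill %/% length(pathways), length(pathways))
  sizes[1] <- sizes[1] + n_fill %% length(pathways)
  dplyr::bind_rows(purrr::map2(
    pathways, sizes,
    function(p, s) pathway_allocation(p, outcome, s, attributes)
  ))
}

fixture_starr_amputation <- function(seed) {
  n <- 77
  doc <- solve_block(list(
    list(steps = .tc[c("AP", "LL", "ER")], rate = 7.79, digits = 2),
    list(steps = .tc[c("AP", "RS", "LL")], rate = 5.19, digits = 2),
    list(steps = .tc[c("RS", "LL", "AP")], rate = 2.6, digits = 1),
    list(steps = .tc[c("ER", "LL")], rate = 1.3, digits = 1),
    list(steps = .tc[c("AP", "LL")], rate = 25.97, digits = 2),
    list(steps = .tc["LL"], rate = 15.58, digits = 2)
  ), n, "AMPUTATION")
  fill <- fillers(n - sum(doc$alloc$n_patients), "AMPUTATION", list(
    .tc["SC"], .tc["ET"], .tc[c("AP", "SC")], .tc[c("LL", "ET")]
  ))
  spec <- synthetic_spec(dplyr::bind_rows(doc$alloc, fill),
    dataset_label = "STARR", seed = seed
  )
  attr(spec, "provenance") <- doc$prov
  spec
}

fixture_allofus_amputation <- function(seed) {
  n <- 176
  doc <- solve_block(list(
    list(steps = .tc["ER"], rate = 13.6, digits = 1),
    list(steps = .tc[c("ER", "RS")], rate = 6.25, digits = 2),
    list(steps = .tc[c("LL", "AP", "ER")], rate = 3.98, digits = 2),
    list(steps = .tc[c("AP", "LL", "ER")], rate = 2.84, digits = 2)
  ), n, "AMPUTATION")
  fill <- fillers(n - sum(doc$alloc$n_patients), "AMPUTATION", list(
    .tc["AP"], .tc["LL"], .tc[c("AP", "LL")], .tc[c("LL", "AP")]
  ))
  spec <- synthetic_spec(dplyr::bind_rows(doc$alloc, fill),
    dataset_label = "All of Us", seed = seed
  )
  attr(spec, "provenance") <- doc$prov
  spec
}

fixture_starr_nonamputation <- function(seed) {
  n <- 5504
  doc <- solve_block(list(
    list(steps = .tc[c("AP", "LL")], rate = 32.29, digits = 2),
    list(steps = .tc[c("LL", "AP")], rate = 24.1, digits = 1),
    list(steps = .tc["LL"], rate = 16.8, digits = 1),
    list(steps = .tc["AP"], rate = 10.2, digits = 1)
  ), n, "NON_AMPUTATION")
  fill <- fillers(n - sum(doc$alloc$n_patients), "NON_AMPUTATION", list(
    .tc["SC"], .tc["ET"], .tc[c("AP", "SC")], .tc[c("LL", "ET")]
  ))
  spec <- synthetic_spec(dplyr::bind_rows(doc$alloc, fill),
    dataset_label = "STARR", seed = seed
  )
  attr(spec, "provenance") <- doc$prov
  spec
}

fixture_starr_hypertension <- function(seed) {
  htn <- list(hypertension = TRUE)
  no_htn <- list(hypertension = FALSE)
  # hypertensive amputation stratum: 56 patients
  doc <- solve_block(list(
    list(steps = .tc[c("RS", "LL", "AP", "ER")], rate = 1.79, digits = 2),
    list(steps = .tc[c("AP", "RS", "LL")], rate = 7.14, digits = 2),
    list(steps = .tc[c("AP", "LL", "ER")], rate = 7.14, digits = 2)
  ), 56, "AMPUTATION", attributes = htn)
  amp_fill <- fillers(56 - sum(doc$alloc$n_patients), "AMPUTATION", list(
    .tc[c("AP", "LL")], .tc["LL"], .tc["AP"], .tc["SC"]
  ), attributes = htn)
  # hypertensive non-amputation stratum: 3812 patients (structural filler)
  non_fill <- fillers(3812, "NON_AMPUTATION", list(
    .tc[c("AP", "LL")], .tc[c("LL", "AP")], .tc["LL"], .tc["AP"]
  ), attributes = htn)
  # non-hypertensive remainder of the full 77 / 5504 cohort
  amp_rest <- fillers(77 - 56, "AMPUTATION", list(
    .tc[c("AP", "LL")], .tc["LL"], .tc["ET"]
  ), attributes = no_htn)
  non_rest <- fillers(5504 - 3812, "NON_AMPUTATION", list(
    .tc[c("AP", "LL")], .tc["SC"], .tc["ET"]
  ), attributes = no_htn)
  spec <- synthetic_spec(
    dplyr::bind_rows(doc$alloc, amp_fill, non_fill, amp_rest, non_rest),
    dataset_label = "STARR", seed = seed
  )
  attr(spec, "provenance") <- doc$prov
  spec
}

fixture_starr_age_le50 <- function(seed) {
  young <- list(age = c(25, 50))
  old <- list(age = c(51, 95))
  # age <= 50 amputation stratum: 3 patients
  doc_amp <- solve_block(list(
    list(steps = .tc[c("AP", "LL")], rate = 66.67, digits = 2),
    list(steps = .tc["AP"], rate = 33.33, digits = 2)
  ), 3, "AMPUTATION", attributes = young)
  # age <= 50 non-amputation stratum: 265 patients
  doc_non <- solve_block(list(
    list(steps = .tc["LL"], rate = 18.49, digits = 2),
    list(steps = .tc[c("LL", "AP")], rate = 17.36, digits = 2),
    list(steps = .tc[c("AP", "ER")], rate = 5.28, digits = 2)
  ), 265, "NON_AMPUTATION", attributes = young)
  non_young_fill <- fillers(
    265 - sum(doc_non$alloc$n_patients), "NON_AMPUTATION",
    list(.tc["AP"], .tc["SC"], .tc[c("AP", "LL")]),
    attributes = young
  )
  # age > 50 remainder of the full 77 / 5504 cohort
  amp_old <- fillers(77 - 3, "AMPUTATION", list(
    .tc[c("AP", "LL")], .tc["LL"], .tc[c("AP", "LL", "ER")]
  ), attributes = old)
  non_old <- fillers(5504 - 265, "NON_AMPUTATION", list(
    .tc[c("AP", "LL")], .tc[c("LL", "AP")], .tc["LL"], .tc["AP"]
  ), attributes = old)
  spec <- synthetic_spec(
    dplyr::bind_rows(
      doc_amp$alloc, doc_non$alloc, non_young_fill, amp_old, non_old
    ),
    dataset_label = "STARR", seed = seed
  )
  attr(spec, "provenance") <- dplyr::bind_rows(doc_amp$prov, doc_non$prov)
  spec
}
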