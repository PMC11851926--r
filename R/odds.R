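#' Build a pathway's 2x2 contingency table
#'
#' Cross-tabulates pathway membership against outcome. Membership means
#' the patient's full extracted sequence equals the pathway exactly
#' (ordered, no prefix/subset containment):
#' `a` = amputation patients following the pathway, `b` = non-amputation
#' patients following it, `c` and `d` their complements within each
#' outcome cohort.
#'
#' @param sequences Sequence tibble from [build_cohort()].
#' @param steps Pathway as a character vector of treatment codes.
#' @return A `contingency_table`: named list with integer cells
#'   `a`, `b`, `c`, `d`.
#' @export
contingency_for_pathway <- function(sequences, steps) {
  key <- pathway_key(check_steps(steps))
  keys <- pathway_key(sequences$steps)
  amp <- sequences$outcome == "AMPUTATION"
  a <- sum(amp & keys == key)
  b <- sum(!amp & keys == key)
  structure(
    list(a = a, b = b, c = sum(amp) - a, d = sum(!amp) - b),
    class = "contingency_table"
  )
}

#' Sample odds ratio of a 2x2 contingency table
#'
#' Computes `(a*d) / (b*c)`. When any cell is zero the Haldane-Anscombe
#' continuity correction is applied (0.5 added to all four cells) so the
#' ratio stays finite and defined; the result is flagged `corrected`.
#' An odds ratio above 1 means the pathway is associated with the
#' amputation outcome, below 1 with non-amputation.
#'
#' @param table A `contingency_table` (or a list/vector with cells
#'   `a`, `b`, `c`, `d`).
#' @return List with `estimate` (numeric) and `corrected` (logical).
#' @examples
#' odds_ratio(list(a = 20, b = 1761, c = 57, d = 3743))$estimate
#' @export
odds_ratio <- function(table) {
  cells <- as.numeric(c(table$a, table$b, table$c, table$d))
  if (length(cells) != 4 || any(is.na(cells)) || any(cells < 0)) {
    stop("contingency table needs four nonnegative cells a, b, c, d",
      call. = FALSE
    )
  }
  if (all(cells == 0)) {
    stop("odds ratio undefined: all four cells are zero", call. = FALSE)
  }
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  list(
    estimate = (cells[1] * cells[4]) / (cells[2] * cells[3]),
    corrected = corrected
  )
}

#' Convert an odds ratio to a probability
#'
#' The probability of the amputation outcome implied by an odds ratio:
#' `p = OR / (1 + OR)` (with `p = 1` for an infinite ratio). The mapping
#' is strictly increasing, takes 0.5 at OR = 1, and values are
#' conventionally reported rounded to two decimals.
#'
#' @param odds_ratio Nonnegative number (may be `Inf`).
#' @param digits Decimal places for rounding; `NULL` for no rounding.
#' @return Probability in `[0, 1]`.
#' @examples
#' or_to_probability(3.21) # 0.76
#' or_to_probability(0.62) # 0.38
#' @export
or_to_probability <- function(odds_ratio, digits = 2) {
  if (any(is.na(odds_ratio)) || any(odds_ratio < 0)) {
    stop("odds ratio must be nonnegative", call. = FALSE)
  }
  p <- ifelse(is.infinite(odds_ratio), 1, odds_ratio / (1 + odds_ratio))
  if (!is.null(digits)) p <- round_half_away(p, digits)
  p
}

#' Per-pathway odds-ratio table
#'
#' Computes an odds ratio and implied probability for each requested
#' pathway (by default every distinct pathway in the cohort), optionally
#' restricted to ratios below or above 1, sorted by odds ratio descending.
#'
#' @param sequences Sequence tibble from [build_cohort()].
#' @param pathways `"all"` (every distinct observed pathway) or a list of
#'   step vectors.
#' @param direction_filter `"all"`, `"below_1"` or `"above_1"`.
#' @param conf_level If non-`NULL`, adds a Woolf (log-normal) confidence
#'   interval at this level, computed on the (possibly corrected) cells.
#' @return Tibble with `pathway`, cells `a`..`d`, `odds_ratio`,
#'   `probability`, `corrected` (and `ci_low`/`ci_high` when requested).
#' @export
odds_table <- function(sequences, pathways = "all",
                       direction_filter = c("all", "below_1", "above_1"),
                       conf_level = NULL) {
  direction_filter <- match.arg(direction_filter)
  if (identical(pathways, "all")) {
    pathways <- unique(lapply(sequences$steps, identity))
    pathways <- pathways[!duplicated(pathway_key(pathways))]
  }
  rows <- purrr::map_dfr(pathways, function(steps) {
    ct <- contingency_for_pathway(sequences, steps)
    or <- odds_ratio(ct)
    row <- tibble(
      pathway = pathway_key(steps),
      a = ct$a, b = ct$b, c = ct$c, d = ct$d,
      odds_ratio = or$estimate,
      probability = or_to_probability(or$estimate),
      corrected = or$corrected
    )
    if (!is.null(conf_level)) {
      cells <- c(ct$a, ct$b, ct$c, ct$d)
      if (or$corrected) cells <- cells + 0.5
      se <- sqrt(sum(1 / cells))
      z <- stats::qnorm(1 - (1 - conf_level) / 2)
      row$ci_low <- exp(log(or$estimate) - z * se)
      row$ci_high <- exp(log(or$estimate) + z * se)
    }
    row
  })
  rows <- switch(direction_filter,
    all = rows,
    below_1 = rows[rows$odds_ratio < 1, , drop = FALSE],
    above_1 = rows[rows$odds_ratio > 1, , drop = FALSE]
  )
  rows[order(-rows$odds_ratio, rows$pathway), , drop = FALSE]
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
    dimnames = list(
      c("pathway", "other"),
      c("amputation", "non_amputation")
    )
  )
  print(m)
  invisible(x)
}
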