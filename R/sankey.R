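new_sankey_graph <- function(nodes, links, dataset_label) {
  structure(
    list(dataset_label = dataset_label, nodes = nodes, links = links),
    class = "sankey_graph"
  )
}

# colors named in the figure convention: deep amber for amputation flows,
# pine green for non-amputation flows
outcome_colors <- function() {
  c(AMPUTATION = "#FF8C00", NON_AMPUTATION = "#01796F")
}

#' Build a stage-indexed Sankey flow graph from treatment sequences
#'
#' Every sequence contributes one unit of flow to each adjacent-pair link
#' along `step1 -> step2 -> ... -> stepL -> outcome`. Nodes are indexed by
#' stage, so the same treatment at stage 1 and stage 2 is two distinct
#' nodes; the two outcome nodes sit in a single terminal stage that any
#' sequence's last treatment links to directly. Flows of different
#' outcomes through a shared node are kept as parallel links (link
#' identity is source, target, outcome), which is what lets the rendered
#' figure color amputation and non-amputation flows separately.
#'
#' @param sequences Sequence tibble from [build_cohort()].
#' @param dataset_label Cohort label carried into exports.
#' @return A `sankey_graph`: list with `nodes` (tibble `node_id`, `stage`,
#'   `label`) and `links` (tibble `source`, `target`, `raw_count`,
#'   `outcome`, `color`; normalization adds `cohort_value` and
#'   `node_value`).
#' @export
build_sankey <- function(sequences, dataset_label = "dataset") {
  if (nrow(sequences) == 0) {
    return(new_sankey_graph(
      tibble(node_id = character(), stage = integer(), label = character()),
      tibble(
        source = character(), target = character(), raw_count = integer(),
        outcome = character(), color = character()
      ),
      dataset_label
    ))
  }
  max_stage <- max(lengths(sequences$steps))
  terminal <- max_stage + 1L

  pairs <- purrr::map2_dfr(sequences$steps, sequences$outcome, function(s, oc) {
    l <- length(s)
    tibble(
      src_stage = seq_len(l),
      src_label = s,
      tgt_stage = c(seq_len(l)[-1], terminal),
      tgt_label = c(s[-1], oc),
      outcome = oc
    )
  })

  links <- pairs |>
    dplyr::count(
      .data$src_stage, .data$src_label, .data$tgt_stage, .data$tgt_label,
      .data$outcome,
      name = "raw_count"
    ) |>
    dplyr::mutate(
      source = paste0("s", .data$src_stage, ":", .data$src_label),
      target = paste0(
        "s", .data$tgt_stage, ":", .data$tgt_label
      ),
      color = unname(outcome_colors()[.data$outcome])
    )

  nodes <- dplyr::bind_rows(
    links |>
      dplyr::transmute(
        node_id = .data$source, stage = .data$src_stage,
        label = .data$src_label
      ),
    links |>
      dplyr::transmute(
        node_id = .data$target, stage = .data$tgt_stage,
        label = .data$tgt_label
      )
  ) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$stage, .data$label)

  links <- links |>
    dplyr::arrange(
      .data$src_stage, .data$src_label, .data$tgt_stage, .data$tgt_label,
      .data$outcome
    ) |>
    dplyr::select(
      "source", "target", "raw_count", "outcome", "color"
    )
  new_sankey_graph(nodes, links, dataset_label)
}

#' Apply cohort- and node-level normalization to a Sankey graph
#'
#' `cohort_value` divides each link's raw count by the size of its outcome
#' cohort, putting the rare amputation flows on the same footing as the
#' much larger non-amputation flows. `node_value` then rescales each
#' source node's outgoing cohort values to sum to 1, which is what makes
#' pathways through a shared node visually comparable. Node normalization
#' is defined on outgoing flows; incoming raw counts still balance
#' outgoing raw counts at every internal node (flow conservation), but
#' incoming node values need not sum to 1 — normalizing both directions
#' simultaneously is not generally satisfiable.
#'
#' @param graph A `sankey_graph` from [build_sankey()].
#' @param cohort_sizes Named vector over the outcome labels; defaults to
#'   the terminal raw-count totals of the graph itself.
#' @return The graph with `cohort_value` and `node_value` columns filled;
#'   raw counts preserved.
#' @export
normalize_sankey <- function(graph, cohort_sizes = NULL) {
  stopifnot(inherits(graph, "sankey_graph"))
  links <- graph$links
  if (nrow(links) == 0) {
    graph$links <- dplyr::mutate(links, cohort_value = numeric(0),
      node_value = numeric(0))
    return(graph)
  }
  if (is.null(cohort_sizes)) {
    terminal_ids <- paste0(
      "s", max(graph$nodes$stage), ":", outcome_levels()
    )
    cohort_sizes <- vapply(outcome_levels(), function(oc) {
      sum(links$raw_count[links$outcome == oc &
        links$target %in% terminal_ids])
    }, numeric(1))
  }
  links$cohort_value <- links$raw_count / as.numeric(cohort_sizes[links$outcome])
  links <- links |>
    dplyr::group_by(.data$source) |>
    dplyr::mutate(node_value = .data$cohort_value / sum(.data$cohort_value)) |>
    dplyr::ungroup()
  graph$links <- links[, c(
    "source", "target", "raw_count", "cohort_value", "node_value",
    "outcome", "color"
  )]
  graph
}

#' Export a Sankey graph as deterministic JSON
#'
#' Writes `{nodes: [{id, stage, label}], links: [{source, target,
#' raw_count, cohort_value, node_value, outcome, color}]}` with nodes
#' ordered by (stage, label) and links by (source, target, outcome), so
#' two exports of the same graph are byte-identical.
#'
#' @param graph A normalized `sankey_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_sankey()] for the inverse.
#' @export
export_sankey <- function(graph, path) {
  stopifnot(inherits(graph, "sankey_graph"))
  nodes <- graph$nodes[order(graph$nodes$stage, graph$nodes$label), ]
  links <- graph$links
  links <- links[order(links$source, links$target, links$outcome), ]
  payload <- list(
    dataset_label = graph$dataset_label,
    nodes = lapply(seq_len(nrow(nodes)), function(i) {
      list(
        id = nodes$node_id[i], stage = nodes$stage[i],
        label = nodes$label[i]
      )
    }),
    links = lapply(seq_len(nrow(links)), function(i) {
      out <- list(
        source = links$source[i], target = links$target[i],
        raw_count = links$raw_count[i]
      )
      if ("cohort_value" %in% names(links)) {
        out$cohort_value <- links$cohort_value[i]
        out$node_value <- links$node_value[i]
      }
      c(out, list(outcome = links$outcome[i], color = links$color[i]))
    })
  )
  json <- jsonlite::toJSON(payload,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  writeLines(json, path)
  invisible(path)
}

#' Read back a Sankey graph exported by [export_sankey()]
#'
#' @param path JSON file path.
#' @return A `sankey_graph`.
#' @export
read_sankey <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  nodes <- as_tibble(payload$nodes)
  names(nodes)[names(nodes) == "id"] <- "node_id"
  nodes$stage <- as.integer(nodes$stage)
  links <- as_tibble(payload$links)
  links$raw_count <- as.integer(links$raw_count)
  keep <- intersect(
    c("source", "target", "raw_count", "cohort_value", "node_value",
      "outcome", "color"),
    names(links)
  )
  new_sankey_graph(nodes, links[, keep], payload$dataset_label)
}

#' @export
print.sankey_graph <- function(x, ...) {
  cat(
    "<sankey_graph> ", x$dataset_label, ": ", nrow(x$nodes), " nodes, ",
    nrow(x$links), " links",
    if ("node_value" %in% names(x$links)) " (normalized)" else "",
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Plot a Sankey graph
#'
#' A simple static rendering: stages on the x axis, nodes as labeled
#' tiles, links as segments whose width is proportional to the
#' node-normalized flow, colored deep amber (amputation) or pine green
#' (non-amputation) per the outcome each flow ends in. Requires ggplot2.
#'
#' @param x A normalized `sankey_graph`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot.sankey_graph <- function(x, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting needs the ggplot2 package", call. = FALSE)
  }
  if (!"node_value" %in% names(x$links)) {
    stop("normalize the graph first (normalize_sankey)", call. = FALSE)
  }
  nodes <- x$nodes |>
    dplyr::group_by(.data$stage) |>
    dplyr::mutate(y = seq_along(.data$label)) |>
    dplyr::ungroup()
  links <- x$links |>
    dplyr::left_join(
      nodes |> dplyr::select(source = "node_id", x0 = "stage", y0 = "y"),
      by = "source"
    ) |>
    dplyr::left_join(
      nodes |> dplyr::select(target = "node_id", x1 = "stage", y1 = "y"),
      by = "target"
    )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = links,
      ggplot2::aes(
        x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1,
        linewidth = .data$node_value, color = .data$outcome
      ),
      alpha = 0.6
    ) +
    ggplot2::geom_label(
      data = nodes,
      ggplot2::aes(x = .data$stage, y = .data$y, label = .data$label),
      size = 2.5
    ) +
    ggplot2::scale_color_manual(values = outcome_colors()) +
    ggplot2::scale_linewidth(range = c(0.2, 4)) +
    ggplot2::labs(
      x = "treatment stage", y = NULL, title = x$dataset_label,
      color = "outcome", linewidth = "node-normalized flow"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.y = ggplot2::element_blank(),
      panel.grid = ggplot2::element_blank()
    )
}
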