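# Greedy enumeration of low-weight paths from the source pathway to one
# target pathway (compiled core in src/screen.cpp). The working graph holds
# the PPI gene-gene edges plus the membership edges of the two endpoint
# pathways only: pathway nodes other than the endpoints are structurally
# excluded as interior nodes, so every admissible path crosses at least one
# protein-protein interaction. Ties between equal-weight shortest paths are
# broken by lexicographic node-sequence order for determinism.

# Shared working-graph machinery. The backbone holds every node, the PPI
# edges, and the source pathway's membership edges as flat integer/double
# arrays; a target pathway's membership edges are appended per candidate (or
# per permutation sample) and the greedy enumeration runs in compiled code.
# Pathway nodes other than the two endpoints have no edges in this working
# graph, so they can never appear inside a path.
source_backbone <- function(net, source) {
  nodes <- net$nodes$node
  vid <- stats::setNames(seq_along(nodes), nodes)
  w <- stats::setNames(net$nodes$weight, nodes)
  src_m <- net$pathways[[source]]
  list(
    n = length(nodes),
    efrom = unname(c(vid[net$ppi_edges$from], rep(vid[[source]], length(src_m)), vid[src_m])),
    eto = unname(c(vid[net$ppi_edges$to], vid[src_m], rep(vid[[source]], length(src_m)))),
    ew = c(net$ppi_edges$weight, unname(w[src_m]), rep(0, length(src_m))),
    vid = vid,
    rank = as.integer(rank(nodes, ties.method = "first")),
    names = nodes,
    w = w,
    source = source
  )
}

empty_paths_tbl <- function() {
  tibble::tibble(
    pathway_id = character(), nodes = list(), node_sequence = character(),
    n_edges = integer(), l = numeric()
  )
}

# Run the greedy enumeration against one target whose membership edges are
# appended to the backbone. Returns the stored paths as a tibble (or, with
# `scores_only`, just the vector of path weight sums).
screen_target_bb <- function(bb, target, members, l_max, scores_only = FALSE) {
  tid <- bb$vid[[target]]
  mid <- unname(bb$vid[members])
  res <- screen_paths_cpp(
    bb$n,
    c(bb$efrom, rep(tid, length(mid)), mid) - 1L,
    c(bb$eto, mid, rep(tid, length(mid))) - 1L,
    c(bb$ew, unname(bb$w[members]), rep(0, length(mid))),
    bb$vid[[bb$source]] - 1L, tid - 1L, l_max, bb$rank
  )
  if (scores_only) {
    return(res$l)
  }
  node_seqs <- lapply(res$paths, function(p) bb$names[p + 1L])
  tibble::tibble(
    nodes = node_seqs,
    node_sequence = vapply(
      node_seqs, function(p) paste(p, collapse = ";"), character(1)
    ),
    n_edges = lengths(node_seqs) - 1L,
    l = res$l
  )
}

#' Enumerate significant paths from the source to one candidate pathway
#'
#' A significant path is a directed path of three or more edges from the
#' source pathway node to the candidate pathway node whose edge-weight sum
#' `l` is strictly below `l_max`. Paths are found greedily: repeatedly take
#' the minimum-weight path, store it if it has at least three edges, delete
#' its interior edges (or, for a two-edge path, its last edge) from a working
#' copy, and continue until no path below the threshold remains. Interior
#' nodes are always gene nodes, so every stored path contains at least one
#' protein-protein interaction.
#'
#' @param net An `interaction_network` from [build_network()].
#' @param source,target Pathway ids present in the network; must differ.
#' @param l_max Positive admissibility threshold on the edge-weight sum
#'   (strict: a path is kept only while `l < l_max`).
#' @return A tibble of stored paths in discovery order: `nodes` (list of node
#'   sequences), `node_sequence` (semicolon-joined), `n_edges`, `l`.
#' @export
find_significant_paths <- function(net, source, target, l_max = 0.9) {
  stopifnot(inherits(net, "interaction_network"))
  if (!is.numeric(l_max) || length(l_max) != 1 || !is.finite(l_max) || l_max <= 0) {
    stop("`l_max` must be a single positive number.", call. = FALSE)
  }
  source <- norm_id(source)
  target <- norm_id(target)
  if (identical(source, target)) {
    stop("`source` and `target` must differ.", call. = FALSE)
  }
  for (id in c(source, target)) {
    if (!id %in% names(net$pathways)) {
      stop("Unknown pathway id: ", id, call. = FALSE)
    }
  }
  bb <- source_backbone(net, source)
  screen_target_bb(bb, target, net$pathways[[target]], l_max)
}

#' Interaction score of a path collection
#'
#' The score of a candidate pathway is the sum of reciprocal path weights
#' over its significant paths, \eqn{\sum_i 1/l_i}: many short low-weight
#' connections to the source yield a large score. An empty collection scores
#' 0.
#'
#' @param paths A tibble with an `l` column (as returned by
#'   [find_significant_paths()]), or a numeric vector of path weight sums.
#' @return A single non-negative number.
#' @export
interaction_score <- function(paths) {
  l <- if (is.data.frame(paths)) paths$l else paths
  if (length(l) == 0) {
    return(0)
  }
  if (!is.numeric(l) || any(!is.finite(l)) || any(l <= 0)) {
    stop("Path weight sums must be finite and strictly positive.", call. = FALSE)
  }
  sum(1 / l)
}

new_pathway_interaction <- function(results, paths, source, l_max, stage) {
  structure(
    list(results = results, paths = paths, source = source, l_max = l_max,
      stage = stage),
    class = "pathway_interaction"
  )
}

#' Screen all candidate pathways for crosstalk with the source
#'
#' Runs [find_significant_paths()] from `source` to every other pathway node
#' and keeps candidates with at least one stored path, each scored by
#' [interaction_score()].
#'
#' @inheritParams find_significant_paths
#' @param l_max Screening threshold on the path weight sum (default 0.9).
#' @return A `pathway_interaction` object; its `results` tibble has columns
#'   `pathway_id`, `name`, `n_paths`, `score`, `empirical_p` (`NA` until
#'   [add_empirical_pvalues()] is run), and its `paths` tibble stacks the
#'   per-pathway path tables.
#' @export
screen_candidates <- function(net, source, l_max = 0.9) {
  stopifnot(inherits(net, "interaction_network"))
  source <- norm_id(source)
  if (!source %in% names(net$pathways)) {
    stop("Unknown source pathway: ", source, call. = FALSE)
  }
  candidates <- setdiff(names(net$pathways), source)
  bb <- source_backbone(net, source)
  path_tbls <- lapply(candidates, function(tgt) {
    p <- screen_target_bb(bb, tgt, net$pathways[[tgt]], l_max)
    if (nrow(p) > 0) dplyr::mutate(p, pathway_id = tgt, .before = 1) else NULL
  })
  paths <- dplyr::bind_rows(path_tbls)
  if (nrow(paths) == 0) {
    paths <- empty_paths_tbl()
    results <- tibble::tibble(
      pathway_id = character(), name = character(), n_paths = integer(),
      score = numeric(), empirical_p = numeric()
    )
  } else {
    results <- paths |>
      dplyr::group_by(.data$pathway_id) |>
      dplyr::summarise(
        n_paths = dplyr::n(), score = interaction_score(.data$l),
        .groups = "drop"
      ) |>
      dplyr::mutate(
        name = unname(net$pathway_names[.data$pathway_id]),
        empirical_p = NA_real_
      ) |>
      dplyr::select("pathway_id", "name", "n_paths", "score", "empirical_p") |>
      dplyr::arrange(dplyr::desc(.data$score), .data$pathway_id)
  }
  new_pathway_interaction(results, paths, source, l_max, stage = "screen")
}

#' Re-collect paths at a relaxed threshold and apply the two-tier filter
#'
#' For the pathways that survived screening and the permutation test, paths
#' are enumerated again at a relaxed threshold (default 1.4) so that paths
#' through moderately regulated genes are also collected, then filtered with
#' the final two-tier rule: a three-edge path is kept only if `l < 0.9`, a
#' longer path only if `l < 1.4`. Scores are recomputed on the kept paths;
#' pathways left without any kept path are dropped (with a message).
#'
#' @inheritParams find_significant_paths
#' @param selected Character vector of pathway ids to re-collect (typically
#'   `select_significant(...)$results$pathway_id`).
#' @param collect_l_max Relaxed collection threshold (default 1.4).
#' @param tier_three Final threshold for three-edge paths (default 0.9).
#' @param tier_longer Final threshold for paths of more than three edges
#'   (default 1.4).
#' @return A `pathway_interaction` object (stage `"final"`).
#' @export
collect_relaxed_and_filter <- function(net, source, selected,
                                       collect_l_max = 1.4,
                                       tier_three = 0.9, tier_longer = 1.4) {
  stopifnot(inherits(net, "interaction_network"))
  source <- norm_id(source)
  selected <- norm_id(selected)
  unknown <- setdiff(selected, names(net$pathways))
  if (length(unknown) > 0) {
    stop("Unknown pathway id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  bb <- source_backbone(net, source)
  path_tbls <- lapply(selected, function(tgt) {
    p <- screen_target_bb(bb, tgt, net$pathways[[tgt]], collect_l_max)
    if (nrow(p) > 0) dplyr::mutate(p, pathway_id = tgt, .before = 1) else NULL
  })
  paths <- dplyr::bind_rows(path_tbls)
  if (nrow(paths) > 0) {
    paths <- dplyr::filter(
      paths,
      (.data$n_edges == 3L & .data$l < tier_three) |
        (.data$n_edges > 3L & .data$l < tier_longer)
    )
  } else {
    paths <- empty_paths_tbl()
  }
  kept_ids <- unique(paths$pathway_id)
  dropped <- setdiff(selected, kept_ids)
  if (length(dropped) > 0) {
    message(
      length(dropped), " pathway(s) lost all paths under the final filter: ",
      paste(dropped, collapse = ", ")
    )
  }
  if (nrow(paths) == 0) {
    paths <- empty_paths_tbl()
    results <- tibble::tibble(
      pathway_id = character(), name = character(), n_paths = integer(),
      score = numeric(), empirical_p = numeric()
    )
  } else {
    results <- paths |>
      dplyr::group_by(.data$pathway_id) |>
      dplyr::summarise(
        n_paths = dplyr::n(), score = interaction_score(.data$l),
        .groups = "drop"
      ) |>
      dplyr::mutate(
        name = unname(net$pathway_names[.data$pathway_id]),
        empirical_p = NA_real_
      ) |>
      dplyr::select("pathway_id", "name", "n_paths", "score", "empirical_p") |>
      dplyr::arrange(dplyr::desc(.data$score), .data$pathway_id)
  }
  new_pathway_interaction(results, paths, source, collect_l_max, stage = "final")
}

#' Genes contributing to the significant path network
#'
#' @param result A `pathway_interaction` object.
#' @return Character vector: the union of interior gene nodes over all kept
#'   paths of all kept pathways.
#' @export
contributing_genes <- function(result) {
  stopifnot(inherits(result, "pathway_interaction"))
  if (nrow(result$paths) == 0) {
    return(character(0))
  }
  sort(unique(unlist(
    lapply(result$paths$nodes, function(n) n[-c(1L, length(n))]),
    use.names = FALSE
  )))
}

#' Sensitivity of the screen to the path threshold
#'
#' Repeats [screen_candidates()] over a grid of `l_max` values and summarises
#' each screen. Because the greedy enumeration visits the same path sequence
#' until the stop condition triggers, the number of detected pathways is
#' non-decreasing in `l_max`.
#'
#' @inheritParams screen_candidates
#' @param grid Strictly increasing vector of positive thresholds.
#' @return A tibble with one row per grid value: `l_max`, `n_pathways`,
#'   `n_paths`, `max_score`, `median_score`.
#' @export
threshold_sensitivity <- function(net, source, grid) {
  if (length(grid) == 0 || any(!is.finite(grid)) || any(grid <= 0) ||
    is.unsorted(grid, strictly = TRUE)) {
    stop("`grid` must be a strictly increasing vector of positive thresholds.",
      call. = FALSE
    )
  }
  purrr::map_dfr(grid, function(lm) {
    sc <- screen_candidates(net, source, l_max = lm)
    tibble::tibble(
      l_max = lm,
      n_pathways = nrow(sc$results),
      n_paths = nrow(sc$paths),
      max_score = if (nrow(sc$results) > 0) max(sc$results$score) else NA_real_,
      median_score = if (nrow(sc$results) > 0) stats::median(sc$results$score) else NA_real_
    )
  })
}

#' @export
print.pathway_interaction <- function(x, ...) {
  cat("<pathway_interaction> stage: ", x$stage,
    ", source: ", x$source, ", l_max: ", format(x$l_max), "\n",
    sep = ""
  )
  cat("  ", nrow(x$results), " pathway(s), ", nrow(x$paths), " path(s)\n", sep = "")
  if (nrow(x$results) > 0) {
    print(utils::head(x$results, 10))
  }
  invisible(x)
}

#' @method tidy pathway_interaction
#' @export
tidy.pathway_interaction <- function(x, ...) {
  x$results
}

#' @method glance pathway_interaction
#' @export
glance.pathway_interaction <- function(x, ...) {
  tibble::tibble(
    stage = x$stage,
    source = x$source,
    l_max = x$l_max,
    n_pathways = nrow(x$results),
    n_paths = nrow(x$paths),
    n_contributing_genes = length(contributing_genes(x))
  )
}

#' Plot pathway interaction scores
#'
#' Lollipop chart of per-pathway interaction scores, coloured by empirical
#' p-value when available.
#'
#' @param object A `pathway_interaction` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot pathway_interaction
#' @export
autoplot.pathway_interaction <- function(object, ...) {
  df <- object$results
  if (nrow(df) == 0) {
    stop("Nothing to plot: no pathway passed the screen.", call. = FALSE)
  }
  df <- dplyr::mutate(df,
    pathway_id = stats::reorder(.data$pathway_id, .data$score)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$pathway_id))
  if (any(!is.na(df$empirical_p))) {
    p <- p +
      ggplot2::geom_segment(
        ggplot2::aes(xend = 0, yend = .data$pathway_id),
        colour = "grey70"
      ) +
      ggplot2::geom_point(ggplot2::aes(colour = .data$empirical_p), size = 2.5) +
      ggplot2::scale_colour_viridis_c(direction = -1, name = "empirical p")
  } else {
    p <- p +
      ggplot2::geom_segment(
        ggplot2::aes(xend = 0, yend = .data$pathway_id),
        colour = "grey70"
      ) +
      ggplot2::geom_point(size = 2.5)
  }
  p +
    ggplot2::labs(
      x = expression(Score == sum(1 / l[i])), y = NULL,
      title = paste0("Pathway crosstalk with ", object$source)
    ) +
    ggplot2::theme_minimal()
}
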