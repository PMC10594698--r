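# Shared fixtures: small hand-built networks and an independent brute-force
# re-implementation of the greedy path enumeration, used as the oracle.

# A network with explicit per-gene weights. `memberships` is a named list
# pathway -> gene vector; `ppi_pairs` a two-column matrix/data.frame of
# undirected gene pairs.
toy_network <- function(weights, memberships, ppi_pairs = NULL) {
  stats <- tibble::tibble(gene_id = names(weights), weight = unname(weights))
  pw <- pathway_collection(
    pathway_id = names(memberships),
    genes = unname(memberships)
  )
  ppi <- if (is.null(ppi_pairs) || nrow(ppi_pairs) == 0) {
    tibble::tibble(gene_a = character(), gene_b = character())
  } else {
    tibble::tibble(gene_a = toupper(ppi_pairs[[1]]), gene_b = toupper(ppi_pairs[[2]]))
  }
  suppressWarnings(build_network(pw, ppi, stats))
}

# Exhaustive enumeration of simple directed source->target paths whose
# interior nodes are gene nodes, on a plain edge data frame. Deliberately
# naive and igraph-free: this is the oracle the compiled core is checked
# against.
oracle_all_paths <- function(edges, source, target, gene_nodes) {
  out <- list()
  walk <- function(node, visited, nodes, l) {
    idx <- which(edges$from == node)
    for (i in idx) {
      nxt <- edges$to[i]
      if (nxt == target) {
        out[[length(out) + 1]] <<- list(nodes = c(nodes, nxt), l = l + edges$weight[i])
      } else if (nxt %in% gene_nodes && !(nxt %in% visited)) {
        walk(nxt, c(visited, nxt), c(nodes, nxt), l + edges$weight[i])
      }
    }
  }
  walk(source, character(0), source, 0)
  out
}

# Replay of the published greedy loop on top of exhaustive enumeration:
# repeatedly take the minimum-weight path (lexicographic node-sequence
# tie-break), stop at l >= l_max, drop the last edge of 2-edge paths, store
# longer paths and drop their interior edges.
oracle_screen <- function(edges, source, target, l_max, gene_nodes) {
  stored <- list()
  drop_edge <- function(edges, a, b) {
    edges[!(edges$from == a & edges$to == b), ]
  }
  repeat {
    paths <- oracle_all_paths(edges, source, target, gene_nodes)
    if (length(paths) == 0) break
    ls <- vapply(paths, `[[`, numeric(1), "l")
    best_l <- min(ls)
    if (best_l >= l_max) break
    cand <- paths[ls == best_l]
    keys <- vapply(cand, function(p) paste(p$nodes, collapse = "\001"), character(1))
    p <- cand[[order(keys)[1]]]
    n_edges <- length(p$nodes) - 1
    if (n_edges == 2) {
      edges <- drop_edge(edges, p$nodes[2], p$nodes[3])
    } else {
      stored[[length(stored) + 1]] <- p
      for (i in 2:(n_edges - 1)) {
        edges <- drop_edge(edges, p$nodes[i], p$nodes[i + 1])
      }
    }
  }
  stored
}

# Random weighted scenario on <= 10 gene nodes with dyadic-rational weights
# (exact in binary, so path sums are associative and tie detection is exact).
random_toy_case <- function(seed) {
  set.seed(seed)
  k <- sample(4:10, 1)
  genes <- sprintf("G%02d", seq_len(k))
  weights <- stats::setNames(sample(1:1023, k, replace = TRUE) / 1024, genes)
  mem_s <- sample(genes, sample(1:3, 1))
  mem_t <- sample(genes, sample(1:3, 1))
  pairs <- t(utils::combn(genes, 2))
  pairs <- pairs[stats::runif(nrow(pairs)) < 0.35, , drop = FALSE]
  l_max <- sample(c(0.5, 0.9, 1.4, 2), 1)
  list(
    weights = weights,
    memberships = list(PS = mem_s, PT = mem_t),
    ppi = as.data.frame(pairs, stringsAsFactors = FALSE),
    l_max = l_max
  )
}

# Small planted scenario used by pipeline-level tests (fast version of the
# default study conditions).
small_planted_params <- function(seed, planted = tibble::tibble(
                                   target = 1:2, chain_length = 2,
                                   connector_t = 6, contrast = "psych"
                                 )) {
  scenario_params(
    seed = seed, n_genes = 560, n_pathways = 12,
    pathway_size_range = c(5, 8), ppi_background_density = 0.004,
    source_members = 12, planted = planted, de_genes = 300,
    n_module_pathways = 1, module_size = 200,
    group_sizes = c(control = 30, psych = 12, nonpsych = 10)
  )
}

# Null calibration configuration: no plants, exchangeable membership (the
# candidate sets partition a pool that includes the deleted-region genes).
null_calibration_params <- function(seed) {
  scenario_params(
    seed = seed, n_genes = 100, n_pathways = 8,
    pathway_size_range = c(8, 12), ppi_background_density = 0.06,
    source_members = 15,
    planted = tibble::tibble(
      target = integer(), chain_length = integer(),
      connector_t = numeric(), contrast = character()
    ),
    de_genes = 50, de_t_range = c(2.5, 4), de_placement = "background",
    n_module_pathways = 0,
    group_sizes = c(control = 30, psych = 15, nonpsych = 5)
  )
}

# Gene-level stats straight from a scenario contrast (no probe layer games).
scenario_stats <- function(scenario, contrast = "psych") {
  ct <- scenario_contrast(scenario, contrast)
  add_weights(collapse_probes_to_genes(
    welch_t_stats(ct$expr, ct$groups), scenario$probe2gene
  ))
}

# Hypergeometric mass by direct enumeration (choose() only); the moments and
# tails derived from it are the independent oracle for the ORA module.
hyper_pmf <- function(N, R, n) {
  k <- max(0, n - (N - R)):min(n, R)
  stats::setNames(choose(R, k) * choose(N - R, n - k) / choose(N, n), k)
}
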