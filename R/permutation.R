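#' Configuration for the stratified permutation test
#'
#' Empirical significance of an interaction score is assessed by rebuilding
#' the candidate pathway's membership from randomly chosen network genes,
#' keeping fixed the number of members on either side of the weight split:
#' genes with weight at or below `weight_split` (the stratum likely to form
#' cheap paths) are replaced by random genes from that same stratum, and the
#' remainder from the complementary stratum.
#'
#' @param n_samples Number of permuted networks per pathway (default 1000).
#' @param weight_split Weight boundary between the strata (default 0.8).
#' @param seed Master integer seed; each pathway derives an independent
#'   sub-stream from it by stable hashing of its id, so adding or removing a
#'   pathway never perturbs the p-values of the others.
#' @param pseudo_count If `TRUE`, report `(count + 1) / (n_samples + 1)`
#'   instead of the literal `count / n_samples` (which can return 0).
#' @param strict_below If `TRUE`, stratify by `weight < weight_split` rather
#'   than the default `weight <= weight_split`.
#' @return A list of class `permutation_config`.
#' @export
permutation_config <- function(n_samples = 1000, weight_split = 0.8, seed = 1,
                               pseudo_count = FALSE, strict_below = FALSE) {
  stopifnot(
    is.numeric(n_samples), length(n_samples) == 1, n_samples >= 1,
    is.numeric(weight_split), length(weight_split) == 1,
    weight_split > 0, weight_split < 1,
    is.numeric(seed), length(seed) == 1, is.finite(seed)
  )
  structure(
    list(
      n_samples = as.integer(n_samples), weight_split = weight_split,
      seed = as.integer(seed) %% 2147483647L,
      pseudo_count = isTRUE(pseudo_count), strict_below = isTRUE(strict_below)
    ),
    class = "permutation_config"
  )
}

# Stable 31-ary string hash modulo 2^31 - 1; used to derive per-pathway RNG
# sub-streams that do not depend on the set of pathways analysed.
hash_id <- function(id) {
  h <- 0
  for (c in utf8ToInt(id)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

pathway_subseed <- function(config, pathway_id) {
  as.integer((config$seed + hash_id(pathway_id)) %% 2147483647)
}

# Split the gene universe (and a member set) at the configured weight
# boundary; boundary genes fall in the low stratum unless `strict_below`.
stratify <- function(weights, config) {
  if (config$strict_below) weights < config$weight_split else weights <= config$weight_split
}

# Draw a stratified random replacement membership: as many low-stratum genes
# as the original membership had, and likewise for the high stratum.
sample_membership <- function(universe, universe_low, members, members_low) {
  k_low <- sum(members_low)
  k_high <- length(members) - k_low
  pool_low <- universe[universe_low]
  pool_high <- universe[!universe_low]
  if (k_low > length(pool_low)) {
    stop("Low-weight stratum has ", length(pool_low), " genes but ", k_low,
      " replacements are required.",
      call. = FALSE
    )
  }
  if (k_high > length(pool_high)) {
    stop("High-weight stratum has ", length(pool_high), " genes but ", k_high,
      " replacements are required.",
      call. = FALSE
    )
  }
  c(
    if (k_low > 0) sample(pool_low, k_low) else character(0),
    if (k_high > 0) sample(pool_high, k_high) else character(0)
  )
}

#' Replace one pathway's membership by stratified random genes
#'
#' Returns a copy of the network in which `pathway_id`'s membership edges are
#' replaced by edges to randomly chosen gene nodes, preserving the number of
#' members in the low-weight and high-weight strata (see
#' [permutation_config()]). PPI edges are untouched. The replacement universe
#' is the gene node set of the network: genes outside the network could never
#' form paths, so admitting them would only deflate null scores.
#'
#' @param net An `interaction_network`.
#' @param pathway_id Pathway whose membership is permuted.
#' @param config A [permutation_config()].
#' @return A modified `interaction_network`.
#' @export
permute_pathway_membership <- function(net, pathway_id, config = permutation_config()) {
  stopifnot(inherits(net, "interaction_network"), inherits(config, "permutation_config"))
  pathway_id <- norm_id(pathway_id)
  if (!pathway_id %in% names(net$pathways)) {
    stop("Unknown pathway id: ", pathway_id, call. = FALSE)
  }
  w <- stats::setNames(net$nodes$weight, net$nodes$node)
  universe <- net$nodes$node[net$nodes$type == "gene"]
  universe_low <- stratify(w[universe], config)
  members <- net$pathways[[pathway_id]]
  members_low <- stratify(w[members], config)
  new_members <- withr::with_seed(
    pathway_subseed(config, pathway_id),
    sample_membership(universe, universe_low, members, members_low)
  )
  net$pathways[[pathway_id]] <- new_members
  keep <- !(net$edges$relation == "member" &
    !is.na(net$edges$pathway) & net$edges$pathway == pathway_id)
  new_edges <- membership_edges(pathway_id, new_members, w)
  new_edges$relation <- "member"
  new_edges$pathway <- pathway_id
  net$edges <- dplyr::bind_rows(net$edges[keep, ], new_edges)
  net
}

#' Empirical p-value of an observed interaction score
#'
#' Rebuilds the candidate pathway's membership `n_samples` times by
#' stratified random replacement, reruns the path screen against each
#' permuted membership, and reports the fraction of permuted networks whose
#' interaction score is greater than or equal to the observed score.
#'
#' @param net An `interaction_network`.
#' @param source Source pathway id.
#' @param pathway_id Candidate pathway id.
#' @param observed_score The pathway's score from the `l_max = 0.9` screen.
#' @param config A [permutation_config()].
#' @param l_max Screening threshold used for the permuted networks; the same
#'   value as the observed screen.
#' @return A single p-value in `[0, 1]`, a multiple of `1/n_samples` (or of
#'   `1/(n_samples+1)` with `pseudo_count`).
#' @export
empirical_pvalue <- function(net, source, pathway_id, observed_score,
                             config = permutation_config(), l_max = 0.9) {
  stopifnot(inherits(net, "interaction_network"), inherits(config, "permutation_config"))
  source <- norm_id(source)
  pathway_id <- norm_id(pathway_id)
  for (id in c(source, pathway_id)) {
    if (!id %in% names(net$pathways)) {
      stop("Unknown pathway id: ", id, call. = FALSE)
    }
  }
  w <- stats::setNames(net$nodes$weight, net$nodes$node)
  universe <- net$nodes$node[net$nodes$type == "gene"]
  universe_low <- stratify(w[universe], config)
  members <- net$pathways[[pathway_id]]
  members_low <- stratify(w[members], config)
  backbone <- source_backbone(net, source)
  count <- withr::with_seed(pathway_subseed(config, pathway_id), {
    n_ge <- 0L
    for (i in seq_len(config$n_samples)) {
      perm <- sample_membership(universe, universe_low, members, members_low)
      l <- screen_target_bb(backbone, pathway_id, perm, l_max, scores_only = TRUE)
      if (interaction_score(l) >= observed_score) n_ge <- n_ge + 1L
    }
    n_ge
  })
  if (config$pseudo_count) {
    (count + 1) / (config$n_samples + 1)
  } else {
    count / config$n_samples
  }
}

#' Attach empirical p-values to a screened result
#'
#' Runs [empirical_pvalue()] for every pathway in a screen-stage
#' `pathway_interaction` result.
#'
#' @param result A `pathway_interaction` from [screen_candidates()].
#' @param net The `interaction_network` the screen was run on.
#' @param config A [permutation_config()].
#' @return `result` with its `empirical_p` column filled in.
#' @export
add_empirical_pvalues <- function(result, net, config = permutation_config()) {
  stopifnot(inherits(result, "pathway_interaction"))
  if (nrow(result$results) == 0) {
    return(result)
  }
  result$results$empirical_p <- vapply(
    seq_len(nrow(result$results)),
    function(i) {
      empirical_pvalue(
        net, result$source, result$results$pathway_id[i],
        observed_score = result$results$score[i],
        config = config, l_max = result$l_max
      )
    },
    numeric(1)
  )
  result
}

#' Keep pathways with empirical p below a cutoff
#'
#' @param result A `pathway_interaction` with `empirical_p` filled in.
#' @param alpha Strict exclusive cutoff (default 0.05).
#' @return The filtered `pathway_interaction` (paths subset accordingly).
#' @export
select_significant <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "pathway_interaction"))
  if (nrow(result$results) > 0 && any(is.na(result$results$empirical_p))) {
    stop("Run `add_empirical_pvalues()` before selecting.", call. = FALSE)
  }
  keep <- result$results$empirical_p < alpha
  result$results <- result$results[keep, ]
  result$paths <- result$paths[result$paths$pathway_id %in% result$results$pathway_id, ]
  result
}
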