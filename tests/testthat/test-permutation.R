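perm_net <- function() {
  toy_network(
    c(G1 = 0.1, G2 = 0.5, G3 = 0.95, G4 = 0.3, G5 = 0.9, G6 = 0.7),
    list(
      PS = c("G1", "G4"),
      PA = c("G1", "G2", "G3"),
      PB = c("G4", "G5", "G6")
    ),
    data.frame(a = c("G1", "G4"), b = c("G2", "G6"))
  )
}

test_that("membership replacement preserves the weight strata exactly", {
  net <- perm_net()
  cfg <- permutation_config(seed = 5)
  perm <- permute_pathway_membership(net, "PA", cfg)
  w <- stats::setNames(net$nodes$weight, net$nodes$node)
  new <- perm$pathways[["PA"]]
  expect_length(new, 3)
  # original members (0.1, 0.5, 0.95): two at or below 0.8, one above
  expect_equal(sum(w[new] <= 0.8), 2)
  expect_equal(sum(w[new] > 0.8), 1)
  # PPI edges untouched, other pathways untouched
  expect_equal(
    dplyr::filter(perm$edges, .data$relation == "ppi"),
    dplyr::filter(net$edges, .data$relation == "ppi")
  )
  expect_equal(perm$pathways[["PB"]], net$pathways[["PB"]])
  # membership edges rebuilt with the head-weight rule
  pa_edges <- dplyr::filter(perm$edges, !is.na(.data$pathway), .data$pathway == "PA")
  expect_equal(nrow(pa_edges), 6)
  expect_equal(
    sort(pa_edges$weight[pa_edges$from == "PA"]),
    sort(unname(w[new]))
  )
})

test_that("replacement is deterministic in the seed and stable across pathways", {
  net <- perm_net()
  cfg <- permutation_config(seed = 42)
  a1 <- permute_pathway_membership(net, "PA", cfg)$pathways[["PA"]]
  a2 <- permute_pathway_membership(net, "PA", cfg)$pathways[["PA"]]
  expect_identical(a1, a2)
  b <- permute_pathway_membership(net, "PA", permutation_config(seed = 43))
  # different master seed gives a different draw (this universe is large
  # enough that collision is essentially impossible)
  expect_false(identical(sort(a1), sort(b$pathways[["PA"]])) &&
    identical(a1, b$pathways[["PA"]]))
})

test_that("a closed universe permutes the same genes and keeps the score", {
  # the pathway contains every network gene, so the replacement must be a
  # permutation of the same set
  net <- toy_network(
    c(G1 = 0.1, G2 = 0.5, G3 = 0.95),
    list(PS = c("G1", "G2", "G3"), PA = c("G1", "G2", "G3")),
    data.frame(a = "G1", b = "G2")
  )
  obs <- interaction_score(find_significant_paths(net, "PS", "PA", 0.9))
  perm <- permute_pathway_membership(net, "PA", permutation_config(seed = 1))
  expect_setequal(perm$pathways[["PA"]], c("G1", "G2", "G3"))
  expect_equal(
    interaction_score(find_significant_paths(perm, "PS", "PA", 0.9)),
    obs
  )
  expect_equal(
    empirical_pvalue(net, "PS", "PA", obs, permutation_config(n_samples = 20, seed = 1)),
    1 # every permuted network is identical, so every score ties
  )
})

test_that("empirical p-values are counts over n_samples with >= comparison", {
  net <- perm_net()
  cfg <- permutation_config(n_samples = 50, seed = 7)
  # an unbeatable observed score gives p = 0 under the literal count rule
  expect_equal(empirical_pvalue(net, "PS", "PA", 1e9, cfg), 0)
  # score 0 is always tied or beaten
  expect_equal(empirical_pvalue(net, "PS", "PA", 0, cfg), 1)
  p <- empirical_pvalue(
    net, "PS", "PA",
    interaction_score(find_significant_paths(net, "PS", "PA", 0.9)), cfg
  )
  expect_true(p >= 0 && p <= 1)
  expect_equal(p * cfg$n_samples, round(p * cfg$n_samples))
  # pseudo-count variant keeps p strictly positive
  cfg2 <- permutation_config(n_samples = 50, seed = 7, pseudo_count = TRUE)
  expect_equal(empirical_pvalue(net, "PS", "PA", 1e9, cfg2), 1 / 51)
})

test_that("the strict-below flag moves boundary genes to the high stratum", {
  net <- toy_network(
    c(G1 = 0.8, G2 = 0.5, G3 = 0.9, G4 = 0.1),
    list(PS = "G4", PA = c("G1", "G2"), PB = c("G3", "G4"))
  )
  w <- stats::setNames(net$nodes$weight, net$nodes$node)
  inclusive <- permute_pathway_membership(net, "PA", permutation_config(seed = 3))
  expect_equal(sum(w[inclusive$pathways[["PA"]]] <= 0.8), 2)
  strict <- permute_pathway_membership(
    net, "PA", permutation_config(seed = 3, strict_below = TRUE)
  )
  expect_equal(sum(w[strict$pathways[["PA"]]] < 0.8), 1)
  expect_equal(sum(w[strict$pathways[["PA"]]] >= 0.8), 1)
})

test_that("selection keeps pathways strictly below alpha", {
  res <- new_screen <- screen_candidates(perm_net(), "PS", 0.9)
  res$results <- tibble::tibble(
    pathway_id = c("PA", "PB", "PC"), name = NA_character_,
    n_paths = 1L, score = 1,
    empirical_p = c(0.049, 0.05, 0.2)
  )
  res$paths <- tibble::tibble(
    pathway_id = c("PA", "PB", "PC"),
    nodes = list("x", "y", "z"), node_sequence = "s", n_edges = 3L, l = 1
  )
  kept <- select_significant(res, alpha = 0.05)
  expect_equal(kept$results$pathway_id, "PA")
  expect_equal(kept$paths$pathway_id, "PA")
  all_kept <- select_significant(res, alpha = 1.0000001)
  expect_equal(nrow(all_kept$results), 3)
  res$results$empirical_p <- NA_real_
  expect_error(select_significant(res), "add_empirical_pvalues")
})
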