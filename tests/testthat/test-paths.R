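test_that("a planted chain is found with the head-weight sum", {
  net <- toy_network(
    c(G1 = 0.2, G2 = 0.3),
    list(PS = "G1", PT = "G2"),
    data.frame(a = "G1", b = "G2")
  )
  p <- find_significant_paths(net, "PS", "PT", l_max = 0.9)
  expect_equal(nrow(p), 1)
  expect_equal(p$n_edges, 3L)
  expect_equal(p$l, 0.5)
  expect_equal(p$node_sequence, "PS;G1;G2;PT")

  # disconnected pathways yield no paths
  net2 <- toy_network(c(G1 = 0.2, G2 = 0.3), list(PS = "G1", PT = "G2"))
  expect_equal(nrow(find_significant_paths(net2, "PS", "PT")), 0)

  expect_error(find_significant_paths(net, "PS", "PS"), "differ")
  expect_error(find_significant_paths(net, "PS", "NOPE"), "Unknown")
  expect_error(find_significant_paths(net, "PS", "PT", l_max = -1), "positive")
})

test_that("two-edge shortcuts are burned, exposing longer paths", {
  # G1 belongs to both pathways: shortest is PS->G1->PT (2 edges), which is
  # never stored; deleting its last edge exposes the 3-edge chain.
  net <- toy_network(
    c(G1 = 0.1, G2 = 0.2),
    list(PS = "G1", PT = c("G1", "G2")),
    data.frame(a = "G1", b = "G2")
  )
  p <- find_significant_paths(net, "PS", "PT", l_max = 0.9)
  expect_equal(p$node_sequence, "PS;G1;G2;PT")
  expect_equal(p$l, 0.1 + 0.2)
})

test_that("interior pathway nodes are never used", {
  # A tempting zero-cost hop through a third pathway node must be ignored.
  net <- toy_network(
    c(G1 = 0.1, G2 = 0.1, G3 = 0.4),
    list(PS = "G1", PM = c("G1", "G2"), PT = c("G2", "G3")),
    data.frame(a = "G1", b = "G3")
  )
  p <- find_significant_paths(net, "PS", "PT", l_max = 2)
  expect_true(all(vapply(
    p$nodes,
    function(n) !any(n[-c(1, length(n))] %in% c("PM")),
    logical(1)
  )))
})

test_that("greedy enumeration matches the brute-force oracle on random graphs", {
  for (seed in 1:60) {
    case <- random_toy_case(seed)
    net <- toy_network(case$weights, case$memberships, case$ppi)
    if (!all(c("PS", "PT") %in% names(net$pathways))) next
    got <- find_significant_paths(net, "PS", "PT", case$l_max)
    want <- oracle_screen(
      net$edges[c("from", "to", "weight")], "PS", "PT", case$l_max,
      gene_nodes = net$nodes$node[net$nodes$type == "gene"]
    )
    expect_equal(nrow(got), length(want), info = paste("seed", seed))
    if (length(want) > 0) {
      expect_equal(
        got$node_sequence,
        vapply(want, function(p) paste(p$nodes, collapse = ";"), character(1)),
        info = paste("seed", seed)
      )
      expect_equal(got$l, vapply(want, `[[`, numeric(1), "l"),
        info = paste("seed", seed)
      )
    }
  }
})

test_that("interaction scores add reciprocals of path weights", {
  expect_equal(interaction_score(c(0.5)), 2)
  expect_equal(interaction_score(c(0.5, 1)), 3)
  expect_equal(interaction_score(numeric(0)), 0)
  expect_equal(interaction_score(tibble::tibble(l = c(0.25, 0.5))), 6)
  expect_error(interaction_score(c(0.5, 0)), "positive")
  set.seed(99)
  for (i in 1:20) {
    l <- runif(sample(1:30, 1), 0.01, 2)
    acc <- 0
    for (x in l) acc <- acc + 1 / x
    expect_equal(interaction_score(l), acc, tolerance = 1e-9)
  }
})

test_that("screening keeps candidates with at least one admissible path", {
  net <- toy_network(
    c(G1 = 0.1, G2 = 0.2, G3 = 0.9, G4 = 0.95),
    list(PS = c("G1", "G3"), PA = "G2", PB = "G4"),
    data.frame(a = c("G1", "G3"), b = c("G2", "G4"))
  )
  sc <- screen_candidates(net, "PS", l_max = 0.9)
  expect_equal(sc$results$pathway_id, "PA") # PB's only path has l = 1.85
  expect_equal(sc$results$score, 1 / 0.3)
  expect_true(is.na(sc$results$empirical_p))
  expect_s3_class(tidy(sc), "tbl_df")
  expect_equal(glance(sc)$n_pathways, 1)
})

test_that("screening finds nothing when all gene weights are near one", {
  # null genes: any 3-edge path weighs about 2
  net <- toy_network(
    c(G1 = 0.97, G2 = 0.98, G3 = 0.99),
    list(PS = "G1", PA = "G2", PB = "G3"),
    data.frame(a = c("G1", "G2"), b = c("G2", "G3"))
  )
  expect_equal(nrow(screen_candidates(net, "PS", l_max = 0.9)$results), 0)
})

test_that("the final two-tier filter keeps exactly the published set", {
  # three candidate pathways realising (3 edges, 0.95), (4 edges, 1.2),
  # (3 edges, 0.85): the first is removed, the others kept
  # B2 sits in an unrelated pathway so it exists as a node and the only
  # route into PB is the four-edge chain
  net <- toy_network(
    c(
      A1 = 0.5, A2 = 0.45,
      B1 = 0.4, B2 = 0.4, B3 = 0.4,
      C1 = 0.5, C2 = 0.35
    ),
    list(
      PS = c("A1", "B1", "C1"),
      PA = "A2", PB = "B3", PC = "C2", PX = "B2"
    ),
    data.frame(
      a = c("A1", "B1", "B2", "C1"),
      b = c("A2", "B2", "B3", "C2")
    )
  )
  out <- suppressMessages(
    collect_relaxed_and_filter(net, "PS", c("PA", "PB", "PC"))
  )
  expect_setequal(out$results$pathway_id, c("PB", "PC"))
  expect_equal(out$paths$l[out$paths$pathway_id == "PB"], 1.2)
  expect_equal(out$paths$n_edges[out$paths$pathway_id == "PB"], 4L)
  expect_equal(out$paths$l[out$paths$pathway_id == "PC"], 0.85)
  expect_message(
    collect_relaxed_and_filter(net, "PS", c("PA")),
    "lost all paths"
  )
})

test_that("contributing genes are the union of interior nodes", {
  net <- toy_network(
    c(G1 = 0.1, G2 = 0.2, G3 = 0.15, G4 = 0.97),
    list(PS = c("G1", "G3"), PA = "G2", PB = c("G2", "G4")),
    data.frame(a = c("G1", "G3"), b = c("G2", "G2"))
  )
  sc <- screen_candidates(net, "PS", l_max = 0.9)
  genes <- contributing_genes(sc)
  expect_true(all(c("G1", "G2") %in% genes))
  expect_false(any(c("PS", "PA", "PB") %in% genes))
  empty <- screen_candidates(net, "PS", l_max = 0.01)
  expect_equal(contributing_genes(empty), character(0))
})

test_that("threshold sensitivity is monotone and consistent with the screen", {
  case <- random_toy_case(7)
  net <- toy_network(case$weights, case$memberships, case$ppi)
  grid <- c(0.5, 0.9, 1.4, 2)
  sens <- threshold_sensitivity(net, "PS", grid)
  expect_equal(sens$l_max, grid)
  expect_true(all(diff(sens$n_pathways) >= 0))
  sc <- screen_candidates(net, "PS", l_max = 0.9)
  expect_equal(sens$n_pathways[2], nrow(sc$results))
  expect_equal(sens$n_paths[2], nrow(sc$paths))
  expect_error(threshold_sensitivity(net, "PS", numeric(0)), "increasing")
  expect_error(threshold_sensitivity(net, "PS", c(1, 0.5)), "increasing")
})
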