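test_that("scenario generation is fully reproducible from the seed", {
  a <- generate_scenario(small_planted_params(3))
  b <- generate_scenario(small_planted_params(3))
  expect_identical(a$pathways, b$pathways)
  expect_identical(a$ppi, b$ppi)
  expect_identical(a$expression, b$expression)
  expect_identical(a$disease, b$disease)
  expect_identical(a$truth, b$truth)
  c <- generate_scenario(small_planted_params(4))
  expect_false(identical(a$expression, c$expression))
})

test_that("planted chains have the promised layout and calibrated statistics", {
  sc <- generate_scenario(small_planted_params(5))
  stats <- scenario_stats(sc, "psych")
  t_by_gene <- stats::setNames(stats$t, stats$gene_id)
  for (i in seq_len(nrow(sc$truth$planted))) {
    chain <- sc$truth$planted$chain_genes[[i]]
    tgt <- sc$truth$planted$target_id[i]
    # first connector joins the source pathway, last the target pathway
    expect_true(chain[1] %in% sc$truth$source_members)
    expect_true(chain[length(chain)] %in%
      sc$pathways$genes[[which(sc$pathways$pathway_id == tgt)]])
    # consecutive connectors share a maximal-confidence PPI edge
    for (j in seq_len(length(chain) - 1)) {
      hit <- sc$ppi$gene_a == chain[j] & sc$ppi$gene_b == chain[j + 1]
      expect_true(any(hit & sc$ppi$combined_score == 999))
    }
    # connectors land exactly on the configured |T| level
    expect_equal(
      unname(abs(t_by_gene[chain])),
      rep(sc$truth$planted$connector_t[i], length(chain)),
      tolerance = 1e-8
    )
  }
  # deleted source members are calibrated to -deletion_t in both contrasts
  src <- setdiff(sc$truth$source_members, unlist(sc$truth$planted$chain_genes))
  expect_equal(unname(t_by_gene[src]), rep(-8, length(src)), tolerance = 1e-8)
  t_np <- stats::setNames(
    scenario_stats(sc, "nonpsych")$t,
    scenario_stats(sc, "nonpsych")$gene_id
  )
  expect_equal(unname(t_np[src]), rep(-8, length(src)), tolerance = 1e-8)
})

test_that("a planted target is screened through its chain at l = 2 w(T)", {
  sc <- generate_scenario(small_planted_params(6))
  stats <- scenario_stats(sc, "psych")
  net <- suppressWarnings(build_network(sc$pathways, filter_ppi(sc$ppi), stats))
  tgt <- sc$truth$planted$target_id[1]
  chain <- sc$truth$planted$chain_genes[[1]]
  p <- find_significant_paths(net, sc$truth$source_id, tgt, l_max = 0.9)
  chain_path <- p[p$node_sequence ==
    paste(c(sc$truth$source_id, chain, tgt), collapse = ";"), ]
  expect_equal(nrow(chain_path), 1)
  expect_equal(chain_path$l, 2 * weight_transform(6), tolerance = 1e-6)
})

test_that("an unplanted null scenario screens no pathway", {
  par <- scenario_params(
    seed = 8, n_genes = 120, n_pathways = 10,
    pathway_size_range = c(5, 8), ppi_background_density = 0.01,
    source_members = 10,
    planted = tibble::tibble(
      target = integer(), chain_length = integer(),
      connector_t = numeric(), contrast = character()
    ),
    deletion_t = 0, null_t_sd = 1, de_genes = 0, n_module_pathways = 0,
    group_sizes = c(control = 30, psych = 12, nonpsych = 8)
  )
  sc <- generate_scenario(par)
  stats <- scenario_stats(sc, "psych")
  # nearly all null genes sit above weight 0.5, so three-edge paths weigh
  # about 2 and none clears the screen threshold
  expect_gt(mean(stats$weight > 0.5), 0.9)
  net <- suppressWarnings(build_network(sc$pathways, filter_ppi(sc$ppi), stats))
  expect_equal(nrow(screen_candidates(net, "WPSRC", 0.9)$results), 0)
})

test_that("scenario bundles round-trip through plain-text files", {
  sc <- generate_scenario(small_planted_params(9))
  dir <- withr::local_tempdir()
  write_scenario(sc, dir)
  back <- read_scenario(dir)
  expect_equal(back$pathways$pathway_id, sc$pathways$pathway_id)
  expect_equal(back$pathways$genes, sc$pathways$genes)
  expect_equal(back$ppi$combined_score, sc$ppi$combined_score)
  expect_equal(back$groups, sc$groups)
  expect_equal(
    as.matrix(back$expression[-1]), as.matrix(sc$expression[-1]),
    tolerance = 1e-9
  )
  expect_equal(back$truth$source_id, sc$truth$source_id)
  expect_setequal(back$disease$geneSymbol, sc$disease$geneSymbol)
  # no NaNs anywhere in the bundle
  expect_false(any(is.na(as.matrix(sc$expression[-1]))))
})

test_that("generate_expression hits its target T in expectation", {
  genes <- sprintf("G%03d", 1:500)
  null_t <- generate_expression(
    tibble::tibble(gene_id = genes, t = 0),
    n_case = 30, n_control = 30, seed = 2
  )
  groups <- null_t$groups
  realized <- welch_t_stats(null_t$expr, groups)$t
  expect_gt(mean(abs(realized) < 3), 0.95)

  strong <- generate_expression(
    tibble::tibble(gene_id = genes, t = 8),
    n_case = 30, n_control = 30, seed = 3
  )
  realized8 <- welch_t_stats(strong$expr, strong$groups)$t
  expect_gt(mean(realized8 > 3), 0.95)
})

test_that("infeasible scenarios are rejected up front", {
  expect_error(scenario_params(n_genes = 50), "Infeasible")
  expect_error(
    scenario_params(planted = tibble::tibble(
      target = 1, chain_length = 1, connector_t = 6, contrast = "psych"
    )),
    "chain_length"
  )
  expect_error(
    scenario_params(de_genes = 10, module_size = 50),
    "module_size"
  )
})
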