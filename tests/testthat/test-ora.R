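test_that("z-score and tail probability match combinatorial enumeration", {
  set.seed(21)
  cases <- 0
  for (i in 1:400) {
    N <- sample(5:50, 1)
    R <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    r <- sample(max(0, n - (N - R)):min(n, R), 1)
    pmf <- hyper_pmf(N, R, n)
    k <- as.numeric(names(pmf))
    mu <- sum(k * pmf)
    sdv <- sqrt(sum((k - mu)^2 * pmf))
    if (sdv == 0) next
    expect_equal(ora_zscore(N, R, n, r), (r - mu) / sdv, tolerance = 1e-9)
    expect_equal(
      ora_hypergeom_p(N, R, n, r),
      sum(pmf[k >= r]),
      tolerance = 1e-9
    )
    cases <- cases + 1
  }
  expect_gt(cases, 300)
})

test_that("z-score centring, monotonicity and worked examples", {
  expect_equal(ora_zscore(100, 10, 10, 1), 0) # r equals its expectation
  expect_equal(
    ora_zscore(100, 10, 10, 5),
    (5 - 1) / sqrt(10 * 0.1 * 0.9 * (1 - 9 / 99)),
    tolerance = 1e-12
  )
  expect_lt(ora_zscore(100, 10, 10, 3), ora_zscore(100, 10, 10, 6))
  expect_error(ora_zscore(10, 10, 5, 5), "Degenerate")
  expect_error(ora_zscore(10, 5, 5, 6), "Invalid")
})

test_that("hypergeometric tail hits its exact boundary values", {
  expect_equal(ora_hypergeom_p(10, 5, 5, 0), 1)
  expect_equal(ora_hypergeom_p(10, 5, 5, 5), 1 / choose(10, 5), tolerance = 1e-12)
  p_seq <- ora_hypergeom_p(50, 20, 10, 0:10)
  expect_true(all(diff(p_seq) < 0)) # non-increasing in r
})

test_that("the ranked ORA table follows the caption rules", {
  # 12 measured genes, 6 significant; PW1 holds 3 significant of 3, PW2 2 of
  # 4 (excluded by the >= 3 rule), PW3 and PW4 are identical member sets
  stats <- tibble::tibble(
    gene_id = sprintf("G%02d", 1:12),
    t = 0, p = rep(c(0.01, 0.5), each = 6),
    log2fc = rep(c(0.5, 0.01), each = 6)
  )
  pw <- pathway_collection(
    c("PW1", "PW2", "PW3", "PW4"),
    genes = list(
      c("G01", "G02", "G03"),
      c("G04", "G05", "G07", "G08"),
      c("G04", "G05", "G06", "G09"),
      c("G04", "G05", "G06", "G09")
    )
  )
  out <- run_ora(stats, pw)
  expect_false("PW2" %in% out$pathway_id) # only two significant members
  expect_equal(out$pathway_id[1], "PW1") # densest significant set ranks first
  expect_equal(out$rank, seq_len(nrow(out)))
  dup <- out[out$pathway_id %in% c("PW3", "PW4"), ]
  expect_equal(dup$z[1], dup$z[2]) # identical membership, identical z
  expect_equal(dup$pathway_id, c("PW3", "PW4")) # id breaks the tie
  expect_equal(out$N[1], 12)
  expect_equal(out$R[1], 6)

  # lowering the threshold admits the two-gene pathway
  out2 <- run_ora(stats, pw, min_sig_genes = 2)
  expect_true("PW2" %in% out2$pathway_id)

  # annotated universe restricts N to pathway members
  out3 <- run_ora(stats, pw, universe = "annotated")
  expect_equal(out3$N[1], length(unique(unlist(pw$genes))))
})

test_that("a fully regulated source pathway tops the ranking", {
  sc <- generate_scenario(small_planted_params(31))
  stats <- scenario_stats(sc, "psych")
  # restrict to the source plus the candidate gene sets (the co-regulated
  # module is a diffuse block, not a curated candidate)
  pw <- sc$pathways[!grepl("^WPM", sc$pathways$pathway_id), ]
  class(pw) <- class(sc$pathways)
  out <- run_ora(stats, pw)
  expect_equal(out$pathway_id[1], "WPSRC")
})

test_that("ora tidiers expose a plain ranked tibble", {
  stats <- tibble::tibble(
    gene_id = sprintf("G%02d", 1:10),
    t = 0, p = rep(c(0.01, 0.5), each = 5), log2fc = rep(c(0.5, 0), each = 5)
  )
  pw <- pathway_collection("PW1", genes = list(sprintf("G%02d", 1:5)))
  out <- run_ora(stats, pw)
  expect_false(inherits(tidy(out), "ora_result"))
  expect_equal(glance(out)$top_pathway, "PW1")
  expect_s3_class(autoplot(out), "ggplot")
})
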