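test_that("weight transform matches the logistic formula and its symmetry", {
  expect_identical(weight_transform(3), 0.5)
  expect_identical(weight_transform(-3), 0.5)
  expect_equal(weight_transform(0), 1 - 1 / (1 + exp(6)), tolerance = 1e-12)
  grid <- seq(-12, 12, by = 0.37)
  expect_equal(weight_transform(grid), weight_transform(-grid))
  w <- weight_transform(seq(0, 20, by = 0.1))
  expect_true(all(diff(w) < 0)) # strictly decreasing in |T|
  expect_true(all(w > 0 & w < 1))
  expect_lt(weight_transform(50), 1e-12)
  expect_error(weight_transform(Inf), "finite")
  expect_error(weight_transform(NA_real_), "finite")
})

test_that("welch_t_stats matches t.test per probe and handles degeneracies", {
  set.seed(11)
  expr <- tibble::tibble(
    probe_id = sprintf("p%02d", 1:6),
    as.data.frame(matrix(rnorm(6 * 9, mean = 7), nrow = 6,
      dimnames = list(NULL, sprintf("s%d", 1:9))
    ))
  )
  groups <- tibble::tibble(
    sample_id = sprintf("s%d", 1:9),
    group = rep(c("case", "control"), c(4, 5))
  )
  res <- welch_t_stats(expr, groups)
  for (i in 1:6) {
    tt <- t.test(
      as.numeric(expr[i, 2:5]), as.numeric(expr[i, 6:10]),
      var.equal = FALSE
    )
    expect_equal(res$t[i], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-12)
    expect_equal(res$log2fc[i], unname(diff(rev(tt$estimate))), tolerance = 1e-12)
  }

  # identical groups -> t = 0, p = 1; pure mean shift -> log2fc equals it
  same <- tibble::tibble(probe_id = "p", s1 = 1, s2 = 2, s3 = 3, s4 = 1, s5 = 2, s6 = 3)
  g6 <- tibble::tibble(
    sample_id = sprintf("s%d", 1:6),
    group = rep(c("case", "control"), each = 3)
  )
  r0 <- welch_t_stats(same, g6)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  shift <- tibble::tibble(
    probe_id = "p",
    s1 = 1.15, s2 = 1.15, s3 = 1.15, s4 = 1, s5 = 1, s6 = 1
  )
  expect_equal(welch_t_stats(shift, g6)$log2fc, 0.15)

  # a 3-vs-3 probe with {4,5,6} vs {1,2,3}: hand-computed Welch values
  hand <- tibble::tibble(probe_id = "p", s1 = 4, s2 = 5, s3 = 6, s4 = 1, s5 = 2, s6 = 3)
  rh <- welch_t_stats(hand, g6)
  expect_equal(rh$t, 3 / sqrt(1 / 3 + 1 / 3), tolerance = 1e-12)
  expect_equal(rh$p, 2 * pt(-3 / sqrt(2 / 3), df = 4), tolerance = 1e-12)

  expect_error(
    welch_t_stats(same, tibble::tibble(
      sample_id = sprintf("s%d", 1:6),
      group = rep(c("case", "control"), c(1, 5))
    )),
    "at least 2"
  )
})

test_that("welch equals the pooled t on balanced equal-variance designs", {
  set.seed(4)
  x <- rnorm(8)
  y <- rnorm(8)
  expr <- tibble::tibble(probe_id = "p", as.data.frame(t(c(x, y))))
  names(expr)[-1] <- sprintf("s%d", 1:16)
  groups <- tibble::tibble(
    sample_id = sprintf("s%d", 1:16),
    group = rep(c("case", "control"), each = 8)
  )
  welch <- welch_t_stats(expr, groups)$t
  pooled <- t.test(x, y, var.equal = TRUE)$statistic
  expect_equal(welch, unname(pooled), tolerance = 1e-9)
})

test_that("probe collapse keeps the lower-median log2FC probe per gene", {
  stats <- tibble::tibble(
    probe_id = c("a1", "a2", "a3", "b1", "b2", "c1"),
    t = 1:6, p = (1:6) / 10,
    log2fc = c(0.1, 0.5, 0.9, 0.5, 0.1, 0.3)
  )
  map <- tibble::tibble(
    probe_id = c("a1", "a2", "a3", "b1", "b2", "c1"),
    gene_id = c("GA", "GA", "GA", "GB", "GB", "GC")
  )
  out <- collapse_probes_to_genes(stats, map)
  expect_equal(out$probe_id[out$gene_id == "GA"], "a2") # odd count: true median
  expect_equal(out$probe_id[out$gene_id == "GB"], "b2") # even count: lower median
  expect_equal(out$probe_id[out$gene_id == "GC"], "c1") # single probe: identity
  # full stats row carried over, not averaged
  expect_equal(out$t[out$gene_id == "GA"], 2)

  # idempotent on one-probe-per-gene tables
  again <- collapse_probes_to_genes(
    dplyr::select(out, "probe_id", "t", "p", "log2fc"),
    dplyr::select(out, "probe_id", "gene_id")
  )
  expect_equal(again, out[names(again)])

  # log2FC ties break by probe id
  tied <- tibble::tibble(
    probe_id = c("z9", "z1"), t = c(1, 2), p = c(0.5, 0.5), log2fc = c(0.2, 0.2)
  )
  tmap <- tibble::tibble(probe_id = c("z9", "z1"), gene_id = "GT")
  expect_equal(collapse_probes_to_genes(tied, tmap)$probe_id, "z1")

  # unmapped probes dropped with a message; ambiguous mapping is an error
  expect_message(
    collapse_probes_to_genes(stats, map[-1, ]),
    "unmapped"
  )
  bad <- dplyr::bind_rows(map, tibble::tibble(probe_id = "a1", gene_id = "GZ"))
  expect_error(collapse_probes_to_genes(stats, bad), "more than one")
})

test_that("significance flag uses strict p and inclusive log2FC thresholds", {
  stats <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4"),
    p = c(0.04, 0.05, 0.01, 0.049),
    log2fc = c(0.15, 1.0, -0.2, 0.149)
  )
  out <- flag_significant(stats)
  expect_equal(out$significant, c(TRUE, FALSE, TRUE, FALSE))
})
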