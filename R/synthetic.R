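#' Parameters for a synthetic pathway-crosstalk scenario
#'
#' The generator emulates the statistical structure of a deletion-syndrome
#' cohort profiled on expression arrays: one control arm shared by two case
#' contrasts (psychiatric and non-psychiatric), a designated source pathway
#' whose members are strongly down-regulated (mimicking a hemizygous
#' deletion), planted PPI chains leading from source-pathway genes through
#' differentially expressed connector genes into target pathways, a block of
#' moderately differentially expressed genes organised into co-regulated
#' "module" gene sets (the analogue of the broad immune-response signal seen
#' in whole-blood cohorts, and the population the permutation test's
#' low-weight stratum draws from), and a background of null genes. The
#' default group sizes (66 controls, 19 psychiatric cases, 27
#' non-psychiatric cases) follow the whole-blood cohort design the method
#' was developed on.
#'
#' @param seed Integer master seed; the whole bundle is reproducible from it.
#' @param n_genes Total genes (default 1740).
#' @param n_pathways Number of candidate pathways (default 50).
#' @param pathway_size_range Inclusive range of candidate pathway sizes
#'   (default 6-10).
#' @param ppi_background_density Fraction of all gene pairs receiving a
#'   high-confidence background PPI edge (default 0.004).
#' @param source_members Number of strongly down-regulated source-pathway
#'   genes (default 30, a deleted-region-sized gene set).
#' @param planted Tibble describing planted crosstalk, one row per target:
#'   `target` (candidate pathway index), `chain_length` (number of connector
#'   genes in the chain, >= 2), `connector_t` (|T| level of the connectors),
#'   `contrast` (`"psych"` or `"nonpsych"`). The default plants five chains
#'   of two connectors at |T| = 6 into pathways 1-5, all in the psychiatric
#'   contrast.
#' @param deletion_t Absolute T-statistic of the down-regulated source
#'   members (default 8; they are calibrated to T = -8 in both contrasts).
#' @param null_t_sd Standard deviation of the null genes' target
#'   T-statistics (default 0.4, chosen so that together with the sampling
#'   noise of the t-statistic the realised null dispersion stays near 1).
#' @param de_genes Number of moderately differentially expressed background
#'   genes (default 1000).
#' @param de_t_range Absolute-T range of the moderately DE genes (default
#'   2.5-4.0); magnitudes are drawn uniformly, signs at random, shared by
#'   both contrasts (a common disease background).
#' @param de_placement `"modules"` (default) concentrates the DE genes in
#'   dedicated co-regulated module gene sets while candidate pathways draw
#'   from the null pool; `"background"` mixes DE and null genes in one pool
#'   that all candidate pathways draw from (membership then carries no
#'   expression information - a null configuration for calibration studies).
#' @param n_module_pathways,module_size Number and size of the co-regulated
#'   module gene sets (defaults 2 and 280: few large modules, so that the
#'   handful of membership-random gene sets contributes almost no false
#'   positives while still carrying the DE block into the network; ignored
#'   under `"background"`).
#' @param group_sizes Named vector `c(control=, psych=, nonpsych=)`.
#' @param disease_fraction Fraction of genes annotated to a disease concept
#'   at random, in addition to the planted connector genes (default 0.1).
#' @return A list of class `scenario_params`.
#' @export
scenario_params <- function(seed = 1,
                            n_genes = 1740,
                            n_pathways = 50,
                            pathway_size_range = c(6, 10),
                            ppi_background_density = 0.004,
                            source_members = 30,
                            planted = tibble::tibble(
                              target = 1:5, chain_length = 2,
                              connector_t = 6, contrast = "psych"
                            ),
                            deletion_t = 8,
                            null_t_sd = 0.4,
                            de_genes = 1000,
                            de_t_range = c(2.5, 4),
                            de_placement = c("modules", "background"),
                            n_module_pathways = 2,
                            module_size = 450,
                            group_sizes = c(control = 66, psych = 19, nonpsych = 27),
                            disease_fraction = 0.1) {
  de_placement <- match.arg(de_placement)
  planted <- tibble::as_tibble(planted)
  if (nrow(planted) > 0) {
    stopifnot(
      all(c("target", "chain_length", "connector_t", "contrast") %in% names(planted)),
      all(planted$target >= 1 & planted$target <= n_pathways),
      all(planted$chain_length >= 2),
      all(planted$contrast %in% c("psych", "nonpsych")),
      !anyDuplicated(planted$target)
    )
  }
  stopifnot(
    length(pathway_size_range) == 2, pathway_size_range[1] >= 1,
    pathway_size_range[1] <= pathway_size_range[2],
    all(c("control", "psych", "nonpsych") %in% names(group_sizes)),
    all(group_sizes >= 3),
    source_members >= 1, n_pathways >= 1,
    ppi_background_density >= 0, ppi_background_density < 1,
    disease_fraction >= 0, disease_fraction <= 1,
    de_genes >= 0, length(de_t_range) == 2, de_t_range[1] <= de_t_range[2],
    n_module_pathways >= 0, module_size >= 1
  )
  if (de_placement == "modules" && n_module_pathways > 0 && de_genes < module_size) {
    stop("`de_genes` must be at least `module_size` to populate the modules.",
      call. = FALSE
    )
  }
  needed <- source_members + sum(planted$chain_length) + de_genes +
    pathway_size_range[2]
  if (n_genes < needed) {
    stop("Infeasible scenario: ", n_genes, " genes cannot host ", needed,
      " member slots; increase `n_genes`.",
      call. = FALSE
    )
  }
  structure(
    list(
      seed = as.integer(seed), n_genes = as.integer(n_genes),
      n_pathways = as.integer(n_pathways),
      pathway_size_range = as.integer(pathway_size_range),
      ppi_background_density = ppi_background_density,
      source_members = as.integer(source_members),
      planted = planted, deletion_t = deletion_t, null_t_sd = null_t_sd,
      de_genes = as.integer(de_genes), de_t_range = de_t_range,
      de_placement = de_placement,
      n_module_pathways = as.integer(n_module_pathways),
      module_size = as.integer(module_size),
      group_sizes = group_sizes, disease_fraction = disease_fraction
    ),
    class = "scenario_params"
  )
}

#' Shift in group means that targets a given expected Welch T
#'
#' Uses the noncentral-t mean approximation
#' `delta = T * sigma * sqrt(1/n1 + 1/n2)`.
#'
#' @param t_target Expected T-statistic.
#' @param n_case,n_control Group sizes.
#' @param sigma Common within-group standard deviation.
#' @return The mean shift to apply to the case group.
#' @export
delta_for_t <- function(t_target, n_case, n_control, sigma = 1) {
  t_target * sigma * sqrt(1 / n_case + 1 / n_control)
}

#' Simulate a two-group expression matrix with per-gene target T-statistics
#'
#' Control samples are drawn from `Normal(mu, sigma)` and case samples from
#' `Normal(mu + delta, sigma)` per gene, with `delta` chosen via
#' [delta_for_t()] so the expected Welch T equals the target; the realised T
#' is stochastic.
#'
#' @param t_targets Tibble with columns `gene_id` and `t` (target value).
#' @param n_case,n_control Group sizes (each >= 3).
#' @param seed Optional integer seed.
#' @param baseline_mean,baseline_sd Distribution of per-gene baselines on the
#'   log2 scale.
#' @param sigma Within-group standard deviation.
#' @return A list with `expr` (tibble: `probe_id` = gene id, one column per
#'   sample) and `groups` (tibble: `sample_id`, `group` in case/control).
#' @export
generate_expression <- function(t_targets, n_case, n_control, seed = NULL,
                                baseline_mean = 7, baseline_sd = 0.5, sigma = 1) {
  stopifnot(
    is.data.frame(t_targets), all(c("gene_id", "t") %in% names(t_targets)),
    n_case >= 3, n_control >= 3
  )
  run <- function() {
    n_genes <- nrow(t_targets)
    mu <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
    delta <- delta_for_t(t_targets$t, n_case, n_control, sigma)
    ctrl <- matrix(
      stats::rnorm(n_genes * n_control, mean = mu, sd = sigma),
      nrow = n_genes
    )
    case <- matrix(
      stats::rnorm(n_genes * n_case, mean = mu + delta, sd = sigma),
      nrow = n_genes
    )
    ctrl_ids <- sprintf("CTRL%03d", seq_len(n_control))
    case_ids <- sprintf("CASE%03d", seq_len(n_case))
    expr <- tibble::as_tibble(
      stats::setNames(
        as.data.frame(cbind(ctrl, case)),
        c(ctrl_ids, case_ids)
      )
    )
    expr <- dplyr::bind_cols(tibble::tibble(probe_id = t_targets$gene_id), expr)
    groups <- tibble::tibble(
      sample_id = c(ctrl_ids, case_ids),
      group = rep(c("control", "case"), c(n_control, n_case))
    )
    list(expr = expr, groups = groups)
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

# Row-wise Welch t of case vs control matrices (genes in rows).
welch_t_mat <- function(case, ctrl) {
  n1 <- ncol(case)
  n2 <- ncol(ctrl)
  m1 <- rowMeans(case)
  m2 <- rowMeans(ctrl)
  v1 <- rowSums((case - m1)^2) / (n1 - 1)
  v2 <- rowSums((ctrl - m2)^2) / (n2 - 1)
  (m1 - m2) / sqrt(v1 / n1 + v2 / n2)
}

# Shift the case arm of selected genes by a constant so their realised Welch
# t against the control arm lands exactly on the target. Adding a constant
# leaves both group variances untouched, so the correction is exact.
pin_welch_t <- function(ctrl, case, rows, targets) {
  if (length(rows) == 0) {
    return(case)
  }
  n1 <- ncol(case)
  n2 <- ncol(ctrl)
  x <- case[rows, , drop = FALSE]
  y <- ctrl[rows, , drop = FALSE]
  m1 <- rowMeans(x)
  m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  se <- sqrt(v1 / n1 + v2 / n2)
  t_real <- (m1 - m2) / se
  case[rows, ] <- x + (targets - t_real) * se
  case
}

#' Generate a complete synthetic scenario bundle
#'
#' Draws pathway gene sets, a scored PPI edge list (high-confidence
#' background plus planted chains plus sub-threshold decoys), a three-arm
#' expression matrix sharing one control group, a curated-style disease
#' table, and truth labels, all reproducibly from `params$seed`.
#'
#' Planted chains are laid out as
#' `source pathway -> c1 -> ... -> ck -> target pathway`: the first connector
#' joins the source pathway's membership, the last joins the target's, and
#' consecutive connectors are linked by maximal-confidence PPI edges. All
#' connectors of a chain carry the configured `connector_t` in the planted
#' contrast (and are null in the other), so a chain of two connectors yields
#' a three-edge path with weight sum `2 * w(connector_t)`. The expression of
#' planted connectors and deleted source members is calibrated so their
#' realised Welch T equals the configured level exactly; all other genes'
#' realised statistics are stochastic around their targets. Background PPI
#' edges are rejection-sampled so that none completes an accidental
#' three-edge source-to-planted-target path with expected weight sum below
#' 0.9; longer accidental paths are allowed and left to the permutation test.
#'
#' @param params A [scenario_params()] object.
#' @return A list of class `crosstalk_scenario` with elements `params`,
#'   `pathways` ([pathway_collection()]: source pathway, candidate pathways,
#'   then module gene sets), `ppi` (raw scored edge tibble), `expression`,
#'   `groups` (three-level grouping), `probe2gene`, `gene_map`, `disease`,
#'   and `truth` (source id, planted targets with their chain genes, module
#'   ids, per-gene target T values).
#' @export
generate_scenario <- function(params = scenario_params()) {
  stopifnot(inherits(params, "scenario_params"))
  withr::with_seed(params$seed, {
    genes <- sprintf("G%04d", seq_len(params$n_genes))
    source_id <- "WPSRC"
    pathway_ids <- sprintf("WP%04d", seq_len(params$n_pathways))
    use_modules <- params$de_placement == "modules" &&
      params$n_module_pathways > 0 && params$de_genes > 0
    module_ids <- if (use_modules) {
      sprintf("WPM%03d", seq_len(params$n_module_pathways))
    } else {
      character(0)
    }

    # gene allocation: source members, connectors, moderate-DE block, nulls
    src_genes <- genes[seq_len(params$source_members)]
    n_conn <- sum(params$planted$chain_length)
    conn_pool <- genes[params$source_members + seq_len(n_conn)]
    de_pool <- genes[params$source_members + n_conn + seq_len(params$de_genes)]
    null_pool <- setdiff(genes, c(src_genes, conn_pool, de_pool))
    # under "background" placement every gene class (including the deleted
    # region) is eligible for candidate membership, so membership carries no
    # information at all and observed pathways are exchangeable with the
    # permutation test's stratified replacements
    cand_pool <- if (params$de_placement == "background") {
      c(null_pool, de_pool, src_genes)
    } else {
      null_pool
    }

    # per-contrast target T values
    t_psych <- stats::setNames(
      stats::rnorm(length(genes), 0, params$null_t_sd), genes
    )
    t_nonpsych <- stats::setNames(
      stats::rnorm(length(genes), 0, params$null_t_sd), genes
    )
    t_psych[src_genes] <- -params$deletion_t
    t_nonpsych[src_genes] <- -params$deletion_t
    if (params$de_genes > 0) {
      de_t <- sample(c(-1, 1), params$de_genes, replace = TRUE) *
        stats::runif(params$de_genes, params$de_t_range[1], params$de_t_range[2])
      t_psych[de_pool] <- de_t
      t_nonpsych[de_pool] <- de_t
    }

    # planted chains
    chains <- vector("list", nrow(params$planted))
    ppi_chain <- NULL
    taken <- 0L
    memberships <- stats::setNames(vector("list", params$n_pathways), pathway_ids)
    extra_source <- character(0)
    if (nrow(params$planted) > 0) {
      for (i in seq_len(nrow(params$planted))) {
        k <- params$planted$chain_length[i]
        chain <- conn_pool[taken + seq_len(k)]
        taken <- taken + k
        chains[[i]] <- chain
        if (params$planted$contrast[i] == "psych") {
          t_psych[chain] <- params$planted$connector_t[i]
        } else {
          t_nonpsych[chain] <- params$planted$connector_t[i]
        }
        extra_source <- c(extra_source, chain[1])
        tgt <- pathway_ids[params$planted$target[i]]
        memberships[[tgt]] <- chain[k]
        if (k > 1) {
          ppi_chain <- dplyr::bind_rows(ppi_chain, tibble::tibble(
            gene_a = chain[-k], gene_b = chain[-1], combined_score = 999
          ))
        }
      }
    }

    # candidate pathway memberships from the candidate pool; under
    # "background" placement the candidates partition the entire pool, so
    # the replacement universe of the permutation test coincides exactly
    # with the pool every membership was drawn from
    if (params$de_placement == "background") {
      shuffled <- sample(cand_pool)
      blocks <- split(shuffled, cut(seq_along(shuffled), params$n_pathways, labels = FALSE))
      for (j in seq_len(params$n_pathways)) {
        memberships[[j]] <- unique(c(memberships[[j]], blocks[[j]]))
      }
    } else {
      sizes <- sample(
        seq(params$pathway_size_range[1], params$pathway_size_range[2]),
        params$n_pathways,
        replace = TRUE
      )
      for (j in seq_len(params$n_pathways)) {
        memberships[[j]] <- unique(c(memberships[[j]], sample(cand_pool, sizes[j])))
      }
    }
    module_memberships <- lapply(module_ids, function(id) {
      sample(de_pool, params$module_size)
    })
    source_members_full <- c(src_genes, unique(extra_source))
    pathways <- pathway_collection(
      pathway_id = c(source_id, pathway_ids, module_ids),
      name = c(
        "Source deletion region gene set",
        sprintf("Synthetic pathway %d", seq_len(params$n_pathways)),
        sprintf("Co-regulated expression module %d", seq_along(module_ids))
      ),
      genes = c(list(source_members_full), unname(memberships), module_memberships)
    )

    # expression first: one shared control arm, two case arms; planted genes
    # are calibrated to land exactly on their target T. Generating expression
    # before the background PPI lets the edge rejection below work on the
    # realised statistics rather than the targets.
    gs <- params$group_sizes
    mu <- stats::rnorm(length(genes), 7, 0.5)
    d_psych <- delta_for_t(t_psych, gs[["psych"]], gs[["control"]])
    d_nonpsych <- delta_for_t(t_nonpsych, gs[["nonpsych"]], gs[["control"]])
    sim_arm <- function(shift, n, prefix) {
      m <- matrix(stats::rnorm(length(genes) * n, mean = mu + shift, sd = 1),
        nrow = length(genes)
      )
      rownames(m) <- genes
      colnames(m) <- sprintf("%s%03d", prefix, seq_len(n))
      m
    }
    ctrl <- sim_arm(0, gs[["control"]], "CTRL")
    psych <- sim_arm(d_psych, gs[["psych"]], "PSY")
    nonpsych <- sim_arm(d_nonpsych, gs[["nonpsych"]], "NPS")
    pin_psych <- c(src_genes, unlist(
      chains[params$planted$contrast == "psych"],
      use.names = FALSE
    ))
    pin_nonpsych <- c(src_genes, unlist(
      chains[params$planted$contrast == "nonpsych"],
      use.names = FALSE
    ))
    psych <- pin_welch_t(ctrl, psych, pin_psych, unname(t_psych[pin_psych]))
    nonpsych <- pin_welch_t(
      ctrl, nonpsych, pin_nonpsych, unname(t_nonpsych[pin_nonpsych])
    )
    arms <- cbind(ctrl, psych, nonpsych)

    # background PPI; reject pairs that would complete an accidental
    # three-edge source-to-pathway path with realised weight sum below 0.9
    # (source-to-source pairs are rejected under the same rule, since a
    # permuted membership containing a deleted gene would otherwise reach
    # the source in two near-free steps)
    n_background <- floor(
      params$ppi_background_density * params$n_genes * (params$n_genes - 1) / 2
    )
    w_psych <- weight_transform(pmax(abs(welch_t_mat(psych, ctrl)), 1e-8))
    w_nonpsych <- weight_transform(pmax(abs(welch_t_mat(nonpsych, ctrl)), 1e-8))
    member_any <- unique(c(
      unlist(memberships, use.names = FALSE),
      unlist(module_memberships, use.names = FALSE)
    ))
    cheap_pair <- function(a, b) {
      in_src_a <- a %in% source_members_full
      in_src_b <- b %in% source_members_full
      ((in_src_a & (b %in% member_any | in_src_b)) |
        (in_src_b & a %in% member_any)) &
        (w_psych[a] + w_psych[b] < 0.9 | w_nonpsych[a] + w_nonpsych[b] < 0.9)
    }
    ppi_bg <- NULL
    if (n_background > 0) {
      cand_a <- sample(genes, 4 * n_background, replace = TRUE)
      cand_b <- sample(genes, 4 * n_background, replace = TRUE)
      ok <- cand_a != cand_b
      if (nrow(params$planted) > 0) {
        ok <- ok & !cheap_pair(cand_a, cand_b)
      }
      keep <- which(ok)[seq_len(min(n_background, sum(ok)))]
      ppi_bg <- tibble::tibble(
        gene_a = cand_a[keep], gene_b = cand_b[keep],
        combined_score = sample(900:1000, length(keep), replace = TRUE)
      )
    }
    n_decoy <- max(5L, floor(n_background / 5))
    ppi_decoy <- tibble::tibble(
      gene_a = sample(genes, n_decoy, replace = TRUE),
      gene_b = sample(genes, n_decoy, replace = TRUE),
      combined_score = sample(100:899, n_decoy, replace = TRUE)
    )
    ppi <- dplyr::bind_rows(ppi_chain, ppi_bg, ppi_decoy)
    expression <- dplyr::bind_cols(
      tibble::tibble(probe_id = paste0("PR_", genes)),
      tibble::as_tibble(as.data.frame(arms))
    )
    groups <- tibble::tibble(
      sample_id = colnames(arms),
      group = rep(c("control", "psych", "nonpsych"),
        c(gs[["control"]], gs[["psych"]], gs[["nonpsych"]])
      )
    )
    probe2gene <- tibble::tibble(probe_id = paste0("PR_", genes), gene_id = genes)

    # curated-style disease table: all planted connectors plus random genes
    cuis <- c("C0036341", "C0004352", "C0033975")
    n_random <- floor(params$disease_fraction * params$n_genes)
    disease_genes <- unique(c(
      unlist(chains, use.names = FALSE),
      if (n_random > 0) sample(genes, n_random) else character(0)
    ))
    disease <- tibble::tibble(
      geneSymbol = disease_genes,
      diseaseId = sample(cuis, length(disease_genes), replace = TRUE)
    )

    truth <- list(
      source_id = source_id,
      source_members = source_members_full,
      module_ids = module_ids,
      de_genes = de_pool,
      planted = if (nrow(params$planted) > 0) {
        tibble::tibble(
          target_id = pathway_ids[params$planted$target],
          contrast = params$planted$contrast,
          connector_t = params$planted$connector_t,
          chain_genes = chains
        )
      } else {
        tibble::tibble(
          target_id = character(), contrast = character(),
          connector_t = numeric(), chain_genes = list()
        )
      },
      t_targets = tibble::tibble(
        gene_id = genes,
        t_psych = unname(t_psych),
        t_nonpsych = unname(t_nonpsych)
      )
    )

    structure(
      list(
        params = params, pathways = pathways, ppi = ppi,
        expression = expression, groups = groups, probe2gene = probe2gene,
        gene_map = tibble::tibble(gene_id = genes, symbol = genes),
        disease = disease, truth = truth
      ),
      class = "crosstalk_scenario"
    )
  })
}

#' Restrict a three-arm scenario to one case/control contrast
#'
#' Convenience selector returning the expression columns and a two-level
#' grouping (`case` / `control`) for one of the two case arms, suitable for
#' [welch_t_stats()] or [run_pathway_crosstalk()].
#'
#' @param scenario A `crosstalk_scenario`.
#' @param contrast `"psych"` or `"nonpsych"`.
#' @return A list with elements `expr` and `groups`.
#' @export
scenario_contrast <- function(scenario, contrast = c("psych", "nonpsych")) {
  stopifnot(inherits(scenario, "crosstalk_scenario"))
  contrast <- match.arg(contrast)
  keep <- scenario$groups$group %in% c("control", contrast)
  groups <- scenario$groups[keep, ]
  groups$group <- ifelse(groups$group == "control", "control", "case")
  list(
    expr = scenario$expression[, c("probe_id", groups$sample_id)],
    groups = groups
  )
}

#' @export
print.crosstalk_scenario <- function(x, ...) {
  cat("<crosstalk_scenario> seed ", x$params$seed, "\n", sep = "")
  cat("  ", x$params$n_genes, " genes, ", nrow(x$pathways),
    " gene sets (source + candidates + modules), ",
    nrow(x$ppi), " raw PPI rows\n",
    sep = ""
  )
  cat("  planted targets: ",
    if (nrow(x$truth$planted) > 0) {
      paste(x$truth$planted$target_id, collapse = ", ")
    } else {
      "none"
    },
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Write / read a scenario bundle as plain-text files
#'
#' Writes `pathways.gmt`, `ppi.tsv`, `expression.tsv`, `groups.tsv`,
#' `probe2gene.tsv`, `gene_map.tsv`, `disease.tsv`, and `truth.json` into
#' `dir`; `read_scenario()` loads them back through the package readers.
#'
#' @param scenario A `crosstalk_scenario`.
#' @param dir Directory (created if missing).
#' @return `write_scenario()`: `dir`, invisibly; `read_scenario()`: a list
#'   with the same tabular elements as the generated bundle.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "crosstalk_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gmt(scenario$pathways, file.path(dir, "pathways.gmt"))
  readr::write_tsv(scenario$ppi, file.path(dir, "ppi.tsv"))
  readr::write_tsv(scenario$expression, file.path(dir, "expression.tsv"))
  readr::write_tsv(scenario$groups, file.path(dir, "groups.tsv"))
  readr::write_tsv(scenario$probe2gene, file.path(dir, "probe2gene.tsv"))
  readr::write_tsv(scenario$gene_map, file.path(dir, "gene_map.tsv"))
  readr::write_tsv(scenario$disease, file.path(dir, "disease.tsv"))
  truth <- scenario$truth
  truth$planted <- as.list(truth$planted)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(dir) {
  list(
    pathways = read_gmt(file.path(dir, "pathways.gmt")),
    ppi = read_ppi(file.path(dir, "ppi.tsv")),
    expression = readr::read_tsv(file.path(dir, "expression.tsv"),
      show_col_types = FALSE
    ),
    groups = readr::read_tsv(file.path(dir, "groups.tsv"), show_col_types = FALSE),
    probe2gene = readr::read_tsv(file.path(dir, "probe2gene.tsv"),
      show_col_types = FALSE
    ),
    gene_map = readr::read_tsv(file.path(dir, "gene_map.tsv"), show_col_types = FALSE),
    disease = read_disease_table(file.path(dir, "disease.tsv")),
    truth = jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  )
}
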