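#' Analysis configuration
#'
#' Collects every tunable of the pipeline with its standard default: PPI
#' confidence cutoff 900, screening threshold 0.9, relaxed collection
#' threshold 1.4 with final two-tier filter (0.9 for three-edge paths, 1.4
#' for longer ones), 1000 stratified permutations split at weight 0.8,
#' selection at empirical p < 0.05, ORA gene criteria p < 0.05 and
#' |log2FC| >= 0.15 with at least 3 significant members, and the three
#' neuropsychiatric disease concepts used for annotation.
#'
#' @param source_pathway_id Id of the fixed source pathway.
#' @param screen_l_max,collect_l_max,tier_three,tier_longer Path thresholds.
#' @param string_min_score Minimum PPI combined score (0-1000).
#' @param n_samples,weight_split,pseudo_count,strict_below Permutation
#'   settings (see [permutation_config()]).
#' @param alpha Empirical p cutoff for pathway selection.
#' @param p_max,lfc_min,min_sig_genes ORA gene / pathway criteria.
#' @param cuis Disease concept ids for the annotation step.
#' @param seed Master seed.
#' @return A list of class `crosstalk_config`.
#' @export
crosstalk_config <- function(source_pathway_id,
                             screen_l_max = 0.9, collect_l_max = 1.4,
                             tier_three = 0.9, tier_longer = 1.4,
                             string_min_score = 900,
                             n_samples = 1000, weight_split = 0.8,
                             pseudo_count = FALSE, strict_below = FALSE,
                             alpha = 0.05,
                             p_max = 0.05, lfc_min = 0.15, min_sig_genes = 3,
                             cuis = c("C0036341", "C0004352", "C0033975"),
                             seed = 1) {
  stopifnot(
    is.character(source_pathway_id), length(source_pathway_id) == 1,
    screen_l_max > 0, collect_l_max > 0, tier_three > 0, tier_longer > 0,
    string_min_score >= 0, string_min_score <= 1000,
    alpha > 0, alpha <= 1, p_max > 0, p_max <= 1, lfc_min >= 0,
    min_sig_genes >= 0
  )
  structure(
    list(
      source_pathway_id = norm_id(source_pathway_id),
      screen_l_max = screen_l_max, collect_l_max = collect_l_max,
      tier_three = tier_three, tier_longer = tier_longer,
      string_min_score = string_min_score,
      n_samples = as.integer(n_samples), weight_split = weight_split,
      pseudo_count = isTRUE(pseudo_count), strict_below = isTRUE(strict_below),
      alpha = alpha, p_max = p_max, lfc_min = lfc_min,
      min_sig_genes = as.integer(min_sig_genes),
      cuis = norm_id(cuis), seed = as.integer(seed)
    ),
    class = "crosstalk_config"
  )
}

#' Read a configuration from a YAML file
#'
#' Fields mirror the arguments of [crosstalk_config()]; absent fields take
#' the defaults, and arguments supplied directly through `...` override the
#' file.
#'
#' @param path Path to a YAML file.
#' @param ... Overrides passed on to [crosstalk_config()].
#' @return A `crosstalk_config`.
#' @export
read_crosstalk_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(crosstalk_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("Unknown config field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(crosstalk_config, vals)
}

#' Run the full pathway-crosstalk pipeline for one contrast
#'
#' Stages: per-gene statistics (Welch t per probe, gene collapse, logistic
#' weights) unless a precomputed `stats` table is supplied; network
#' construction; candidate screening at `screen_l_max`; stratified
#' permutation p-values; selection at `alpha`; relaxed path collection with
#' the final two-tier filter; contributing-gene extraction; and the
#' companion overrepresentation analysis.
#'
#' @param pathways A [pathway_collection()] containing the source pathway.
#' @param ppi Raw PPI edge tibble (`gene_a`, `gene_b`, `combined_score`);
#'   filtered internally at `config$string_min_score`.
#' @param config A [crosstalk_config()].
#' @param expr,groups Expression matrix and two-group labels (see
#'   [welch_t_stats()]); required unless `stats` is given.
#' @param probe2gene Probe-to-gene mapping for the collapse step; defaults
#'   to the identity mapping on `expr$probe_id`.
#' @param stats Optional precomputed per-gene table (`gene_id`, `t`, `p`,
#'   `log2fc`), e.g. moderated statistics computed elsewhere; bypasses the
#'   expression stages.
#' @param case,control Group labels for the Welch stage.
#' @return A list of class `crosstalk_run` with elements `stats`, `network`,
#'   `screen`, `selected`, `final`, `genes` (contributing genes), `ora`, and
#'   `config`.
#' @export
run_pathway_crosstalk <- function(pathways, ppi, config,
                                  expr = NULL, groups = NULL,
                                  probe2gene = NULL, stats = NULL,
                                  case = "case", control = "control") {
  stopifnot(inherits(config, "crosstalk_config"))
  if (is.null(stats)) {
    if (is.null(expr) || is.null(groups)) {
      stop("Supply either `stats` or both `expr` and `groups`.", call. = FALSE)
    }
    if (is.null(probe2gene)) {
      probe2gene <- tibble::tibble(
        probe_id = expr$probe_id, gene_id = expr$probe_id
      )
    }
    stats <- welch_t_stats(expr, groups, case = case, control = control) |>
      collapse_probes_to_genes(probe2gene)
  }
  stats <- add_weights(stats)
  ppi_clean <- filter_ppi(ppi, min_score = config$string_min_score)
  net <- build_network(pathways, ppi_clean, stats)
  src <- config$source_pathway_id
  if (!src %in% names(net$pathways)) {
    stop("Source pathway ", src, " absent from the network.", call. = FALSE)
  }
  screen <- screen_candidates(net, src, l_max = config$screen_l_max)
  perm_cfg <- permutation_config(
    n_samples = config$n_samples, weight_split = config$weight_split,
    seed = config$seed, pseudo_count = config$pseudo_count,
    strict_below = config$strict_below
  )
  screen <- add_empirical_pvalues(screen, net, perm_cfg)
  selected <- select_significant(screen, alpha = config$alpha)
  final <- collect_relaxed_and_filter(
    net, src, selected$results$pathway_id,
    collect_l_max = config$collect_l_max,
    tier_three = config$tier_three, tier_longer = config$tier_longer
  )
  # carry the screening-stage empirical p over to the final path collection
  final$results$empirical_p <- selected$results$empirical_p[
    match(final$results$pathway_id, selected$results$pathway_id)
  ]
  ora <- run_ora(stats, pathways,
    p_max = config$p_max, lfc_min = config$lfc_min,
    min_sig_genes = config$min_sig_genes
  )
  structure(
    list(
      stats = stats, network = net, screen = screen, selected = selected,
      final = final, genes = contributing_genes(final), ora = ora,
      config = config, ppi_clean = ppi_clean
    ),
    class = "crosstalk_run"
  )
}

#' @export
print.crosstalk_run <- function(x, ...) {
  cat("<crosstalk_run> source: ", x$config$source_pathway_id, "\n", sep = "")
  cat("  screened: ", nrow(x$screen$results),
    ", selected (p < ", x$config$alpha, "): ", nrow(x$selected$results),
    ", final: ", nrow(x$final$results), " pathway(s)\n",
    sep = ""
  )
  cat("  contributing genes: ", length(x$genes),
    "; ORA-ranked pathways: ", nrow(x$ora), "\n",
    sep = ""
  )
  invisible(x)
}

#' @method glance crosstalk_run
#' @export
glance.crosstalk_run <- function(x, ...) {
  tibble::tibble(
    source = x$config$source_pathway_id,
    n_screened = nrow(x$screen$results),
    n_selected = nrow(x$selected$results),
    n_final = nrow(x$final$results),
    n_contributing_genes = length(x$genes),
    n_ora_pathways = nrow(x$ora)
  )
}

#' Compare two contrast runs and build the combined disease subnetwork
#'
#' Computes shared and exclusive pathway and disease-gene sets between two
#' completed runs (typically the psychiatric and non-psychiatric contrasts),
#' extracts the induced PPI subnetwork of arm A's exclusive disease genes
#' (optionally extended by hand-picked neighbour genes), and attaches arm
#' A's exclusive ORA genes that interact directly with that subnetwork.
#'
#' @param run_a,run_b `crosstalk_run` objects sharing a gene universe.
#' @param disease A `disease_gene_set` from [load_disease_genes()].
#' @param neighbor_genes Optional hand-picked first-degree neighbour genes
#'   added to the subnetwork (the analyst's analogue of pulling in known
#'   deleted-region partners).
#' @param source_pathway_members Members of the source pathway, used to draw
#'   the membership edge for neighbour genes inside the deleted region;
#'   defaults to arm A's source pathway membership.
#' @return A list of class `crosstalk_comparison`: `pathways` (shared /
#'   exclusive pathway ids), `genes` (shared / exclusive disease genes for
#'   the interaction method and for ORA), `subnetwork`, and
#'   `extended_subnetwork`.
#' @export
compare_groups <- function(run_a, run_b, disease,
                           neighbor_genes = character(0),
                           source_pathway_members = NULL) {
  stopifnot(inherits(run_a, "crosstalk_run"), inherits(run_b, "crosstalk_run"))
  if (!setequal(run_a$stats$gene_id, run_b$stats$gene_id)) {
    stop("The two runs do not share a gene universe.", call. = FALSE)
  }
  src <- run_a$config$source_pathway_id
  if (is.null(source_pathway_members)) {
    source_pathway_members <- run_a$network$pathways[[src]]
  }
  pw_a <- run_a$final$results$pathway_id
  pw_b <- run_b$final$results$pathway_id
  genes_a <- run_a$genes
  genes_b <- run_b$genes
  ora_genes <- function(run) {
    flagged <- flag_significant(run$stats,
      p_max = run$config$p_max, lfc_min = run$config$lfc_min
    )
    flagged$gene_id[flagged$significant]
  }
  ora_a <- ora_genes(run_a)
  ora_b <- ora_genes(run_b)
  excl_a <- exclusive_genes(genes_a, genes_b, disease)
  excl_b <- exclusive_genes(genes_b, genes_a, disease)
  ora_excl_a <- exclusive_genes(ora_a, ora_b, disease)
  ora_excl_b <- exclusive_genes(ora_b, ora_a, disease)
  sub <- extract_subnetwork(
    run_a$ppi_clean,
    seed_genes = excl_a, extra_genes = neighbor_genes,
    source_pathway_members = source_pathway_members,
    source_pathway_id = src
  )
  extended <- extend_with_ppi_neighbors(sub, ora_excl_a, run_a$ppi_clean)
  structure(
    list(
      pathways = list(
        shared = intersect(pw_a, pw_b),
        exclusive_a = setdiff(pw_a, pw_b),
        exclusive_b = setdiff(pw_b, pw_a)
      ),
      genes = list(
        interaction = list(
          shared = intersect(
            intersect(genes_a, disease$union), intersect(genes_b, disease$union)
          ),
          exclusive_a = excl_a, exclusive_b = excl_b
        ),
        ora = list(
          shared = intersect(
            intersect(ora_a, disease$union), intersect(ora_b, disease$union)
          ),
          exclusive_a = ora_excl_a, exclusive_b = ora_excl_b
        )
      ),
      subnetwork = sub,
      extended_subnetwork = extended
    ),
    class = "crosstalk_comparison"
  )
}

#' @export
print.crosstalk_comparison <- function(x, ...) {
  cat("<crosstalk_comparison>\n")
  cat("  pathways: ", length(x$pathways$shared), " shared, ",
    length(x$pathways$exclusive_a), " exclusive to A, ",
    length(x$pathways$exclusive_b), " exclusive to B\n",
    sep = ""
  )
  cat("  disease genes (interaction): ",
    length(x$genes$interaction$exclusive_a), " exclusive to A, ",
    length(x$genes$interaction$exclusive_b), " exclusive to B\n",
    sep = ""
  )
  cat("  disease genes (ORA): ",
    length(x$genes$ora$exclusive_a), " exclusive to A, ",
    length(x$genes$ora$exclusive_b), " exclusive to B\n",
    sep = ""
  )
  print(x$subnetwork)
  invisible(x)
}
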