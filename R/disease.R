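#' Load curated disease-gene associations for selected disease terms
#'
#' Filters a curated association table to the requested disease concept ids
#' (UMLS CUIs) and groups the gene symbols per concept. Symbol matching is
#' case-insensitive.
#'
#' @param table A tibble with columns `geneSymbol` and `diseaseId` (see
#'   [read_disease_table()]), or a path to such a TSV.
#' @param cuis Character vector of disease concept ids to keep, e.g.
#'   `c("C0036341", "C0004352", "C0033975")` for schizophrenia, autistic
#'   disorder, and psychotic disorders.
#' @return A list of class `disease_gene_set` with elements `per_cui` (named
#'   list of character vectors) and `union` (character vector).
#' @export
load_disease_genes <- function(table, cuis) {
  if (is.character(table) && length(table) == 1) {
    table <- read_disease_table(table)
  }
  stopifnot(is.data.frame(table))
  if (!all(c("geneSymbol", "diseaseId") %in% names(table))) {
    stop("Disease table must have `geneSymbol` and `diseaseId` columns.",
      call. = FALSE
    )
  }
  cuis <- norm_id(cuis)
  tab <- table |>
    dplyr::transmute(
      geneSymbol = norm_id(.data$geneSymbol),
      diseaseId = norm_id(.data$diseaseId)
    ) |>
    dplyr::filter(.data$diseaseId %in% cuis) |>
    dplyr::distinct()
  per_cui <- lapply(
    stats::setNames(cuis, cuis),
    function(id) sort(tab$geneSymbol[tab$diseaseId == id])
  )
  structure(
    list(per_cui = per_cui, union = sort(unique(tab$geneSymbol))),
    class = "disease_gene_set"
  )
}

#' Disease genes exclusive to one analysis arm
#'
#' Restricts `group_a`'s genes to the disease-associated ones, then removes
#' everything also found by `group_b`: the disease genes detected only in
#' arm A.
#'
#' @param group_a,group_b Character vectors of gene ids/symbols (e.g. the
#'   [contributing_genes()] of the two contrasts).
#' @param disease A `disease_gene_set` from [load_disease_genes()], or a
#'   character vector of disease genes.
#' @return A character vector: `(group_a` \eqn{\cap} `disease) \ group_b`.
#' @export
exclusive_genes <- function(group_a, group_b, disease) {
  disease_union <- if (inherits(disease, "disease_gene_set")) disease$union else disease
  sort(setdiff(
    intersect(norm_id(group_a), norm_id(disease_union)),
    norm_id(group_b)
  ))
}

#' Extract an induced PPI subnetwork around a gene set
#'
#' Builds the subgraph induced by `seed_genes` and `extra_genes` on the
#' filtered PPI edge list. If an extra gene is a member of the source
#' pathway, the source pathway node is added with a single membership edge
#' to that gene, so that the link between the subnetwork and the deleted
#' region stays visible; all other edges are protein-protein interactions.
#'
#' @param ppi Filtered PPI tibble (`gene_a`, `gene_b`).
#' @param seed_genes Character vector of genes anchoring the subnetwork.
#' @param extra_genes Additional genes (e.g. hand-picked first-degree
#'   neighbours) to include.
#' @param source_pathway_members Members of the source pathway (used only to
#'   decide membership edges for `extra_genes`).
#' @param source_pathway_id Node id for the source pathway (default
#'   `"SOURCE"`).
#' @return A list of class `gene_subnetwork`: `nodes` (tibble `node`, `type`,
#'   `origin`), `edges` (tibble `from`, `to`, `relation`), `n_components`,
#'   `fully_connected`.
#' @export
extract_subnetwork <- function(ppi, seed_genes, extra_genes = character(0),
                               source_pathway_members = character(0),
                               source_pathway_id = "SOURCE") {
  seed_genes <- unique(norm_id(seed_genes))
  extra_genes <- setdiff(unique(norm_id(extra_genes)), seed_genes)
  members <- norm_id(source_pathway_members)
  gene_nodes <- c(seed_genes, extra_genes)
  ppi <- dplyr::mutate(ppi,
    gene_a = norm_id(.data$gene_a), gene_b = norm_id(.data$gene_b)
  )
  edges <- ppi |>
    dplyr::filter(.data$gene_a %in% gene_nodes, .data$gene_b %in% gene_nodes) |>
    dplyr::transmute(from = .data$gene_a, to = .data$gene_b, relation = "ppi")
  nodes <- tibble::tibble(
    node = gene_nodes,
    type = "gene",
    origin = c(rep("seed", length(seed_genes)), rep("extra", length(extra_genes)))
  )
  anchored <- intersect(extra_genes, members)
  if (length(anchored) > 0) {
    nodes <- dplyr::bind_rows(
      nodes,
      tibble::tibble(node = source_pathway_id, type = "pathway", origin = "source")
    )
    edges <- dplyr::bind_rows(
      edges,
      tibble::tibble(from = source_pathway_id, to = anchored, relation = "member")
    )
  }
  g <- igraph::graph_from_data_frame(
    edges[c("from", "to")],
    directed = FALSE, vertices = nodes$node
  )
  comps <- igraph::components(g)
  structure(
    list(
      nodes = nodes, edges = edges,
      n_components = comps$no,
      fully_connected = comps$no == 1
    ),
    class = "gene_subnetwork"
  )
}

#' @export
print.gene_subnetwork <- function(x, ...) {
  cat("<gene_subnetwork> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
    " edges, ", x$n_components, " component(s)",
    if (x$fully_connected) " (fully connected)" else "", "\n",
    sep = ""
  )
  invisible(x)
}

#' Extend a subnetwork with directly interacting candidate genes
#'
#' Adds each candidate gene that has at least one protein-protein
#' interaction with a node already in the subnetwork, together with those
#' edges. Candidates without any such interaction are reported in the
#' `unattached` attribute instead of being added. The operation is
#' idempotent: extending twice with the same candidates changes nothing.
#'
#' @param subnetwork A `gene_subnetwork` from [extract_subnetwork()].
#' @param candidate_genes Character vector of genes to try to attach (e.g.
#'   significant genes from the companion overrepresentation analysis).
#' @param ppi Filtered PPI tibble.
#' @return The extended `gene_subnetwork`; attached candidates get origin
#'   `"attached"`, and `$unattached` lists the rest.
#' @export
extend_with_ppi_neighbors <- function(subnetwork, candidate_genes, ppi) {
  stopifnot(inherits(subnetwork, "gene_subnetwork"))
  candidate_genes <- setdiff(unique(norm_id(candidate_genes)), subnetwork$nodes$node)
  ppi <- dplyr::mutate(ppi,
    gene_a = norm_id(.data$gene_a), gene_b = norm_id(.data$gene_b)
  )
  existing <- subnetwork$nodes$node[subnetwork$nodes$type == "gene"]
  touching <- ppi |>
    dplyr::filter(
      (.data$gene_a %in% candidate_genes & .data$gene_b %in% existing) |
        (.data$gene_b %in% candidate_genes & .data$gene_a %in% existing)
    )
  attached <- intersect(candidate_genes, c(touching$gene_a, touching$gene_b))
  unattached <- setdiff(candidate_genes, attached)
  if (length(attached) > 0) {
    subnetwork$nodes <- dplyr::bind_rows(
      subnetwork$nodes,
      tibble::tibble(node = attached, type = "gene", origin = "attached")
    )
    subnetwork$edges <- dplyr::bind_rows(
      subnetwork$edges,
      dplyr::transmute(touching,
        from = .data$gene_a, to = .data$gene_b, relation = "ppi"
      )
    ) |> dplyr::distinct()
    g <- igraph::graph_from_data_frame(
      subnetwork$edges[c("from", "to")],
      directed = FALSE, vertices = subnetwork$nodes$node
    )
    comps <- igraph::components(g)
    subnetwork$n_components <- comps$no
    subnetwork$fully_connected <- comps$no == 1
  }
  subnetwork$unattached <- union(subnetwork$unattached, unattached)
  subnetwork
}
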