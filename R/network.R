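#' Build the bidirectional weighted gene-pathway-PPI network
#'
#' Gene nodes are the pathway-member genes that have an expression weight;
#' protein-protein interaction pairs extend connections between those genes.
#' Every retained gene-pathway membership and every retained PPI pair
#' contributes two directed edges, one per direction, each weighted by the
#' weight of the node the edge points at ("head-weight rule"); edges pointing
#' at a pathway node carry weight 0, so entering a pathway is free while
#' entering a gene costs its differential-expression weight.
#'
#' @param pathways A [pathway_collection()] tibble.
#' @param ppi A filtered PPI edge tibble (see [filter_ppi()]); columns
#'   `gene_a`, `gene_b`.
#' @param stats Per-gene statistics with columns `gene_id` and `weight`
#'   (see [add_weights()]).
#' @param include_orphan_ppi_genes If `TRUE`, weighted genes that appear only
#'   in the PPI file (in no pathway) are also admitted as nodes. The default
#'   `FALSE` restricts the node set to pathway members, since the gene
#'   universe is built from the pathways and merely extended by PPI links.
#' @return An `interaction_network` object: a list with `nodes` (tibble:
#'   `node`, `type`, `weight`), `edges` (tibble: `from`, `to`, `weight`,
#'   `relation`), `pathways` (named list of retained member vectors), and
#'   `dropped` (bookkeeping counts).
#' @export
build_network <- function(pathways, ppi, stats, include_orphan_ppi_genes = FALSE) {
  stopifnot(inherits(pathways, "pathway_collection") || is.data.frame(pathways))
  stopifnot(is.data.frame(stats), all(c("gene_id", "weight") %in% names(stats)))
  if (any(!is.finite(stats$weight)) || any(stats$weight <= 0 | stats$weight >= 1)) {
    stop("Gene weights must lie strictly inside (0, 1).", call. = FALSE)
  }
  stats <- dplyr::mutate(stats, gene_id = norm_id(.data$gene_id))
  if (anyDuplicated(stats$gene_id)) {
    stop("Duplicate gene ids in `stats`.", call. = FALSE)
  }
  w <- stats::setNames(stats$weight, stats$gene_id)

  member_genes <- unique(unlist(pathways$genes, use.names = FALSE))
  gene_nodes <- intersect(member_genes, names(w))
  if (include_orphan_ppi_genes && nrow(ppi) > 0) {
    ppi_genes <- unique(c(norm_id(ppi$gene_a), norm_id(ppi$gene_b)))
    gene_nodes <- union(gene_nodes, intersect(ppi_genes, names(w)))
  }
  n_unweighted <- length(setdiff(member_genes, names(w)))

  memberships <- pathways |>
    dplyr::mutate(genes = lapply(.data$genes, intersect, y = gene_nodes))
  empty <- lengths(memberships$genes) == 0
  if (any(empty)) {
    warning(sum(empty), " pathway(s) with no weighted member gene dropped: ",
      paste(utils::head(memberships$pathway_id[empty], 5), collapse = ", "),
      if (sum(empty) > 5) ", ..." else "",
      call. = FALSE
    )
    memberships <- memberships[!empty, ]
  }
  if (nrow(memberships) == 0 || length(gene_nodes) == 0) {
    stop("Empty network: no pathway retains a weighted member gene.", call. = FALSE)
  }
  clash <- intersect(memberships$pathway_id, gene_nodes)
  if (length(clash) > 0) {
    stop("Identifier collision between pathway and gene ids: ",
      paste(utils::head(clash, 3), collapse = ", "),
      call. = FALSE
    )
  }

  ppi_keep <- ppi |>
    dplyr::mutate(gene_a = norm_id(.data$gene_a), gene_b = norm_id(.data$gene_b)) |>
    dplyr::filter(.data$gene_a %in% gene_nodes, .data$gene_b %in% gene_nodes)
  n_ppi_dropped <- nrow(ppi) - nrow(ppi_keep)

  mem_long <- memberships |>
    dplyr::select("pathway_id", "genes") |>
    tidyr::unnest_longer("genes", values_to = "gene_id")
  member_edges <- dplyr::bind_rows(
    tibble::tibble(
      from = mem_long$pathway_id, to = mem_long$gene_id,
      weight = unname(w[mem_long$gene_id]), relation = "member",
      pathway = mem_long$pathway_id
    ),
    tibble::tibble(
      from = mem_long$gene_id, to = mem_long$pathway_id,
      weight = 0, relation = "member", pathway = mem_long$pathway_id
    )
  )
  ppi_edges <- dplyr::bind_rows(
    tibble::tibble(
      from = ppi_keep$gene_a, to = ppi_keep$gene_b,
      weight = unname(w[ppi_keep$gene_b]), relation = "ppi", pathway = NA_character_
    ),
    tibble::tibble(
      from = ppi_keep$gene_b, to = ppi_keep$gene_a,
      weight = unname(w[ppi_keep$gene_a]), relation = "ppi", pathway = NA_character_
    )
  )

  nodes <- dplyr::bind_rows(
    tibble::tibble(node = gene_nodes, type = "gene", weight = unname(w[gene_nodes])),
    tibble::tibble(node = memberships$pathway_id, type = "pathway", weight = NA_real_)
  )

  structure(
    list(
      nodes = nodes,
      edges = dplyr::bind_rows(member_edges, ppi_edges),
      ppi_edges = ppi_edges,
      pathways = stats::setNames(memberships$genes, memberships$pathway_id),
      pathway_names = stats::setNames(memberships$name, memberships$pathway_id),
      dropped = list(
        unweighted_member_genes = n_unweighted,
        empty_pathways = sum(empty),
        ppi_edges_outside_node_set = n_ppi_dropped
      )
    ),
    class = "interaction_network"
  )
}

#' @export
print.interaction_network <- function(x, ...) {
  n_gene <- sum(x$nodes$type == "gene")
  n_pw <- sum(x$nodes$type == "pathway")
  cat("<interaction_network>\n")
  cat("  ", n_gene, " gene nodes, ", n_pw, " pathway nodes\n", sep = "")
  cat("  ", nrow(x$edges), " directed edges (",
    sum(x$edges$relation == "member"), " member, ",
    sum(x$edges$relation == "ppi"), " ppi)\n",
    sep = ""
  )
  invisible(x)
}

#' Convert an interaction network to an igraph graph
#'
#' @param net An `interaction_network`.
#' @return A directed `igraph` graph with `weight` and `relation` edge
#'   attributes and a `type` node attribute.
#' @export
network_to_igraph <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  igraph::graph_from_data_frame(
    net$edges[c("from", "to", "weight", "relation")],
    directed = TRUE,
    vertices = net$nodes
  )
}

# Membership edges of one pathway (both directions), with members possibly
# replaced; used by the screening and permutation code.
membership_edges <- function(pathway_id, members, w) {
  tibble::tibble(
    from = c(rep(pathway_id, length(members)), members),
    to = c(members, rep(pathway_id, length(members))),
    weight = c(unname(w[members]), rep(0, length(members)))
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy interaction_network
#' @export
tidy.interaction_network <- function(x, ...) {
  tibble::as_tibble(x$edges[c("from", "to", "weight", "relation")])
}

#' @method glance interaction_network
#' @export
glance.interaction_network <- function(x, ...) {
  tibble::tibble(
    n_gene_nodes = sum(x$nodes$type == "gene"),
    n_pathway_nodes = sum(x$nodes$type == "pathway"),
    n_edges = nrow(x$edges),
    n_member_edges = sum(x$edges$relation == "member"),
    n_ppi_edges = sum(x$edges$relation == "ppi")
  )
}
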