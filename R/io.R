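# Identifier hygiene applied everywhere: verbatim matching after
# whitespace-trim and case-fold; no identifier mapping service is consulted.
norm_id <- function(x) toupper(trimws(as.character(x)))

#' Build a pathway collection
#'
#' @param pathway_id Character vector of unique pathway ids.
#' @param name Character vector of display names (recycled if length 1).
#' @param genes List of character vectors of member gene ids; duplicates
#'   within a pathway are removed (memberships are sets).
#' @return A tibble with columns `pathway_id`, `name`, `genes` (list column),
#'   class `pathway_collection`.
#' @export
pathway_collection <- function(pathway_id, name = pathway_id, genes) {
  pathway_id <- norm_id(pathway_id)
  if (anyDuplicated(pathway_id)) {
    stop("Pathway ids must be unique.", call. = FALSE)
  }
  stopifnot(is.list(genes), length(genes) == length(pathway_id))
  out <- tibble::tibble(
    pathway_id = pathway_id,
    name = rep_len(as.character(name), length(pathway_id)),
    genes = lapply(genes, function(g) unique(norm_id(g)))
  )
  class(out) <- c("pathway_collection", class(out))
  out
}

#' Read gene sets from a GMT file
#'
#' One pathway per line: id, description, then member gene ids, tab-separated.
#'
#' @param path Path to a GMT file.
#' @return A [pathway_collection()] tibble.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0) {
    stop("GMT line ", bad[1], " has fewer than 3 fields.", call. = FALSE)
  }
  pathway_collection(
    pathway_id = vapply(fields, `[[`, character(1), 1),
    name = vapply(fields, `[[`, character(1), 2),
    genes = lapply(fields, function(f) f[-(1:2)])
  )
}

#' Write gene sets to a GMT file
#'
#' @param pathways A [pathway_collection()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, path) {
  lines <- mapply(
    function(id, nm, g) paste(c(id, nm, g), collapse = "\t"),
    pathways$pathway_id, pathways$name, pathways$genes
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a protein-protein interaction edge list
#'
#' Accepts the STRING "protein links" dialect: three columns (node, node,
#' combined score on the 0-1000 scale), space- or tab-separated, with or
#' without a header line.
#'
#' @param path Path to the edge-list file.
#' @return A tibble with columns `gene_a`, `gene_b`, `combined_score`.
#' @export
read_ppi <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  toks <- strsplit(trimws(first), "[ \t]+")[[1]]
  has_header <- length(toks) >= 3 && is.na(suppressWarnings(as.numeric(toks[3])))
  df <- utils::read.table(
    path,
    header = has_header, sep = "", stringsAsFactors = FALSE,
    col.names = c("gene_a", "gene_b", "combined_score"),
    colClasses = c("character", "character", "character")
  )
  score <- suppressWarnings(as.numeric(df$combined_score))
  if (any(is.na(score))) {
    bad <- which(is.na(score))[1] + has_header
    stop("Malformed combined_score at line ", bad, " of ", path, ".", call. = FALSE)
  }
  tibble::tibble(
    gene_a = norm_id(df$gene_a),
    gene_b = norm_id(df$gene_b),
    combined_score = score
  )
}

#' Filter and clean a PPI edge list
#'
#' Keeps rows with `combined_score >= min_score` (the default 900 retains
#' only highest-confidence STRING edges), drops self-loops, and collapses
#' duplicate unordered pairs keeping the maximum score.
#'
#' @param edges Tibble with columns `gene_a`, `gene_b`, `combined_score`.
#' @param min_score Inclusive minimum combined score (0-1000 scale).
#' @return A deduplicated tibble of undirected pairs with `gene_a < gene_b`.
#' @export
filter_ppi <- function(edges, min_score = 900) {
  stopifnot(is.data.frame(edges))
  req <- c("gene_a", "gene_b", "combined_score")
  if (!all(req %in% names(edges))) {
    stop("`edges` must have columns ", paste(req, collapse = ", "), ".", call. = FALSE)
  }
  if (any(!is.finite(edges$combined_score)) ||
    any(edges$combined_score < 0 | edges$combined_score > 1000)) {
    stop("Combined scores must be finite and within [0, 1000].", call. = FALSE)
  }
  edges |>
    dplyr::mutate(gene_a = norm_id(.data$gene_a), gene_b = norm_id(.data$gene_b)) |>
    dplyr::filter(.data$combined_score >= min_score, .data$gene_a != .data$gene_b) |>
    dplyr::mutate(
      u = pmin(.data$gene_a, .data$gene_b),
      v = pmax(.data$gene_a, .data$gene_b)
    ) |>
    dplyr::group_by(.data$u, .data$v) |>
    dplyr::summarise(combined_score = max(.data$combined_score), .groups = "drop") |>
    dplyr::transmute(
      gene_a = .data$u, gene_b = .data$v,
      combined_score = .data$combined_score
    )
}

#' Read an expression matrix and its sample grouping
#'
#' @param expr_path TSV with first column `probe_id` and one column per
#'   sample (header row holds sample ids); values are log2 intensities.
#' @param groups_path Two-column TSV `sample_id`, `group`.
#' @return A list with elements `expr` (tibble) and `groups` (tibble).
#' @export
read_expression <- function(expr_path, groups_path) {
  expr <- readr::read_tsv(expr_path, show_col_types = FALSE)
  names(expr)[1] <- "probe_id"
  expr$probe_id <- as.character(expr$probe_id)
  groups <- readr::read_tsv(groups_path, show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  names(groups)[1:2] <- c("sample_id", "group")
  list(expr = expr, groups = groups)
}

#' Read / write a per-gene statistics table
#'
#' Columns: `gene_id`, `t`, `p`, `log2fc`, and optionally `weight`. A table
#' read this way can be fed straight into [build_network()], which allows
#' statistics computed elsewhere (e.g. moderated t-statistics) to be used in
#' place of the built-in Welch stage.
#'
#' @param path File path.
#' @return `read_gene_stats()`: a tibble; `write_gene_stats()`: `path`,
#'   invisibly.
#' @export
read_gene_stats <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  req <- c("gene_id", "t", "p", "log2fc")
  if (!all(req %in% names(out))) {
    stop("Gene stats table must have columns ", paste(req, collapse = ", "),
      ".", call. = FALSE)
  }
  out$gene_id <- norm_id(out$gene_id)
  out
}

#' @rdname read_gene_stats
#' @param stats Tibble of per-gene statistics.
#' @export
write_gene_stats <- function(stats, path) {
  readr::write_tsv(stats, path)
  invisible(path)
}

#' Write a network to SIF (simple interaction format)
#'
#' One line per directed relation pair (undirected relations are written
#' once), `node <relation> node`, with relation strings `"ppi"` and
#' `"member"`.
#'
#' @param edges Tibble with columns `from`, `to`, `relation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(edges, path) {
  und <- edges |>
    dplyr::mutate(u = pmin(.data$from, .data$to), v = pmax(.data$from, .data$to)) |>
    dplyr::distinct(.data$u, .data$v, .data$relation)
  writeLines(paste(und$u, und$relation, und$v, sep = "\t"), path)
  invisible(path)
}

#' Write a network to GraphML
#'
#' @param net An `interaction_network` or a tibble of edges with `from`,
#'   `to`, `weight`, `relation` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  g <- if (inherits(net, "interaction_network")) {
    network_to_igraph(net)
  } else {
    igraph::graph_from_data_frame(net, directed = TRUE)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a curated gene-disease association table
#'
#' @param path TSV with (at least) columns `geneSymbol` and `diseaseId`.
#' @return A tibble with those two columns, symbols case-folded.
#' @export
read_disease_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  if (!all(c("geneSymbol", "diseaseId") %in% names(df))) {
    stop("Disease table must have `geneSymbol` and `diseaseId` columns.",
      call. = FALSE
    )
  }
  dplyr::transmute(df,
    geneSymbol = norm_id(.data$geneSymbol),
    diseaseId = norm_id(.data$diseaseId)
  )
}
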