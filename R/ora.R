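#' Standardized hypergeometric z-score for overrepresentation
#'
#' With `N` measured genes of which `R` are significant, a pathway containing
#' `n` measured genes and `r` significant ones is scored as
#' \deqn{z = \frac{r - nR/N}{\sqrt{n (R/N)(1 - R/N)(1 - \frac{n-1}{N-1})}}}
#' i.e. the significant-member count centred and scaled by the mean and
#' standard deviation of the hypergeometric distribution.
#'
#' @param N Measured genes in the universe (`N > 1`).
#' @param R Significant genes in the universe (`0 < R < N`).
#' @param n Measured genes in the pathway (`0 < n < N` for a finite z).
#' @param r Significant genes in the pathway (`0 <= r <= min(n, R)`).
#' @return Numeric z-score(s); vectorised over its arguments.
#' @export
ora_zscore <- function(N, R, n, r) {
  check_ora_counts(N, R, n, r)
  if (any(R == 0 | R == N | n == N)) {
    stop("Degenerate universe: z is undefined when R = 0, R = N, or n = N.",
      call. = FALSE
    )
  }
  p <- R / N
  v <- n * p * (1 - p) * (1 - (n - 1) / (N - 1))
  (r - n * p) / sqrt(v)
}

#' Upper-tail hypergeometric p-value for overrepresentation
#'
#' `P(X >= r)` for `X ~ Hypergeometric(N, R, n)`: the probability of drawing
#' at least `r` significant genes when `n` genes are sampled without
#' replacement from a universe of `N` genes containing `R` significant ones.
#'
#' @inheritParams ora_zscore
#' @return Numeric p-value(s) in `[0, 1]`; vectorised.
#' @export
ora_hypergeom_p <- function(N, R, n, r) {
  check_ora_counts(N, R, n, r)
  stats::phyper(r - 1, R, N - R, n, lower.tail = FALSE)
}

check_ora_counts <- function(N, R, n, r) {
  if (any(!is.finite(N) | !is.finite(R) | !is.finite(n) | !is.finite(r)) ||
    any(N < 1 | R < 0 | n < 0 | r < 0) ||
    any(R > N | n > N | r > n | r > R)) {
    stop("Invalid counts: need 0 <= r <= min(n, R), n <= N, R <= N.",
      call. = FALSE
    )
  }
  invisible(TRUE)
}

#' Pathway overrepresentation analysis
#'
#' Flags significant genes (strict `p < p_max`, inclusive
#' `|log2fc| >= lfc_min`), counts them per pathway against the measured-gene
#' universe, and ranks pathways containing at least `min_sig_genes`
#' significant members by decreasing z-score (ties broken by ascending
#' hypergeometric p, then pathway id). P-values are reported unadjusted.
#'
#' @param stats Per-gene statistics with columns `gene_id`, `p`, `log2fc`
#'   (a `significant` column, e.g. from [flag_significant()], is used as-is
#'   if present).
#' @param pathways A [pathway_collection()].
#' @param p_max,lfc_min Significance criteria passed to [flag_significant()].
#' @param min_sig_genes Minimum significant members for a pathway to be
#'   ranked (default 3).
#' @param universe `"measured"` (default) uses all genes in `stats` as the
#'   universe `N`; `"annotated"` restricts it to genes belonging to at least
#'   one pathway.
#' @return A tibble of class `ora_result`: `pathway_id`, `name`, `N`, `R`,
#'   `n`, `r`, `z`, `p_hyper`, `rank`.
#' @export
run_ora <- function(stats, pathways, p_max = 0.05, lfc_min = 0.15,
                    min_sig_genes = 3, universe = c("measured", "annotated")) {
  universe <- match.arg(universe)
  stopifnot(is.data.frame(stats), "gene_id" %in% names(stats))
  if (!"significant" %in% names(stats)) {
    stats <- flag_significant(stats, p_max = p_max, lfc_min = lfc_min)
  }
  stats <- dplyr::mutate(stats, gene_id = norm_id(.data$gene_id))
  if (anyDuplicated(stats$gene_id)) {
    stop("Duplicate gene ids in `stats`.", call. = FALSE)
  }
  genes <- stats$gene_id
  if (universe == "annotated") {
    annotated <- unique(unlist(pathways$genes, use.names = FALSE))
    genes <- intersect(genes, annotated)
  }
  if (length(genes) == 0) {
    stop("Empty gene universe.", call. = FALSE)
  }
  sig <- stats$gene_id[stats$significant]
  sig <- intersect(sig, genes)
  N <- length(genes)
  R <- length(sig)
  measured <- genes
  out <- pathways |>
    tibble::as_tibble() |>
    dplyr::mutate(
      members = lapply(.data$genes, intersect, y = measured),
      n = lengths(.data$members),
      r = vapply(.data$members, function(m) length(intersect(m, sig)), integer(1)),
      N = N, R = R
    ) |>
    dplyr::filter(.data$r >= min_sig_genes, .data$n > 0, .data$n < N)
  if (R == 0 || R == N) {
    stop("Degenerate universe: ", R, " of ", N, " genes significant.",
      call. = FALSE
    )
  }
  out <- out |>
    dplyr::mutate(
      z = ora_zscore(.data$N, .data$R, .data$n, .data$r),
      p_hyper = ora_hypergeom_p(.data$N, .data$R, .data$n, .data$r)
    ) |>
    dplyr::arrange(dplyr::desc(.data$z), .data$p_hyper, .data$pathway_id) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select(
      "pathway_id", "name", "N", "R", "n", "r", "z", "p_hyper", "rank"
    )
  class(out) <- c("ora_result", class(out))
  out
}

#' @method tidy ora_result
#' @export
tidy.ora_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "ora_result")
  out
}

#' @method glance ora_result
#' @export
glance.ora_result <- function(x, ...) {
  tibble::tibble(
    n_pathways = nrow(x),
    N = if (nrow(x) > 0) x$N[1] else NA_integer_,
    R = if (nrow(x) > 0) x$R[1] else NA_integer_,
    top_pathway = if (nrow(x) > 0) x$pathway_id[1] else NA_character_,
    top_z = if (nrow(x) > 0) x$z[1] else NA_real_
  )
}

#' Plot overrepresentation z-scores
#'
#' @param object An `ora_result` tibble.
#' @param top Number of top-ranked pathways to show (default 10).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ora_result
#' @export
autoplot.ora_result <- function(object, top = 10, ...) {
  df <- utils::head(tidy(object), top)
  if (nrow(df) == 0) {
    stop("Nothing to plot: no pathway passed the ranking filter.", call. = FALSE)
  }
  df <- dplyr::mutate(df, pathway_id = stats::reorder(.data$pathway_id, .data$z))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$pathway_id)) +
    ggplot2::geom_col(ggplot2::aes(fill = -log10(pmax(.data$p_hyper, 1e-16)))) +
    ggplot2::scale_fill_viridis_c(name = expression(-log[10](p))) +
    ggplot2::labs(x = "overrepresentation z-score", y = NULL) +
    ggplot2::theme_minimal()
}
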