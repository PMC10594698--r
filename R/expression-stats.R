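#' Logistic weight transform of a t-statistic
#'
#' Maps a differential-expression t-statistic to the edge weight used by the
#' pathway interaction network:
#' \deqn{w(T) = 1 - \frac{1}{1 + e^{-2(|T| - 3)}}}
#' The transform is symmetric in the sign of `t_stat`, strictly decreasing in
#' `|T|`, equals 0.5 at `|T| = 3` (roughly unadjusted p = 0.004 for moderate
#' sample sizes), and stays inside the open interval (0, 1). Strongly
#' differentially expressed genes therefore make cheap path steps.
#'
#' @param t_stat Numeric vector of finite t-statistics.
#' @return Numeric vector of weights in (0, 1).
#' @examples
#' weight_transform(c(-3, 0, 3, 6))
#' @export
weight_transform <- function(t_stat) {
  if (!is.numeric(t_stat)) {
    stop("`t_stat` must be numeric.", call. = FALSE)
  }
  if (length(t_stat) > 0 && any(!is.finite(t_stat))) {
    stop("`t_stat` must be finite.", call. = FALSE)
  }
  # algebraically 1 - 1/(1+e^(-a)) with a = 2(|T|-3), computed as
  # e^(-a)/(1+e^(-a)) so extreme statistics do not underflow to exactly 0
  e <- exp(-2 * (abs(t_stat) - 3))
  e / (1 + e)
}

#' Per-probe Welch t-statistics for a two-group design
#'
#' Computes, for every probe, the unequal-variance (Welch) t-statistic, its
#' two-sided p-value, and the log2 fold change `mean(case) - mean(control)`.
#' Expression values are assumed to be on the log2 scale already. When both
#' groups have zero variance the probe is degenerate: `t = 0, p = 1` if the
#' group means coincide, otherwise a signed infinite t with `p = 0` (such
#' probes cannot be weighted downstream and should be inspected).
#'
#' @param expr Data frame with a `probe_id` column followed by one numeric
#'   column per sample (log2 intensities).
#' @param groups Data frame with columns `sample_id` and `group`; `group`
#'   must be a two-level labelling, by default `"case"` / `"control"`.
#' @param case,control The group labels contrasted as case vs control.
#' @return A tibble with columns `probe_id`, `t`, `p`, `log2fc`.
#' @examples
#' expr <- tibble::tibble(
#'   probe_id = "pr1",
#'   s1 = 1, s2 = 2, s3 = 3, s4 = 4, s5 = 5, s6 = 6
#' )
#' groups <- tibble::tibble(
#'   sample_id = paste0("s", 1:6),
#'   group = rep(c("control", "case"), each = 3)
#' )
#' welch_t_stats(expr, groups)
#' @export
welch_t_stats <- function(expr, groups, case = "case", control = "control") {
  stopifnot(is.data.frame(expr), is.data.frame(groups))
  if (!"probe_id" %in% names(expr)) {
    stop("`expr` must have a `probe_id` column.", call. = FALSE)
  }
  if (!all(c("sample_id", "group") %in% names(groups))) {
    stop("`groups` must have `sample_id` and `group` columns.", call. = FALSE)
  }
  if (anyDuplicated(expr$probe_id)) {
    stop("Duplicate probe ids in `expr`.", call. = FALSE)
  }
  if (anyDuplicated(groups$sample_id)) {
    stop("Duplicate sample ids in `groups`.", call. = FALSE)
  }
  sample_cols <- setdiff(names(expr), "probe_id")
  missing <- setdiff(sample_cols, groups$sample_id)
  if (length(missing) > 0) {
    stop("Samples without a group label: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  grp <- stats::setNames(groups$group, groups$sample_id)[sample_cols]
  case_cols <- sample_cols[grp == case]
  ctrl_cols <- sample_cols[grp == control]
  if (length(case_cols) < 2 || length(ctrl_cols) < 2) {
    stop("Each group needs at least 2 samples (case: ", length(case_cols),
      ", control: ", length(ctrl_cols), ").",
      call. = FALSE
    )
  }
  x <- as.matrix(expr[case_cols])
  y <- as.matrix(expr[ctrl_cols])
  if (!is.numeric(x) || !is.numeric(y) || any(!is.finite(x)) || any(!is.finite(y))) {
    stop("Expression values must be finite numerics.", call. = FALSE)
  }
  n1 <- ncol(x)
  n2 <- ncol(y)
  m1 <- rowMeans(x)
  m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  diff <- m1 - m2
  t_stat <- ifelse(se2 > 0, diff / sqrt(se2), ifelse(diff == 0, 0, sign(diff) * Inf))
  # Welch-Satterthwaite df; degenerate zero-variance probes get df = n1+n2-2
  df <- ifelse(
    se2 > 0,
    se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1))),
    n1 + n2 - 2
  )
  p <- ifelse(is.finite(t_stat), 2 * stats::pt(-abs(t_stat), df), 0)
  p[t_stat == 0] <- 1
  tibble::tibble(probe_id = expr$probe_id, t = t_stat, p = p, log2fc = diff)
}

#' Collapse probe-level statistics to gene level
#'
#' For each gene, keeps the complete statistics row of the single probe whose
#' log2 fold change is the median among the gene's probes; for an even probe
#' count the lower median is used so that an actual observed probe, never an
#' average, represents the gene. Ties on log2 fold change are broken by
#' lexicographic probe id. Probes without a gene mapping are dropped (their
#' count is reported via a message).
#'
#' @param probe_stats Tibble from [welch_t_stats()] (columns `probe_id`, `t`,
#'   `p`, `log2fc`), or any table with those columns.
#' @param probe2gene Data frame with columns `probe_id`, `gene_id`; each probe
#'   may map to at most one gene.
#' @return A tibble with one row per gene: `gene_id`, `probe_id`, `t`, `p`,
#'   `log2fc`.
#' @export
collapse_probes_to_genes <- function(probe_stats, probe2gene) {
  stopifnot(is.data.frame(probe_stats), is.data.frame(probe2gene))
  req <- c("probe_id", "t", "p", "log2fc")
  if (!all(req %in% names(probe_stats))) {
    stop("`probe_stats` must have columns ", paste(req, collapse = ", "), ".",
      call. = FALSE
    )
  }
  if (!all(c("probe_id", "gene_id") %in% names(probe2gene))) {
    stop("`probe2gene` must have `probe_id` and `gene_id` columns.", call. = FALSE)
  }
  probe2gene <- dplyr::distinct(probe2gene, .data$probe_id, .data$gene_id)
  if (anyDuplicated(probe2gene$probe_id)) {
    stop("A probe maps to more than one gene; supply a one-to-at-most-one mapping.",
      call. = FALSE
    )
  }
  if (nrow(probe2gene) == 0) {
    warning("Empty probe-to-gene mapping; returning zero genes.", call. = FALSE)
  }
  mapped <- dplyr::inner_join(probe_stats, probe2gene, by = "probe_id")
  n_dropped <- nrow(probe_stats) - nrow(mapped)
  if (n_dropped > 0) {
    message(n_dropped, " unmapped probe(s) dropped during gene collapse.")
  }
  mapped |>
    dplyr::arrange(.data$gene_id, .data$log2fc, .data$probe_id) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::slice(floor((dplyr::n() + 1) / 2)) |>
    dplyr::ungroup() |>
    dplyr::select("gene_id", "probe_id", "t", "p", "log2fc")
}

#' Attach network weights to a gene statistics table
#'
#' @param stats Tibble with at least `gene_id` and `t` columns.
#' @return `stats` with a `weight` column appended (see [weight_transform()]).
#' @export
add_weights <- function(stats) {
  stopifnot(is.data.frame(stats), all(c("gene_id", "t") %in% names(stats)))
  dplyr::mutate(stats, weight = weight_transform(.data$t))
}

#' Flag significantly differentially expressed genes
#'
#' A gene is significant when its p-value is strictly below `p_max` and the
#' absolute log2 fold change is at least `lfc_min` (inclusive). The defaults
#' (`p < 0.05`, `|log2FC| >= 0.15`, i.e. about 10% regulation) are the
#' criteria used for the companion overrepresentation analysis.
#'
#' @param stats Tibble with columns `p` and `log2fc`.
#' @param p_max Exclusive upper bound on the p-value.
#' @param lfc_min Inclusive lower bound on `|log2fc|`.
#' @return `stats` with a logical `significant` column appended.
#' @export
flag_significant <- function(stats, p_max = 0.05, lfc_min = 0.15) {
  stopifnot(is.data.frame(stats), all(c("p", "log2fc") %in% names(stats)))
  dplyr::mutate(
    stats,
    significant = .data$p < p_max & abs(.data$log2fc) >= lfc_min
  )
}
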