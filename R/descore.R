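#' Mild expression filter
#'
#' Retains genes with average log2 CPM (`a_value`) at or above `a_min`.
#' The default 0.5 corresponds to an average CPM of about 1.4 and is meant
#' to drop genes whose fold-change estimates are unreliable while keeping
#' the filter mild.
#'
#' @param stats Gene statistics tibble (from [nb_exact_test()] or
#'   [read_gene_stats()]); needs `a_value`.
#' @param a_min Inclusive threshold on `a_value`.
#' @return The retained rows; the retained fraction is attached as
#'   attribute `"retained_fraction"`.
#' @export
expression_filter <- function(stats, a_min = 0.5) {
  if (!all(is.finite(stats$a_value))) {
    rlang::abort("'a_value' must be finite")
  }
  out <- dplyr::filter(stats, .data$a_value >= a_min)
  if (nrow(out) == 0) {
    rlang::abort(
      "expression filter removed every gene; review the 'a_min' threshold")
  }
  attr(out, "retained_fraction") <- nrow(out) / nrow(stats)
  out
}

#' Composite DE score
#'
#' For each gene, `de_score = sign(log2FC) x (-log10 p) x scaled_a`, where
#' `scaled_a` is the average expression min-max scaled to `[0, 1]` over
#' `scaling_universe` (by default the filtered table itself). The score
#' keeps the direction of change, weights genes by statistical confidence,
#' and down-weights low-expression genes whose fold changes are noisy.
#'
#' Zero p-values are replaced by half the smallest nonzero p before the
#' log transform so the score stays finite. If all `a_value`s are equal,
#' `scaled_a` is set to 1 (with a warning) so significance still ranks
#' genes.
#'
#' @param stats Expression-filtered gene statistics tibble.
#' @param scaling_universe Tibble whose `a_value` range defines the
#'   min-max scaling (defaults to `stats`).
#' @return A `scored_genes` tibble: input columns + `scaled_a`,
#'   `de_score`, `rank` (1 = largest score; ties broken by gene id).
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 200, seed = 3))
#' stats <- nb_exact_test(sim$counts, sim$samples, tmm_factors(sim$counts))
#' scored <- compute_de_score(expression_filter(stats))
#' head(dplyr::arrange(scored, rank))
#' @export
compute_de_score <- function(stats, scaling_universe = stats) {
  if (any(stats$p_value < 0 | stats$p_value > 1)) {
    rlang::abort("p-values must lie in [0, 1]")
  }
  p <- stats$p_value
  if (any(p == 0)) {
    nz <- p[p > 0]
    if (length(nz) == 0) rlang::abort("all p-values are zero")
    p[p == 0] <- min(nz) / 2
  }
  a_lo <- min(scaling_universe$a_value)
  a_hi <- max(scaling_universe$a_value)
  if (a_hi == a_lo) {
    rlang::warn("constant a_value; scaled_a set to 1 for all genes")
    scaled_a <- rep(1, nrow(stats))
  } else {
    scaled_a <- (stats$a_value - a_lo) / (a_hi - a_lo)
  }
  out <- dplyr::mutate(stats, scaled_a = scaled_a,
                       de_score = sign(.data$m_value) * (-log10(p)) *
                         scaled_a)
  out <- dplyr::mutate(out,
    rank = order(order(-.data$de_score, .data$gene_id)))
  class(out) <- c("scored_genes", class(out))
  out
}

#' Select differentially expressed genes by DE score
#'
#' Among genes passing nominal significance (`p < p_threshold`), takes the
#' `k` largest positive DE scores as upregulated DEGs and the `k` smallest
#' negative scores as downregulated DEGs. When fewer than `k` are
#' available in a direction, all are taken (with a warning). The full
#' filtered table is kept as the enrichment background.
#'
#' @param scored A `scored_genes` tibble from [compute_de_score()].
#' @param k Genes per direction (default 300).
#' @param p_threshold Nominal significance threshold (default 0.05).
#' @return A `deg_selection` list: `up`, `down` (gene ids ordered by
#'   decreasing `|de_score|`), `background`, `k_requested`, `p_threshold`,
#'   `n_significant`.
#' @export
select_degs <- function(scored, k = 300, p_threshold = 0.05) {
  if (nrow(scored) == 0) rlang::abort("'scored' is empty")
  sig <- dplyr::filter(scored, .data$p_value < p_threshold)
  pos <- dplyr::arrange(
    dplyr::filter(sig, .data$de_score > 0),
    dplyr::desc(.data$de_score), .data$gene_id)
  neg <- dplyr::arrange(
    dplyr::filter(sig, .data$de_score < 0),
    .data$de_score, .data$gene_id)
  if (k > 0 && (nrow(pos) < k || nrow(neg) < k)) {
    rlang::warn(sprintf(
      "fewer than k = %d genes available (up: %d, down: %d); taking all",
      k, nrow(pos), nrow(neg)))
  }
  structure(list(
    up = head(pos$gene_id, k),
    down = head(neg$gene_id, k),
    background = scored$gene_id,
    k_requested = as.integer(k),
    p_threshold = p_threshold,
    n_significant = nrow(sig)
  ), class = "deg_selection")
}

#' @export
print.deg_selection <- function(x, ...) {
  cat(sprintf(
    "DEG selection: %d up, %d down (k = %d, p < %g, %d significant of %d)\n",
    length(x$up), length(x$down), x$k_requested, x$p_threshold,
    x$n_significant, length(x$background)))
  invisible(x)
}
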