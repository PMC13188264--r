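# broom-style tidiers for the package's result objects.

#' Tidy a DEG selection
#'
#' @param x A `deg_selection`.
#' @param ... Unused.
#' @return Tibble: `gene_id`, `direction`, `rank` (within direction).
#' @method tidy deg_selection
#' @export
tidy.deg_selection <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(gene_id = x$up, direction = "up",
                   rank = seq_along(x$up)),
    tibble::tibble(gene_id = x$down, direction = "down",
                   rank = seq_along(x$down)))
}

#' @rdname tidy.deg_selection
#' @method glance deg_selection
#' @export
glance.deg_selection <- function(x, ...) {
  tibble::tibble(n_up = length(x$up), n_down = length(x$down),
                 k_requested = x$k_requested,
                 p_threshold = x$p_threshold,
                 n_significant = x$n_significant,
                 n_background = length(x$background))
}

#' Tidy a resampling report
#'
#' @param x A `resample_report`.
#' @param ... Unused.
#' @return Per-iteration tibble of Jaccard indices (empty for the
#'   permutation scheme, whose draws are a null statistic, not Jaccards).
#' @method tidy resample_report
#' @export
tidy.resample_report <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$jaccard_up), scheme = x$scheme,
                 jaccard_up = x$jaccard_up, jaccard_down = x$jaccard_down)
}

#' @rdname tidy.resample_report
#' @method glance resample_report
#' @export
glance.resample_report <- function(x, ...) {
  tibble::tibble(
    scheme = x$scheme, iterations = x$iterations,
    mean_jaccard_up = if (length(x$jaccard_up)) mean(x$jaccard_up)
                      else NA_real_,
    mean_jaccard_down = if (length(x$jaccard_down)) mean(x$jaccard_down)
                        else NA_real_,
    empirical_p = x$empirical_p %||% NA_real_,
    skipped = x$skipped, seed = x$seed)
}

#' Glance at a group-separation report
#'
#' @param x A `separation_report`.
#' @param ... Unused.
#' @return One-row tibble of the multivariate separation statistics.
#' @method glance separation_report
#' @export
glance.separation_report <- function(x, ...) {
  tibble::tibble(
    pc1_fraction = x$pc_variance_fractions[1],
    pc2_fraction = x$pc_variance_fractions[2],
    permanova_F = x$permanova_F, permanova_R2 = x$permanova_R2,
    permanova_p = x$permanova_p, anosim_R = x$anosim_R,
    anosim_p = x$anosim_p, wilks_lambda = x$wilks_lambda,
    manova_p = x$manova_p,
    n_permutations_enumerated = x$n_permutations_enumerated,
    exhaustive = x$exhaustive)
}
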