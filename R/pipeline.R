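#' Differential-expression pipeline configuration
#'
#' Bundles the parameters of the normalization -> exact test -> DE score
#' -> DEG selection chain so resampling schemes can rerun the identical
#' pipeline. Defaults follow the analysis conventions this package
#' implements: DEGES iterations 3 (FDR cutoff 0.1, elimination threshold
#' 0.05, no low-count filtering inside the test), expression filter
#' `a_value >= 0.5`, top/bottom `k = 300` DEGs among `p < 0.05` genes.
#'
#' @param a_min Expression-filter threshold on average log2 CPM.
#' @param k DEGs per direction.
#' @param p_threshold Nominal significance threshold for DEG eligibility.
#' @param deges A [deges_config()]; `iterations = 0` gives plain TMM.
#' @param prior_count Fold-change moderation prior.
#' @param dispersion Optional fixed NB dispersion (estimated when `NULL`).
#' @export
pipeline_config <- function(a_min = 0.5, k = 300, p_threshold = 0.05,
                            deges = deges_config(), prior_count = 0.125,
                            dispersion = NULL) {
  structure(list(a_min = a_min, k = as.integer(k),
                 p_threshold = p_threshold, deges = deges,
                 prior_count = prior_count, dispersion = dispersion),
            class = "pipeline_config")
}

#' Run the DE-score pipeline on a count matrix
#'
#' Normalizes (TMM or DEGES-iterated TMM), runs the NB exact test,
#' applies the expression filter, computes DE scores and selects DEGs.
#'
#' @param counts Counts tibble or matrix.
#' @param samples Sample metadata (`sample_id`, `group`).
#' @param config A [pipeline_config()].
#' @return List of class `de_run`: `factors`, `stats` (all genes),
#'   `scored` (filtered + scored), `selection` (a `deg_selection`).
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 300, seed = 11))
#' run <- run_de_pipeline(sim$counts, sim$samples,
#'                        pipeline_config(k = 20, deges = deges_config(0)))
#' run$selection
#' @export
run_de_pipeline <- function(counts, samples, config = pipeline_config()) {
  factors <- deges_factors(counts, samples, deges = config$deges)
  stats <- nb_exact_test(counts, samples, factors,
                         dispersion = config$dispersion,
                         prior_count = config$prior_count)
  filtered <- expression_filter(stats, a_min = config$a_min)
  scored <- compute_de_score(filtered)
  selection <- suppressWarnings(
    select_degs(scored, k = config$k, p_threshold = config$p_threshold))
  structure(list(factors = factors, stats = stats, scored = scored,
                 selection = selection, config = config),
            class = "de_run")
}
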