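#' TMM scaling factors
#'
#' Trimmed mean of M-values normalization for between-sample composition
#' bias. The reference sample is the one whose upper-quartile CPM is
#' closest to the mean upper-quartile. Per-sample factors are the
#' inverse-asymptotic-variance weighted mean of gene-wise M-values after
#' trimming 30% of M-values and 5% of A-values (symmetric tails), then
#' renormalized to unit geometric mean.
#'
#' @param counts Counts tibble (`gene_id` + one column per sample) or an
#'   integer matrix with gene rownames.
#' @param lib_sizes Optional named per-sample library sizes; defaults to
#'   column sums.
#' @return Tibble with `sample_id`, `lib_size`, `norm_factor`;
#'   `prod(norm_factor) == 1` up to rounding.
#' @examples
#' cfg <- sim_config(n_genes = 300, seed = 7)
#' sim <- simulate_counts(cfg)
#' tmm_factors(sim$counts)
#' @export
tmm_factors <- function(counts, lib_sizes = NULL) {
  m <- counts_matrix(counts)
  if (ncol(m) < 2) rlang::abort("at least 2 samples are required")
  zero <- colSums(m) == 0
  if (any(zero)) {
    rlang::abort(paste0("sample(s) with all-zero counts: ",
                        paste(colnames(m)[zero], collapse = ", ")))
  }
  lib <- lib_sizes %||% colSums(m)
  if (!is.null(names(lib))) lib <- lib[colnames(m)]
  f75 <- vapply(seq_len(ncol(m)),
                function(j) quantile(m[, j] / lib[j], 0.75), numeric(1))
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(m)), function(j) {
    tmm_pair_factor(m[, j], m[, ref], lib[j], lib[ref])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  tibble::tibble(sample_id = colnames(m), lib_size = unname(lib),
                 norm_factor = f)
}

# One-sample-vs-reference TMM factor (weighted trimmed mean of M-values).
tmm_pair_factor <- function(obs, ref, n_obs, n_ref,
                            logratio_trim = 0.3, sum_trim = 0.05) {
  logR <- log2((obs / n_obs) / (ref / n_ref))
  absE <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(logR) & is.finite(absE)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (length(logR) == 0 || max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1
  hiL <- n + 1 - loL
  loS <- floor(n * sum_trim) + 1
  hiS <- n + 1 - loS
  keep <- rank(logR) >= loL & rank(logR) <= hiL &
    rank(absE) >= loS & rank(absE) <= hiS
  f <- sum(logR[keep] / v[keep]) / sum(1 / v[keep])
  if (!is.finite(f)) f <- 0
  2^f
}

#' DEGES configuration
#'
#' Parameters of the iterated (DEG-elimination) normalization: at each
#' iteration, putative DEGs (BH q below `fdr_cutoff`, or nominal p below
#' `elimination_threshold` when no gene clears the FDR cutoff) are removed
#' before recomputing TMM factors.
#'
#' @param iterations Non-negative integer (default 3).
#' @param fdr_cutoff FDR cutoff flagging putative DEGs (default 0.1).
#' @param elimination_threshold Fallback nominal-p cutoff (default 0.05).
#' @export
deges_config <- function(iterations = 3L, fdr_cutoff = 0.1,
                         elimination_threshold = 0.05) {
  check_fraction(fdr_cutoff, "fdr_cutoff", 0, 1, TRUE, TRUE)
  check_fraction(elimination_threshold, "elimination_threshold",
                 0, 1, TRUE, TRUE)
  if (iterations < 0) rlang::abort("'iterations' must be >= 0")
  structure(list(iterations = as.integer(iterations),
                 fdr_cutoff = fdr_cutoff,
                 elimination_threshold = elimination_threshold),
            class = "deges_config")
}

#' DEGES-iterated TMM factors
#'
#' Runs TMM, then `iterations` rounds of: exact-test the counts with the
#' current factors, flag putative DEGs, and recompute TMM factors on the
#' remaining genes. With `iterations = 0` this is identical to
#' [tmm_factors()]. If an iteration flags every gene, iteration stops with
#' a warning and the last valid factors are returned.
#'
#' @inheritParams tmm_factors
#' @param samples Sample metadata tibble (`sample_id`, `group`).
#' @param deges A [deges_config()].
#' @return As [tmm_factors()].
#' @export
deges_factors <- function(counts, samples, deges = deges_config(),
                          lib_sizes = NULL) {
  m <- counts_matrix(counts)
  factors <- tmm_factors(m, lib_sizes = lib_sizes)
  if (deges$iterations == 0) return(factors)
  lib <- setNames(factors$lib_size, factors$sample_id)
  for (it in seq_len(deges$iterations)) {
    stats <- nb_exact_test(m, samples, factors)
    flag <- stats$q_value < deges$fdr_cutoff
    if (!any(flag)) flag <- stats$p_value < deges$elimination_threshold
    if (all(flag)) {
      rlang::warn("all genes flagged as putative DEGs; stopping iteration")
      return(factors)
    }
    keep <- m[!flag, , drop = FALSE]
    if (any(colSums(keep) == 0)) {
      rlang::warn("DEG elimination left an all-zero sample; stopping")
      return(factors)
    }
    factors <- tmm_factors(keep, lib_sizes = lib)
  }
  factors
}

#' Counts per million
#'
#' `1e6 * count / (library size x normalization factor)` per cell.
#'
#' @inheritParams tmm_factors
#' @param factors Output of [tmm_factors()]/[deges_factors()]; `NULL`
#'   means unit factors with column-sum library sizes.
#' @return Numeric matrix (genes x samples) of CPM values.
#' @export
cpm_matrix <- function(counts, factors = NULL) {
  m <- counts_matrix(counts)
  eff <- effective_lib_sizes(m, factors)
  t(t(m) / eff) * 1e6
}

effective_lib_sizes <- function(m, factors) {
  if (is.null(factors)) {
    eff <- colSums(m)
  } else {
    i <- match(colnames(m), factors$sample_id)
    if (anyNA(i)) rlang::abort("factors missing for some samples")
    eff <- factors$lib_size[i] * factors$norm_factor[i]
  }
  if (any(eff <= 0)) rlang::abort("zero effective library size")
  setNames(eff, colnames(m))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (monotone, clipped to 1). Thin validated wrapper
#' around [stats::p.adjust()] so the adjustment used everywhere in the
#' pipeline is a single auditable choice.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, `q >= p` elementwise.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    rlang::abort("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Negative-binomial exact test for a two-group design
#'
#' Estimates a common NB dispersion by maximizing the conditional
#' likelihood of depth-equalized pseudo-counts (golden-section search on
#' log-dispersion in `[1e-6, 10]`), then tests each gene with a doubly
#' conditional exact test: the probability of the observed split of the
#' gene's group totals given the overall total, summing all splits at most
#' as probable as the observed one (two-sided, ties included).
#'
#' Fold changes are moderated: `m_value` is the log2 ratio of group mean
#' CPMs after adding a prior count (default 0.125, expressed on the CPM
#' scale at average depth); `a_value` is the mean over samples of
#' `log2(CPM + prior)`.
#'
#' @inheritParams deges_factors
#' @param factors Normalization factors (see [cpm_matrix()]).
#' @param dispersion Optional fixed NB dispersion; estimated when `NULL`.
#' @param prior_count Prior count for fold-change moderation.
#' @return Tibble with `gene_id`, `m_value` (log2FC, group 2 vs group 1),
#'   `a_value` (average log2 CPM), `p_value`, `q_value` (BH). The
#'   estimated dispersion is attached as attribute `"dispersion"`.
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 200, seed = 3))
#' fac <- tmm_factors(sim$counts)
#' head(nb_exact_test(sim$counts, sim$samples, fac))
#' @export
nb_exact_test <- function(counts, samples, factors = NULL,
                          dispersion = NULL, prior_count = 0.125) {
  m <- counts_matrix(counts)
  g <- group_factor(samples, m)
  if (any(table(g) < 2)) {
    rlang::abort("each group needs at least 2 samples")
  }
  eff <- effective_lib_sizes(m, factors)
  i1 <- which(g == levels(g)[1])
  i2 <- which(g == levels(g)[2])

  # depth-equalized pseudo-counts for conditioning
  gm <- exp(mean(log(eff)))
  pse <- round(t(t(m) * (gm / eff)))
  if (is.null(dispersion)) {
    dispersion <- estimate_common_dispersion(pse, i1, i2)
  }
  s1 <- rowSums(pse[, i1, drop = FALSE])
  s2 <- rowSums(pse[, i2, drop = FALSE])
  pvals <- vapply(seq_len(nrow(m)), function(gi) {
    nb_exact_pvalue(s1[gi], s2[gi], length(i1), length(i2), dispersion)
  }, numeric(1))

  cpm <- t(t(m) / eff) * 1e6
  prior_cpm <- prior_count * 1e6 / mean(eff)
  mean1 <- rowMeans(cpm[, i1, drop = FALSE])
  mean2 <- rowMeans(cpm[, i2, drop = FALSE])
  m_value <- log2((mean2 + prior_cpm) / (mean1 + prior_cpm))
  a_value <- rowMeans(log2(cpm + prior_cpm))
  out <- tibble::tibble(gene_id = rownames(m),
                        m_value = unname(m_value),
                        a_value = unname(a_value),
                        p_value = unname(pvals),
                        q_value = unname(bh_adjust(pvals)))
  attr(out, "dispersion") <- dispersion
  out
}

# Common dispersion by conditional maximum likelihood on pseudo-counts.
estimate_common_dispersion <- function(pse, i1, i2,
                                       interval = c(1e-6, 10)) {
  groups <- list(i1, i2)
  cml <- function(log_phi) {
    r <- 1 / 10^log_phi
    ll <- 0
    for (idx in groups) {
      y <- pse[, idx, drop = FALSE]
      n <- length(idx)
      z <- rowSums(y)
      ll <- ll + sum(rowSums(lgamma(y + r)) - n * lgamma(r) +
                       lgamma(n * r) - lgamma(z + n * r))
    }
    ll
  }
  opt <- optimize(cml, interval = log10(interval), maximum = TRUE,
                  tol = 1e-4)
  10^opt$maximum
}

# Exact conditional two-sided p for a split (s1, s2) of t = s1 + s2
# between groups of n1 and n2 samples under NB(mu, phi) per sample.
nb_exact_pvalue <- function(s1, s2, n1, n2, phi) {
  t <- s1 + s2
  if (t == 0) return(1)
  mu <- t / (n1 + n2)
  r1 <- n1 / phi
  r2 <- n2 / phi
  if (t <= 20000) {
    ks <- 0:t
  } else {
    lo <- min(qnbinom(1e-15, size = r1, mu = n1 * mu), s1)
    hi <- max(qnbinom(1e-15, size = r1, mu = n1 * mu,
                      lower.tail = FALSE), s1)
    lo2 <- t - max(qnbinom(1e-15, size = r2, mu = n2 * mu,
                           lower.tail = FALSE), s2)
    hi2 <- t - min(qnbinom(1e-15, size = r2, mu = n2 * mu), s2)
    ks <- max(0, min(lo, lo2)):min(t, max(hi, hi2))
  }
  pk <- dnbinom(ks, size = r1, mu = n1 * mu) *
    dnbinom(t - ks, size = r2, mu = n2 * mu)
  tot <- sum(pk)
  if (tot == 0) return(1)
  p_obs <- pk[match(s1, ks)]
  min(1, sum(pk[pk <= p_obs * (1 + 1e-10)]) / tot)
}
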