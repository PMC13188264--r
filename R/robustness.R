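#' Jaccard index of two id sets
#'
#' `|a n b| / |a u b|`; two empty sets give 1 by convention (identical
#' selections).
#'
#' @param a,b Character vectors (treated as sets).
#' @return Real in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

new_resample_report <- function(scheme, jaccard_up, jaccard_down,
                                empirical_p = NULL, seed, skipped = 0L,
                                extra = list()) {
  structure(c(list(scheme = scheme, iterations = length(jaccard_up),
                   jaccard_up = jaccard_up, jaccard_down = jaccard_down,
                   empirical_p = empirical_p, seed = seed,
                   skipped = skipped), extra),
            class = "resample_report")
}

#' @export
print.resample_report <- function(x, ...) {
  cat(sprintf("resample_report [%s]: %d iterations (seed %d)\n",
              x$scheme, x$iterations, x$seed))
  cat(sprintf("  mean Jaccard up: %.3f  down: %.3f\n",
              mean(x$jaccard_up), mean(x$jaccard_down)))
  if (!is.null(x$empirical_p)) {
    cat(sprintf("  empirical p: %.4f\n", x$empirical_p))
  }
  invisible(x)
}

#' Stratified bootstrap validation of the DEG selection
#'
#' Resamples samples with replacement within each group (group sizes
#' preserved), reruns the full pipeline, and records the Jaccard index of
#' the resampled up/down DEG sets against the full-data selection.
#' Iterations where a resampled group has zero total counts are skipped
#' and counted.
#'
#' @inheritParams run_de_pipeline
#' @param n_iter Number of bootstrap iterations (default 500).
#' @param seed RNG seed (default 123).
#' @return A `resample_report` (scheme `"bootstrap"`).
#' @export
bootstrap_validation <- function(counts, samples,
                                 config = pipeline_config(),
                                 n_iter = 500, seed = 123) {
  resample_validation(counts, samples, config, n_iter, seed, "bootstrap")
}

#' Leave-one-out subsampling validation of the DEG selection
#'
#' Each iteration drops one randomly chosen sample from each group,
#' reruns the pipeline and records Jaccard indices against the full-data
#' selection. Requires at least 3 samples per group.
#'
#' @inheritParams bootstrap_validation
#' @param n_iter Number of iterations (default 100).
#' @return A `resample_report` (scheme `"subsample"`).
#' @export
subsample_validation <- function(counts, samples,
                                 config = pipeline_config(),
                                 n_iter = 100, seed = 123) {
  m <- counts_matrix(counts)
  g <- group_factor(samples, m)
  if (any(table(g) < 3)) {
    rlang::abort("leave-one-out subsampling needs >= 3 samples per group")
  }
  resample_validation(counts, samples, config, n_iter, seed, "subsample")
}

resample_validation <- function(counts, samples, config, n_iter, seed,
                                scheme) {
  m <- counts_matrix(counts)
  g <- group_factor(samples, m)
  full <- run_de_pipeline(m, samples, config)
  idx_by_group <- split(seq_len(ncol(m)), g)
  ju <- jd <- numeric(0)
  skipped <- 0L
  withr::with_seed(seed, {
    for (it in seq_len(n_iter)) {
      idx <- unlist(lapply(idx_by_group, function(ix) {
        if (scheme == "bootstrap") sample(ix, length(ix), replace = TRUE)
        else sample(ix, length(ix) - 1)
      }), use.names = FALSE)
      sub <- m[, idx, drop = FALSE]
      colnames(sub) <- sprintf("r%d_%d", it, seq_along(idx))
      if (any(vapply(split(colSums(sub), g[idx]), sum, numeric(1)) == 0)) {
        skipped <- skipped + 1L
        next
      }
      smp <- tibble::tibble(sample_id = colnames(sub),
                            group = as.character(g[idx]))
      run <- run_de_pipeline(sub, smp, config)
      ju <- c(ju, jaccard(run$selection$up, full$selection$up))
      jd <- c(jd, jaccard(run$selection$down, full$selection$down))
    }
  })
  new_resample_report(scheme, ju, jd, seed = seed, skipped = skipped)
}

#' Permutation null for the DEG ranking strength
#'
#' The observed statistic is the mean `|de_score|` over the selected
#' up-and-down DEG sets. The null distribution reruns the pipeline under
#' group-label permutations: when the number of distinct label
#' assignments (minus the observed one) is at most `n_iter` they are all
#' enumerated, otherwise `n_iter` random relabelings are drawn.
#' `empirical_p = (1 + #\{T_null >= T_obs\}) / (1 + N)`.
#'
#' @inheritParams bootstrap_validation
#' @param n_iter Maximum null draws (default 1000).
#' @return A `resample_report` (scheme `"permutation"`) with
#'   `empirical_p`, `t_observed`, `t_null` and `exhaustive`.
#' @export
permutation_null <- function(counts, samples, config = pipeline_config(),
                             n_iter = 1000, seed = 123) {
  m <- counts_matrix(counts)
  g <- group_factor(samples, m)
  n <- ncol(m)
  n1 <- sum(g == levels(g)[1])
  full <- run_de_pipeline(m, samples, config)
  t_obs <- selection_statistic(full)
  obs_idx <- which(g == levels(g)[1])
  assigns <- combn(n, n1)
  exhaustive <- (ncol(assigns) - 1) <= n_iter
  withr::with_seed(seed, {
    if (exhaustive) {
      keep <- !apply(assigns, 2, function(ix) identical(ix, obs_idx))
      draws <- assigns[, keep, drop = FALSE]
    } else {
      draws <- replicate(n_iter, sort(sample(n, n1)))
    }
    t_null <- apply(draws, 2, function(ix) {
      gp <- rep(levels(g)[2], n)
      gp[ix] <- levels(g)[1]
      smp <- tibble::tibble(sample_id = colnames(m), group = gp)
      selection_statistic(run_de_pipeline(m, smp, config))
    })
  })
  p <- (1 + sum(t_null >= t_obs - 1e-12)) / (1 + length(t_null))
  new_resample_report("permutation", numeric(0), numeric(0),
                      empirical_p = p, seed = seed,
                      extra = list(t_observed = t_obs, t_null = t_null,
                                   exhaustive = exhaustive))
}

selection_statistic <- function(run) {
  sel <- c(run$selection$up, run$selection$down)
  if (length(sel) == 0) return(0)
  mean(abs(run$scored$de_score[run$scored$gene_id %in% sel]))
}

#' PCA scores and variance fractions
#'
#' Column-centered singular value decomposition of a samples x features
#' matrix.
#'
#' @param x Numeric matrix, samples in rows.
#' @return List with `scores` (tibble: `sample_id`, `PC1`, `PC2`, ...)
#'   and `variance_fractions` (sums to 1).
#' @export
pca_scores <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) rlang::abort("at least 2 samples are required")
  if (all(apply(x, 2, var) == 0)) rlang::abort("constant matrix")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  scores <- tibble::as_tibble(pc$x)
  scores <- dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(x) %||%
                     sprintf("s%d", seq_len(nrow(x)))), scores)
  list(scores = scores,
       variance_fractions = pc$sdev^2 / sum(pc$sdev^2))
}

# Shared permutation machinery: statistic fn maps a label vector to a
# scalar; exhaustive when factorial(n) - 1 <= max_perms.
permute_pvalue <- function(labels, stat_fn, max_perms, seed = 123) {
  n <- length(labels)
  obs <- stat_fn(labels)
  n_total <- factorial(n)
  exhaustive <- (n_total - 1) <= max_perms
  if (exhaustive) {
    perms <- all_permutations(n)[-1, , drop = FALSE]
    stats <- apply(perms, 1, function(p) stat_fn(labels[p]))
  } else {
    stats <- withr::with_seed(seed, {
      replicate(max_perms, stat_fn(labels[sample(n)]))
    })
  }
  list(observed = obs,
       p = (1 + sum(stats >= obs - 1e-12)) / (1 + length(stats)),
       n_enumerated = length(stats), exhaustive = exhaustive)
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: pseudo-F and
#' `R^2 = SS_between / SS_total` computed from squared distances. When
#' the number of non-identity sample orderings is at most `max_perms`
#' (719 for six samples) they are enumerated exhaustively, giving exact
#' permutation p-values on the grid `m / (n_enumerated + 1)`; otherwise
#' `max_perms` random orderings are sampled.
#'
#' @param d A `dist` or symmetric matrix with zero diagonal.
#' @param labels Group labels (>= 2 levels).
#' @param max_perms Enumeration threshold / number of sampled orderings.
#' @param seed RNG seed used only in sampled mode.
#' @return List: `F`, `R2`, `p`, `n_enumerated`, `exhaustive`.
#' @export
permanova <- function(d, labels, max_perms = 999, seed = 123) {
  dm <- as.matrix(d)
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) rlang::abort("labels need >= 2 levels")
  n <- nrow(dm)
  k <- nlevels(labels)
  d2 <- dm^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- function(lab) {
    sum(vapply(split(seq_len(n), lab), function(ix) {
      sub <- d2[ix, ix, drop = FALSE]
      sum(sub[upper.tri(sub)]) / length(ix)
    }, numeric(1)))
  }
  f_stat <- function(lab) {
    ssw <- ss_within(lab)
    ((ss_total - ssw) / (k - 1)) / (ssw / (n - k))
  }
  perm <- permute_pvalue(labels, f_stat, max_perms, seed)
  ssw_obs <- ss_within(labels)
  list(F = perm$observed, R2 = (ss_total - ssw_obs) / ss_total,
       p = perm$p, n_enumerated = perm$n_enumerated,
       exhaustive = perm$exhaustive)
}

#' ANOSIM on a distance matrix
#'
#' Analysis of similarities: `R = (mean rank of between-group distances -
#' mean rank of within-group distances) / (M / 2)` with `M = n(n-1)/2`,
#' bounded in `[-1, 1]`. Permutation p-values as in [permanova()]
#' (exhaustive enumeration of the 719 non-identity orderings for six
#' samples).
#'
#' @inheritParams permanova
#' @return List: `R`, `p`, `n_enumerated`, `exhaustive`.
#' @export
anosim <- function(d, labels, max_perms = 999, seed = 123) {
  dm <- as.matrix(d)
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) rlang::abort("labels need >= 2 levels")
  n <- nrow(dm)
  ut <- upper.tri(dm)
  rk <- rank(dm[ut])
  pair_i <- row(dm)[ut]
  pair_j <- col(dm)[ut]
  m_half <- (n * (n - 1) / 2) / 2
  r_stat <- function(lab) {
    between <- lab[pair_i] != lab[pair_j]
    (mean(rk[between]) - mean(rk[!between])) / m_half
  }
  perm <- permute_pvalue(labels, r_stat, max_perms, seed)
  list(R = perm$observed, p = perm$p,
       n_enumerated = perm$n_enumerated, exhaustive = perm$exhaustive)
}

#' MANOVA with Wilks' lambda
#'
#' `lambda = det(W) / det(W + B)` for within/between sums-of-squares
#' matrices, with a p-value from Rao's F approximation. At one response
#' variable and two groups this reduces exactly to the squared two-sample
#' t statistic.
#'
#' @param x Samples x variables matrix (e.g. the first PCs of the DEG
#'   expression matrix).
#' @param labels Group labels.
#' @return List: `lambda`, `F`, `df1`, `df2`, `p`.
#' @export
manova_wilks <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.factor(labels)
  n <- nrow(x)
  q <- ncol(x)
  k <- nlevels(labels)
  if (q > n - k - 1) {
    rlang::abort("too many response variables; use fewer components")
  }
  centered <- scale(x, scale = FALSE)
  tot <- crossprod(centered)
  w <- matrix(0, q, q)
  for (ix in split(seq_len(n), labels)) {
    cg <- scale(x[ix, , drop = FALSE], scale = FALSE)
    w <- w + crossprod(cg)
  }
  dw <- det(w)
  if (!is.finite(dw) || dw <= 0) {
    rlang::abort("singular within-group matrix; use fewer components")
  }
  lambda <- dw / det(tot)
  vh <- k - 1
  ve <- n - k
  s <- if (q^2 + vh^2 - 5 > 0) {
    sqrt((q^2 * vh^2 - 4) / (q^2 + vh^2 - 5))
  } else 1
  df1 <- q * vh
  mm <- ve + vh - (q + vh + 1) / 2
  df2 <- mm * s - q * vh / 2 + 1
  f <- ((1 - lambda^(1 / s)) / lambda^(1 / s)) * df2 / df1
  list(lambda = lambda, F = f, df1 = df1, df2 = df2,
       p = pf(f, df1, df2, lower.tail = FALSE))
}

#' Multivariate group-separation report for a DEG selection
#'
#' Builds the `log2(CPM + 1)` matrix of the selected genes, then runs PCA,
#' PERMANOVA and ANOSIM on Euclidean distances, and MANOVA (Wilks) on the
#' first `n_pcs` principal components.
#'
#' @inheritParams run_de_pipeline
#' @param selection A `deg_selection`.
#' @param factors Normalization factors.
#' @param n_pcs Components used for MANOVA (default 2; six samples allow
#'   no more).
#' @param max_perms See [permanova()].
#' @return A `separation_report` list.
#' @export
separation_analysis <- function(counts, samples, selection,
                                factors = NULL, n_pcs = 2,
                                max_perms = 999) {
  m <- counts_matrix(counts)
  g <- group_factor(samples, m)
  genes <- c(selection$up, selection$down)
  lcpm <- log2(cpm_matrix(m, factors)[genes, , drop = FALSE] + 1)
  x <- t(lcpm)
  pca <- pca_scores(x)
  d <- stats::dist(x)
  pmv <- permanova(d, g, max_perms = max_perms)
  ano <- anosim(d, g, max_perms = max_perms)
  mw <- manova_wilks(as.matrix(pca$scores[, 1 + seq_len(n_pcs)]), g)
  structure(list(
    pc_variance_fractions = pca$variance_fractions, pca = pca,
    permanova_F = pmv$F, permanova_R2 = pmv$R2, permanova_p = pmv$p,
    anosim_R = ano$R, anosim_p = ano$p,
    wilks_lambda = mw$lambda, manova_p = mw$p,
    n_permutations_enumerated = pmv$n_enumerated,
    exhaustive = pmv$exhaustive
  ), class = "separation_report")
}

#' @export
print.separation_report <- function(x, ...) {
  cat(sprintf(
    paste0("separation_report: PERMANOVA R2 = %.4f (p = %.4f), ",
           "ANOSIM R = %.3f (p = %.4f),\n  MANOVA lambda = %.4f ",
           "(p = %.4f); %d permutations%s; PC1 %.1f%%\n"),
    x$permanova_R2, x$permanova_p, x$anosim_R, x$anosim_p,
    x$wilks_lambda, x$manova_p, x$n_permutations_enumerated,
    if (x$exhaustive) " (exhaustive)" else "",
    100 * x$pc_variance_fractions[1]))
  invisible(x)
}
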