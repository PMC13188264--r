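test_that("jaccard follows the set definition with the empty convention", {
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard(c("a", "b"), c("c", "d")), 0)
  expect_equal(jaccard(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard(character(0), character(0)), 1)
  expect_equal(jaccard(c("a", "a", "b"), c("a", "b")), 1)  # set semantics
})

test_that("resampling reports are deterministic under a fixed seed", {
  sim <- fixture_deletion_sim(n_genes = 150, seed = 51)
  cfg <- pipeline_config(k = 30, dispersion = 0.05,
                         deges = deges_config(0))
  b1 <- bootstrap_validation(sim$counts, sim$samples, cfg, n_iter = 5,
                             seed = 123)
  b2 <- bootstrap_validation(sim$counts, sim$samples, cfg, n_iter = 5,
                             seed = 123)
  expect_identical(b1, b2)
  expect_equal(b1$iterations, 5)
  expect_true(all(b1$jaccard_up >= 0 & b1$jaccard_up <= 1))

  s1 <- subsample_validation(sim$counts, sim$samples, cfg, n_iter = 4,
                             seed = 123)
  s2 <- subsample_validation(sim$counts, sim$samples, cfg, n_iter = 4,
                             seed = 123)
  expect_identical(s1, s2)

  two <- sim$counts[, c(1, 2, 3, 5, 6)]   # 2 samples per group
  smp <- sim$samples[c(1, 2, 4, 5), ]
  expect_error(subsample_validation(two, smp, cfg), ">= 3")
})

test_that("permutation null hits the enumeration floor for strong
           effects and follows the +1 formula", {
  sim <- simulate_counts(sim_config(
    n_genes = 250, lib_size_mean = 1e5, dispersion = 0.01,
    deletion_block = 1:40, deletion_dosage = 0.25, seed = 53))
  cfg <- pipeline_config(k = 300, dispersion = 0.05,
                         deges = deges_config(0))
  pr <- permutation_null(sim$counts, sim$samples, cfg, seed = 123)
  expect_true(pr$exhaustive)
  expect_length(pr$t_null, choose(6, 3) - 1)
  # observed equals its label-swapped mirror, so the minimum attainable
  # p is 2/20; a real effect should sit exactly on that floor
  expect_equal(pr$empirical_p, 0.1)
  expect_equal(pr$empirical_p,
               (1 + sum(pr$t_null >= pr$t_observed)) /
                 (1 + length(pr$t_null)))
})

test_that("PCA scores separate constructed clusters and fractions sum
           to 1", {
  withr::local_seed(5)
  x <- rbind(matrix(rnorm(20, 0, 0.1), 5), matrix(rnorm(20, 8, 0.1), 5))
  pc <- pca_scores(x)
  expect_equal(sum(pc$variance_fractions), 1)
  expect_gt(pc$variance_fractions[1], max(pc$variance_fractions[-1]))
  expect_error(pca_scores(matrix(1, 4, 3)), "constant")
})

test_that("PERMANOVA and ANOSIM agree with vegan and enumerate 719
           orderings for 3v3", {
  withr::local_seed(7)
  x <- rbind(matrix(rnorm(6, 0), 3, 2), matrix(rnorm(6, 100), 3, 2))
  lab <- rep(c("a", "b"), each = 3)
  d <- stats::dist(x)
  pm <- permanova(d, lab)
  expect_equal(pm$n_enumerated, 719)
  expect_true(pm$exhaustive)
  expect_equal(pm$p, 0.1)
  ad <- vegan::adonis2(d ~ lab, permutations = 5)
  expect_equal(pm$F, ad$F[1], tolerance = 1e-10)
  expect_equal(pm$R2, ad$R2[1], tolerance = 1e-10)

  an <- anosim(d, lab)
  expect_equal(an$R, 1)
  expect_equal(an$p, 0.1)
  va <- suppressWarnings(vegan::anosim(d, grouping = lab,
                                       permutations = 5))
  expect_equal(an$R, unname(va$statistic), tolerance = 1e-10)

  # shuffled labels on structureless data: small R2, p on the grid
  xn <- matrix(rnorm(24), 6)
  pn <- permanova(stats::dist(xn), lab)
  expect_gte(pn$p, 0.1)
  expect_lt(pn$R2, 0.7)
  expect_equal(pn$p * 720, round(pn$p * 720))

  # ANOSIM R stays in [-1, 1] on random distance matrices and is
  # centred near 0 for labels independent of structure
  rs <- sapply(1:30, function(i) {
    anosim(stats::dist(matrix(rnorm(24), 6)), lab)$R
  })
  expect_true(all(rs >= -1 & rs <= 1))
  expect_lt(abs(mean(rs)), 0.25)

  expect_error(permanova(d, rep("a", 6)), "levels")
})

test_that("Wilks' lambda matches the two-sample t-test at q = 1 and
           tracks separation", {
  withr::local_seed(11)
  y <- c(rnorm(6), rnorm(7, 2))
  g <- rep(c("a", "b"), c(6, 7))
  mw <- manova_wilks(matrix(y), g)
  tt <- stats::t.test(y ~ g, var.equal = TRUE)
  expect_equal(mw$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(mw$p, tt$p.value, tolerance = 1e-10)

  x_sep <- rbind(matrix(rnorm(20, 0, 0.01), 10),
                 matrix(rnorm(20, 5, 0.01), 10))
  lab <- rep(c("a", "b"), each = 10)
  expect_lt(manova_wilks(x_sep, lab)$lambda, 0.01)

  x_same <- matrix(rnorm(60), 30)
  expect_gt(manova_wilks(x_same, rep(c("a", "b"), each = 15))$lambda,
            0.5)
  expect_error(manova_wilks(matrix(rnorm(12), 4, 3),
                            rep(c("a", "b"), 2)), "components")
})

test_that("separation analysis bundles the statistics coherently", {
  sim <- fixture_deletion_sim(n_genes = 200, seed = 59)
  run <- run_de_pipeline(sim$counts, sim$samples,
                         pipeline_config(k = 40, dispersion = 0.05,
                                         deges = deges_config(0)))
  sep <- separation_analysis(sim$counts, sim$samples, run$selection,
                             run$factors)
  expect_s3_class(sep, "separation_report")
  expect_equal(sum(sep$pc_variance_fractions), 1)
  expect_equal(sep$n_permutations_enumerated, 719)
  expect_true(sep$anosim_R >= -1 && sep$anosim_R <= 1)
  expect_true(sep$permanova_R2 >= 0 && sep$permanova_R2 <= 1)
  gl <- glance(sep)
  expect_equal(gl$anosim_R, sep$anosim_R)
  expect_equal(nrow(gl), 1)
})
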