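test_that("TMM factors are 1 for compositionally identical samples and
           multiply to 1 in general", {
  m <- matrix(rpois(200, 50), ncol = 2,
              dimnames = list(sprintf("g%03d", 1:100), c("s1", "s2")))
  m[, 2] <- m[, 1] * 2          # same composition, double depth
  f <- tmm_factors(m)
  expect_equal(f$norm_factor, c(1, 1))

  sim <- fixture_null_sim(n_genes = 300, seed = 17)
  f <- tmm_factors(sim$counts)
  expect_equal(prod(f$norm_factor), 1, tolerance = 1e-12)

  bad <- m; bad[, 2] <- 0
  expect_error(tmm_factors(bad), "s2")
})

test_that("a spiked sample gets a compensating factor, matching a
           brute-force trimmed weighted mean and edgeR", {
  withr::local_seed(99)
  m <- matrix(rnbinom(3000, mu = 100, size = 20), ncol = 3,
              dimnames = list(sprintf("g%04d", 1:1000),
                              c("s1", "s2", "s3")))
  spiked <- sample(1000, 50)
  m[spiked, 3] <- m[spiked, 3] * 10
  f <- tmm_factors(m)
  # spiked sample's non-spiked genes are diluted -> factor below 1
  expect_lt(f$norm_factor[3] / exp(mean(log(f$norm_factor))), 1)

  # independent brute-force recomputation of the pairwise factor
  lib <- colSums(m)
  f75 <- sapply(1:3, function(j) quantile(m[, j] / lib[j], 0.75))
  ref <- which.min(abs(f75 - mean(f75)))
  obs <- m[, 3]; rf <- m[, ref]
  ok <- obs > 0 & rf > 0
  M <- log2((obs[ok] / lib[3]) / (rf[ok] / lib[ref]))
  A <- (log2(obs[ok] / lib[3]) + log2(rf[ok] / lib[ref])) / 2
  w <- (lib[3] - obs[ok]) / (lib[3] * obs[ok]) +
    (lib[ref] - rf[ok]) / (lib[ref] * rf[ok])
  n <- length(M)
  keepM <- rank(M) >= floor(n * 0.3) + 1 & rank(M) <= n - floor(n * 0.3)
  keepA <- rank(A) >= floor(n * 0.05) + 1 & rank(A) <= n - floor(n * 0.05)
  keep <- keepM & keepA
  brute <- 2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  raw3 <- descore:::tmm_pair_factor(m[, 3], m[, ref], lib[3], lib[ref])
  expect_equal(raw3, brute, tolerance = 1e-12)

  eg <- edgeR::calcNormFactors(edgeR::DGEList(m))
  expect_equal(f$norm_factor, eg$samples$norm.factors,
               tolerance = 1e-10)
})

test_that("cpm matrix follows the definition and scale cancellation", {
  m <- matrix(c(100, 0, 900, 0, 0, 0), ncol = 2,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  fac <- tibble::tibble(sample_id = c("s1", "s2"),
                        lib_size = c(1e6, 1e6), norm_factor = c(1, 1))
  cp <- cpm_matrix(m, fac)
  expect_equal(cp["g1", "s1"], 100)
  expect_equal(unname(cp["g2", ]), c(0, 0))

  sim <- fixture_null_sim(n_genes = 100, seed = 3)
  m <- as.matrix(sim$counts[, -1])
  rownames(m) <- sim$counts$gene_id
  m2 <- m; m2[, 1] <- m2[, 1] * 2
  expect_equal(cpm_matrix(m)[, 1], cpm_matrix(m2)[, 1])

  expect_error(cpm_matrix(m, tibble::tibble(
    sample_id = colnames(m), lib_size = 0, norm_factor = 1)),
    "library")
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  withr::local_seed(1)
  for (i in 1:10) {
    p <- runif(sample(5:50, 1))
    q <- bh_adjust(p)
    expect_equal(q, brute_bh(p))
    expect_true(all(q >= p))
  }
})

test_that("exact test respects symmetry contracts", {
  sim <- fixture_deletion_sim(n_genes = 200, seed = 9)
  fac <- tmm_factors(sim$counts)
  st <- nb_exact_test(sim$counts, sim$samples, fac)

  # permuting sample order within groups changes nothing
  perm_cols <- c("gene_id", "s2_g1", "s1_g1", "s3_g1",
                 "s5_g2", "s6_g2", "s4_g2")
  st2 <- nb_exact_test(sim$counts[, perm_cols], sim$samples, fac)
  expect_equal(st, st2, ignore_attr = TRUE)

  # a no-change gene with equal effective libraries has m = 0
  m <- matrix(c(50, 10, 50, 10, 50, 12, 50, 12), nrow = 2,
              dimnames = list(c("g1", "g2"),
                              c("a1", "a2", "b1", "b2")))
  smp <- tibble::tibble(sample_id = colnames(m),
                        group = c("a", "a", "b", "b"))
  fac0 <- tibble::tibble(sample_id = colnames(m),
                         lib_size = 100, norm_factor = 1)
  st3 <- nb_exact_test(m, smp, fac0)
  expect_equal(st3$m_value[1], 0)
  expect_equal(st3$p_value[1], 1)

  expect_error(nb_exact_test(m, tibble::tibble(
    sample_id = colnames(m), group = c("a", "b", "b", "b"))),
    "at least 2")
})

test_that("exact-test p-values are near-uniform under the null and
           concordant with edgeR", {
  sim <- fixture_null_sim(n_genes = 2000, seed = 1)
  fac <- tmm_factors(sim$counts)
  st <- nb_exact_test(sim$counts, sim$samples, fac)
  grid <- seq(0.01, 0.99, by = 0.01)
  ks <- max(abs(sapply(grid, function(t) mean(st$p_value <= t) - t)))
  expect_lt(ks, 0.1)

  m <- as.matrix(sim$counts[, -1])
  rownames(m) <- sim$counts$gene_id
  d <- edgeR::DGEList(m, group = sim$samples$group)
  d <- edgeR::calcNormFactors(d)
  d <- edgeR::estimateCommonDisp(d)
  expect_equal(attr(st, "dispersion"), d$common.dispersion,
               tolerance = 0.15)
  et <- edgeR::exactTest(d)
  expect_gt(cor(st$p_value, et$table$PValue, method = "spearman"),
            0.99)
})

test_that("DEGES iteration reduces to TMM with no signal and converges", {
  sim <- fixture_null_sim(n_genes = 300, seed = 23)
  f_tmm <- tmm_factors(sim$counts)
  f_0 <- deges_factors(sim$counts, sim$samples, deges_config(0))
  expect_identical(f_tmm, f_0)

  f_3 <- deges_factors(sim$counts, sim$samples, deges_config(3))
  expect_equal(f_3$norm_factor, f_tmm$norm_factor, tolerance = 0.01)

  del <- fixture_deletion_sim(n_genes = 400, seed = 29)
  f2 <- deges_factors(del$counts, del$samples, deges_config(2))
  f3 <- deges_factors(del$counts, del$samples, deges_config(3))
  expect_equal(f3$norm_factor, f2$norm_factor, tolerance = 0.005)
})
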