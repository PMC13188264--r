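fixture_join <- function(n_extra = 80, n_uu = 9, n_dd = 12,
                         n_disc = 2, seed = 3) {
  withr::with_seed(seed, {
    n_sh <- n_uu + n_dd + n_disc
    sgn_a <- c(rep(1, n_uu), rep(-1, n_dd), rep(1, n_disc))
    sgn_b <- c(rep(1, n_uu), rep(-1, n_dd), rep(-1, n_disc))
    tibble::tibble(
      id_a = sprintf("A%03d", 1:(n_sh + n_extra)),
      id_b = sprintf("B%03d", 1:(n_sh + n_extra)),
      de_score_a = c(sgn_a * runif(n_sh, 0.5, 3),
                     rnorm(n_extra, 0, 0.2)),
      de_score_b = c(sgn_b * runif(n_sh, 0.5, 3),
                     rnorm(n_extra, 0, 0.2)),
      deg_a = c(rep("up", n_uu), rep("down", n_dd), rep("up", n_disc),
                rep("none", n_extra)),
      deg_b = c(rep("up", n_uu), rep("down", n_dd), rep("down", n_disc),
                rep("none", n_extra)))
  })
}

test_that("ortholog join restricts to mapped, filtered genes", {
  sa <- tibble::tibble(gene_id = c("a1", "a2", "a3"),
                       de_score = c(1, -1, 2))
  sb <- tibble::tibble(gene_id = c("b1", "b2"), de_score = c(0.5, -2))
  map <- tibble::tibble(id_a = c("a1", "a2", "a9"),
                        id_b = c("b1", "b2", "b9"))
  expect_message(j <- join_orthologs(sa, sb, map), "dropped")
  expect_equal(nrow(j), 2)
  expect_equal(j$de_score_b, c(0.5, -2))
  expect_equal(j$deg_a, c("none", "none"))

  bad <- tibble::tibble(id_a = c("a1", "a1"), id_b = c("b1", "b2"))
  expect_error(join_orthologs(sa, sb, bad), "a1")
})

test_that("score correlation recovers exact and null relationships", {
  j <- fixture_join()
  j1 <- dplyr::mutate(j, de_score_b = .data$de_score_a)
  expect_equal(score_correlation(j1)$spearman_rho, 1)
  j2 <- dplyr::mutate(j, de_score_b = -.data$de_score_a)
  expect_equal(score_correlation(j2)$spearman_rho, -1)

  # null: independent scores, n = 1000; |rho| < 0.08 is ~2.5 sigma
  hits <- sum(sapply(1:20, function(s) {
    withr::with_seed(s, {
      jj <- tibble::tibble(id_a = as.character(1:1000),
                           id_b = as.character(1:1000),
                           de_score_a = rnorm(1000),
                           de_score_b = rnorm(1000),
                           deg_a = "none", deg_b = "none")
    })
    abs(score_correlation(jj)$spearman_rho) < 0.08
  }))
  expect_gte(hits, 18)

  expect_error(score_correlation(dplyr::mutate(j, de_score_b = 1)),
               "constant")
})

test_that("DEG overlap reproduces the worked concordance arithmetic", {
  j <- fixture_join(n_uu = 9, n_dd = 12, n_disc = 2)
  rep <- deg_overlap(j)
  expect_equal(rep$n_shared_degs, 23)
  expect_equal(rep$n_up_up, 9)
  expect_equal(rep$n_down_down, 12)
  expect_equal(rep$n_concordant, 21)
  expect_equal(rep$concordance_rate, 21 / 23)
  expect_equal(round(100 * rep$concordance_rate, 1), 91.3)
  expect_equal(rep$n_concordant + 2, rep$n_shared_degs)

  # symmetric under species swap
  js <- dplyr::rename(j, id_a = "id_b", id_b = "id_a",
                      de_score_a = "de_score_b",
                      de_score_b = "de_score_a",
                      deg_a = "deg_b", deg_b = "deg_a")
  rs <- deg_overlap(js)
  expect_equal(rs$fisher_or, rep$fisher_or)
  expect_equal(rs$fisher_p, rep$fisher_p)
  expect_equal(rs$concordance_rate, rep$concordance_rate)
})

test_that("Fisher p matches exhaustive enumeration on small joins", {
  # join of 10: 5 DEG in A; arrange B's 5 DEGs exactly on A's
  j <- tibble::tibble(
    id_a = sprintf("A%02d", 1:10), id_b = sprintf("B%02d", 1:10),
    de_score_a = c(rep(2, 5), rep(0.1, 5)),
    de_score_b = c(rep(2, 5), rep(0.1, 5)),
    deg_a = c(rep("up", 5), rep("none", 5)),
    deg_b = c(rep("up", 5), rep("none", 5)))
  rep <- deg_overlap(j)
  # enumeration at fixed margins: P(X = k) = C(5,k) C(5,5-k) / C(10,5);
  # two-sided p sums all tables no more probable than X = 5
  probs <- dhyper(0:5, 5, 5, 5)
  p_enum <- sum(probs[probs <= probs[6] + 1e-12])
  expect_equal(rep$fisher_p, p_enum, tolerance = 1e-12)
  expect_equal(rep$fisher_p, 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(rep$fisher_or, NA_real_)   # zero off-diagonal margin

  # balanced 2x2 -> OR 1, p 1
  jb <- tibble::tibble(
    id_a = sprintf("A%02d", 1:40), id_b = sprintf("B%02d", 1:40),
    de_score_a = rep(c(2, 2, 0.1, 0.1), 10),
    de_score_b = rep(c(2, 0.1, 2, 0.1), 10),
    deg_a = rep(c("up", "up", "none", "none"), 10),
    deg_b = rep(c("up", "none", "up", "none"), 10))
  rb <- deg_overlap(jb)
  expect_equal(rb$fisher_or, 1)
  expect_equal(rb$fisher_p, 1)
})

test_that("fully shared strong signal yields near-total concordance", {
  cfg_a <- sim_config(n_genes = 400, lib_size_mean = 2e5,
                      dispersion = 0.02, de_up_fraction = 0.08,
                      de_down_fraction = 0.08,
                      de_log2fc_range = c(1.5, 3), seed = 61)
  cfg_b <- sim_config(n_genes = 400, n_per_group = c(10L, 10L),
                      lib_size_mean = 2e5, dispersion = 0.02,
                      de_log2fc_range = c(1.5, 3), seed = 62)
  pair <- simulate_species_pair(cfg_a, cfg_b,
                                shared_signal_fraction = 1)
  cfg <- pipeline_config(k = 50, deges = deges_config(0))
  run_a <- run_de_pipeline(pair$species_a$counts,
                           pair$species_a$samples, cfg)
  run_b <- run_de_pipeline(pair$species_b$counts,
                           pair$species_b$samples, cfg)
  j <- suppressMessages(join_orthologs(run_a$scored, run_b$scored,
                                       pair$ortholog_map,
                                       run_a$selection,
                                       run_b$selection))
  rep <- deg_overlap(j)
  expect_gt(rep$n_shared_degs, 10)
  expect_gte(rep$concordance_rate, 0.9)
  corr <- score_correlation(j)
  expect_gt(corr$spearman_rho, 0.2)
  expect_lt(corr$spearman_p, 0.001)
})

test_that("cross-species pathway consensus distinguishes strict and
           union sharing", {
  mk_ora <- function(sets, qs) tibble::tibble(set = sets, q_value = qs)
  ora_a <- list(up = mk_ora(c("P1", "P2"), c(0.01, 0.01)),
                down = mk_ora("P5", 0.01))
  ora_b <- list(up = mk_ora(c("P1", "P3"), c(0.01, 0.01)),
                down = mk_ora("P5", 0.2))
  gsea_a <- tibble::tibble(set = c("P1", "P2", "P5"),
                           fdr_q = c(0.01, 0.2, 0.01), nes = c(2, 1, -2),
                           direction = c("up", "up", "down"))
  gsea_b <- tibble::tibble(set = c("P1", "P3", "P5"),
                           fdr_q = c(0.01, 0.01, 0.01),
                           nes = c(2, 1.5, -2),
                           direction = c("up", "up", "down"))
  expect_warning(
    out <- cross_pathway_consensus(ora_a, gsea_a, ora_b, gsea_b),
    "too few")
  # strict: P1 passes both methods in both species; P5 fails ORA in B
  expect_equal(out$strict$up, "P1")
  expect_length(out$strict$down, 0)
  # union-shared: {P1,P2,P5} in A intersected with {P1,P3,P5} in B
  expect_setequal(out$shared, c("P1", "P5"))
  expect_null(out$correlation)   # two pathways cannot be correlated
  # identical species: three union-shared pathways, perfect correlation
  out2 <- cross_pathway_consensus(ora_a, gsea_a, ora_a, gsea_a)
  expect_setequal(out2$shared, c("P1", "P2", "P5"))
  expect_equal(out2$correlation$pearson_r, 1, tolerance = 1e-12)
})
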