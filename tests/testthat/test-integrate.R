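fixture_scored <- function(ids, de) {
  tibble::tibble(gene_id = ids, m_value = sign(de), a_value = 1,
                 p_value = 0.01, q_value = 0.05, scaled_a = 0.5,
                 de_score = de, rank = order(order(-de, ids)))
}

test_that("hub ranking uses term count then |DE score| then gene id", {
  scored <- fixture_scored(c("g1", "g2", "g3"), c(0.5, -2, 2))
  ora_res <- tibble::tibble(
    set = c("T1", "T2", "T3"),
    overlap = 2, set_size = 10, query_size = 5,
    p_value = c(0.001, 0.002, 0.003),
    q_value = c(0.01, 0.02, 0.03),
    overlap_genes = list(c("g1", "g2"), c("g1", "g3"), c("g2", "g3")))
  clusters <- tibble::tibble(cluster_id = 1:3,
                             representative = c("T1", "T2", "T3"),
                             representative_q = c(0.01, 0.02, 0.03),
                             n_members = 1,
                             members = list("T1", "T2", "T3"))
  hubs <- hub_genes_ora(clusters, ora_res, scored, top_n = 20)
  # every gene appears in 2 representative terms; |de| breaks the ties
  expect_equal(hubs$term_count, rep(2L, 3))
  expect_equal(hubs$gene_id, c("g2", "g3", "g1"))
  expect_equal(hubs$rank, 1:3)

  # restricting to representatives only: drop T3 from the clusters
  hubs2 <- hub_genes_ora(clusters[1:2, ], ora_res, scored, top_n = 20)
  expect_equal(hubs2$gene_id[1], "g1")     # now g1 leads with 2 terms
  expect_equal(hubs2$term_count, c(2L, 1L, 1L))

  expect_equal(nrow(hub_genes_ora(clusters, ora_res, scored,
                                  top_n = 0)), 0)
})

test_that("GSEA hub genes count leading-edge membership", {
  scored <- fixture_scored(c("g1", "g2", "g3"), c(1, 1.5, -0.5))
  gres <- tibble::tibble(
    set = c("P1", "P2", "P3"), size = 10, es = 0.5, nes = 2,
    p_value = 0.001, fdr_q = 0.01, direction = "up",
    leading_edge = list(c("g1", "g2"), c("g1", "g2"), "g1"))
  hubs <- hub_genes_gsea(gres, scored, top_n = 2)
  expect_equal(hubs$gene_id, c("g1", "g2"))
  expect_equal(hubs$term_count, c(3L, 2L))
  expect_false("g3" %in% hubs$gene_id)   # never a leading-edge member
})

test_that("consensus requires both methods to agree in direction", {
  ora_up <- tibble::tibble(set = c("P1", "P2"),
                           q_value = c(0.01, 0.2))
  ora_down <- tibble::tibble(set = c("P3", "P4"),
                             q_value = c(0.01, 0.01))
  gsea <- tibble::tibble(
    set = c("P1", "P2", "P3", "P4"),
    fdr_q = c(0.01, 0.01, 0.01, 0.2),
    direction = c("up", "up", "down", "down"))
  cons <- consensus_pathways(ora_up, ora_down, gsea)
  expect_equal(cons$up, "P1")     # P2 fails ORA q
  expect_equal(cons$down, "P3")   # P4 fails GSEA q

  # a pathway up in ORA but negatively enriched in GSEA is excluded
  gsea2 <- dplyr::mutate(gsea,
    direction = ifelse(.data$set == "P1", "down", .data$direction))
  expect_length(consensus_pathways(ora_up, ora_down, gsea2)$up, 0)

  # identical significant sets intersect fully
  ora_all <- tibble::tibble(set = paste0("Q", 1:5), q_value = 0.01)
  gsea_all <- tibble::tibble(set = paste0("Q", 1:5), fdr_q = 0.01,
                             direction = "up")
  expect_length(consensus_pathways(
    ora_all, ora_all[0, ], gsea_all)$up, 5)
})

test_that("combined score follows the Euclidean-norm formula", {
  ps <- combined_score(tibble::tibble(
    set = "P", ora_q = 0.05, nes = 2, gsea_q = 0.05))
  expect_equal(ps$ora_score, 1.30103, tolerance = 1e-5)
  expect_equal(ps$gsea_score, 2.60206, tolerance = 1e-5)
  expect_equal(ps$combined, 2.909193, tolerance = 1e-5)
  expect_gte(ps$combined, max(ps$ora_score, ps$gsea_score))

  zero <- combined_score(tibble::tibble(
    set = "P", ora_q = 1, nes = 2, gsea_q = 1))
  expect_equal(zero$combined, 0)

  neg <- combined_score(tibble::tibble(
    set = "P", ora_q = 0.05, nes = -2, gsea_q = 0.05))
  expect_equal(neg$combined, ps$combined)
  expect_equal(neg$direction, "down")

  expect_error(combined_score(tibble::tibble(
    set = "P", ora_q = 0, nes = 1, gsea_q = 0.5)), "zero-replacement")
})

test_that("priority scores multiply count, mean combined and |DE|", {
  sets <- gene_set_collection(list(P1 = c("g1", "g2"),
                                   P2 = c("g1", "g3"),
                                   P3 = c("g9")))
  ps <- combined_score(tibble::tibble(
    set = c("P1", "P2", "P3"),
    ora_q = 10^-c(3, 5, 1), nes = 1, gsea_q = 1))
  ps$combined <- c(3, 5, 1)   # exact arithmetic for the hand check
  pri <- priority_scores(c("P1", "P2", "P3"), ps, sets,
                         degs = c("g1", "g2"),
                         scored = fixture_scored(c("g1", "g2", "g3"),
                                                 c(2, -1, 1)))
  g1 <- pri[pri$gene_id == "g1", ]
  expect_equal(g1$pathway_count, 2L)
  expect_equal(g1$mean_combined, 4)
  expect_equal(g1$priority, 2 * 4 * 2)   # = 16
  expect_false("g3" %in% pri$gene_id)    # not a DEG
  expect_false("g9" %in% pri$gene_id)

  # doubling |de_score| doubles priority
  pri2 <- priority_scores(c("P1", "P2", "P3"), ps, sets,
                          degs = c("g1", "g2"),
                          scored = fixture_scored(c("g1", "g2", "g3"),
                                                  c(4, -2, 2)))
  expect_equal(pri2$priority[pri2$gene_id == "g1"], 32)
})

test_that("chord export caps pathways and genes deterministically", {
  ids <- sprintf("g%02d", 1:60)
  sets <- gene_set_collection(list(P1 = ids[1:50], P2 = ids[51:55],
                                   P3 = ids[56:58]))
  ps <- combined_score(tibble::tibble(
    set = c("P1", "P2", "P3"), ora_q = c(1e-4, 1e-3, 1e-2),
    nes = 1.5, gsea_q = 0.01))
  scored <- fixture_scored(ids, seq(2, 0.5, length.out = 60))
  pri <- priority_scores(c("P1", "P2", "P3"), ps, sets, degs = ids,
                         scored = scored)
  ch <- chord_export(c("P1", "P2", "P3"), ps, pri, sets, degs = ids,
                     top_pathways = 5, top_genes = 20)
  expect_setequal(unique(ch$set), c("P1", "P2", "P3"))
  expect_equal(sum(ch$set == "P1"), 20)   # capped from 50 members
  expect_equal(sum(ch$set == "P2"), 5)
  ch2 <- chord_export(c("P1", "P2", "P3"), ps, pri, sets, degs = ids,
                      top_pathways = 2, top_genes = 20)
  expect_setequal(unique(ch2$set), c("P1", "P2"))
})
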