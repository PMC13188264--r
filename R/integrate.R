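rank_hub_table <- function(counts_tbl, scored, top_n) {
  de <- setNames(scored$de_score, scored$gene_id)
  out <- dplyr::mutate(counts_tbl,
                       de_score = unname(de[.data$gene_id]))
  out <- dplyr::arrange(out, dplyr::desc(.data$term_count),
                        dplyr::desc(abs(.data$de_score)), .data$gene_id)
  out <- dplyr::mutate(out, rank = dplyr::row_number())
  head(out, top_n)
}

#' Hub genes from ORA representative terms
#'
#' Counts, for each DEG, how many representative terms (one per semantic
#' cluster) include it among their overlap genes; genes are ranked by
#' term count (descending) with ties broken by `|de_score|`, then gene
#' id, and the top `top_n` returned.
#'
#' @param clusters A `term_clusters` table ([cluster_terms()]) whose
#'   representatives index rows of `ora_results`.
#' @param ora_results An `ora_result` table carrying `overlap_genes`.
#' @param scored A `scored_genes` table (source of DE scores).
#' @param top_n Genes to return (default 20).
#' @return Tibble: `gene_id`, `term_count`, `de_score`, `rank`.
#' @export
hub_genes_ora <- function(clusters, ora_results, scored, top_n = 20) {
  reps <- clusters$representative
  sub <- dplyr::filter(ora_results, .data$set %in% reps)
  genes <- unlist(sub$overlap_genes)
  if (length(genes) == 0 || top_n == 0) {
    if (length(genes) == 0) {
      rlang::warn("no overlap genes in representative terms")
    }
    return(tibble::tibble(gene_id = character(0), term_count = integer(0),
                          de_score = numeric(0), rank = integer(0)))
  }
  tc <- dplyr::count(tibble::tibble(gene_id = genes), .data$gene_id,
                     name = "term_count")
  rank_hub_table(tc, scored, top_n)
}

#' Hub genes from GSEA leading edges
#'
#' Counts, for each gene, how many significantly enriched pathways
#' include it as a leading-edge member; ranking as in [hub_genes_ora()].
#'
#' @param gsea_results A `gsea_result` table already filtered to
#'   significant pathways (e.g. `fdr_q < 0.05`), typically one direction.
#' @inheritParams hub_genes_ora
#' @return Tibble: `gene_id`, `term_count`, `de_score`, `rank`.
#' @export
hub_genes_gsea <- function(gsea_results, scored, top_n = 20) {
  genes <- unlist(gsea_results$leading_edge)
  if (length(genes) == 0 || top_n == 0) {
    if (length(genes) == 0) rlang::warn("no leading-edge genes")
    return(tibble::tibble(gene_id = character(0), term_count = integer(0),
                          de_score = numeric(0), rank = integer(0)))
  }
  tc <- dplyr::count(tibble::tibble(gene_id = genes), .data$gene_id,
                     name = "term_count")
  rank_hub_table(tc, scored, top_n)
}

#' Consensus pathways between ORA and GSEA
#'
#' Per direction, the intersection of pathways significant in ORA
#' (q below threshold, queried with that direction's DEG list) and in
#' GSEA (FDR q below threshold with matching enrichment-score sign).
#'
#' @param ora_up,ora_down `ora_result` tables for the up/down DEG
#'   queries.
#' @param gsea_results A full `gsea_result` table (both signs).
#' @param q_threshold Significance cutoff applied to both methods.
#' @return List with character vectors `up` and `down`.
#' @export
consensus_pathways <- function(ora_up, ora_down, gsea_results,
                               q_threshold = 0.05) {
  sig_ora <- function(x) x$set[x$q_value < q_threshold]
  sig_gsea <- function(dir) {
    gsea_results$set[gsea_results$fdr_q < q_threshold &
                       gsea_results$direction == dir]
  }
  list(up = sort(intersect(sig_ora(ora_up), sig_gsea("up"))),
       down = sort(intersect(sig_ora(ora_down), sig_gsea("down"))))
}

#' Combined pathway score
#'
#' `ORAscore = -log10(ORA q)`, `GSEAscore = |NES| x -log10(GSEA q)`,
#' `combined = sqrt(ORAscore^2 + GSEAscore^2)`. Zero q-values must have
#' been replaced beforehand (see [neglog10_q()], applied here with the
#' same cap); non-positive q-values are an error.
#'
#' @param pathways Tibble with `set`, `ora_q`, `nes`, `gsea_q`.
#' @param cap Cap on each `-log10 q` component (default 50).
#' @return Tibble with `ora_score`, `gsea_score`, `combined` and
#'   `direction` (sign of NES) added.
#' @export
combined_score <- function(pathways, cap = 50) {
  pathways <- tibble::as_tibble(pathways)
  if (any(pathways$ora_q <= 0 | pathways$gsea_q <= 0)) {
    rlang::abort(
      "non-positive q-values: run the zero-replacement transform first")
  }
  dplyr::mutate(pathways,
    ora_score = pmin(-log10(.data$ora_q), cap),
    gsea_score = abs(.data$nes) * pmin(-log10(.data$gsea_q), cap),
    combined = sqrt(.data$ora_score^2 + .data$gsea_score^2),
    direction = ifelse(.data$nes >= 0, "up", "down"))
}

#' Gene priority scores over consensus pathways
#'
#' `priority = (number of consensus pathways containing the gene) x
#' mean(combined score of those pathways) x |DE score|`. A gene belongs
#' to a pathway when it is a member of the pathway's gene set and of the
#' direction's DEG list. Genes absent from the scored table are dropped.
#'
#' @param consensus Character vector of consensus pathway ids (one
#'   direction).
#' @param pathway_scores Output of [combined_score()] covering
#'   `consensus`.
#' @param sets A [gene_set_collection()].
#' @param degs Character vector: the direction's DEG list.
#' @param scored A `scored_genes` table.
#' @return Tibble: `gene_id`, `pathway_count`, `mean_combined`,
#'   `abs_de_score`, `priority`, ordered by decreasing priority (ties by
#'   gene id).
#' @export
priority_scores <- function(consensus, pathway_scores, sets, degs,
                            scored) {
  if (length(consensus) == 0) rlang::abort("'consensus' is empty")
  sl <- collection_list(sets)[consensus]
  comb <- setNames(pathway_scores$combined, pathway_scores$set)
  membership <- purrr::map_dfr(consensus, function(p) {
    g <- intersect(sl[[p]], degs)
    if (length(g) == 0) return(NULL)
    tibble::tibble(set = p, gene_id = g, combined = unname(comb[p]))
  })
  if (nrow(membership) == 0) {
    return(tibble::tibble(gene_id = character(0),
                          pathway_count = integer(0),
                          mean_combined = numeric(0),
                          abs_de_score = numeric(0), priority = numeric(0)))
  }
  de <- setNames(scored$de_score, scored$gene_id)
  missing <- setdiff(unique(membership$gene_id), names(de))
  if (length(missing) > 0) {
    rlang::inform(paste0("genes absent from scored table dropped: ",
                         paste(head(missing, 5), collapse = ", ")))
    membership <- dplyr::filter(membership, !.data$gene_id %in% missing)
  }
  out <- dplyr::summarise(
    dplyr::group_by(membership, .data$gene_id),
    pathway_count = dplyr::n(),
    mean_combined = mean(.data$combined), .groups = "drop")
  out <- dplyr::mutate(out,
    abs_de_score = abs(unname(de[.data$gene_id])),
    priority = .data$pathway_count * .data$mean_combined *
      .data$abs_de_score)
  dplyr::arrange(out, dplyr::desc(.data$priority), .data$gene_id)
}

#' Chord-plot-ready export of top pathways and genes
#'
#' For the `top_pathways` consensus pathways by combined score, emits up
#' to `top_genes` member genes per pathway (ranked by priority, ties by
#' gene id) as a long-format table ready for chord/alluvial plotting.
#'
#' @inheritParams priority_scores
#' @param priorities Output of [priority_scores()].
#' @param top_pathways Pathways to export (default 5).
#' @param top_genes Genes per pathway (default 20).
#' @return Tibble: `set`, `combined`, `gene_id`, `priority`.
#' @export
chord_export <- function(consensus, pathway_scores, priorities, sets,
                         degs, top_pathways = 5, top_genes = 20) {
  ps <- dplyr::filter(pathway_scores, .data$set %in% consensus)
  ps <- dplyr::arrange(ps, dplyr::desc(.data$combined), .data$set)
  ps <- head(ps, top_pathways)
  sl <- collection_list(sets)
  pri <- setNames(priorities$priority, priorities$gene_id)
  purrr::map_dfr(seq_len(nrow(ps)), function(i) {
    g <- intersect(intersect(sl[[ps$set[i]]], degs), names(pri))
    if (length(g) == 0) return(NULL)
    ord <- g[order(-pri[g], g)]
    tibble::tibble(set = ps$set[i], combined = ps$combined[i],
                   gene_id = head(ord, top_genes),
                   priority = unname(pri[head(ord, top_genes)]))
  })
}
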