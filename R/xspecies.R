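check_one_to_one <- function(map) {
  for (col in c("id_a", "id_b")) {
    dup <- map[[col]][duplicated(map[[col]])]
    if (length(dup) > 0) {
      rlang::abort(sprintf(
        "ortholog map is not one-to-one: '%s' appears twice in %s",
        dup[1], col))
    }
  }
  invisible(map)
}

deg_flags <- function(ids, selection) {
  if (is.null(selection)) return(rep("none", length(ids)))
  ifelse(ids %in% selection$up, "up",
         ifelse(ids %in% selection$down, "down", "none"))
}

#' Join two species' scored gene tables through an ortholog map
#'
#' Inner join of the (expression-filtered) scored tables on a strictly
#' one-to-one ortholog map; ids in the map but absent from either table
#' are dropped. DEG flags are attached from each species' selection.
#'
#' @param scored_a,scored_b `scored_genes` tables for species A and B.
#' @param map Tibble with columns `id_a`, `id_b` (one-to-one).
#' @param selection_a,selection_b Optional `deg_selection`s providing
#'   `up`/`down` flags.
#' @return A `xspecies_join` tibble: `id_a`, `id_b`, `de_score_a`,
#'   `de_score_b`, `deg_a`, `deg_b`.
#' @export
join_orthologs <- function(scored_a, scored_b, map,
                           selection_a = NULL, selection_b = NULL) {
  map <- tibble::as_tibble(map)
  check_one_to_one(map)
  n0 <- nrow(map)
  map <- dplyr::filter(map, .data$id_a %in% scored_a$gene_id,
                       .data$id_b %in% scored_b$gene_id)
  if (nrow(map) < n0) {
    rlang::inform(sprintf(
      "%d ortholog pair(s) dropped (absent or filtered in a species)",
      n0 - nrow(map)))
  }
  da <- setNames(scored_a$de_score, scored_a$gene_id)
  db <- setNames(scored_b$de_score, scored_b$gene_id)
  out <- dplyr::mutate(map,
    de_score_a = unname(da[.data$id_a]),
    de_score_b = unname(db[.data$id_b]),
    deg_a = deg_flags(.data$id_a, selection_a),
    deg_b = deg_flags(.data$id_b, selection_b))
  class(out) <- c("xspecies_join", class(out))
  out
}

#' Cross-species correlation of DE scores
#'
#' Spearman's rho and Pearson's r (two-sided) over the ortholog-joined DE
#' scores.
#'
#' @param join An `xspecies_join` from [join_orthologs()].
#' @return One-row tibble: `n_joined`, `spearman_rho`, `spearman_p`,
#'   `pearson_r`, `pearson_p`.
#' @export
score_correlation <- function(join) {
  if (nrow(join) < 3) rlang::abort("need at least 3 joined pairs")
  if (sd(join$de_score_a) == 0 || sd(join$de_score_b) == 0) {
    rlang::abort("constant DE score vector")
  }
  sp <- suppressWarnings(cor.test(join$de_score_a, join$de_score_b,
                                  method = "spearman", exact = FALSE))
  pe <- cor.test(join$de_score_a, join$de_score_b, method = "pearson")
  tibble::tibble(n_joined = nrow(join),
                 spearman_rho = unname(sp$estimate),
                 spearman_p = sp$p.value,
                 pearson_r = unname(pe$estimate),
                 pearson_p = pe$p.value)
}

#' Cross-species DEG overlap and concordance
#'
#' Builds the 2x2 table (DEG in species A x DEG in species B, any
#' direction) over the joined universe; two-sided Fisher exact p and the
#' sample (cross-product) odds ratio. Among shared DEGs, concordance is
#' the fraction with matching DE-score sign.
#'
#' @param join An `xspecies_join` with DEG flags.
#' @return A `concordance_report` (one-row tibble): `n_joined`,
#'   `n_deg_a`, `n_deg_b`, `n_shared_degs`, `n_up_up`, `n_down_down`,
#'   `n_concordant`, `concordance_rate`, `fisher_or`, `fisher_p`. The
#'   odds ratio is `NA` when a table margin is zero.
#' @export
deg_overlap <- function(join) {
  if (nrow(join) == 0) rlang::abort("empty join")
  in_a <- join$deg_a != "none"
  in_b <- join$deg_b != "none"
  tab <- matrix(c(sum(in_a & in_b), sum(in_a & !in_b),
                  sum(!in_a & in_b), sum(!in_a & !in_b)), 2, 2)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  if (!is.finite(or)) or <- NA_real_
  fp <- fisher.test(tab, alternative = "two.sided")$p.value
  shared <- join[in_a & in_b, ]
  n_uu <- sum(shared$de_score_a > 0 & shared$de_score_b > 0)
  n_dd <- sum(shared$de_score_a < 0 & shared$de_score_b < 0)
  out <- tibble::tibble(
    n_joined = nrow(join), n_deg_a = sum(in_a), n_deg_b = sum(in_b),
    n_shared_degs = nrow(shared), n_up_up = n_uu, n_down_down = n_dd,
    n_concordant = n_uu + n_dd,
    concordance_rate = if (nrow(shared) > 0) (n_uu + n_dd) / nrow(shared)
                       else NA_real_,
    fisher_or = or, fisher_p = fp)
  class(out) <- c("concordance_report", class(out))
  out
}

#' Cross-species pathway consensus and combined-score correlation
#'
#' Two notions of shared pathways: (i) strict consensus — significant in
#' ORA and GSEA, in both species, per direction; (ii) union-shared —
#' significant by ORA and/or GSEA in each species. Over the union-shared
#' set, combined scores ([combined_score()]) are correlated across
#' species (a pathway missing from a method contributes q = 1, i.e.
#' score 0).
#'
#' @param ora_a,ora_b Named lists `list(up =, down =)` of `ora_result`
#'   tables per species.
#' @param gsea_a,gsea_b `gsea_result` tables per species.
#' @param q_threshold Significance cutoff (default 0.05).
#' @return List: `strict` (`list(up =, down =)` pathway ids), `shared`
#'   (union-shared ids), `scores` (per-pathway combined scores by
#'   species), `correlation` (tibble or `NULL` when fewer than 3 shared
#'   pathways, with a warning).
#' @export
cross_pathway_consensus <- function(ora_a, gsea_a, ora_b, gsea_b,
                                    q_threshold = 0.05) {
  strict_a <- consensus_pathways(ora_a$up, ora_a$down, gsea_a, q_threshold)
  strict_b <- consensus_pathways(ora_b$up, ora_b$down, gsea_b, q_threshold)
  strict <- list(up = intersect(strict_a$up, strict_b$up),
                 down = intersect(strict_a$down, strict_b$down))
  union_sig <- function(ora, gsea) {
    union(c(ora$up$set[ora$up$q_value < q_threshold],
            ora$down$set[ora$down$q_value < q_threshold]),
          gsea$set[gsea$fdr_q < q_threshold])
  }
  shared <- intersect(union_sig(ora_a, gsea_a), union_sig(ora_b, gsea_b))
  if (length(shared) == 0) {
    rlang::warn("no shared significant pathway between species")
    return(list(strict = strict, shared = shared, scores = NULL,
                correlation = NULL))
  }
  species_scores <- function(ora, gsea) {
    oq <- setNames(c(ora$up$q_value, ora$down$q_value),
                   c(ora$up$set, ora$down$set))
    gq <- setNames(gsea$fdr_q, gsea$set)
    gn <- setNames(gsea$nes, gsea$set)
    tab <- tibble::tibble(
      set = shared,
      ora_q = pmax(ifelse(is.na(oq[shared]), 1, oq[shared]), 1e-50),
      nes = ifelse(is.na(gn[shared]), 0, gn[shared]),
      gsea_q = pmax(ifelse(is.na(gq[shared]), 1, gq[shared]), 1e-50))
    combined_score(tab)$combined
  }
  scores <- tibble::tibble(set = shared,
                           combined_a = species_scores(ora_a, gsea_a),
                           combined_b = species_scores(ora_b, gsea_b))
  correlation <- NULL
  if (nrow(scores) >= 3 && sd(scores$combined_a) > 0 &&
      sd(scores$combined_b) > 0) {
    sp <- suppressWarnings(cor.test(scores$combined_a, scores$combined_b,
                                    method = "spearman", exact = FALSE))
    pe <- cor.test(scores$combined_a, scores$combined_b,
                   method = "pearson")
    correlation <- tibble::tibble(
      n_shared = nrow(scores),
      spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
      pearson_r = unname(pe$estimate), pearson_p = pe$p.value)
  } else {
    rlang::warn("too few shared pathways for a correlation")
  }
  list(strict = strict, shared = shared, scores = scores,
       correlation = correlation)
}
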