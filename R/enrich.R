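#' Gene set collection
#'
#' A tibble with one row per set (`set`, `description`, and a `genes`
#' list-column) plus class `gene_set_collection`. Construct from a named
#' list of member vectors or read from GMT with [read_gmt()].
#'
#' @param sets Named list of character vectors (members).
#' @param descriptions Optional character vector parallel to `sets`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    rlang::abort("set names must be present and unique")
  }
  if (any(lengths(sets) == 0)) rlang::abort("empty gene sets not allowed")
  out <- tibble::tibble(
    set = names(sets),
    description = descriptions %||% rep("na", length(sets)),
    genes = lapply(unname(sets), function(g) unique(as.character(g))))
  class(out) <- c("gene_set_collection", class(out))
  out
}

collection_list <- function(sets) {
  if (inherits(sets, "gene_set_collection") || is.data.frame(sets)) {
    setNames(sets$genes, sets$set)
  } else sets
}

#' Read a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then members. Duplicate members within a set are dropped; duplicate set
#' names, lines with fewer than three fields, or sets with no members are
#' errors.
#'
#' @param path File path.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    rlang::abort(sprintf("GMT line %d has fewer than 3 fields", short[1]))
  }
  nm <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(nm)) {
    rlang::abort(sprintf("duplicate set name: %s", nm[duplicated(nm)][1]))
  }
  members <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  if (any(lengths(members) == 0)) {
    rlang::abort("GMT set with empty member list")
  }
  gene_set_collection(setNames(members, nm),
                      vapply(fields, `[[`, character(1), 2))
}

#' Write a GMT file
#'
#' @param sets A [gene_set_collection()] (or named list).
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  sets <- if (is.data.frame(sets)) sets else gene_set_collection(sets)
  lines <- vapply(seq_len(nrow(sets)), function(i) {
    paste(c(sets$set[i], sets$description[i], sets$genes[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Over-representation analysis (hypergeometric + BH)
#'
#' For each gene set, the upper-tail hypergeometric probability of the
#' observed overlap between the query list and the set, both restricted
#' to the background universe; BH adjustment across tested sets. Sets with
#' no member in the background are skipped.
#'
#' @param query Character vector of gene ids (must be a subset of
#'   `background`).
#' @param background Character vector: the enrichment universe (e.g. all
#'   expression-filtered genes).
#' @param sets A [gene_set_collection()].
#' @param q_threshold Stored on the result for downstream significance
#'   calls (default 0.05).
#' @return An `ora_result` tibble: `set`, `overlap`, `set_size`,
#'   `query_size`, `p_value`, `q_value`, `overlap_genes` (list-column),
#'   ordered by p.
#' @export
ora <- function(query, background, sets, q_threshold = 0.05) {
  query <- unique(query)
  background <- unique(background)
  off <- setdiff(query, background)
  if (length(off) > 0) {
    rlang::abort(paste0("query genes outside the background: ",
                        paste(head(off, 5), collapse = ", ")))
  }
  sl <- collection_list(sets)
  sl <- lapply(sl, intersect, background)
  keep <- lengths(sl) >= 1
  sl <- sl[keep]
  n_bg <- length(background)
  n_q <- length(query)
  res <- purrr::map2_dfr(names(sl), sl, function(nm, members) {
    ov <- intersect(query, members)
    tibble::tibble(
      set = nm, overlap = length(ov), set_size = length(members),
      query_size = n_q,
      p_value = phyper(length(ov) - 1, length(members),
                       n_bg - length(members), n_q, lower.tail = FALSE),
      overlap_genes = list(ov))
  })
  if (nrow(res) == 0) {
    rlang::warn("no gene set overlaps the background")
    res <- tibble::tibble(set = character(0), overlap = integer(0),
                          set_size = integer(0), query_size = integer(0),
                          p_value = numeric(0), q_value = numeric(0),
                          overlap_genes = list())
    attr(res, "q_threshold") <- q_threshold
    class(res) <- c("ora_result", class(res))
    return(res)
  }
  res$q_value <- bh_adjust(res$p_value)
  res <- dplyr::arrange(res, .data$p_value, .data$set)
  res <- dplyr::relocate(res, "q_value", .after = "p_value")
  attr(res, "q_threshold") <- q_threshold
  class(res) <- c("ora_result", class(res))
  res
}

# Weighted enrichment score from hit positions in a ranked list.
# pos: 1-based positions of the set's genes (sorted); w: |score|^weight at
# those positions; n: length of the ranked list.
# Returns ES and the extreme position (signed choice documented below).
gsea_es <- function(pos, w, n) {
  K <- length(pos)
  w_sum <- sum(w)
  if (w_sum == 0) w <- rep(1 / K, K) else w <- w / w_sum
  p_hit <- cumsum(w)
  miss_unit <- 1 / (n - K)
  # running sum just after each hit, and just before each hit
  after <- p_hit - (pos - seq_len(K)) * miss_unit
  before <- c(0, p_hit[-K]) - (pos - 1 - (seq_len(K) - 1)) * miss_unit
  hi <- max(after)
  lo <- min(before)
  # extremum tie: the deviation encountered first along the list wins
  if (abs(hi) >= abs(lo)) {
    if (abs(hi) == abs(lo)) {
      i_hi <- pos[which.max(after)]
      i_lo <- pos[which.min(before)] - 1
      if (i_lo < i_hi) return(list(es = lo, at = i_lo))
    }
    list(es = hi, at = pos[which.max(after)])
  } else {
    list(es = lo, at = pos[which.min(before)] - 1)
  }
}

#' Preranked gene set enrichment analysis
#'
#' Walks the score-ranked gene list accumulating weighted hits
#' (`|score|^weight`, normalized to sum 1) against uniform misses; the
#' enrichment score (ES) is the maximal deviation of the running sum. The
#' null distribution permutes gene labels (random sets of equal size);
#' `NES = ES / mean(|null ES| of the same sign)`, nominal p from the
#' same-sign null, and FDR q from the pooled normalized null (two-tailed,
#' computed within each NES sign). The leading edge contains the set
#' members up to the ES extremum (from the extremum onward for negative
#' ES).
#'
#' @param ranked Tibble/data frame with `gene_id` and `score` (a full
#'   ranked gene list, e.g. DE scores); ids must be unique, scores finite.
#'   Ties in `score` are broken by gene id.
#' @param sets A [gene_set_collection()].
#' @param n_perm Gene-label permutations (default 1000).
#' @param weight Hit-weight exponent (default 1; 0 gives the classic
#'   Kolmogorov-Smirnov form).
#' @param min_size,max_size Set-size bounds after restriction to the
#'   ranked universe (defaults 15 / 500).
#' @param seed RNG seed for the permutation null.
#' @return A `gsea_result` tibble: `set`, `size`, `es`, `nes`, `p_value`,
#'   `fdr_q`, `direction`, `leading_edge` (list-column). Skipped sets
#'   (outside size bounds or absent from the universe) are recorded in
#'   attribute `"skipped"`.
#' @export
gsea_preranked <- function(ranked, sets, n_perm = 1000, weight = 1,
                           min_size = 15, max_size = 500, seed = 123) {
  ranked <- tibble::as_tibble(ranked)
  if (anyDuplicated(ranked$gene_id)) {
    rlang::abort("duplicate gene ids in ranked list")
  }
  if (!all(is.finite(ranked$score))) rlang::abort("scores must be finite")
  ranked <- dplyr::arrange(ranked, dplyr::desc(.data$score),
                           .data$gene_id)
  ids <- ranked$gene_id
  n <- length(ids)
  wts <- abs(ranked$score)^weight
  sl <- collection_list(sets)
  pos_list <- lapply(sl, function(g) sort(match(intersect(g, ids), ids)))
  sizes <- lengths(pos_list)
  keep <- sizes >= min_size & sizes <= max_size & sizes < n
  skipped <- names(sl)[!keep]
  pos_list <- pos_list[keep]
  sizes <- sizes[keep]
  if (length(pos_list) == 0) {
    rlang::warn("no gene set within size bounds")
    out <- tibble::tibble(set = character(0), size = integer(0),
                          es = numeric(0), nes = numeric(0),
                          p_value = numeric(0), fdr_q = numeric(0),
                          direction = character(0),
                          leading_edge = list())
    attr(out, "skipped") <- skipped
    return(out)
  }
  es_obs <- numeric(length(pos_list))
  led <- vector("list", length(pos_list))
  for (i in seq_along(pos_list)) {
    pos <- pos_list[[i]]
    r <- gsea_es(pos, wts[pos], n)
    es_obs[i] <- r$es
    led[[i]] <- if (r$es >= 0) ids[pos[pos <= r$at]]
                else ids[pos[pos > r$at]]
  }
  # gene-label permutation null, one matrix of ES draws per set
  uniq_sizes <- sort(unique(sizes))
  null_by_size <- withr::with_seed(seed, {
    lapply(setNames(uniq_sizes, uniq_sizes), function(K) {
      vapply(seq_len(n_perm), function(b) {
        pos <- sort(sample.int(n, K))
        gsea_es(pos, wts[pos], n)$es
      }, numeric(1))
    })
  })
  nes_obs <- numeric(length(es_obs))
  p_nom <- numeric(length(es_obs))
  nes_null <- vector("list", length(es_obs))
  for (i in seq_along(es_obs)) {
    null_es <- null_by_size[[as.character(sizes[i])]]
    pos_mean <- mean(null_es[null_es >= 0])
    neg_mean <- mean(abs(null_es[null_es < 0]))
    norm <- ifelse(null_es >= 0,
                   null_es / ifelse(is.nan(pos_mean), 1, pos_mean),
                   null_es / ifelse(is.nan(neg_mean), 1, neg_mean))
    if (es_obs[i] >= 0) {
      nes_obs[i] <- es_obs[i] / ifelse(is.nan(pos_mean), 1, pos_mean)
      same <- null_es[null_es >= 0]
      p_nom[i] <- (1 + sum(same >= es_obs[i])) / (1 + length(same))
    } else {
      nes_obs[i] <- -abs(es_obs[i]) / ifelse(is.nan(neg_mean), 1, neg_mean)
      same <- null_es[null_es < 0]
      p_nom[i] <- (1 + sum(same <= es_obs[i])) / (1 + length(same))
    }
    nes_null[[i]] <- norm
  }
  all_null <- unlist(nes_null)
  fdr <- vapply(nes_obs, function(nes) {
    if (nes >= 0) {
      num <- mean(all_null[all_null >= 0] >= nes)
      den <- mean(nes_obs[nes_obs >= 0] >= nes)
    } else {
      num <- mean(all_null[all_null < 0] <= nes)
      den <- mean(nes_obs[nes_obs < 0] <= nes)
    }
    if (!is.finite(num / den)) return(1)
    min(1, num / den)
  }, numeric(1))
  # enforce monotonicity: a larger |NES| never gets a larger q within
  # its direction
  for (pos in c(TRUE, FALSE)) {
    idx <- which((nes_obs >= 0) == pos)
    if (length(idx) > 1) {
      ord <- idx[order(-abs(nes_obs[idx]))]
      fdr[ord] <- cummax(fdr[ord])
    }
  }
  out <- tibble::tibble(
    set = names(pos_list), size = as.integer(sizes), es = es_obs,
    nes = nes_obs, p_value = p_nom, fdr_q = fdr,
    direction = ifelse(es_obs >= 0, "up", "down"),
    leading_edge = led)
  out <- dplyr::arrange(out, dplyr::desc(abs(.data$nes)))
  attr(out, "skipped") <- skipped
  class(out) <- c("gsea_result", class(out))
  out
}

#' Capped -log10 transform of FDR q-values
#'
#' Zero q-values are replaced with half the smallest nonzero q, then
#' `-log10` is applied and capped at `cap` (default 50).
#'
#' @param q Vector of q-values in `[0, 1]`.
#' @param cap Upper cap on the transformed values.
#' @return `pmin(-log10(q'), cap)`.
#' @export
neglog10_q <- function(q, cap = 50) {
  if (anyNA(q) || any(q < 0 | q > 1)) {
    rlang::abort("q-values must lie in [0, 1]")
  }
  if (any(q == 0)) {
    nz <- q[q > 0]
    if (length(nz) == 0) {
      rlang::abort("all q-values are zero; no nonzero reference")
    }
    q[q == 0] <- min(nz) / 2
  }
  pmin(-log10(q), cap)
}
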