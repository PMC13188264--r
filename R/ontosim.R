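#' Ontology DAG from a typed edge list
#'
#' Terms and `(child, parent, relation)` edges with relations `is_a`
#' (contribution weight 0.8) and `part_of` (0.6). The DAG must be acyclic
#' with a single root reachable from every term.
#'
#' @param edges Tibble/data frame with columns `child`, `parent`,
#'   `relation`.
#' @param weights Named contribution weights per relation.
#' @return An `ontology_dag` list with `edges`, `terms`, `root`,
#'   `weights` and a child -> parent adjacency list.
#' @export
ontology_dag <- function(edges, weights = c(is_a = 0.8, part_of = 0.6)) {
  edges <- tibble::as_tibble(edges)
  if (!all(c("child", "parent", "relation") %in% names(edges))) {
    rlang::abort("edges need columns child, parent, relation")
  }
  bad <- setdiff(unique(edges$relation), names(weights))
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown relation(s): ", paste(bad, collapse = ", ")))
  }
  terms <- union(edges$child, edges$parent)
  roots <- setdiff(edges$parent, edges$child)
  if (length(roots) != 1) {
    rlang::abort(sprintf("DAG must have exactly one root (found %d)",
                         length(roots)))
  }
  parents <- split(
    data.frame(parent = edges$parent, w = unname(weights[edges$relation]),
               stringsAsFactors = FALSE),
    edges$child)
  # cycle check: every term must reach the root through finitely many edges
  depth_guard <- length(terms) + 1
  for (t in setdiff(terms, roots)) {
    seen <- character(0)
    frontier <- t
    for (step in seq_len(depth_guard)) {
      frontier <- unique(unlist(
        lapply(frontier, function(x) parents[[x]]$parent)))
      frontier <- setdiff(frontier, seen)
      if (length(frontier) == 0) break
      if (t %in% frontier) rlang::abort("cycle detected in DAG")
      seen <- c(seen, frontier)
    }
    if (!roots %in% c(seen, t)) {
      rlang::abort(sprintf("term '%s' cannot reach the root", t))
    }
  }
  structure(list(edges = edges, terms = terms, root = roots,
                 parents = parents, weights = weights),
            class = "ontology_dag")
}

# S-values of a term: named vector over its ancestor closure (incl.
# itself), S(t) = max over paths of the product of edge weights from the
# term up to t. Computed by relaxation from the term upward.
wang_svalues <- function(term, dag) {
  s <- setNames(1, term)
  frontier <- term
  while (length(frontier) > 0) {
    nxt <- character(0)
    for (ch in frontier) {
      pr <- dag$parents[[ch]]
      if (is.null(pr)) next
      cand <- s[[ch]] * pr$w
      for (j in seq_along(pr$parent)) {
        p <- pr$parent[j]
        if (is.null(s[p]) || is.na(s[p]) || cand[j] > s[p]) {
          s[p] <- cand[j]
          nxt <- c(nxt, p)
        }
      }
    }
    frontier <- unique(nxt)
  }
  s
}

#' Wang semantic similarity of two ontology terms
#'
#' Each term's ancestors receive S-values: 1 for the term itself and, for
#' an ancestor, the maximum over paths of the product of edge contribution
#' weights. The similarity is the sum of both terms' S-values over their
#' shared ancestors, divided by the sum of all their S-values:
#' `sim(A, B) = sum_{t in T_A n T_B} (S_A(t) + S_B(t)) / (SV(A) + SV(B))`.
#'
#' @param a,b Term ids present in `dag`.
#' @param dag An [ontology_dag()].
#' @return Similarity in `(0, 1]`; `wang_similarity(t, t, dag) == 1`.
#' @export
wang_similarity <- function(a, b, dag) {
  for (t in c(a, b)) {
    if (!t %in% dag$terms) {
      rlang::abort(sprintf("unknown term '%s'", t))
    }
  }
  sa <- wang_svalues(a, dag)
  sb <- wang_svalues(b, dag)
  shared <- intersect(names(sa), names(sb))
  (sum(sa[shared]) + sum(sb[shared])) / (sum(sa) + sum(sb))
}

#' Pairwise Wang similarity matrix
#'
#' @param terms Character vector of term ids.
#' @inheritParams wang_similarity
#' @return Symmetric matrix with unit diagonal.
#' @export
wang_sim_matrix <- function(terms, dag) {
  sv <- lapply(setNames(terms, terms), wang_svalues, dag = dag)
  n <- length(terms)
  m <- diag(1, n)
  dimnames(m) <- list(terms, terms)
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- sv[[i]]; sb <- sv[[j]]
      shared <- intersect(names(sa), names(sb))
      m[i, j] <- m[j, i] <-
        (sum(sa[shared]) + sum(sb[shared])) / (sum(sa) + sum(sb))
    }
  }
  m
}

#' Cluster enriched terms by semantic similarity
#'
#' Complete-linkage agglomeration on `distance = 1 - Wang similarity`,
#' cut at `cut_height`: clusters are the connected components of the
#' dendrogram formed by merges at heights strictly below the cut. Each
#' cluster's representative is the member with the smallest q-value (ties
#' broken by lexicographic term id). Terms absent from the DAG are
#' excluded and recorded.
#'
#' @param terms Tibble with `term_id` and `q_value` (enriched terms).
#' @param dag An [ontology_dag()].
#' @param cut_height Dendrogram cut (default 0.7).
#' @return A `term_clusters` tibble: `cluster_id`, `representative`,
#'   `representative_q`, `n_members`, `members` (list-column). Excluded
#'   terms are in attribute `"excluded"`.
#' @export
cluster_terms <- function(terms, dag, cut_height = 0.7) {
  terms <- tibble::as_tibble(terms)
  if (nrow(terms) < 1) rlang::abort("at least one term is required")
  known <- terms$term_id %in% dag$terms
  excluded <- terms$term_id[!known]
  if (length(excluded) > 0) {
    rlang::inform(paste0("terms absent from DAG excluded: ",
                         paste(excluded, collapse = ", ")))
  }
  terms <- terms[known, ]
  if (nrow(terms) == 0) rlang::abort("no clusterable term remains")
  ids <- terms$term_id
  if (length(ids) == 1) {
    memb <- 1L
  } else {
    sim <- wang_sim_matrix(ids, dag)
    hc <- hclust(as.dist(1 - sim), method = "complete")
    k <- length(ids) - sum(hc$height < cut_height)
    memb <- cutree(hc, k = k)
  }
  qv <- setNames(terms$q_value, ids)
  out <- purrr::map_dfr(sort(unique(memb)), function(cl) {
    mm <- sort(ids[memb == cl])
    rep_id <- mm[order(qv[mm], mm)][1]
    tibble::tibble(representative = rep_id,
                   representative_q = unname(qv[rep_id]),
                   n_members = length(mm), members = list(mm))
  })
  # stable cluster ids: order by representative q then id
  out <- dplyr::arrange(out, .data$representative_q, .data$representative)
  out <- dplyr::mutate(out, cluster_id = dplyr::row_number(),
                       .before = 1)
  attr(out, "excluded") <- excluded
  class(out) <- c("term_clusters", class(out))
  out
}
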