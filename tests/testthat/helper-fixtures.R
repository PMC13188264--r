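# Shared fixtures, built in code at test time.

# Small mouse-like simulation with a hemizygous deletion block.
fixture_deletion_sim <- function(n_genes = 600, dispersion = 0.05,
                                 dosage = 0.5, seed = 123) {
  simulate_counts(sim_config(
    n_genes = n_genes, n_per_group = c(3L, 3L), lib_size_mean = 3e5,
    dispersion = dispersion, deletion_block = 1:20,
    deletion_dosage = dosage, seed = seed))
}

# Pure-null simulation (no DE signal anywhere).
fixture_null_sim <- function(n_genes = 500, dispersion = 0.05,
                             seed = 123, n_per_group = c(3L, 3L)) {
  simulate_counts(sim_config(
    n_genes = n_genes, n_per_group = n_per_group, lib_size_mean = 3e5,
    dispersion = dispersion, seed = seed))
}

# A 4-term toy DAG: root R; A,B is_a R; C,D is_a A (deep siblings).
fixture_toy_dag <- function() {
  ontology_dag(tibble::tibble(
    child = c("A", "B", "C", "D"),
    parent = c("R", "R", "A", "A"),
    relation = "is_a"))
}

# Brute-force GSEA running sum: O(n) reference implementation.
brute_es <- function(ids, scores, set, weight = 1) {
  ord <- order(-scores, ids)
  ids <- ids[ord]
  scores <- scores[ord]
  hit <- ids %in% set
  w <- abs(scores)^weight
  w[!hit] <- 0
  if (sum(w) == 0) w[hit] <- 1
  inc <- ifelse(hit, w / sum(w), -1 / sum(!hit))
  run <- cumsum(inc)
  run[which.max(abs(run))]
}

# Direct BH step-up definition: q_i = min over j >= i of n p_(j) / j.
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- rev(cummin(rev(n * p[o] / seq_len(n))))
  pmin(1, q)[order(o)]
}
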