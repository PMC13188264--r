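#' Simulation configuration for two-group RNA-seq counts
#'
#' Defines the generative model used throughout the package's tests and
#' demos: negative-binomial counts for two groups, an optional contiguous
#' "deletion block" of genes expressed at a fixed dosage in the second
#' group (emulating a hemizygous microdeletion, where ~0.5 dosage is
#' expected), sparse up/down differential genes, and optional
#' pathway-coordinated shifts applied to named gene sets.
#'
#' The negative binomial is parameterized by the dispersion `phi` so that
#' `Var = mu + phi * mu^2`. Library sizes are drawn log-normal with the
#' stated mean and coefficient of variation.
#'
#' @param n_genes Number of genes.
#' @param n_per_group Integer pair: samples in group 1 (reference) and
#'   group 2 (affected).
#' @param lib_size_mean Mean library size in reads.
#' @param lib_size_cv Coefficient of variation of library sizes, in `[0, 1)`.
#' @param dispersion NB dispersion `phi` (> 0); variance `mu + phi mu^2`.
#' @param deletion_block Integer vector of gene indices expressed at
#'   `deletion_dosage` in group 2.
#' @param deletion_dosage Relative dosage of deletion-block genes in
#'   group 2, in `(0, 1]`. The default 0.5 emulates hemizygosity.
#' @param de_up_fraction,de_down_fraction Fractions of genes (outside the
#'   deletion block and pathway sets) that are up-/down-regulated in
#'   group 2.
#' @param de_log2fc_range Interval from which `|log2FC|` of up/down genes
#'   is drawn uniformly.
#' @param pathway_shift_sets List of `list(set_id =, genes =, shift =)`
#'   entries: gene indices receiving a coordinated mean log2FC `shift`;
#'   `simulate_gene_sets()` emits a matching gene set per entry.
#' @param seed Integer seed; a fixed seed makes all simulation output
#'   byte-identical across calls.
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_genes = 500, deletion_block = 1:20, seed = 1)
#' sim <- simulate_counts(cfg)
#' dplyr::count(sim$truth, class)
#' @export
sim_config <- function(n_genes = 2000,
                       n_per_group = c(3L, 3L),
                       lib_size_mean = 5e5,
                       lib_size_cv = 0.1,
                       dispersion = 0.05,
                       deletion_block = integer(0),
                       deletion_dosage = 0.5,
                       de_up_fraction = 0,
                       de_down_fraction = 0,
                       de_log2fc_range = c(0.5, 2),
                       pathway_shift_sets = list(),
                       seed = 123L) {
  if (!is.numeric(n_genes) || length(n_genes) != 1 || n_genes < 1) {
    rlang::abort("'n_genes' must be a positive integer")
  }
  if (length(n_per_group) != 2 || any(n_per_group < 1)) {
    rlang::abort("'n_per_group' must be a pair of positive integers")
  }
  if (!is.numeric(lib_size_mean) || lib_size_mean <= 0) {
    rlang::abort("'lib_size_mean' must be positive")
  }
  check_fraction(lib_size_cv, "lib_size_cv", 0, 1, hi_open = TRUE)
  if (!is.numeric(dispersion) || dispersion <= 0) {
    rlang::abort("'dispersion' must be a positive real")
  }
  deletion_block <- as.integer(deletion_block)
  if (length(deletion_block) > 0 &&
      (min(deletion_block) < 1 || max(deletion_block) > n_genes)) {
    rlang::abort("'deletion_block' indices outside 1..n_genes")
  }
  check_fraction(deletion_dosage, "deletion_dosage", 0, 1, lo_open = TRUE)
  check_fraction(de_up_fraction, "de_up_fraction", 0, 1, hi_open = TRUE)
  check_fraction(de_down_fraction, "de_down_fraction", 0, 1, hi_open = TRUE)
  if (de_up_fraction + de_down_fraction >= 1) {
    rlang::abort("'de_up_fraction' + 'de_down_fraction' must be < 1")
  }
  if (length(de_log2fc_range) != 2 || diff(de_log2fc_range) < 0) {
    rlang::abort("'de_log2fc_range' must be an increasing interval")
  }
  shift_genes <- integer(0)
  for (ps in pathway_shift_sets) {
    if (!all(c("set_id", "genes", "shift") %in% names(ps))) {
      rlang::abort(
        "'pathway_shift_sets' entries need set_id, genes and shift")
    }
    shift_genes <- c(shift_genes, as.integer(ps$genes))
  }
  if (length(shift_genes) > 0 &&
      (min(shift_genes) < 1 || max(shift_genes) > n_genes)) {
    rlang::abort("'pathway_shift_sets' gene indices outside 1..n_genes")
  }
  if (length(intersect(shift_genes, deletion_block)) > 0) {
    rlang::abort(
      "'deletion_block' must be disjoint from 'pathway_shift_sets' genes")
  }
  structure(list(
    n_genes = as.integer(n_genes), n_per_group = as.integer(n_per_group),
    lib_size_mean = lib_size_mean, lib_size_cv = lib_size_cv,
    dispersion = dispersion, deletion_block = deletion_block,
    deletion_dosage = deletion_dosage,
    de_up_fraction = de_up_fraction, de_down_fraction = de_down_fraction,
    de_log2fc_range = de_log2fc_range,
    pathway_shift_sets = pathway_shift_sets,
    seed = as.integer(seed)
  ), class = "sim_config")
}

gene_ids_for <- function(n, prefix = "G") sprintf("%s%06d", prefix, seq_len(n))

# Draw per-gene truth (true log2FC + class label) implied by a config.
sim_truth <- function(config, prefix = "G") {
  n <- config$n_genes
  lfc <- rep(0, n)
  class <- rep("null", n)
  if (length(config$deletion_block) > 0) {
    lfc[config$deletion_block] <- log2(config$deletion_dosage)
    class[config$deletion_block] <- "deletion"
  }
  for (ps in config$pathway_shift_sets) {
    idx <- as.integer(ps$genes)
    lfc[idx] <- ps$shift
    class[idx] <- "pathway-shifted"
  }
  free <- which(class == "null")
  n_up <- round(config$de_up_fraction * n)
  n_down <- round(config$de_down_fraction * n)
  if (n_up + n_down > length(free)) {
    rlang::abort("DE fractions leave no room outside deletion/pathway genes")
  }
  pick <- sample(free, n_up + n_down)
  up <- pick[seq_len(n_up)]
  down <- pick[n_up + seq_len(n_down)]
  r <- config$de_log2fc_range
  lfc[up] <- runif(n_up, r[1], r[2])
  lfc[down] <- -runif(n_down, r[1], r[2])
  class[up] <- "up"
  class[down] <- "down"
  tibble::tibble(gene_id = gene_ids_for(n, prefix),
                 true_log2fc = lfc, class = class)
}

# Counts given a truth table (shared by simulate_counts and the
# cross-species generator). Assumes the RNG state is already set.
sim_counts_from_truth <- function(config, truth, prefix = "G",
                                  sample_prefix = "s") {
  n <- config$n_genes
  n1 <- config$n_per_group[1]
  n2 <- config$n_per_group[2]
  ns <- n1 + n2
  q <- rlnorm(n, meanlog = 0, sdlog = 1)
  q <- q / sum(q)
  if (config$lib_size_cv > 0) {
    sdl <- sqrt(log(1 + config$lib_size_cv^2))
    lib <- rlnorm(ns, meanlog = log(config$lib_size_mean) - sdl^2 / 2,
                  sdlog = sdl)
  } else {
    lib <- rep(config$lib_size_mean, ns)
  }
  group <- rep(c("g1", "g2"), c(n1, n2))
  fold <- outer(truth$true_log2fc, as.numeric(group == "g2"),
                function(l, g) 2^(l * g))
  mu <- (q %o% lib) * fold
  y <- matrix(rnbinom(n * ns, mu = mu, size = 1 / config$dispersion),
              nrow = n)
  sample_id <- sprintf("%s%d_%s", sample_prefix, seq_len(ns), group)
  colnames(y) <- sample_id
  counts <- tibble::as_tibble(y)
  counts <- dplyr::bind_cols(
    tibble::tibble(gene_id = gene_ids_for(n, prefix)), counts)
  list(counts = counts,
       samples = tibble::tibble(sample_id = sample_id, group = group))
}

#' Simulate a two-group RNA-seq count matrix with known truth
#'
#' Draws `counts[g, s] ~ NB(lib_s * q_g * 2^(log2FC_g * [s in group 2]),
#' phi)` with gene abundances `q_g` log-normal and normalized to sum 1.
#' Deletion-block genes carry `log2FC = log2(deletion_dosage)`; null genes
#' carry 0. Output is byte-identical for a fixed `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_data` with elements `counts` (tibble:
#'   `gene_id` + one column per sample), `samples` (tibble: `sample_id`,
#'   `group`) and `truth` (tibble: `gene_id`, `true_log2fc`, `class`).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    truth <- sim_truth(config)
    sim <- sim_counts_from_truth(config, truth)
  })
  structure(c(sim, list(truth = truth, config = config)),
            class = "sim_data")
}

#' Simulate gene sets and a toy ontology DAG
#'
#' Generates `n_sets` gene sets drawn from the simulated gene universe
#' (any `pathway_shift_sets` in the config become sets with exactly their
#' member genes) together with a rooted acyclic term DAG whose leaf terms
#' are the sets, with edges typed `is_a` / `part_of` — the structure the
#' Wang similarity and term-clustering stages operate on.
#'
#' @param config A [sim_config()].
#' @param n_sets Number of random gene sets (in addition to any
#'   pathway-shift sets from the config).
#' @param set_size_range Inclusive size interval for the random sets.
#' @param dag_depth Depth of the DAG below the root (1 = all leaves hang
#'   from the root).
#' @param p_part_of Probability that an edge is `part_of` (else `is_a`).
#' @return List with `sets` (a `gene_set_collection` tibble) and `dag`
#'   (tibble: `child`, `parent`, `relation`).
#' @export
simulate_gene_sets <- function(config, n_sets = 20,
                               set_size_range = c(15, 40),
                               dag_depth = 3, p_part_of = 0.2) {
  stopifnot(inherits(config, "sim_config"))
  if (max(set_size_range) > config$n_genes) {
    rlang::abort("'set_size_range' exceeds the gene universe size")
  }
  universe <- gene_ids_for(config$n_genes)
  withr::with_seed(config$seed + 1L, {
    sets <- list()
    for (ps in config$pathway_shift_sets) {
      sets[[ps$set_id]] <- universe[as.integer(ps$genes)]
    }
    size_rng <- seq.int(set_size_range[1], set_size_range[2])
    sizes <- size_rng[sample.int(length(size_rng), n_sets,
                                 replace = TRUE)]
    for (i in seq_len(n_sets)) {
      sets[[sprintf("T%04d", i)]] <- sort(sample(universe, sizes[i]))
    }
    leaf <- names(sets)
    edges <- list()
    prev <- "ROOT"
    for (d in seq_len(dag_depth - 1)) {
      size_d <- max(1L, round(length(leaf)^(d / dag_depth)))
      level <- sprintf("L%d_%03d", d, seq_len(size_d))
      edges[[d]] <- tibble::tibble(
        child = level,
        parent = sample(prev, size_d, replace = TRUE),
        relation = ifelse(runif(size_d) < p_part_of, "part_of", "is_a"))
      prev <- level
    }
    edges[[dag_depth]] <- tibble::tibble(
      child = leaf,
      parent = sample(prev, length(leaf), replace = TRUE),
      relation = ifelse(runif(length(leaf)) < p_part_of, "part_of", "is_a"))
  })
  collection <- gene_set_collection(sets)
  list(sets = collection, dag = dplyr::bind_rows(edges))
}

#' Simulate an ortholog-mapped pair of species datasets
#'
#' Species A is simulated from `config_a`. A partial one-to-one ortholog
#' map is drawn (default ~75% of the smaller gene universe), and species
#' B's differential signal is derived from A's across the map: each mapped
#' DE gene of A is DE in B with the same sign with probability
#' `shared_signal_fraction`, and with a random sign otherwise (so at 0 the
#' cross-species sign concordance of true-DE pairs sits at chance).
#'
#' @param config_a,config_b [sim_config()]s for the two species; group
#'   sizes, depth and dispersion may differ (e.g. 3v3 mouse-like vs 39v38
#'   human-like).
#' @param shared_signal_fraction Real in `[0, 1]`.
#' @param ortholog_fraction Fraction of the smaller universe that is
#'   ortholog-mapped.
#' @return List with `species_a`, `species_b` (each a `sim_data`) and
#'   `ortholog_map` (tibble: `id_a`, `id_b`).
#' @export
simulate_species_pair <- function(config_a, config_b,
                                  shared_signal_fraction = 0.5,
                                  ortholog_fraction = 0.75) {
  stopifnot(inherits(config_a, "sim_config"),
            inherits(config_b, "sim_config"))
  check_fraction(shared_signal_fraction, "shared_signal_fraction")
  sim_a <- simulate_counts(config_a)
  ids_b <- gene_ids_for(config_b$n_genes, "H")
  withr::with_seed(config_b$seed, {
    n_map <- floor(ortholog_fraction * min(config_a$n_genes,
                                           config_b$n_genes))
    map <- tibble::tibble(
      id_a = sort(sample(sim_a$truth$gene_id, n_map)),
      id_b = sort(sample(ids_b, n_map)))
    lfc_b <- rep(0, config_b$n_genes)
    class_b <- rep("null", config_b$n_genes)
    de_a <- dplyr::filter(sim_a$truth, .data$class != "null",
                          .data$gene_id %in% map$id_a)
    idx_b <- match(map$id_b[match(de_a$gene_id, map$id_a)], ids_b)
    r <- config_b$de_log2fc_range
    mag <- runif(nrow(de_a), r[1], r[2])
    same <- runif(nrow(de_a)) < shared_signal_fraction
    sgn <- ifelse(same, sign(de_a$true_log2fc),
                  sample(c(-1, 1), nrow(de_a), replace = TRUE))
    lfc_b[idx_b] <- sgn * mag
    class_b[idx_b] <- ifelse(sgn > 0, "up", "down")
    if (length(config_b$deletion_block) > 0) {
      del <- setdiff(config_b$deletion_block, idx_b)
      lfc_b[del] <- log2(config_b$deletion_dosage)
      class_b[del] <- "deletion"
    }
    truth_b <- tibble::tibble(gene_id = ids_b, true_log2fc = lfc_b,
                              class = class_b)
    sim_b <- sim_counts_from_truth(config_b, truth_b, prefix = "H",
                                   sample_prefix = "h")
  })
  sim_b <- structure(c(sim_b, list(truth = truth_b, config = config_b)),
                     class = "sim_data")
  list(species_a = sim_a, species_b = sim_b, ortholog_map = map)
}
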