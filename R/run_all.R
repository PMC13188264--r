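#' Full-analysis run configuration
#'
#' Collects every input and tunable of the end-to-end pipeline with the
#' package's standard defaults: expression filter `a_min = 0.5`, top/
#' bottom `k = 300` DEGs at `p < 0.05`, DEGES iterations 3 (FDR cutoff
#' 0.1, elimination threshold 0.05), bootstrap 500 / subsampling 100 /
#' permutation 1000, GSEA set sizes 15-500 with 1000 permutations,
#' semantic-cluster cut height 0.7, significance q < 0.05, `-log10 q` cap
#' 50, and seed 123.
#'
#' Inputs may be file paths (TSV/GMT, see the `read_*` functions) or
#' in-memory tibbles. Alternatively `simulate` may carry
#' `list(config =, config_b =, shared_signal_fraction =, n_sets =, ...)`
#' to generate all inputs on the fly.
#'
#' @param counts,samples Count matrix and sample metadata (path or
#'   tibble); required unless `simulate` is given.
#' @param sets,dag Gene sets (GMT path or collection) and ontology DAG
#'   (TSV path or [ontology_dag()]).
#' @param counts_b,samples_b,orthologs Optional second species and
#'   one-to-one ortholog map for the cross-species stage.
#' @param simulate Optional simulation request (see above).
#' @param a_min,k,p_threshold,deges_iterations,fdr_cutoff,
#'   elimination_threshold,n_boot,n_subsample,n_perm,gsea_min,gsea_max,
#'   n_perm_gsea,cut_height,q_threshold,cap,top_n_hub,top_pathways,
#'   top_genes,max_perms,seed Stage parameters (defaults above).
#' @return A `run_config` list.
#' @export
run_config <- function(counts = NULL, samples = NULL, sets = NULL,
                       dag = NULL, counts_b = NULL, samples_b = NULL,
                       orthologs = NULL, simulate = NULL,
                       a_min = 0.5, k = 300, p_threshold = 0.05,
                       deges_iterations = 3, fdr_cutoff = 0.1,
                       elimination_threshold = 0.05,
                       n_boot = 500, n_subsample = 100, n_perm = 1000,
                       gsea_min = 15, gsea_max = 500, n_perm_gsea = 1000,
                       cut_height = 0.7, q_threshold = 0.05, cap = 50,
                       top_n_hub = 20, top_pathways = 5, top_genes = 20,
                       max_perms = 999, seed = 123) {
  if (is.null(simulate) && (is.null(counts) || is.null(samples))) {
    rlang::abort("config requires 'counts' and 'samples' (or 'simulate')")
  }
  structure(as.list(environment()), class = "run_config")
}

#' Demo configuration on small synthetic data
#'
#' A fully self-contained configuration: a 3v3 "mouse-like" dataset with
#' a 20-gene deletion block at 0.5 dosage plus two coordinately shifted
#' pathways, a larger-group second species sharing most of the signal,
#' matched gene sets and toy DAG. Resampling iteration counts are scaled
#' to desk size; statistical defaults are unchanged.
#'
#' @param n_genes Genes per species.
#' @param seed Master seed.
#' @export
demo_run_config <- function(n_genes = 400, seed = 123) {
  shift_sets <- list(
    list(set_id = "PS_UP", genes = 41:70, shift = 0.8),
    list(set_id = "PS_DOWN", genes = 71:100, shift = -0.8))
  cfg_a <- sim_config(
    n_genes = n_genes, n_per_group = c(3L, 3L), lib_size_mean = 2e5,
    dispersion = 0.05, deletion_block = 1:20, deletion_dosage = 0.5,
    de_up_fraction = 0.03, de_down_fraction = 0.03,
    pathway_shift_sets = shift_sets, seed = seed)
  cfg_b <- sim_config(
    n_genes = n_genes, n_per_group = c(10L, 10L), lib_size_mean = 2e5,
    dispersion = 0.1, de_log2fc_range = c(0.4, 1.5), seed = seed + 1)
  run_config(
    simulate = list(config = cfg_a, config_b = cfg_b,
                    shared_signal_fraction = 0.8, n_sets = 25,
                    set_size_range = c(15, 40), dag_depth = 3),
    k = 60, n_boot = 20, n_subsample = 20, n_perm = 1000,
    n_perm_gsea = 200, seed = seed)
}

resolve_input <- function(x, reader) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1) reader(x) else x
}

flatten_list_col <- function(df, cols) {
  for (col in intersect(cols, names(df))) {
    df[[col]] <- vapply(df[[col]], paste, character(1), collapse = ",")
  }
  df
}

run_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the complete analysis
#'
#' Executes simulate (optional) -> normalize/test -> score/select ->
#' resampling and separation validation -> ORA + GSEA -> semantic term
#' clustering -> hub genes, consensus pathways, combined/priority scores
#' -> cross-species concordance (when a second species is provided), and
#' writes every artifact plus a manifest (parameters and md5 of each
#' output) under `out_dir`. Identical config and seed give byte-identical
#' outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @param dry_run If `TRUE`, prints the planned stages and writes
#'   nothing.
#' @return Invisibly, a list with the main in-memory results.
#' @export
run_all <- function(config, out_dir, dry_run = FALSE) {
  stopifnot(inherits(config, "run_config"))
  stages <- c("simulate", "de", "score", "validate", "enrich",
              "cluster-terms", "integrate", "cross-species", "manifest")
  if (dry_run) {
    cat("planned stages:", paste(stages, collapse = " -> "), "\n")
    return(invisible(stages))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character(0)
  note <- function(w) warnings_log <<- c(warnings_log, w)
  outputs <- character(0)
  emit <- function(writer, obj, name) {
    path <- file.path(out_dir, name)
    writer(obj, path)
    outputs <<- c(outputs, path)
    path
  }

  # --- inputs -------------------------------------------------------
  pair <- NULL
  if (!is.null(config$simulate)) {
    run_log("simulate", "generating synthetic inputs")
    s <- config$simulate
    if (!is.null(s$config_b)) {
      pair <- simulate_species_pair(
        s$config, s$config_b,
        shared_signal_fraction = s$shared_signal_fraction %||% 0.8)
      sim <- pair$species_a
      sim_b <- pair$species_b
      map <- pair$ortholog_map
    } else {
      sim <- simulate_counts(s$config)
      sim_b <- NULL
      map <- NULL
    }
    gs <- simulate_gene_sets(s$config, n_sets = s$n_sets %||% 20,
                             set_size_range = s$set_size_range %||%
                               c(15, 40),
                             dag_depth = s$dag_depth %||% 3)
    counts <- sim$counts; samples <- sim$samples
    sets <- gs$sets; dag <- ontology_dag(gs$dag)
    emit(write_counts, counts, "counts.tsv")
    emit(write_samples, samples, "samples.tsv")
    emit(write_tsv_fmt, sim$truth, "truth.tsv")
    emit(write_gmt, sets, "sets.gmt")
    emit(write_dag, dag, "dag.tsv")
    if (!is.null(sim_b)) {
      emit(write_counts, sim_b$counts, "counts_b.tsv")
      emit(write_samples, sim_b$samples, "samples_b.tsv")
      emit(write_orthologs, map, "orthologs.tsv")
    }
    counts_b <- if (is.null(sim_b)) NULL else sim_b$counts
    samples_b <- if (is.null(sim_b)) NULL else sim_b$samples
  } else {
    counts <- resolve_input(config$counts, read_counts)
    samples <- resolve_input(config$samples, read_samples)
    sets <- resolve_input(config$sets, read_gmt)
    dag <- resolve_input(config$dag, read_dag)
    counts_b <- resolve_input(config$counts_b, read_counts)
    samples_b <- resolve_input(config$samples_b, read_samples)
    map <- resolve_input(config$orthologs, read_orthologs)
  }

  pcfg <- pipeline_config(
    a_min = config$a_min, k = config$k,
    p_threshold = config$p_threshold,
    deges = deges_config(config$deges_iterations, config$fdr_cutoff,
                         config$elimination_threshold))

  run_species <- function(counts, samples, tag) {
    run_log("de", "species %s: normalization and exact test", tag)
    run <- withCallingHandlers(
      run_de_pipeline(counts, samples, pcfg),
      warning = function(w) {
        note(conditionMessage(w)); invokeRestart("muffleWarning")
      })
    run
  }

  run_a <- run_species(counts, samples, "A")
  emit(write_gene_stats, run_a$stats, "gene_stats.tsv")
  scored_flat <- run_a$scored
  emit(write_tsv_fmt, scored_flat, "scored.tsv")
  emit(function(x, p) writeLines(x, p), run_a$selection$up,
       "degs_up.txt")
  emit(function(x, p) writeLines(x, p), run_a$selection$down,
       "degs_down.txt")

  # --- validation ---------------------------------------------------
  run_log("validate", "resampling (%d boot, %d subsample, perm<=%d)",
          config$n_boot, config$n_subsample, config$n_perm)
  boot <- bootstrap_validation(counts, samples, pcfg,
                               n_iter = config$n_boot,
                               seed = config$seed)
  sub <- subsample_validation(counts, samples, pcfg,
                              n_iter = config$n_subsample,
                              seed = config$seed)
  perm <- permutation_null(counts, samples, pcfg,
                           n_iter = config$n_perm, seed = config$seed)
  sep <- separation_analysis(counts, samples, run_a$selection,
                             run_a$factors, max_perms = config$max_perms)
  emit(write_tsv_fmt, tibble::tibble(
    iteration = seq_along(boot$jaccard_up),
    scheme = "bootstrap",
    jaccard_up = boot$jaccard_up, jaccard_down = boot$jaccard_down),
    "jaccard_bootstrap.tsv")
  emit(write_tsv_fmt, tibble::tibble(
    iteration = seq_along(sub$jaccard_up), scheme = "subsample",
    jaccard_up = sub$jaccard_up, jaccard_down = sub$jaccard_down),
    "jaccard_subsample.tsv")
  validation <- list(
    bootstrap = glance(boot), subsample = glance(sub),
    permutation = list(empirical_p = perm$empirical_p,
                       t_observed = perm$t_observed,
                       exhaustive = perm$exhaustive),
    separation = list(
      permanova_F = sep$permanova_F, permanova_R2 = sep$permanova_R2,
      permanova_p = sep$permanova_p, anosim_R = sep$anosim_R,
      anosim_p = sep$anosim_p, wilks_lambda = sep$wilks_lambda,
      manova_p = sep$manova_p,
      n_permutations_enumerated = sep$n_permutations_enumerated,
      exhaustive = sep$exhaustive,
      pc_variance_fractions = sep$pc_variance_fractions))
  emit(function(x, p) jsonlite::write_json(x, p, auto_unbox = TRUE,
                                           digits = 10, pretty = TRUE),
       validation, "validation.json")

  # --- enrichment ---------------------------------------------------
  enrich_species <- function(run, tag) {
    bg <- run$scored$gene_id
    ora_up <- ora(run$selection$up, bg, sets, config$q_threshold)
    ora_down <- ora(run$selection$down, bg, sets, config$q_threshold)
    ranked <- dplyr::select(run$scored, "gene_id", score = "de_score")
    gsea <- gsea_preranked(ranked, sets, n_perm = config$n_perm_gsea,
                           min_size = config$gsea_min,
                           max_size = config$gsea_max,
                           seed = config$seed)
    list(ora = list(up = ora_up, down = ora_down), gsea = gsea)
  }
  run_log("enrich", "ORA + preranked GSEA")
  enr_a <- enrich_species(run_a, "A")
  emit(write_tsv_fmt, flatten_list_col(enr_a$ora$up, "overlap_genes"),
       "ora_up.tsv")
  emit(write_tsv_fmt, flatten_list_col(enr_a$ora$down, "overlap_genes"),
       "ora_down.tsv")
  emit(write_tsv_fmt, flatten_list_col(enr_a$gsea, "leading_edge"),
       "gsea.tsv")

  # --- term clustering + hubs + integration -------------------------
  run_log("cluster-terms", "Wang similarity clustering (cut %.2f)",
          config$cut_height)
  integrate_direction <- function(dir_tag) {
    ora_res <- enr_a$ora[[dir_tag]]
    degs <- run_a$selection[[dir_tag]]
    sig <- dplyr::filter(ora_res, .data$q_value < config$q_threshold)
    hubs_o <- clusters <- NULL
    if (nrow(sig) > 0 && !is.null(dag)) {
      cl_in <- tibble::tibble(term_id = sig$set, q_value = sig$q_value)
      clusters <- cluster_terms(cl_in, dag,
                                cut_height = config$cut_height)
      hubs_o <- hub_genes_ora(clusters, ora_res, run_a$scored,
                              top_n = config$top_n_hub)
    }
    gsea_sig <- dplyr::filter(enr_a$gsea,
                              .data$fdr_q < config$q_threshold,
                              .data$direction == dir_tag)
    hubs_g <- if (nrow(gsea_sig) > 0) {
      hub_genes_gsea(gsea_sig, run_a$scored, top_n = config$top_n_hub)
    } else NULL
    list(clusters = clusters, hubs_ora = hubs_o, hubs_gsea = hubs_g,
         degs = degs)
  }
  int_up <- integrate_direction("up")
  int_down <- integrate_direction("down")
  for (tag in c("up", "down")) {
    obj <- if (tag == "up") int_up else int_down
    if (!is.null(obj$clusters)) {
      emit(write_tsv_fmt, flatten_list_col(obj$clusters, "members"),
           sprintf("term_clusters_%s.tsv", tag))
    }
    if (!is.null(obj$hubs_ora)) {
      emit(write_tsv_fmt, obj$hubs_ora,
           sprintf("hub_genes_ora_%s.tsv", tag))
    }
    if (!is.null(obj$hubs_gsea)) {
      emit(write_tsv_fmt, obj$hubs_gsea,
           sprintf("hub_genes_gsea_%s.tsv", tag))
    }
  }
  run_log("integrate", "consensus pathways and priority scores")
  cons <- consensus_pathways(enr_a$ora$up, enr_a$ora$down, enr_a$gsea,
                             config$q_threshold)
  venn <- list()
  integration <- list()
  for (tag in c("up", "down")) {
    ora_res <- enr_a$ora[[tag]]
    sig_o <- ora_res$set[ora_res$q_value < config$q_threshold]
    sig_g <- enr_a$gsea$set[enr_a$gsea$fdr_q < config$q_threshold &
                              enr_a$gsea$direction == tag]
    venn[[tag]] <- list(ora_only = length(setdiff(sig_o, cons[[tag]])),
                        gsea_only = length(setdiff(sig_g, cons[[tag]])),
                        consensus = length(cons[[tag]]))
    if (length(cons[[tag]]) == 0) next
    oq <- setNames(ora_res$q_value, ora_res$set)
    gq <- setNames(enr_a$gsea$fdr_q, enr_a$gsea$set)
    gn <- setNames(enr_a$gsea$nes, enr_a$gsea$set)
    tab <- tibble::tibble(set = cons[[tag]],
                          ora_q = pmax(oq[cons[[tag]]], 1e-50),
                          nes = gn[cons[[tag]]],
                          gsea_q = pmax(gq[cons[[tag]]], 1e-50))
    ps <- combined_score(tab, cap = config$cap)
    degs <- run_a$selection[[tag]]
    pri <- priority_scores(cons[[tag]], ps, sets, degs, run_a$scored)
    chord <- chord_export(cons[[tag]], ps, pri, sets, degs,
                          top_pathways = config$top_pathways,
                          top_genes = config$top_genes)
    emit(write_tsv_fmt, ps, sprintf("pathway_scores_%s.tsv", tag))
    emit(write_tsv_fmt, pri, sprintf("priority_scores_%s.tsv", tag))
    emit(write_tsv_fmt, chord, sprintf("chord_%s.tsv", tag))
    integration[[tag]] <- list(pathway_scores = ps, priorities = pri)
  }
  emit(function(x, p) jsonlite::write_json(x, p, auto_unbox = TRUE,
                                           pretty = TRUE),
       venn, "venn_counts.json")

  # --- cross-species ------------------------------------------------
  xsp <- NULL
  if (!is.null(counts_b) && !is.null(map)) {
    run_log("cross-species", "ortholog join and concordance")
    run_b <- run_species(counts_b, samples_b, "B")
    # enrichment for species B runs in the shared pathway namespace:
    # ortholog-mapped genes are relabeled with species-A ids
    to_a <- setNames(map$id_a, map$id_b)
    run_b_shared <- run_b
    run_b_shared$scored <- dplyr::mutate(
      dplyr::filter(run_b$scored, .data$gene_id %in% map$id_b),
      gene_id = unname(to_a[.data$gene_id]))
    run_b_shared$selection$up <-
      unname(to_a[intersect(run_b$selection$up, map$id_b)])
    run_b_shared$selection$down <-
      unname(to_a[intersect(run_b$selection$down, map$id_b)])
    run_b_shared$selection$background <- run_b_shared$scored$gene_id
    enr_b <- enrich_species(run_b_shared, "B")
    join <- join_orthologs(run_a$scored, run_b$scored, map,
                           run_a$selection, run_b$selection)
    corr <- score_correlation(join)
    overlap <- deg_overlap(join)
    pw <- cross_pathway_consensus(enr_a$ora, enr_a$gsea, enr_b$ora,
                                  enr_b$gsea, config$q_threshold)
    emit(write_gene_stats, run_b$stats, "gene_stats_b.tsv")
    emit(write_tsv_fmt, join, "xspecies_join.tsv")
    shared_genes <- join$id_a[join$deg_a != "none" &
                                join$deg_b != "none"]
    emit(function(x, p) writeLines(x, p), shared_genes,
         "xspecies_shared_degs.txt")
    if (!is.null(pw$scores)) {
      emit(write_tsv_fmt, pw$scores, "xspecies_pathway_scores.tsv")
    }
    xsp_json <- list(
      correlation = as.list(corr), overlap = as.list(overlap),
      strict_consensus = pw$strict,
      pathway_correlation = if (is.null(pw$correlation)) NULL
                            else as.list(pw$correlation))
    emit(function(x, p) jsonlite::write_json(x, p, auto_unbox = TRUE,
                                             digits = 10, pretty = TRUE),
         xsp_json, "xspecies.json")
    xsp <- list(join = join, correlation = corr, overlap = overlap,
                pathways = pw)
  }

  # --- manifest -----------------------------------------------------
  manifest <- list(
    parameters = config[setdiff(names(config),
                                c("counts", "samples", "sets", "dag",
                                  "counts_b", "samples_b", "orthologs",
                                  "simulate"))],
    warnings = warnings_log,
    files = lapply(setNames(basename(outputs), basename(outputs)),
                   function(f) unname(tools::md5sum(
                     file.path(out_dir, f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(run = run_a, validation = validation, enrich = enr_a,
                 integration = integration, consensus = cons,
                 xspecies = xsp, manifest = manifest,
                 out_dir = out_dir))
}
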