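# Readers/writers for the pipeline's plain-text interchange formats.
# All numeric TSV output uses fixed 6-significant-digit formatting so
# reruns are byte-identical.

#' Read / write a counts table
#'
#' TSV with genes in rows: first column `gene_id`, then one integer
#' column per sample.
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}

#' @rdname read_counts
#' @param counts Counts tibble.
#' @export
write_counts <- function(counts, path) {
  utils::write.table(as.data.frame(counts), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write sample metadata (`sample_id`, `group`)
#'
#' @param path File path.
#' @export
read_samples <- function(path) {
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE,
                                      colClasses = "character"))
}

#' @rdname read_samples
#' @param samples Samples tibble.
#' @export
write_samples <- function(samples, path) {
  utils::write.table(as.data.frame(samples), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write per-gene differential statistics
#'
#' The TSV uses the field's column names `gene_id`, `m.value`, `a.value`,
#' `p.value`, `q.value`; in-memory tables use `m_value`, `a_value`,
#' `p_value`, `q_value`. Any external backend producing this TSV can feed
#' the scoring stage.
#'
#' @param path File path.
#' @export
read_gene_stats <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df) <- sub("^m\\.value$", "m_value", names(df))
  names(df) <- sub("^a\\.value$", "a_value", names(df))
  names(df) <- sub("^p\\.value$", "p_value", names(df))
  names(df) <- sub("^q\\.value$", "q_value", names(df))
  tibble::as_tibble(df)
}

#' @rdname read_gene_stats
#' @param stats Gene statistics tibble.
#' @export
write_gene_stats <- function(stats, path) {
  df <- as.data.frame(stats)
  names(df) <- sub("^m_value$", "m.value", names(df))
  names(df) <- sub("^a_value$", "a.value", names(df))
  names(df) <- sub("^p_value$", "p.value", names(df))
  names(df) <- sub("^q_value$", "q.value", names(df))
  write_tsv_fmt(df, path)
}

#' Read / write an ontology DAG edge list
#'
#' TSV with columns `child`, `parent`, `relation` (`is_a` / `part_of`).
#'
#' @param path File path.
#' @param ... Passed to [ontology_dag()].
#' @export
read_dag <- function(path, ...) {
  ontology_dag(utils::read.delim(path, stringsAsFactors = FALSE), ...)
}

#' @rdname read_dag
#' @param dag An [ontology_dag()] or its edge tibble.
#' @export
write_dag <- function(dag, path) {
  edges <- if (inherits(dag, "ontology_dag")) dag$edges else dag
  utils::write.table(as.data.frame(edges), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a one-to-one ortholog map (`id_a`, `id_b`)
#'
#' @param path File path.
#' @export
read_orthologs <- function(path) {
  map <- tibble::as_tibble(utils::read.delim(path,
                                             stringsAsFactors = FALSE,
                                             colClasses = "character"))
  names(map)[1:2] <- c("id_a", "id_b")
  check_one_to_one(map)
}

#' @rdname read_orthologs
#' @param map Ortholog map tibble.
#' @export
write_orthologs <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write simulated data to a directory
#'
#' Writes `counts.tsv`, `samples.tsv` and `truth.tsv` for a `sim_data`
#' object.
#'
#' @param sim A `sim_data` from [simulate_counts()].
#' @param dir Output directory (created if needed).
#' @export
write_sim_data <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_counts(sim$counts, file.path(dir, "counts.tsv"))
  write_samples(sim$samples, file.path(dir, "samples.tsv"))
  write_tsv_fmt(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
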