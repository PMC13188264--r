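# Internal helpers shared across modules.

# Coerce a counts tibble (gene_id + one column per sample) to an integer
# matrix with gene ids as rownames. Accepts a matrix as-is.
counts_matrix <- function(counts) {
  if (is.matrix(counts)) {
    m <- counts
    if (is.null(rownames(m))) {
      rlang::abort("count matrix must have gene ids as rownames")
    }
  } else {
    counts <- tibble::as_tibble(counts)
    if (!"gene_id" %in% names(counts)) {
      rlang::abort("counts must contain a 'gene_id' column")
    }
    m <- as.matrix(counts[setdiff(names(counts), "gene_id")])
    rownames(m) <- counts$gene_id
  }
  if (anyDuplicated(rownames(m))) rlang::abort("duplicate gene ids in counts")
  if (anyDuplicated(colnames(m))) rlang::abort("duplicate sample ids in counts")
  if (any(m < 0)) rlang::abort("counts must be non-negative")
  if (any(abs(m - round(m)) > 1e-8)) rlang::abort("counts must be integers")
  storage.mode(m) <- "double"
  m
}

# Validate sample metadata against a count matrix; returns a factor of group
# labels ordered like colnames(m).
group_factor <- function(samples, m, require_two = TRUE) {
  samples <- tibble::as_tibble(samples)
  if (!all(c("sample_id", "group") %in% names(samples))) {
    rlang::abort("samples must contain 'sample_id' and 'group' columns")
  }
  missing <- setdiff(colnames(m), samples$sample_id)
  if (length(missing) > 0) {
    rlang::abort(paste0("samples without group metadata: ",
                        paste(missing, collapse = ", ")))
  }
  g <- factor(samples$group[match(colnames(m), samples$sample_id)])
  if (require_two && nlevels(g) != 2) {
    rlang::abort("exactly 2 group levels are required")
  }
  g
}

check_fraction <- function(x, name, lo = 0, hi = 1,
                           lo_open = FALSE, hi_open = FALSE) {
  bad <- !is.numeric(x) || anyNA(x) ||
    any(if (lo_open) x <= lo else x < lo) ||
    any(if (hi_open) x >= hi else x > hi)
  if (bad) {
    rlang::abort(sprintf("'%s' must lie in %s%g, %g%s",
                         name, if (lo_open) "(" else "[", lo, hi,
                         if (hi_open) ")" else "]"))
  }
  invisible(x)
}

# All permutations of seq_len(n) as an n! x n integer matrix (first row is
# the identity). Only called for n with factorial(n) small.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- matrix(0L, nrow(sub), n)
    block[, pos] <- n
    block[, setdiff(seq_len(n), pos)] <- sub
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  # reorder so the identity comes first
  id <- which(apply(out, 1, function(p) all(p == seq_len(n))))
  out[c(id, setdiff(seq_len(nrow(out)), id)), , drop = FALSE]
}

# Fixed text formatting for numeric TSV output: 6 significant digits,
# plain decimal point, no scientific notation for moderate magnitudes.
format_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(signif(x, 6), format = "g", digits = 6))
}

write_tsv_fmt <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- format_num(df[[j]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}
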