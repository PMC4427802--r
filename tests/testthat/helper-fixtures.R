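# Shared fixture builders and independent oracles.

# Quick intensity table from a numeric matrix (proteins x samples).
make_intensity <- function(mat, stages = "log2") {
  rn <- rownames(mat)
  if (is.null(rn) || any(rn == "") || anyDuplicated(rn)) {
    rownames(mat) <- sprintf("P%03d", seq_len(nrow(mat)))
  }
  cn <- colnames(mat)
  if (is.null(cn) || any(cn == "") || anyDuplicated(cn)) {
    colnames(mat) <- sprintf("S%02d", seq_len(ncol(mat)))
  }
  df <- tibble::tibble(protein = rownames(mat))
  for (j in seq_len(ncol(mat))) df[[colnames(mat)[j]]] <- unname(mat[, j])
  intensity_tbl(df, stages = stages)
}

# Minimal two-group design over the columns of an intensity table.
make_design <- function(x, n_cca) {
  ids <- names(x)[-1]
  tibble::tibble(
    sample_id = ids,
    group = rep(c("CCA", "BBTD"), c(n_cca, length(ids) - n_cca))
  )
}

# Brute-force quantile-normalization oracle for complete matrices: sort each
# column, average across columns at each rank, map values back through each
# column's rank order. Independent of limma.
quantile_normalize_oracle <- function(mat) {
  sorted <- apply(mat, 2, sort)
  ref <- rowMeans(sorted)
  out <- mat
  for (j in seq_len(ncol(mat))) {
    out[, j] <- ref[rank(mat[, j], ties.method = "average")]
  }
  out
}

# Direct Welch formula evaluation from summaries (oracle for welch_*).
welch_oracle <- function(m1, s1, n1, m2, s2, n2) {
  se2 <- s1^2 / n1 + s2^2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# The published reference cohort dimensions used throughout.
ref_config <- function(...) {
  sim_config(...)
}
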