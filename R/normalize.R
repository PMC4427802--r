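#' Normalization chain for intensity tables
#'
#' The analysis normalizes a protein-by-sample quantitation matrix in three
#' stages: (1) log2 transform of the raw relative-quantitation ratios, (2)
#' per-sample median normalization — subtracting each sample's median so all
#' samples share a common centre, and (3) rank (quantile) normalization across
#' the data set — replacing each sample's values by the cross-sample mean value
#' at the same within-sample rank, so all sample distributions coincide. Each
#' stage records itself in the table's stage attribute; `log2_transform`
#' refuses to run twice.
#'
#' Missing entries are preserved by every stage and excluded from medians and
#' ranks; for samples with unequal numbers of observed values the reference
#' quantile profile is interpolated linearly (the behaviour of
#' `limma::normalizeQuantiles`, which backs the quantile method).
#'
#' @param x An [intensity_tbl()].
#' @param method For `rank_normalize`: `"quantile"` (default; cross-sample
#'   quantile normalization with tie-averaged ranks) or `"protein_rank"`
#'   (replace each protein's values by their average ranks across samples; an
#'   alternative reading of rank normalization, off by default).
#' @return The normalized `intensity_tbl`.
#' @name normalization
#' @examples
#' m <- intensity_tbl(data.frame(protein = c("a", "b", "c"),
#'   s1 = c(2, 0, 4), s2 = c(10, 8, 12)), stages = "log2")
#' rank_normalize(median_normalize(m))
NULL

check_columns_observed <- function(mat) {
  empty <- colSums(!is.na(mat)) == 0
  if (any(empty)) {
    abort(
      paste0(
        "Sample column(s) with no observed values: ",
        paste(colnames(mat)[empty], collapse = ", ")
      ),
      class = "serodiff_data_error"
    )
  }
}

#' @rdname normalization
#' @export
log2_transform <- function(x) {
  if (has_stage(x, "log2")) {
    abort("Matrix is already on the log2 scale; refusing to transform twice.",
      class = "serodiff_stage_error"
    )
  }
  mat <- intensity_matrix(x)
  bad <- which(!is.na(mat) & mat <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(
      sprintf(
        "Non-positive value for protein `%s`, sample `%s`: cannot log2-transform.",
        rownames(mat)[bad[1, 1]], colnames(mat)[bad[1, 2]]
      ),
      class = "serodiff_data_error"
    )
  }
  add_stage(set_intensity_values(x, log2(mat)), "log2")
}

#' @rdname normalization
#' @export
median_normalize <- function(x) {
  mat <- intensity_matrix(x)
  check_columns_observed(mat)
  med <- apply(mat, 2, median, na.rm = TRUE)
  add_stage(set_intensity_values(x, sweep(mat, 2, med)), "median")
}

#' @rdname normalization
#' @export
rank_normalize <- function(x, method = c("quantile", "protein_rank")) {
  method <- match.arg(method)
  mat <- intensity_matrix(x)
  check_columns_observed(mat)
  out <- if (method == "quantile") {
    limma::normalizeQuantiles(mat, ties = TRUE)
  } else {
    t(apply(mat, 1, function(r) {
      r[!is.na(r)] <- rank(r[!is.na(r)])
      r
    }))
  }
  dimnames(out) <- dimnames(mat)
  add_stage(set_intensity_values(x, out), "rank")
}

#' Apply the full normalization chain
#'
#' Runs the configured stages in order: optional log2 transform (off by
#' default, for matrices whose values are already log2 ratios), per-sample
#' median normalization, then rank normalization across samples.
#'
#' @inheritParams normalization
#' @param log2 Apply [log2_transform()] first? Use `TRUE` for raw-scale
#'   ratios.
#' @param median,rank Apply the respective stage (both default `TRUE`).
#' @param rank_method Passed to [rank_normalize()].
#' @return The normalized `intensity_tbl`.
#' @export
normalize_intensity <- function(x, log2 = FALSE, median = TRUE, rank = TRUE,
                                rank_method = c("quantile", "protein_rank")) {
  if (log2) x <- log2_transform(x)
  if (median) x <- median_normalize(x)
  if (rank) x <- rank_normalize(x, method = rank_method)
  x
}
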