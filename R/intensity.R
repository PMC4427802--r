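#' Intensity tables
#'
#' A protein-by-sample table of (possibly missing) relative-quantitation
#' values. The first column, `protein`, holds unique protein identifiers;
#' every other column is one sample. An `intensity_tbl` is an ordinary tibble
#' carrying a `stages` attribute that records which normalization stages
#' (`"log2"`, `"median"`, `"rank"`) have been applied, so stages cannot be
#' applied twice or out of order by accident.
#'
#' @param x A data frame whose first column is `protein` (character, unique)
#'   and whose remaining columns are numeric sample intensities.
#' @param stages Character vector of normalization stages already applied.
#' @return A tibble of class `intensity_tbl`.
#' @examples
#' m <- intensity_tbl(data.frame(protein = c("P1", "P2"), S1 = c(1, 2), S2 = c(3, 4)))
#' intensity_stages(m)
#' @export
intensity_tbl <- function(x, stages = character()) {
  x <- tibble::as_tibble(x)
  if (ncol(x) < 2L || names(x)[1] != "protein") {
    abort("An intensity table needs a first column `protein` plus >= 1 sample column.",
      class = "serodiff_format_error"
    )
  }
  x$protein <- as.character(x$protein)
  if (anyDuplicated(x$protein)) {
    dup <- unique(x$protein[duplicated(x$protein)])
    abort(paste0("Duplicate protein ids: ", paste(head(dup, 5), collapse = ", ")),
      class = "serodiff_format_error"
    )
  }
  if (anyDuplicated(names(x))) {
    abort("Duplicate sample ids in intensity table.", class = "serodiff_format_error")
  }
  for (j in seq(2L, ncol(x))) {
    if (!is.numeric(x[[j]])) {
      abort(sprintf("Sample column `%s` is not numeric.", names(x)[j]),
        class = "serodiff_format_error"
      )
    }
  }
  new_intensity_tbl(x, stages)
}

new_intensity_tbl <- function(x, stages = character()) {
  structure(x,
    class = c("intensity_tbl", class(tibble::tibble())),
    stages = unique(as.character(stages))
  )
}

#' @rdname intensity_tbl
#' @export
intensity_stages <- function(x) {
  attr(x, "stages") %||% character()
}

has_stage <- function(x, stage) stage %in% intensity_stages(x)

add_stage <- function(x, stage) {
  attr(x, "stages") <- union(intensity_stages(x), stage)
  x
}

#' Extract the numeric value matrix of an intensity table
#'
#' @param x An `intensity_tbl`.
#' @return A numeric matrix, proteins in rows (rownames = protein ids),
#'   samples in columns.
#' @export
intensity_matrix <- function(x) {
  mat <- as.matrix(as.data.frame(x[, -1, drop = FALSE]))
  rownames(mat) <- x$protein
  mat
}

# Rebuild an intensity_tbl from a replacement value matrix, keeping ids,
# column order and the stage record.
set_intensity_values <- function(x, mat) {
  stopifnot(nrow(mat) == nrow(x), ncol(mat) == ncol(x) - 1L)
  out <- x
  for (j in seq_len(ncol(mat))) {
    out[[j + 1L]] <- unname(mat[, j])
  }
  out
}

sample_ids <- function(x) names(x)[-1]
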