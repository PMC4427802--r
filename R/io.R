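#' Read and write pipeline files
#'
#' The matrix dialect is TSV: first column `protein`, header row of sample
#' ids, missing values encoded as empty fields (never a sentinel number).
#' Cohort designs are CSV with columns `sample_id`, `group` (exactly `"CCA"`
#' or `"BBTD"`), and optional clinical covariates. Fold plans round-trip as
#' JSON. All writers round-trip losslessly with their readers (values are
#' written with full precision).
#'
#' @param x,plan Object to write.
#' @param path File path.
#' @param stages Normalization stages already applied to the matrix being
#'   read (recorded on the returned [intensity_tbl()]).
#' @return Readers return the parsed object; writers return `path`
#'   invisibly.
#' @name serodiff-io
NULL

#' @rdname serodiff-io
#' @export
write_intensity <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path, na = "")
  invisible(path)
}

#' @rdname serodiff-io
#' @export
read_intensity <- function(path, stages = character()) {
  df <- readr::read_tsv(path,
    na = "", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_double(), protein = readr::col_character())
  )
  pb <- readr::problems(df)
  if (nrow(pb) > 0) {
    abort(
      paste0(
        "Malformed matrix file; first problem at line ",
        pb$row[1] + 1L, ": ", pb$expected[1], " vs ", pb$actual[1]
      ),
      class = "serodiff_format_error"
    )
  }
  intensity_tbl(df, stages = stages)
}

#' @rdname serodiff-io
#' @export
write_design <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path, na = "")
  invisible(path)
}

#' @rdname serodiff-io
#' @export
read_design <- function(path) {
  df <- readr::read_csv(path, na = "", show_col_types = FALSE, progress = FALSE)
  pb <- readr::problems(df)
  if (nrow(pb) > 0) {
    abort(sprintf("Malformed design file at line %d.", pb$row[1] + 1L),
      class = "serodiff_format_error"
    )
  }
  if (!all(c("sample_id", "group") %in% names(df))) {
    abort("Design file needs columns `sample_id` and `group`.",
      class = "serodiff_format_error"
    )
  }
  bad <- which(!df$group %in% c("CCA", "BBTD"))
  if (length(bad) > 0) {
    abort(
      sprintf(
        "Unknown group label `%s` at line %d (expected CCA or BBTD).",
        df$group[bad[1]], bad[1] + 1L
      ),
      class = "serodiff_format_error"
    )
  }
  if (anyDuplicated(df$sample_id)) {
    dup <- df$sample_id[duplicated(df$sample_id)][1]
    abort(sprintf("Duplicate sample id `%s` in design file.", dup),
      class = "serodiff_format_error"
    )
  }
  tibble::as_tibble(df)
}

#' @rdname serodiff-io
#' @export
write_folds <- function(plan, path) {
  k <- fold_k(plan)
  doc <- list(
    k = k,
    mode = attr(plan, "mode"),
    seed = attr(plan, "seed"),
    folds = purrr::map(seq_len(k), function(f) {
      list(
        fold = f,
        train = fold_ids(plan, f, "train"),
        validation = fold_ids(plan, f, "validation")
      )
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname serodiff-io
#' @export
read_folds <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  plan <- purrr::map_dfr(seq_len(doc$k), function(f) {
    fd <- doc$folds[f, ]
    tr <- unlist(fd$train)
    va <- unlist(fd$validation)
    tibble::tibble(
      fold = as.integer(fd$fold),
      sample_id = c(tr, va),
      role = rep(c("train", "validation"), c(length(tr), length(va)))
    )
  })
  structure(plan,
    class = c("fold_plan", class(tibble::tibble())),
    k = as.integer(doc$k), mode = doc$mode,
    seed = if (is.null(doc$seed)) NULL else as.integer(doc$seed)
  )
}
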