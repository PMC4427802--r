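#' Cross-validated Welch-test selection of differentially expressed proteins
#'
#' Implements the intersection selection rule: a protein is called
#' differentially expressed (DE) only if its two-sided Welch p-value is below
#' `alpha` in *every* fold of the cross-validation plan. By default each
#' fold's test runs on its training samples (`test_scope = "train"`); the
#' small validation sets (2--4 per group at the reference cohort size) barely
#' support a t-test, but `test_scope = "all"` is available to test each fold
#' on the full cohort instead.
#'
#' A protein is *quantifiable* only if it has at least `min_obs_per_group`
#' observed values per group in every fold's tested set; unquantifiable
#' proteins are never selected and carry `NA` fold p-values. No
#' multiple-testing correction is applied by the selection rule itself — the
#' intersection over folds is the stringency device — but a
#' Benjamini-Hochberg-adjusted all-sample p-value (`p_bh`) is reported as an
#' audit column.
#'
#' @param x A normalized [intensity_tbl()].
#' @param design Cohort tibble with `sample_id` and `group`.
#' @param folds A [build_folds()] plan over `design`.
#' @param alpha Per-fold significance cutoff, strict (`p < alpha`), in (0, 1).
#' @param min_obs_per_group Minimum observed values per group per fold.
#' @param test_scope `"train"` (default) or `"all"`.
#' @return A tibble of class `de_table`, one row per protein: group sizes,
#'   all-sample group means and SDs, `log2_fc` (CCA minus BBTD), per-fold
#'   p-values (`p_fold_1`, ...), `max_fold_p`, all-sample Welch `p_all` and
#'   `p_bh`, `quantifiable`, `is_de`, and `direction` (`"up"` = CCA > BBTD,
#'   `"down"` = CCA < BBTD).
#' @examples
#' cfg <- sim_config(n_proteins = 60, seed = 2)
#' design <- simulate_cohort(cfg)
#' sim <- simulate_matrix(cfg, design)
#' norm <- normalize_intensity(sim$matrix)
#' de <- select_de(norm, design, build_folds(design, seed = 2))
#' glance(de)
#' @export
select_de <- function(x, design, folds, alpha = 0.01, min_obs_per_group = 2L,
                      test_scope = c("train", "all")) {
  test_scope <- match.arg(test_scope)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single number in (0, 1).", class = "serodiff_config_error")
  }
  stopifnot_scalar_count(min_obs_per_group, "min_obs_per_group", min = 1L)
  validate_fold_plan(folds, design)
  mat <- intensity_matrix(x)
  if (!setequal(colnames(mat), design$sample_id)) {
    abort("Matrix sample ids do not match the design.", class = "serodiff_config_error")
  }
  k <- fold_k(folds)
  grp <- stats::setNames(design$group, design$sample_id)

  fold_p <- matrix(NA_real_, nrow = nrow(mat), ncol = k)
  fold_ok <- matrix(FALSE, nrow = nrow(mat), ncol = k)
  for (f in seq_len(k)) {
    ids <- if (test_scope == "train") fold_ids(folds, f, "train") else design$sample_id
    a <- row_group_stats(mat[, ids[grp[ids] == "CCA"], drop = FALSE])
    b <- row_group_stats(mat[, ids[grp[ids] == "BBTD"], drop = FALSE])
    ok <- a$n >= min_obs_per_group & b$n >= min_obs_per_group
    st <- welch_stats(a$mean, a$var, a$n, b$mean, b$var, b$n)
    fold_ok[, f] <- ok
    fold_p[, f] <- ifelse(ok, st$p, NA_real_)
  }
  quantifiable <- rowSums(fold_ok) == k

  ids_cca <- design$sample_id[design$group == "CCA"]
  ids_bbtd <- design$sample_id[design$group == "BBTD"]
  all_a <- row_group_stats(mat[, ids_cca, drop = FALSE])
  all_b <- row_group_stats(mat[, ids_bbtd, drop = FALSE])
  all_st <- welch_stats(all_a$mean, all_a$var, all_a$n, all_b$mean, all_b$var, all_b$n)
  overall_ok <- all_a$n >= 2 & all_b$n >= 2
  p_all <- ifelse(overall_ok, all_st$p, NA_real_)

  max_fold_p <- ifelse(quantifiable, apply(fold_p, 1, max), NA_real_)
  is_de <- quantifiable & rowSums(fold_p < alpha, na.rm = TRUE) == k
  log2_fc <- all_a$mean - all_b$mean
  direction <- dplyr::case_when(
    is.na(log2_fc) | log2_fc == 0 ~ NA_character_,
    log2_fc > 0 ~ "up",
    TRUE ~ "down"
  )

  out <- tibble::tibble(
    protein = rownames(mat),
    n_cca = all_a$n, n_bbtd = all_b$n,
    mean_cca = all_a$mean, sd_cca = sqrt(all_a$var),
    mean_bbtd = all_b$mean, sd_bbtd = sqrt(all_b$var),
    log2_fc = log2_fc
  )
  colnames(fold_p) <- sprintf("p_fold_%d", seq_len(k))
  out <- dplyr::bind_cols(out, tibble::as_tibble(fold_p))
  out$max_fold_p <- max_fold_p
  out$p_all <- p_all
  out$p_bh <- p.adjust(p_all, method = "BH")
  out$quantifiable <- quantifiable
  out$is_de <- is_de
  out$direction <- direction
  structure(out,
    class = c("de_table", class(tibble::tibble())),
    alpha = alpha, k = k, test_scope = test_scope,
    min_obs_per_group = as.integer(min_obs_per_group)
  )
}

#' Split a DE table by direction of change
#'
#' @param table A [select_de()] result.
#' @return A list with tibbles `up` (CCA > BBTD) and `down` (CCA < BBTD),
#'   each restricted to selected proteins and ordered by `max_fold_p`
#'   ascending.
#' @export
partition_up_down <- function(table) {
  if (!inherits(table, "de_table")) {
    abort("`table` must be a de_table from select_de().", class = "serodiff_config_error")
  }
  de <- dplyr::arrange(dplyr::filter(table, .data$is_de), .data$max_fold_p)
  list(
    up = tibble::as_tibble(dplyr::filter(de, .data$direction == "up")),
    down = tibble::as_tibble(dplyr::filter(de, .data$direction == "down"))
  )
}

#' @method tidy de_table
#' @export
tidy.de_table <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @method glance de_table
#' @export
glance.de_table <- function(x, ...) {
  tibble::tibble(
    n_proteins = nrow(x),
    n_quantifiable = sum(x$quantifiable),
    n_de = sum(x$is_de),
    n_up = sum(x$is_de & x$direction == "up", na.rm = TRUE),
    n_down = sum(x$is_de & x$direction == "down", na.rm = TRUE),
    alpha = attr(x, "alpha"),
    k = attr(x, "k"),
    test_scope = attr(x, "test_scope")
  )
}
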