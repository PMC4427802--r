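#' Hierarchical clustering of samples and proteins
#'
#' Unsupervised validation view of a selected protein set: per-protein
#' z-standardization (clipped to ±3 for display), agglomerative clustering of
#' proteins and of samples (Euclidean distance, average linkage by default),
#' and a 2-cluster cut of the sample tree compared against the known group
#' labels. Constant protein rows cannot be standardized and are dropped with
#' a warning.
#'
#' @param x An [intensity_tbl()], typically restricted to DE proteins via
#'   `proteins`.
#' @param design Cohort tibble with `sample_id` and `group`.
#' @param proteins Optional character vector of protein ids to cluster
#'   (default: all rows of `x`).
#' @param distance Distance measure for [stats::dist()] (default
#'   `"euclidean"`).
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @param clip Display clip bound for standardized values (default 3).
#' @return An object of class `cluster_result`: `sample_hclust` and
#'   `protein_hclust` trees, `display` (long tibble of clipped standardized
#'   values), `assignments` (tibble `sample_id`, `group`, `cluster` at the
#'   2-cluster cut), `confusion` (2x2 table), `misassignments` (count under
#'   the best cluster-to-group matching), and the leaf orders.
#' @examples
#' cfg <- sim_config(n_proteins = 20, frac_de = 0.5, effect_low = 1.5,
#'   effect_high = 2, sd_low = 0.2, sd_high = 0.3, missing_rate = 0, seed = 5)
#' sim <- simulate_matrix(cfg, simulate_cohort(cfg))
#' cl <- cluster_heatmap(sim$matrix, simulate_cohort(cfg))
#' cl$misassignments
#' @export
cluster_heatmap <- function(x, design, proteins = NULL,
                            distance = "euclidean", linkage = "average",
                            clip = 3) {
  mat <- subset_proteins(x, proteins)
  mat <- mat[, design$sample_id, drop = FALSE]
  if (nrow(mat) < 2L) {
    abort("Clustering needs at least 2 proteins.", class = "serodiff_data_error")
  }
  if (min(table(design$group)) < 2L) {
    abort("Clustering needs at least 2 samples per group.", class = "serodiff_data_error")
  }
  st <- row_group_stats(mat)
  constant <- st$var == 0 | is.na(st$var)
  if (any(constant)) {
    warn(sprintf("Dropping %d constant protein row(s) before standardization.", sum(constant)))
    mat <- mat[!constant, , drop = FALSE]
    st <- row_group_stats(mat)
  }
  if (nrow(mat) < 2L) {
    abort("Fewer than 2 non-constant proteins left to cluster.",
      class = "serodiff_data_error"
    )
  }
  z <- (mat - st$mean) / sqrt(st$var)
  z_disp <- pmin(pmax(z, -clip), clip)

  sample_hc <- hclust(dist(t(z), method = distance), method = linkage)
  protein_hc <- hclust(dist(z, method = distance), method = linkage)
  cut2 <- cutree(sample_hc, k = 2)
  grp <- stats::setNames(design$group, design$sample_id)[names(cut2)]
  confusion <- table(cluster = cut2, group = grp)
  # misassignments under the better of the two cluster-to-group matchings
  mis <- if (all(dim(confusion) == c(2L, 2L))) {
    min(
      confusion[1, "CCA"] + confusion[2, "BBTD"],
      confusion[1, "BBTD"] + confusion[2, "CCA"]
    )
  } else {
    min(table(grp))
  }
  display <- tibble::as_tibble(as.data.frame.table(z_disp, stringsAsFactors = FALSE))
  names(display) <- c("protein", "sample_id", "z")
  structure(
    list(
      sample_hclust = sample_hc,
      protein_hclust = protein_hc,
      display = display,
      assignments = tibble::tibble(
        sample_id = names(cut2), group = unname(grp), cluster = unname(cut2)
      ),
      confusion = confusion,
      misassignments = as.integer(mis),
      sample_order = sample_hc$labels[sample_hc$order],
      protein_order = protein_hc$labels[protein_hc$order],
      clip = clip
    ),
    class = "cluster_result"
  )
}

#' Principal component analysis of samples over a protein set
#'
#' Samples are observations and (centered, unscaled by default) protein
#' values are features. PCA needs complete features; missing values are
#' filled with the protein's observed mean by default (a zero-information
#' placement at the feature centre), or proteins with any missing value can
#' be dropped via `na_action = "drop"`. A group-separation summary — the
#' distance between the two group centroids divided by the mean within-group
#' distance to centroid, in the space of the first `n_comp` components — is
#' reported alongside scores and explained-variance fractions.
#'
#' @inheritParams cluster_heatmap
#' @param n_comp Number of components to keep (default 3).
#' @param scale. Scale features to unit variance? Default `FALSE` (inputs are
#'   already rank-normalized in the standard chain).
#' @param na_action `"impute_mean"` (default) or `"drop"`.
#' @return An object of class `pca_result`: `scores` (tibble `sample_id`,
#'   `group`, `PC1..PCn`), `explained` (variance fractions), `separation`.
#'   `tidy()` returns the scores, `glance()` the summary.
#' @export
pca_scores <- function(x, design, proteins = NULL, n_comp = 3L, scale. = FALSE,
                       na_action = c("impute_mean", "drop")) {
  na_action <- match.arg(na_action)
  mat <- subset_proteins(x, proteins)
  mat <- mat[, design$sample_id, drop = FALSE]
  if (ncol(mat) < 2L) {
    abort("PCA needs at least 2 samples.", class = "serodiff_data_error")
  }
  incomplete <- rowSums(is.na(mat)) > 0
  if (any(incomplete)) {
    if (na_action == "drop") {
      warn(sprintf("Dropping %d protein(s) with missing values before PCA.", sum(incomplete)))
      mat <- mat[!incomplete, , drop = FALSE]
    } else {
      rm_mean <- rowMeans(mat, na.rm = TRUE)
      idx <- which(is.na(mat), arr.ind = TRUE)
      mat[idx] <- rm_mean[idx[, 1]]
      drop_all_na <- is.na(rowMeans(mat))
      mat <- mat[!drop_all_na, , drop = FALSE]
    }
  }
  if (nrow(mat) < 1L) {
    abort("No complete proteins left for PCA.", class = "serodiff_data_error")
  }
  n_comp <- min(as.integer(n_comp), ncol(mat) - 1L, nrow(mat))
  pc <- prcomp(t(mat), center = TRUE, scale. = scale.)
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x[, seq_len(n_comp), drop = FALSE]
  grp <- stats::setNames(design$group, design$sample_id)[rownames(scores)]
  cent <- rowsum(scores, grp) / as.vector(table(grp)[sort(unique(grp))])
  between <- sqrt(sum((cent[1, ] - cent[2, ])^2))
  within <- mean(sqrt(rowSums((scores - cent[grp, , drop = FALSE])^2)))
  scores_tbl <- dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(scores), group = unname(grp)),
    tibble::as_tibble(scores)
  )
  structure(
    list(
      scores = scores_tbl,
      explained = explained[seq_len(n_comp)],
      separation = between / within,
      n_proteins = nrow(mat)
    ),
    class = "pca_result"
  )
}

#' @method tidy pca_result
#' @export
tidy.pca_result <- function(x, ...) x$scores

#' @method glance pca_result
#' @export
glance.pca_result <- function(x, ...) {
  out <- tibble::tibble(
    n_proteins = x$n_proteins,
    separation = x$separation
  )
  for (i in seq_along(x$explained)) {
    out[[sprintf("var_pc%d", i)]] <- x$explained[i]
  }
  out
}

#' Volcano coordinates for a DE table
#'
#' One point per quantifiable protein: log2 fold change (CCA minus BBTD)
#' against -log10 of the worst (maximum) per-fold p-value, flagged at a
#' strict `p < cutoff`. At the cutoff used for selection the flags reproduce
#' the DE calls exactly.
#'
#' @param detable A [select_de()] result.
#' @param cutoff Significance cutoff (default 0.01, strict).
#' @return A tibble: `protein`, `log2_fc`, `p`, `neg_log10_p`, `de`.
#' @export
volcano <- function(detable, cutoff = 0.01) {
  if (!inherits(detable, "de_table")) {
    abort("`detable` must come from select_de().", class = "serodiff_config_error")
  }
  pts <- dplyr::filter(tibble::as_tibble(detable), .data$quantifiable)
  tibble::tibble(
    protein = pts$protein,
    log2_fc = pts$log2_fc,
    p = pts$max_fold_p,
    neg_log10_p = -log10(pts$max_fold_p),
    de = pts$max_fold_p < cutoff
  )
}

#' Per-group five-number summaries for selected proteins
#'
#' Box-plot coordinates (min, Q1, median, Q3, max; quartiles by linear
#' interpolation, `stats::quantile` type 7) per protein and group, computed
#' on normalized log2 values. By default the top `n_top` proteins by absolute
#' log2 fold change among the DE calls of `detable` are summarized.
#'
#' @inheritParams cluster_heatmap
#' @param detable Optional [select_de()] result used to pick the top
#'   proteins when `proteins` is not given.
#' @param n_top How many top-|fold change| DE proteins to take from
#'   `detable`.
#' @return A tibble: `protein`, `group`, `n`, `min`, `q1`, `median`, `q3`,
#'   `max`.
#' @export
top_protein_boxes <- function(x, design, proteins = NULL, detable = NULL,
                              n_top = 5L) {
  if (is.null(proteins)) {
    if (is.null(detable)) {
      abort("Provide `proteins` or a `detable` to pick the top proteins from.",
        class = "serodiff_config_error"
      )
    }
    de <- dplyr::filter(tibble::as_tibble(detable), .data$is_de)
    proteins <- head(de$protein[order(-abs(de$log2_fc))], n_top)
  }
  missing_ids <- setdiff(proteins, x$protein)
  if (length(missing_ids) > 0) {
    abort(paste0(
      "Unknown protein id(s): ", paste(missing_ids, collapse = ", ")
    ), class = "serodiff_data_error")
  }
  mat <- subset_proteins(x, proteins)
  grp <- stats::setNames(design$group, design$sample_id)
  long <- tibble::as_tibble(as.data.frame.table(mat, stringsAsFactors = FALSE))
  names(long) <- c("protein", "sample_id", "value")
  long$group <- unname(grp[long$sample_id])
  long |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$protein, .data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      min = min(.data$value),
      q1 = quantile(.data$value, 0.25, type = 7, names = FALSE),
      median = quantile(.data$value, 0.5, type = 7, names = FALSE),
      q3 = quantile(.data$value, 0.75, type = 7, names = FALSE),
      max = max(.data$value),
      .groups = "drop"
    ) |>
    dplyr::mutate(protein = factor(.data$protein, levels = proteins)) |>
    dplyr::arrange(.data$protein, .data$group) |>
    dplyr::mutate(protein = as.character(.data$protein))
}

# Value matrix restricted to a protein subset (NULL = all), order preserved.
subset_proteins <- function(x, proteins) {
  mat <- intensity_matrix(x)
  if (is.null(proteins)) {
    return(mat)
  }
  missing_ids <- setdiff(proteins, rownames(mat))
  if (length(missing_ids) > 0) {
    abort(paste0(
      "Unknown protein id(s): ", paste(missing_ids, collapse = ", ")
    ), class = "serodiff_data_error")
  }
  mat[proteins, , drop = FALSE]
}
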