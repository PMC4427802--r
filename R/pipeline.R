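#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis: input paths (or a
#' simulation config when no inputs are given), the normalization switches,
#' fold parameters, the selection cutoff and quantifiability threshold,
#' multivariate options, and the master seed. The per-fold selection cutoff
#' defaults to 0.01 and the cross-validation to k = 6 folds, the constants of
#' the reference analysis.
#'
#' @param out_dir Output directory for [run_pipeline()].
#' @param matrix_path,design_path Optional input files (TSV matrix / CSV
#'   design). When `NULL`, a synthetic data set from `sim` is generated.
#' @param sim A [sim_config()] used when no input paths are given.
#' @param log2,median,rank,rank_method Normalization switches, see
#'   [normalize_intensity()]. `log2 = FALSE` by default: simulated matrices
#'   and typical label-free ratio exports are already on the log2 scale.
#' @param k,fold_mode Cross-validation parameters, see [build_folds()].
#' @param alpha Per-fold DE cutoff in (0, 1).
#' @param min_obs_per_group,test_scope See [select_de()].
#' @param n_top Top proteins summarized by [top_protein_boxes()].
#' @param seed Master seed; stage seeds are derived from it deterministically.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            matrix_path = NULL, design_path = NULL,
                            sim = sim_config(),
                            log2 = FALSE, median = TRUE, rank = TRUE,
                            rank_method = "quantile",
                            k = 6L, fold_mode = "partition",
                            alpha = 0.01, min_obs_per_group = 2L,
                            test_scope = "train",
                            n_top = 5L, seed = 1L) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be in (0, 1).", class = "serodiff_config_error")
  }
  stopifnot_scalar_count(k, "k", min = 2L)
  stopifnot_scalar_count(seed, "seed", min = 0L)
  for (p in c(matrix_path, design_path)) {
    if (!is.null(p) && !file.exists(p)) {
      abort(sprintf("Input file does not exist: %s", p), class = "serodiff_config_error")
    }
  }
  structure(
    list(
      out_dir = out_dir, matrix_path = matrix_path, design_path = design_path,
      sim = sim, log2 = log2, median = median, rank = rank,
      rank_method = rank_method, k = as.integer(k), fold_mode = fold_mode,
      alpha = alpha, min_obs_per_group = as.integer(min_obs_per_group),
      test_scope = test_scope, n_top = as.integer(n_top),
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Run the full differential-abundance pipeline
#'
#' Executes normalize -> build_folds -> select_de -> partition_up_down ->
#' multivariate views -> compare_cohorts on the configured inputs (or on a
#' synthetic data set when none are given) and writes every result plus a run
#' manifest to `config$out_dir`. Reruns with an identical config and inputs
#' are byte-identical. A per-stage funnel (rows in / selected) is recorded in
#' the manifest, and any stage failure aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`design`, `matrix`,
#'   `folds`, `de`, `up_down`, `volcano`, `cluster`, `pca`, `boxes`,
#'   `cohort`, `manifest`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must come from pipeline_config().", class = "serodiff_config_error")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("serodiff")),
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    complete = FALSE,
    funnel = list()
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  write_manifest <- function() {
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      manifest$error <<- list(stage = stage, message = conditionMessage(e))
      write_manifest()
      abort(sprintf("Pipeline stage `%s` failed: %s", stage, conditionMessage(e)),
        class = "serodiff_stage_error"
      )
    })
  }

  res <- list()
  run_stage("inputs", {
    if (is.null(config$matrix_path)) {
      sim <- config$sim
      sim$seed <- stage_seed(config$seed, 0L)
      res$design <- simulate_cohort(sim)
      simd <- simulate_matrix(sim, res$design)
      res$matrix_raw <- simd$matrix
      res$truth <- simd$truth
      write_design(res$design, file.path(config$out_dir, "design.csv"))
      write_intensity(res$matrix_raw, file.path(config$out_dir, "matrix_raw.tsv"))
      readr::write_tsv(res$truth, file.path(config$out_dir, "truth.tsv"), na = "")
    } else {
      res$matrix_raw <- read_intensity(
        config$matrix_path,
        stages = if (config$log2) character() else "log2"
      )
      res$design <- read_design(config$design_path)
    }
  })
  manifest$funnel$proteins_in <- nrow(res$matrix_raw)
  manifest$funnel$samples <- nrow(res$design)

  run_stage("normalize", {
    res$matrix <- normalize_intensity(res$matrix_raw,
      log2 = config$log2, median = config$median, rank = config$rank,
      rank_method = config$rank_method
    )
    write_intensity(res$matrix, file.path(config$out_dir, "matrix_normalized.tsv"))
  })

  run_stage("build_folds", {
    res$folds <- build_folds(res$design,
      k = config$k, mode = config$fold_mode,
      seed = stage_seed(config$seed, 1L)
    )
    write_folds(res$folds, file.path(config$out_dir, "folds.json"))
  })

  run_stage("select_de", {
    res$de <- select_de(res$matrix, res$design, res$folds,
      alpha = config$alpha, min_obs_per_group = config$min_obs_per_group,
      test_scope = config$test_scope
    )
    readr::write_tsv(tibble::as_tibble(res$de),
      file.path(config$out_dir, "de_table.tsv"),
      na = ""
    )
    res$up_down <- partition_up_down(res$de)
  })
  g <- glance(res$de)
  manifest$funnel$proteins_quantifiable <- g$n_quantifiable
  manifest$funnel$proteins_de <- g$n_de
  manifest$funnel$de_up <- g$n_up
  manifest$funnel$de_down <- g$n_down

  run_stage("multivariate", {
    res$volcano <- volcano(res$de, cutoff = config$alpha)
    readr::write_tsv(res$volcano, file.path(config$out_dir, "volcano.tsv"), na = "")
    de_ids <- res$de$protein[res$de$is_de]
    if (length(de_ids) >= 2L) {
      res$cluster <- cluster_heatmap(res$matrix, res$design, proteins = de_ids)
      readr::write_tsv(res$cluster$assignments,
        file.path(config$out_dir, "cluster_assignments.tsv"),
        na = ""
      )
      res$pca <- pca_scores(res$matrix, res$design, proteins = de_ids)
      readr::write_tsv(tidy(res$pca), file.path(config$out_dir, "pca_scores.tsv"), na = "")
      res$boxes <- top_protein_boxes(res$matrix, res$design,
        detable = res$de, n_top = config$n_top
      )
      readr::write_tsv(res$boxes, file.path(config$out_dir, "top_protein_boxes.tsv"), na = "")
      manifest$funnel$cluster_misassignments <- res$cluster$misassignments
      manifest$funnel$pca_separation <- res$pca$separation
    } else {
      manifest$funnel$multivariate <- "skipped: fewer than 2 DE proteins"
    }
  })

  run_stage("compare_cohorts", {
    if (all(c("sex", "age") %in% names(res$design))) {
      res$cohort <- compare_cohorts(res$design)
      readr::write_tsv(res$cohort, file.path(config$out_dir, "cohort_comparison.tsv"), na = "")
    }
  })

  manifest$complete <- TRUE
  write_manifest()
  res$manifest <- manifest
  invisible(res)
}
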