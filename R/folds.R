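#' Build a cross-validation fold plan
#'
#' Splits the cohort into `k` train/validation folds, stratified by group. At
#' the reference cohort size (17 BBTD + 19 CCA, k = 6) every fold has a
#' 30-sample training set with 13--15 BBTD and 15--17 CCA and a 6-sample
#' validation set with 2--4 of each group; for other cohorts the per-group
#' validation counts must fall within `round(n_group / k) ± 1` (never below
#' 1), the proportional generalization of those bounds.
#'
#' In `"partition"` mode (default, the conventional reading of k-fold
#' cross-validation) the k validation sets are disjoint and cover the whole
#' cohort: samples are shuffled within each group and dealt round-robin to the
#' folds, with rejection-resampling should a count bound fail. In
#' `"resample"` mode each fold's split is drawn independently.
#'
#' @param design A cohort tibble with columns `sample_id` and `group`
#'   (values `"CCA"` / `"BBTD"`).
#' @param k Number of folds (>= 2; default 6).
#' @param mode `"partition"` or `"resample"`.
#' @param seed Integer seed for the fold assignment.
#' @param max_tries Rejection-resampling cap before giving up.
#' @return A tibble of class `fold_plan` with columns `fold`, `sample_id`,
#'   `role` (`"train"` / `"validation"`), carrying `k`, `mode`, `seed` and the
#'   per-group validation-count bounds as attributes.
#' @examples
#' design <- simulate_cohort(sim_config(seed = 1))
#' plan <- build_folds(design, k = 6, seed = 1)
#' dplyr::count(plan, fold, role)
#' @export
build_folds <- function(design, k = 6L, mode = c("partition", "resample"),
                        seed = 1L, max_tries = 1000L) {
  mode <- match.arg(mode)
  stopifnot_scalar_count(k, "k", min = 2L)
  k <- as.integer(k)
  if (!all(c("sample_id", "group") %in% names(design))) {
    abort("`design` needs columns `sample_id` and `group`.",
      class = "serodiff_config_error"
    )
  }
  groups <- split(design$sample_id, design$group)
  if (!setequal(names(groups), c("CCA", "BBTD"))) {
    abort("`design$group` must contain exactly the groups CCA and BBTD.",
      class = "serodiff_config_error"
    )
  }
  bounds <- purrr::map(groups, function(ids) {
    centre <- round(length(ids) / k)
    c(lo = max(1L, centre - 1L), hi = centre + 1L)
  })
  for (g in names(groups)) {
    n_g <- length(groups[[g]])
    if (mode == "partition" && (n_g < k * bounds[[g]]["lo"] || n_g > k * bounds[[g]]["hi"])) {
      abort(
        sprintf(
          "Cannot partition %d %s samples into %d validation sets of %d-%d each.",
          n_g, g, k, bounds[[g]]["lo"], bounds[[g]]["hi"]
        ),
        class = "serodiff_config_error"
      )
    }
    if (mode == "resample" && bounds[[g]]["lo"] > n_g - 2L) {
      abort(
        sprintf("Group %s too small to leave >= 2 training samples per fold.", g),
        class = "serodiff_config_error"
      )
    }
  }
  assignment <- with_seed(seed, {
    if (mode == "partition") {
      partition_folds(groups, k, bounds, max_tries)
    } else {
      resample_folds(groups, k, bounds, max_tries)
    }
  })
  all_ids <- design$sample_id
  plan <- purrr::map_dfr(seq_len(k), function(f) {
    val <- assignment[[f]]
    tibble::tibble(
      fold = f,
      sample_id = c(setdiff(all_ids, val), val),
      role = rep(c("train", "validation"), c(length(all_ids) - length(val), length(val)))
    )
  })
  structure(plan,
    class = c("fold_plan", class(tibble::tibble())),
    k = k, mode = mode, seed = if (is.null(seed)) NULL else as.integer(seed),
    bounds = bounds
  )
}

# Stratified partition into k validation sets: per group, each fold gets
# floor(n_g / k) members plus at most one extra; extras are re-drawn until
# fold totals are balanced (differ by <= 1) and every per-group count bound
# holds. Returns a list of k validation id vectors forming a partition.
partition_folds <- function(groups, k, bounds, max_tries) {
  for (try in seq_len(max_tries)) {
    counts <- matrix(0L, nrow = k, ncol = length(groups),
      dimnames = list(NULL, names(groups))
    )
    for (g in names(groups)) {
      n_g <- length(groups[[g]])
      base <- n_g %/% k
      counts[, g] <- base
      extra <- n_g - base * k
      if (extra > 0) {
        idx <- if (k == 1L) 1L else sample.int(k, extra)
        counts[idx, g] <- counts[idx, g] + 1L
      }
    }
    totals <- rowSums(counts)
    ok <- (max(totals) - min(totals) <= 1L) &&
      all(purrr::map_lgl(names(groups), function(g) {
        all(counts[, g] >= bounds[[g]]["lo"]) && all(counts[, g] <= bounds[[g]]["hi"])
      }))
    if (ok) {
      folds <- vector("list", k)
      for (g in names(groups)) {
        shuffled <- sample(groups[[g]])
        stops <- cumsum(counts[, g])
        starts <- c(1L, head(stops, -1L) + 1L)
        for (f in seq_len(k)) {
          if (counts[f, g] > 0) {
            folds[[f]] <- c(folds[[f]], shuffled[starts[f]:stops[f]])
          }
        }
      }
      return(folds)
    }
  }
  abort("Could not satisfy fold count bounds.", class = "serodiff_config_error")
}

# Independent stratified draws per fold; validation size is round(n / k)
# with per-group counts sampled among those satisfying the bounds.
resample_folds <- function(groups, k, bounds, max_tries) {
  n <- sum(lengths(groups))
  m <- round(n / k)
  g1 <- names(groups)[1]
  g2 <- names(groups)[2]
  feas <- Filter(
    function(b) {
      c2 <- m - b
      b >= bounds[[g1]]["lo"] && b <= bounds[[g1]]["hi"] &&
        b <= length(groups[[g1]]) - 2L &&
        c2 >= bounds[[g2]]["lo"] && c2 <= bounds[[g2]]["hi"] &&
        c2 <= length(groups[[g2]]) - 2L
    },
    seq(0L, m)
  )
  if (length(feas) == 0) {
    abort(
      sprintf("No per-group split of a %d-sample validation set satisfies the count bounds.", m),
      class = "serodiff_config_error"
    )
  }
  purrr::map(seq_len(k), function(f) {
    b <- if (length(feas) == 1L) feas[[1]] else sample(unlist(feas), 1L)
    c(sample(groups[[g1]], b), sample(groups[[g2]], m - b))
  })
}

#' @rdname build_folds
#' @param plan A `fold_plan`.
#' @export
fold_k <- function(plan) attr(plan, "k")

# Sample ids for one fold and role.
fold_ids <- function(plan, fold, role) {
  plan$sample_id[plan$fold == fold & plan$role == role]
}

# Assert a plan's structural invariants against a design; used by select_de.
validate_fold_plan <- function(plan, design) {
  if (!inherits(plan, "fold_plan") || nrow(plan) == 0) {
    abort("`folds` must be a non-empty fold_plan from build_folds().",
      class = "serodiff_config_error"
    )
  }
  k <- fold_k(plan)
  for (f in seq_len(k)) {
    tr <- fold_ids(plan, f, "train")
    va <- fold_ids(plan, f, "validation")
    if (length(intersect(tr, va)) > 0 || !setequal(c(tr, va), design$sample_id)) {
      abort(sprintf("Fold %d is not a train/validation split of the design.", f),
        class = "serodiff_config_error"
      )
    }
  }
  invisible(plan)
}
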