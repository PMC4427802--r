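#' Compare clinical characteristics between cohorts
#'
#' Reproduces the standard case/control clinical comparison for this design:
#' sex by Pearson chi-squared on the 2x2 count table (no continuity
#' correction by default), age by two-sample Student t-test, and the
#' right-skewed, assay-censored tumor markers CEA and CA19-9 by Mann-Whitney
#' U. The Mann-Whitney test is exact for small cohorts (<= 20 samples total,
#' no ties) and uses the tie-corrected normal approximation otherwise.
#'
#' @param design Cohort tibble with `group` plus any of `sex`, `age`, `cea`,
#'   `ca19_9`.
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @param yates Apply Yates continuity correction to the chi-squared test?
#' @return A tibble, one row per variable: `variable`, `test`, `statistic`,
#'   `p`, `significant`, and per-group descriptors (`cca`, `bbtd`) — counts
#'   for sex, mean ± SD for age, median (min--max) for the markers. A
#'   variable that is constant across both groups gets `NA` statistics and a
#'   `note`.
#' @examples
#' compare_cohorts(simulate_cohort(sim_config(seed = 1)))
#' @export
compare_cohorts <- function(design, alpha = 0.05, yates = FALSE) {
  grp <- design$group
  if (!all(c("CCA", "BBTD") %in% grp)) {
    abort("Both groups (CCA, BBTD) must be present.", class = "serodiff_config_error")
  }
  rows <- list()
  describe <- function(x, fmt) {
    if (identical(fmt, "mean_sd")) {
      sprintf("%.1f ± %.1f", mean(x, na.rm = TRUE), sd(x, na.rm = TRUE))
    } else {
      sprintf(
        "%.2f (%.2f–%.2f)", median(x, na.rm = TRUE),
        min(x, na.rm = TRUE), max(x, na.rm = TRUE)
      )
    }
  }
  constant_row <- function(variable, test, cca, bbtd) {
    tibble::tibble(
      variable = variable, test = test, statistic = NA_real_, p = NA_real_,
      significant = NA, cca = cca, bbtd = bbtd,
      note = "constant in both groups; statistic undefined"
    )
  }
  if ("sex" %in% names(design)) {
    tab <- table(factor(grp, c("CCA", "BBTD")), factor(design$sex, c("male", "female")))
    counts <- function(g) sprintf("%d : %d", tab[g, "male"], tab[g, "female"])
    if (any(colSums(tab) == 0)) {
      rows$sex <- constant_row("sex", "pearson_chi_squared", counts("CCA"), counts("BBTD"))
    } else {
      ct <- suppressWarnings(chisq.test(tab, correct = yates))
      rows$sex <- tibble::tibble(
        variable = "sex", test = "pearson_chi_squared",
        statistic = unname(ct$statistic), p = ct$p.value,
        significant = ct$p.value < alpha,
        cca = counts("CCA"), bbtd = counts("BBTD"), note = NA_character_
      )
    }
  }
  numeric_row <- function(variable, test_name) {
    x <- design[[variable]]
    a <- x[grp == "CCA"]
    b <- x[grp == "BBTD"]
    fmt <- if (test_name == "student_t") "mean_sd" else "median_range"
    if (length(unique(stats::na.omit(x))) <= 1L) {
      return(constant_row(variable, test_name, describe(a, fmt), describe(b, fmt)))
    }
    ht <- if (test_name == "student_t") {
      t.test(a, b, var.equal = TRUE)
    } else {
      n_tot <- sum(!is.na(a)) + sum(!is.na(b))
      suppressWarnings(wilcox.test(a, b, exact = n_tot <= 20, correct = TRUE))
    }
    tibble::tibble(
      variable = variable, test = test_name,
      statistic = unname(ht$statistic), p = ht$p.value,
      significant = ht$p.value < alpha,
      cca = describe(a, fmt), bbtd = describe(b, fmt), note = NA_character_
    )
  }
  if ("age" %in% names(design)) rows$age <- numeric_row("age", "student_t")
  if ("cea" %in% names(design)) rows$cea <- numeric_row("cea", "mann_whitney_u")
  if ("ca19_9" %in% names(design)) rows$ca19_9 <- numeric_row("ca19_9", "mann_whitney_u")
  dplyr::bind_rows(rows)
}

#' Audit a published mean/SD summary table
#'
#' Recomputes the two-sided Welch p-value for each row of a summary table
#' (group means, SDs, group sizes) via [welch_from_summary()] and flags rows
#' whose recomputed p-value fails the stated cutoff, rows whose *printed*
#' p-value fails it, and rows whose direction label contradicts the sign of
#' `mean_a - mean_b`. Printed p-values may be censored strings such as
#' `"<0.001"`, which count as below any cutoff >= their bound. Malformed rows
#' (non-positive SD, missing values) are reported with a `note` and skipped,
#' not fatal.
#'
#' @param rows Tibble with columns `mean_a`, `sd_a`, `mean_b`, `sd_b`, and
#'   optionally `label`, `printed_p` (numeric or character), `direction`
#'   (`"up"` meaning a > b).
#' @param n_a,n_b Group sizes behind the summaries (defaults 19 CCA / 17
#'   BBTD).
#' @param alpha Cutoff the table claims (default 0.01).
#' @return `rows` augmented with `p_recomputed`, `flag_recomputed_p`,
#'   `flag_printed_p`, `flag_direction`, `note`.
#' @examples
#' audit_summary_table(de_summary_reference()[1:5, ])
#' @export
audit_summary_table <- function(rows, n_a = 19L, n_b = 17L, alpha = 0.01) {
  rows <- tibble::as_tibble(rows)
  if (!"label" %in% names(rows) && "symbol" %in% names(rows)) {
    rows$label <- rows$symbol
  }
  if (all(c("mean_cca", "sd_cca", "mean_bbtd", "sd_bbtd") %in% names(rows)) &&
    !all(c("mean_a", "sd_a") %in% names(rows))) {
    rows$mean_a <- rows$mean_cca
    rows$sd_a <- rows$sd_cca
    rows$mean_b <- rows$mean_bbtd
    rows$sd_b <- rows$sd_bbtd
  }
  need <- c("mean_a", "sd_a", "mean_b", "sd_b")
  if (!all(need %in% names(rows))) {
    abort(paste0(
      "Summary table needs columns: ", paste(need, collapse = ", "), "."
    ), class = "serodiff_format_error")
  }
  out <- rows
  out$p_recomputed <- NA_real_
  out$flag_recomputed_p <- NA
  out$flag_printed_p <- NA
  out$flag_direction <- NA
  out$note <- NA_character_
  for (i in seq_len(nrow(out))) {
    ok <- tryCatch(
      {
        r <- welch_from_summary(
          out$mean_a[i], out$sd_a[i], n_a,
          out$mean_b[i], out$sd_b[i], n_b
        )
        out$p_recomputed[i] <- r$p
        TRUE
      },
      error = function(e) {
        out$note[i] <<- conditionMessage(e)
        FALSE
      }
    )
    if (!ok) next
    out$flag_recomputed_p[i] <- !(out$p_recomputed[i] < alpha)
    if ("printed_p" %in% names(out)) {
      pp <- parse_printed_p(out$printed_p[i])
      out$flag_printed_p[i] <- if (is.na(pp$value)) {
        NA
      } else if (pp$censored) {
        !(pp$value <= alpha) # "<bound" passes any cutoff at or above the bound
      } else {
        !(pp$value < alpha)
      }
    }
    if ("direction" %in% names(out) && !is.na(out$direction[i])) {
      diff <- out$mean_a[i] - out$mean_b[i]
      out$flag_direction[i] <- (out$direction[i] == "up") != (diff > 0)
    }
  }
  out
}

# Parse a printed p entry: numeric, or a censored bound like "<0.001".
parse_printed_p <- function(p) {
  if (is.numeric(p)) {
    return(list(value = as.numeric(p), censored = FALSE))
  }
  s <- trimws(as.character(p))
  if (grepl("^<", s)) {
    list(value = suppressWarnings(as.numeric(sub("^<\\s*", "", s))), censored = TRUE)
  } else {
    list(value = suppressWarnings(as.numeric(s)), censored = FALSE)
  }
}

#' Published DE protein summary table
#'
#' The transcribed summary statistics (per-protein group means ± SD on the
#' normalized log2 scale, printed p-values, direction of change) for the 93
#' serum proteins reported as differentially abundant between CCA (n = 19)
#' and BBTD (n = 17) in the reference cohort. Shipped as a plain-text fixture
#' for use with [audit_summary_table()] and as a source of realistic effect
#' sizes.
#'
#' @return A tibble with columns `symbol`, `description`, `accession`,
#'   `mean_cca`, `sd_cca`, `mean_bbtd`, `sd_bbtd`, `printed_p` (character;
#'   may be censored, e.g. `"<0.001"`), `direction` (`"up"` = CCA > BBTD).
#' @export
de_summary_reference <- function() {
  path <- system.file("extdata", "cca_bbtd_de_summary.tsv",
    package = "serodiff", mustWork = TRUE
  )
  readr::read_tsv(path,
    col_types = readr::cols(
      symbol = readr::col_character(),
      description = readr::col_character(),
      accession = readr::col_character(),
      printed_p = readr::col_character(),
      direction = readr::col_character(),
      .default = readr::col_double()
    ), progress = FALSE
  )
}
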