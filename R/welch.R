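#' Two-sample Welch t-test
#'
#' The core statistic of the pipeline: a two-sample t-test with unpooled
#' variances and Welch-Satterthwaite degrees of freedom,
#' \deqn{t = (\bar x_a - \bar x_b) / \sqrt{s_a^2/n_a + s_b^2/n_b},}
#' \deqn{\nu = (s_a^2/n_a + s_b^2/n_b)^2 /
#'   \left[\frac{(s_a^2/n_a)^2}{n_a - 1} + \frac{(s_b^2/n_b)^2}{n_b - 1}\right],}
#' with the two-sided p-value from the t distribution at \eqn{\nu}.
#' Degenerate inputs follow the limiting conventions: when both group
#' variances are zero, equal means give p = 1 and unequal means give p = 0
#' (complete separation); a group with fewer than two observed values makes
#' the comparison unquantifiable (`quantifiable = FALSE`, statistics `NA`)
#' rather than an error.
#'
#' `welch_from_summary()` evaluates the same formulas from summary statistics
#' (group mean, SD, n), so published mean ± SD tables can be audited; fed a
#' sample's own summaries it reproduces `welch_test()` exactly.
#'
#' @param a,b Numeric vectors of log2-scale values for the two groups;
#'   missing values are dropped.
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b Group summary statistics
#'   (vectorized; SDs must be positive, ns at least 2).
#' @return A tibble with one row per comparison: `estimate`
#'   (`mean_a - mean_b`), `t`, `df`, `p`, the group means, SDs and ns, and
#'   `quantifiable`.
#' @examples
#' welch_test(c(1.1, 1.4, 0.9), c(0.2, 0.5, 0.1))
#' welch_from_summary(1.20, 0.4, 19, 0.82, 0.3, 17)
#' @export
welch_test <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    return(tibble::tibble(
      estimate = NA_real_, t = NA_real_, df = NA_real_, p = NA_real_,
      mean_a = if (length(a)) mean(a) else NA_real_,
      mean_b = if (length(b)) mean(b) else NA_real_,
      sd_a = NA_real_, sd_b = NA_real_,
      n_a = length(a), n_b = length(b), quantifiable = FALSE
    ))
  }
  st <- welch_stats(mean(a), var(a), length(a), mean(b), var(b), length(b))
  tibble::tibble(
    estimate = st$estimate, t = st$t, df = st$df, p = st$p,
    mean_a = mean(a), mean_b = mean(b), sd_a = sd(a), sd_b = sd(b),
    n_a = length(a), n_b = length(b), quantifiable = TRUE
  )
}

#' @rdname welch_test
#' @export
welch_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (any(sd_a <= 0, na.rm = TRUE) || any(sd_b <= 0, na.rm = TRUE)) {
    abort("Group SDs must be positive.", class = "serodiff_config_error")
  }
  if (any(n_a < 2, na.rm = TRUE) || any(n_b < 2, na.rm = TRUE)) {
    abort("Group sizes must be at least 2.", class = "serodiff_config_error")
  }
  st <- welch_stats(mean_a, sd_a^2, n_a, mean_b, sd_b^2, n_b)
  tibble::tibble(
    estimate = st$estimate, t = st$t, df = st$df, p = st$p,
    mean_a = mean_a, mean_b = mean_b, sd_a = sd_a, sd_b = sd_b,
    n_a = n_a, n_b = n_b, quantifiable = TRUE
  )
}

# Vectorized Welch formulas shared by the scalar wrappers and the per-fold
# matrix path in select_de(). Inputs are group means, variances and counts.
welch_stats <- function(m_a, v_a, n_a, m_b, v_b, n_b) {
  se2 <- v_a / n_a + v_b / n_b
  estimate <- m_a - m_b
  t <- ifelse(se2 > 0, estimate / sqrt(se2),
    ifelse(estimate == 0, 0, sign(estimate) * Inf)
  )
  df <- ifelse(
    se2 > 0,
    se2^2 / ((v_a / n_a)^2 / (n_a - 1) + (v_b / n_b)^2 / (n_b - 1)),
    NA_real_
  )
  p <- ifelse(
    se2 > 0,
    2 * pt(-abs(t), df),
    ifelse(estimate == 0, 1, 0)
  )
  list(estimate = estimate, t = t, df = df, p = p)
}
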