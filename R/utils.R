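# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random-number stream. `seed = NULL` leaves the stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed != trunc(seed)) {
    abort("`seed` must be a single integer.", class = "serodiff_config_error")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a per-stage seed from the pipeline seed, kept inside 32-bit range.
stage_seed <- function(seed, offset) {
  if (is.null(seed)) {
    return(NULL)
  }
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != trunc(x) || x < min) {
    abort(
      sprintf("`%s` must be a single integer >= %d.", name, min),
      class = "serodiff_config_error"
    )
  }
  invisible(as.integer(x))
}

stopifnot_fraction <- function(x, name, closed_upper = TRUE) {
  hi_ok <- if (closed_upper) x <= 1 else x < 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || !hi_ok) {
    abort(
      sprintf(
        "`%s` must be a single number in [0, 1%s.",
        name, if (closed_upper) "]" else ")"
      ),
      class = "serodiff_config_error"
    )
  }
  invisible(as.numeric(x))
}

# Row-wise mean / variance / count over a numeric matrix with missing values,
# computed in one pass (no per-row apply); variance uses the n-1 denominator.
row_group_stats <- function(mat) {
  obs <- !is.na(mat)
  n <- rowSums(obs)
  s <- rowSums(mat, na.rm = TRUE)
  m <- ifelse(n > 0, s / n, NA_real_)
  ss <- rowSums(mat^2, na.rm = TRUE)
  v <- ifelse(n > 1, (ss - n * m^2) / (n - 1), NA_real_)
  v <- pmax(v, 0) # guard tiny negative values from cancellation
  list(n = n, mean = m, var = v)
}
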