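# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package functions do not
#' disturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Draw `n` sub-seeds from a base seed, all < 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Sample variance with the 0-for-degenerate convention used by the feature
# bank (n < 2 or non-finite -> 0).
safe_var <- function(x) {
  if (length(x) < 2L) return(0)
  v <- stats::var(x)
  if (!is.finite(v)) 0 else v
}

safe_sd <- function(x) sqrt(safe_var(x))

# Moment skewness m3 / sd^3 with degenerate inputs mapped to 0.
safe_skewness <- function(x) {
  n <- length(x)
  if (n < 3L) return(0)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(0)
  m3 <- mean((x - mean(x))^3)
  v <- m3 / s^3
  if (is.finite(v)) v else 0
}

# Pearson correlation with zero-variance inputs mapped to 0.
safe_cor <- function(x, y) {
  if (length(x) < 2L || stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  v <- stats::cor(x, y)
  if (is.finite(v)) v else 0
}

`%||%` <- function(a, b) if (is.null(a)) b else a
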