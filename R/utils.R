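# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Truncate a number at a fixed count of decimal places
#'
#' Truncation (toward zero), not rounding: `trunc_dec(58.4355, 2)` is
#' `58.43`. Used when formatting percentage and micrometre summaries so
#' printed values match the truncation convention of tabulated QWA reports.
#'
#' @param x numeric vector.
#' @param digits number of decimal places kept.
#' @return numeric vector truncated at `digits` decimals.
#' @export
#' @examples
#' trunc_dec(91.7983, 2)
trunc_dec <- function(x, digits = 2) {
  f <- 10^digits
  trunc(x * f) / f
}

stop_if_not <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

is_count <- function(x, positive = TRUE) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x == round(x) &&
    (if (positive) x >= 1 else x >= 0)
}

is_scalar <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

# Clamp a numeric vector into [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
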