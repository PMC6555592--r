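#' Internal input validators
#'
#' Small assertion helpers shared across stages.  All raise classed errors
#' via [rlang::abort()] so callers and tests can match on `class`.
#'
#' @name vaxsig-validators
#' @keywords internal
NULL

stop_config <- function(msg, field = NULL) {
  abort(msg, class = "vaxsig_config_error", field = field)
}

stop_input <- function(msg, ...) {
  abort(msg, class = "vaxsig_input_error", ...)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_config(sprintf("`%s` must be a single finite number", name), name)
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop_config(sprintf(
      "`%s` = %g is outside the allowed range %s%g, %g%s", name, x,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]"
    ), name)
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  check_number(x, name, lower = min)
  if (x != as.integer(x)) {
    stop_config(sprintf("`%s` must be an integer count", name), name)
  }
  invisible(as.integer(x))
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so deterministic internals (e.g. the
#' randomized lattice rule inside [mvtnorm::pmvt()]) do not perturb the
#' caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# deterministic sub-seed derivation, kept < 2^31
derive_seed <- function(seed, offset) {
  (abs(as.integer(seed)) + 10007L * as.integer(offset)) %% 2147483647L
}

#' Benjamini-Hochberg adjustment with validation
#'
#' Step-up false-discovery-rate adjustment of raw p-values.  A thin,
#' validating wrapper around [stats::p.adjust()] (`method = "BH"`): results
#' are clipped to `[0, 1]` and are monotone non-decreasing in `p`.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`; `NaN` is rejected.
#' @return numeric vector of adjusted q-values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (!is.numeric(p) || anyNA(p)) {
    stop_input("`p` must be numeric with no NA/NaN values")
  }
  if (any(p < 0 | p > 1)) stop_input("p-values must lie in [0, 1]")
  pmin(1, pmax(0, p.adjust(p, method = "BH")))
}
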