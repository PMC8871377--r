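#' @importFrom rlang abort warn .data %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map_int map2 imap list_rbind
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All package randomness funnels
# through this so that library users' RNG streams are never disturbed.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Counter-based seed splitting: derive an independent per-item seed from a
# top-level seed and one or two integer counters, so that (e.g.) changing the
# number of images in one class never perturbs the pixels of another class.
# Constants are the classic Lehmer multiplier and a large prime modulus that
# keeps results inside the 32-bit signed range R requires of set.seed().
derive_seed <- function(seed, stream, counter = 0L) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m)
  s <- (s * 48271 + as.numeric(stream) * 7919 + as.numeric(counter) * 104729) %% m
  as.integer(s)
}

#' Round half away from zero
#'
#' Reporting-layer rounding used for printed percentages (2 decimals) and AUC
#' (4 decimals). Unlike [base::round()], which rounds half to even, ties are
#' rounded up, matching how clinical tables are conventionally printed.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
#' @examples
#' round_half_up(99.865, 2) # 99.87, not 99.86
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

assert_positive_int <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0 || x != floor(x)) {
    abort(sprintf("`%s` must be a positive integer, got %s", name, deparse(x)))
  }
  invisible(as.integer(x))
}
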