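#' Derive a per-operation RNG seed
#'
#' Each generator draws from its own stream, obtained by mixing the user seed
#' with an operation tag. Adding a new generator therefore never perturbs the
#' draws of an existing one at the same seed.
#'
#' @param seed Integer base seed.
#' @param tag Character operation tag (e.g. `"cohort"`).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @keywords internal
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  # linear-congruential mix kept in double precision (< 2^53, so exact)
  as.integer((abs(as.numeric(seed)) %% 2147483647 * 69069 +
                h * 2654435 + 1) %% 2147483647)
}

#' Evaluate an expression under a derived, restored RNG state
#' @keywords internal
#' @noRd
with_op_seed <- function(seed, tag, code) {
  withr::with_seed(derive_seed(seed, tag), code)
}
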