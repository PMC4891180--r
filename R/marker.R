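#' Marker labeling index
#'
#' Percent of cells whose normalized staining intensity lies strictly above
#' the threshold (cells at exactly the threshold are negative). The study's
#' scoring cutoff is 20--25% of maximal staining; the default is the
#' midpoint 0.225. The 95% CI is the Wilson score interval.
#'
#' @param intensities Per-cell intensities as fractions of maximum, in
#'   `[0, 1]`.
#' @param threshold_frac Positivity cutoff (default 0.225).
#' @return A `labeling_counts`: list with `positive`, `total`, `percent`,
#'   `ci_lo`, `ci_hi`, `threshold_frac`.
#' @examples
#' labeling_index(c(0.1, 0.3, 0.9, 0.2))
#' @export
labeling_index <- function(intensities, threshold_frac = 0.225) {
  if (length(intensities) < 1L) stop("empty intensity vector")
  stopifnot(all(intensities >= 0 & intensities <= 1))
  pos <- sum(intensities > threshold_frac)
  n <- length(intensities)
  # Wilson score interval; the chi-square small-count warning does not
  # concern the interval itself
  ci <- suppressWarnings(stats::prop.test(pos, n, correct = FALSE))$conf.int
  structure(list(positive = pos, total = n,
                 percent = 100 * pos / n,
                 ci_lo = 100 * ci[1], ci_hi = 100 * ci[2],
                 threshold_frac = threshold_frac),
            class = "labeling_counts")
}

#' @export
print.labeling_counts <- function(x, ...) {
  cat(sprintf("<labeling_counts> %d/%d positive = %.1f%% (95%% CI %.1f-%.1f) at cutoff %.3g\n",
              x$positive, x$total, x$percent, x$ci_lo, x$ci_hi, x$threshold_frac))
  invisible(x)
}

#' Compare two labeling indices
#'
#' Default mode is a pooled two-proportion z-test (two-sided) on the counts.
#' `mode = "replicates"` instead treats the inputs as per-replicate percent
#' vectors and delegates to [welch_t()], matching studies that t-test
#' replicate-level labeling percentages.
#'
#' @param a,b `labeling_counts` objects (mode `"pooled"`) or numeric
#'   per-replicate percent vectors (mode `"replicates"`).
#' @param mode `"pooled"` or `"replicates"`.
#' @return List with `statistic`, `p_value`, `mode`.
#' @export
compare_proportions <- function(a, b, mode = c("pooled", "replicates")) {
  mode <- match.arg(mode)
  if (mode == "replicates") {
    res <- welch_t(a, mean_b = b)
    return(list(statistic = res$t, p_value = res$p_value, mode = mode))
  }
  stopifnot(inherits(a, "labeling_counts"), inherits(b, "labeling_counts"),
            a$total >= 1, b$total >= 1)
  p_pool <- (a$positive + b$positive) / (a$total + b$total)
  se <- sqrt(p_pool * (1 - p_pool) * (1 / a$total + 1 / b$total))
  if (se == 0) {
    # all-positive or all-negative in both groups: no evidence of difference
    return(list(statistic = 0, p_value = 1, mode = mode))
  }
  z <- (a$positive / a$total - b$positive / b$total) / se
  list(statistic = z, p_value = 2 * stats::pnorm(-abs(z)), mode = mode)
}
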