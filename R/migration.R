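#' Per-cell distance to the pial surface
#'
#' Euclidean minimum distance from each cell center to the surface polyline,
#' taken over every segment (true point-to-segment projection, not
#' vertex-only). Distances are unsigned: cells on either side of the
#' polyline get positive distances.
#'
#' @param cohort A `cell_cohort` (see [new_cell_cohort()]).
#' @return Numeric vector of distances (um), one per cell.
#' @examples
#' coh <- generate_cohort(cohort_preset("demo", 50, 10, 100), seed = 1)
#' summary(distance_to_surface(coh))
#' @export
distance_to_surface <- function(cohort) {
  stopifnot(inherits(cohort, "cell_cohort"))
  sx <- cohort$surface$x_um
  sy <- cohort$surface$y_um
  px <- cohort$cells$x_um
  py <- cohort$cells$y_um
  nseg <- length(sx) - 1L
  seg_len2 <- (sx[-1] - sx[-length(sx)])^2 + (sy[-1] - sy[-length(sy)])^2
  if (all(seg_len2 == 0)) stop("degenerate surface: all segments zero-length")
  d2 <- matrix(Inf, nrow = length(px), ncol = nseg)
  for (s in seq_len(nseg)) {
    ax <- sx[s]; ay <- sy[s]
    dx <- sx[s + 1L] - ax; dy <- sy[s + 1L] - ay
    if (seg_len2[s] == 0) {
      d2[, s] <- (px - ax)^2 + (py - ay)^2
    } else {
      t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / seg_len2[s]))
      d2[, s] <- (px - (ax + t * dx))^2 + (py - (ay + t * dy))^2
    }
  }
  sqrt(apply(d2, 1L, min))
}

#' Summarize a distance cohort into a migration profile
#'
#' Fixed histogram bins of width `bin_width_um` over `[0, domain_max_um]`,
#' sample mean and SD (n - 1 denominator), and the 99th-percentile migration
#' front by linear interpolation (type-7 quantile).
#'
#' @param distances Numeric vector of per-cell distances (um).
#' @param bin_width_um Histogram bin width, um (default 10).
#' @param domain_max_um Domain ceiling, um (default 450).
#' @param condition Optional condition label.
#' @return A `migration_profile`: list with `distances`, `breaks`, `counts`,
#'   `mean_um`, `sd_um`, `n`, `p99_um`, `condition`.
#' @export
summarize_cohort <- function(distances, bin_width_um = 10,
                             domain_max_um = 450, condition = NA_character_) {
  if (length(distances) < 1L) stop("empty distance vector")
  stopifnot(all(is.finite(distances)), all(distances >= 0))
  breaks <- seq(0, domain_max_um, by = bin_width_um)
  if (breaks[length(breaks)] < domain_max_um) breaks <- c(breaks, domain_max_um)
  # right = FALSE: bins are [lo, hi); include.lowest closes the final bin so
  # a cell at exactly domain_max is counted
  counts <- as.integer(table(cut(pmin(distances, domain_max_um), breaks,
                                 include.lowest = TRUE, right = FALSE)))
  structure(list(distances = distances, breaks = breaks, counts = counts,
                 mean_um = mean(distances),
                 sd_um = stats::sd(distances),
                 n = length(distances),
                 p99_um = unname(stats::quantile(distances, 0.99, type = 7)),
                 condition = condition),
            class = "migration_profile")
}

#' @export
print.migration_profile <- function(x, ...) {
  cat(sprintf(
    "<migration_profile> %s: n = %d, mean = %.1f um, sd = %.1f um, p99 = %.1f um\n",
    ifelse(is.na(x$condition), "(unnamed)", x$condition),
    x$n, x$mean_um, ifelse(is.na(x$sd_um), 0, x$sd_um), x$p99_um))
  invisible(x)
}

#' Chi-square comparison of two binned migration distributions
#'
#' Two-sample chi-square test on the 2 x bins contingency table of histogram
#' counts. Bins whose expected count (under independence) falls below
#' `min_expected` in either condition are merged rightward (into the next
#' bin) before testing; a trailing under-filled group is merged into the last
#' kept group. The p-value uses (merged bins - 1) degrees of freedom.
#'
#' @param profile_a,profile_b `migration_profile`s sharing bin edges.
#' @param min_expected Minimum expected count per cell (default 5).
#' @return List with `statistic`, `p_value`, `df`, `n_bins_used`.
#' @export
compare_distributions <- function(profile_a, profile_b, min_expected = 5) {
  stopifnot(inherits(profile_a, "migration_profile"),
            inherits(profile_b, "migration_profile"))
  if (!isTRUE(all.equal(profile_a$breaks, profile_b$breaks))) {
    stop("profiles do not share bin edges")
  }
  merged <- merge_low_expected(rbind(profile_a$counts, profile_b$counts),
                               min_expected)
  if (ncol(merged) < 2L) stop("fewer than 2 usable bins after merging")
  if (identical(merged[1, ], merged[2, ])) {
    # identical histograms: statistic exactly 0, p exactly 1
    return(list(statistic = 0, p_value = 1, df = ncol(merged) - 1L,
                n_bins_used = ncol(merged)))
  }
  ct <- suppressWarnings(stats::chisq.test(merged, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value),
       df = unname(ct$parameter), n_bins_used = ncol(merged))
}

#' Merge adjacent histogram bins rightward until expected counts pass
#' @param counts 2 x k matrix of bin counts.
#' @keywords internal
merge_low_expected <- function(counts, min_expected = 5) {
  groups <- list()
  acc <- c(0, 0)
  row_tot <- rowSums(counts)
  grand <- sum(counts)
  for (j in seq_len(ncol(counts))) {
    acc <- acc + counts[, j]
    expected <- row_tot * sum(acc) / grand
    if (all(expected >= min_expected)) {
      groups[[length(groups) + 1L]] <- acc
      acc <- c(0, 0)
    }
  }
  if (sum(acc) > 0) {
    if (length(groups) == 0L) {
      groups[[1L]] <- acc
    } else {
      groups[[length(groups)]] <- groups[[length(groups)]] + acc
    }
  }
  do.call(cbind, groups)
}

#' Welch two-sample t-test from summary statistics or raw samples
#'
#' Accepts either two raw sample vectors or the summary triplets (mean, SD,
#' n) printed in figure legends, so published summaries are directly
#' testable. Uses the unequal-variance Welch statistic with
#' Welch--Satterthwaite degrees of freedom.
#'
#' @param mean_a,mean_b Group means, or raw numeric vectors (then the
#'   remaining arguments are ignored for that group).
#' @param sd_a,sd_b Group SDs.
#' @param n_a,n_b Group sizes.
#' @return List with `t`, `df`, `p_value` (two-sided).
#' @examples
#' welch_t(34.2, 10.1, 7358, 67.5, 18.1, 4693)$p_value
#' @export
welch_t <- function(mean_a, sd_a = NULL, n_a = NULL,
                    mean_b, sd_b = NULL, n_b = NULL) {
  if (length(mean_a) > 1L) {
    x <- mean_a; n_a <- length(x); sd_a <- stats::sd(x); mean_a <- mean(x)
  }
  if (length(mean_b) > 1L) {
    x <- mean_b; n_b <- length(x); sd_b <- stats::sd(x); mean_b <- mean(x)
  }
  stopifnot(n_a >= 2, n_b >= 2, sd_a >= 0, sd_b >= 0)
  if (sd_a == 0 && sd_b == 0) {
    if (mean_a == mean_b) {
      message("both SDs zero with equal means; returning p = 1 by convention")
      return(list(t = 0, df = NA_real_, p_value = 1))
    }
    stop("both SDs zero with unequal means: t undefined")
  }
  se2 <- sd_a^2 / n_a + sd_b^2 / n_b
  t <- (mean_a - mean_b) / sqrt(se2)
  df <- se2^2 / (sd_a^4 / (n_a^2 * (n_a - 1)) + sd_b^4 / (n_b^2 * (n_b - 1)))
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Classify a rescue condition
#'
#' A test condition is called rescued when its binned migration distribution
#' is statistically indistinguishable from the control (chi-square p > 0.8)
#' while its mean migration distance differs from the phenotype condition
#' (Welch t-test p < 0.01). Both sub-results are reported.
#'
#' @param control,phenotype,test `migration_profile`s on shared bins.
#' @param chi2_threshold Chi-square p-value floor for similarity to control.
#' @param t_threshold t-test p-value ceiling for difference from phenotype.
#' @return A `rescue_verdict`: list with `chi2_p_vs_control`,
#'   `t_p_vs_phenotype`, `rescued`, and the thresholds used.
#' @export
classify_rescue <- function(control, phenotype, test,
                            chi2_threshold = 0.8, t_threshold = 0.01) {
  chi2 <- compare_distributions(test, control)
  tt <- welch_t(test$mean_um, test$sd_um, test$n,
                phenotype$mean_um, phenotype$sd_um, phenotype$n)
  structure(list(
    chi2_p_vs_control = chi2$p_value,
    t_p_vs_phenotype = tt$p_value,
    rescued = chi2$p_value > chi2_threshold && tt$p_value < t_threshold,
    chi2_threshold = chi2_threshold,
    t_threshold = t_threshold), class = "rescue_verdict")
}

#' @export
print.rescue_verdict <- function(x, ...) {
  cat(sprintf(
    "<rescue_verdict> rescued = %s (chi2 p vs control = %.3g [> %g], t p vs phenotype = %.3g [< %g])\n",
    x$rescued, x$chi2_p_vs_control, x$chi2_threshold,
    x$t_p_vs_phenotype, x$t_threshold))
  invisible(x)
}
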