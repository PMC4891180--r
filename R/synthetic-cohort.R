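#' Simulate a slice-migration cohort from a printed preset
#'
#' Draws `n_cells` surface distances from a normal distribution with the
#' preset's printed mean and SD, truncated by rejection to
#' `[0, domain_max_um]` (the slice scoring domain). Cells are laid out in the
#' plane against a straight vertical surface at x = 0, so that
#' [distance_to_surface()] recovers exactly the drawn distances. For every
#' printed preset the nearest truncation boundary is more than 3 SD from the
#' mean, so the truncation bias is negligible (see the methods vignette).
#'
#' @param preset A [cohort_preset()].
#' @param seed Integer seed; the draw is deterministic given `seed`.
#' @param max_retries Rejection retry cap per cell before the preset is
#'   declared infeasible.
#' @return A `cell_cohort`: list with `cells` (data.frame `cell_id`, `x_um`,
#'   `y_um`), `condition`, and `surface` (data.frame of ordered polyline
#'   vertices `x_um`, `y_um`).
#' @examples
#' coh <- generate_cohort(get_preset("fig2s1:control-24h"), seed = 1)
#' mean(distance_to_surface(coh))
#' @export
generate_cohort <- function(preset, seed, max_retries = 1000L) {
  stopifnot(inherits(preset, "cohort_preset"))
  n <- preset$n_cells
  with_op_seed(seed, "cohort", {
    if (preset$sd_um == 0) {
      d <- rep(preset$mean_um, n)
    } else {
      d <- rep(NA_real_, n)
      todo <- seq_len(n)
      tries <- 0L
      while (length(todo) > 0L) {
        tries <- tries + 1L
        if (tries > max_retries) {
          stop(sprintf(
            "rejection sampling failed to place %d cells after %d retries: infeasible preset '%s'",
            length(todo), max_retries, preset$name))
        }
        draw <- stats::rnorm(length(todo), preset$mean_um, preset$sd_um)
        ok <- draw >= 0 & draw <= preset$domain_max_um
        d[todo[ok]] <- draw[ok]
        todo <- todo[!ok]
      }
    }
    cells <- data.frame(
      cell_id = sprintf("cell%06d", seq_len(n)),
      x_um = d,
      y_um = stats::runif(n, 0, 100),
      stringsAsFactors = FALSE
    )
    new_cell_cohort(cells, preset$name,
                    surface = data.frame(x_um = c(0, 0), y_um = c(-10, 110)))
  })
}

#' Construct a cell cohort
#'
#' @param cells data.frame with `cell_id`, `x_um`, `y_um`.
#' @param condition Condition label.
#' @param surface data.frame of ordered polyline vertices (`x_um`, `y_um`)
#'   tracing the pial surface.
#' @return A `cell_cohort` object.
#' @export
new_cell_cohort <- function(cells, condition, surface) {
  stopifnot(is.data.frame(cells), nrow(cells) >= 1L,
            all(c("x_um", "y_um") %in% names(cells)),
            is.data.frame(surface), nrow(surface) >= 2L,
            all(is.finite(cells$x_um)), all(is.finite(cells$y_um)),
            all(is.finite(surface$x_um)), all(is.finite(surface$y_um)))
  structure(list(cells = cells, condition = condition, surface = surface),
            class = "cell_cohort")
}

#' @export
print.cell_cohort <- function(x, ...) {
  cat(sprintf("<cell_cohort> '%s': %d cells, surface polyline with %d vertices\n",
              x$condition, nrow(x$cells), nrow(x$surface)))
  invisible(x)
}

#' Simulate a per-cell marker-intensity table
#'
#' Each cell is positive with probability `p_positive`; positive cells draw a
#' normalized staining intensity strictly above `threshold`, negative cells at
#' or below it, so that [labeling_index()] at the same threshold recovers the
#' binomial positive count exactly.
#'
#' @param n_cells Number of cells.
#' @param p_positive Probability a cell is marker-positive.
#' @param threshold Intensity cutoff as a fraction of maximal staining.
#' @param seed Integer seed.
#' @param condition Condition label attached to the table.
#' @return data.frame with `cell_id`, `condition`, `intensity_frac`.
#' @examples
#' tab <- generate_labeling(2000, p_positive = 0.226, seed = 1)
#' labeling_index(tab$intensity_frac)
#' @export
generate_labeling <- function(n_cells, p_positive, threshold = 0.225,
                              seed = 1L, condition = "cond") {
  stopifnot(p_positive >= 0, p_positive <= 1, n_cells >= 1)
  with_op_seed(seed, "labeling", {
    pos <- stats::runif(n_cells) < p_positive
    intensity <- ifelse(pos,
                        stats::runif(n_cells, threshold, 1),
                        stats::runif(n_cells, 0, threshold))
    # runif on (threshold, 1) is open at the boundary so positives are
    # strictly above threshold; negatives land in [0, threshold]
    data.frame(cell_id = sprintf("cell%06d", seq_len(n_cells)),
               condition = condition,
               intensity_frac = intensity,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a qPCR Ct table realizing known fold changes
#'
#' Builds a two-condition Ct table (reference condition and "treated")
#' whose delta-delta-Ct analysis against the reference gene recovers
#' `true_folds` exactly in the noise-free case. Each sample carries a random
#' global Ct offset (pipetting/loading surrogate) that normalization against
#' the reference gene must remove.
#'
#' @param true_folds Named numeric vector: target-gene fold change of the
#'   treated condition relative to the reference condition. All folds > 0.
#' @param reference_ct Ct of the reference gene before per-sample offsets.
#' @param seed Integer seed.
#' @param replicates Replicates per condition.
#' @param noise_sd SD of optional Gaussian Ct noise (0 = noise-free).
#' @param reference_gene Reference gene label.
#' @param conditions Length-2 character vector: reference condition first.
#' @return data.frame with `gene`, `condition`, `replicate`, `ct`.
#' @examples
#' ct <- generate_ct_table(c(Pard6a = 2, Chl1 = 0.5), seed = 1)
#' ddct_relative_expression(ct, reference_condition = "control")
#' @export
generate_ct_table <- function(true_folds, reference_ct = 12, seed = 1L,
                              replicates = 3L, noise_sd = 0,
                              reference_gene = "18S",
                              conditions = c("control", "treated")) {
  if (any(true_folds <= 0)) stop("all folds must be > 0")
  if (is.null(names(true_folds))) stop("true_folds must be named by gene")
  stopifnot(length(conditions) == 2L, replicates >= 1L)
  base_ct <- 25  # arbitrary target-gene baseline in the reference condition
  with_op_seed(seed, "ct", {
    rows <- list()
    for (ci in seq_along(conditions)) {
      cond <- conditions[ci]
      for (r in seq_len(replicates)) {
        offset <- stats::runif(1, -2, 2)  # per-sample global shift
        ct_ref <- reference_ct + offset
        ct_tgt <- base_ct + offset -
          if (ci == 2L) log2(true_folds) else rep(0, length(true_folds))
        if (noise_sd > 0) {
          ct_ref <- ct_ref + stats::rnorm(1, 0, noise_sd)
          ct_tgt <- ct_tgt + stats::rnorm(length(ct_tgt), 0, noise_sd)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          gene = c(reference_gene, names(true_folds)),
          condition = cond,
          replicate = r,
          ct = c(ct_ref, ct_tgt),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}
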