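#' Construct a cohort preset
#'
#' A preset holds the printed per-condition summary (mean, SD, number of
#' cells) of a migration-distance or neurite-length cohort, plus the domain
#' ceiling of the measurement (slices are scored on a 0--450 um scale).
#'
#' @param name Condition label.
#' @param mean_um Printed mean, um.
#' @param sd_um Printed sample SD, um.
#' @param n_cells Printed number of cells.
#' @param domain_max_um Upper bound of the measurement domain, um.
#' @return An object of class `cohort_preset`.
#' @examples
#' cohort_preset("control", mean_um = 34.2, sd_um = 10.1, n_cells = 7358)
#' @export
cohort_preset <- function(name, mean_um, sd_um, n_cells, domain_max_um = 450) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!(sd_um >= 0)) stop("sd_um must be >= 0")
  if (!(n_cells >= 1)) stop("n_cells must be >= 1")
  if (!(mean_um > 0 && mean_um < domain_max_um)) {
    stop("mean_um must lie strictly inside (0, domain_max_um)")
  }
  structure(
    list(name = name, mean_um = mean_um, sd_um = sd_um,
         n_cells = as.integer(n_cells), domain_max_um = domain_max_um),
    class = "cohort_preset"
  )
}

#' @export
print.cohort_preset <- function(x, ...) {
  cat(sprintf("<cohort_preset> %s: %.1f +/- %.1f um, n = %d (domain 0-%g um)\n",
              x$name, x$mean_um, x$sd_um, x$n_cells, x$domain_max_um))
  invisible(x)
}

#' Registry of printed cohort presets
#'
#' Named registry of the per-condition mean/SD/n summaries printed in the
#' study's slice-migration figure supplements and neurite-length legends.
#' Keys are `figure:condition`. `fig2s1:*` are the 24 h / 48 h ex vivo
#' electroporation cohorts, `fig6s1:*` the 48 h rescue screen cohorts,
#' `fig8:*` the Ptch1-conditional cohorts, and `fig2a:*` the in vitro
#' neurite-length cohorts.
#'
#' @return A named list of [cohort_preset()] objects.
#' @examples
#' cohort_presets()[["fig2s1:control-24h"]]
#' @export
cohort_presets <- function() {
  list(
    # 24 h / 48 h slice migration, Zeb1 silencing and over-expression
    `fig2s1:control-24h`  = cohort_preset("control-24h",  34.2, 10.1, 7358),
    `fig2s1:shZeb1-24h`   = cohort_preset("shZeb1-24h",   67.5, 18.1, 4693),
    `fig2s1:control-48h`  = cohort_preset("control-48h",  75.2,  3.5, 9744),
    `fig2s1:Zeb1-OE-48h`  = cohort_preset("Zeb1-OE-48h",  40.2,  6.0, 5359),
    # 48 h rescue screen
    `fig6s1:control-48h`  = cohort_preset("control-48h",  74.0,  8.3, 13064),
    `fig6s1:Zeb1`         = cohort_preset("Zeb1",         42.4,  7.6, 13424),
    `fig6s1:Pard6a`       = cohort_preset("Pard6a",       79.8,  5.2, 3886),
    `fig6s1:Pard3a`       = cohort_preset("Pard3a",       73.9,  4.5, 8622),
    `fig6s1:Jam-Nec`      = cohort_preset("Jam-Nec",      71.7,  5.5, 11333),
    `fig6s1:Chl1`         = cohort_preset("Chl1",         79.4,  6.9, 3006),
    # Ptch1 conditional deletion (Cre wild-type) vs catalytically dead Cre
    `fig8:CreMut`         = cohort_preset("CreMut",       71.2,  7.8, 9471),
    `fig8:CreWT`          = cohort_preset("CreWT",        41.4,  5.8, 9872),
    # in vitro neurite lengths, 24 h
    `fig2a:control`       = cohort_preset("control",     139.8, 13.3, 1045),
    `fig2a:Zeb1`          = cohort_preset("Zeb1",         59.6,  3.0, 1164)
  )
}

#' Fetch one preset by registry key
#' @param key Registry key, e.g. `"fig2s1:control-24h"`.
#' @return A [cohort_preset()].
#' @export
get_preset <- function(key) {
  reg <- cohort_presets()
  if (!key %in% names(reg)) {
    stop(sprintf("unknown preset '%s'; see names(cohort_presets())", key))
  }
  reg[[key]]
}

#' Binomial labeling presets
#'
#' EdU labeling-index probabilities printed in the results text:
#' 24 h control vs Zeb1-silenced, and 48 h control vs Zeb1-over-expressing.
#'
#' @return Named numeric vector of positive-cell probabilities.
#' @export
labeling_presets <- function() {
  c(`edu:control-24h` = 0.226,
    `edu:shZeb1-24h`  = 0.076,
    `edu:control-48h` = 0.033,
    `edu:Zeb1-48h`    = 0.109)
}
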