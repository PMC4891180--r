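#' Run an end-to-end synthetic workflow
#'
#' Drives simulate -> quantify -> test for one of the two study workflows
#' and returns (optionally writes) a JSON-serializable report carrying every
#' statistic together with the seed, thresholds and a config hash.
#'
#' Workflows:
#' \describe{
#'   \item{`migration`}{Generates cohorts from preset registry keys
#'     (`control`, `phenotype`, plus any `tests`), measures distances,
#'     summarizes, and classifies each test condition for rescue.}
#'   \item{`association`}{Generates a planted genome/peak set and expression
#'     matrix, selects deregulated genes, assigns peaks to nearest TSSs and
#'     tests binding association for the down- and up-regulated sets.}
#' }
#'
#' @param config List. Common: `workflow`, `seed`. Migration:
#'   `control`, `phenotype`, `tests` (preset keys), optional `bin_width_um`,
#'   `chi2_threshold`, `t_threshold`. Association: `n_genes`,
#'   `n_target_genes`, `p_bind_target`, `p_bind_background`, optional
#'   `log2_effect`, `noise_sd`, `replicates`, `n_resample`.
#' @param out_dir Optional directory; when given, `report.json` (and the
#'   simulated inputs) are written there.
#' @return The report, invisibly a list.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(is.list(config), !is.null(config$workflow), !is.null(config$seed))
  report <- switch(
    config$workflow,
    migration = run_migration_workflow(config, out_dir),
    association = run_association_workflow(config, out_dir),
    stop("unknown workflow: ", config$workflow))
  report$seed <- config$seed
  report$config_hash <- config_hash(config)
  report$package_version <- as.character(utils::packageVersion("gzexit"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}

run_migration_workflow <- function(config, out_dir = NULL) {
  bw <- config$bin_width_um %||% 10
  profile_of <- function(key) {
    coh <- generate_cohort(get_preset(key), seed = config$seed)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      safe <- gsub("[^A-Za-z0-9._-]", "_", key)
      write_cells(coh, file.path(out_dir, paste0(safe, "_cells.csv")),
                  file.path(out_dir, paste0(safe, "_surface.csv")))
    }
    summarize_cohort(distance_to_surface(coh), bin_width_um = bw,
                     condition = key)
  }
  ctrl <- profile_of(config$control)
  phen <- profile_of(config$phenotype)
  verdicts <- lapply(config$tests %||% character(0), function(key) {
    v <- classify_rescue(ctrl, phen, profile_of(key),
                         chi2_threshold = config$chi2_threshold %||% 0.8,
                         t_threshold = config$t_threshold %||% 0.01)
    c(list(condition = key), unclass(v))
  })
  strip <- function(p) p[c("mean_um", "sd_um", "n", "p99_um", "condition")]
  list(workflow = "migration", bin_width_um = bw,
       control = strip(ctrl), phenotype = strip(phen),
       phenotype_vs_control = list(
         chi2 = compare_distributions(phen, ctrl),
         t = welch_t(phen$mean_um, phen$sd_um, phen$n,
                     ctrl$mean_um, ctrl$sd_um, ctrl$n)),
       verdicts = verdicts)
}

run_association_workflow <- function(config, out_dir = NULL) {
  cfg <- planted_association_config(
    n_genes = config$n_genes, n_target_genes = config$n_target_genes,
    p_bind_target = config$p_bind_target,
    p_bind_background = config$p_bind_background,
    seed = config$seed)
  gp <- generate_genome_and_peaks(cfg)
  expr <- generate_expression(expression_sim_config(
    n_genes = config$n_genes,
    repressed_block_size = config$n_target_genes,
    log2_effect = config$log2_effect %||% 2,
    noise_sd = config$noise_sd %||% 0.25,
    replicates = config$replicates %||% 4L,
    seed = config$seed))
  de <- select_deregulated(expr, "control", "Zeb1")
  assignments <- assign_peaks_to_genes(gp$peaks, gp$genes)
  assoc_of <- function(set) {
    if (length(set) < 1L) return(NULL)
    unclass(resample_association(assignments, set,
                                 universe = gp$genes$gene_id,
                                 n_resample = config$n_resample %||% 1000L,
                                 seed = config$seed))
  }
  down <- de$gene_id[de$selected & de$direction == "down"]
  up <- de$gene_id[de$selected & de$direction == "up"]
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_bed(gp$peaks, file.path(out_dir, "peaks.bed"))
    write_gene_table(gp$genes, file.path(out_dir, "genes.tsv"))
    write_matrix(expr, file.path(out_dir, "expression.csv"))
    utils::write.csv(de, file.path(out_dir, "de_table.csv"), row.names = FALSE)
  }
  list(workflow = "association",
       n_selected_down = length(down), n_selected_up = length(up),
       n_peaks = nrow(gp$peaks),
       association_down = assoc_of(down),
       association_up = assoc_of(up))
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
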