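#' Configuration for the planted binding-association generator
#'
#' @param n_genes Number of genes on the synthetic chromosome.
#' @param n_target_genes Size of the planted target block.
#' @param p_bind_target Probability a target gene receives a promoter peak.
#' @param p_bind_background Same for background genes.
#' @param chrom_length_bp Chromosome length.
#' @param seed Integer seed.
#' @return A `planted_association_config` list.
#' @export
planted_association_config <- function(n_genes, n_target_genes,
                                       p_bind_target, p_bind_background,
                                       chrom_length_bp = 1e8, seed = 1L) {
  if (!(p_bind_background >= 0 && p_bind_background <= p_bind_target &&
        p_bind_target <= 1)) {
    stop("need 0 <= p_bind_background <= p_bind_target <= 1")
  }
  if (n_target_genes > n_genes) stop("n_target_genes must be <= n_genes")
  structure(list(n_genes = as.integer(n_genes),
                 n_target_genes = as.integer(n_target_genes),
                 p_bind_target = p_bind_target,
                 p_bind_background = p_bind_background,
                 chrom_length_bp = chrom_length_bp, seed = seed),
            class = "planted_association_config")
}

#' Simulate a gene model, a peak set, and a planted target gene set
#'
#' Places `n_genes` TSSs uniformly on one synthetic chromosome with a
#' minimum spacing of 2001 bp (so +/- 1 kb promoter windows never overlap)
#' and random strands. Target-block genes receive a 200 bp peak whose summit
#' lies within +/- 1 kb of their TSS with probability `p_bind_target`;
#' background genes with probability `p_bind_background`. Peaks carry a
#' pseudo p-value drawn log-uniformly from 1e-8 to 1e-2.
#'
#' Coordinates: gene TSS are 1-based; peaks are BED-style 0-based half-open
#' with a 0-based summit satisfying `start <= summit < end`.
#'
#' @param cfg A [planted_association_config()].
#' @return List with `genes` (data.frame `gene_id`, `chrom`, `tss`,
#'   `strand`), `peaks` (a `peak_set` data.frame), and `targets`
#'   (character vector of planted gene ids).
#' @export
generate_genome_and_peaks <- function(cfg) {
  stopifnot(inherits(cfg, "planted_association_config"))
  gap <- 2001
  slack <- cfg$chrom_length_bp - cfg$n_genes * gap
  if (slack <= cfg$n_genes) {
    stop("chromosome too short to place genes without promoter-window overlap")
  }
  with_op_seed(cfg$seed, "genome", {
    # min-separation uniform placement: uniform draws + deterministic spacing
    tss <- sort(sample.int(slack, cfg$n_genes)) +
      (seq_len(cfg$n_genes) - 1L) * gap + 1000L
    genes <- data.frame(
      gene_id = sprintf("g%04d", seq_len(cfg$n_genes)),
      chrom = "chrS",
      tss = tss,
      strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
      stringsAsFactors = FALSE)
    targets <- genes$gene_id[seq_len(cfg$n_target_genes)]
    p_bind <- ifelse(genes$gene_id %in% targets,
                     cfg$p_bind_target, cfg$p_bind_background)
    bound <- stats::runif(cfg$n_genes) < p_bind
    idx <- which(bound)
    summit1 <- genes$tss[idx] + round(stats::runif(length(idx), -1000, 1000))
    summit1 <- pmax(summit1, 101)
    peaks <- data.frame(
      chrom = "chrS",
      start = summit1 - 101L,          # 0-based: 100 bp flank left of summit
      end = summit1 + 100L,
      name = sprintf("peak%04d", seq_along(idx)),
      summit = summit1 - 1L,           # 0-based summit
      p_value = 10^(-stats::runif(length(idx), 2, 8)),
      stringsAsFactors = FALSE)
    list(genes = genes, peaks = as_peak_set(peaks), targets = targets)
  })
}

#' Validate and class a peak table
#'
#' @param df data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   optional `name`, `summit` (0-based), `p_value`.
#' @return The data.frame with class `peak_set` prepended.
#' @export
as_peak_set <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (is.null(df$summit)) df$summit <- floor((df$start + df$end) / 2)
  if (is.null(df$name)) df$name <- sprintf("peak%04d", seq_len(nrow(df)))
  if (is.null(df$p_value)) df$p_value <- 1
  if (any(df$start >= df$end)) stop("peak with start >= end")
  if (any(df$summit < df$start | df$summit >= df$end)) {
    stop("peak summit outside [start, end)")
  }
  if (any(df$p_value <= 0 | df$p_value > 1)) stop("peak p_value outside (0, 1]")
  class(df) <- unique(c("peak_set", class(df)))
  df
}

#' Configuration for the planted expression-block generator
#'
#' @param n_genes Number of genes.
#' @param conditions Condition labels; the last is the perturbed condition.
#' @param repressed_block_size Genes in the planted repressed block.
#' @param log2_effect Magnitude of the block's log2 repression.
#' @param noise_sd Gaussian noise SD (log2 intensity units).
#' @param replicates Replicates per condition.
#' @param seed Integer seed.
#' @return An `expression_sim_config` list.
#' @export
expression_sim_config <- function(n_genes, conditions = c("control", "Zeb1"),
                                  repressed_block_size, log2_effect,
                                  noise_sd = 0.25, replicates = 4L, seed = 1L) {
  if (repressed_block_size > n_genes) stop("block larger than gene universe")
  if (!(noise_sd > 0)) stop("noise_sd must be > 0")
  if (replicates < 2L) stop("need >= 2 replicates")
  structure(list(n_genes = as.integer(n_genes), conditions = conditions,
                 repressed_block_size = as.integer(repressed_block_size),
                 log2_effect = log2_effect, noise_sd = noise_sd,
                 replicates = as.integer(replicates), seed = seed),
            class = "expression_sim_config")
}

#' Simulate a log2 expression matrix with a planted repressed block
#'
#' Per-gene baselines are uniform on log2 intensities 6--12; the first
#' `repressed_block_size` genes are shifted by `-log2_effect` in the last
#' (perturbed) condition; i.i.d. Gaussian noise with `noise_sd` is added.
#'
#' @param cfg An [expression_sim_config()].
#' @return An `expression_matrix`: list with `values` (genes x samples log2
#'   matrix), `samples` (data.frame `sample`, `condition`, `replicate`),
#'   and `block_genes` (planted gene ids).
#' @export
generate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "expression_sim_config"))
  with_op_seed(cfg$seed, "expression", {
    genes <- sprintf("g%04d", seq_len(cfg$n_genes))
    samples <- expand.grid(replicate = seq_len(cfg$replicates),
                           condition = cfg$conditions,
                           stringsAsFactors = FALSE)[, 2:1]
    samples$sample <- sprintf("%s_r%d", samples$condition, samples$replicate)
    baseline <- stats::runif(cfg$n_genes, 6, 12)
    vals <- matrix(baseline, nrow = cfg$n_genes, ncol = nrow(samples))
    perturbed <- samples$condition == cfg$conditions[length(cfg$conditions)]
    block <- seq_len(cfg$repressed_block_size)
    vals[block, perturbed] <- vals[block, perturbed] - cfg$log2_effect
    vals <- vals + stats::rnorm(length(vals), 0, cfg$noise_sd)
    dimnames(vals) <- list(genes, samples$sample)
    structure(list(values = vals, samples = samples,
                   block_genes = genes[block]),
              class = "expression_matrix")
  })
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$samples$condition), collapse = ", ")))
  invisible(x)
}
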