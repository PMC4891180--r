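#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up FDR q-values: `q_(i) = min_{j >= i} p_(j) * m / j`, clipped at 1,
#' returned in the input order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  stats::p.adjust(pvalues, method = "BH")
}

#' Select deregulated genes between two conditions
#'
#' Per-gene Welch t-test on log2 intensities with BH FDR; a gene is selected
#' when its linear fold change reaches `fc_cutoff` and its q-value is at or
#' below `q_cutoff`. `log2fc` is conditionB minus conditionA, so `direction`
#' reads as regulation in B relative to A. Genes with zero variance in both
#' groups get p = 1 and are flagged.
#'
#' @param mat An `expression_matrix` (see [generate_expression()]).
#' @param condition_a,condition_b Condition labels present in the design.
#' @param fc_cutoff Linear fold-change cutoff (default 1.5).
#' @param q_cutoff FDR cutoff (default 0.05).
#' @return data.frame with `gene_id`, `log2fc`, `p`, `q`, `direction`
#'   (`"up"`/`"down"`), `selected`, `flagged_zero_var`.
#' @export
select_deregulated <- function(mat, condition_a, condition_b,
                               fc_cutoff = 1.5, q_cutoff = 0.05) {
  stopifnot(inherits(mat, "expression_matrix"))
  ia <- mat$samples$condition == condition_a
  ib <- mat$samples$condition == condition_b
  if (sum(ia) < 2L || sum(ib) < 2L) stop("need >= 2 replicates per condition")
  a <- mat$values[, ia, drop = FALSE]
  b <- mat$values[, ib, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1L, stats::var); vb <- apply(b, 1L, stats::var)
  log2fc <- mb - ma
  se2 <- va / na + vb / nb
  zero_var <- se2 == 0
  t <- ifelse(zero_var, 0, log2fc / sqrt(se2))
  df <- ifelse(zero_var, NA_real_,
               se2^2 / (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1))))
  p <- ifelse(zero_var, 1, 2 * stats::pt(-abs(t), df))
  if (any(zero_var)) {
    message(sprintf("%d gene(s) with zero variance in both groups: p set to 1",
                    sum(zero_var)))
  }
  q <- bh_fdr(p)
  data.frame(
    gene_id = rownames(mat$values),
    log2fc = log2fc, p = p, q = q,
    direction = ifelse(log2fc >= 0, "up", "down"),
    selected = abs(log2fc) >= log2(fc_cutoff) & q <= q_cutoff,
    flagged_zero_var = zero_var,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Delta-delta-Ct relative expression
#'
#' Per sample, `dCt = Ct_target - Ct_reference_gene`; per condition,
#' `ddCt = mean dCt(condition) - mean dCt(reference_condition)`; fold change
#' `= 2^(-ddCt)` (amplification efficiency fixed at 2). The reference
#' condition's fold is exactly 1 for every gene.
#'
#' @param ct data.frame with `gene`, `condition`, `replicate`, `ct`.
#' @param reference_gene Normalizer gene (default `"18S"`).
#' @param reference_condition Condition all folds are relative to.
#' @return data.frame with `gene`, `condition`, `ddct`, `fold`.
#' @export
ddct_relative_expression <- function(ct, reference_gene = "18S",
                                     reference_condition) {
  stopifnot(all(c("gene", "condition", "replicate", "ct") %in% names(ct)))
  if (!reference_condition %in% ct$condition) {
    stop(sprintf("reference condition '%s' absent", reference_condition))
  }
  ref <- ct[ct$gene == reference_gene, ]
  if (nrow(ref) == 0L) stop(sprintf("reference gene '%s' absent", reference_gene))
  key <- function(d) paste(d$condition, d$replicate, sep = "\r")
  ref_ct <- stats::setNames(ref$ct, key(ref))
  tgt <- ct[ct$gene != reference_gene, ]
  miss <- setdiff(unique(key(tgt)), names(ref_ct))
  if (length(miss) > 0L) stop("reference-gene well missing for some samples")
  tgt$dct <- tgt$ct - ref_ct[key(tgt)]
  agg <- stats::aggregate(dct ~ gene + condition, data = tgt, FUN = mean)
  base <- agg[agg$condition == reference_condition, ]
  base_dct <- stats::setNames(base$dct, base$gene)
  agg$ddct <- agg$dct - base_dct[agg$gene]
  agg$fold <- 2^(-agg$ddct)
  agg[order(agg$gene, agg$condition), c("gene", "condition", "ddct", "fold")]
}

#' ChIP-qPCR fold enrichment over the IgG control
#'
#' Fold enrichment of each assayed region: percent-input of the specific
#' antibody divided by percent-input of the IgG control, so the IgG channel
#' is by definition exactly 1.
#'
#' @param sample_pct_input Numeric vector, percent input of the specific IP.
#' @param igg_pct_input Numeric vector (or scalar), percent input of IgG.
#' @return List with `fold` and `igg_fold` (all exactly 1).
#' @export
chip_fold_enrichment <- function(sample_pct_input, igg_pct_input) {
  if (any(igg_pct_input <= 0)) stop("IgG percent-input must be > 0")
  list(fold = sample_pct_input / igg_pct_input,
       igg_fold = rep(1, length(sample_pct_input)))
}
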