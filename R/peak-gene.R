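#' Assign each ChIP peak to its nearest-TSS gene
#'
#' Each peak is assigned the gene with the minimum `|summit - TSS|` on its
#' chromosome (ties broken by lexicographically smallest `gene_id`, so the
#' assignment is deterministic and independent of peak-file order). The
#' signed distance is strand-aware: negative values lie upstream of the TSS
#' in the gene's orientation. Feature classes: `promoter` when the summit
#' falls in the strand-aware window `[-upstream, +downstream]` around the
#' TSS, `gene-proximal` within `proximal_bp`, else `distal`. Peaks on
#' chromosomes without genes are returned unassigned (NA gene) and logged.
#'
#' @param peaks A `peak_set` (0-based half-open; 0-based summit).
#' @param genes data.frame with `gene_id`, `chrom`, `tss` (1-based),
#'   `strand`.
#' @param promoter_window Length-2 numeric: upstream, downstream extent (bp)
#'   of the promoter class. Default 2000 up, 500 down.
#' @param proximal_bp Absolute distance bound of the `gene-proximal` class.
#' @return data.frame with `name`, `chrom`, `summit`, `gene_id`,
#'   `signed_distance`, `feature_class`, row per peak, in input order.
#' @export
assign_peaks_to_genes <- function(peaks, genes,
                                  promoter_window = c(2000, 500),
                                  proximal_bp = 10000) {
  stopifnot(inherits(peaks, "peak_set"),
            all(c("gene_id", "chrom", "tss", "strand") %in% names(genes)))
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id in gene model")
  pos1 <- peaks$summit + 1L  # 0-based summit -> 1-based genome position
  out <- data.frame(name = peaks$name, chrom = peaks$chrom, summit = peaks$summit,
                    gene_id = NA_character_, signed_distance = NA_real_,
                    feature_class = "unassigned", stringsAsFactors = FALSE)
  for (chr in unique(peaks$chrom)) {
    g <- genes[genes$chrom == chr, , drop = FALSE]
    pk <- which(peaks$chrom == chr)
    if (nrow(g) == 0L) {
      message(sprintf("%d peak(s) on chromosome '%s' have no genes; left unassigned",
                      length(pk), chr))
      next
    }
    ord <- order(g$tss, g$gene_id)
    ts <- g$tss[ord]
    ids <- g$gene_id[ord]
    strands <- g$strand[ord]
    n <- length(ts)
    for (i in pk) {
      p <- pos1[i]
      k <- findInterval(p, ts)
      lo <- max(k, 1L); hi <- min(k + 1L, n)
      dmin <- min(abs(p - ts[lo]), abs(p - ts[hi]))
      # candidate indices at exactly dmin (handles equidistant flanking TSSs
      # and duplicated TSS coordinates)
      cand <- integer(0)
      j <- lo
      while (j >= 1L && abs(p - ts[j]) == dmin) { cand <- c(cand, j); j <- j - 1L }
      j <- lo + 1L
      while (j <= n && abs(p - ts[j]) == dmin) { cand <- c(cand, j); j <- j + 1L }
      best <- cand[ids[cand] == min(ids[cand])][1]
      signed <- if (strands[best] == "+") p - ts[best] else ts[best] - p
      out$gene_id[i] <- ids[best]
      out$signed_distance[i] <- signed
      out$feature_class[i] <-
        if (signed >= -promoter_window[1] && signed <= promoter_window[2]) {
          "promoter"
        } else if (abs(signed) <= proximal_bp) "gene-proximal" else "distal"
    }
  }
  out
}

#' Count binding events associated with a gene set
#'
#' Counts peaks (binding events) whose assigned gene belongs to `gene_set`.
#' With `mode = "genes"` counts distinct bound genes instead.
#'
#' @param assignments Output of [assign_peaks_to_genes()].
#' @param gene_set Character vector of gene ids.
#' @param mode `"peaks"` (default; events) or `"genes"` (distinct genes).
#' @return Integer count.
#' @export
count_binding_events <- function(assignments, gene_set,
                                 mode = c("peaks", "genes")) {
  mode <- match.arg(mode)
  if (length(gene_set) == 0L) {
    warning("empty gene set: 0 binding events")
    return(0L)
  }
  hit <- assignments$gene_id[!is.na(assignments$gene_id) &
                               assignments$gene_id %in% gene_set]
  if (mode == "peaks") length(hit) else length(unique(hit))
}

#' Resampling null for binding/gene-set association
#'
#' Draws `n_resample` random gene sets of the observed size from the array
#' universe (without replacement), counts binding events for each, and
#' scores the observed count against the null's mean and SD assuming a
#' normal null (z and one-sided upper-tail p by default). Also returns the
#' boxplot summary of the null (median, quartiles, whiskers at 1.5 IQR
#' clipped to the observed null range).
#'
#' @param assignments Output of [assign_peaks_to_genes()].
#' @param gene_set Character vector; must be a subset of `universe`.
#' @param universe Character vector of all genes represented on the array.
#' @param n_resample Number of random sets (default 1000).
#' @param seed Integer seed.
#' @param tail `"greater"` (enrichment, default) or `"two.sided"`.
#' @return An `association_result`: list with `observed`, `null_mean`,
#'   `null_sd`, `z`, `p_value`, `null_draws`, `boxplot`, `tail`.
#' @export
resample_association <- function(assignments, gene_set, universe,
                                 n_resample = 1000L, seed = 1L,
                                 tail = c("greater", "two.sided")) {
  tail <- match.arg(tail)
  if (!all(gene_set %in% universe)) stop("gene_set must be a subset of universe")
  k <- length(gene_set)
  if (k < 1L) stop("empty gene set")
  # per-gene binding-event counts over the universe
  tab <- table(factor(assignments$gene_id[!is.na(assignments$gene_id)],
                      levels = universe))
  cnt <- as.numeric(tab)
  observed <- count_binding_events(assignments, gene_set)
  null <- with_op_seed(seed, "resample", {
    vapply(seq_len(n_resample),
           function(i) sum(cnt[sample.int(length(universe), k)]),
           numeric(1))
  })
  null_sd <- stats::sd(null)
  if (null_sd == 0) {
    stop("degenerate null: every resampled gene set has identical binding count ",
         "(is gene_set the whole universe, or are no peaks assigned?)")
  }
  z <- (observed - mean(null)) / null_sd
  p <- switch(tail,
              greater = stats::pnorm(z, lower.tail = FALSE),
              two.sided = 2 * stats::pnorm(-abs(z)))
  q <- stats::quantile(null, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  structure(list(
    observed = observed, null_mean = mean(null), null_sd = null_sd,
    z = z, p_value = p, null_draws = n_resample,
    boxplot = list(median = q[2], q1 = q[1], q3 = q[3],
                   whisker_lo = max(min(null), q[1] - 1.5 * iqr),
                   whisker_hi = min(max(null), q[3] + 1.5 * iqr)),
    tail = tail), class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf(
    "<association_result> observed = %d events; null = %.1f +/- %.1f (%d draws); z = %.2f, p = %.3g (%s)\n",
    x$observed, x$null_mean, x$null_sd, x$null_draws, x$z, x$p_value, x$tail))
  invisible(x)
}

#' Default p-value threshold grid (half-log steps, 1e-5 to 0.05)
#' @return Increasing numeric vector of significance cutoffs.
#' @export
default_p_thresholds <- function() {
  sort(unique(c(10^seq(-5, -2, by = 0.5), 0.05)))
}

#' Cumulative-fraction map of direct regulation
#'
#' For each regulation direction (up, down), genes are sorted by decreasing
#' `|log2 fold change|` and split into `n_fc_bins` equal-size bins. Entry
#' (i, j) is the fraction of genes in cumulative bins 1..i whose best
#' binding p-value is at or below threshold j. The control panel repeats the
#' computation `n_random` times with the bound-gene labels reassigned
#' uniformly at random over the universe (p-value multiset preserved) and
#' reports the mean.
#'
#' @param de_table data.frame with `gene_id` and `log2fc`; its genes form
#'   the universe.
#' @param bound_gene_pvalues Named numeric vector: best (smallest) binding
#'   p-value per bound gene.
#' @param n_fc_bins Number of equal-size fold-change bins (default 20).
#' @param p_thresholds Increasing grid of significance cutoffs.
#' @param n_random Random reassignments for the control mean (default 100).
#' @param seed Integer seed.
#' @return A `cumulative_fraction_map`: list with `up` and `down`, each
#'   holding `fractions` and `control_mean` (bins x thresholds matrices),
#'   `fc_bin_max` (|log2fc| upper edge per bin) and `genes_per_bin`;
#'   plus `p_thresholds`.
#' @export
cumulative_fraction_map <- function(de_table, bound_gene_pvalues,
                                    n_fc_bins = 20L,
                                    p_thresholds = default_p_thresholds(),
                                    n_random = 100L, seed = 1L) {
  stopifnot(all(c("gene_id", "log2fc") %in% names(de_table)),
            !is.unsorted(p_thresholds))
  if (!all(names(bound_gene_pvalues) %in% de_table$gene_id)) {
    stop("bound genes must belong to the de_table universe")
  }
  universe <- de_table$gene_id
  one_direction <- function(sub, pvals) {
    if (n_fc_bins > nrow(sub)) {
      stop(sprintf("n_fc_bins = %d exceeds the %d genes in this direction",
                   n_fc_bins, nrow(sub)))
    }
    ord <- order(-abs(sub$log2fc), sub$gene_id)
    g <- sub$gene_id[ord]
    bin <- ceiling(seq_along(g) * n_fc_bins / length(g))
    p_of <- pvals[g]                      # NA when unbound
    frac <- matrix(0, n_fc_bins, length(p_thresholds),
                   dimnames = list(NULL, signif(p_thresholds, 3)))
    for (i in seq_len(n_fc_bins)) {
      in_cum <- bin <= i
      denom <- sum(in_cum)
      for (j in seq_along(p_thresholds)) {
        frac[i, j] <- sum(!is.na(p_of[in_cum]) &
                            p_of[in_cum] <= p_thresholds[j]) / denom
      }
    }
    list(fractions = frac,
         fc_bin_max = vapply(split(abs(sub$log2fc[ord]), bin), max, numeric(1)),
         genes_per_bin = as.integer(table(bin)))
  }
  up <- de_table[de_table$log2fc > 0, , drop = FALSE]
  down <- de_table[de_table$log2fc < 0, , drop = FALSE]
  obs_up <- one_direction(up, bound_gene_pvalues)
  obs_down <- one_direction(down, bound_gene_pvalues)
  ctrl <- with_op_seed(seed, "cfmap", {
    acc_up <- 0; acc_down <- 0
    nb <- length(bound_gene_pvalues)
    for (r in seq_len(n_random)) {
      rnd <- stats::setNames(
        sample(unname(bound_gene_pvalues)),
        sample(universe, nb))
      acc_up <- acc_up + one_direction(up, rnd)$fractions
      acc_down <- acc_down + one_direction(down, rnd)$fractions
    }
    list(up = acc_up / n_random, down = acc_down / n_random)
  })
  structure(list(
    up = c(obs_up, list(control_mean = ctrl$up)),
    down = c(obs_down, list(control_mean = ctrl$down)),
    p_thresholds = p_thresholds), class = "cumulative_fraction_map")
}

#' E-box motif density around peak summits
#'
#' For every offset in `[-window, window)` relative to each peak summit,
#' the fraction of peaks with a motif match starting at that offset on
#' either strand (a minus-strand match is located by the leftmost base of
#' its reverse complement on the forward strand). Motifs are IUPAC strings;
#' the default `CACCTG` is the Zeb-class E-box core (`CANNTG` is accepted).
#' Windows truncated at contig ends are dropped and logged.
#'
#' @param peaks A `peak_set`.
#' @param seqs Named character vector or `Biostrings::DNAStringSet` of
#'   contig sequences covering the peaks' chromosomes.
#' @param motif IUPAC motif string (default `"CACCTG"`).
#' @param window Half-window, bp (default 2000; profile spans 4 kb).
#' @return List with `offsets`, `frequency`, `n_peaks_used`, `motif`.
#' @export
ebox_density <- function(peaks, seqs, motif = "CACCTG", window = 2000L) {
  stopifnot(inherits(peaks, "peak_set"))
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  mlen <- nchar(motif)
  fwd <- Biostrings::DNAString(motif)
  rev <- Biostrings::reverseComplement(fwd)
  offsets <- seq.int(-window, window - 1L)
  counts <- numeric(length(offsets))
  used <- 0L
  for (i in seq_len(nrow(peaks))) {
    chr <- peaks$chrom[i]
    if (!chr %in% names(seqs)) stop(sprintf("no sequence for contig '%s'", chr))
    summit1 <- peaks$summit[i] + 1L
    lo <- summit1 - window
    hi <- summit1 + window - 1L + (mlen - 1L)
    if (lo < 1L || hi > length(seqs[[chr]])) {
      message(sprintf("peak %s window truncated at contig end; dropped",
                      peaks$name[i]))
      next
    }
    used <- used + 1L
    win <- Biostrings::subseq(seqs[[chr]], lo, hi)
    starts <- unique(c(
      Biostrings::start(Biostrings::matchPattern(fwd, win, fixed = FALSE)),
      Biostrings::start(Biostrings::matchPattern(rev, win, fixed = FALSE))))
    starts <- starts[starts <= 2L * window]
    counts[starts] <- counts[starts] + 1L
  }
  if (used == 0L) stop("no peak window fits inside the supplied contigs")
  list(offsets = offsets, frequency = counts / used,
       n_peaks_used = used, motif = motif)
}
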