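random_instance <- function(n_peaks, n_genes, seed) {
  set.seed(seed)
  genes <- data.frame(
    gene_id = sample(sprintf("g%03d", seq_len(n_genes))),  # shuffled ids
    chrom = sample(c("chr1", "chr2"), n_genes, replace = TRUE),
    tss = sample.int(5e5, n_genes),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    stringsAsFactors = FALSE)
  summit <- sample.int(5e5, n_peaks)
  peaks <- as_peak_set(data.frame(
    chrom = sample(c("chr1", "chr2"), n_peaks, replace = TRUE),
    start = summit - 50, end = summit + 50, summit = summit,
    stringsAsFactors = FALSE))
  list(peaks = peaks, genes = genes)
}

test_that("nearest-TSS assignment matches the exhaustive all-pairs oracle", {
  inst <- random_instance(50, 20, seed = 201)
  got <- assign_peaks_to_genes(inst$peaks, inst$genes)
  expect_equal(got$gene_id, oracle_assign(inst$peaks, inst$genes))
  # assignment is order-independent w.r.t. peak ordering
  perm <- sample(nrow(inst$peaks))
  got_perm <- assign_peaks_to_genes(inst$peaks[perm, ], inst$genes)
  expect_equal(got_perm$gene_id, got$gene_id[perm])
  # and idempotent
  expect_equal(assign_peaks_to_genes(inst$peaks, inst$genes), got)
})

test_that("assignment handles exact TSS hits, ties and empty chromosomes", {
  genes <- data.frame(gene_id = c("gB", "gA"), chrom = "chr1",
                      tss = c(1000, 3000), strand = c("+", "-"),
                      stringsAsFactors = FALSE)
  peaks <- as_peak_set(data.frame(
    chrom = c("chr1", "chr1", "chr9"),
    start = c(899, 1899, 99), end = c(1100, 2100, 300),
    summit = c(999, 1999, 200),  # 0-based; 1-based positions 1000, 2000, 201
    stringsAsFactors = FALSE))
  got <- suppressMessages(assign_peaks_to_genes(peaks, genes))
  # summit exactly at a TSS: distance 0, promoter class
  expect_equal(got$gene_id[1], "gB")
  expect_equal(got$signed_distance[1], 0)
  expect_equal(got$feature_class[1], "promoter")
  # equidistant between the two TSSs: lexicographically smaller id wins
  expect_equal(got$gene_id[2], "gA")
  # minus-strand gene: position left of the TSS is downstream (positive)
  expect_equal(got$signed_distance[2], 1000)
  # chromosome without genes: unassigned
  expect_true(is.na(got$gene_id[3]))
  expect_equal(got$feature_class[3], "unassigned")
})

test_that("binding-event counts match filter-and-count enumeration", {
  inst <- random_instance(80, 25, seed = 202)
  asn <- assign_peaks_to_genes(inst$peaks, inst$genes)
  set <- sample(inst$genes$gene_id, 10)
  expect_equal(count_binding_events(asn, set),
               sum(asn$gene_id %in% set))
  expect_equal(count_binding_events(asn, set, mode = "genes"),
               length(unique(asn$gene_id[asn$gene_id %in% set])))
  expect_warning(n0 <- count_binding_events(asn, character(0)), "empty")
  expect_equal(n0, 0L)
  # toy: three peaks on one gene count as three events
  toy <- data.frame(gene_id = c("A", "A", "A", "B"))
  expect_equal(count_binding_events(toy, "A"), 3L)
})

test_that("resampling null matches exhaustive enumeration on a small universe", {
  universe <- sprintf("u%02d", 1:10)
  # fixed per-gene binding counts: genes u01..u04 carry 2,1,1,3 peaks
  asn <- data.frame(gene_id = rep(c("u01", "u02", "u03", "u04"),
                                  times = c(2, 1, 1, 3)))
  res <- resample_association(asn, c("u01", "u02", "u05"), universe,
                              n_resample = 1e4, seed = 301)
  combos <- combn(10, 3)
  cnt <- c(2, 1, 1, 3, rep(0, 6))
  exact_counts <- apply(combos, 2, function(ix) sum(cnt[ix]))
  exact_mean <- mean(exact_counts)
  mc_se <- sd(exact_counts) / sqrt(1e4)
  expect_lt(abs(res$null_mean - exact_mean), 3 * mc_se)
  expect_equal(res$observed, 3L)
  expect_equal(res$null_draws, 1e4)
  # boxplot whiskers respect the 1.5 IQR rule clipped to the null range
  bx <- res$boxplot
  expect_gte(bx$whisker_lo, min(exact_counts))
  expect_lte(bx$whisker_hi, max(exact_counts))
  expect_gte(bx$q3, bx$q1)
})

test_that("degenerate nulls are refused and z is relabeling-invariant", {
  universe <- sprintf("u%02d", 1:10)
  asn <- data.frame(gene_id = c("u01", "u02"))
  expect_error(resample_association(asn, universe, universe, 100, seed = 1),
               "degenerate")
  expect_error(resample_association(asn, c("zz"), universe), "subset")

  inst <- random_instance(60, 30, seed = 203)
  asn2 <- assign_peaks_to_genes(inst$peaks, inst$genes)
  set <- sort(sample(inst$genes$gene_id, 8))
  r1 <- resample_association(asn2, set, sort(inst$genes$gene_id),
                             n_resample = 2000, seed = 77)
  # relabel every gene id bijectively: z must be unchanged
  relab <- setNames(sprintf("x%03d", seq_along(inst$genes$gene_id)),
                    sort(inst$genes$gene_id))
  asn3 <- asn2; asn3$gene_id <- unname(relab[asn2$gene_id])
  r2 <- resample_association(asn3, unname(relab[set]), unname(relab),
                             n_resample = 2000, seed = 77)
  expect_equal(r2$z, r1$z)
  expect_equal(r2$p_value, r1$p_value)
})

test_that("planted binding enrichment is detected with high power", {
  p <- vapply(1:20, function(s) {
    gp <- generate_genome_and_peaks(
      planted_association_config(1000, 100, 0.8, 0.1, seed = s))
    asn <- assign_peaks_to_genes(gp$peaks, gp$genes)
    resample_association(asn, gp$targets, gp$genes$gene_id,
                         n_resample = 500, seed = s)$p_value
  }, numeric(1))
  expect_gte(mean(p < 1e-3), 0.95)
})

test_that("cumulative-fraction maps match hand enumeration on a toy input", {
  de <- data.frame(gene_id = c("a", "b", "c", "d", "e", "f", "g"),
                   log2fc = c(-3, -2.5, -2, -1.5, -1, 2, 1.5),
                   stringsAsFactors = FALSE)
  bound <- c(a = 1e-4, c = 1e-2)
  m <- cumulative_fraction_map(de, bound, n_fc_bins = 2,
                               p_thresholds = c(1e-3, 0.05),
                               n_random = 5, seed = 1)
  # down direction, sorted by |fc|: bins {a,b}(i=1), {c,d,e} cumulative (i=2)
  # wait: 5 down genes over 2 bins -> bins of size 2 and 3 (ceiling rule)
  expect_equal(m$down$genes_per_bin, c(2L, 3L))
  expect_equal(m$down$fractions[1, ], c(`0.001` = 1/2, `0.05` = 1/2))
  expect_equal(m$down$fractions[2, ], c(`0.001` = 1/5, `0.05` = 2/5))
  # rows are non-decreasing along the p-threshold axis
  expect_true(all(apply(m$down$fractions, 1, function(r) !is.unsorted(r))))
  expect_true(all(m$down$control_mean >= 0 & m$down$control_mean <= 1))
})

test_that("cumulative-fraction maps hit the all-zero and all-one extremes", {
  de <- data.frame(gene_id = sprintf("g%02d", 1:20),
                   log2fc = c(seq(-2, -0.5, length.out = 10),
                              seq(0.5, 2, length.out = 10)))
  none <- cumulative_fraction_map(de, setNames(numeric(0), character(0)),
                                  n_fc_bins = 5, p_thresholds = c(0.01, 0.05),
                                  n_random = 3, seed = 2)
  expect_true(all(none$down$fractions == 0))
  expect_true(all(none$up$fractions == 0))
  all_p <- setNames(rep(1e-6, 20), de$gene_id)
  full <- cumulative_fraction_map(de, all_p, n_fc_bins = 5,
                                  p_thresholds = c(0.01, 0.05),
                                  n_random = 3, seed = 2)
  expect_true(all(full$down$fractions == 1))
  expect_true(all(full$up$control_mean == 1))
  expect_error(
    cumulative_fraction_map(de, all_p, n_fc_bins = 50, n_random = 2, seed = 1),
    "exceeds")
})

test_that("E-box density profiles behave at the extremes and in expectation", {
  withr::local_seed(205)
  win <- 50L
  # 10 peaks on one 4 kb contig of pure A: no CACCTG anywhere
  seqs <- c(chrZ = paste(rep("A", 4000), collapse = ""))
  summits <- seq(500, 3200, length.out = 10)
  peaks <- as_peak_set(data.frame(chrom = "chrZ", start = summits - 10,
                                  end = summits + 10, summit = summits))
  prof <- ebox_density(peaks, seqs, motif = "CACCTG", window = win)
  expect_true(all(prof$frequency == 0))
  expect_equal(prof$n_peaks_used, 10)

  # motif planted at every summit: profile maximum exactly at offset 0
  chars <- strsplit(seqs[["chrZ"]], "")[[1]]
  for (s in summits) chars[(s + 1):(s + 6)] <- c("C", "A", "C", "C", "T", "G")
  planted <- c(chrZ = paste(chars, collapse = ""))
  prof2 <- ebox_density(peaks, planted, motif = "CACCTG", window = win)
  expect_equal(prof2$frequency[prof2$offsets == 0], 1)
  expect_true(all(prof2$frequency[prof2$offsets != 0] < 1))

  # uniform random sequence: mean per-position frequency ~ 2 * (1/4)^6
  rnd <- c(chrR = paste(sample(c("A", "C", "G", "T"), 3e5, replace = TRUE),
                        collapse = ""))
  s2 <- seq(3000, 295000, length.out = 60)
  pk2 <- as_peak_set(data.frame(chrom = "chrR", start = s2 - 10,
                                end = s2 + 10, summit = s2))
  prof3 <- ebox_density(pk2, rnd, motif = "CACCTG", window = 2000L)
  expected <- 2 * (1 / 4)^6
  se <- sd(prof3$frequency) / sqrt(length(prof3$frequency))
  expect_lt(abs(mean(prof3$frequency) - expected), 3 * se + 1e-5)

  # windows that fall off the contig are dropped and reported
  both <- as_peak_set(data.frame(chrom = "chrZ",
                                 start = c(0, summits[1] - 10),
                                 end = c(20, summits[1] + 10),
                                 summit = c(5, summits[1])))
  expect_message(p4 <- ebox_density(both, seqs, window = win), "truncated")
  expect_equal(p4$n_peaks_used, 1)
})
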