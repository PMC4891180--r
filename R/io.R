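#' Read a peak BED file
#'
#' Tab-separated, at least 3 columns (`chrom`, `start`, `end`; 0-based
#' half-open). Optional columns 4--7 are `name`, `score` (stored as the peak
#' p-value), `strand`, and the summit offset relative to `start`. When the
#' summit column is absent the interval midpoint is used (logged).
#'
#' @param path File path.
#' @return A `peak_set` data.frame.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty BED file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3L)) {
    stop(sprintf("malformed BED line %d: fewer than 3 columns",
                 which(ncol < 3L)[1]))
  }
  get <- function(i, default = NA) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else as.character(default),
           character(1))
  }
  start <- suppressWarnings(as.numeric(get(2)))
  end <- suppressWarnings(as.numeric(get(3)))
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad) > 0L) {
    stop(sprintf("malformed BED line %d: need numeric start < end", bad[1]))
  }
  n4 <- get(4); n5 <- get(5); n7 <- get(7)
  has_summit <- !is.na(n7)
  if (any(!has_summit)) {
    message(sprintf("%d peak(s) without summit column: midpoint used",
                    sum(!has_summit)))
  }
  summit <- ifelse(has_summit,
                   start + suppressWarnings(as.numeric(n7)),
                   floor((start + end) / 2))
  df <- data.frame(
    chrom = get(1),
    start = start, end = end,
    name = ifelse(is.na(n4), sprintf("peak%04d", seq_along(lines)), n4),
    summit = summit,
    p_value = ifelse(is.na(n5), 1, suppressWarnings(as.numeric(n5))),
    stringsAsFactors = FALSE)
  as_peak_set(df)
}

#' Write a peak set as BED6 + summit-offset
#'
#' Column 5 carries the peak p-value at full precision; column 7 the summit
#' offset relative to `start`, so [read_bed()] round-trips exactly.
#'
#' @param peaks A `peak_set`.
#' @param path Output path.
#' @export
write_bed <- function(peaks, path) {
  stopifnot(inherits(peaks, "peak_set"))
  writeLines(sprintf("%s\t%d\t%d\t%s\t%.17g\t.\t%d",
                     peaks$chrom, as.integer(peaks$start), as.integer(peaks$end),
                     peaks$name, peaks$p_value,
                     as.integer(peaks$summit - peaks$start)),
             path)
  invisible(path)
}

#' Read a gene model table
#'
#' TSV with header `gene_id`, `chrom`, `tss` (1-based), `strand`.
#'
#' @param path File path.
#' @return data.frame of gene records.
#' @export
read_gene_table <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "tss", "strand")
  miss <- setdiff(need, names(g))
  if (length(miss) > 0L) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(g$gene_id)) {
    stop("duplicate gene_id: ", g$gene_id[duplicated(g$gene_id)][1])
  }
  if (!is.numeric(g$tss) || any(is.na(g$tss)) || any(g$tss < 1)) {
    stop("tss must be numeric and >= 1")
  }
  if (!all(g$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  g[need]
}

#' @rdname read_gene_table
#' @param genes data.frame of gene records.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cell cohort (cells CSV + surface CSV)
#'
#' Cells: `cell_id`, `x_um`, `y_um`, `condition` (one condition per file).
#' Surface: ordered polyline vertices `x_um`, `y_um`.
#'
#' @param cells_path,surface_path File paths.
#' @return A `cell_cohort`.
#' @export
read_cells <- function(cells_path, surface_path) {
  cells <- utils::read.csv(cells_path, stringsAsFactors = FALSE)
  need <- c("cell_id", "x_um", "y_um", "condition")
  miss <- setdiff(need, names(cells))
  if (length(miss) > 0L) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(cells$x_um) || !is.numeric(cells$y_um) ||
      anyNA(cells$x_um) || anyNA(cells$y_um)) {
    stop("non-numeric cell coordinates")
  }
  cond <- unique(cells$condition)
  if (length(cond) != 1L) stop("cells file must hold exactly one condition")
  surface <- utils::read.csv(surface_path, stringsAsFactors = FALSE)
  if (!all(c("x_um", "y_um") %in% names(surface))) {
    stop("surface file needs x_um, y_um columns")
  }
  new_cell_cohort(cells[c("cell_id", "x_um", "y_um")], cond, surface)
}

#' @rdname read_cells
#' @param cohort A `cell_cohort`.
#' @export
write_cells <- function(cohort, cells_path, surface_path) {
  stopifnot(inherits(cohort, "cell_cohort"))
  cells <- cohort$cells
  cells$condition <- cohort$condition
  utils::write.csv(cells, cells_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$surface, surface_path, row.names = FALSE, quote = FALSE)
  invisible(cells_path)
}

#' Read a log2 expression matrix CSV
#'
#' First column `gene_id`; remaining columns are samples named
#' `<condition>_r<replicate>`; the design is inferred from the names.
#'
#' @param path File path.
#' @return An `expression_matrix`.
#' @export
read_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "gene_id") stop("first column must be gene_id")
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in matrix")
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals) || anyNA(vals)) stop("non-numeric or missing intensities")
  rownames(vals) <- df$gene_id
  m <- regmatches(colnames(vals), regexec("^(.*)_r(\\d+)$", colnames(vals)))
  if (any(lengths(m) != 3L)) {
    stop("sample names must look like <condition>_r<replicate>")
  }
  samples <- data.frame(
    condition = vapply(m, `[`, character(1), 2L),
    replicate = as.integer(vapply(m, `[`, character(1), 3L)),
    sample = colnames(vals), stringsAsFactors = FALSE)
  structure(list(values = vals, samples = samples, block_genes = NULL),
            class = "expression_matrix")
}

#' @rdname read_matrix
#' @param mat An `expression_matrix`.
#' @export
write_matrix <- function(mat, path) {
  stopifnot(inherits(mat, "expression_matrix"))
  df <- data.frame(gene_id = rownames(mat$values),
                   mat$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a qPCR Ct table CSV (`gene`, `condition`, `replicate`, `ct`)
#' @param path File path.
#' @return data.frame.
#' @export
read_ct <- function(path) {
  ct <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "condition", "replicate", "ct")
  miss <- setdiff(need, names(ct))
  if (length(miss) > 0L) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(ct$ct) || anyNA(ct$ct)) stop("non-numeric Ct values")
  ct[need]
}

#' Stable short hash of a configuration (for report provenance)
#' @keywords internal
config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967296)
}
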