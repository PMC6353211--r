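# Downstream transcriptomic classification of transcription-factor
# variants: strand-aware promoter/peak intersection, log2 fold changes
# versus a non-transfected reference, the median logFC-ratio estimator,
# row z-scores, hierarchical clustering and qPCR normalized relative
# quantities.

#' Read a BED6 gene annotation
#'
#' @param path path to a BED6 file (0-based half-open, strand in column 6).
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`
#'   (coordinates kept 0-based half-open).
#' @export
read_genes_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(gene_id = if (!is.null(gr$name)) as.character(gr$name)
             else paste0("gene", seq_along(gr)),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Read a BED3 peak file
#'
#' @param path path to a BED3 file.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
read_peaks_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Strand-aware promoter/gene window intersection with peaks
#'
#' Retains the genes whose strand-extended window overlaps at least one
#' peak by at least 1 bp (half-open coordinates). The window covers the
#' gene body plus a `pad` bp promoter extension upstream of the
#' transcription start: `[start - pad, end)` for `+` genes and
#' `[start, end + pad)` for `-` genes. Negative coordinates are clipped
#' to 0.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (0-based half-open; strand `+` or `-`).
#' @param peaks data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param pad promoter extension, bp (default 2000).
#' @return The subset of `genes` rows with at least one overlapping peak.
#' @export
promoter_peak_intersect <- function(genes, peaks, pad = 2000) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in%
                  names(genes)),
            all(c("chrom", "start", "end") %in% names(peaks)))
  .check_number(pad, "pad", lower = 0)
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'", call. = FALSE)
  }
  if (nrow(genes) == 0L || nrow(peaks) == 0L) {
    return(genes[integer(), , drop = FALSE])
  }
  w_start <- ifelse(genes$strand == "+", pmax(genes$start - pad, 0),
                    genes$start)
  w_end <- ifelse(genes$strand == "+", genes$end, genes$end + pad)
  windows <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(start = w_start + 1L, end = w_end))
  pk <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(start = peaks$start + 1L,
                                  end = peaks$end))
  hits <- GenomicRanges::findOverlaps(windows, pk, minoverlap = 1L)
  out <- genes[sort(unique(S4Vectors::queryHits(hits))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-gene log2 fold changes versus a reference condition
#'
#' Converts counts to counts-per-million, then computes per-sample
#' `log2((cpm + pseudocount) / (cpm_ref + pseudocount))` against the mean
#' CPM of the reference condition, and averages replicates of each
#' condition on the log scale. The reference column is 0 by definition.
#'
#' @param counts non-negative matrix, genes x samples.
#' @param conditions condition label for each column.
#' @param reference the reference condition label (default `"NT"`).
#' @param pseudocount CPM pseudocount (default 0.5).
#' @return Matrix genes x conditions of log2 fold changes.
#' @export
log2fc_vs_reference <- function(counts, conditions, reference = "NT",
                                pseudocount = 0.5) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (length(conditions) != ncol(counts)) {
    stop("'conditions' must have one label per column", call. = FALSE)
  }
  if (!reference %in% conditions) {
    stop(sprintf("reference condition '%s' not present", reference),
         call. = FALSE)
  }
  libs <- colSums(counts)
  if (any(libs <= 0)) stop("zero library size", call. = FALSE)
  cpm <- sweep(counts, 2, libs, "/") * 1e6
  ref_cpm <- rowMeans(cpm[, conditions == reference, drop = FALSE])
  conds <- unique(conditions)
  out <- matrix(0, nrow = nrow(counts), ncol = length(conds),
                dimnames = list(rownames(counts), conds))
  for (cd in setdiff(conds, reference)) {
    cols <- which(conditions == cd)
    lfc <- log2(sweep(cpm[, cols, drop = FALSE] + pseudocount, 1,
                      ref_cpm + pseudocount, "/"))
    out[, cd] <- rowMeans(lfc)
  }
  out
}

#' Classify a variant against the wild type by the median logFC ratio
#'
#' For each gene, the logFC ratio is the difference of log2 fold changes
#' (both versus the non-transfected reference):
#' `ratio_g = log2FC_mut(g) - log2FC_wt(g)`, i.e. the log2 of the
#' fold-change ratio. The variant is called a gain of function when the
#' median ratio over the gene subset is positive, a loss of function
#' otherwise; the Pearson correlation between the two log2FC vectors
#' quantifies target-specificity agreement.
#'
#' @param fc_mut,fc_wt named numeric vectors of per-gene log2 fold changes
#'   versus the reference.
#' @param gene_subset genes over which to classify (default: all shared
#'   genes).
#' @param condition optional label stored in the result.
#' @return An object of class `classification_result` with
#'   `median_log2fc_ratio`, `pearson_r`, `call` (`"gain"`/`"loss"`),
#'   `n_genes` and the per-gene `ratios` with up/down labels.
#' @export
classify_mutant <- function(fc_mut, fc_wt, gene_subset = NULL,
                            condition = NA_character_) {
  if (is.null(names(fc_mut)) || is.null(names(fc_wt))) {
    stop("fc_mut and fc_wt must be named by gene", call. = FALSE)
  }
  if (is.null(gene_subset)) {
    gene_subset <- intersect(names(fc_mut), names(fc_wt))
  }
  if (length(gene_subset) == 0L) stop("empty gene subset", call. = FALSE)
  if (!all(gene_subset %in% names(fc_mut)) ||
      !all(gene_subset %in% names(fc_wt))) {
    stop("gene_subset contains genes absent from a fold-change table",
         call. = FALSE)
  }
  m <- fc_mut[gene_subset]
  w <- fc_wt[gene_subset]
  ratios <- m - w
  med <- stats::median(ratios)
  r <- if (stats::sd(m) > 0 && stats::sd(w) > 0) stats::cor(m, w) else NA_real_
  structure(list(condition = condition,
                 median_log2fc_ratio = med,
                 pearson_r = r,
                 call = if (med > 0) "gain" else "loss",
                 n_genes = length(gene_subset),
                 ratios = ratios,
                 direction = ifelse(ratios > 0, "up", "down")),
            class = "classification_result")
}

#' Row-standardize a matrix (z-scores)
#'
#' Each row is centred to mean 0 and scaled to (sample) standard deviation
#' 1: \eqn{z = (x - \mu)/\sigma}.
#'
#' @param m numeric matrix; every row must have positive SD.
#' @return The row-standardized matrix.
#' @export
zscore_rows <- function(m) {
  m <- as.matrix(m)
  mu <- rowMeans(m)
  sd_ <- apply(m, 1, stats::sd)
  bad <- which(sd_ == 0 | !is.finite(sd_))
  if (length(bad)) {
    ids <- if (!is.null(rownames(m))) rownames(m)[bad] else bad
    stop("zero-variance rows cannot be standardized: ",
         paste(utils::head(ids, 5), collapse = ", "), call. = FALSE)
  }
  sweep(sweep(m, 1, mu, "-"), 1, sd_, "/")
}

#' Hierarchical clustering of a standardized matrix
#'
#' Agglomerative clustering with Euclidean distance and average linkage,
#' applied to rows and columns. Leaf orders are deterministic (ties broken
#' by input order via the distance computation).
#'
#' @param zmatrix a row-standardized matrix, e.g. from [zscore_rows()].
#' @return A list with `row_order`, `col_order` (integer leaf orders) and
#'   the `hclust` trees `row_tree`, `col_tree` (NULL when that dimension
#'   has fewer than 2 elements).
#' @export
cluster_rows_cols <- function(zmatrix) {
  zmatrix <- as.matrix(zmatrix)
  cl <- function(x) {
    if (nrow(x) < 2L) return(list(order = seq_len(nrow(x)), tree = NULL))
    tree <- stats::hclust(stats::dist(x, method = "euclidean"),
                          method = "average")
    list(order = tree$order, tree = tree)
  }
  rows <- cl(zmatrix)
  cols <- cl(t(zmatrix))
  list(row_order = rows$order, col_order = cols$order,
       row_tree = rows$tree, col_tree = cols$tree)
}

#' Normalized relative quantities from qPCR Ct values
#'
#' Assuming an amplification efficiency of 2, the relative quantity of gene
#' g in sample s against a calibrator sample is
#' `RQ(s, g) = 2^(Ct(cal, g) - Ct(s, g))`; the normalized relative quantity
#' divides by the geometric mean of the RQs of the reference (housekeeping)
#' genes of that sample:
#' `NRQ(s, g) = RQ(s, g) / geomean_r RQ(s, r)`.
#'
#' @param ct data.frame with columns `sample`, `gene`, `ct` (Ct > 0).
#' @param reference_genes character vector of housekeeping genes (>= 1),
#'   present in every sample.
#' @param calibrator_sample the calibrator sample name.
#' @return Matrix samples x genes of NRQ values. Samples with missing Ct
#'   values are dropped with a warning.
#' @export
nrq_from_ct <- function(ct, reference_genes, calibrator_sample) {
  stopifnot(all(c("sample", "gene", "ct") %in% names(ct)))
  if (length(reference_genes) < 1L) {
    stop("at least one reference gene is required", call. = FALSE)
  }
  if (any(ct$ct <= 0, na.rm = TRUE)) stop("Ct values must be > 0",
                                          call. = FALSE)
  wide <- stats::xtabs(ct ~ sample + gene, data = ct)
  present <- stats::xtabs(~ sample + gene, data = ct) > 0
  mat <- matrix(NA_real_, nrow(wide), ncol(wide), dimnames = dimnames(wide))
  mat[present] <- wide[present]
  genes <- colnames(mat)
  if (!all(reference_genes %in% genes)) {
    stop("reference genes missing from the Ct table", call. = FALSE)
  }
  if (!calibrator_sample %in% rownames(mat)) {
    stop("calibrator sample missing from the Ct table", call. = FALSE)
  }
  complete <- !apply(is.na(mat), 1, any)
  if (!all(complete)) {
    warning("excluding samples with missing Ct values: ",
            paste(rownames(mat)[!complete], collapse = ", "))
    if (!complete[calibrator_sample]) {
      stop("calibrator sample has missing Ct values", call. = FALSE)
    }
    mat <- mat[complete, , drop = FALSE]
  }
  rq <- 2 ^ sweep(-mat, 2, mat[calibrator_sample, ], "+")  # Ct(cal) - Ct(s)
  norm <- apply(rq[, reference_genes, drop = FALSE], 1, .geometric_mean)
  sweep(rq, 1, norm, "/")
}
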