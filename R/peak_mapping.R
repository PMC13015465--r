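#' Quality-filter MeRIP-seq peaks
#'
#' Applies the peak QC used before site intersection: FDR < 0.05, exactly one
#' assigned gene with detectable expression (FPKM > 0 in the peak's own
#' sample), non-zero IP and input counts, and peak length strictly below
#' 1000 bp. Peaks referencing genes absent from the expression matrix are
#' dropped with a warning; the count of such peaks is attached as attribute
#' `n_unknown_gene`.
#'
#' @param peaks peak data.frame with columns `chrom`, `start`, `end`,
#'   `strand`, `sample_id`, `gene_id`, `fdr`, `ip_count`, `input_count`.
#' @param expression FPKM matrix, genes x samples.
#' @return filtered peak data.frame.
#' @export
qc_filter_peaks <- function(peaks, expression) {
  single_gene <- !grepl(",", peaks$gene_id, fixed = TRUE)
  known <- single_gene & peaks$gene_id %in% rownames(expression)
  n_unknown <- sum(single_gene & !known)
  if (n_unknown > 0L) {
    warning(n_unknown, " peak(s) reference unknown genes and were dropped")
  }
  expressed <- rep(FALSE, nrow(peaks))
  ok_sample <- peaks$sample_id %in% colnames(expression)
  idx <- which(known & ok_sample)
  if (length(idx)) {
    expressed[idx] <- expression[cbind(peaks$gene_id[idx], peaks$sample_id[idx])] > 0
  }
  keep <- peaks$fdr < 0.05 &
    single_gene & known & expressed &
    peaks$ip_count > 0 & peaks$input_count > 0 &
    (peaks$end - peaks$start) < 1000L
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unknown_gene") <- n_unknown
  out
}

#' Intersect the site catalog with per-sample peaks
#'
#' A site is detected in a sample iff its position falls in `[start, end)` of
#' at least one same-strand peak of that sample; its methylation level is the
#' library-size-normalized enrichment ratio
#' `(ip_count/ip_libsize) / (input_count/input_libsize)` of the overlapping
#' peak. When several peaks overlap the one with the smallest FDR wins (ties:
#' larger IP ratio).
#'
#' @param catalog background catalog (columns `chrom`, `pos`, `strand`,
#'   `site`).
#' @param peaks QC-filtered peak table with `ip_libsize`, `input_libsize`.
#' @param samples sample sheet (`sample_id`, `dataset`, `tissue`).
#' @return list with `detection` (logical matrix sites x samples) and
#'   `methylation` (numeric matrix, NA where undetected).
#' @export
map_sites_to_peaks <- function(catalog, peaks, samples) {
  if (anyDuplicated(catalog$site)) stop("duplicate site keys in catalog")
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids")
  if (nrow(peaks) && any(peaks$ip_libsize <= 0 | peaks$input_libsize <= 0)) {
    stop("library sizes must be positive")
  }
  det <- matrix(FALSE, nrow(catalog), nrow(samples),
                dimnames = list(catalog$site, samples$sample_id))
  meth <- matrix(NA_real_, nrow(catalog), nrow(samples),
                 dimnames = dimnames(det))
  sgr <- sites_granges(catalog)
  for (s in samples$sample_id) {
    pk <- peaks[peaks$sample_id == s, , drop = FALSE]
    if (!nrow(pk)) next
    pgr <- GenomicRanges::GRanges(
      seqnames = pk$chrom,
      ranges = IRanges::IRanges(start = pk$start + 1L, end = pk$end),
      strand = pk$strand
    )
    hits <- GenomicRanges::findOverlaps(sgr, pgr)
    if (!length(hits)) next
    qi <- S4Vectors::queryHits(hits)
    pi <- S4Vectors::subjectHits(hits)
    ratio <- (pk$ip_count[pi] / pk$ip_libsize[pi]) /
      (pk$input_count[pi] / pk$input_libsize[pi])
    ord <- order(qi, pk$fdr[pi], -ratio)
    first <- !duplicated(qi[ord])
    qi <- qi[ord][first]
    det[cbind(qi, match(s, samples$sample_id))] <- TRUE
    meth[cbind(qi, match(s, samples$sample_id))] <- ratio[ord][first]
  }
  list(detection = det, methylation = meth)
}

#' Rounded per-sample mean
#'
#' @param total total event count over a dataset.
#' @param n_samples number of samples.
#' @return `round(total / n_samples)` as an integer-valued numeric.
#' @export
per_sample_mean <- function(total, n_samples) {
  if (n_samples <= 0) return(NA_real_)
  round(total / n_samples)
}

#' Cross-dataset overlap percentage, rounded to integer
#'
#' @param common number of sites common to both datasets.
#' @param unique_sites unique site count of the reference dataset.
#' @return integer-valued percentage.
#' @export
overlap_percent <- function(common, unique_sites) {
  round(100 * common / unique_sites)
}

#' Percentage of shared sites that are tissue-conserved, one decimal
#'
#' @param n_tc number of TC sites.
#' @param n_shared number of cross-dataset shared sites.
#' @return percentage rounded to one decimal.
#' @export
shared_tc_percent <- function(n_tc, n_shared) {
  round(100 * n_tc / n_shared, 1)
}

#' Dataset-level landscape report
#'
#' Bookkeeping over a detection matrix: per-dataset detection totals and
#' rounded per-sample means, per-dataset unique site counts, the
#' cross-dataset common site count with its rounded percentage of each
#' dataset's unique sites, and (when `n_tc` is given) the TC percentage of
#' the common sites.
#'
#' @param detection logical matrix sites x samples.
#' @param samples sample sheet aligned with the matrix columns.
#' @param n_tc optional TC site count.
#' @return nested list; per-dataset fields are NULL for empty datasets.
#' @export
summarize_landscape <- function(detection, samples, n_tc = NULL) {
  out <- list(datasets = list())
  uniq <- list()
  for (ds in c("A", "B")) {
    cols <- samples$sample_id[samples$dataset == ds]
    if (!length(cols)) {
      out$datasets[[ds]] <- NULL
      next
    }
    sub <- detection[, cols, drop = FALSE]
    total <- sum(sub)
    uniq[[ds]] <- rownames(sub)[rowSums(sub) > 0L]
    out$datasets[[ds]] <- list(
      n_samples = length(cols),
      total_detections = total,
      mean_per_sample = per_sample_mean(total, length(cols)),
      unique_sites = length(uniq[[ds]])
    )
  }
  if (length(uniq) == 2L) {
    common <- length(intersect(uniq$A, uniq$B))
    out$common_sites <- common
    out$common_pct_of_A <- overlap_percent(common, length(uniq$A))
    out$common_pct_of_B <- overlap_percent(common, length(uniq$B))
    if (!is.null(n_tc)) out$tc_pct_of_common <- shared_tc_percent(n_tc, common)
  }
  out
}
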