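# internal: one-sided (greater) Fisher p and sample odds ratio for a 2x2
fisher_greater <- function(a, b, c_, d) {
  tab <- matrix(c(a, b, c_, d), 2L, byrow = TRUE)
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  or <- if (b * c_ == 0) { if (a * d > 0) Inf else NaN } else (a * d) / (b * c_)
  list(or = or, p = p)
}

#' zFPKM transform of an expression vector
#'
#' log2(FPKM + 0.01) values are centered at the mode of their Gaussian kernel
#' density (Silverman's rule-of-thumb bandwidth) and scaled by the
#' half-normal estimate of the expressed-peak spread,
#' `sigma = mean(x[x > mu] - mu) * sqrt(pi / 2)`. Genes with median zFPKM
#' above -3 across tissues are conventionally treated as active.
#'
#' @param fpkm non-negative numeric vector (one sample/tissue, all genes).
#' @return numeric vector of z-scores, names preserved.
#' @export
zfpkm_transform <- function(fpkm) {
  if (any(fpkm < 0, na.rm = TRUE)) stop("FPKM must be non-negative")
  x <- log2(fpkm + 0.01)
  if (length(unique(x)) < 2L) stop("constant input has no density mode")
  d <- stats::density(x, bw = "nrd0")
  mu <- d$x[which.max(d$y)]
  upper <- x[x > mu]
  if (!length(upper)) stop("no values above the density mode")
  sigma <- mean(upper - mu) * sqrt(pi / 2)
  stats::setNames((x - mu) / sigma, names(fpkm))
}

#' Filter RBPs by expression activity and peak length
#'
#' Keeps RBPs that are active (median per-tissue zFPKM > `zfpkm_min`) and
#' consistently expressed (cross-tissue CV of FPKM below `cv_max`), then
#' drops binding intervals longer than `max_peak_len` bp. RBPs absent from
#' the expression matrix are dropped with a warning. Peak centers
#' `floor((start + end) / 2)` are attached.
#'
#' @param expression_by_tissue FPKM matrix genes x tissues; must contain the
#'   RBP genes (plus the rest of the transcriptome for a stable density fit).
#' @param bindings named list RBP -> interval data.frame (`chrom`, `start`,
#'   `end`, 0-based half-open).
#' @param zfpkm_min activity floor on the median zFPKM (default -3).
#' @param cv_max ceiling on the cross-tissue CV of FPKM (default 1).
#' @param max_peak_len maximum retained interval length (default 100).
#' @return named list of filtered interval tables with a `center` column.
#' @export
filter_rbps <- function(expression_by_tissue, bindings, zfpkm_min = -3,
                        cv_max = 1.0, max_peak_len = 100L) {
  z <- apply(expression_by_tissue, 2L, zfpkm_transform)
  out <- list()
  for (r in names(bindings)) {
    if (!r %in% rownames(expression_by_tissue)) {
      warning("RBP ", r, " absent from expression; dropped")
      next
    }
    med_z <- stats::median(z[r, ])
    fp <- expression_by_tissue[r, ]
    cv <- stats::sd(fp) / mean(fp)
    if (!(med_z > zfpkm_min) || !(cv < cv_max)) next
    iv <- bindings[[r]]
    iv <- iv[(iv$end - iv$start) <= max_peak_len, , drop = FALSE]
    iv$center <- (iv$start + iv$end) %/% 2L
    rownames(iv) <- NULL
    out[[r]] <- iv
  }
  out
}

#' Flag sites bound by one RBP and measure center distances
#'
#' Overlap mode: a site is bound iff its position falls inside `[start, end)`
#' of an interval; window mode: iff the nearest interval center lies within
#' `window` bp. The reported distance is `|center - pos|` to the nearest
#' qualifying interval.
#'
#' @param sites data.frame with `chrom`, `pos`, `strand`, `site`.
#' @param binding_set one RBP's interval table (needs `center`; computed if
#'   absent).
#' @param mode `"overlap"` (default) or `"window"`.
#' @param window half-window in bp for window mode (default 50).
#' @return data.frame `site`, `bound`, `distance` (NA when unbound).
#' @export
bind_sites <- function(sites, binding_set, mode = c("overlap", "window"),
                       window = 50L) {
  mode <- match.arg(mode)
  iv <- binding_set
  if (any(iv$start >= iv$end)) stop("malformed binding interval")
  if (is.null(iv$center)) iv$center <- (iv$start + iv$end) %/% 2L
  bound <- rep(FALSE, nrow(sites))
  distance <- rep(NA_real_, nrow(sites))
  if (nrow(iv)) {
    if (mode == "overlap") {
      igr <- GenomicRanges::GRanges(iv$chrom, IRanges::IRanges(iv$start + 1L, iv$end))
    } else {
      igr <- GenomicRanges::GRanges(
        iv$chrom, IRanges::IRanges(iv$center + 1L - window, iv$center + 1L + window)
      )
    }
    sgr <- GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos + 1L, width = 1L))
    hits <- GenomicRanges::findOverlaps(sgr, igr)
    if (length(hits)) {
      qi <- S4Vectors::queryHits(hits)
      di <- abs(iv$center[S4Vectors::subjectHits(hits)] - sites$pos[qi])
      ord <- order(qi, di)
      keep <- !duplicated(qi[ord])
      bound[qi[ord][keep]] <- TRUE
      distance[qi[ord][keep]] <- di[ord][keep]
    }
  }
  data.frame(site = sites$site, bound = bound, distance = distance,
             stringsAsFactors = FALSE)
}

#' Per-RBP binding enrichment of a site class over background
#'
#' For each RBP, tests whether the class sites are bound more often than the
#' background sites: 2x2 table, one-sided (greater) Fisher p, BH adjustment
#' across RBPs, sorted by FDR. Mean |center - site| distance over bound class
#' sites is reported when distances are supplied.
#'
#' @param class_bound named list (or data.frame) RBP -> logical bound flags
#'   of the class sites.
#' @param background_bound same structure for the disjoint background sites.
#' @param class_distance optional list RBP -> distances aligned with the
#'   class flags.
#' @return data.frame `rbp`, `a`..`d`, `odds_ratio`, `p`, `fdr`,
#'   `mean_distance`, ordered by FDR.
#' @export
rbp_fisher <- function(class_bound, background_bound, class_distance = NULL) {
  rbps <- names(class_bound)
  if (!length(rbps)) stop("no RBPs to test")
  rows <- lapply(rbps, function(r) {
    cb <- class_bound[[r]]
    bb <- background_bound[[r]]
    if (!length(bb)) stop("empty background site set")
    ft <- fisher_greater(sum(cb), sum(!cb), sum(bb), sum(!bb))
    md <- if (!is.null(class_distance)) {
      d <- class_distance[[r]][cb]
      if (length(d)) mean(d, na.rm = TRUE) else NA_real_
    } else NA_real_
    data.frame(rbp = r, a = sum(cb), b = sum(!cb), c = sum(bb), d = sum(!bb),
               odds_ratio = ft$or, p = ft$p, mean_distance = md,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$fdr, out$p, out$rbp), , drop = FALSE]
  rownames(out) <- NULL
  out[c("rbp", "a", "b", "c", "d", "odds_ratio", "p", "fdr", "mean_distance")]
}

# internal: genomic window of a site-relative offset interval, strand-aware
# (negative offsets are upstream, i.e. 5' of the site)
roi_genomic_window <- function(pos, strand, roi_offsets) {
  o1 <- roi_offsets[1L]; o2 <- roi_offsets[2L]
  if (o2 < o1) stop("ROI window of non-positive length")
  start <- ifelse(strand == "+", pos + o1, pos - o2)
  end <- ifelse(strand == "+", pos + o2 + 1L, pos - o1 + 1L)
  data.frame(start = start, end = end)
}

#' RBP enrichment inside a site-anchored ROI window
#'
#' A site counts as ROI-bound for an RBP iff any binding interval overlaps
#' the ROI window anchored at the site in transcript orientation (upstream
#' offsets point 5' of the site on either strand). Each RBP is then tested
#' for greater binding among `sites_high` than `sites_low` with BH
#' adjustment, as in [rbp_fisher()]; swap the arguments to test enrichment in
#' the low cluster.
#'
#' @param sites_high,sites_low data.frames (`chrom`, `pos`, `strand`, `site`)
#'   of the high- and low-methylation clusters.
#' @param binding_set named list RBP -> interval table.
#' @param roi_offsets `c(start_offset, end_offset)` relative to the site,
#'   e.g. `c(-64, -15)`.
#' @return the [rbp_fisher()] data.frame.
#' @export
roi_window_enrichment <- function(sites_high, sites_low, binding_set, roi_offsets) {
  roi_bound <- function(sites) {
    win <- roi_genomic_window(sites$pos, sites$strand, roi_offsets)
    wgr <- GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(win$start + 1L, win$end))
    lapply(binding_set, function(iv) {
      igr <- GenomicRanges::GRanges(iv$chrom, IRanges::IRanges(iv$start + 1L, iv$end))
      IRanges::overlapsAny(wgr, igr)
    })
  }
  rbp_fisher(roi_bound(sites_high), roi_bound(sites_low))
}

#' Fisher enrichment of a gene set among differentially expressed genes
#'
#' DE status is `adjusted p < 0.05 AND |log2 fold change| > 1` (both strict).
#' One table per cohort; with several cohorts the one-sided p-values are BH
#' adjusted across cohorts.
#'
#' @param gene_set character vector of genes.
#' @param de_table data.frame (`gene`, `log2fc`, `padj`) or named list of
#'   such data.frames (one per cohort).
#' @return data.frame `cohort`, `a`..`d`, `odds_ratio`, `p`, `fdr`.
#' @export
gene_set_enrichment <- function(gene_set, de_table) {
  tables <- if (is.data.frame(de_table)) list(cohort = de_table) else de_table
  rows <- lapply(names(tables), function(nm) {
    tab <- tables[[nm]]
    in_set <- tab$gene %in% gene_set
    if (!any(in_set)) stop("gene set is disjoint from the DE table universe")
    de <- tab$padj < 0.05 & abs(tab$log2fc) > 1
    ft <- fisher_greater(sum(in_set & de), sum(in_set & !de),
                         sum(!in_set & de), sum(!in_set & !de))
    data.frame(cohort = nm, a = sum(in_set & de), b = sum(in_set & !de),
               c = sum(!in_set & de), d = sum(!in_set & !de),
               odds_ratio = ft$or, p = ft$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
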