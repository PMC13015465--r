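#' Transcript annotation container
#'
#' Builds the package's transcript model from an exon table and optional CDS
#' spans. All coordinates are 0-based half-open on the genome; transcript
#' offsets are 0-based in 5'->3' transcript orientation.
#'
#' @param exons data.frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand` (`"+"`/`"-"`), `start`, `end` (0-based half-open). Exons of a
#'   transcript must not overlap.
#' @param cds optional data.frame with columns `transcript_id`, `start`, `end`
#'   giving the genomic CDS span (0-based half-open; may cross introns).
#' @return object of class `tx_annotation` with elements `exons` (ranked),
#'   `transcripts` (per-transcript lengths and 5'UTR/CDS/3'UTR split) and
#'   `genes` (gene spans).
#' @export
tx_annotation <- function(exons, cds = NULL) {
  needed <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end")
  if (!all(needed %in% names(exons))) {
    stop("exons must have columns ", paste(needed, collapse = ", "))
  }
  exons <- exons[needed]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (any(exons$start >= exons$end) || any(exons$start < 0)) {
    stop("exon intervals must satisfy 0 <= start < end")
  }
  if (!all(exons$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL

  # per-transcript: check non-overlap, assign 5'->3' exon ranks
  sp <- split(seq_len(nrow(exons)), exons$transcript_id)
  exons$exon_rank <- NA_integer_
  for (idx in sp) {
    if (length(idx) > 1L &&
        any(exons$start[idx][-1L] < exons$end[idx][-length(idx)])) {
      stop("overlapping exons in transcript ", exons$transcript_id[idx[1L]])
    }
    minus <- exons$strand[idx[1L]] == "-"
    exons$exon_rank[idx] <- if (minus) rev(seq_along(idx)) else seq_along(idx)
  }

  tx <- do.call(rbind, lapply(sp, function(idx) {
    data.frame(
      transcript_id = exons$transcript_id[idx[1L]],
      gene_id = exons$gene_id[idx[1L]],
      chrom = exons$chrom[idx[1L]],
      strand = exons$strand[idx[1L]],
      tx_start = min(exons$start[idx]),
      tx_end = max(exons$end[idx]),
      n_exons = length(idx),
      tx_len = sum(exons$end[idx] - exons$start[idx]),
      stringsAsFactors = FALSE
    )
  }))
  rownames(tx) <- NULL

  ann <- structure(list(exons = exons, transcripts = tx), class = "tx_annotation")

  tx$utr5_len <- NA_integer_
  tx$cds_len <- NA_integer_
  tx$utr3_len <- NA_integer_
  if (!is.null(cds) && nrow(cds)) {
    for (i in seq_len(nrow(cds))) {
      t_id <- cds$transcript_id[i]
      j <- match(t_id, tx$transcript_id)
      if (is.na(j)) stop("CDS references unknown transcript ", t_id)
      first0 <- as.integer(cds$start[i])
      last0 <- as.integer(cds$end[i]) - 1L
      if (tx$strand[j] == "-") { tmp <- first0; first0 <- last0; last0 <- tmp }
      o1 <- tx_offset(ann, t_id, first0)
      o2 <- tx_offset(ann, t_id, last0)
      if (is.na(o1) || is.na(o2)) stop("CDS span of ", t_id, " not exonic")
      tx$utr5_len[j] <- o1
      tx$cds_len[j] <- o2 - o1 + 1L
      tx$utr3_len[j] <- tx$tx_len[j] - o2 - 1L
    }
  }
  ann$transcripts <- tx

  g <- split(seq_len(nrow(tx)), tx$gene_id)
  ann$genes <- do.call(rbind, lapply(g, function(idx) {
    data.frame(
      gene_id = tx$gene_id[idx[1L]],
      chrom = tx$chrom[idx[1L]],
      strand = tx$strand[idx[1L]],
      start = min(tx$tx_start[idx]),
      end = max(tx$tx_end[idx]),
      stringsAsFactors = FALSE
    )
  }))
  rownames(ann$genes) <- NULL
  ann
}

#' @export
print.tx_annotation <- function(x, ...) {
  cat(
    "tx_annotation:", nrow(x$genes), "genes,", nrow(x$transcripts),
    "transcripts,", nrow(x$exons), "exons\n"
  )
  invisible(x)
}

# internal: exon table of one transcript, genomic order
exons_of <- function(annotation, transcript_id) {
  ex <- annotation$exons
  ex[ex$transcript_id == transcript_id, , drop = FALSE]
}

#' Transcript offset of genomic positions
#'
#' Maps 0-based genomic positions to 0-based offsets along the spliced
#' transcript (5'->3'). Positions outside the transcript's exons map to `NA`.
#'
#' @param annotation a [tx_annotation].
#' @param transcript_id single transcript id.
#' @param pos integer vector of 0-based genomic positions.
#' @return integer vector of transcript offsets.
#' @export
tx_offset <- function(annotation, transcript_id, pos) {
  ex <- exons_of(annotation, transcript_id)
  if (!nrow(ex)) stop("unknown transcript ", transcript_id)
  w <- ex$end - ex$start
  minus <- ex$strand[1L] == "-"
  # cumulative spliced length upstream of each exon, in transcript orientation
  before <- if (minus) rev(cumsum(c(0L, rev(w)))[seq_len(nrow(ex))]) else
    cumsum(c(0L, w))[seq_len(nrow(ex))]
  out <- rep(NA_integer_, length(pos))
  for (i in seq_len(nrow(ex))) {
    hit <- !is.na(pos) & pos >= ex$start[i] & pos < ex$end[i]
    if (any(hit)) {
      within <- if (minus) ex$end[i] - 1L - pos[hit] else pos[hit] - ex$start[i]
      out[hit] <- before[i] + within
    }
  }
  out
}

# internal: genomic intervals (0-based half-open) covering a transcript-offset
# interval [tx_start, tx_end_incl]
tx_interval_to_genomic <- function(annotation, transcript_id, tx_start, tx_end_incl) {
  ex <- exons_of(annotation, transcript_id)
  w <- ex$end - ex$start
  minus <- ex$strand[1L] == "-"
  ord <- if (minus) rev(seq_len(nrow(ex))) else seq_len(nrow(ex))
  res <- list()
  off <- 0L
  for (i in ord) {
    lo <- max(tx_start - off, 0L)
    hi <- min(tx_end_incl - off, w[i] - 1L)
    if (lo <= hi) {
      if (minus) {
        res[[length(res) + 1L]] <- c(ex$end[i] - 1L - hi, ex$end[i] - lo)
      } else {
        res[[length(res) + 1L]] <- c(ex$start[i] + lo, ex$start[i] + hi + 1L)
      }
    }
    off <- off + w[i]
  }
  m <- do.call(rbind, res)
  data.frame(start = m[, 1L], end = m[, 2L])
}

# internal: GRanges of 1 bp sites from chrom/pos/strand columns
sites_granges <- function(sites) {
  GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$pos + 1L, width = 1L),
    strand = sites$strand
  )
}

# internal: GRanges of exons with row index metadata
exons_granges <- function(annotation) {
  ex <- annotation$exons
  gr <- GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(start = ex$start + 1L, end = ex$end),
    strand = ex$strand
  )
  S4Vectors::mcols(gr)$exon_row <- seq_len(nrow(ex))
  gr
}

#' Annotate transcript regions of single-base sites
#'
#' Assigns each site a region label: `5UTR`, `CDS_exon` or `3UTR` when the
#' position is exonic (using the transcript's CDS split), `intron` when inside
#' a same-strand gene span but not exonic, `intergenic` otherwise. When a
#' position is exonic on several transcripts the longest transcript (summed
#' exon length; ties broken by transcript id) of the host gene decides.
#' Exonic sites on transcripts without an annotated CDS are labelled
#' `CDS_exon`.
#'
#' @param sites data.frame with columns `chrom`, `pos` (0-based), `strand`.
#' @param annotation a [tx_annotation].
#' @return data.frame with columns `region`, `gene_id`, `transcript_id`
#'   (NA for intergenic sites) aligned with `sites` rows.
#' @export
annotate_region <- function(sites, annotation) {
  n <- nrow(sites)
  out <- data.frame(
    region = rep("intergenic", n),
    gene_id = rep(NA_character_, n),
    transcript_id = rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
  if (!n) return(out)
  ex <- annotation$exons
  tx <- annotation$transcripts
  hits <- GenomicRanges::findOverlaps(sites_granges(sites), exons_granges(annotation))
  if (length(hits)) {
    h <- data.frame(
      site = S4Vectors::queryHits(hits),
      transcript_id = ex$transcript_id[S4Vectors::subjectHits(hits)],
      stringsAsFactors = FALSE
    )
    h <- unique(h)
    h$tx_len <- tx$tx_len[match(h$transcript_id, tx$transcript_id)]
    h <- h[order(h$site, -h$tx_len, h$transcript_id), , drop = FALSE]
    h <- h[!duplicated(h$site), , drop = FALSE]
    for (i in seq_len(nrow(h))) {
      s <- h$site[i]
      t_id <- h$transcript_id[i]
      j <- match(t_id, tx$transcript_id)
      off <- tx_offset(annotation, t_id, sites$pos[s])
      reg <- if (is.na(tx$cds_len[j])) "CDS_exon"
      else if (off < tx$utr5_len[j]) "5UTR"
      else if (off < tx$utr5_len[j] + tx$cds_len[j]) "CDS_exon"
      else "3UTR"
      out$region[s] <- reg
      out$gene_id[s] <- tx$gene_id[j]
      out$transcript_id[s] <- t_id
    }
  }
  # remaining sites inside same-strand gene spans are intronic
  left <- which(out$region == "intergenic")
  if (length(left)) {
    g <- annotation$genes
    ggr <- GenomicRanges::GRanges(
      seqnames = g$chrom,
      ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
      strand = g$strand
    )
    gh <- GenomicRanges::findOverlaps(sites_granges(sites[left, , drop = FALSE]), ggr)
    if (length(gh)) {
      first <- !duplicated(S4Vectors::queryHits(gh))
      qi <- left[S4Vectors::queryHits(gh)[first]]
      out$region[qi] <- "intron"
      out$gene_id[qi] <- g$gene_id[S4Vectors::subjectHits(gh)[first]]
    }
  }
  out
}

#' Write annotation as GTF
#'
#' Emits gene, transcript, exon and CDS features with `gene_id` and
#' `transcript_id` attributes (GTF is 1-based inclusive).
#'
#' @param annotation a [tx_annotation].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  tx <- annotation$transcripts
  lines <- character(0)
  fmt <- function(chrom, feat, start0, end0, strand, attr) {
    paste(chrom, "tcm6a", feat, start0 + 1L, end0, ".", strand, ".", attr,
          sep = "\t")
  }
  g <- annotation$genes
  for (i in seq_len(nrow(g))) {
    gi <- g[i, ]
    lines <- c(lines, fmt(gi$chrom, "gene", gi$start, gi$end, gi$strand,
                          sprintf('gene_id "%s";', gi$gene_id)))
    for (j in which(tx$gene_id == gi$gene_id)) {
      tj <- tx[j, ]
      at <- sprintf('gene_id "%s"; transcript_id "%s";', tj$gene_id, tj$transcript_id)
      lines <- c(lines, fmt(tj$chrom, "transcript", tj$tx_start, tj$tx_end,
                            tj$strand, at))
      ex <- exons_of(annotation, tj$transcript_id)
      for (k in seq_len(nrow(ex))) {
        lines <- c(lines, fmt(ex$chrom[k], "exon", ex$start[k], ex$end[k],
                              ex$strand[k], at))
      }
      if (!is.na(tj$cds_len) && tj$cds_len > 0L) {
        cds <- tx_interval_to_genomic(annotation, tj$transcript_id,
                                      tj$utr5_len, tj$utr5_len + tj$cds_len - 1L)
        for (k in seq_len(nrow(cds))) {
          lines <- c(lines, fmt(tj$chrom, "CDS", cds$start[k], cds$end[k],
                                tj$strand, at))
        }
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GTF into the package's annotation container
#'
#' Uses exon features to build transcript models and CDS features (genomic
#' min/max per transcript) for the UTR/CDS split.
#'
#' @param path GTF file with `gene_id` and `transcript_id` attributes.
#' @return a [tx_annotation].
#' @export
read_gtf_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  keep <- md$type == "exon"
  if (!any(keep)) stop("no exon features in ", path)
  exons <- data.frame(
    transcript_id = as.character(md$transcript_id[keep]),
    gene_id = as.character(md$gene_id[keep]),
    chrom = as.character(GenomicRanges::seqnames(gr)[keep]),
    strand = as.character(GenomicRanges::strand(gr)[keep]),
    start = GenomicRanges::start(gr)[keep] - 1L,
    end = GenomicRanges::end(gr)[keep],
    stringsAsFactors = FALSE
  )
  cds <- NULL
  is_cds <- md$type == "CDS"
  if (any(is_cds)) {
    cid <- as.character(md$transcript_id[is_cds])
    cs <- GenomicRanges::start(gr)[is_cds] - 1L
    ce <- GenomicRanges::end(gr)[is_cds]
    cds <- do.call(rbind, lapply(split(seq_along(cid), cid), function(idx) {
      data.frame(transcript_id = cid[idx[1L]], start = min(cs[idx]),
                 end = max(ce[idx]), stringsAsFactors = FALSE)
    }))
  }
  tx_annotation(exons, cds)
}
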