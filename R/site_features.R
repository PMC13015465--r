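# IUPAC nucleotide code sets (DNA alphabet; U is read as T)
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), W = c("A", "T"), S = c("C", "G"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Same-class neighbor counts around each site
#'
#' For every site, counts the OTHER sites that carry the same class label and
#' lie on the same transcript within `window_bp` of genomic distance. Sites
#' without a transcript assignment are excluded with a warning (count NA).
#'
#' @param sites data.frame with columns `site`, `pos`, `transcript_id`,
#'   `class`.
#' @param window_bp half-window in bp (e.g. 25, 50, 100, 200).
#' @return integer vector of neighbor counts aligned with `sites` rows.
#' @export
neighbor_counts <- function(sites, window_bp) {
  out <- rep(NA_integer_, nrow(sites))
  no_tx <- is.na(sites$transcript_id)
  if (any(no_tx)) warning(sum(no_tx), " site(s) lack a transcript assignment")
  groups <- split(which(!no_tx), list(sites$transcript_id[!no_tx], sites$class[!no_tx]),
                  drop = TRUE)
  for (idx in groups) {
    pos <- sort(sites$pos[idx])
    lo <- findInterval(sites$pos[idx] - window_bp - 1L, pos)
    hi <- findInterval(sites$pos[idx] + window_bp, pos)
    out[idx] <- hi - lo - 1L
  }
  out
}

#' Match a sequence window against an IUPAC pattern
#'
#' The pattern is anchored so that its first literal `A` (the methylated
#' adenosine; position 3 for DRACH and RGACW) aligns with `center_offset` in
#' the window. `U` and `T` are equivalent on both sides.
#'
#' @param sequence_window character string (DNA or RNA).
#' @param iupac_pattern IUPAC pattern, e.g. `"DRACH"` or `"RGACW"`.
#' @param center_offset 1-based position of the site base within the window;
#'   default is the window midpoint.
#' @return TRUE iff every pattern position admits the aligned base.
#' @export
motif_match <- function(sequence_window, iupac_pattern,
                        center_offset = (nchar(sequence_window) + 1L) %/% 2L) {
  pat <- strsplit(toupper(iupac_pattern), "")[[1L]]
  bad <- !pat %in% names(IUPAC_CODES)
  if (any(bad)) stop("non-IUPAC character in pattern: ", pat[which(bad)[1L]])
  anchor <- match("A", pat)
  if (is.na(anchor)) stop("pattern has no A anchor")
  seqc <- strsplit(toupper(sequence_window), "")[[1L]]
  seqc[seqc == "U"] <- "T"
  start <- center_offset - anchor + 1L
  if (start < 1L || start + length(pat) - 1L > length(seqc)) {
    stop("window does not cover the pattern span")
  }
  all(vapply(seq_along(pat), function(i) {
    seqc[start + i - 1L] %in% IUPAC_CODES[[pat[i]]]
  }, logical(1L)))
}

#' Sequence window around a site, in transcript orientation
#'
#' @param sequences named character vector of transcript sequences.
#' @param transcript_id transcript holding the site.
#' @param tx_off 0-based transcript offset of the site.
#' @param flank bases on each side.
#' @return character window (site base at position `flank + 1`); positions
#'   outside the transcript are filled with `N`.
#' @export
site_sequence_window <- function(sequences, transcript_id, tx_off, flank = 2L) {
  seqv <- sequences[[transcript_id]]
  L <- nchar(seqv)
  idx <- (tx_off - flank):(tx_off + flank)
  chars <- ifelse(idx >= 0L & idx < L,
                  substring(seqv, idx + 1L, idx + 1L), "N")
  paste(chars, collapse = "")
}

#' Exon rank and length of a site's host exon
#'
#' Rank is the 1-based exon index in 5'->3' transcript orientation divided by
#' the transcript's exon count, so the last exon has rank 1.
#'
#' @param pos 0-based genomic position of the site.
#' @param transcript_id host transcript.
#' @param annotation a [tx_annotation].
#' @return list with `rank` in (0, 1] and `exon_length` in bp.
#' @export
exon_context <- function(pos, transcript_id, annotation) {
  ex <- exons_of(annotation, transcript_id)
  hit <- which(pos >= ex$start & pos < ex$end)
  if (!length(hit)) stop("site is not exonic on transcript ", transcript_id)
  list(
    rank = ex$exon_rank[hit] / nrow(ex),
    exon_length = ex$end[hit] - ex$start[hit]
  )
}

#' Conservation score at the focal base of each site
#'
#' Extracts the track value covering exactly the site position. Uncovered
#' positions yield NA; when several track lines overlap a position the last
#' one (file order) wins, with a warning.
#'
#' @param sites data.frame with `chrom`, `pos`, `strand`.
#' @param track bedGraph-like data.frame `chrom`, `start`, `end`, `score`
#'   (0-based half-open).
#' @return numeric vector of scores (NA where absent).
#' @export
conservation_at_sites <- function(sites, track) {
  if (any(track$start >= track$end)) stop("malformed track interval (start >= end)")
  tgr <- GenomicRanges::GRanges(
    seqnames = track$chrom,
    ranges = IRanges::IRanges(start = track$start + 1L, end = track$end)
  )
  sgr <- GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$pos + 1L, width = 1L)
  )
  hits <- GenomicRanges::findOverlaps(sgr, tgr)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  if (anyDuplicated(qi)) {
    warning("overlapping track lines; the last line wins")
    ord <- order(qi, si)
    qi <- qi[ord]; si <- si[ord]
    keep <- !duplicated(qi, fromLast = TRUE)
    qi <- qi[keep]; si <- si[keep]
  }
  out <- rep(NA_real_, nrow(sites))
  out[qi] <- track$score[si]
  out
}

#' Fisher enrichment of a site class in a reference flag set
#'
#' Builds the 2x2 table (class in reference, class not, others in reference,
#' others not), reports the sample odds ratio `ad/bc` (Inf when `bc = 0` and
#' `ad > 0`) and the one-sided (greater) Fisher p-value from the
#' hypergeometric tail.
#'
#' @param class_flags logical: site belongs to the focal class.
#' @param reference_flags logical: site belongs to the reference set (same
#'   site universe, same order).
#' @return list with `odds_ratio`, `p`, `table`.
#' @export
category_enrichment <- function(class_flags, reference_flags) {
  if (!length(class_flags) || length(class_flags) != length(reference_flags)) {
    stop("flag vectors must be nonempty and aligned")
  }
  a <- sum(class_flags & reference_flags)
  b <- sum(class_flags & !reference_flags)
  c_ <- sum(!class_flags & reference_flags)
  d <- sum(!class_flags & !reference_flags)
  tab <- matrix(c(a, b, c_, d), 2L, byrow = TRUE,
                dimnames = list(c("class", "other"), c("in_ref", "not_in_ref")))
  or <- if (b * c_ == 0) { if (a * d > 0) Inf else NaN } else (a * d) / (b * c_)
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  list(odds_ratio = or, p = p, table = tab)
}

#' Metagene coordinate of a site
#'
#' Maps the site's fractional position within its transcript region onto
#' [0,1) for the 5'UTR, [1,2) for the CDS and [2,3) for the 3'UTR, using
#' transcript-orientation distances.
#'
#' @param pos 0-based genomic position.
#' @param transcript_id host transcript.
#' @param annotation a [tx_annotation].
#' @return coordinate in [0, 3), or NA (with a warning) when the transcript
#'   lacks a CDS.
#' @export
metagene_coordinate <- function(pos, transcript_id, annotation) {
  tx <- annotation$transcripts
  j <- match(transcript_id, tx$transcript_id)
  if (is.na(j)) stop("unknown transcript ", transcript_id)
  if (is.na(tx$cds_len[j])) {
    warning("transcript ", transcript_id, " has no CDS; coordinate undefined")
    return(NA_real_)
  }
  off <- tx_offset(annotation, transcript_id, pos)
  if (is.na(off)) stop("site is not exonic on transcript ", transcript_id)
  u5 <- tx$utr5_len[j]; cl <- tx$cds_len[j]; u3 <- tx$utr3_len[j]
  if (off < u5) off / u5
  else if (off < u5 + cl) 1 + (off - u5) / cl
  else 2 + (off - u5 - cl) / u3
}

#' Seeded downsampling of a site set
#'
#' Comparative analyses between unequal site classes downsample the larger
#' set; this helper makes that reproducible.
#'
#' @param keys vector to sample from.
#' @param n target size (returns all keys if `n >= length(keys)`).
#' @param seed integer seed.
#' @return sampled vector.
#' @export
downsample_to_match <- function(keys, n, seed = 1L) {
  if (n >= length(keys)) return(keys)
  set.seed(seed)
  keys[sample.int(length(keys), n)]
}
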