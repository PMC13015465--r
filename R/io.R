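# column layout of the BED6+ dialects this package writes; BED files carry no
# header, so readers and writers share these definitions
SITE_BED_COLS <- c("chrom", "start", "end", "name", "score", "strand",
                   "support", "source")
PEAK_BED_COLS <- c("chrom", "start", "end", "name", "score", "strand",
                   "fdr", "ip_count", "input_count", "ip_libsize",
                   "input_libsize", "gene_id", "sample_id")

write_tsv <- function(x, path, col.names = TRUE) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = col.names)
  invisible(path)
}

#' Write a site catalog as BED6+
#'
#' Columns: BED6 (name = site key, score 0) plus comma-joined techniques and
#' source; no header.
#'
#' @param catalog site data.frame (`chrom`, `pos`, `strand`, `support`,
#'   `source`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_site_bed <- function(catalog, path) {
  bed <- data.frame(
    chrom = catalog$chrom, start = catalog$pos, end = catalog$pos + 1L,
    name = site_key(catalog$chrom, catalog$pos, catalog$strand),
    score = 0L, strand = catalog$strand,
    support = catalog$support,
    source = if ("source" %in% names(catalog)) catalog$source else "unknown",
    stringsAsFactors = FALSE
  )
  write_tsv(bed, path, col.names = FALSE)
}

#' Read a BED6+ site catalog
#'
#' @param path file written by [write_site_bed()] (or matching that layout).
#' @return data.frame with `chrom`, `pos`, `strand`, `support`, `source`.
#' @export
read_site_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           col.names = SITE_BED_COLS)
  data.frame(chrom = bed$chrom, pos = bed$start, strand = bed$strand,
             support = bed$support, source = bed$source,
             stringsAsFactors = FALSE)
}

#' Write peaks as BED6+ tables, one file per sample
#'
#' @param peaks peak data.frame from [simulate_sample_peaks()] or equivalent.
#' @param dir output directory (created if missing); files are named
#'   `<sample_id>.bed`.
#' @return the directory, invisibly.
#' @export
write_peak_beds <- function(peaks, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (s in unique(peaks$sample_id)) {
    pk <- peaks[peaks$sample_id == s, , drop = FALSE]
    write_tsv(pk[PEAK_BED_COLS], file.path(dir, paste0(s, ".bed")),
              col.names = FALSE)
  }
  invisible(dir)
}

#' Read peak BED6+ files
#'
#' @param paths one or more files written by [write_peak_beds()].
#' @return one peak data.frame.
#' @export
read_peak_beds <- function(paths) {
  out <- do.call(rbind, lapply(paths, function(p) {
    utils::read.table(p, sep = "\t", stringsAsFactors = FALSE,
                      col.names = PEAK_BED_COLS)
  }))
  rownames(out) <- NULL
  out
}

#' Write a numeric matrix as TSV with row keys
#'
#' @param mat matrix with dimnames.
#' @param path output file; first column is named `key`.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(key = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a matrix TSV written by [write_matrix_tsv()]
#'
#' @param path input file.
#' @return numeric matrix with row and column names.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Write transcript sequences as FASTA
#'
#' @param sequences named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Read transcript sequences from FASTA
#'
#' @param path input file.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(s), names(s))
}

#' Write a conservation track as bedGraph
#'
#' @param track data.frame `chrom`, `start`, `end`, `score` (0-based
#'   half-open).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  write_tsv(track[c("chrom", "start", "end", "score")], path, col.names = FALSE)
}

#' Read a bedGraph conservation track
#'
#' @param path input file.
#' @return data.frame `chrom`, `start`, `end`, `score`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    score = S4Vectors::mcols(gr)$score,
    stringsAsFactors = FALSE
  )
}

#' Write attribution tracks as TSV (site key + 201 offset columns)
#'
#' @param attribution matrix sites x offsets from [simulate_aux_tracks()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_attribution_tsv <- function(attribution, path) {
  write_matrix_tsv(attribution, path)
}

#' Read attribution tracks written by [write_attribution_tsv()]
#'
#' @param path input file.
#' @return matrix sites x offsets.
#' @export
read_attribution_tsv <- function(path) {
  read_matrix_tsv(path)
}

#' Write every artifact of a simulated study to a directory
#'
#' Emits `annotation.gtf`, `transcripts.fa`, `sites.bed`, `peaks/<sample>.bed`,
#' `expression.tsv`, `rbp/<rbp>.bed`, `rbp_expression.tsv`,
#' `conservation.bedgraph`, `attribution.tsv`, `samples.tsv` and `truth.tsv`.
#' Identical studies produce byte-identical files.
#'
#' @param sim a [simulate_study()] result.
#' @param outdir output directory.
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  write_gtf(sim$annotation, file.path(outdir, "annotation.gtf"))
  write_fasta(sim$sequences, file.path(outdir, "transcripts.fa"))
  write_site_bed(sim$catalog, file.path(outdir, "sites.bed"))
  write_peak_beds(sim$peaks, file.path(outdir, "peaks"))
  write_matrix_tsv(sim$expression, file.path(outdir, "expression.tsv"))
  rbp_dir <- file.path(outdir, "rbp")
  if (!dir.exists(rbp_dir)) dir.create(rbp_dir)
  for (r in names(sim$rbp_peaks)) {
    iv <- sim$rbp_peaks[[r]]
    bed <- data.frame(chrom = iv$chrom, start = iv$start, end = iv$end,
                      name = r, score = 0L, strand = ".",
                      stringsAsFactors = FALSE)
    write_tsv(bed, file.path(rbp_dir, paste0(r, ".bed")), col.names = FALSE)
  }
  write_matrix_tsv(sim$rbp_expression, file.path(outdir, "rbp_expression.tsv"))
  write_bedgraph(sim$conservation, file.path(outdir, "conservation.bedgraph"))
  if (!is.null(sim$attribution)) {
    write_attribution_tsv(sim$attribution, file.path(outdir, "attribution.tsv"))
  }
  write_tsv(sim$samples, file.path(outdir, "samples.tsv"))
  write_tsv(sim$truth, file.path(outdir, "truth.tsv"))
  invisible(outdir)
}
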