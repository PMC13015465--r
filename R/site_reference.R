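# technique labels the reference filter understands out of the box
KNOWN_TECHNIQUES <- c(
  "GLORI", "miCLIP", "miCLIP2", "m6A-SAC-seq", "DART-seq", "eTAM-seq",
  "MAZTER-seq", "m6A-REF-seq", "m6A-label-seq", "eTAM"
)

# internal: collapse technique labels to effective methodological categories;
# miCLIP and miCLIP2 share antibody chemistry and count once
effective_categories <- function(techniques) {
  unique(ifelse(techniques %in% c("miCLIP", "miCLIP2"), "miCLIP", techniques))
}

#' Build the high-confidence background site catalog
#'
#' Takes one or more raw single-base site tables, deduplicates them by
#' (chrom, pos, strand) while merging technique support and source sets,
#' annotates transcript regions, and applies the reference filters: at least
#' two effective technique categories (miCLIP and miCLIP2 count as one) and
#' an exonic location (5'UTR, CDS exon or 3'UTR); intronic and intergenic
#' sites are excluded. Filtering is idempotent.
#'
#' @param raw_catalogs a site data.frame or list of them; each needs columns
#'   `chrom`, `pos` (0-based), `strand`, `support` (comma-joined technique
#'   labels) and optionally `source`.
#' @param annotation a [tx_annotation] used for region labels.
#' @param unknown_techniques `"reject"` (default) errors on a technique label
#'   outside the known set; `"category"` keeps it as its own category.
#' @return filtered catalog data.frame with columns `chrom`, `pos`, `strand`,
#'   `site`, `gene_id`, `transcript_id`, `region`, `support`, `source`,
#'   `n_categories`.
#' @export
build_background_catalog <- function(raw_catalogs, annotation,
                                     unknown_techniques = c("reject", "category")) {
  unknown_techniques <- match.arg(unknown_techniques)
  if (is.data.frame(raw_catalogs)) raw_catalogs <- list(raw_catalogs)
  raw <- do.call(rbind, lapply(raw_catalogs, function(x) {
    if (!all(c("chrom", "pos", "strand", "support") %in% names(x))) {
      stop("raw catalogs need chrom, pos, strand, support columns")
    }
    data.frame(
      chrom = x$chrom, pos = as.integer(x$pos), strand = x$strand,
      support = x$support,
      source = if ("source" %in% names(x)) x$source else "unknown",
      stringsAsFactors = FALSE
    )
  }))
  key <- site_key(raw$chrom, raw$pos, raw$strand)
  sp <- split(seq_len(nrow(raw)), key)
  merged <- do.call(rbind, lapply(sp, function(idx) {
    tech <- sort(unique(unlist(strsplit(raw$support[idx], ",", fixed = TRUE))))
    data.frame(
      chrom = raw$chrom[idx[1L]], pos = raw$pos[idx[1L]],
      strand = raw$strand[idx[1L]],
      support = paste(tech, collapse = ","),
      source = paste(sort(unique(raw$source[idx])), collapse = ","),
      stringsAsFactors = FALSE
    )
  }))
  rownames(merged) <- NULL

  tech_list <- strsplit(merged$support, ",", fixed = TRUE)
  if (unknown_techniques == "reject") {
    unk <- setdiff(unique(unlist(tech_list)), KNOWN_TECHNIQUES)
    if (length(unk)) stop("unknown technique label(s): ", paste(unk, collapse = ", "))
  }
  n_cat <- vapply(tech_list, function(t) length(effective_categories(t)), integer(1L))

  reg <- annotate_region(merged, annotation)
  keep <- n_cat >= 2L & reg$region %in% c("5UTR", "CDS_exon", "3UTR")
  out <- merged[keep, , drop = FALSE]
  out$site <- site_key(out$chrom, out$pos, out$strand)
  out$gene_id <- reg$gene_id[keep]
  out$transcript_id <- reg$transcript_id[keep]
  out$region <- reg$region[keep]
  out$n_categories <- n_cat[keep]
  rownames(out) <- NULL
  out[c("chrom", "pos", "strand", "site", "gene_id", "transcript_id",
        "region", "support", "source", "n_categories")]
}

#' Region composition of a site catalog
#'
#' @param catalog data.frame with a `region` column.
#' @return named numeric vector of percentages (sums to 100 up to rounding).
#' @export
region_composition <- function(catalog) {
  tab <- table(catalog$region)
  100 * as.numeric(tab) / sum(tab) -> pct
  stats::setNames(pct, names(tab))
}
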