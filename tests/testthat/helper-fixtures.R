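# Hand-built two-gene annotation used across tests.
# geneP (+): exons [100,200) and [300,500); CDS spans tx offsets 30..219
#   (genomic 130..420), so 5'UTR = 30 nt, CDS = 190 nt, 3'UTR = 80 nt.
# geneM (-): exons [1000,1100) and [1300,1400); transcript runs 3'<-5' in
#   genomic terms, CDS tx offsets 20..159.
tiny_annotation <- function() {
  exons <- data.frame(
    transcript_id = c("tP", "tP", "tM", "tM"),
    gene_id = c("geneP", "geneP", "geneM", "geneM"),
    chrom = "chrT",
    strand = c("+", "+", "-", "-"),
    start = c(100L, 300L, 1000L, 1300L),
    end = c(200L, 500L, 1100L, 1400L),
    stringsAsFactors = FALSE
  )
  # tM 5' end is at genomic 1399; tx offset 20 -> genomic 1379,
  # tx offset 159 -> 100 exon1 bases (1399..1300) + 60 into exon [1000,1100)
  # -> genomic 1040. CDS genomic span [1040, 1380).
  cds <- data.frame(
    transcript_id = c("tP", "tM"),
    start = c(130L, 1040L),
    end = c(420L, 1380L),
    stringsAsFactors = FALSE
  )
  tx_annotation(exons, cds)
}

# small, fast simulation config for unit tests; dots override the shrunken
# defaults
small_config <- function(seed = 11L, ...) {
  args <- list(seed = seed, n_genes = 40L, n_background_sites = 300L,
               rbp_peaks_per_rbp = 60L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulation_config, args)
}

# the default-scale study is expensive; build it once and share
.sim_cache <- new.env(parent = emptyenv())
default_study <- function() {
  if (is.null(.sim_cache$sim)) {
    sim <- simulate_study(simulation_config(seed = 2026L))
    ref <- build_background_catalog(sim$catalog, sim$annotation)
    pk <- qc_filter_peaks(sim$peaks, sim$expression)
    mp <- map_sites_to_peaks(ref, pk, sim$samples)
    calls <- call_tc_sites(mp$detection, sim$samples, n_perm = 1000L, seed = 2026L)
    .sim_cache$sim <- list(sim = sim, ref = ref, peaks = pk, map = mp, calls = calls)
  }
  .sim_cache$sim
}

# independent step-up oracles used to cross-check the adjustment wrappers
brute_by <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  q <- numeric(m)
  prev <- Inf
  for (i in rev(seq_len(m))) {
    prev <- min(prev, p[o[i]] * m * cm / i)
    q[o[i]] <- min(prev, 1)
  }
  q
}
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- Inf
  for (i in rev(seq_len(m))) {
    prev <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- min(prev, 1)
  }
  q
}

# hypergeometric enumeration oracle for the one-sided (greater) Fisher test
brute_fisher_greater <- function(a, b, c_, d) {
  m <- a + b          # class sites
  n <- c_ + d         # other sites
  k <- a + c_         # sites in the reference set
  amax <- min(m, k)
  tot <- choose(m + n, k)
  sum(vapply(a:amax, function(x) choose(m, x) * choose(n, k - x), numeric(1))) / tot
}

# scan oracle for ROI segmentation: collect maximal positive runs, merge,
# then length-filter
brute_roi <- function(track, min_len = 5L, max_gap = 3L) {
  runs <- list()
  i <- 1L
  while (i <= length(track)) {
    if (track[i] > 0) {
      j <- i
      while (j < length(track) && track[j + 1L] > 0) j <- j + 1L
      runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(runs)) return(matrix(integer(0), ncol = 2L))
  merged <- list(runs[[1L]])
  for (r in runs[-1L]) {
    last <- merged[[length(merged)]]
    if (r[1L] - last[2L] - 1L <= max_gap) {
      merged[[length(merged)]] <- c(last[1L], r[2L])
    } else merged[[length(merged) + 1L]] <- r
  }
  keep <- Filter(function(r) (r[2L] - r[1L] + 1L) > min_len, merged)
  if (!length(keep)) return(matrix(integer(0), ncol = 2L))
  do.call(rbind, keep)
}

# exhaustive best single-threshold 1-D partition by within-cluster SSE
brute_threshold_split <- function(x) {
  xs <- sort(x)
  best <- NULL
  best_sse <- Inf
  for (cut in seq_len(length(xs) - 1L)) {
    lo <- xs[seq_len(cut)]
    hi <- xs[-seq_len(cut)]
    sse <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (sse < best_sse) {
      best_sse <- sse
      best <- xs[cut]
    }
  }
  list(threshold = best, sse = best_sse)
}
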