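#' Configuration for the synthetic MeRIP-seq study generator
#'
#' Bundles and validates every knob of the synthetic two-dataset, multi-tissue
#' m6A study. Defaults describe the study design the generator emulates: a
#' planted tissue-conserved (TC) class detected in nearly every sample
#' (`p_detect_conserved = 0.98`), tissue-specific and infrequent classes, a
#' negative coupling between gene-level methylation and expression sized to
#' realize a Spearman correlation near -0.5, RBP binding concentrated at
#' conserved sites (82.5% coverage by the focal RBP), and attribution tracks
#' with planted positive segments at -64..-15 and -98..-91.
#'
#' @param seed integer seed; identical configs produce identical output.
#' @param n_genes number of genes.
#' @param exons_per_gene_range,exon_length_range integer (min, max) ranges.
#' @param n_background_sites total catalog size before reference filtering.
#' @param frac_conserved,frac_tissue_specific,frac_infrequent class fractions
#'   among filter-passing sites; remainder is background-only.
#' @param tissue_panel character vector of tissue names.
#' @param samples_per_tissue named list `tissue -> c(countA, countB)` giving
#'   per-dataset sample counts; default 2 and 2 for every tissue.
#' @param p_detect_conserved,p_detect_specific_home,p_detect_specific_away,p_detect_noise
#'   per-sample Bernoulli detection probabilities by class.
#' @param p_detect_infrequent_home detection probability of infrequent sites in
#'   their home tissues (never detected elsewhere).
#' @param infrequent_home_weights probabilities of an infrequent site having
#'   1, 2 or 3 home tissues.
#' @param meth_high_params,meth_low_params `c(shape, rate)` of the gamma
#'   distributions for enrichment ratios of conserved vs other sites.
#' @param meth_noise_sd sd of the multiplicative log-normal noise on conserved
#'   site methylation across samples.
#' @param expr_coupling slope linking gene mean methylation to log2 expression
#'   (negative couples high methylation to low expression).
#' @param expr_basal_mean,expr_basal_sd basal log2 FPKM distribution.
#' @param expr_noise_sd,expr_noise_sd_conserved per-sample log2 noise sd for
#'   ordinary vs conserved-site-hosting genes.
#' @param rbp_near_prob probability that the focal RBP covers a conserved site.
#' @param n_rbps number of simulated RBPs (first one is the focal RBP).
#' @param rbp_peaks_per_rbp background binding peaks per non-focal RBP.
#' @param attribution_roi_spec list of `c(start_offset, end_offset)` planted
#'   positive attribution segments, offsets in -100..100.
#' @param attribution_noise_sd sd of sub-threshold attribution noise.
#' @param frac_intronic probability a catalog site is placed intronic (fails
#'   the exonic filter).
#' @param frac_single_support probability an exonic site carries fewer than two
#'   effective technique categories (fails the support filter).
#' @param decoy_peak_frac fraction of extra peaks violating one QC rule each.
#' @param motif_fidelity probability a site's 5-mer context is forced to RGACW.
#' @param tc_region_mix,bg_region_mix placement mix over
#'   (3UTR, CDS_exon, 5UTR) for conserved vs other sites.
#' @param cons_base,cons_uplift mean conservation score of ordinary sites and
#'   additive uplift at conserved sites.
#' @param frac_conserved_host_genes fraction of genes eligible to host
#'   conserved clusters.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(
    seed = 1L,
    n_genes = 200L,
    exons_per_gene_range = c(2L, 6L),
    exon_length_range = c(200L, 800L),
    n_background_sites = 2000L,
    frac_conserved = 0.10,
    frac_tissue_specific = 0.15,
    frac_infrequent = 0.15,
    tissue_panel = c("brain", "liver", "lung", "kidney", "heart", "muscle"),
    samples_per_tissue = NULL,
    p_detect_conserved = 0.98,
    p_detect_specific_home = 0.75,
    p_detect_specific_away = 0.02,
    p_detect_noise = 0.02,
    p_detect_infrequent_home = 0.50,
    infrequent_home_weights = c(0.75, 0.17, 0.08),
    meth_high_params = c(shape = 8, rate = 2),
    meth_low_params = c(shape = 2, rate = 2),
    meth_noise_sd = 0.10,
    expr_coupling = -0.5,
    expr_basal_mean = 5,
    expr_basal_sd = 1.05,
    expr_noise_sd = 0.4,
    expr_noise_sd_conserved = 0.2,
    rbp_near_prob = 0.825,
    n_rbps = 5L,
    rbp_peaks_per_rbp = 300L,
    attribution_roi_spec = list(c(-64L, -15L), c(-98L, -91L)),
    attribution_noise_sd = 0.05,
    frac_intronic = 0.05,
    frac_single_support = 0.10,
    decoy_peak_frac = 0.05,
    motif_fidelity = 0.90,
    tc_region_mix = c(`3UTR` = 0.70, CDS_exon = 0.28, `5UTR` = 0.02),
    bg_region_mix = c(`3UTR` = 0.53, CDS_exon = 0.41, `5UTR` = 0.06),
    cons_base = 0.45,
    cons_uplift = 0.35,
    frac_conserved_host_genes = 0.20) {
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  cfg$n_genes <- as.integer(n_genes)
  cfg$exons_per_gene_range <- check_range(exons_per_gene_range, "exons_per_gene_range")
  cfg$exon_length_range <- check_range(exon_length_range, "exon_length_range")
  for (p in c("frac_conserved", "frac_tissue_specific", "frac_infrequent",
              "p_detect_conserved", "p_detect_specific_home",
              "p_detect_specific_away", "p_detect_noise",
              "p_detect_infrequent_home", "rbp_near_prob", "frac_intronic",
              "frac_single_support", "motif_fidelity")) {
    check_prob(cfg[[p]], p)
  }
  if (frac_conserved + frac_tissue_specific + frac_infrequent > 1) {
    stop("class fractions must sum to at most 1")
  }
  if (!length(tissue_panel)) stop("tissue_panel must be nonempty")
  if (is.null(samples_per_tissue)) {
    samples_per_tissue <- stats::setNames(
      rep(list(c(2L, 2L)), length(tissue_panel)), tissue_panel
    )
  }
  if (!all(tissue_panel %in% names(samples_per_tissue))) {
    stop("samples_per_tissue must cover every tissue in the panel")
  }
  cfg$samples_per_tissue <- samples_per_tissue
  for (roi in attribution_roi_spec) {
    if (length(roi) != 2L || roi[1L] > roi[2L] || roi[1L] < -100L || roi[2L] > 100L) {
      stop("attribution_roi_spec segments must be (start, end) within -100..100")
    }
  }
  if (any(meth_high_params <= 0) || any(meth_low_params <= 0)) {
    stop("gamma parameters must be positive")
  }
  structure(cfg, class = "simulation_config")
}

#' Sample sheet implied by a simulation config
#'
#' Deterministic (no random numbers): one row per sample with its dataset
#' (`A`/`B`) and tissue.
#'
#' @param config a [simulation_config].
#' @return data.frame with columns `sample_id`, `dataset`, `tissue`.
#' @export
sample_sheet <- function(config) {
  rows <- list()
  for (tissue in config$tissue_panel) {
    counts <- config$samples_per_tissue[[tissue]]
    for (d in 1:2) {
      ds <- c("A", "B")[d]
      n <- counts[d]
      if (n > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_%s_%d", ds, tissue, seq_len(n)),
          dataset = ds, tissue = tissue, stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate gene/transcript annotation and transcript sequences
#'
#' Lays genes head to tail on a single synthetic chromosome with random
#' strands, partitions each (single-transcript) gene into 5'UTR/CDS/3'UTR and
#' draws a uniform random nucleotide sequence per transcript. Coordinates are
#' 0-based half-open. Uses the current RNG state; seed before calling (or use
#' [simulate_study()]).
#'
#' @param config a [simulation_config].
#' @return list with `annotation` (a [tx_annotation]) and `sequences` (named
#'   character vector of spliced transcript sequences, 5'->3').
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  exr <- config$exons_per_gene_range
  lenr <- config$exon_length_range
  cursor <- 1000L
  ex_rows <- list()
  for (g in seq_len(config$n_genes)) {
    gid <- sprintf("g%04d", g)
    tid <- sprintf("t%04d", g)
    strand <- sample_vec(c("+", "-"), 1L)
    n_ex <- sample_vec(seq(exr[1L], exr[2L]), 1L)
    lens <- sample_vec(seq(lenr[1L], lenr[2L]), n_ex, replace = TRUE)
    introns <- if (n_ex > 1L) sample_vec(100:500, n_ex - 1L, replace = TRUE) else integer(0)
    starts <- cursor + cumsum(c(0L, lens[-n_ex] + introns))
    ex_rows[[g]] <- data.frame(
      transcript_id = tid, gene_id = gid, chrom = "chrS", strand = strand,
      start = starts, end = starts + lens, stringsAsFactors = FALSE
    )
    cursor <- max(starts + lens) + sample_vec(500:2000, 1L)
  }
  exons <- do.call(rbind, ex_rows)
  ann <- tx_annotation(exons)
  tx <- ann$transcripts
  # UTR/CDS split in transcript coordinates, then back to a genomic CDS span
  cds <- data.frame(transcript_id = character(0), start = integer(0), end = integer(0))
  seqs <- character(nrow(tx))
  names(seqs) <- tx$transcript_id
  for (i in seq_len(nrow(tx))) {
    L <- tx$tx_len[i]
    u5 <- max(20L, as.integer(round(0.10 * L)))
    u3 <- max(50L, as.integer(round(0.35 * L)))
    cds_len <- L - u5 - u3
    span <- tx_interval_to_genomic(ann, tx$transcript_id[i], u5, u5 + cds_len - 1L)
    cds <- rbind(cds, data.frame(
      transcript_id = tx$transcript_id[i],
      start = min(span$start), end = max(span$end), stringsAsFactors = FALSE
    ))
    seqs[i] <- paste(sample_vec(c("A", "C", "G", "T"), L, replace = TRUE),
                     collapse = "")
  }
  list(annotation = tx_annotation(exons, cds), sequences = seqs)
}

# internal: one row per exonic position with transcript offset and region
exonic_positions <- function(annotation) {
  tx <- annotation$transcripts
  out <- vector("list", nrow(tx))
  for (i in seq_len(nrow(tx))) {
    ex <- exons_of(annotation, tx$transcript_id[i])
    w <- ex$end - ex$start
    minus <- ex$strand[1L] == "-"
    before <- if (minus) rev(cumsum(c(0L, rev(w)))[seq_len(nrow(ex))]) else
      cumsum(c(0L, w))[seq_len(nrow(ex))]
    pos <- unlist(lapply(seq_len(nrow(ex)), function(k) seq(ex$start[k], ex$end[k] - 1L)))
    off <- unlist(lapply(seq_len(nrow(ex)), function(k) {
      within <- seq_len(w[k]) - 1L
      if (minus) before[k] + (w[k] - 1L - within) else before[k] + within
    }))
    region <- ifelse(off < tx$utr5_len[i], "5UTR",
                     ifelse(off < tx$utr5_len[i] + tx$cds_len[i], "CDS_exon", "3UTR"))
    out[[i]] <- data.frame(
      transcript_id = tx$transcript_id[i], gene_id = tx$gene_id[i],
      chrom = tx$chrom[i], strand = tx$strand[i],
      pos = pos, tx_off = off, region = region, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Simulate the single-base site catalog with planted truth
#'
#' Places `n_background_sites` sites: a binomial share intronic (to exercise
#' the exonic filter) and a share with insufficient technique support (to
#' exercise the two-category filter); the remaining filter-passing sites get
#' class labels in the configured proportions. Conserved sites are laid down
#' in clusters (pairwise within +/-200 bp on one transcript) with a 3'UTR-
#' biased region mix; each site's 5-mer context is forced to RGACW with
#' probability `motif_fidelity`.
#'
#' @param sim_ann output of [simulate_annotation()].
#' @param config a [simulation_config].
#' @return list with `catalog` (site table), `truth` (per-site labels plus a
#'   `genes` attribute with basal expression) and `sequences` (motif-forced).
#' @export
simulate_site_catalog <- function(sim_ann, config) {
  annotation <- sim_ann$annotation
  seqs <- sim_ann$sequences
  pool <- exonic_positions(annotation)
  n <- config$n_background_sites
  n_int <- rbinom(1L, n, config$frac_intronic)
  n_exonic <- n - n_int
  n_single <- rbinom(1L, n_exonic, config$frac_single_support)
  n_pass <- n_exonic - n_single
  n_cons <- as.integer(round(config$frac_conserved * n_pass))
  n_spec <- as.integer(round(config$frac_tissue_specific * n_pass))
  n_inf <- as.integer(round(config$frac_infrequent * n_pass))
  n_bg <- n_pass - n_cons - n_spec - n_inf
  if (n_pass > nrow(pool)) stop("more sites requested than available exonic positions")

  avail <- rep(TRUE, nrow(pool))
  take <- function(idx) { avail[idx] <<- FALSE; idx }

  # conserved clusters on a subset of host genes
  genes <- annotation$genes$gene_id
  hosts <- sample_vec(genes, max(1L, round(config$frac_conserved_host_genes * length(genes))))
  cons_idx <- integer(0)
  cons_clustered <- logical(0)
  mix <- config$tc_region_mix
  while (length(cons_idx) < n_cons) {
    gene <- sample_vec(hosts, 1L)
    region <- sample_vec(names(mix), 1L, prob = mix)
    cand <- which(avail & pool$gene_id == gene & pool$region == region)
    if (!length(cand)) next
    anchor <- sample_vec(cand, 1L)
    k <- min(sample_vec(2:4, 1L), n_cons - length(cons_idx))
    near <- which(avail & pool$transcript_id == pool$transcript_id[anchor] &
                    abs(pool$pos - pool$pos[anchor]) <= 100L)
    got <- if (length(near) <= k) near else
      unique(c(anchor, sample_vec(setdiff(near, anchor), k - 1L)))
    take(got)
    cons_idx <- c(cons_idx, got)
    cons_clustered <- c(cons_clustered, rep(length(got) >= 2L, length(got)))
  }

  # keep other classes out of peak reach (<= 150 bp flanks) of conserved
  # sites, so a conserved peak never covers a differently-labelled site
  if (length(cons_idx)) {
    cons_pos <- pool$pos[cons_idx]
    for (cp in cons_pos) {
      avail[avail & abs(pool$pos - cp) <= 160L] <- FALSE
    }
  }

  # remaining classes: region-weighted draws from what is left
  draw_mix <- function(k, mix) {
    cand <- which(avail)
    if (k > length(cand)) stop("more sites requested than available exonic positions")
    wts <- mix[pool$region[cand]]
    wts <- wts / table(pool$region[cand])[pool$region[cand]]
    wts[is.na(wts)] <- 0
    got <- if (k == 0L) integer(0) else sample_vec(cand, k, prob = as.numeric(wts))
    take(got)
  }
  spec_idx <- draw_mix(n_spec, config$bg_region_mix)
  inf_idx <- draw_mix(n_inf, config$bg_region_mix)
  bg_idx <- draw_mix(n_bg, config$bg_region_mix)
  single_idx <- draw_mix(n_single, config$bg_region_mix)

  exonic <- pool[c(cons_idx, spec_idx, inf_idx, bg_idx, single_idx), , drop = FALSE]
  exonic$class <- c(rep("conserved", length(cons_idx)),
                    rep("tissue_specific", n_spec),
                    rep("infrequent", n_inf),
                    rep("background_only", n_bg),
                    rep("background_only", n_single))
  exonic$clustered <- c(cons_clustered, rep(FALSE, n_spec + n_inf + n_bg + n_single))
  exonic$passes <- c(rep(TRUE, length(cons_idx) + n_spec + n_inf + n_bg),
                     rep(FALSE, n_single))
  single_flag <- c(rep(FALSE, length(cons_idx) + n_spec + n_inf + n_bg),
                   rep(TRUE, n_single))

  # intronic decoys: gene spans minus exonic positions
  if (n_int > 0L) {
    ex <- annotation$exons
    g <- annotation$genes
    intronic <- list()
    for (i in seq_len(nrow(g))) {
      exg <- ex[ex$gene_id == g$gene_id[i], , drop = FALSE]
      all_pos <- seq(g$start[i], g$end[i] - 1L)
      inx <- rep(TRUE, length(all_pos))
      for (k in seq_len(nrow(exg))) {
        inx[all_pos >= exg$start[k] & all_pos < exg$end[k]] <- FALSE
      }
      if (any(inx)) {
        intronic[[length(intronic) + 1L]] <- data.frame(
          gene_id = g$gene_id[i], chrom = g$chrom[i], strand = g$strand[i],
          pos = all_pos[inx], stringsAsFactors = FALSE
        )
      }
    }
    intronic <- do.call(rbind, intronic)
    pick <- intronic[sample.int(nrow(intronic), min(n_int, nrow(intronic))), , drop = FALSE]
    pick$transcript_id <- NA_character_
    pick$tx_off <- NA_integer_
    pick$region <- "intron"
    pick$class <- "background_only"
    pick$clustered <- FALSE
    pick$passes <- FALSE
    single_flag <- c(single_flag, rep(FALSE, nrow(pick)))
    exonic <- rbind(exonic, pick[names(exonic)])
  }
  sites <- exonic
  rownames(sites) <- NULL

  # technique support: >=2 effective categories unless planted as single
  eff_pool <- c("GLORI", "miCLIP*", "m6A-SAC-seq", "DART-seq", "eTAM-seq")
  support <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    if (single_flag[i]) {
      support[i] <- if (runif(1L) < 0.5) "miCLIP,miCLIP2" else
        sample_vec(c("GLORI", "miCLIP", "m6A-SAC-seq", "DART-seq", "eTAM-seq"), 1L)
    } else {
      eff <- sample_vec(eff_pool, sample_vec(2:3, 1L))
      tech <- unlist(lapply(eff, function(e) {
        if (e == "miCLIP*") sample_vec(list("miCLIP", "miCLIP2", c("miCLIP", "miCLIP2")), 1L)[[1L]]
        else e
      }))
      support[i] <- paste(sort(tech), collapse = ",")
    }
  }
  sites$support <- support
  sites$source <- "synthetic"

  # force RGACW context at sites (R = A/G, W = A/T), central A at the site
  for (i in seq_len(nrow(sites))) {
    if (is.na(sites$tx_off[i])) next
    if (runif(1L) >= config$motif_fidelity) next
    L <- nchar(seqs[[sites$transcript_id[i]]])
    o <- sites$tx_off[i]
    if (o < 2L || o > L - 3L) next
    motif <- paste0(sample_vec(c("A", "G"), 1L), "GAC", sample_vec(c("A", "T"), 1L))
    substr(seqs[[sites$transcript_id[i]]], o - 1L, o + 3L) <- motif
  }

  # truth: home tissues, mean methylation, per-gene basal expression
  tissues <- config$tissue_panel
  home <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    home[i] <- switch(
      sites$class[i],
      tissue_specific = sample_vec(tissues, 1L),
      infrequent = paste(sort(sample_vec(
        tissues,
        sample_vec(1:3, 1L, prob = config$infrequent_home_weights)
      )), collapse = ","),
      ""
    )
  }
  # conserved methylation is a per-host-gene set-point: all conserved sites of
  # a gene share one high-distribution draw, so site methylation and the
  # expression coupling below move together
  mean_meth <- rgamma(nrow(sites), config$meth_low_params[["shape"]],
                      config$meth_low_params[["rate"]])
  cons_rows <- which(sites$class == "conserved")
  if (length(cons_rows)) {
    cons_genes <- unique(sites$gene_id[cons_rows])
    gene_level <- stats::setNames(
      rgamma(length(cons_genes), config$meth_high_params[["shape"]],
             config$meth_high_params[["rate"]]),
      cons_genes
    )
    mean_meth[cons_rows] <- gene_level[sites$gene_id[cons_rows]]
  }
  keys <- site_key(sites$chrom, sites$pos, sites$strand)
  truth <- data.frame(
    site = keys, class = sites$class, home_tissues = home,
    mean_meth = mean_meth, clustered = sites$clustered,
    passes_reference_filter = sites$passes, gene_id = sites$gene_id,
    stringsAsFactors = FALSE
  )
  hosts_cons <- unique(sites$gene_id[sites$class == "conserved"])
  gene_truth <- data.frame(
    gene_id = annotation$genes$gene_id,
    basal_expr = rnorm(nrow(annotation$genes), config$expr_basal_mean, config$expr_basal_sd),
    hosts_conserved = annotation$genes$gene_id %in% hosts_cons,
    stringsAsFactors = FALSE
  )
  catalog <- data.frame(
    chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
    site = keys, gene_id = sites$gene_id, transcript_id = sites$transcript_id,
    region = sites$region, tx_off = sites$tx_off, support = sites$support,
    source = sites$source, stringsAsFactors = FALSE
  )
  list(catalog = catalog, truth = truth, gene_truth = gene_truth, sequences = seqs)
}

#' Simulate per-sample MeRIP-seq peak tables
#'
#' Each filter-passing site is detected per sample by a class/tissue-dependent
#' Bernoulli draw; every detection is covered by one peak (< 1000 bp,
#' FDR < 0.05, positive IP/input counts) whose library-normalized IP/input
#' ratio realizes the site's methylation draw. A configurable fraction of
#' decoy peaks violates one QC rule each and carries the rule name in the
#' hidden `qc_violation` column.
#'
#' @param catalog,truth from [simulate_site_catalog()].
#' @param config a [simulation_config].
#' @return list with `peaks` (one table, `sample_id` column) and `samples`
#'   (the [sample_sheet()]).
#' @export
simulate_sample_peaks <- function(catalog, truth, config) {
  samples <- sample_sheet(config)
  if (!nrow(samples)) stop("empty tissue panel")
  pass <- truth$passes_reference_filter
  cat_p <- catalog[pass, , drop = FALSE]
  tru_p <- truth[pass, , drop = FALSE]
  home_list <- strsplit(tru_p$home_tissues, ",", fixed = TRUE)
  genes <- unique(catalog$gene_id)
  peak_rows <- list()
  for (s in seq_len(nrow(samples))) {
    tissue <- samples$tissue[s]
    sid <- samples$sample_id[s]
    ip_lib <- sample_vec(15000000:30000000, 1L)
    input_lib <- sample_vec(15000000:30000000, 1L)
    p <- vapply(seq_len(nrow(tru_p)), function(i) {
      switch(tru_p$class[i],
        conserved = config$p_detect_conserved,
        tissue_specific = if (identical(tru_p$home_tissues[i], tissue))
          config$p_detect_specific_home else config$p_detect_specific_away,
        infrequent = if (tissue %in% home_list[[i]])
          config$p_detect_infrequent_home else 0,
        background_only = config$p_detect_noise
      )
    }, numeric(1L))
    det <- runif(nrow(tru_p)) < p
    idx <- which(det)
    if (!length(idx)) next
    ratio <- ifelse(
      tru_p$class[idx] == "conserved",
      tru_p$mean_meth[idx] * exp(rnorm(length(idx), 0, config$meth_noise_sd)),
      rgamma(length(idx), config$meth_low_params[["shape"]], config$meth_low_params[["rate"]])
    )
    up <- sample_vec(20:150, length(idx), replace = TRUE)
    down <- sample_vec(20:150, length(idx), replace = TRUE)
    input_count <- sample_vec(20:120, length(idx), replace = TRUE)
    ip_count <- pmax(1L, as.integer(round(ratio * input_count * ip_lib / input_lib)))
    pk <- data.frame(
      chrom = cat_p$chrom[idx],
      start = pmax(0L, cat_p$pos[idx] - up),
      end = cat_p$pos[idx] + down + 1L,
      name = sprintf("%s_pk%05d", sid, seq_along(idx)),
      score = 0L,
      strand = cat_p$strand[idx],
      sample_id = sid,
      gene_id = cat_p$gene_id[idx],
      fdr = runif(length(idx), 0, 0.0499),
      ip_count = ip_count,
      input_count = as.integer(input_count),
      ip_libsize = ip_lib,
      input_libsize = input_lib,
      qc_violation = "",
      origin_site = cat_p$site[idx],
      stringsAsFactors = FALSE
    )
    # decoys cycling through the four QC violations
    n_dec <- as.integer(round(config$decoy_peak_frac * length(idx)))
    if (n_dec > 0L) {
      rules <- rep(c("fdr", "length", "zero_input", "multi_gene"), length.out = n_dec)
      di <- sample_vec(seq_len(nrow(cat_p)), n_dec, replace = TRUE)
      dup <- sample_vec(20:150, n_dec, replace = TRUE)
      dec <- data.frame(
        chrom = cat_p$chrom[di],
        start = pmax(0L, cat_p$pos[di] - dup),
        end = cat_p$pos[di] + sample_vec(20:150, n_dec, replace = TRUE) + 1L,
        name = sprintf("%s_dk%05d", sid, seq_len(n_dec)),
        score = 0L,
        strand = cat_p$strand[di],
        sample_id = sid,
        gene_id = cat_p$gene_id[di],
        fdr = runif(n_dec, 0, 0.0499),
        ip_count = sample_vec(10:200, n_dec, replace = TRUE),
        input_count = sample_vec(20:120, n_dec, replace = TRUE),
        ip_libsize = ip_lib,
        input_libsize = input_lib,
        qc_violation = rules,
        origin_site = NA_character_,
        stringsAsFactors = FALSE
      )
      dec$fdr[rules == "fdr"] <- runif(sum(rules == "fdr"), 0.05, 0.5)
      long <- rules == "length"
      dec$end[long] <- dec$start[long] + 1000L + sample_vec(0:500, sum(long), replace = TRUE)
      dec$input_count[rules == "zero_input"] <- 0L
      multi <- which(rules == "multi_gene")
      for (m in multi) {
        other <- sample_vec(setdiff(genes, dec$gene_id[m]), 1L)
        dec$gene_id[m] <- paste(dec$gene_id[m], other, sep = ",")
      }
      pk <- rbind(pk, dec)
    }
    peak_rows[[length(peak_rows) + 1L]] <- pk
  }
  peaks <- do.call(rbind, peak_rows)
  rownames(peaks) <- NULL
  list(peaks = peaks, samples = samples)
}

#' Simulate an FPKM expression matrix coupled to methylation
#'
#' Per gene and sample, log2 FPKM = basal + `expr_coupling` x (gene mean
#' methylation) + Gaussian noise; genes hosting conserved sites get the
#' smaller noise sd so their cross-tissue CV is lower by construction. FPKM is
#' the exponential, hence strictly positive.
#'
#' @param truth,gene_truth from [simulate_site_catalog()].
#' @param config a [simulation_config].
#' @return numeric matrix genes x samples (FPKM).
#' @export
simulate_expression <- function(truth, gene_truth, config) {
  samples <- sample_sheet(config)
  pass <- truth[truth$passes_reference_filter, , drop = FALSE]
  # genes hosting conserved sites are driven by their conserved set-point;
  # other genes by the mean over their (low-distribution) sites
  cons <- pass[pass$class == "conserved", , drop = FALSE]
  mg <- tapply(pass$mean_meth, pass$gene_id, mean)
  if (nrow(cons)) {
    mg_cons <- tapply(cons$mean_meth, cons$gene_id, mean)
    mg[names(mg_cons)] <- mg_cons
  }
  low_mean <- config$meth_low_params[["shape"]] / config$meth_low_params[["rate"]]
  m <- as.numeric(ifelse(is.na(mg[gene_truth$gene_id]), low_mean, mg[gene_truth$gene_id]))
  sd_g <- ifelse(gene_truth$hosts_conserved,
                 config$expr_noise_sd_conserved, config$expr_noise_sd)
  base <- gene_truth$basal_expr + config$expr_coupling * m
  noise <- matrix(rnorm(nrow(gene_truth) * nrow(samples)), nrow(gene_truth)) * sd_g
  fpkm <- 2^(base + noise)
  dimnames(fpkm) <- list(gene_truth$gene_id, samples$sample_id)
  fpkm
}

#' Simulate RBP binding sets, conservation track and attribution tracks
#'
#' The focal RBP (`RBP1`) covers each conserved site with probability
#' `rbp_near_prob` with a short peak (20-80 bp, ~10 bp mean center offset);
#' all RBPs additionally bind uniformly placed exonic positions and carry a
#' few oversize (> 100 bp) decoy peaks. Conservation scores are uplifted at
#' conserved sites. Attribution tracks are strictly non-positive off the
#' planted segments and positive on them.
#'
#' @param catalog,truth from [simulate_site_catalog()].
#' @param config a [simulation_config].
#' @param n_attribution_tracks number of conserved sites given a track.
#' @return list with `rbp_peaks` (named list of interval tables),
#'   `rbp_expression` (FPKM matrix, RBP genes x tissues, including one
#'   inactive and one high-variability control), `conservation` (bedGraph-like
#'   table), `attribution` (matrix sites x 201 offsets) and `focal_rbp`.
#' @export
simulate_aux_tracks <- function(catalog, truth, config, n_attribution_tracks = 100L) {
  if (!nrow(catalog)) stop("catalog is empty")
  for (roi in config$attribution_roi_spec) {
    if (roi[1L] < -100L || roi[2L] > 100L) stop("ROI spec outside the +/-100 bp window")
  }
  cons <- which(truth$class == "conserved")
  rbps <- sprintf("RBP%d", seq_len(config$n_rbps))
  rbp_peaks <- list()
  uniform_peaks <- function(k) {
    ci <- sample_vec(seq_len(nrow(catalog)), k, replace = TRUE)
    len <- sample_vec(20:80, k, replace = TRUE)
    off <- sample_vec(-200:200, k, replace = TRUE)
    start <- pmax(0L, catalog$pos[ci] + off - len %/% 2L)
    data.frame(chrom = catalog$chrom[ci], start = start, end = start + len,
               stringsAsFactors = FALSE)
  }
  cons_pk <- parse_site_key(truth$site[cons])
  cons_pos_sorted <- sort(cons_pk$pos)
  for (r in rbps) {
    pk <- uniform_peaks(config$rbp_peaks_per_rbp)
    if (r == rbps[1L] && length(cons)) {
      # the focal RBP's background peaks stay clear of conserved sites and
      # each targeted peak is clipped at neighbouring conserved sites, so the
      # covered fraction is exactly Bernoulli(rbp_near_prob)
      touches_cons <- vapply(seq_len(nrow(pk)), function(i) {
        any(cons_pk$pos >= pk$start[i] & cons_pk$pos < pk$end[i])
      }, logical(1L))
      pk <- pk[!touches_cons, , drop = FALSE]
      hit <- which(runif(length(cons)) < config$rbp_near_prob)
      if (length(hit)) {
        pos <- cons_pk$pos[hit]
        # center offset spans +/-21 bp (mean |offset| ~ 10.7 bp)
        delta <- sample_vec(-21:21, length(hit), replace = TRUE)
        len <- vapply(delta, function(d) {
          sample_vec(seq(max(2L * abs(d) + 10L, 20L), 80L), 1L)
        }, integer(1L))
        start <- pos + delta - len %/% 2L
        end <- start + len
        prev_idx <- findInterval(pos - 1L, cons_pos_sorted)
        prev_cons <- ifelse(prev_idx == 0L, -1L, cons_pos_sorted[pmax(prev_idx, 1L)])
        nxt_idx <- findInterval(pos, cons_pos_sorted) + 1L
        nxt_cons <- ifelse(nxt_idx > length(cons_pos_sorted), .Machine$integer.max,
                           cons_pos_sorted[pmin(nxt_idx, length(cons_pos_sorted))])
        start <- pmax(start, prev_cons + 1L, 0L)
        end <- pmin(end, nxt_cons)
        near <- data.frame(
          chrom = cons_pk$chrom[hit], start = start, end = end,
          stringsAsFactors = FALSE
        )
        pk <- rbind(near, pk)
      }
    }
    # oversize decoys, removed by the <= 100 bp filter
    big_start <- pk$start[seq_len(3L)] + 5L
    pk <- rbind(pk, data.frame(
      chrom = pk$chrom[seq_len(3L)], start = big_start,
      end = big_start + sample_vec(120:400, 3L, replace = TRUE),
      stringsAsFactors = FALSE
    ))
    pk <- pk[order(pk$chrom, pk$start), , drop = FALSE]
    rownames(pk) <- NULL
    rbp_peaks[[r]] <- pk
  }

  tissues <- config$tissue_panel
  rbp_genes <- c(rbps, "RBPinactive", "RBPvariable")
  expr <- matrix(NA_real_, length(rbp_genes), length(tissues),
                 dimnames = list(rbp_genes, tissues))
  for (r in rbps) expr[r, ] <- 2^rnorm(length(tissues), log2(20), 0.2)
  expr["RBPinactive", ] <- 2^rnorm(length(tissues), -7, 0.3)
  expr["RBPvariable", ] <- 2^rnorm(length(tissues), log2(20), 2)

  score <- ifelse(
    truth$class == "conserved",
    config$cons_base + config$cons_uplift + rnorm(nrow(truth), 0, 0.08),
    config$cons_base + rnorm(nrow(truth), 0, 0.15)
  )
  cons_track <- data.frame(
    chrom = catalog$chrom, start = catalog$pos, end = catalog$pos + 1L,
    score = pmin(1, pmax(0, score)), stringsAsFactors = FALSE
  )
  cons_track <- cons_track[order(cons_track$chrom, cons_track$start), , drop = FALSE]
  rownames(cons_track) <- NULL

  n_tr <- min(n_attribution_tracks, length(cons))
  offsets <- -100:100
  attribution <- NULL
  if (n_tr > 0L) {
    pick <- cons[seq_len(n_tr)]
    in_roi <- rep(FALSE, length(offsets))
    for (roi in config$attribution_roi_spec) {
      in_roi[offsets >= roi[1L] & offsets <= roi[2L]] <- TRUE
    }
    attribution <- matrix(0, n_tr, length(offsets),
                          dimnames = list(truth$site[pick], paste0("off_", offsets)))
    for (i in seq_len(n_tr)) {
      bg <- -abs(rnorm(length(offsets), 0, config$attribution_noise_sd))
      fg <- pmax(0.05, 0.5 + rnorm(length(offsets), 0, config$attribution_noise_sd))
      attribution[i, ] <- ifelse(in_roi, fg, bg)
    }
  }
  list(rbp_peaks = rbp_peaks, rbp_expression = expr, conservation = cons_track,
       attribution = attribution, focal_rbp = rbps[1L])
}

#' Run the whole synthetic study
#'
#' Seeds the RNG from the config and generates annotation, site catalog with
#' truth labels, per-sample peaks, expression and auxiliary tracks in a fixed
#' order, so identical configs give identical output.
#'
#' @param config a [simulation_config].
#' @return list with elements `config`, `annotation`, `sequences`, `catalog`,
#'   `truth`, `gene_truth`, `peaks`, `samples`, `expression`, `rbp_peaks`,
#'   `rbp_expression`, `conservation`, `attribution`, `focal_rbp`.
#' @export
simulate_study <- function(config = simulation_config()) {
  set.seed(config$seed)
  sim_ann <- simulate_annotation(config)
  cat_out <- simulate_site_catalog(sim_ann, config)
  pk <- simulate_sample_peaks(cat_out$catalog, cat_out$truth, config)
  expr <- simulate_expression(cat_out$truth, cat_out$gene_truth, config)
  aux <- simulate_aux_tracks(cat_out$catalog, cat_out$truth, config)
  c(
    list(config = config, annotation = sim_ann$annotation,
         sequences = cat_out$sequences, catalog = cat_out$catalog,
         truth = cat_out$truth, gene_truth = cat_out$gene_truth,
         peaks = pk$peaks, samples = pk$samples, expression = expr),
    aux
  )
}
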