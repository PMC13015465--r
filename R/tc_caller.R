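#' Permutation null for cross-sample site sharing
#'
#' Shuffles site occurrences across samples: per replicate, each sample's
#' detected-site set is redrawn uniformly without replacement from the full
#' catalog, preserving that sample's detection count (column margins). The
#' per-site sample counts of every replicate are pooled into count tallies.
#'
#' @param detection logical matrix sites x samples.
#' @param n_perm number of replicates (>= 1).
#' @param seed integer seed.
#' @return object of class `perm_null`: `tallies` (counts of 0..n_samples),
#'   `n_perm`, `n_samples`, `n_sites`, `seed`.
#' @export
permutation_null <- function(detection, n_perm, seed = 1L) {
  if (!nrow(detection) || !ncol(detection)) stop("detection matrix is empty")
  if (n_perm < 1L) stop("n_perm must be >= 1")
  n_sites <- nrow(detection)
  k <- colSums(detection)
  if (any(k > n_sites)) stop("a sample detects more sites than the catalog holds")
  set.seed(seed)
  tallies <- numeric(ncol(detection) + 1L)
  for (r in seq_len(n_perm)) {
    cnt <- integer(n_sites)
    for (j in seq_along(k)) {
      if (k[j] > 0L) {
        idx <- sample.int(n_sites, k[j])
        cnt[idx] <- cnt[idx] + 1L
      }
    }
    tallies <- tallies + tabulate(cnt + 1L, nbins = ncol(detection) + 1L)
  }
  structure(
    list(tallies = stats::setNames(tallies, 0:ncol(detection)),
         n_perm = as.integer(n_perm), n_samples = ncol(detection),
         n_sites = n_sites, seed = as.integer(seed)),
    class = "perm_null"
  )
}

#' Poisson-binomial upper tail
#'
#' Exact `P(X >= q)` for a sum of independent Bernoulli variables with success
#' probabilities `probs`, by dynamic-programming convolution.
#'
#' @param q integer quantile(s).
#' @param probs Bernoulli probabilities.
#' @return upper-tail probabilities, same length as `q`.
#' @export
poisbinom_tail <- function(q, probs) {
  pmf <- 1
  for (p in probs) pmf <- c(pmf * (1 - p), 0) + c(0, pmf * p)
  tail <- rev(cumsum(rev(pmf)))  # tail[i] = P(X >= i - 1)
  ifelse(q <= 0, 1, ifelse(q > length(probs), 0, tail[pmin(q, length(probs)) + 1L]))
}

#' Per-site sharing p-values
#'
#' Empirical mode compares each site's observed sample count against the
#' pooled permutation tallies with a +1 pseudo-count, so p is always in
#' (0, 1]: `p = (1 + #null >= obs) / (1 + total)`. Analytic mode is the
#' closed-form equivalent: the Poisson-binomial upper tail with
#' `p_j = detection count of sample j / catalog size`.
#'
#' @param detection logical matrix sites x samples.
#' @param null a `perm_null` (required for empirical mode).
#' @param mode `"empirical"` or `"analytic"`.
#' @return data.frame with `site`, `observed`, `p`.
#' @export
site_pvalues <- function(detection, null = NULL, mode = c("empirical", "analytic")) {
  mode <- match.arg(mode)
  obs <- rowSums(detection)
  if (any(obs > ncol(detection))) stop("observed count exceeds the sample count")
  if (mode == "empirical") {
    if (is.null(null)) stop("empirical mode needs a permutation null")
    tallies <- null$tallies
    total <- sum(tallies)
    tail_ge <- rev(cumsum(rev(tallies)))  # tail_ge[c+1] = #null >= c
    p <- (1 + tail_ge[obs + 1L]) / (1 + total)
  } else {
    pj <- colSums(detection) / nrow(detection)
    tail <- poisbinom_tail(0:ncol(detection), pj)
    p <- tail[obs + 1L]
    p[obs == 0L] <- 1
    p <- pmin(pmax(p, .Machine$double.xmin), 1)
  }
  data.frame(site = rownames(detection), observed = as.integer(obs), p = as.numeric(p),
             stringsAsFactors = FALSE)
}

#' Benjamini-Yekutieli adjustment
#'
#' Step-up FDR control valid under arbitrary dependence:
#' `q_(i) = min_{j >= i} p_(j) * m * c(m) / j`, `c(m) = sum_{k=1}^m 1/k`,
#' capped at 1.
#'
#' @param pvals p-values in (0, 1].
#' @return adjusted values, order-preserving.
#' @export
by_adjust <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (any(pvals <= 0 | pvals > 1)) stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvals, method = "BY")
}

#' Classify catalog sites from two-dataset sharing results
#'
#' Per dataset a site is "significantly shared" iff its BY-adjusted q is below
#' `q_thresh` AND it is detected in every tissue of that dataset. Labels:
#' `TC` = significantly shared in both datasets (hence present in all tissues
#' overall); `infrequent` = detected in 1..`infreq_max_tissues` distinct
#' tissue types pooled across datasets and not TC; `shared` = q below
#' threshold in both datasets without full tissue coverage; everything else
#' `background`.
#'
#' @param results_A,results_B data.frames from [site_pvalues()] with a `q`
#'   column added, computed per dataset on the same catalog.
#' @param detection logical matrix sites x samples (both datasets).
#' @param samples sample sheet.
#' @param q_thresh significance threshold on q (default 0.01).
#' @param infreq_max_tissues pooled tissue-count ceiling for the infrequent
#'   class (default 3).
#' @return data.frame: `site`, `count`, `tissues_A`, `tissues_B`,
#'   `tissues_pooled`, `p_A`, `q_A`, `p_B`, `q_B`, `label`.
#' @export
classify_sites <- function(results_A, results_B, detection, samples,
                           q_thresh = 0.01, infreq_max_tissues = 3L) {
  if (!identical(sort(results_A$site), sort(results_B$site))) {
    stop("the two result sets cover different catalogs")
  }
  if (!all(colnames(detection) %in% samples$sample_id)) {
    stop("detection columns missing from the sample sheet")
  }
  sites <- rownames(detection)
  results_A <- results_A[match(sites, results_A$site), , drop = FALSE]
  results_B <- results_B[match(sites, results_B$site), , drop = FALSE]

  tissue_of <- samples$tissue[match(colnames(detection), samples$sample_id)]
  ds_of <- samples$dataset[match(colnames(detection), samples$sample_id)]
  tissues_in <- function(ds) sort(unique(samples$tissue[samples$dataset == ds]))
  n_tissues_detected <- function(cols) {
    sub <- detection[, cols, drop = FALSE]
    apply(sub, 1L, function(row) length(unique(tissue_of[cols][row])))
  }
  colA <- which(ds_of == "A")
  colB <- which(ds_of == "B")
  tis_A <- n_tissues_detected(colA)
  tis_B <- n_tissues_detected(colB)
  tis_pool <- apply(detection, 1L, function(row) length(unique(tissue_of[row])))

  shared_A <- results_A$q < q_thresh & tis_A == length(tissues_in("A"))
  shared_B <- results_B$q < q_thresh & tis_B == length(tissues_in("B"))
  tc <- shared_A & shared_B
  infreq <- !tc & tis_pool >= 1L & tis_pool <= infreq_max_tissues
  sig_both <- !tc & !infreq & results_A$q < q_thresh & results_B$q < q_thresh
  label <- ifelse(tc, "TC", ifelse(infreq, "infrequent",
                                   ifelse(sig_both, "shared", "background")))
  data.frame(
    site = sites, count = as.integer(rowSums(detection)),
    tissues_A = as.integer(tis_A), tissues_B = as.integer(tis_B),
    tissues_pooled = as.integer(tis_pool),
    p_A = results_A$p, q_A = results_A$q,
    p_B = results_B$p, q_B = results_B$q,
    label = label, stringsAsFactors = FALSE
  )
}

#' One-call TC site discovery
#'
#' Runs the per-dataset permutation null (seeds `seed` and `seed + 1`),
#' empirical or analytic p-values, BY adjustment and the final
#' classification.
#'
#' @param detection logical matrix sites x samples.
#' @param samples sample sheet.
#' @param n_perm permutation replicates per dataset.
#' @param seed integer seed.
#' @param mode `"empirical"` or `"analytic"`.
#' @param q_thresh,infreq_max_tissues passed to [classify_sites()].
#' @return the [classify_sites()] data.frame.
#' @export
call_tc_sites <- function(detection, samples, n_perm = 1000L, seed = 1L,
                          mode = c("empirical", "analytic"),
                          q_thresh = 0.01, infreq_max_tissues = 3L) {
  mode <- match.arg(mode)
  res <- list()
  for (i in 1:2) {
    ds <- c("A", "B")[i]
    cols <- samples$sample_id[samples$dataset == ds]
    sub <- detection[, cols, drop = FALSE]
    nul <- if (mode == "empirical") {
      permutation_null(sub, n_perm, seed = seed + i - 1L)
    }
    r <- site_pvalues(sub, nul, mode)
    r$q <- by_adjust(r$p)
    res[[ds]] <- r
  }
  classify_sites(res$A, res$B, detection, samples,
                 q_thresh = q_thresh, infreq_max_tissues = infreq_max_tissues)
}
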