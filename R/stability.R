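#' Cosine similarity of two non-negative vectors
#'
#' @param u,v numeric vectors of equal length.
#' @return cosine similarity (NA when either vector is all-zero).
#' @export
cosine_similarity <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(NA_real_)
  sum(u * v) / (nu * nv)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Average ranks for ties; exact enumeration when the two samples together
#' hold at most 12 untied values, otherwise the normal approximation with tie
#' correction and continuity correction. Two groups that are identical
#' constants give p = 1 by convention.
#'
#' @param x,y nonempty numeric vectors.
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (x relative to y).
#' @return list with `U` (Mann-Whitney statistic of `x`) and `p`.
#' @export
rank_sum_test <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("both groups must be nonempty")
  r <- rank(c(x, y))
  u <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  if (length(unique(c(x, y))) == 1L) {
    return(list(U = u, p = 1))
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = alternative,
    exact = (length(x) + length(y) <= 12L) && !ties,
    correct = TRUE
  ))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Cross-tissue stability of a site-level matrix
#'
#' Collapses samples to per-tissue mean profiles, then contrasts observed
#' statistics with a shuffle null: observed = cosine similarity of every
#' unordered tissue pair (site vectors, NA treated as 0) and the per-site
#' standard deviation across tissue means (sites with >= 2 covered tissues);
#' null = the same statistics after independently permuting site labels
#' within each tissue profile, `n_null` times. One-sided rank-sum p-values
#' test for higher-than-null cosine and lower-than-null SD.
#'
#' @param matrix numeric matrix sites x samples, NA where undetected.
#' @param tissue_of_sample tissue per column.
#' @param n_null shuffle replicates.
#' @param seed integer seed.
#' @return list with `observed_cosine`, `null_cosine`, `observed_sd`,
#'   `null_sd`, `p_cosine_greater`, `p_sd_less`, `tissue_means`.
#' @export
stability_profile <- function(matrix, tissue_of_sample, n_null = 100L, seed = 1L) {
  tissues <- unique(tissue_of_sample)
  if (length(tissues) < 2L) stop("at least two tissues are required")
  tm <- vapply(tissues, function(t) {
    rowMeans(matrix[, tissue_of_sample == t, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(matrix)))
  tm <- base::matrix(tm, nrow = nrow(matrix),
                     dimnames = list(rownames(matrix), tissues))
  tm[is.nan(tm)] <- NA_real_
  tm0 <- tm; tm0[is.na(tm0)] <- 0
  pairs <- utils::combn(length(tissues), 2L)
  pair_cos <- function(m) {
    apply(pairs, 2L, function(pr) cosine_similarity(m[, pr[1L]], m[, pr[2L]]))
  }
  site_sd <- function(m) {
    ok <- rowSums(!is.na(m)) >= 2L
    out <- rep(NA_real_, nrow(m))
    out[ok] <- apply(m[ok, , drop = FALSE], 1L, stats::sd, na.rm = TRUE)
    out
  }
  obs_cos <- pair_cos(tm0)
  obs_sd <- site_sd(tm)
  set.seed(seed)
  null_cos <- numeric(0)
  null_sd <- numeric(0)
  for (r in seq_len(n_null)) {
    perm <- apply(tm, 2L, function(col) col[sample.int(nrow(tm))])
    perm <- base::matrix(perm, nrow = nrow(tm))
    perm0 <- perm; perm0[is.na(perm0)] <- 0
    null_cos <- c(null_cos, pair_cos(perm0))
    null_sd <- c(null_sd, site_sd(perm))
  }
  list(
    observed_cosine = obs_cos, null_cosine = null_cos,
    observed_sd = obs_sd, null_sd = null_sd,
    p_cosine_greater = rank_sum_test(obs_cos[!is.na(obs_cos)],
                                     null_cos[!is.na(null_cos)], "greater")$p,
    p_sd_less = rank_sum_test(obs_sd[!is.na(obs_sd)],
                              null_sd[!is.na(null_sd)], "less")$p,
    tissue_means = tm
  )
}

#' Coefficient of variation per gene across tissues
#'
#' Observations are per-tissue means over that tissue's samples; CV is the
#' sample (n-1) standard deviation divided by the mean. Genes with zero mean
#' get NA (undefined), flagged via the `undefined` attribute.
#'
#' @param expression non-negative matrix genes x samples.
#' @param groups tissue per column.
#' @return named numeric vector of CVs.
#' @export
cv_per_gene <- function(expression, groups) {
  tissues <- unique(groups)
  if (length(tissues) < 2L) stop("at least two tissues are required")
  tm <- vapply(tissues, function(t) {
    rowMeans(expression[, groups == t, drop = FALSE])
  }, numeric(nrow(expression)))
  tm <- matrix(tm, nrow = nrow(expression),
               dimnames = list(rownames(expression), tissues))
  mu <- rowMeans(tm)
  cv <- apply(tm, 1L, stats::sd) / mu
  cv[mu == 0] <- NA_real_
  attr(cv, "undefined") <- which(mu == 0)
  cv
}

#' Spearman correlation between site methylation and host-gene expression
#'
#' Pairs every detected (site, sample) methylation value with the host gene's
#' expression in the same sample; Spearman with average-rank ties and a
#' large-sample normal p-value (`z = rho * sqrt(n - 1)`).
#'
#' @param methylation matrix sites x samples (NA where undetected).
#' @param expression matrix genes x samples.
#' @param site_to_gene named character vector, site key -> gene id.
#' @return list with `rho`, `p`, `n_pairs`; `rho` is NA (flagged) when either
#'   pair member is constant.
#' @export
methylation_expression_correlation <- function(methylation, expression, site_to_gene) {
  genes <- site_to_gene[rownames(methylation)]
  usable <- !is.na(genes) & genes %in% rownames(expression)
  common <- intersect(colnames(methylation), colnames(expression))
  m <- methylation[usable, common, drop = FALSE]
  e <- expression[genes[usable], common, drop = FALSE]
  keep <- !is.na(m)
  x <- m[keep]; y <- e[keep]
  if (length(x) < 3L) stop("fewer than 3 (site, sample) pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    return(list(rho = NA_real_, p = NA_real_, n_pairs = length(x)))
  }
  rho <- stats::cor(rank(x), rank(y))
  z <- rho * sqrt(length(x) - 1)
  list(rho = rho, p = 2 * stats::pnorm(-abs(z)), n_pairs = length(x))
}

#' Stratify sites into high/low methylation clusters
#'
#' One-dimensional two-cluster k-means: because an optimal 2-means partition
#' on the line is always a threshold partition, the within-cluster
#' sum-of-squares objective is minimized exactly by a prefix-sum scan over
#' the n - 1 sorted splits. This is deterministic (no initialization, no
#' iteration-order effects; SSE ties break at the lowest threshold) and
#' coincides with converged Lloyd iterations wherever those reach the global
#' optimum. The cluster with the higher center is `high`.
#'
#' @param mean_methylation numeric vector (>= 2 distinct values) of per-site
#'   average methylation.
#' @param seed unused (the solution is deterministic); kept so callers can
#'   treat all stratifiers uniformly.
#' @return list with `label` (character `"high"`/`"low"` per site),
#'   `centers` (named low/high cluster means) and `threshold` (largest value
#'   assigned to the low cluster).
#' @export
stratify_clusters <- function(mean_methylation, seed = NULL) {
  x <- mean_methylation
  if (length(unique(x)) < 2L) stop("constant input cannot be stratified")
  xs <- sort(x)
  n <- length(xs)
  cs <- cumsum(xs)
  cs2 <- cumsum(xs^2)
  k <- seq_len(n - 1L)
  sse_lo <- cs2[k] - cs[k]^2 / k
  sse_hi <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  cut <- which.min(sse_lo + sse_hi)
  thr <- xs[cut]
  label <- ifelse(x <= thr, "low", "high")
  names(label) <- names(x)
  list(
    label = label,
    centers = c(low = mean(x[x <= thr]), high = mean(x[x > thr])),
    threshold = thr
  )
}
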