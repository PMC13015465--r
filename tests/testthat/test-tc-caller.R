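random_detection <- function(n_sites, n_samples, p, seed) {
  set.seed(seed)
  matrix(runif(n_sites * n_samples) < p, n_sites, n_samples,
         dimnames = list(sprintf("s%03d", seq_len(n_sites)),
                         sprintf("c%02d", seq_len(n_samples))))
}

test_that("permutation null preserves margins and degenerate cases", {
  # every sample detects every site: all null counts equal the sample count
  det <- matrix(TRUE, 10L, 4L, dimnames = list(letters[1:10], LETTERS[1:4]))
  nul <- permutation_null(det, n_perm = 5L, seed = 1L)
  expect_equal(unname(nul$tallies[["4"]]), 50)
  expect_equal(sum(nul$tallies), 5 * 10)

  # a sample with zero detections contributes nothing anywhere
  det0 <- det; det0[, 1L] <- FALSE
  nul0 <- permutation_null(det0, n_perm = 5L, seed = 1L)
  expect_equal(unname(nul0$tallies[["3"]]), 50)
  expect_equal(unname(nul0$tallies[["4"]]), 0)

  # tallies always pool n_perm draws of the whole catalog
  det_r <- random_detection(50L, 6L, 0.3, seed = 2L)
  nul_r <- permutation_null(det_r, n_perm = 20L, seed = 3L)
  expect_equal(sum(nul_r$tallies), 20 * 50)
})

test_that("Poisson-binomial tail matches exhaustive enumeration", {
  set.seed(7L)
  for (rep in 1:5) {
    n <- sample(2:8, 1L)
    probs <- runif(n)
    # enumerate all 2^n outcomes
    outcomes <- expand.grid(rep(list(0:1), n))
    pr <- apply(outcomes, 1L, function(o) prod(ifelse(o == 1, probs, 1 - probs)))
    counts <- rowSums(outcomes)
    for (q in 0:n) {
      expect_equal(poisbinom_tail(q, probs), sum(pr[counts >= q]),
                   tolerance = 1e-12)
    }
  }
  # three fair coins, all heads: closed form 0.5^3
  expect_equal(poisbinom_tail(3, rep(0.5, 3)), 0.125)
})

test_that("empirical and analytic p-values agree within Monte Carlo error", {
  det <- random_detection(20L, 5L, 0.4, seed = 11L)
  nul <- permutation_null(det, n_perm = 10000L, seed = 12L)
  emp <- site_pvalues(det, nul, mode = "empirical")
  ana <- site_pvalues(det, mode = "analytic")
  n_draws <- sum(nul$tallies)
  se <- sqrt(ana$p * (1 - ana$p) / n_draws)
  expect_true(all(abs(emp$p - ana$p) <= 3 * se + 1e-8))

  # observed zero gives p = 1 under either mode
  det0 <- det; det0[1L, ] <- FALSE
  nul0 <- permutation_null(det0, n_perm = 100L, seed = 1L)
  expect_equal(site_pvalues(det0, nul0, "empirical")$p[1L], 1)
  expect_equal(site_pvalues(det0, mode = "analytic")$p[1L], 1)
})

test_that("p-values never increase with the observed sample count", {
  det <- random_detection(100L, 8L, 0.3, seed = 21L)
  nul <- permutation_null(det, n_perm = 200L, seed = 22L)
  for (mode in c("empirical", "analytic")) {
    res <- site_pvalues(det, nul, mode)
    ord <- order(res$observed)
    expect_true(all(diff(res$p[ord]) <= 1e-12))
  }
})

test_that("BY adjustment equals the step-up definition", {
  expect_equal(by_adjust(0.02), 0.02)
  expect_equal(by_adjust(c(0.01, 0.02, 0.03)), rep(0.055, 3L))
  expect_equal(by_adjust(rep(1, 5L)), rep(1, 5L))
  expect_error(by_adjust(c(0.5, 0)), "0, 1")
  set.seed(31L)
  for (i in 1:1000) {
    p <- runif(sample(1:30, 1L))
    expect_equal(by_adjust(p), brute_by(p), tolerance = 1e-12)
  }
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(p.adjust(c(0.01, 0.04, 0.03), "BH"), c(0.03, 0.04, 0.04))
  set.seed(32L)
  for (i in 1:1000) {
    p <- runif(sample(1:30, 1L))
    expect_equal(p.adjust(p, "BH"), brute_bh(p), tolerance = 1e-12)
  }
})

test_that("labels follow TC, infrequent, shared, background precedence", {
  tissues <- paste0("t", 1:4)
  samples <- data.frame(
    sample_id = c(paste0("A_", tissues), paste0("B_", tissues)),
    dataset = rep(c("A", "B"), each = 4L),
    tissue = rep(tissues, 2L)
  )
  det <- rbind(
    tc = rep(TRUE, 8L),                                   # everywhere
    infreq = c(TRUE, rep(FALSE, 3L), TRUE, rep(FALSE, 3L)),  # one tissue
    a_only = c(rep(TRUE, 4L), rep(FALSE, 4L)),            # all of A, no B
    part_b = c(rep(TRUE, 4L), TRUE, TRUE, TRUE, FALSE),   # missing one B tissue
    none = rep(FALSE, 8L)
  )
  colnames(det) <- samples$sample_id
  res <- function(q) data.frame(site = rownames(det), observed = rowSums(det),
                                p = q, q = q, stringsAsFactors = FALSE)
  qa <- c(0.001, 0.5, 0.001, 0.001, 1)
  qb <- c(0.001, 0.5, 0.5, 0.001, 1)
  out <- classify_sites(res(qa), res(qb), det, samples)
  # significant in A only with > 3 pooled tissues falls through to background;
  # significant in both without full B coverage is "shared"
  expect_equal(out$label,
               c("TC", "infrequent", "background", "shared", "background"))
  expect_equal(out$tissues_A[out$site == "a_only"], 4L)
  expect_equal(out$tissues_B[out$site == "a_only"], 0L)
  expect_equal(out$tissues_pooled[out$site == "infreq"], 1L)
})

test_that("detection in exactly three pooled tissues is infrequent", {
  samples <- data.frame(
    sample_id = c("A_t1", "A_t2", "A_t3", "A_t4", "B_t1"),
    dataset = c("A", "A", "A", "A", "B"),
    tissue = c("t1", "t2", "t3", "t4", "t1")
  )
  det <- matrix(c(TRUE, TRUE, TRUE, FALSE, TRUE), 1L,
                dimnames = list("x", samples$sample_id))
  r <- data.frame(site = "x", observed = 4L, p = 0.5, q = 0.5)
  out <- classify_sites(r, r, det, samples)
  expect_equal(out$tissues_pooled, 3L)
  expect_equal(out$label, "infrequent")
})

test_that("empirical p-values are super-uniform on random detection", {
  det <- random_detection(400L, 10L, 0.3, seed = 41L)
  nul <- permutation_null(det, n_perm = 400L, seed = 42L)
  res <- site_pvalues(det, nul, "empirical")
  for (alpha in c(0.01, 0.05, 0.1)) {
    se <- sqrt(alpha * (1 - alpha) / nrow(det))
    expect_lte(mean(res$p <= alpha), alpha + 3 * se)
  }
})
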