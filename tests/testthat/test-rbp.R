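test_that("zFPKM centers the expressed-peak mode and is monotone", {
  set.seed(1L)
  lg <- rnorm(5000L, 5, 1)
  fpkm <- setNames(2^lg, sprintf("g%04d", seq_along(lg)))
  z <- zfpkm_transform(fpkm)
  probe <- which.min(abs(lg - 5))
  expect_lt(abs(z[probe]), 0.1)
  expect_true(all(diff(z[order(fpkm)]) >= 0))
  # a silent gene sits far in the left tail
  z0 <- zfpkm_transform(c(fpkm, silent = 0))
  expect_lt(z0["silent"], -3)
  expect_error(zfpkm_transform(rep(4, 10L)), "constant")
  expect_error(zfpkm_transform(c(-1, 2)), "non-negative")
})

test_that("RBP filtering enforces activity, consistency and peak length", {
  set.seed(2L)
  tissues <- paste0("t", 1:6)
  backdrop <- matrix(2^rnorm(300L * 6L, 5, 1), 300L, 6L,
                     dimnames = list(sprintf("g%03d", 1:300), tissues))
  expr <- rbind(
    backdrop,
    active = 2^rnorm(6L, 4.3, 0.1),
    silent = 2^rnorm(6L, -7, 0.1),
    wobbly = 2^(c(12, -6, 12, -6, 12, -6))
  )
  iv <- data.frame(chrom = "c", start = c(0L, 200L, 400L),
                   end = c(100L, 301L, 500L))  # lengths 100, 101, 100
  bindings <- list(active = iv, silent = iv, wobbly = iv, ghost = iv)
  expect_warning(out <- filter_rbps(expr, bindings), "ghost")
  expect_equal(names(out), "active")
  # length exactly 100 retained, 101 dropped
  expect_equal(nrow(out$active), 2L)
  expect_equal(out$active$center, c(50L, 450L))
})

test_that("site binding respects overlap, windows and nearest centers", {
  sites <- data.frame(chrom = "c", pos = c(110L, 500L), strand = c("+", "-"),
                      site = c("a", "b"), stringsAsFactors = FALSE)
  iv <- data.frame(chrom = "c", start = 100L, end = 140L)
  ov <- bind_sites(sites, iv)
  expect_equal(ov$bound, c(TRUE, FALSE))
  expect_equal(ov$distance, c(10, NA))

  # two covering peaks: the nearer center wins
  iv2 <- rbind(iv, data.frame(chrom = "c", start = 104L, end = 124L))
  expect_equal(bind_sites(sites, iv2)$distance[1L], 4)

  # window mode keys on center distance, not overlap
  far <- data.frame(chrom = "c", start = 130L, end = 160L)  # center 145
  expect_false(bind_sites(sites, far, mode = "overlap")$bound[1L])
  expect_true(bind_sites(sites, far, mode = "window", window = 50L)$bound[1L])
  expect_false(bind_sites(sites, far, mode = "window", window = 20L)$bound[1L])

  # overlap distances ignore strand
  flipped <- sites; flipped$strand <- c("-", "+")
  expect_equal(bind_sites(flipped, iv2)$distance, bind_sites(sites, iv2)$distance)
})

test_that("per-RBP Fisher enrichment is one-sided greater with BH control", {
  equal <- rbp_fisher(
    class_bound = list(r1 = rep(c(TRUE, FALSE), 10L)),
    background_bound = list(r1 = rep(c(TRUE, FALSE), 10L))
  )
  expect_equal(equal$odds_ratio, 1)
  expect_gt(equal$fdr, 0.5)

  sep <- rbp_fisher(
    class_bound = list(r1 = rep(TRUE, 10L)),
    background_bound = list(r1 = rep(FALSE, 10L)),
    class_distance = list(r1 = rep(7, 10L))
  )
  expect_equal(sep$p, 1 / choose(20, 10), tolerance = 1e-12)
  expect_equal(sep$mean_distance, 7)
  expect_error(rbp_fisher(list(r1 = TRUE), list(r1 = logical(0))), "empty")
})

test_that("ROI windows reflect across strands and drive cluster contrasts", {
  # plus strand site at 1000 with ROI -64..-15 covers [936, 986)
  hi <- data.frame(chrom = "c", pos = 1000L, strand = "+", site = "p",
                   stringsAsFactors = FALSE)
  lo <- data.frame(chrom = "c", pos = 5000L, strand = "+", site = "q",
                   stringsAsFactors = FALSE)
  at_936 <- list(r1 = data.frame(chrom = "c", start = 930L, end = 937L))
  at_986 <- list(r1 = data.frame(chrom = "c", start = 986L, end = 990L))
  expect_equal(roi_window_enrichment(hi, lo, at_936, c(-64L, -15L))$a, 1L)
  expect_equal(roi_window_enrichment(hi, lo, at_986, c(-64L, -15L))$a, 0L)

  # minus strand: same ROI maps to [1015, 1065)
  him <- hi; him$strand <- "-"
  at_1015 <- list(r1 = data.frame(chrom = "c", start = 1010L, end = 1016L))
  at_1065 <- list(r1 = data.frame(chrom = "c", start = 1065L, end = 1070L))
  expect_equal(roi_window_enrichment(him, lo, at_1015, c(-64L, -15L))$a, 1L)
  expect_equal(roi_window_enrichment(him, lo, at_1065, c(-64L, -15L))$a, 0L)

  none <- list(r1 = data.frame(chrom = character(0), start = integer(0),
                               end = integer(0)))
  res <- roi_window_enrichment(hi, lo, none, c(-64L, -15L))
  expect_equal(res$a + res$c, 0L)
  expect_gt(res$fdr, 0.99)
  expect_error(roi_window_enrichment(hi, lo, at_936, c(-10L, -20L)), "length")
})

test_that("gene-set DE enrichment uses strict DE cutoffs", {
  de <- data.frame(
    gene = sprintf("g%02d", 1:10),
    log2fc = c(2, -2, 1.5, 1.0, 0.2, 2.5, 0.1, -1.2, 0.3, 0.9),
    padj = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.2, 0.6, 0.03, 0.5, 0.04)
  )
  # DE genes: |lfc| > 1 (strictly) and padj < 0.05 -> g01, g02, g03, g08
  gs <- c("g01", "g02", "g03", "g04")
  out <- gene_set_enrichment(gs, de)
  expect_equal(out$a, 3L)
  expect_equal(out$c, 1L)
  expect_equal(out$p, brute_fisher_greater(3L, 1L, 1L, 5L), tolerance = 1e-10)
  # log2fc exactly 1 with tiny padj is still not DE
  expect_equal(out$b, 1L)
  expect_error(gene_set_enrichment("missing", de), "disjoint")

  cohorts <- list(c1 = de, c2 = de)
  multi <- gene_set_enrichment(gs, cohorts)
  expect_equal(nrow(multi), 2L)
  expect_equal(multi$fdr, p.adjust(multi$p, "BH"))
})

test_that("the planted focal RBP dominates the enrichment ranking", {
  st <- default_study()
  sim <- st$sim
  tc <- st$calls$site[st$calls$label == "TC"]
  bg <- st$calls$site[st$calls$label == "background"]
  tc_df <- st$ref[match(tc, st$ref$site), ]
  bg_df <- st$ref[match(bg, st$ref$site), ]
  cb <- lapply(sim$rbp_peaks, function(iv) bind_sites(tc_df, iv)$bound)
  bb <- lapply(sim$rbp_peaks, function(iv) bind_sites(bg_df, iv)$bound)
  res <- rbp_fisher(cb, bb)
  expect_equal(res$rbp[1L], sim$focal_rbp)
  expect_lt(res$fdr[1L], 1e-10)
  expect_gt(min(res$fdr[-1L]), res$fdr[1L])
})
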