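test_that("neighbor counting is same-class, same-transcript and windowed", {
  sites <- data.frame(
    site = c("a", "b", "c", "d", "e"),
    pos = c(0L, 100L, 300L, 10L, 100L),
    transcript_id = c("t1", "t1", "t1", "t1", "t2"),
    class = c("TC", "TC", "TC", "infrequent", "TC"),
    stringsAsFactors = FALSE
  )
  expect_equal(neighbor_counts(sites, 200L), c(1L, 2L, 1L, 0L, 0L))
  expect_equal(neighbor_counts(sites, 25L), c(0L, 0L, 0L, 0L, 0L))
  # a different-class site 10 bp away is never counted
  expect_equal(neighbor_counts(sites, 200L)[1L], 1L)
  # missing transcript assignment warns and yields NA
  sites$transcript_id[5L] <- NA
  expect_warning(nc <- neighbor_counts(sites, 200L), "transcript")
  expect_true(is.na(nc[5L]))
})

test_that("neighbor counts are symmetric and window-monotone", {
  set.seed(5L)
  sites <- data.frame(
    site = sprintf("s%d", 1:60),
    pos = sample.int(2000L, 60L),
    transcript_id = sample(c("t1", "t2"), 60L, replace = TRUE),
    class = sample(c("x", "y"), 60L, replace = TRUE),
    stringsAsFactors = FALSE
  )
  n50 <- neighbor_counts(sites, 50L)
  n200 <- neighbor_counts(sites, 200L)
  expect_true(all(n200 >= n50))
  # symmetry: b counts a whenever a counts b, so group totals are even
  for (w in c(50L, 200L)) {
    nc <- neighbor_counts(sites, w)
    for (g in split(nc, paste(sites$transcript_id, sites$class))) {
      expect_equal(sum(g) %% 2L, 0L)
    }
  }
})

test_that("IUPAC motif matching anchors the methylated A", {
  expect_true(motif_match("GGACU", "DRACH", center_offset = 3L))
  expect_false(motif_match("GCACU", "RGACW", center_offset = 3L))
  expect_true(motif_match("AGACA", "RGACW", center_offset = 3L))
  # T and U are interchangeable
  expect_true(motif_match("GGACT", "DRACH", center_offset = 3L))
  expect_error(motif_match("GGACU", "DRXCH", center_offset = 3L), "non-IUPAC")
  expect_error(motif_match("GA", "DRACH", center_offset = 1L), "span")
  # default anchor is the window midpoint
  expect_true(motif_match("TTGGACUTT", "DRACH"))
})

test_that("exon rank runs 5' to 3' regardless of strand", {
  exons <- data.frame(
    transcript_id = "t4", gene_id = "g", chrom = "c", strand = "+",
    start = c(0L, 100L, 200L, 300L), end = c(50L, 150L, 250L, 350L)
  )
  ann <- tx_annotation(exons)
  expect_equal(exon_context(210L, "t4", ann)$rank, 0.75)
  expect_equal(exon_context(210L, "t4", ann)$exon_length, 50L)

  single <- tx_annotation(data.frame(
    transcript_id = "t1", gene_id = "g", chrom = "c", strand = "+",
    start = 0L, end = 100L
  ))
  expect_equal(exon_context(10L, "t1", single)$rank, 1)

  # minus strand: the genomically-first exon is the transcript's last
  minus <- tx_annotation(data.frame(
    transcript_id = "tm", gene_id = "g", chrom = "c", strand = "-",
    start = c(0L, 200L), end = c(100L, 300L)
  ))
  expect_equal(exon_context(10L, "tm", minus)$rank, 1)
  expect_equal(exon_context(250L, "tm", minus)$rank, 0.5)
  expect_error(exon_context(150L, "tm", minus), "not exonic")
})

test_that("conservation extraction is positional with last-wins overlaps", {
  track <- data.frame(chrom = "c", start = c(100L, 200L), end = c(101L, 210L),
                      score = c(0.9, 0.2))
  sites <- data.frame(chrom = "c", pos = c(100L, 205L, 500L), strand = "+")
  expect_equal(conservation_at_sites(sites, track), c(0.9, 0.2, NA))
  over <- rbind(track, data.frame(chrom = "c", start = 100L, end = 101L, score = 0.1))
  expect_warning(sc <- conservation_at_sites(sites, over), "last")
  expect_equal(sc[1L], 0.1)
  bad <- data.frame(chrom = "c", start = 10L, end = 10L, score = 1)
  expect_error(conservation_at_sites(sites, bad), "malformed")
})

test_that("category enrichment reports sample odds ratio and exact tail", {
  flat <- category_enrichment(rep(c(TRUE, FALSE), each = 20L),
                              rep(c(TRUE, FALSE), 20L))
  expect_equal(flat$odds_ratio, 1)
  expect_gte(flat$p, 0.5)

  skew <- category_enrichment(c(rep(TRUE, 4L), rep(FALSE, 4L)),
                              c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(skew$odds_ratio, 9)
  expect_equal(skew$p, 17 / 70, tolerance = 1e-12)

  sep <- category_enrichment(c(TRUE, TRUE, FALSE, FALSE),
                             c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(sep$odds_ratio, Inf)
  expect_error(category_enrichment(logical(0), logical(0)), "nonempty")
})

test_that("one-sided Fisher p equals hypergeometric enumeration", {
  # exhaustive over all small tables, then random larger ones up to N = 40
  for (a in 0:3) for (b in 0:3) for (c_ in 0:3) for (d in 0:3) {
    if (a + b == 0 || c_ + d == 0) next
    got <- category_enrichment(rep(c(TRUE, FALSE), c(a + b, c_ + d)),
                               rep(c(TRUE, FALSE, TRUE, FALSE), c(a, b, c_, d)))
    expect_equal(got$p, brute_fisher_greater(a, b, c_, d), tolerance = 1e-10)
  }
  set.seed(6L)
  for (i in 1:200) {
    n <- sample(4:40, 1L)
    cls <- sample(c(TRUE, FALSE), n, replace = TRUE)
    ref <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(cls) || all(cls)) next
    got <- category_enrichment(cls, ref)
    expect_equal(got$p, brute_fisher_greater(
      sum(cls & ref), sum(cls & !ref), sum(!cls & ref), sum(!cls & !ref)
    ), tolerance = 1e-10)
  }
})

test_that("metagene coordinate maps regions onto [0, 3)", {
  exons <- data.frame(transcript_id = "t", gene_id = "g", chrom = "c",
                      strand = "+", start = 0L, end = 1000L)
  cds <- data.frame(transcript_id = "t", start = 100L, end = 700L)
  ann <- tx_annotation(exons, cds)
  expect_equal(metagene_coordinate(400L, "t", ann), 1.5)
  expect_equal(metagene_coordinate(700L, "t", ann), 2.0)
  expect_equal(metagene_coordinate(0L, "t", ann), 0.0)
  expect_equal(metagene_coordinate(100L, "t", ann), 1.0)
  no_cds <- tx_annotation(exons)
  expect_warning(mc <- metagene_coordinate(400L, "t", no_cds), "CDS")
  expect_true(is.na(mc))
})

test_that("downsampling is seeded and size-capped", {
  expect_setequal(downsample_to_match(letters, 30L, seed = 1L), letters)
  a <- downsample_to_match(letters, 5L, seed = 2L)
  b <- downsample_to_match(letters, 5L, seed = 2L)
  expect_identical(a, b)
  expect_length(a, 5L)
})
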