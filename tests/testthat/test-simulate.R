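test_that("planted class fractions and flags honour the config", {
  sim <- simulate_study(small_config(seed = 3L, n_background_sites = 1000L))
  truth <- sim$truth
  n_pass <- sum(truth$passes_reference_filter)
  for (pair in list(c("conserved", 0.10), c("tissue_specific", 0.15),
                    c("infrequent", 0.15))) {
    expect_lte(abs(sum(truth$class == pair[1L] & truth$passes_reference_filter) -
                     as.numeric(pair[2L]) * n_pass), 1)
  }
  # no conserved class when its fraction is zero
  none <- simulate_study(small_config(seed = 4L, frac_conserved = 0))
  expect_false(any(none$truth$class == "conserved"))
})

test_that("intronic placement count is binomial around its configured fraction", {
  sim <- simulate_study(small_config(seed = 8L, n_background_sites = 1000L,
                                     frac_intronic = 0.1))
  n_int <- sum(sim$catalog$region == "intron")
  ci <- qbinom(c(0.005, 0.995), 1000L, 0.1)
  expect_gte(n_int, ci[1L])
  expect_lte(n_int, ci[2L])
})

test_that("clustered conserved sites have a same-class neighbor within 200 bp", {
  sim <- simulate_study(simulation_config(seed = 12L, n_background_sites = 800L))
  tr <- sim$truth
  cat <- sim$catalog
  idx <- which(tr$class == "conserved" & tr$clustered)
  expect_gt(length(idx), 0L)
  for (i in idx) {
    mates <- which(tr$class == "conserved" &
                     cat$transcript_id == cat$transcript_id[i])
    mates <- setdiff(mates, i)
    expect_true(any(abs(cat$pos[mates] - cat$pos[i]) <= 200L))
  }
})

test_that("detection draws follow the per-class probabilities", {
  # deterministic corner: conserved always detected, nothing else ever
  cfg <- small_config(seed = 21L, p_detect_conserved = 1,
                      p_detect_specific_home = 0, p_detect_specific_away = 0,
                      p_detect_infrequent_home = 0, p_detect_noise = 0,
                      decoy_peak_frac = 0)
  sim <- simulate_study(cfg)
  cons <- sim$truth$site[sim$truth$class == "conserved"]
  origin <- table(sim$peaks$origin_site)
  expect_true(all(cons %in% names(origin)))
  expect_true(all(origin[cons] == nrow(sim$samples)))
  expect_setequal(unique(sim$peaks$origin_site), cons)

  # decoy fraction 0 means the QC filter removes nothing
  kept <- qc_filter_peaks(sim$peaks, sim$expression)
  expect_equal(nrow(kept), nrow(sim$peaks))

  # default config: conserved detection rate within binomial tolerance of 0.98
  sim2 <- default_study()$sim
  cons2 <- sim2$truth$site[sim2$truth$class == "conserved"]
  hits <- sum(!is.na(sim2$peaks$origin_site) & sim2$peaks$origin_site %in% cons2)
  n_trials <- length(cons2) * nrow(sim2$samples)
  ci <- qbinom(c(0.005, 0.995), n_trials, 0.98)
  expect_gte(hits, ci[1L])
  expect_lte(hits, ci[2L])
})

test_that("decoy peaks each violate exactly the planted QC rule", {
  sim <- default_study()$sim
  pk <- sim$peaks
  dec <- pk[pk$qc_violation != "", ]
  expect_gt(nrow(dec), 0L)
  expect_true(all(dec$fdr[dec$qc_violation == "fdr"] >= 0.05))
  expect_true(all((dec$end - dec$start)[dec$qc_violation == "length"] >= 1000L))
  expect_true(all(dec$input_count[dec$qc_violation == "zero_input"] == 0L))
  expect_true(all(grepl(",", dec$gene_id[dec$qc_violation == "multi_gene"])))
  kept <- qc_filter_peaks(pk, sim$expression)
  expect_false(any(kept$qc_violation != ""))
})

test_that("expression realizes the methylation coupling and positivity", {
  cfg <- small_config(seed = 31L, expr_coupling = 0, expr_noise_sd = 0,
                      expr_noise_sd_conserved = 0)
  sim <- simulate_study(cfg)
  expect_true(all(sim$expression > 0))
  expect_true(all(apply(sim$expression, 1L, sd) == 0))

  strong <- simulate_study(small_config(seed = 32L, expr_coupling = -1,
                                        expr_noise_sd = 0.05,
                                        expr_noise_sd_conserved = 0.05,
                                        expr_basal_sd = 0.3))
  pass <- strong$truth[strong$truth$passes_reference_filter, ]
  mg <- tapply(pass$mean_meth, pass$gene_id, mean)
  cons <- pass[pass$class == "conserved", ]
  mg[unique(cons$gene_id)] <- tapply(cons$mean_meth, cons$gene_id, mean)
  e <- rowMeans(log2(strong$expression[names(mg), ]))
  expect_lt(cor(mg, e, method = "spearman"), -0.4)
})

test_that("auxiliary tracks plant RBP proximity, conservation uplift and ROIs", {
  cfg <- small_config(seed = 41L, rbp_near_prob = 1)
  sim <- simulate_study(cfg)
  cons_keys <- sim$truth$site[sim$truth$class == "conserved"]
  sites <- sim$catalog[match(cons_keys, sim$catalog$site), ]
  bound <- bind_sites(sites, sim$rbp_peaks[[sim$focal_rbp]])
  expect_true(all(bound$bound))

  cons_score <- conservation_at_sites(sim$catalog, sim$conservation)
  expect_gt(mean(cons_score[sim$truth$class == "conserved"]),
            mean(cons_score[sim$truth$class == "background_only"]))

  clean <- simulate_study(small_config(
    seed = 42L, attribution_noise_sd = 0,
    attribution_roi_spec = list(c(-64L, -15L))
  ))
  seg <- roi_segments(clean$attribution[1L, ])
  expect_equal(seg$start_offset, -64L)
  expect_equal(seg$end_offset, -15L)
  expect_error(simulation_config(attribution_roi_spec = list(c(-120L, -90L))),
               "-100")
})

test_that("identical configs give byte-identical study output", {
  cfg <- small_config(seed = 77L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(simulate_study(cfg), d1)
  write_simulation(simulate_study(cfg), d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE),
                     label = f)
  }
})

test_that("forced motif contexts match RGACW at the configured rate", {
  sim <- default_study()$sim
  exonic <- sim$catalog[!is.na(sim$catalog$tx_off), ]
  ok <- vapply(seq_len(nrow(exonic)), function(i) {
    win <- site_sequence_window(sim$sequences, exonic$transcript_id[i],
                                exonic$tx_off[i], flank = 2L)
    if (grepl("N", win)) return(NA)
    motif_match(win, "RGACW", center_offset = 3L)
  }, logical(1L))
  rate <- mean(ok, na.rm = TRUE)
  # forced with prob 0.9; chance matches add a little on top
  expect_gt(rate, 0.85)
})
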