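test_that("transcriptome generation is deterministic and respects planted truth", {
  cfg <- small_sim()
  a <- generate_transcriptome(cfg)
  b <- generate_transcriptome(cfg)
  expect_identical(a$genes, b$genes)
  expect_identical(a$truth, b$truth)
  # truth covers every gene exactly once
  expect_setequal(a$truth$gene_id, a$genes$gene_id)
  expect_equal(anyDuplicated(a$truth$gene_id), 0L)
  # every CDS is a well-formed ORF
  expect_true(all(nchar(a$genes$cds) %% 3 == 0))
  expect_true(all(substr(a$genes$cds, 1, 3) == "AUG"))
  # ribosomal proteins are drawn from a short-length range
  len <- gene_lengths(a$genes)
  rp <- a$genes$class_label == "ribosomal_protein"
  expect_lt(max(len$transcript[rp]), min(quantile(len$transcript[!rp], 0.9)))
})

test_that("planted uORF/TOP flags are exactly recoverable by the scanners", {
  cfg <- small_sim(n_genes = 300, seed = 11)
  tx <- generate_transcriptome(cfg)
  for (i in seq_len(nrow(tx$genes))) {
    has_uorf <- nrow(detect_uorfs(tx$genes$utr5[i])) > 0
    expect_identical(has_uorf, tx$truth$uorf_planted[i])
    expect_identical(detect_top(tx$genes$utr5[i])$top, tx$truth$top_planted[i])
  }
})

test_that("uORF planting probability zero yields a uORF-free class", {
  probs <- c(ieg_shared = 0, cfc_only_deg = 0, cfc_only_dtg = 0,
             shock_only_deg = 0, shock_only_dtg = 0,
             ribosomal_protein = 0, null = 0)
  cfg <- small_sim(n_genes = 150, seed = 3, uorf_prob = probs)
  tx <- generate_transcriptome(cfg)
  null_utr5 <- tx$genes$utr5[tx$genes$class_label == "null"]
  n_with <- sum(vapply(null_utr5, function(s) nrow(detect_uorfs(s)) > 0,
                       logical(1)))
  expect_identical(n_with, 0L)
})

test_that("counts honour the effect construction: TE effect moves footprints only", {
  cfg <- sim_config(n_genes = 400, seed = 5, library_size = 2e6,
                    dispersion = Inf)
  tx <- generate_transcriptome(cfg)
  cm <- simulate_counts(tx$genes, tx$truth, cfg)
  # median-ratio normalization removes the compositional depth bias that a
  # fixed library size imposes on perturbed samples
  expr_fp <- normalize_libraries(compute_rpkm(cm$footprint, tx$genes),
                                 "median-ratio")
  expr_to <- normalize_libraries(compute_rpkm(cm$total_mrna, tx$genes),
                                 "median-ratio")
  tt <- compute_te(list(expr_fp, expr_to))
  dtg_up <- tx$truth$gene_id[tx$truth$te_log2fc_cfc > 0]
  r_fp <- rowMeans(tt$group_rpkm_fp[dtg_up, "cfc", drop = FALSE]) /
    rowMeans(tt$group_rpkm_fp[dtg_up, "homecage", drop = FALSE])
  r_to <- rowMeans(tt$group_rpkm_total[dtg_up, "cfc", drop = FALSE]) /
    rowMeans(tt$group_rpkm_total[dtg_up, "homecage", drop = FALSE])
  expect_equal(mean(log2(r_fp)), 1, tolerance = 0.1)
  expect_equal(mean(log2(r_to)), 0, tolerance = 0.1)
})

test_that("Poisson-limit large libraries reach replicate R^2 >= 0.98", {
  cfg <- sim_config(n_genes = 500, seed = 2, library_size = 1e6,
                    dispersion = Inf)
  tx <- generate_transcriptome(cfg)
  cm <- simulate_counts(tx$genes, tx$truth, cfg)
  rc <- replicate_correlation(compute_rpkm(cm$total_mrna, tx$genes))
  expect_true(all(rc$r_squared >= 0.98))
})

test_that("null simulation produces equal group means within tolerance", {
  cfg <- sim_config(n_genes = 300, seed = 9, library_size = 1e6,
                    dispersion = Inf, effect_log2 = 0)
  tx <- generate_transcriptome(cfg)
  expect_true(all(tx$truth$mrna_log2fc_cfc == 0))
  cm <- simulate_counts(tx$genes, tx$truth, cfg)
  tt <- compute_te(list(compute_rpkm(cm$footprint, tx$genes),
                        compute_rpkm(cm$total_mrna, tx$genes)))
  lr <- log2(condition_ratio(tt, "cfc", "homecage", "transcription"))
  expect_lt(max(abs(lr)), 0.3)
})

test_that("empirical group log2 ratios converge to the planted effects", {
  cfg <- sim_config(n_genes = 200, seed = 4, library_size = 1e6,
                    dispersion = Inf)
  tx <- generate_transcriptome(cfg)
  cm <- simulate_counts(tx$genes, tx$truth, cfg)
  tt <- compute_te(list(
    normalize_libraries(compute_rpkm(cm$footprint, tx$genes),
                        "median-ratio"),
    normalize_libraries(compute_rpkm(cm$total_mrna, tx$genes),
                        "median-ratio")))
  lr <- log2(condition_ratio(tt, "cfc", "homecage", "transcription"))
  planted <- tx$truth$mrna_log2fc_cfc
  expect_lt(max(abs(lr - planted)), 0.35)
  expect_equal(mean(abs(lr - planted)), 0, tolerance = 0.1)
})

test_that("footprint reads reproduce the configured length and frame structure", {
  cfg <- small_sim(n_genes = 100, seed = 6, frame_fidelity = 1)
  tx <- generate_transcriptome(cfg)
  cm <- simulate_counts(tx$genes, tx$truth, cfg)
  reads <- simulate_footprint_reads(tx$genes, cm$footprint, cfg,
                                    n_reads = 3e4)
  h <- footprint_length_distribution(reads)
  expect_equal(as.integer(names(which.max(h$histogram))), 29L)
  f <- frame_distribution(reads, tx$genes, cfg$psite_offset)
  expect_equal(unname(f["f0"]), 1.0)

  cfg3 <- small_sim(n_genes = 100, seed = 6, frame_fidelity = 1 / 3)
  reads3 <- simulate_footprint_reads(tx$genes, cm$footprint, cfg3,
                                     n_reads = 3e4)
  f3 <- frame_distribution(reads3, tx$genes, cfg$psite_offset)
  expect_true(all(abs(f3 - 1 / 3) < 0.02))
})

test_that("polysome trace generator is seeded with analytic area truth", {
  pk <- data.frame(center = c(10, 15, 30, 70), area = c(0.2, 0.3, 1, 3),
                   sd = c(1, 1, 2, 2),
                   label = c("40S", "60S", "80S", "heavy"))
  tr <- simulate_polysome_trace(pk, baseline = 0, noise_sd = 0, seed = 1)
  expect_equal(tr$truth$pm_ratio, 3)
  pk$area[4] <- 1
  tr1 <- simulate_polysome_trace(pk, baseline = 0, noise_sd = 0, seed = 1)
  expect_equal(tr1$truth$pm_ratio, 1)
  tr2a <- simulate_polysome_trace(noise_sd = 0.01, seed = 42)
  tr2b <- simulate_polysome_trace(noise_sd = 0.01, seed = 42)
  expect_identical(tr2a$trace, tr2b$trace)
  expect_error(simulate_polysome_trace(pk[c(2, 1, 3, 4), ]), "increasing")
})

test_that("qPCR and freezing generators invert exactly at zero noise", {
  fc <- data.frame(gene = "g", condition = c("homecage", "cfc"), fc = c(1, 4))
  ct <- simulate_qpcr(fc, noise_sd = 0, seed = 1)
  expect_equal(ddct_fold_change(ct)$fold_change, 4.0)
  expect_error(simulate_qpcr(data.frame(gene = "g", condition = "c",
                                        fc = -1)), "> 0")

  fz0 <- simulate_freezing(c(hc = 0), n_mice = 5, seed = 1)
  expect_true(all(freezing_summary(fz0)$freezing_percent == 0))
  fz <- simulate_freezing(c(cfc = 0.7), n_mice = 200, seed = 1)
  expect_equal(mean(freezing_summary(fz)$freezing_percent), 70,
               tolerance = 0.02)
})
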