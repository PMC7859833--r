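test_that("UTR basic stats: exact GC and length, undefined GC for empty regions", {
  g <- list(utr5 = "GCGC", utr3 = "AUAU")
  st <- utr_basic_stats(g)
  expect_equal(st$gc_percent, c(100, 0))
  st2 <- utr_basic_stats(list(utr5 = "AUGC", utr3 = ""))
  expect_equal(st2$length, c(4, 0))
  expect_equal(st2$gc_percent[1], 50)
  expect_true(is.na(st2$gc_percent[2]))
})

test_that("folding energy handles unpairable and hand-solved sequences", {
  expect_equal(fold_min_energy("AAAA"), 0)
  expect_equal(fold_min_energy("GGGAAACCC"), -9)   # 3 G-C pairs, AAA loop
  expect_error(fold_min_energy("AXGC"), "non-RNA")
  expect_equal(fold_min_energy("ACGT"), fold_min_energy("ACGU"))
})

test_that("folding DP equals the exhaustive-enumeration minimum on short sequences", {
  set.seed(17)
  for (i in 1:60) {
    s <- random_rna_str(sample(4:12, 1))
    expect_equal(fold_min_energy(s), bf_mfe(s), info = s)
  }
})

test_that("folding energy symmetries hold and energy is monotone under stem extension", {
  comp_rev <- function(s) {
    paste(rev(chartr("ACGU", "UGCA", strsplit(s, "")[[1]])), collapse = "")
  }
  rev_str <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  set.seed(19)
  # exact model symmetry: plain reversal preserves the pair multiset
  for (i in 1:30) {
    s <- random_rna_str(sample(6:12, 1))
    expect_equal(fold_min_energy(s), fold_min_energy(rev_str(s)), info = s)
  }
  # complement-reversal is a symmetry on wobble-free alphabets, where every
  # usable pair maps to a pair of the same energy
  for (i in 1:15) {
    s <- random_rna_str(sample(6:12, 1), letters = c("A", "U"))
    expect_equal(fold_min_energy(s), fold_min_energy(comp_rev(s)), info = s)
    s2 <- random_rna_str(sample(6:12, 1), letters = c("G", "C"))
    expect_equal(fold_min_energy(s2), fold_min_energy(comp_rev(s2)),
                 info = s2)
  }
  for (i in 1:15) {
    s <- random_rna_str(sample(8:40, 1))
    closed <- paste0("GGG", s, "CCC")
    expect_lte(fold_min_energy(closed), fold_min_energy(s))
  }
})

test_that("uORF detection matches hand enumeration and its corner cases", {
  u <- detect_uorfs("AAAUGGCUUAAGG")
  expect_equal(nrow(u), 1)
  expect_equal(u$start, 2L)     # 0-based AUG offset
  expect_equal(u$end, 11L)      # half-open end of UAA
  expect_equal(u$n_codons, 3L)
  expect_equal(nrow(detect_uorfs("AUGAAAAAA")), 0)  # no in-frame stop inside
  expect_equal(nrow(detect_uorfs("")), 0)
  expect_equal(nrow(detect_uorfs("AUGUAA")), 1)     # minimal 2-codon uORF
  # stop out of frame does not terminate
  expect_equal(nrow(detect_uorfs("AUGAUAAAA")), 0)
})

test_that("uORF and TOP scanners agree with brute-force enumerators on random UTRs", {
  set.seed(23)
  for (i in 1:300) {
    s <- random_rna_str(sample(0:60, 1))
    got <- detect_uorfs(s)
    want <- bf_uorfs(s)
    expect_equal(got[, c("start", "end")], want, info = s,
                 ignore_attr = TRUE)
    expect_identical(detect_top(s)$top, bf_top(s), info = s)
  }
})

test_that("TOP detection applies the C + >=4 pyrimidine rule exactly", {
  t1 <- detect_top("CUUUCCAGG")
  expect_true(t1$top); expect_equal(t1$tract_length, 6L)
  expect_false(detect_top("GCUUUUAAA")$top)   # first base not C
  expect_false(detect_top("CUUAGGG")$top)     # run of 2 < 4
  expect_true(detect_top("CCCCCA")$top)
  expect_false(detect_top("")$top)
})

test_that("motif scanning finds registry patterns at printed offsets", {
  g <- list(gene_id = "g1", utr5 = "CUUUUUAAACAAUAAAGG",
            utr3 = "GGGAAUAAACCAUUUAGAUUUAGG")
  sc <- scan_motifs(g)
  pas5 <- sc$hits[sc$hits$motif == "PAS_like_5p", ]
  expect_equal(pas5$start, 10L)
  are <- sc$hits[sc$hits$motif == "ARE", ]
  expect_equal(nrow(are), 2)           # two AUUUA copies -> present
  expect_true(sc$presence$present[sc$presence$motif == "ARE"])
  pas3 <- sc$hits[sc$hits$motif == "PAS" & sc$hits$region == "utr3", ]
  expect_equal(pas3$start, 3L)
  # no-match sequence yields an empty hit list
  g0 <- list(gene_id = "g0", utr5 = "GGGGG", utr3 = "GGGGG")
  expect_equal(nrow(scan_motifs(g0)$hits), 0)
  bad <- data.frame(name = "x", region = "cds", kind = "iupac",
                    pattern = "AUG", min_copies = 1L)
  expect_error(scan_motifs(g, bad), "region")
})

test_that("IUPAC expansion covers degenerate codes", {
  expect_equal(iupac_to_regex("AWUAAA"), "A[AU]UAAA")
  expect_true(grepl(iupac_to_regex("RYN"), "AUC"))
  expect_error(iupac_to_regex("AXZ"), "IUPAC")
})

test_that("default registry has 4 five-prime and 9 three-prime motif types", {
  reg <- default_motif_registry()
  expect_equal(sum(reg$region == "utr5"), 4)
  expect_equal(sum(reg$region == "utr3"), 9)
  expect_equal(anyDuplicated(reg$name), 0L)
})

test_that("two-way motif ANOVA matches the sums-of-squares oracle and reports the block dfs", {
  set.seed(29)
  pct <- expand.grid(motif = paste0("m", 1:4), group = paste0("g", 1:4),
                     stringsAsFactors = FALSE)
  pct$percent <- round(runif(16, 0, 100), 1)
  presence <- do.call(rbind, lapply(seq_len(nrow(pct)), function(i) {
    n <- 10
    k <- round(pct$percent[i] / 10)
    data.frame(gene_id = sprintf("%s_%s_%d", pct$motif[i], pct$group[i], 1:n),
               region = "utr5", motif = pct$motif[i],
               present = c(rep(TRUE, k), rep(FALSE, n - k)),
               group_label = pct$group[i], stringsAsFactors = FALSE)
  }))
  groups <- setNames(presence$group_label, presence$gene_id)
  features <- data.frame(gene_id = presence$gene_id, region = "utr5",
                         length = rnorm(nrow(presence), 100),
                         gc_percent = 50, mfe = -10)
  res <- compare_utr_features(features, presence[, 1:4], groups)
  an <- res$anova
  expect_equal(an$df1[an$factor == "motif"], 3)
  expect_equal(an$df2[an$factor == "motif"], 9)
  p <- res$percentages
  o <- oracle_anova2(p$percent, p$motif, p$group)
  expect_equal(an$F[an$factor == "motif"], o$Fa, tolerance = 1e-6)
  expect_equal(an$F[an$factor == "group"], o$Fb, tolerance = 1e-6)

  # no group effect (group means identical): group factor F = 0, p = 1
  base_k <- c(m1 = 2, m2 = 4, m3 = 6, m4 = 8)
  d <- matrix(c(1, -1, 0, 0, -1, 1, 0, 0, 0, 0, 1, -1, 0, 0, -1, 1), 4, 4,
              dimnames = list(names(base_k), paste0("g", 1:4)))
  pres_null <- do.call(rbind, lapply(seq_len(nrow(pct)), function(i) {
    k <- base_k[pct$motif[i]] + d[pct$motif[i], pct$group[i]]
    data.frame(gene_id = sprintf("%s_%s_%d", pct$motif[i], pct$group[i],
                                 1:10),
               region = "utr5", motif = pct$motif[i],
               present = c(rep(TRUE, k), rep(FALSE, 10 - k)),
               stringsAsFactors = FALSE)
  }))
  res0 <- compare_utr_features(features, pres_null, groups)
  expect_lt(res0$anova$F[res0$anova$factor == "group"], 1e-20)
  expect_equal(res0$anova$p[res0$anova$factor == "group"], 1,
               tolerance = 1e-8)
})

test_that("t-test feature comparisons have calibrated type-I error", {
  set.seed(31)
  reject <- 0; n_rep <- 400
  for (i in seq_len(n_rep)) {
    x <- rnorm(15); y <- rnorm(15)
    if (t.test(x, y, var.equal = TRUE)$p.value < 0.05) reject <- reject + 1
  }
  band <- qbinom(c(0.005, 0.995), n_rep, 0.05)
  expect_gte(reject, band[1]); expect_lte(reject, band[2])

  # the wrapper returns matching t statistics for a fixed comparison
  features <- data.frame(
    gene_id = sprintf("g%02d", 1:20), region = "utr5",
    length = c(rnorm(10, 100, 5), rnorm(10, 130, 5)),
    gc_percent = 50, mfe = -5)
  presence <- data.frame(gene_id = features$gene_id, region = "utr5",
                         motif = "uORF", present = TRUE)
  groups <- setNames(rep(c("a", "b"), each = 10), features$gene_id)
  res <- compare_utr_features(features, presence, groups)
  row <- res$t_tests[res$t_tests$feature == "length", ]
  ref <- t.test(features$length[1:10], features$length[11:20],
                var.equal = TRUE)
  expect_equal(row$t[1], unname(ref$statistic), tolerance = 1e-9)
  expect_equal(row$p[1], ref$p.value, tolerance = 1e-9)
})

test_that("planted motif classes are recovered at 100% by the feature table", {
  cfg <- small_sim(n_genes = 120, seed = 37)
  tx <- generate_transcriptome(cfg)
  planted <- tx$truth$gene_id[tx$truth$uorf_planted]
  sub <- tx$genes[tx$genes$gene_id %in% planted, ]
  ft <- utr_feature_table(sub, mfe = FALSE)
  pres <- ft$presence[ft$presence$motif == "uORF", ]
  expect_true(all(pres$present))
})
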