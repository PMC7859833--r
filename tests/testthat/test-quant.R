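mini_design <- function(n_rep = 2, assays = c("footprint", "total_mrna"),
                        groups = "homecage") {
  g <- expand.grid(rep = seq_len(n_rep), group = groups, assay = assays,
                   stringsAsFactors = FALSE)
  library_design(paste(g$assay, g$group, g$rep, sep = "_"),
                 g$assay, g$group, g$rep)
}

mini_genes <- function(lengths, ids = sprintf("g%02d", seq_along(lengths))) {
  # transcripts of the requested total length: 10 nt 5' UTR, CDS a multiple
  # of 3, remainder absorbed by the 3' UTR
  cds_len <- lengths - 20
  rem <- cds_len %% 3
  cds_len <- cds_len - rem
  stopifnot(all(cds_len >= 6))
  cds <- vapply(cds_len, function(l) {
    paste0("AUG", strrep("GCU", (l - 6) / 3), "UAA")
  }, character(1))
  gene_models(ids, paste0(ids, ".t"), "protein_coding",
              utr5 = strrep("C", 10), cds = cds,
              utr3 = vapply(rem, function(r) strrep("A", 10 + r),
                            character(1)))
}

test_that("RPKM follows the closed form and scales with length and library size", {
  genes <- mini_genes(c(1000, 500, 1000))
  m <- matrix(c(10L, 10L, 0L), ncol = 1,
              dimnames = list(genes$gene_id, "total_mrna_homecage_1"))
  # pad library to size 1e6
  m <- cbind(m)
  m["g03", 1] <- 1e6L - 20L
  d <- library_design("total_mrna_homecage_1", "total_mrna", "homecage", 1)
  expr <- compute_rpkm(count_matrix(m, d), genes)
  expect_equal(unname(expr$rpkm["g01", 1]), 10.0)      # 10*1e9/(1000*1e6)
  expect_equal(unname(expr$rpkm["g02", 1] / expr$rpkm["g01", 1]), 2)
  zero <- m; zero["g01", 1] <- 0L
  expr0 <- compute_rpkm(count_matrix(zero, d), genes)
  expect_equal(unname(expr0$rpkm["g01", 1]), 0)
  expect_false(expr0$expressible["g01", 1])
})

test_that("TE is footprint RPKM over total RPKM with undefined-flag propagation", {
  genes <- mini_genes(c(600, 900, 600))
  d <- mini_design()
  # balanced column sums (300) so library-size normalization cancels
  counts <- matrix(100L, nrow = 3, ncol = 4,
                   dimnames = list(genes$gene_id, d$library_id))
  counts["g01", "footprint_homecage_1"] <- 200L
  counts["g03", "footprint_homecage_1"] <- 0L
  cm <- count_matrix(counts, d)
  tt <- compute_te(compute_rpkm(cm, genes))
  expect_equal(unname(tt$te["g01", "homecage:1"]), 2.0)
  # identical fp and total counts give TE exactly 1
  expect_equal(unname(tt$te["g02", ]), c(1, 1))
  # zero footprint RPKM: undefined flag, group TE from the defined replicate
  expect_true(is.na(tt$te["g03", "homecage:1"]))
  expect_equal(unname(tt$group_te["g03", "homecage"]), 1)
  # zero total RPKM: undefined flag, not infinity
  counts["g02", "total_mrna_homecage_2"] <- 0L
  tt2 <- compute_te(compute_rpkm(count_matrix(counts, d), genes))
  expect_true(is.na(tt2$te["g02", "homecage:2"]))
  expect_false(tt2$defined["g02", "homecage:2"])
  expect_true(all(is.finite(tt2$group_te)))
})

test_that("compute_te rejects unpaired libraries naming the orphan", {
  d <- rbind(
    data.frame(library_id = "fp1", assay = "footprint", group = "cfc",
               replicate = 1),
    data.frame(library_id = "to1", assay = "total_mrna", group = "cfc",
               replicate = 1),
    data.frame(library_id = "fp2", assay = "footprint", group = "cfc",
               replicate = 2))
  expr <- structure(list(
    rpkm = matrix(1, 2, 3, dimnames = list(c("g1", "g2"), d$library_id)),
    design = d), class = "expression_table")
  expect_error(compute_te(expr), "cfc:2")
})

test_that("quantile normalization equalizes library distributions; median-ratio removes scale factors", {
  genes <- mini_genes(rep(600, 50))
  d <- mini_design(n_rep = 2, assays = "total_mrna")
  set.seed(1)
  base <- rpois(50, 200)
  m <- cbind(base, as.integer(base * 2))
  dimnames(m) <- list(genes$gene_id, d$library_id)
  expr <- compute_rpkm(count_matrix(m, d), genes)

  q <- normalize_libraries(expr, "quantile")
  expect_equal(sort(q$rpkm[, 1]), sort(q$rpkm[, 2]), ignore_attr = TRUE)
  # rank-preserving within library
  expect_equal(order(q$rpkm[, 1]), order(expr$rpkm[, 1]))

  mr <- normalize_libraries(expr, "median-ratio")
  expect_equal(mr$rpkm[, 1], mr$rpkm[, 2], ignore_attr = TRUE)

  # identical libraries are a fixed point
  m2 <- cbind(base, base); dimnames(m2) <- dimnames(m)
  expr2 <- compute_rpkm(count_matrix(m2, d), genes)
  expect_equal(normalize_libraries(expr2, "quantile")$rpkm, expr2$rpkm)
})

test_that("replicate correlation is sign-blind and flags degenerate input", {
  genes <- mini_genes(rep(600, 20))
  d <- mini_design(n_rep = 2, assays = "total_mrna")
  set.seed(2)
  a <- rpois(20, 500) + 1L
  m <- cbind(a, a); dimnames(m) <- list(genes$gene_id, d$library_id)
  expr <- compute_rpkm(count_matrix(m, d), genes)
  expect_equal(replicate_correlation(expr)$r_squared, 1.0)

  # y = -x on the log scale (reciprocal counts ~ scaled): R^2 still 1
  recip <- as.integer(round(1e6 / a))
  m2 <- cbind(a, recip); dimnames(m2) <- dimnames(m)
  expr2 <- compute_rpkm(count_matrix(m2, d), genes)
  expect_gt(replicate_correlation(expr2)$r_squared, 0.999)

  m3 <- matrix(7L, 20, 2, dimnames = dimnames(m))
  expr3 <- compute_rpkm(count_matrix(m3, d), genes)
  expect_warning(rc3 <- replicate_correlation(expr3), "variance")
  expect_true(is.na(rc3$r_squared))
})

test_that("pca_cluster standardizes per gene, merges duplicates first, and recovers groups", {
  set.seed(3)
  base <- matrix(2^rnorm(200 * 6, 6, 1), 200, 6)
  base[, 2] <- base[, 1]            # duplicated sample
  colnames(base) <- paste0("s", 1:6)
  pc <- pca_cluster(base)
  expect_equal(sum(pc$var_explained), 1, tolerance = 1e-8)
  m1 <- pc$hclust$merge[1, ]
  expect_setequal(abs(m1), c(1, 2))
  expect_equal(pc$hclust$height[1], 0)

  # three well-separated groups are recovered at k = 3
  g <- rep(1:3, each = 2)
  sig <- matrix(2^(rnorm(300 * 6, 8, 0.1) + 2 * outer(rnorm(300), g)),
                300, 6)
  colnames(sig) <- paste0("s", 1:6)
  cl <- cutree(pca_cluster(sig)$hclust, k = 3)
  expect_equal(length(unique(tapply(cl, g, function(v) v[1]))), 3)
  expect_true(all(tapply(cl, g, function(v) length(unique(v))) == 1))
})

test_that("gene-class TE summary builds the length-matched set correctly", {
  cfg <- small_sim(n_genes = 300, seed = 8)
  tx <- generate_transcriptome(cfg)
  cm <- simulate_counts(tx$genes, tx$truth, cfg)
  tt <- compute_te(list(compute_rpkm(cm$footprint, tx$genes),
                        compute_rpkm(cm$total_mrna, tx$genes)))
  te <- setNames(tt$group_te[, "homecage"], rownames(tt$group_te))
  s <- te_by_gene_class(te, tx$genes)
  expect_setequal(
    s$class, c("all_protein_coding", "ribosomal_protein", "length_matched"))
  # planted RP TE shift of -0.5 log2 puts the RP median below the matched set
  expect_lt(s$median[s$class == "ribosomal_protein"],
            s$median[s$class == "length_matched"])
  # matched set is exactly the non-RP genes within the RP length range
  len <- gene_lengths(tx$genes)
  rp <- tx$genes$class_label == "ribosomal_protein"
  rng <- range(len$transcript[rp])
  expect_equal(s$n[s$class == "length_matched"],
               sum(!rp & len$transcript >= rng[1] & len$transcript <= rng[2]))
  genes_norp <- tx$genes[!rp, ]
  expect_error(te_by_gene_class(te, genes_norp), "ribosomal_protein")
})
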