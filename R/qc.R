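#' Footprint length histogram and 28-32 nt fraction
#'
#' @param reads read table (gene_id, start, length).
#' @return list: `histogram` (named integer counts by length),
#'   `fraction_28_32`.
#' @export
footprint_length_distribution <- function(reads) {
  if (!nrow(reads)) stop("no reads")
  h <- table(reads$length)
  list(histogram = h,
       fraction_28_32 = mean(reads$length >= 28 & reads$length <= 32))
}

#' Estimate the 5'-end to P-site offset per read length
#'
#' For each read length the offset maximizing meta-coverage at the first
#' nucleotide of the CDS start codon is chosen from `candidates`; ties break
#' toward 12. Lengths with fewer than `min_reads` reads fall back to the
#' default offset 12 with a warning.
#'
#' @param reads read table.
#' @param genes a `gene_models`.
#' @param candidates candidate offsets (nt).
#' @param min_reads minimum reads per length class.
#' @return named integer vector of offsets by read length.
#' @export
estimate_psite_offsets <- function(reads, genes, candidates = 10:15,
                                   min_reads = 100) {
  len <- gene_lengths(genes)
  cds_start <- setNames(len$utr5, len$gene_id)[reads$gene_id]
  cand <- candidates[order(abs(candidates - 12), candidates)]  # ties -> 12
  lens <- sort(unique(reads$length))
  out <- setNames(integer(length(lens)), lens)
  fallback <- character(0)
  for (L in lens) {
    sel <- reads$length == L
    if (sum(sel) < min_reads) {
      out[as.character(L)] <- 12L
      fallback <- c(fallback, as.character(L))
      next
    }
    cov <- vapply(cand, function(o) {
      sum(reads$start[sel] + o == cds_start[sel])
    }, integer(1))
    out[as.character(L)] <- as.integer(cand[which.max(cov)])
  }
  if (length(fallback))
    warning("fewer than ", min_reads, " reads for length(s) ",
            paste(fallback, collapse = ", "), "; default offset 12 used")
  out
}

read_psites <- function(reads, genes, offsets) {
  len <- gene_lengths(genes)
  off <- psite_offset_for(offsets, reads$length)
  list(psite = reads$start + off,
       cds_start = setNames(len$utr5, len$gene_id)[reads$gene_id],
       cds_end = setNames(len$utr5 + len$cds, len$gene_id)[reads$gene_id])
}

#' Reading-frame distribution of P-sites within the CDS
#'
#' Frame = (P-site - CDS start) mod 3, counted only for P-sites inside the
#' CDS (UTR P-sites are excluded from the denominator).
#'
#' @param reads read table.
#' @param genes a `gene_models`.
#' @param offsets per-length P-site offsets (from
#'   [estimate_psite_offsets()]) or a scalar.
#' @return numeric vector (f0, f1, f2) summing to 1.
#' @export
frame_distribution <- function(reads, genes, offsets = 12L) {
  p <- read_psites(reads, genes, offsets)
  in_cds <- p$psite >= p$cds_start & p$psite < p$cds_end
  if (!any(in_cds)) stop("no P-sites inside any CDS")
  f <- (p$psite[in_cds] - p$cds_start[in_cds]) %% 3
  tab <- tabulate(f + 1, 3) / sum(in_cds)
  setNames(tab, c("f0", "f1", "f2"))
}

#' Metagene P-site coverage around the CDS start and 3-nt periodicity score
#'
#' P-site coverage is summed across genes at positions relative to the CDS
#' start. The periodicity score is the spectral power at period 3 of the
#' mean-centred CDS-region profile divided by the total power over periods
#' 2..6; it lies in \[0, 1\], is ~1 for a perfect 3-periodic impulse train
#' and ~1/5 on average for an unstructured profile.
#'
#' @param reads read table.
#' @param genes a `gene_models`.
#' @param offsets per-length P-site offsets or scalar.
#' @param window integer c(from, to) around the CDS start, e.g. c(-20, 60).
#' @return list: `positions`, `coverage`, `periodicity_score`.
#' @export
metagene_periodicity <- function(reads, genes, offsets = 12L,
                                 window = c(-20L, 60L)) {
  len <- gene_lengths(genes)
  if (window[2] - window[1] + 1 > max(len$transcript))
    stop("window exceeds every transcript")
  p <- read_psites(reads, genes, offsets)
  rel <- p$psite - p$cds_start
  keep <- rel >= window[1] & rel <= window[2]
  positions <- window[1]:window[2]
  coverage <- tabulate(rel[keep] - window[1] + 1, length(positions))
  names(coverage) <- positions
  cds_prof <- coverage[positions >= 0]
  if (all(cds_prof == 0)) stop("coverage all zero in window")
  list(positions = positions, coverage = coverage,
       periodicity_score = periodicity_score(cds_prof))
}

#' Period-3 spectral periodicity score of a coverage profile
#'
#' @param profile numeric coverage vector (one value per nt).
#' @param periods periods whose power forms the denominator.
#' @return power at period 3 over total power across `periods`; NA with a
#'   warning when the centred profile carries no power at any probed period.
#' @export
periodicity_score <- function(profile, periods = 2:6) {
  x <- profile - mean(profile)
  t <- seq_along(x) - 1
  pw <- vapply(periods, function(p) {
    Mod(sum(x * exp(-2i * pi * t / p)))^2
  }, numeric(1))
  tot <- sum(pw)
  if (tot < .Machine$double.eps) {
    warning("profile has no spectral power at the probed periods")
    return(NA_real_)
  }
  unname(pw[periods == 3] / tot)
}

#' Pairwise replicate R-squared of log2 values
#'
#' For each assay and group, the squared Pearson correlation of log2 RPKM
#' between replicate libraries, over genes defined (> 0) in both.
#'
#' @param expr an `expression_table`.
#' @return data.frame(assay, group, rep_a, rep_b, n_genes, r_squared).
#' @export
replicate_correlation <- function(expr) {
  d <- expr$design
  out <- list()
  for (assay in unique(d$assay)) for (g in unique(d$group)) {
    libs <- d$library_id[d$assay == assay & d$group == g]
    if (length(libs) < 2) next
    for (i in seq_along(libs)) for (j in seq_along(libs)) {
      if (j <= i) next
      a <- expr$rpkm[, libs[i]]; b <- expr$rpkm[, libs[j]]
      ok <- a > 0 & b > 0
      r2 <- NA_real_
      if (sum(ok) < 3) {
        warning("fewer than 3 shared defined genes for ", libs[i], " vs ",
                libs[j])
      } else if (sd(log2(a[ok])) == 0 || sd(log2(b[ok])) == 0) {
        warning("zero variance in ", libs[i], " or ", libs[j])
      } else {
        r2 <- cor(log2(a[ok]), log2(b[ok]))^2
      }
      out[[length(out) + 1]] <- data.frame(
        assay = assay, group = g, rep_a = libs[i], rep_b = libs[j],
        n_genes = sum(ok), r_squared = r2, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' PCA and complete-linkage clustering of samples
#'
#' Genes with any undefined (non-positive) value are excluded; log2 values
#' are standardized per gene (mean 0, SD 1; zero-variance genes excluded
#' with a count); samples are ordinated by PCA and clustered by
#' complete linkage on Euclidean distances of the same standardized data.
#'
#' @param mat genes x samples matrix of positive values (RPKM or TE), or an
#'   `expression_table` (its RPKM matrix is used).
#' @return list: `scores` (samples x PCs), `var_explained`, `dist`,
#'   `hclust`, `n_excluded_undefined`, `n_excluded_zero_var`.
#' @export
pca_cluster <- function(mat) {
  if (inherits(mat, "expression_table")) mat <- mat$rpkm
  if (ncol(mat) < 3) stop("need at least 3 samples")
  defined <- rowSums(!is.finite(log2(mat))) == 0
  l <- log2(mat[defined, , drop = FALSE])
  v <- apply(l, 1, sd)
  zero_var <- v == 0
  z <- (l[!zero_var, , drop = FALSE] - rowMeans(l[!zero_var, , drop = FALSE])) /
    v[!zero_var]
  pc <- prcomp(t(z), center = FALSE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  dd <- dist(t(z))
  list(scores = pc$x, var_explained = ve, dist = dd,
       hclust = hclust(dd, method = "complete"),
       n_excluded_undefined = sum(!defined),
       n_excluded_zero_var = sum(zero_var))
}

#' TE distribution summaries by gene class with a length-matched set
#'
#' Reports all protein-coding genes, ribosomal proteins, mitochondrial
#' ribosomal proteins (when present) and the length-matched set: non-RP
#' protein-coding genes whose transcript length falls within the
#' \[min, max\] range of ribosomal-protein transcript lengths.
#'
#' @param te named per-gene TE vector (undefined as NA).
#' @param genes a `gene_models`.
#' @return data.frame(class, n, q1, median, q3).
#' @export
te_by_gene_class <- function(te, genes) {
  len <- gene_lengths(genes)
  rp <- genes$class_label == "ribosomal_protein"
  if (!any(rp)) stop("no ribosomal_protein genes in annotation")
  te <- te[genes$gene_id]
  rng <- range(len$transcript[rp])
  matched <- !rp & len$transcript >= rng[1] & len$transcript <= rng[2]
  sets <- list(all_protein_coding = rep(TRUE, nrow(genes)),
               ribosomal_protein = rp,
               mito_ribosomal_protein =
                 genes$class_label == "mito_ribosomal_protein",
               length_matched = matched)
  rows <- lapply(names(sets), function(nm) {
    v <- te[sets[[nm]]]; v <- v[!is.na(v)]
    if (!length(v)) return(NULL)
    data.frame(class = nm, n = length(v),
               q1 = unname(quantile(v, 0.25)), median = median(v),
               q3 = unname(quantile(v, 0.75)), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
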