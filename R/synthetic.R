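#' Derive a deterministic per-component child seed
#'
#' One global seed drives the whole simulation; each generator component uses
#' a child seed derived from the component name so stages are individually
#' reproducible. Result is always in [1, 2^31 - 2].
#'
#' @param seed integer global seed.
#' @param name component name.
#' @return integer seed.
#' @export
child_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name))) %% 1000003L
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483645) + 1L
}

#' Simulation configuration with the study-design defaults
#'
#' Defaults emulate the experimental design: 3 groups (homecage,
#' immediate_shock, cfc) x 2 replicates, paired footprint/total libraries,
#' planted gene classes with |log2 FC| of 1 (above the log2 1.5 callable
#' cutoff), footprint lengths supported on 26-34 nt with mode 29, and
#' class-dependent uORF/TOP planting.
#'
#' @param n_genes number of genes.
#' @param seed global seed.
#' @param groups group names; first is the baseline.
#' @param n_replicates replicates per group.
#' @param library_size expected reads per library.
#' @param baseline_meanlog,baseline_sdlog log-normal baseline abundance.
#' @param dispersion negative-binomial size (Inf = Poisson).
#' @param class_props named proportions over planted classes (sum to 1).
#' @param effect_log2 planted |log2 fold change| for perturbed classes.
#' @param rp_te_shift_log2 constant (all-group) TE shift of the
#'   ribosomal_protein class, log2 units.
#' @param uorf_prob,top_prob named per-class planting probabilities.
#' @param fp_lengths,fp_length_probs footprint read-length distribution.
#' @param frame_fidelity probability a footprint P-site sits in CDS frame 0.
#' @param psite_offset true 5'-end to P-site offset in nt (scalar or named by
#'   read length).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000L,
                       seed = 1L,
                       groups = c("homecage", "immediate_shock", "cfc"),
                       n_replicates = 2L,
                       library_size = 1e6,
                       baseline_meanlog = log(100),
                       baseline_sdlog = 1,
                       dispersion = 1000,
                       class_props = c(ieg_shared = 0.05,
                                       cfc_only_deg = 0.05,
                                       cfc_only_dtg = 0.05,
                                       shock_only_deg = 0.05,
                                       shock_only_dtg = 0.05,
                                       ribosomal_protein = 0.05,
                                       null = 0.70),
                       effect_log2 = 1,
                       rp_te_shift_log2 = -0.5,
                       uorf_prob = c(ieg_shared = 0.10, cfc_only_deg = 0.10,
                                     cfc_only_dtg = 0.60, shock_only_deg = 0.10,
                                     shock_only_dtg = 0.10,
                                     ribosomal_protein = 0.05, null = 0.10),
                       top_prob = c(ieg_shared = 0.02, cfc_only_deg = 0.02,
                                    cfc_only_dtg = 0.02, shock_only_deg = 0.30,
                                    shock_only_dtg = 0.50,
                                    ribosomal_protein = 0.90, null = 0.02),
                       fp_lengths = 26:34,
                       fp_length_probs = c(0.01, 0.02, 0.10, 0.30, 0.25,
                                           0.15, 0.10, 0.05, 0.02),
                       frame_fidelity = 0.85,
                       psite_offset = 12L) {
  stopifnot(length(groups) >= 2, n_replicates >= 1, library_size > 0)
  if (abs(sum(class_props) - 1) > 1e-9) stop("class proportions must sum to 1")
  if (effect_log2 != 0 && effect_log2 < log2(1.5))
    stop("planted |log2 effect| must be >= log2(1.5) so planted genes are ",
         "callable at the fold-change cutoff (0 simulates the global null)")
  if (frame_fidelity < 1 / 3 || frame_fidelity > 1)
    stop("frame_fidelity must be in [1/3, 1]")
  stopifnot(length(fp_lengths) == length(fp_length_probs),
            abs(sum(fp_length_probs) - 1) < 1e-9)
  mode_len <- fp_lengths[which.max(fp_length_probs)]
  if (mode_len < 28 || mode_len > 32)
    stop("footprint length mode must lie within 28-32 nt")
  structure(list(
    n_genes = as.integer(n_genes), seed = as.integer(seed),
    groups = groups, baseline_group = groups[1],
    n_replicates = as.integer(n_replicates),
    library_size = library_size,
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
    dispersion = dispersion,
    class_props = class_props, effect_log2 = effect_log2,
    rp_te_shift_log2 = rp_te_shift_log2,
    uorf_prob = uorf_prob, top_prob = top_prob,
    fp_lengths = as.integer(fp_lengths), fp_length_probs = fp_length_probs,
    frame_fidelity = frame_fidelity, psite_offset = psite_offset,
    # per-class transcript geometry (nt / codons); ribosomal proteins short
    len_cfg = list(
      default = list(utr5_meanlog = log(150), utr5_sdlog = 0.4,
                     utr5_min = 20, utr5_max = 600,
                     utr3_meanlog = log(300), utr3_sdlog = 0.5,
                     utr3_min = 20, utr3_max = 1200,
                     cds_codons = c(100L, 500L)),
      ribosomal_protein = list(utr5_meanlog = log(40), utr5_sdlog = 0.3,
                               utr5_min = 20, utr5_max = 80,
                               utr3_meanlog = log(80), utr3_sdlog = 0.3,
                               utr3_min = 20, utr3_max = 150,
                               cds_codons = c(60L, 160L))
    ),
    gc_utr5 = 0.55, gc_utr3 = 0.45
  ), class = "sim_config")
}

random_rna <- function(len, gc) {
  if (len <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  paste(sample(RNA_ALPHABET, len, replace = TRUE, prob = p), collapse = "")
}

# remove every AUG triplet (any phase) by mutating its G to C
scrub_aug <- function(seq) {
  repeat {
    m <- regexpr("AUG", seq, fixed = TRUE)
    if (m < 0) return(seq)
    substr(seq, m + 2, m + 2) <- "C"
  }
}

non_stop_codons <- function() {
  all3 <- apply(expand.grid(RNA_ALPHABET, RNA_ALPHABET, RNA_ALPHABET), 1,
                paste, collapse = "")
  setdiff(all3, STOP_CODONS)
}

#' Generate a synthetic transcriptome with planted ground truth
#'
#' Genes are assigned to planted classes; ribosomal-protein genes get short
#' transcripts (so length-matched selection is exercised); uORF-planted genes
#' carry at least one complete AUG..in-frame-stop inside the 5' UTR (5' UTRs
#' of unplanted genes are AUG-free, so uORF content is exactly the planted
#' truth); TOP-planted transcripts start with C followed by >= 4 pyrimidines.
#' Deterministic given the config seed.
#'
#' @param config a `sim_config`.
#' @return list with `genes` (a `gene_models`) and `truth` (per-gene class,
#'   per-group true mRNA/TE log2 fold changes vs baseline, planting flags,
#'   baseline abundances).
#' @export
generate_transcriptome <- function(config) {
  set.seed(child_seed(config$seed, "transcriptome"))
  n <- config$n_genes
  cls_names <- names(config$class_props)
  counts <- floor(config$class_props * n)
  counts["null"] <- counts["null"] + (n - sum(counts))
  classes <- rep(cls_names, times = counts)
  ids <- sprintf("g%04d", seq_len(n))
  pool <- non_stop_codons()

  stim <- setdiff(config$groups, config$baseline_group)
  grp_cfc <- if ("cfc" %in% stim) "cfc" else stim[length(stim)]
  grp_shock <- if ("immediate_shock" %in% stim) "immediate_shock" else stim[1]

  e <- config$effect_log2
  sign <- ifelse(runif(n) < 0.5, 1, -1)
  sign[classes == "ieg_shared"] <- 1  # IEGs are induced
  mrna <- matrix(0, n, length(config$groups),
                 dimnames = list(ids, config$groups))
  te <- matrix(0, n, length(config$groups),
               dimnames = list(ids, config$groups))
  mrna[classes == "ieg_shared", c(grp_shock, grp_cfc)] <- e
  mrna[classes == "cfc_only_deg", grp_cfc] <-
    e * sign[classes == "cfc_only_deg"]
  mrna[classes == "shock_only_deg", grp_shock] <-
    e * sign[classes == "shock_only_deg"]
  te[classes == "cfc_only_dtg", grp_cfc] <- e * sign[classes == "cfc_only_dtg"]
  te[classes == "shock_only_dtg", grp_shock] <-
    e * sign[classes == "shock_only_dtg"]
  te_base <- ifelse(classes == "ribosomal_protein",
                    config$rp_te_shift_log2, 0)
  baseline <- rlnorm(n, config$baseline_meanlog, config$baseline_sdlog)
  uorf <- runif(n) < config$uorf_prob[classes]
  top <- runif(n) < config$top_prob[classes]

  draw_len <- function(cfg, region) {
    ml <- cfg[[paste0(region, "_meanlog")]]; sl <- cfg[[paste0(region, "_sdlog")]]
    mn <- cfg[[paste0(region, "_min")]]; mx <- cfg[[paste0(region, "_max")]]
    min(max(round(rlnorm(1, ml, sl)), mn), mx)
  }

  utr5 <- utr3 <- cds <- character(n)
  for (i in seq_len(n)) {
    cfg <- config$len_cfg[[classes[i]]]
    if (is.null(cfg)) cfg <- config$len_cfg$default
    ncod <- sample(cfg$cds_codons[1]:cfg$cds_codons[2], 1)
    cds[i] <- paste0("AUG",
                     paste(sample(pool, ncod - 2, replace = TRUE),
                           collapse = ""),
                     sample(STOP_CODONS, 1))
    utr3[i] <- random_rna(draw_len(cfg, "utr3"), config$gc_utr3)

    # uORF insert prepared first so the UTR length can be regenerated if the
    # planting constraints are infeasible at the drawn length
    uorf_seq <- if (uorf[i]) {
      paste0("AUG", paste(sample(pool, sample(1:5, 1), replace = TRUE),
                          collapse = ""), sample(STOP_CODONS, 1))
    } else ""
    k_top <- if (top[i]) sample(4:12, 1) else 0L
    prefix_len <- if (top[i]) k_top + 2L else 0L
    repeat {
      l5 <- draw_len(cfg, "utr5")
      if (l5 >= prefix_len + nchar(uorf_seq) + 2) break
    }
    s5 <- random_rna(l5, config$gc_utr5)
    if (top[i]) {
      pyr <- paste(sample(c("C", "U"), k_top, replace = TRUE), collapse = "")
      prefix <- paste0("C", pyr, "A")  # purine terminates the tract
      substr(s5, 1, prefix_len) <- prefix
    }
    s5 <- scrub_aug(s5)
    if (!top[i] && detect_top(s5)$top) {
      # background tract would contaminate the planted truth; G cannot seed
      # an AUG or a pyrimidine run
      substr(s5, 1, 1) <- "G"
    }
    if (uorf[i]) {
      lo <- prefix_len + 1L
      hi <- l5 - nchar(uorf_seq) + 1L
      at <- if (hi > lo) sample(lo:hi, 1) else lo
      substr(s5, at, at + nchar(uorf_seq) - 1L) <- uorf_seq
    }
    utr5[i] <- s5
  }

  genes <- gene_models(ids, paste0(ids, ".t1"),
                       class_label = classes,
                       utr5 = utr5, cds = cds, utr3 = utr3)
  truth <- data.frame(
    gene_id = ids, class_label = classes,
    baseline = baseline, te_base_log2 = te_base,
    uorf_planted = uorf, top_planted = top,
    stringsAsFactors = FALSE
  )
  for (g in config$groups) {
    truth[[paste0("mrna_log2fc_", g)]] <- mrna[, g]
    truth[[paste0("te_log2fc_", g)]] <- te[, g]
  }
  list(genes = genes, truth = truth)
}

#' Simulate paired footprint and total-mRNA count matrices
#'
#' Expected relative abundance per gene is baseline x 2^(mRNA effect) x length
#' for total libraries and additionally x 2^(TE effect + class TE shift) for
#' footprint libraries; counts are negative-binomial with the configured
#' dispersion (Poisson in the `dispersion = Inf` limit). Seeded.
#'
#' @param genes a `gene_models`.
#' @param truth truth table from [generate_transcriptome()].
#' @param config a `sim_config`.
#' @return list with `footprint` and `total_mrna` `count_matrix` objects.
#' @export
simulate_counts <- function(genes, truth, config) {
  if (!setequal(genes$gene_id, truth$gene_id))
    stop("truth table must cover every gene exactly once")
  if (config$library_size <= 0) stop("zero library size")
  set.seed(child_seed(config$seed, "counts"))
  truth <- truth[match(genes$gene_id, truth$gene_id), ]
  len <- gene_lengths(genes)$transcript
  draw <- function(mu) {
    if (is.infinite(config$dispersion)) rpois(length(mu), mu)
    else rnbinom(length(mu), mu = mu, size = config$dispersion)
  }
  mats <- list()
  for (assay in c("total_mrna", "footprint")) {
    cols <- list(); ids <- character(0); des <- list()
    for (g in config$groups) for (r in seq_len(config$n_replicates)) {
      eff <- truth[[paste0("mrna_log2fc_", g)]]
      if (assay == "footprint")
        eff <- eff + truth[[paste0("te_log2fc_", g)]] + truth$te_base_log2
      w <- truth$baseline * 2^eff * len
      mu <- config$library_size * w / sum(w)
      lib <- paste(ifelse(assay == "footprint", "fp", "total"), g,
                   paste0("r", r), sep = "_")
      cols[[lib]] <- draw(mu)
      des[[lib]] <- data.frame(library_id = lib, assay = assay, group = g,
                               replicate = r, stringsAsFactors = FALSE)
    }
    m <- do.call(cbind, cols)
    rownames(m) <- genes$gene_id
    storage.mode(m) <- "integer"
    mats[[assay]] <- list(m = m, des = do.call(rbind, des))
  }
  des_all <- library_design(
    c(mats$footprint$des$library_id, mats$total_mrna$des$library_id),
    c(mats$footprint$des$assay, mats$total_mrna$des$assay),
    c(mats$footprint$des$group, mats$total_mrna$des$group),
    c(mats$footprint$des$replicate, mats$total_mrna$des$replicate)
  )
  list(
    footprint = count_matrix(mats$footprint$m,
                             des_all[des_all$assay == "footprint", ]),
    total_mrna = count_matrix(mats$total_mrna$m,
                              des_all[des_all$assay == "total_mrna", ])
  )
}

#' Simulate individual footprint alignments
#'
#' Reads are drawn per gene proportional to footprint counts; lengths from
#' the configured distribution; the 5' end is placed so the P-site
#' (start + offset) falls on CDS frame 0 with probability `frame_fidelity`
#' (else uniformly on the other two frames), uniformly along the CDS.
#'
#' @param genes a `gene_models`.
#' @param counts footprint `count_matrix`.
#' @param config a `sim_config`.
#' @param n_reads number of reads to emit (a seeded subsample of the counted
#'   footprints; default 1e5).
#' @return data.frame (gene_id, start, length, truncated); `start` is the
#'   0-based 5'-end offset within the transcript.
#' @export
simulate_footprint_reads <- function(genes, counts, config, n_reads = 1e5) {
  set.seed(child_seed(config$seed, "reads"))
  len <- gene_lengths(genes)
  w <- rowSums(counts$counts)[genes$gene_id]
  if (all(w == 0)) stop("no footprint counts to sample reads from")
  gi <- sample.int(nrow(genes), n_reads, replace = TRUE, prob = w)
  L <- sample(config$fp_lengths, n_reads, replace = TRUE,
              prob = config$fp_length_probs)
  off <- psite_offset_for(config$psite_offset, L)
  shift <- ifelse(runif(n_reads) < config$frame_fidelity, 0L,
                  sample(c(1L, 2L), n_reads, replace = TRUE))
  cds_start <- len$utr5[gi]
  tx_len <- len$transcript[gi]
  ncod <- len$cds[gi] %/% 3L
  # feasible codon index range so the read stays within the transcript
  kmin <- pmax(0L, ceiling((off - shift - cds_start) / 3))
  kmax <- pmin(ncod - 1L,
               floor((tx_len - L - cds_start - shift + off) / 3))
  feasible <- kmax >= kmin
  k <- integer(n_reads)
  k[feasible] <- kmin[feasible] +
    floor(runif(sum(feasible)) * (kmax[feasible] - kmin[feasible] + 1L))
  start <- cds_start + 3L * k + shift - off
  start[!feasible] <- 0L
  data.frame(gene_id = genes$gene_id[gi], start = as.integer(start),
             length = as.integer(L), truncated = !feasible,
             stringsAsFactors = FALSE)
}

psite_offset_for <- function(psite_offset, lengths) {
  if (length(psite_offset) == 1L && is.null(names(psite_offset)))
    return(rep(as.integer(psite_offset), length(lengths)))
  o <- psite_offset[as.character(lengths)]
  o[is.na(o)] <- 12L
  as.integer(o)
}

#' Simulate a polysome absorbance trace with analytic truth
#'
#' Sum of Gaussian peaks plus a flat baseline plus seeded Gaussian noise on a
#' uniform position grid. The analytic per-peak areas (and the implied
#' polysome/monosome area ratio) are returned as planted truth; peak pairs
#' whose analytic valley is not resolvable above the noise floor are flagged.
#'
#' @param peaks data.frame(center, area, sd, label) with labels among
#'   40S, 60S, 80S, light, heavy; centers must be increasing.
#' @param baseline flat absorbance offset (subtracted truthfully downstream).
#' @param noise_sd Gaussian noise standard deviation.
#' @param from,to,by position grid.
#' @param seed RNG seed for the noise.
#' @return list of class `polysome_trace`: `trace` (position, a254), `peaks`,
#'   `baseline`, and `truth` (areas, monosome/polysome areas, pm_ratio,
#'   resolvable flags).
#' @export
simulate_polysome_trace <- function(peaks = data.frame(
                                      center = c(10, 15, 22, 32, 38, 44,
                                                 52, 60, 70),
                                      area = c(0.5, 0.7, 2.0, 0.8, 0.7, 0.6,
                                               0.5, 0.45, 0.4),
                                      sd = c(1, 1, 1.2, 1.5, 1.5, 1.5,
                                             2, 2, 2),
                                      label = c("40S", "60S", "80S", "light",
                                                "light", "light", "heavy",
                                                "heavy", "heavy")),
                                    baseline = 0.02, noise_sd = 0,
                                    from = 0, to = 100, by = 0.05,
                                    seed = 1L) {
  if (is.unsorted(peaks$center, strictly = TRUE))
    stop("peak centers must be strictly increasing (40S < 60S < 80S < polysomes)")
  set.seed(child_seed(seed, "trace"))
  analytic <- function(x) {
    v <- numeric(length(x)) + baseline
    for (i in seq_len(nrow(peaks)))
      v <- v + peaks$area[i] * stats::dnorm(x, peaks$center[i], peaks$sd[i])
    v
  }
  pos <- seq(from, to, by = by)
  a254 <- pmax(0, analytic(pos) + rnorm(length(pos), 0, noise_sd))
  resolvable <- logical(nrow(peaks) - 1)
  for (i in seq_len(nrow(peaks) - 1)) {
    xs <- seq(peaks$center[i], peaks$center[i + 1], length.out = 200)
    valley <- min(analytic(xs))
    h <- min(analytic(peaks$center[i]), analytic(peaks$center[i + 1]))
    resolvable[i] <- (h - valley) > 3 * noise_sd
  }
  mono <- sum(peaks$area[peaks$label == "80S"])
  poly <- sum(peaks$area[peaks$label %in% c("light", "heavy")])
  structure(list(
    trace = data.frame(position = pos, a254 = a254),
    peaks = peaks, baseline = baseline,
    truth = list(areas = setNames(peaks$area, peaks$label),
                 monosome_area = mono, polysome_area = poly,
                 pm_ratio = poly / mono, resolvable = resolvable)
  ), class = "polysome_trace")
}

#' @export
print.polysome_trace <- function(x, ...) {
  cat("polysome_trace:", nrow(x$trace), "samples,", nrow(x$peaks), "peaks;",
      "true P/M =", format(x$truth$pm_ratio, digits = 4), "\n")
  invisible(x)
}

#' Simulate a qPCR Ct table from known fold changes
#'
#' Ct of the gene of interest is `ct_base - log2(fold change) + noise`; the
#' loading-control Ct is constant across conditions up to noise, so the
#' delta-delta-Ct analysis recovers the planted fold change exactly at zero
#' noise.
#'
#' @param fold_changes data.frame(gene, condition, fc); fc is relative to the
#'   reference condition (whose rows should carry fc = 1) and must be > 0.
#' @param ct_base base cycle threshold of each gene at fold change 1.
#' @param ct_lc loading-control cycle threshold.
#' @param noise_sd Gaussian Ct noise.
#' @param seed RNG seed.
#' @return data.frame(gene, condition, ct_gene, ct_lc).
#' @export
simulate_qpcr <- function(fold_changes, ct_base = 28, ct_lc = 20,
                          noise_sd = 0, seed = 1L) {
  if (any(fold_changes$fc <= 0)) stop("fold changes must be > 0")
  set.seed(child_seed(seed, "qpcr"))
  n <- nrow(fold_changes)
  data.frame(
    gene = fold_changes$gene,
    condition = fold_changes$condition,
    ct_gene = ct_base - log2(fold_changes$fc) + rnorm(n, 0, noise_sd),
    ct_lc = ct_lc + rnorm(n, 0, noise_sd),
    stringsAsFactors = FALSE
  )
}

#' Simulate per-interval freezing scores
#'
#' Each mouse is scored frozen / not frozen in 5-s intervals over a 5-min
#' test (60 intervals by default), Bernoulli with its group's freezing
#' probability.
#'
#' @param p_freeze named per-group freezing probability in \[0, 1\].
#' @param n_mice mice per group.
#' @param n_intervals intervals per session.
#' @param seed RNG seed.
#' @return data.frame(mouse_id, group, interval, frozen).
#' @export
simulate_freezing <- function(p_freeze = c(homecage = 0.05,
                                           immediate_shock = 0.10,
                                           cfc = 0.70),
                              n_mice = 12L, n_intervals = 60L, seed = 1L) {
  stopifnot(all(p_freeze >= 0 & p_freeze <= 1), n_intervals > 0)
  set.seed(child_seed(seed, "freezing"))
  out <- list()
  for (g in names(p_freeze)) for (m in seq_len(n_mice)) {
    out[[paste(g, m)]] <- data.frame(
      mouse_id = sprintf("%s_m%02d", g, m), group = g,
      interval = seq_len(n_intervals),
      frozen = rbinom(n_intervals, 1, p_freeze[g]),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
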