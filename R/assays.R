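#' Detect monosome/polysome boundaries on an absorbance trace
#'
#' Peaks are located on a moving-average-smoothed copy of the trace; the
#' boundaries are a = valley between the 60S and 80S peaks (peaks 2 and 3),
#' b = valley between the 80S peak and the first polysome peak, c = the last
#' recorded position. A manual override is returned verbatim.
#'
#' @param trace data.frame(position, a254) or a `polysome_trace`.
#' @param smooth_window moving-average window (samples).
#' @param min_peak_height minimum smoothed absorbance for a peak; default
#'   2% of the trace maximum above the trace minimum.
#' @param manual optional numeric c(a, b, c) override.
#' @return named numeric c(a, b, c).
#' @export
detect_trace_boundaries <- function(trace, smooth_window = 11L,
                                    min_peak_height = NULL, manual = NULL) {
  if (inherits(trace, "polysome_trace")) trace <- trace$trace
  if (!is.null(manual)) {
    stopifnot(length(manual) == 3, manual[1] < manual[2],
              manual[2] < manual[3])
    return(setNames(as.numeric(manual), c("a", "b", "c")))
  }
  pos <- trace$position; y <- trace$a254
  if (is.unsorted(pos, strictly = TRUE))
    stop("positions must be strictly increasing")
  sm <- as.numeric(filter(y, rep(1 / smooth_window, smooth_window),
                          sides = 2))
  sm[is.na(sm)] <- y[is.na(sm)]
  if (is.null(min_peak_height))
    min_peak_height <- min(sm) + 0.02 * (max(sm) - min(sm))
  pk <- pracma::findpeaks(sm, minpeakheight = min_peak_height,
                          minpeakdistance = max(3L, smooth_window))
  if (is.null(pk) || nrow(pk) < 4)
    stop("fewer than 4 resolvable peaks; supply manual boundaries ",
         "(manual = c(a, b, c))")
  pk <- pk[order(pk[, 2]), , drop = FALSE]  # by position
  valley <- function(i1, i2) {
    seg <- i1:i2
    pos[seg[which.min(sm[seg])]]
  }
  a <- valley(pk[2, 2], pk[3, 2])
  b <- valley(pk[3, 2], pk[4, 2])
  setNames(c(a, b, pos[length(pos)]), c("a", "b", "c"))
}

trapz_between <- function(pos, y, lo, hi) {
  inside <- pos > lo & pos < hi
  xs <- c(lo, pos[inside], hi)
  ys <- c(approx(pos, y, lo)$y, y[inside], approx(pos, y, hi)$y)
  pracma::trapz(xs, ys)
}

#' Polysome-to-monosome area ratio
#'
#' Trapezoidal area under the (baseline-subtracted) A254 curve between b and
#' c (polysomes), divided by the area between a and b (80S monosome).
#'
#' @param trace data.frame(position, a254) or a `polysome_trace` (its stored
#'   flat baseline is subtracted automatically).
#' @param a,b,c boundary positions with a < b < c.
#' @return P/M area ratio.
#' @export
polysome_monosome_ratio <- function(trace, a, b, c) {
  baseline <- 0
  if (inherits(trace, "polysome_trace")) {
    baseline <- trace$baseline
    trace <- trace$trace
  }
  if (!(a < b && b < c)) stop("boundaries must satisfy a < b < c")
  pos <- trace$position
  if (a < min(pos) || c > max(pos)) stop("boundaries outside the trace range")
  y <- trace$a254 - baseline
  mono <- trapz_between(pos, y, a, b)
  if (mono <= 0) stop("monosome area is not positive")
  unname(trapz_between(pos, y, b, c) / mono)
}

#' Heavy/light polysome mRNA abundance ratio with spike-in normalization
#'
#' Per fraction, relative abundance = 2^(Ct_spike - Ct_gene) scaled by the
#' fraction's total-RNA balance factor; the reported statistic is heavy
#' abundance / light abundance per gene, averaged over replicates with SEM.
#' Any per-fraction recovery loss shifting gene and spike-in Ct equally
#' cancels.
#'
#' @param measurements data.frame(gene, replicate, fraction in
#'   \{light, heavy\}, ct_gene, ct_spike, total_rna_factor (optional,
#'   default 1)).
#' @return data.frame(gene, n, ratio, sem).
#' @export
heavy_light_ratio <- function(measurements) {
  m <- measurements
  need <- c("gene", "replicate", "fraction", "ct_gene", "ct_spike")
  if (!all(need %in% names(m)))
    stop("measurements need columns: ", paste(need, collapse = ", "))
  if (any(is.na(m$ct_spike)))
    stop("missing spike-in Ct: normalization impossible")
  if (is.null(m$total_rna_factor)) m$total_rna_factor <- 1
  m$abundance <- 2^(m$ct_spike - m$ct_gene) * m$total_rna_factor
  out <- list()
  for (g in unique(m$gene)) {
    sub <- m[m$gene == g, ]
    ratios <- sapply(unique(sub$replicate), function(r) {
      h <- sub$abundance[sub$replicate == r & sub$fraction == "heavy"]
      l <- sub$abundance[sub$replicate == r & sub$fraction == "light"]
      if (length(h) != 1 || length(l) != 1) return(NA_real_)
      h / l
    })
    ratios <- ratios[!is.na(ratios)]
    out[[g]] <- data.frame(
      gene = g, n = length(ratios), ratio = mean(ratios),
      sem = if (length(ratios) > 1) sd(ratios) / sqrt(length(ratios))
            else NA_real_,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Delta-delta-Ct expression fold change
#'
#' Delta-Ct = Ct(gene) - Ct(loading control) per condition;
#' delta-delta-Ct = delta-Ct(condition) - delta-Ct(reference);
#' fold change = 2^(-delta-delta-Ct). Assumes PCR efficiency 2.
#'
#' @param measurements data.frame(gene, condition, ct_gene, ct_lc).
#' @param reference reference condition name (default "homecage").
#' @return data.frame(gene, condition, ddct, fold_change, log2_fold_change)
#'   for non-reference conditions.
#' @export
ddct_fold_change <- function(measurements, reference = "homecage") {
  m <- measurements
  if (any(is.na(m$ct_lc))) stop("missing loading-control Ct")
  if (any(is.na(m$ct_gene))) stop("missing gene Ct")
  if (!reference %in% m$condition)
    stop("reference condition absent: ", reference)
  m$dct <- m$ct_gene - m$ct_lc
  out <- list()
  for (g in unique(m$gene)) {
    sub <- m[m$gene == g, ]
    ref <- sub$dct[sub$condition == reference]
    if (length(ref) != 1) stop("need exactly one reference row per gene (",
                               g, ")")
    for (cond in setdiff(unique(sub$condition), reference)) {
      ddct <- sub$dct[sub$condition == cond] - ref
      out[[length(out) + 1]] <- data.frame(
        gene = g, condition = cond, ddct = ddct,
        fold_change = 2^(-ddct), log2_fold_change = -ddct,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Percentage of intervals scored frozen
#'
#' @param scores binary per-interval freeze scores for one session.
#' @return 100 x frozen intervals / total intervals.
#' @export
freezing_percent <- function(scores) {
  if (!length(scores)) stop("empty session")
  if (!all(scores %in% c(0, 1))) stop("scores must be binary")
  100 * mean(scores)
}

#' Per-mouse freezing percentages from an interval score table
#' @param session data.frame(mouse_id, group, interval, frozen).
#' @return data.frame(mouse_id, group, freezing_percent).
#' @export
freezing_summary <- function(session) {
  out <- list()
  for (m in unique(session$mouse_id)) {
    sub <- session[session$mouse_id == m, ]
    out[[m]] <- data.frame(mouse_id = m, group = sub$group[1],
                           freezing_percent = freezing_percent(sub$frozen),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Group comparison statistics for assay read-outs
#'
#' One-way ANOVA with Tukey or Bonferroni post-hoc, or a two-sided Student's
#' t-test for exactly two groups.
#'
#' @param values numeric response.
#' @param groups group labels (same length).
#' @param test "anova" or "t".
#' @param posthoc "tukey" or "bonferroni" (ANOVA only).
#' @return list with the test statistics (F/t, dfs, p) and, for ANOVA, a
#'   post-hoc table.
#' @export
group_compare <- function(values, groups, test = c("anova", "t"),
                          posthoc = c("tukey", "bonferroni")) {
  test <- match.arg(test); posthoc <- match.arg(posthoc)
  groups <- factor(groups)
  if (test == "t") {
    if (nlevels(groups) != 2) stop("t-test needs exactly 2 groups")
    ts <- t.test(values ~ groups, var.equal = TRUE)
    return(list(test = "t", t = unname(ts$statistic),
                df = unname(ts$parameter), p = ts$p.value))
  }
  sizes <- table(groups)
  if (any(sizes < 2))
    stop("singleton group in ANOVA: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  fit <- aov(values ~ groups)
  s <- summary(fit)[[1]]
  res <- list(test = "anova", F = s["groups", "F value"],
              df1 = s["groups", "Df"], df2 = s["Residuals", "Df"],
              p = s["groups", "Pr(>F)"])
  if (posthoc == "tukey") {
    res$posthoc <- as.data.frame(TukeyHSD(fit)$groups)
  } else {
    pw <- pairwise.t.test(values, groups, p.adjust.method = "bonferroni",
                          pool.sd = TRUE)
    res$posthoc <- as.data.frame(as.table(pw$p.value),
                                 stringsAsFactors = FALSE)
    names(res$posthoc) <- c("group1", "group2", "p_adjusted")
    res$posthoc <- res$posthoc[!is.na(res$posthoc$p_adjusted), ]
  }
  res
}
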