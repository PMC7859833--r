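#' Basic per-region UTR statistics
#'
#' @param gene one row of a `gene_models` table (or a list with utr5/utr3).
#' @return data.frame(region, length, gc_percent); GC is NA for an empty
#'   region (explicit undefined, not 0).
#' @export
utr_basic_stats <- function(gene) {
  one <- function(region, s) {
    n <- nchar(s)
    gc <- if (n > 0) {
      100 * (n - nchar(gsub("[GC]", "", s))) / n
    } else NA_real_
    data.frame(region = region, length = n, gc_percent = gc,
               stringsAsFactors = FALSE)
  }
  rbind(one("utr5", gene$utr5), one("utr3", gene$utr3))
}

PAIR_ENERGY <- c("GC" = -3, "CG" = -3, "AU" = -2, "UA" = -2,
                 "GU" = -1, "UG" = -1)

#' Minimum free energy of a nested RNA secondary structure
#'
#' A simplified base-pairing energy model: each pair contributes a fixed
#' energy (G-C -3, A-U -2, G-U -1 kcal/mol), structures are nested with a
#' minimum hairpin loop of `min_loop` unpaired nucleotides, and the minimum
#' total energy is computed by Nussinov-style dynamic programming. This is a
#' deliberately simple stand-in for nearest-neighbour folding engines —
#' adequate for relative (between-group) comparisons, not for absolute
#' energies.
#'
#' @param sequence RNA string (T is accepted and normalized to U).
#' @param min_loop minimum unpaired nucleotides in a hairpin loop.
#' @param cap sequences longer than this are still folded on their full
#'   length, with a warning (the DP is O(n^3)).
#' @return MFE in kcal/mol (<= 0; 0 when nothing can pair).
#' @export
fold_min_energy <- function(sequence, min_loop = 3L, cap = 4000L) {
  s <- as_rna(sequence)
  n <- nchar(s)
  if (n < 1) stop("sequence must have length >= 1")
  if (n > cap) warning("sequence longer than ", cap,
                       " nt folded on the full length")
  .nussinov_mfe(s, as.integer(min_loop))
}

#' Find upstream open reading frames in a 5' UTR
#'
#' A uORF is an AUG followed by an in-frame stop codon whose last nucleotide
#' lies within the UTR, with a minimum length of `min_codons` codons
#' including the stop. Each AUG is paired with its first in-frame stop;
#' overlapping and nested uORFs are all reported.
#'
#' @param utr5 5' UTR sequence (may be empty).
#' @param min_codons minimum codons including the stop (default 2, i.e.
#'   >= 6 nt).
#' @return data.frame(start, end, n_codons) in 0-based half-open UTR
#'   coordinates; zero rows when none.
#' @export
detect_uorfs <- function(utr5, min_codons = 2L) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      n_codons = integer(0))
  if (is.na(utr5) || nchar(utr5) < min_codons * 3) return(empty)
  s <- as_rna(utr5)
  n <- nchar(s)
  augs <- gregexpr("AUG", s, fixed = TRUE)[[1]]
  if (augs[1] < 0) return(empty)
  rows <- list()
  for (a in augs) {
    j <- a + 3
    while (j + 2 <= n) {
      cod <- substr(s, j, j + 2)
      if (cod %in% STOP_CODONS) {
        ncod <- (j + 3 - a) / 3
        if (ncod >= min_codons)
          rows[[length(rows) + 1]] <- data.frame(
            start = a - 1L, end = j + 2L, n_codons = as.integer(ncod))
        break
      }
      j <- j + 3
    }
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Detect a 5' terminal oligopyrimidine (TOP) tract
#'
#' TOP-positive iff the first transcribed nucleotide is C and it is followed
#' by an uninterrupted run of at least `min_run` pyrimidines (C/U).
#'
#' @param utr5 transcript 5'-end sequence.
#' @param min_run minimum pyrimidines after the initial C.
#' @return list(top = logical, tract_length = C plus the following
#'   pyrimidine run).
#' @export
detect_top <- function(utr5, min_run = 4L) {
  if (is.na(utr5) || nchar(utr5) == 0)
    return(list(top = FALSE, tract_length = 0L))
  s <- as_rna(utr5)
  if (substr(s, 1, 1) != "C") {
    run0 <- attr(regexpr("^[CU]*", s), "match.length")
    return(list(top = FALSE, tract_length = as.integer(run0)))
  }
  run <- attr(regexpr("^[CU]*", substr(s, 2, nchar(s))), "match.length")
  list(top = run >= min_run, tract_length = as.integer(1L + run))
}

#' Translate an IUPAC nucleotide pattern to an RNA regular expression
#' @param pattern IUPAC string (RNA; T treated as U).
#' @return character regex.
#' @export
iupac_to_regex <- function(pattern) {
  map <- c(A = "A", C = "C", G = "G", U = "U", T = "U",
           R = "[AG]", Y = "[CU]", S = "[GC]", W = "[AU]",
           K = "[GU]", M = "[AC]", B = "[CGU]", D = "[AGU]",
           H = "[ACU]", V = "[ACG]", N = "[ACGU]")
  ch <- strsplit(toupper(pattern), "")[[1]]
  if (any(!ch %in% names(map))) stop("unknown IUPAC letter in: ", pattern)
  paste(map[ch], collapse = "")
}

#' Default UTR motif registry
#'
#' 4 motif types for the 5' UTR (uORF, TOP, a PAS-like AAUAAA, and a
#' pyrimidine-rich element of >= 8 nt) and 9 for the 3' UTR (PAS, AU-rich
#' element with >= 2 AUUUA copies, CPE, Musashi element, Brd-box, K-box,
#' GY-box, a 15-LOX-DICE-like element, and a UA-rich element of >= 6 nt).
#' The registry is fully configurable; the exact membership is a documented
#' choice and is recorded in the run summary.
#'
#' @return data.frame(name, region, kind, pattern, min_copies) of class
#'   `motif_registry`; `kind` is "rule" (uORF/TOP scanners), "iupac" or
#'   "regex".
#' @export
default_motif_registry <- function() {
  reg <- rbind(
    data.frame(name = "uORF", region = "utr5", kind = "rule",
               pattern = "uorf", min_copies = 1L),
    data.frame(name = "TOP", region = "utr5", kind = "rule",
               pattern = "top", min_copies = 1L),
    data.frame(name = "PAS_like_5p", region = "utr5", kind = "iupac",
               pattern = "AAUAAA", min_copies = 1L),
    data.frame(name = "pyrimidine_rich", region = "utr5", kind = "regex",
               pattern = "[CU]{8,}", min_copies = 1L),
    data.frame(name = "PAS", region = "utr3", kind = "iupac",
               pattern = "AWUAAA", min_copies = 1L),
    data.frame(name = "ARE", region = "utr3", kind = "iupac",
               pattern = "AUUUA", min_copies = 2L),
    data.frame(name = "CPE", region = "utr3", kind = "iupac",
               pattern = "UUUUUAU", min_copies = 1L),
    data.frame(name = "Musashi", region = "utr3", kind = "iupac",
               pattern = "AUAGU", min_copies = 1L),
    data.frame(name = "Brd_box", region = "utr3", kind = "iupac",
               pattern = "AGCUUUA", min_copies = 1L),
    data.frame(name = "K_box", region = "utr3", kind = "iupac",
               pattern = "UGUGAU", min_copies = 1L),
    data.frame(name = "GY_box", region = "utr3", kind = "iupac",
               pattern = "GUCUUCC", min_copies = 1L),
    data.frame(name = "DICE_like", region = "utr3", kind = "iupac",
               pattern = "CCCCRCCCUCYUCCCC", min_copies = 1L),
    data.frame(name = "UA_rich", region = "utr3", kind = "regex",
               pattern = "[AU]{6,}", min_copies = 1L)
  )
  if (anyDuplicated(reg$name)) stop("registry names must be unique")
  class(reg) <- c("motif_registry", "data.frame")
  reg
}

#' Scan a gene's UTRs against a motif registry
#'
#' Pattern motifs are matched after IUPAC expansion; algorithmic motifs
#' dispatch to [detect_uorfs()] and [detect_top()]. Hit coordinates are
#' 0-based half-open within the region. Results are independent of scan
#' order.
#'
#' @param gene one row of a `gene_models`.
#' @param registry a `motif_registry` (default [default_motif_registry()]).
#' @return list: `hits` data.frame(gene_id, region, motif, start, end) and
#'   `presence` data.frame(gene_id, region, motif, present) honouring each
#'   motif's `min_copies`.
#' @export
scan_motifs <- function(gene, registry = default_motif_registry()) {
  if (!all(registry$region %in% c("utr5", "utr3")))
    stop("motif registered for unknown region: ",
         paste(setdiff(registry$region, c("utr5", "utr3")), collapse = ", "))
  hits <- list(); pres <- list()
  for (i in seq_len(nrow(registry))) {
    r <- registry[i, ]
    seqr <- if (r$region == "utr5") gene$utr5 else gene$utr3
    hh <- NULL
    if (r$kind == "rule") {
      if (r$pattern == "uorf") {
        u <- detect_uorfs(seqr)
        if (nrow(u)) hh <- data.frame(start = u$start, end = u$end)
      } else if (r$pattern == "top") {
        tp <- detect_top(seqr)
        if (tp$top) hh <- data.frame(start = 0L, end = tp$tract_length)
      } else stop("unknown algorithmic rule: ", r$pattern)
    } else {
      rx <- if (r$kind == "iupac") iupac_to_regex(r$pattern) else r$pattern
      m <- gregexpr(rx, as_rna(seqr))[[1]]
      if (m[1] > 0) {
        hh <- data.frame(start = as.integer(m) - 1L,
                         end = as.integer(m) - 1L +
                           attr(m, "match.length"))
      }
    }
    n_hits <- if (is.null(hh)) 0L else nrow(hh)
    if (n_hits)
      hits[[length(hits) + 1]] <- data.frame(
        gene_id = gene$gene_id, region = r$region, motif = r$name, hh,
        stringsAsFactors = FALSE)
    pres[[length(pres) + 1]] <- data.frame(
      gene_id = gene$gene_id, region = r$region, motif = r$name,
      present = n_hits >= r$min_copies, stringsAsFactors = FALSE)
  }
  list(
    hits = if (length(hits)) do.call(rbind, hits) else
      data.frame(gene_id = character(0), region = character(0),
                 motif = character(0), start = integer(0), end = integer(0)),
    presence = do.call(rbind, pres)
  )
}

#' Full UTR feature table for a set of genes
#'
#' @param genes a `gene_models` (subset to the genes of interest first).
#' @param registry a `motif_registry`.
#' @param mfe compute the folding minimum free energy per region (O(n^3)
#'   per sequence; skip for large unfiltered sets).
#' @return list: `features` data.frame(gene_id, region, length, gc_percent,
#'   mfe), `presence`, `hits`.
#' @export
utr_feature_table <- function(genes, registry = default_motif_registry(),
                              mfe = TRUE) {
  feats <- list(); pres <- list(); hits <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    st <- utr_basic_stats(g)
    st$gene_id <- g$gene_id
    st$mfe <- NA_real_
    if (mfe) {
      if (nchar(g$utr5)) st$mfe[st$region == "utr5"] <- fold_min_energy(g$utr5)
      if (nchar(g$utr3)) st$mfe[st$region == "utr3"] <- fold_min_energy(g$utr3)
    }
    feats[[i]] <- st[, c("gene_id", "region", "length", "gc_percent", "mfe")]
    sc <- scan_motifs(g, registry)
    pres[[i]] <- sc$presence
    hits[[i]] <- sc$hits
  }
  list(features = do.call(rbind, feats),
       presence = do.call(rbind, pres),
       hits = do.call(rbind, hits))
}

#' Group comparison of UTR features and motif content
#'
#' Numeric features (length, GC, MFE) are compared between all group pairs
#' with two-sided Student's t-tests (equal variance). Motif content is
#' compared per region by a two-way ANOVA of presence percentage with
#' factors motif type and experimental group (no replication within cells:
#' additive model, so with m motifs and g groups the motif factor has
#' df (m-1, (m-1)(g-1))), followed by Bonferroni-adjusted pairwise group
#' contrasts on the residual mean square.
#'
#' @param features feature table (gene_id, region, length, gc_percent, mfe)
#'   as from [utr_feature_table()].
#' @param presence motif presence table (gene_id, region, motif, present).
#' @param groups named group assignment: gene_id -> group label.
#' @return list: `t_tests`, `anova`, `posthoc`, `percentages`.
#' @export
compare_utr_features <- function(features, presence, groups) {
  features$group <- groups[features$gene_id]
  presence$group <- groups[presence$gene_id]
  features <- features[!is.na(features$group), ]
  presence <- presence[!is.na(presence$group), ]
  glev <- sort(unique(features$group))
  if (length(glev) < 2) stop("need at least 2 groups")

  tt <- list()
  for (region in unique(features$region)) {
    for (feat in c("length", "gc_percent", "mfe")) {
      for (i in seq_along(glev)) for (j in seq_along(glev)) {
        if (j <= i) next
        x <- features[features$region == region &
                        features$group == glev[i], feat]
        y <- features[features$region == region &
                        features$group == glev[j], feat]
        x <- x[!is.na(x)]; y <- y[!is.na(y)]
        if (length(x) < 2 || length(y) < 2) {
          tt[[length(tt) + 1]] <- data.frame(
            region = region, feature = feat, group1 = glev[i],
            group2 = glev[j], t = NA_real_, df = NA_real_, p = NA_real_,
            skipped = TRUE, stringsAsFactors = FALSE)
          next
        }
        ts <- tryCatch(t.test(x, y, var.equal = TRUE),
                       error = function(e) NULL)  # e.g. constant data
        tt[[length(tt) + 1]] <- if (is.null(ts)) data.frame(
          region = region, feature = feat, group1 = glev[i],
          group2 = glev[j], t = NA_real_, df = NA_real_, p = NA_real_,
          skipped = TRUE, stringsAsFactors = FALSE)
        else data.frame(
          region = region, feature = feat, group1 = glev[i],
          group2 = glev[j], t = unname(ts$statistic),
          df = unname(ts$parameter), p = ts$p.value, skipped = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  }

  an <- list(); ph <- list(); pcts <- list()
  for (region in unique(presence$region)) {
    sub <- presence[presence$region == region, ]
    pct <- aggregate(present ~ motif + group, sub,
                     function(v) 100 * mean(v))
    names(pct)[3] <- "percent"
    pct$region <- region
    pcts[[region]] <- pct
    if (length(unique(pct$motif)) < 2) next
    fit <- aov(percent ~ motif + group, data = pct)
    s <- summary(fit)[[1]]
    an[[region]] <- data.frame(
      region = region,
      factor = trimws(rownames(s))[1:2],
      df1 = s[1:2, "Df"], df2 = s["Residuals", "Df"],
      F = s[1:2, "F value"], p = s[1:2, "Pr(>F)"],
      stringsAsFactors = FALSE)
    # Bonferroni post-hoc group contrasts on the residual MS
    mse <- s["Residuals", "Mean Sq"]; dfr <- s["Residuals", "Df"]
    nm <- length(unique(pct$motif))
    gmeans <- tapply(pct$percent, pct$group, mean)
    pairs <- utils::combn(names(gmeans), 2)
    np <- ncol(pairs)
    for (k in seq_len(np)) {
      d <- gmeans[pairs[1, k]] - gmeans[pairs[2, k]]
      se <- sqrt(mse * 2 / nm)
      tstat <- d / se
      p <- min(1, 2 * pt(-abs(tstat), dfr) * np)
      ph[[length(ph) + 1]] <- data.frame(
        region = region, group1 = pairs[1, k], group2 = pairs[2, k],
        diff_percent = unname(d), t = unname(tstat), df = dfr,
        p_bonferroni = unname(p), stringsAsFactors = FALSE)
    }
  }
  list(t_tests = do.call(rbind, tt),
       anova = do.call(rbind, an),
       posthoc = if (length(ph)) do.call(rbind, ph) else NULL,
       percentages = do.call(rbind, pcts))
}
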