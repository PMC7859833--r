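#' Per-gene ratio of a stimulated group to the baseline group
#'
#' Transcription level uses group-mean total-mRNA RPKM; translation level
#' uses group-mean TE. Undefined values (baseline zero/undefined, or group
#' value undefined) propagate as NA.
#'
#' @param tt a `te_table` from [compute_te()].
#' @param group stimulated group name.
#' @param baseline baseline group (default "homecage").
#' @param level "transcription" (RPKM) or "translation" (TE).
#' @return named numeric ratio vector with NA for undefined genes.
#' @export
condition_ratio <- function(tt, group, baseline = "homecage",
                            level = c("transcription", "translation")) {
  level <- match.arg(level)
  m <- if (level == "transcription") tt$group_rpkm_total else tt$group_te
  if (!all(c(group, baseline) %in% colnames(m)))
    stop("group or baseline not present: ", group, ", ", baseline)
  num <- m[, group]; den <- m[, baseline]
  ratio <- num / den
  ratio[is.na(num) | is.na(den) | den <= 0 | num < 0] <- NA_real_
  ratio[!is.na(num) & num == 0 & !is.na(den) & den > 0] <- NA_real_
  ratio
}

#' Call up/down/unchanged at fold-change cutoffs
#'
#' Strict inequalities: up iff ratio > `up_cutoff`, down iff
#' ratio < `down_cutoff`; a ratio exactly at a cutoff is unchanged.
#' NA ratios are "undefined".
#'
#' @param ratios named ratio vector.
#' @param up_cutoff,down_cutoff cutoffs with down < 1 < up (defaults 1.5 and
#'   0.667).
#' @return named character vector in \{up, down, unchanged, undefined\}.
#' @export
call_changes <- function(ratios, up_cutoff = 1.5, down_cutoff = 0.667) {
  if (!(down_cutoff < 1 && 1 < up_cutoff))
    stop("cutoffs must satisfy down_cutoff < 1 < up_cutoff")
  out <- rep("unchanged", length(ratios))
  out[ratios > up_cutoff] <- "up"
  out[ratios < down_cutoff] <- "down"
  out[is.na(ratios)] <- "undefined"
  setNames(out, names(ratios))
}

#' Contrast set algebra between two call vectors
#'
#' "Shared" requires a same-direction call in both groups; genes called in
#' one group only (in that direction) form the group-exclusive sets — the
#' "CFC minus immediate shock" subtraction. Gene lists are sorted.
#'
#' @param calls_a,calls_b named call vectors over the same gene universe
#'   (e.g. CFC and immediate shock).
#' @param labels names for the two groups.
#' @return object of class `contrast_result`: per direction, sorted gene
#'   lists `a_only`, `b_only`, `shared`, plus Venn `counts`.
#' @export
contrast_sets <- function(calls_a, calls_b, labels = c("cfc", "shock")) {
  if (!setequal(names(calls_a), names(calls_b)) ||
      length(calls_a) != length(calls_b))
    stop("call vectors must cover the same gene universe")
  calls_b <- calls_b[names(calls_a)]
  per_dir <- lapply(c(up = "up", down = "down"), function(dir) {
    a <- names(calls_a)[calls_a == dir]
    b <- names(calls_b)[calls_b == dir]
    list(a_only = sort(setdiff(a, b)),
         b_only = sort(setdiff(b, a)),
         shared = sort(intersect(a, b)))
  })
  counts <- do.call(rbind, lapply(names(per_dir), function(dir) {
    s <- per_dir[[dir]]
    data.frame(direction = dir,
               region = c(paste0(labels[1], "_only"),
                          paste0(labels[2], "_only"), "shared"),
               n = c(length(s$a_only), length(s$b_only), length(s$shared)),
               stringsAsFactors = FALSE)
  }))
  structure(list(sets = per_dir, counts = counts, labels = labels),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat("contrast_result (", paste(x$labels, collapse = " vs "), ")\n", sep = "")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' @export
summary.contrast_result <- function(object, ...) {
  cat("Venn regions by direction:\n")
  print(object$counts, row.names = FALSE)
  for (dir in names(object$sets)) {
    s <- object$sets[[dir]]
    cat(dir, "shared:", paste(head(s$shared, 8), collapse = ", "),
        if (length(s$shared) > 8) "..." else "", "\n")
  }
  invisible(object)
}

#' Cross-condition correlation of log2 ratios
#'
#' Squared Pearson correlation of the two groups' log2 ratios-to-baseline
#' over jointly defined genes; also returns the scatter table.
#'
#' @param ratios_a,ratios_b named ratio vectors on the same genes.
#' @return list: `r_squared`, `n_genes`, `scatter` data.frame.
#' @export
cross_condition_correlation <- function(ratios_a, ratios_b) {
  ratios_b <- ratios_b[names(ratios_a)]
  ok <- !is.na(ratios_a) & !is.na(ratios_b) & ratios_a > 0 & ratios_b > 0
  if (sum(ok) < 3) stop("need at least 3 genes with both ratios defined")
  la <- log2(ratios_a[ok]); lb <- log2(ratios_b[ok])
  r2 <- NA_real_
  if (sd(la) == 0 || sd(lb) == 0) warning("zero variance in log2 ratios")
  else r2 <- cor(la, lb)^2
  list(r_squared = r2, n_genes = sum(ok),
       scatter = data.frame(gene_id = names(ratios_a)[ok],
                            log2_ratio_a = la, log2_ratio_b = lb,
                            stringsAsFactors = FALSE))
}
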