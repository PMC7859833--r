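#' Compute RPKM from a count matrix
#'
#' RPKM(g, lib) = count x 10^9 / (transcript length in nt x library size).
#'
#' @param counts a `count_matrix`.
#' @param genes a `gene_models` covering its genes (lengths taken from here).
#' @return object of class `expression_table`: `rpkm` matrix, `design`,
#'   `length` (nt), `expressible` logical matrix (count > 0).
#' @export
compute_rpkm <- function(counts, genes) {
  if (any(counts$library_size <= 0)) stop("zero library size")
  len <- gene_lengths(genes)
  len <- setNames(len$transcript, len$gene_id)[rownames(counts$counts)]
  if (any(is.na(len))) stop("gene(s) in counts missing from annotation")
  if (any(len <= 0)) stop("transcript lengths must be > 0")
  rpkm <- sweep(counts$counts / len, 2, counts$library_size, "/") * 1e9
  structure(list(rpkm = rpkm, design = counts$design, length = len,
                 expressible = counts$counts > 0),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat("expression_table:", nrow(x$rpkm), "genes x", ncol(x$rpkm),
      "libraries (", paste(unique(x$design$assay), collapse = "+"), ")\n")
  invisible(x)
}

#' Normalize RPKM across libraries
#'
#' Quantile normalization (the default, applied within each assay) equalizes
#' the whole RPKM distribution across libraries; "median-ratio" rescales each
#' library by the median ratio to the per-gene geometric mean. Both are
#' rank-preserving within each library.
#'
#' @param expr an `expression_table`.
#' @param method "quantile" or "median-ratio".
#' @return normalized `expression_table`.
#' @export
normalize_libraries <- function(expr, method = c("quantile", "median-ratio")) {
  method <- match.arg(method)
  if (ncol(expr$rpkm) < 2) {
    warning("single library: normalization is the identity")
    return(expr)
  }
  for (assay in unique(expr$design$assay)) {
    sel <- expr$design$assay == assay
    m <- expr$rpkm[, sel, drop = FALSE]
    if (ncol(m) < 2) next
    if (method == "quantile") {
      m2 <- limma::normalizeQuantiles(m)
    } else {
      pos <- rowSums(m > 0) == ncol(m)
      gm <- exp(rowMeans(log(m[pos, , drop = FALSE])))
      sf <- apply(m[pos, , drop = FALSE], 2, function(col) median(col / gm))
      m2 <- sweep(m, 2, sf, "/")
    }
    dimnames(m2) <- dimnames(m)
    expr$rpkm[, sel] <- m2
  }
  expr$normalization <- method
  expr
}

#' Translational efficiency per replicate pair and per group
#'
#' TE(g, group, rep) = footprint RPKM / total RPKM for the paired libraries;
#' pairs where either RPKM is zero are undefined (flagged, excluded
#' downstream). Group TE is the mean of the defined replicate TEs (natural
#' scale by default; log-scale averaging by flag). Group mean RPKM per assay
#' is carried along for transcription-level contrasts.
#'
#' @param expr an `expression_table` containing both assays, or a list of two
#'   expression tables (footprint, total_mrna).
#' @param log_scale average replicate TEs on the log2 scale.
#' @return object of class `te_table`: `te` (genes x group:replicate),
#'   `group_te`, `group_rpkm_total`, `group_rpkm_fp`, `defined` matrices.
#' @export
compute_te <- function(expr, log_scale = FALSE) {
  if (!inherits(expr, "expression_table") && is.list(expr)) {
    rpkm <- cbind(expr[[1]]$rpkm, expr[[2]]$rpkm)
    design <- rbind(expr[[1]]$design, expr[[2]]$design)
  } else {
    rpkm <- expr$rpkm; design <- expr$design
  }
  fp <- design[design$assay == "footprint", ]
  to <- design[design$assay == "total_mrna", ]
  key <- function(d) paste(d$group, d$replicate, sep = ":")
  orphan <- c(setdiff(key(fp), key(to)), setdiff(key(to), key(fp)))
  if (length(orphan))
    stop("unpaired footprint/total library for (group:replicate) ",
         paste(orphan, collapse = ", "))
  fp <- fp[order(key(fp)), ]; to <- to[order(key(to)), ]
  num <- rpkm[, fp$library_id, drop = FALSE]
  den <- rpkm[, to$library_id, drop = FALSE]
  te <- num / den
  te[num == 0 | den == 0] <- NA_real_
  colnames(te) <- key(fp)
  groups <- unique(fp$group)
  agg <- function(m, cols) {
    sapply(cols, function(cs) {
      sub <- m[, cs, drop = FALSE]
      if (log_scale) 2^rowMeans(log2(sub), na.rm = TRUE)
      else rowMeans(sub, na.rm = TRUE)
    })
  }
  group_cols <- lapply(groups, function(g) key(fp)[fp$group == g])
  names(group_cols) <- groups
  group_te <- agg(te, group_cols)
  group_te[is.nan(group_te)] <- NA_real_
  grp_mean <- function(d) {
    sapply(groups, function(g) {
      rowMeans(rpkm[, d$library_id[d$group == g], drop = FALSE])
    })
  }
  structure(list(
    te = te, group_te = group_te,
    group_rpkm_total = grp_mean(to), group_rpkm_fp = grp_mean(fp),
    defined = !is.na(te), groups = groups, log_scale = log_scale
  ), class = "te_table")
}

#' @export
print.te_table <- function(x, ...) {
  cat("te_table:", nrow(x$te), "genes;", ncol(x$te), "replicate pairs;",
      "groups:", paste(x$groups, collapse = ", "), "\n")
  cat("fully defined genes:", sum(rowSums(!x$defined) == 0), "\n")
  invisible(x)
}
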