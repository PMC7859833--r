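#' ribocontrast: two-contrast ribosome profiling analysis
#'
#' Separates genes responsive to a footshock stimulus alone from genes
#' responsive to context-shock association in paired footprint / total-mRNA
#' sequencing designs, with a planted-truth simulator covering every stage.
#'
#' @importFrom stats aggregate aov approx cor dist filter hclust median
#'   pairwise.t.test prcomp pt quantile rbinom rlnorm rnbinom rnorm rpois
#'   runif sd setNames t.test TukeyHSD
#' @importFrom utils head read.csv read.delim write.csv write.table
#' @importFrom Rcpp evalCpp
#' @useDynLib ribocontrast, .registration = TRUE
#' @keywords internal
"_PACKAGE"

RNA_ALPHABET <- c("A", "C", "G", "U")
STOP_CODONS <- c("UAA", "UAG", "UGA")

#' Normalize a nucleotide string to the internal RNA alphabet
#'
#' DNA letters are accepted and T is mapped to U; case is folded to upper.
#'
#' @param x character vector of sequences.
#' @return character vector over \{A,C,G,U\}.
#' @export
as_rna <- function(x) {
  x <- chartr("t", "u", chartr("T", "U", toupper(x)))
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    stop("non-RNA characters in sequence(s): ",
         paste(head(which(bad), 5), collapse = ", "))
  }
  x
}

#' Construct a table of gene models
#'
#' One row per gene: the representative transcript's 5' UTR, CDS and 3' UTR
#' sequences (RNA alphabet) plus a class label. Lengths are derived, never
#' stored.
#'
#' @param gene_id,transcript_id character vectors.
#' @param class_label character vector (e.g. "protein_coding",
#'   "ribosomal_protein").
#' @param utr5,cds,utr3 nucleotide strings; UTRs may be empty.
#' @param check_cds validate CDS start/stop/frame (TRUE for generated data).
#' @return a data.frame of class `gene_models` with a logical
#'   `cds_frame_ok` column.
#' @export
gene_models <- function(gene_id, transcript_id, class_label, utr5, cds, utr3,
                        check_cds = TRUE) {
  utr5 <- as_rna(utr5); utr3 <- as_rna(utr3); cds <- as_rna(cds)
  if (anyDuplicated(gene_id)) stop("duplicate gene_id in gene models")
  frame_ok <- nchar(cds) > 0 & nchar(cds) %% 3 == 0
  if (check_cds) {
    if (any(!frame_ok)) {
      warning(sum(!frame_ok), " gene(s) with CDS length not a multiple of 3; ",
              "flagged cds_frame_ok = FALSE and excluded from frame logic")
    }
    starts_aug <- substr(cds, 1, 3) == "AUG"
    last <- substr(cds, nchar(cds) - 2, nchar(cds))
    if (any(frame_ok & (!starts_aug | !(last %in% STOP_CODONS)))) {
      warning("CDS without AUG start or stop end present")
    }
  }
  tx_len <- nchar(utr5) + nchar(cds) + nchar(utr3)
  if (any(tx_len <= 0)) stop("transcript length must be > 0")
  out <- data.frame(
    gene_id = as.character(gene_id),
    transcript_id = as.character(transcript_id),
    class_label = as.character(class_label),
    utr5 = utr5, cds = cds, utr3 = utr3,
    cds_frame_ok = frame_ok,
    stringsAsFactors = FALSE
  )
  class(out) <- c("gene_models", "data.frame")
  out
}

#' Derived lengths of gene models
#' @param genes a `gene_models` table.
#' @return data.frame with utr5/cds/utr3/transcript lengths in nt.
#' @export
gene_lengths <- function(genes) {
  data.frame(
    gene_id = genes$gene_id,
    utr5 = nchar(genes$utr5),
    cds = nchar(genes$cds),
    utr3 = nchar(genes$utr3),
    transcript = nchar(genes$utr5) + nchar(genes$cds) + nchar(genes$utr3),
    stringsAsFactors = FALSE
  )
}

#' Library design table
#'
#' @param library_id character vector of unique library identifiers.
#' @param assay one of "footprint"/"total_mrna" per library.
#' @param group experimental group per library.
#' @param replicate positive integer per library.
#' @return data.frame of class `library_design`.
#' @export
library_design <- function(library_id, assay, group, replicate) {
  assay <- match.arg(assay, c("footprint", "total_mrna"), several.ok = TRUE)
  replicate <- as.integer(replicate)
  if (any(replicate < 1)) stop("replicate must be a positive integer")
  d <- data.frame(library_id = as.character(library_id), assay = assay,
                  group = as.character(group), replicate = replicate,
                  stringsAsFactors = FALSE)
  if (anyDuplicated(d[c("assay", "group", "replicate")]))
    stop("(assay, group, replicate) triples must be unique")
  if (anyDuplicated(d$library_id)) stop("duplicate library_id")
  fp <- d[d$assay == "footprint", c("group", "replicate")]
  to <- d[d$assay == "total_mrna", c("group", "replicate")]
  key <- function(x) paste(x$group, x$replicate)
  # pairing is checked for full (two-assay) designs; single-assay designs
  # are paired later when the two halves meet in compute_te()
  if (nrow(fp) && nrow(to) && !setequal(key(fp), key(to)))
    stop("every footprint library needs a matching total_mrna library ",
         "(same group, replicate)")
  class(d) <- c("library_design", "data.frame")
  d
}

#' Count matrix with design metadata
#'
#' @param counts non-negative integer matrix, genes x libraries, with
#'   rownames = gene ids and colnames = library ids.
#' @param design a `library_design` covering all columns.
#' @return object of class `count_matrix` with components `counts`, `design`,
#'   `library_size` (column sums).
#' @export
count_matrix <- function(counts, design) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and library colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene_id rows in counts")
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  missing_lib <- setdiff(colnames(counts), design$library_id)
  if (length(missing_lib))
    stop("library absent from design: ", paste(missing_lib, collapse = ", "))
  design <- design[match(colnames(counts), design$library_id), , drop = FALSE]
  structure(list(counts = counts, design = design,
                 library_size = colSums(counts)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "libraries\n")
  cat("assays:", paste(unique(x$design$assay), collapse = ", "),
      "| groups:", paste(unique(x$design$group), collapse = ", "), "\n")
  cat("library sizes:", paste(format(x$library_size, big.mark = ","),
                              collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

# 1-based inclusive (annotation file) <-> 0-based half-open (internal)
coords_to_internal <- function(start1, end1) {
  cbind(start = start1 - 1L, end = end1)
}
coords_to_gtf <- function(start0, end0) {
  cbind(start = start0 + 1L, end = end0)
}
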