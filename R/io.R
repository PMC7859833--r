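#' Read a transcript annotation plus sequences into gene models
#'
#' The annotation is GTF-style (1-based inclusive coordinates) with
#' `five_prime_utr`, `CDS` and `three_prime_utr` features laid out in
#' transcript coordinates: each FASTA record is one transcript and the GTF
#' seqname refers to it. When a gene has several transcripts, the longest
#' 5' UTR and the longest 3' UTR across its transcripts are retained (the CDS
#' comes from the transcript with the longest CDS); ties go to the
#' lexicographically smallest transcript_id. T is normalized to U.
#'
#' @param annotation_path path to the GTF file.
#' @param fasta_path path to the transcript FASTA.
#' @return a `gene_models` table.
#' @export
read_annotation <- function(annotation_path, fasta_path) {
  gr <- rtracklayer::import(annotation_path, format = "gtf")
  seqs <- Biostrings::readBStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seq_chr <- as_rna(as.character(seqs))

  md <- S4Vectors::mcols(gr)
  keep <- md$type %in% c("five_prime_utr", "CDS", "three_prime_utr")
  gr <- gr[keep]; md <- S4Vectors::mcols(gr)
  feat <- data.frame(
    tx = as.character(GenomicRanges::seqnames(gr)),
    type = as.character(md$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    gene_id = as.character(md$gene_id),
    transcript_id = as.character(md$transcript_id),
    stringsAsFactors = FALSE
  )
  absent <- setdiff(unique(feat$tx), names(seq_chr))
  if (length(absent))
    stop("missing sequence for annotated transcript(s): ",
         paste(absent, collapse = ", "))

  region_seq <- function(rows) {
    if (!nrow(rows)) return("")
    rows <- rows[order(rows$start), , drop = FALSE]
    ir <- coords_to_internal(rows$start, rows$end)  # 0-based half-open
    paste(substring(seq_chr[rows$tx], ir[, "start"] + 1L, ir[, "end"]),
          collapse = "")
  }

  per_tx <- split(feat, feat$transcript_id)
  tx_tab <- do.call(rbind, lapply(per_tx, function(f) {
    data.frame(
      gene_id = f$gene_id[1],
      transcript_id = f$transcript_id[1],
      utr5 = region_seq(f[f$type == "five_prime_utr", ]),
      cds = region_seq(f[f$type == "CDS", ]),
      utr3 = region_seq(f[f$type == "three_prime_utr", ]),
      stringsAsFactors = FALSE
    )
  }))

  pick <- function(tab, field) {
    tab <- tab[order(-nchar(tab[[field]]), tab$transcript_id), , drop = FALSE]
    tab[1, ]
  }
  per_gene <- split(tx_tab, tx_tab$gene_id)
  rows <- do.call(rbind, lapply(per_gene, function(tab) {
    rep_tx <- pick(tab, "cds")
    data.frame(
      gene_id = tab$gene_id[1],
      transcript_id = rep_tx$transcript_id,
      utr5 = pick(tab, "utr5")$utr5,
      cds = rep_tx$cds,
      utr3 = pick(tab, "utr3")$utr3,
      stringsAsFactors = FALSE
    )
  }))
  rows <- rows[order(rows$gene_id), , drop = FALSE]
  gene_models(rows$gene_id, rows$transcript_id,
              class_label = "protein_coding",
              utr5 = rows$utr5, cds = rows$cds, utr3 = rows$utr3,
              check_cds = TRUE)
}

#' Read a design CSV (library_id, assay, group, replicate)
#' @param design_path CSV path.
#' @return a `library_design`.
#' @export
read_design <- function(design_path) {
  d <- read.csv(design_path, stringsAsFactors = FALSE)
  need <- c("library_id", "assay", "group", "replicate")
  if (!all(need %in% names(d)))
    stop("design file must have columns: ", paste(need, collapse = ", "))
  library_design(d$library_id, d$assay, d$group, d$replicate)
}

#' Read a genes x libraries count table plus its design
#'
#' @param tsv_path tab-separated table; first column `gene_id`, remaining
#'   columns one per library, non-negative integer counts.
#' @param design_path CSV mapping library_id to (assay, group, replicate).
#' @return a `count_matrix`; library sizes are the column sums.
#' @export
read_counts <- function(tsv_path, design_path) {
  tab <- read.delim(tsv_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1] != "gene_id") stop("first column must be gene_id")
  if (anyDuplicated(tab$gene_id))
    stop("duplicate gene_id rows: ",
         paste(unique(tab$gene_id[duplicated(tab$gene_id)]), collapse = ", "))
  m <- as.matrix(tab[, -1, drop = FALSE])
  bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad))
    stop("negative or non-integer count at row ", tab$gene_id[bad[1, 1]],
         ", column ", colnames(m)[bad[1, 2]])
  storage.mode(m) <- "integer"
  rownames(m) <- tab$gene_id
  count_matrix(m, read_design(design_path))
}

#' Write result tables and a deterministic run summary
#'
#' Tables are written as header-stable TSV (NA as empty field); a
#' `run_summary.json` records package version, seed and a hash of the
#' configuration. Identical inputs and seed give byte-identical files.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed recorded in the summary.
#' @param config configuration list recorded (hashed) in the summary.
#' @return invisibly, the paths written.
#' @export
write_results <- function(tables, out_dir, seed = NA_integer_, config = list()) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) stop("cannot create directory: ", out_dir)
  }
  if (file.access(out_dir, 2) != 0) stop("directory not writable: ", out_dir)
  stopifnot(is.list(tables), !is.null(names(tables)))
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write.table(tables[[nm]], p, sep = "\t", quote = FALSE,
                row.names = FALSE, na = "")
    paths <- c(paths, p)
  }
  sanitize <- function(x) {
    if (is.data.frame(x)) return(data.frame(x, stringsAsFactors = FALSE))
    if (is.list(x)) return(lapply(unclass(x), sanitize))
    x
  }
  cfg_json <- jsonlite::toJSON(sanitize(config), auto_unbox = TRUE,
                               digits = NA)
  tf <- tempfile(); writeLines(as.character(cfg_json), tf)
  cfg_hash <- unname(tools::md5sum(tf)); unlink(tf)
  summary <- list(
    package = "ribocontrast",
    version = as.character(utils::packageVersion("ribocontrast")),
    seed = seed,
    config_hash = cfg_hash,
    tables = names(tables)
  )
  sp <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(summary, sp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, sp))
}

#' Write a count matrix (TSV counts + CSV design)
#' @param cm a `count_matrix`.
#' @param tsv_path,design_path output paths.
#' @export
write_counts <- function(cm, tsv_path, design_path) {
  tab <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.csv(as.data.frame(cm$design), design_path, row.names = FALSE,
            quote = FALSE)
  invisible(c(tsv_path, design_path))
}

#' Write gene models as transcript FASTA + GTF annotation
#'
#' Each transcript is a FASTA record; the GTF places five_prime_utr / CDS /
#' three_prime_utr features in 1-based inclusive transcript coordinates.
#'
#' @param genes a `gene_models` table.
#' @param fasta_path,gtf_path output paths.
#' @export
write_annotation <- function(genes, fasta_path, gtf_path) {
  len <- gene_lengths(genes)
  seqs <- Biostrings::RNAStringSet(paste0(genes$utr5, genes$cds, genes$utr3))
  names(seqs) <- genes$transcript_id
  Biostrings::writeXStringSet(seqs, fasta_path)

  rows <- list()
  for (i in seq_len(nrow(genes))) {
    segs <- data.frame(
      type = c("five_prime_utr", "CDS", "three_prime_utr"),
      len = c(len$utr5[i], len$cds[i], len$utr3[i]),
      stringsAsFactors = FALSE
    )
    segs <- segs[segs$len > 0, , drop = FALSE]
    end0 <- cumsum(segs$len); start0 <- end0 - segs$len
    g1 <- coords_to_gtf(start0, end0)
    rows[[i]] <- data.frame(
      tx = genes$transcript_id[i], type = segs$type,
      start = g1[, "start"], end = g1[, "end"],
      gene_id = genes$gene_id[i], transcript_id = genes$transcript_id[i],
      stringsAsFactors = FALSE
    )
  }
  rows <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = rows$tx,
    ranges = IRanges::IRanges(start = rows$start, end = rows$end),
    strand = "+"
  )
  S4Vectors::mcols(gr)$type <- rows$type
  S4Vectors::mcols(gr)$phase <- ifelse(rows$type == "CDS", 0L, NA_integer_)
  S4Vectors::mcols(gr)$source <- "ribocontrast"
  S4Vectors::mcols(gr)$gene_id <- rows$gene_id
  S4Vectors::mcols(gr)$transcript_id <- rows$transcript_id
  rtracklayer::export(gr, gtf_path, format = "gtf")
  invisible(c(fasta_path, gtf_path))
}
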