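#' Build a pipeline run configuration
#'
#' @param seed global seed; drives every stage through per-component child
#'   seeds.
#' @param sim a `sim_config` (defaults to `sim_config(seed = seed)`).
#' @param up_cutoff,down_cutoff fold-change call cutoffs.
#' @param normalization "quantile" or "median-ratio".
#' @param registry motif registry for the UTR stage.
#' @param qc_n_reads simulated footprints used for QC.
#' @param qc_window metagene window around the CDS start.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, sim = NULL,
                       up_cutoff = 1.5, down_cutoff = 0.667,
                       normalization = c("quantile", "median-ratio"),
                       registry = default_motif_registry(),
                       qc_n_reads = 2e4, qc_window = c(-20L, 60L)) {
  structure(list(
    seed = as.integer(seed),
    sim = if (is.null(sim)) sim_config(seed = seed) else sim,
    up_cutoff = up_cutoff, down_cutoff = down_cutoff,
    normalization = match.arg(normalization),
    registry = registry, qc_n_reads = qc_n_reads, qc_window = qc_window
  ), class = "run_config")
}

#' True perturbation direction per gene at a given group and level
#'
#' @param truth truth table from [generate_transcriptome()].
#' @param group stimulated group.
#' @param level "transcription" or "translation".
#' @return named vector in \{-1, 0, 1\}.
#' @export
planted_direction <- function(truth, group,
                              level = c("transcription", "translation")) {
  level <- match.arg(level)
  col <- paste0(if (level == "transcription") "mrna_log2fc_" else "te_log2fc_",
                group)
  setNames(sign(truth[[col]]), truth$gene_id)
}

#' Sensitivity and precision of differential calls against planted truth
#'
#' @param calls named call vector from [call_changes()].
#' @param truth_dir named true directions from [planted_direction()].
#' @param classes optional named class labels to stratify sensitivity.
#' @return list: overall `sensitivity`, `precision`, and per-class
#'   sensitivity when classes are given.
#' @export
recovery_stats <- function(calls, truth_dir, classes = NULL) {
  truth_dir <- truth_dir[names(calls)]
  called_dir <- ifelse(calls == "up", 1, ifelse(calls == "down", -1, 0))
  planted <- truth_dir != 0
  called <- called_dir != 0
  sens <- if (any(planted)) mean(called_dir[planted] == truth_dir[planted])
          else NA_real_
  prec <- if (any(called)) mean(truth_dir[called] == called_dir[called])
          else NA_real_
  out <- list(sensitivity = sens, precision = prec,
              n_planted = sum(planted), n_called = sum(called))
  if (!is.null(classes)) {
    classes <- classes[names(calls)]
    by_class <- sapply(unique(classes[planted]), function(cl) {
      sel <- planted & classes == cl
      mean(called_dir[sel] == truth_dir[sel])
    })
    out$sensitivity_by_class <- by_class
  }
  out
}

stage_msg <- function(log_path, stage, t0) {
  line <- sprintf("[%s] completed in %.2f s", stage,
                  as.numeric(proc.time()["elapsed"]) - t0)
  cat(line, "\n", file = log_path, append = TRUE)
}

#' Run the full pipeline on synthetic data
#'
#' Generation -> write/read of the plain-file inputs -> quantification and
#' QC -> differential contrasts -> UTR characterization of the
#' contrast-exclusive translationally changed gene sets -> validation-assay
#' analytics, all seeded from the config. Outputs are per-stage TSV files
#' plus `summary.json`; identical config and seed give byte-identical
#' outputs (stage timings go to `run.log`, which is excluded from that
#' contract).
#'
#' @param config a `run_config`.
#' @param out_dir run directory (created).
#' @return invisibly, the summary list.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  cat("ribocontrast run, seed ", config$seed, "\n", sep = "",
      file = log_path)
  run_stage <- function(stage, expr) {
    t0 <- as.numeric(proc.time()["elapsed"])
    res <- tryCatch(expr, error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           " (partial outputs preserved in ", out_dir, ")", call. = FALSE)
    })
    stage_msg(log_path, stage, t0)
    res
  }

  # --- simulate ----------------------------------------------------------
  sim <- run_stage("simulate", {
    tx <- generate_transcriptome(config$sim)
    cm <- simulate_counts(tx$genes, tx$truth, config$sim)
    inputs <- file.path(out_dir, "inputs")
    dir.create(inputs, showWarnings = FALSE)
    write_annotation(tx$genes, file.path(inputs, "transcripts.fa"),
                     file.path(inputs, "annotation.gtf"))
    write_counts(cm$footprint, file.path(inputs, "counts_footprint.tsv"),
                 file.path(inputs, "design_footprint.csv"))
    write_counts(cm$total_mrna, file.path(inputs, "counts_total.tsv"),
                 file.path(inputs, "design_total.csv"))
    reads <- simulate_footprint_reads(tx$genes, cm$footprint, config$sim,
                                      n_reads = config$qc_n_reads)
    trace <- simulate_polysome_trace(seed = config$seed)
    freezing <- simulate_freezing(seed = config$seed)
    list(tx = tx, cm = cm, reads = reads, trace = trace,
         freezing = freezing, inputs = inputs)
  })

  # stage compositionality: quantify from the files just written
  cm_fp <- run_stage("read_back", {
    read_counts(file.path(sim$inputs, "counts_footprint.tsv"),
                file.path(sim$inputs, "design_footprint.csv"))
  })
  cm_to <- read_counts(file.path(sim$inputs, "counts_total.tsv"),
                       file.path(sim$inputs, "design_total.csv"))

  # --- quantification and QC --------------------------------------------
  q <- run_stage("quant_qc", {
    genes <- sim$tx$genes
    expr_fp <- normalize_libraries(compute_rpkm(cm_fp, genes),
                                   config$normalization)
    expr_to <- normalize_libraries(compute_rpkm(cm_to, genes),
                                   config$normalization)
    tt <- compute_te(list(expr_fp, expr_to))
    lens <- footprint_length_distribution(sim$reads)
    offsets <- suppressWarnings(estimate_psite_offsets(sim$reads, genes))
    frames <- frame_distribution(sim$reads, genes, offsets)
    meta <- metagene_periodicity(sim$reads, genes, offsets, config$qc_window)
    repcor_fp <- replicate_correlation(expr_fp)
    repcor_to <- replicate_correlation(expr_to)
    pca <- pca_cluster(expr_to)
    te_class <- te_by_gene_class(
      setNames(tt$group_te[, config$sim$baseline_group],
               rownames(tt$group_te)), genes)
    list(expr_fp = expr_fp, expr_to = expr_to, tt = tt, lens = lens,
         offsets = offsets, frames = frames, meta = meta,
         repcor = rbind(repcor_fp, repcor_to), pca = pca,
         te_class = te_class)
  })

  # --- differential ------------------------------------------------------
  d <- run_stage("differential", {
    base <- config$sim$baseline_group
    stim <- setdiff(config$sim$groups, base)
    grp_cfc <- stim[length(stim)]; grp_shock <- stim[1]
    lvls <- c("transcription", "translation")
    res <- list()
    for (lvl in lvls) {
      r_cfc <- condition_ratio(q$tt, grp_cfc, base, lvl)
      r_sh <- condition_ratio(q$tt, grp_shock, base, lvl)
      calls_cfc <- call_changes(r_cfc, config$up_cutoff, config$down_cutoff)
      calls_sh <- call_changes(r_sh, config$up_cutoff, config$down_cutoff)
      sets <- contrast_sets(calls_cfc, calls_sh,
                            labels = c(grp_cfc, grp_shock))
      xcor <- cross_condition_correlation(r_cfc, r_sh)
      rec_cfc <- recovery_stats(
        calls_cfc, planted_direction(sim$tx$truth, grp_cfc, lvl),
        setNames(sim$tx$truth$class_label, sim$tx$truth$gene_id))
      res[[lvl]] <- list(ratio_cfc = r_cfc, ratio_shock = r_sh,
                         calls_cfc = calls_cfc, calls_shock = calls_sh,
                         sets = sets, r_squared = xcor$r_squared,
                         recovery_cfc = rec_cfc)
    }
    res
  })

  # --- UTR features of contrast-exclusive DTG sets -----------------------
  u <- run_stage("utr", {
    tr <- d$translation
    groups_map <- c(
      setNames(rep("cfc_up", length(tr$sets$sets$up$a_only)),
               tr$sets$sets$up$a_only),
      setNames(rep("cfc_down", length(tr$sets$sets$down$a_only)),
               tr$sets$sets$down$a_only),
      setNames(rep("shock_up", length(tr$sets$sets$up$b_only)),
               tr$sets$sets$up$b_only),
      setNames(rep("shock_down", length(tr$sets$sets$down$b_only)),
               tr$sets$sets$down$b_only))
    if (length(groups_map) < 8 || length(unique(groups_map)) < 2)
      return(list(skipped = TRUE))
    sub <- sim$tx$genes[sim$tx$genes$gene_id %in% names(groups_map), ]
    ft <- utr_feature_table(sub, config$registry, mfe = TRUE)
    cmp <- compare_utr_features(ft$features, ft$presence, groups_map)
    list(skipped = FALSE, table = ft, compare = cmp,
         groups_map = groups_map)
  })

  # --- validation-assay analytics ----------------------------------------
  a <- run_stage("assays", {
    bnd <- detect_trace_boundaries(sim$trace)
    pm <- polysome_monosome_ratio(sim$trace, bnd["a"], bnd["b"], bnd["c"])
    fc_tab <- data.frame(
      gene = rep(c("ieg1", "cfc1"), each = 3),
      condition = rep(config$sim$groups, 2),
      fc = c(1, 4, 4, 1, 1, 4))
    qpcr <- simulate_qpcr(fc_tab, noise_sd = 0, seed = config$seed)
    ddct <- ddct_fold_change(qpcr, reference = config$sim$baseline_group)
    fz <- freezing_summary(sim$freezing)
    fz_test <- group_compare(fz$freezing_percent, fz$group,
                             test = "anova", posthoc = "tukey")
    list(boundaries = bnd, pm_ratio = pm, pm_truth = sim$trace$truth$pm_ratio,
         ddct = ddct, freezing = fz, fz_test = fz_test)
  })

  # --- reports -----------------------------------------------------------
  invisible(run_stage("report", {
    tables <- list(
      expression_te = data.frame(
        gene_id = rownames(q$tt$group_te),
        q$tt$group_te, check.names = FALSE),
      replicate_correlation = q$repcor,
      te_by_class = q$te_class,
      venn_transcription = d$transcription$sets$counts,
      venn_translation = d$translation$sets$counts,
      ddct = a$ddct,
      freezing = a$freezing
    )
    calls_tab <- data.frame(
      gene_id = names(d$transcription$calls_cfc),
      deg_call_cfc = d$transcription$calls_cfc,
      deg_call_shock = d$transcription$calls_shock,
      dtg_call_cfc = d$translation$calls_cfc,
      dtg_call_shock = d$translation$calls_shock,
      stringsAsFactors = FALSE)
    tables$calls <- calls_tab
    if (!isTRUE(u$skipped)) {
      tables$utr_features <- u$table$features
      tables$utr_motif_percent <- u$compare$percentages
    }
    cfg_ser <- unclass(config)
    cfg_ser$sim <- unclass(cfg_ser$sim)
    cfg_ser$registry <- as.data.frame(unclass(config$registry))
    write_results(tables, out_dir, seed = config$seed,
                  config = cfg_ser)

    ieg <- sim$tx$truth$gene_id[sim$tx$truth$class_label == "ieg_shared"]
    shared_up <- d$transcription$sets$sets$up$shared
    summary <- list(
      seed = config$seed,
      n_genes = config$sim$n_genes,
      qc = list(
        fraction_28_32 = q$lens$fraction_28_32,
        frame = as.list(q$frames),
        periodicity_score = q$meta$periodicity_score,
        min_replicate_r2 = min(q$repcor$r_squared, na.rm = TRUE),
        psite_offsets = as.list(q$offsets)
      ),
      differential = list(
        venn_transcription = d$transcription$sets$counts,
        venn_translation = d$translation$sets$counts,
        cross_condition_r2_transcription = d$transcription$r_squared,
        cross_condition_r2_translation = d$translation$r_squared,
        deg_recovery_cfc = d$transcription$recovery_cfc[
          c("sensitivity", "precision")],
        dtg_recovery_cfc = d$translation$recovery_cfc[
          c("sensitivity", "precision")],
        ieg_shared_fraction = if (length(ieg))
          mean(ieg %in% shared_up) else NA
      ),
      utr = if (!isTRUE(u$skipped)) list(
        anova = u$compare$anova
      ) else list(skipped = TRUE),
      assays = list(
        pm_ratio = a$pm_ratio, pm_ratio_truth = a$pm_truth,
        freezing_anova_p = a$fz_test$p,
        mean_freezing = tapply(a$freezing$freezing_percent,
                               a$freezing$group, mean)
      )
    )
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    summary
  }))
}
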