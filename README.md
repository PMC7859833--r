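# ribocontrast

Tools for a two-contrast ribosome-profiling analysis: separating genes that
respond to an aversive stimulus alone from genes that respond to the
*association* of that stimulus with a context. The motivating design is
contextual fear conditioning in mouse dorsal hippocampus with three groups —
**homecage** (naive), **immediate shock** (footshock without context
association) and **CFC** (context–shock pairing) — each profiled with paired
ribosome-footprint and total-mRNA sequencing libraries. Comparing only a
conditioned group against naive animals conflates stimulus-driven and
memory-specific regulation; subtracting the immediate-shock response
isolates the association-specific gene sets.

The package is aimed at analysts working with (or planning) such paired
footprint/total designs, and ships a planted-truth synthetic-data module so
the entire pipeline runs and is testable without any animal-derived data.

## What it computes

For gene *g* in library *ℓ* (transcript length *L_g* nt, library size *N_ℓ*):

    RPKM(g, ℓ) = 10^9 · count(g, ℓ) / (L_g · N_ℓ)
    TE(g)      = RPKM_footprint(g) / RPKM_total(g)

per replicate pair, with zero-expression pairs flagged undefined. Per
stimulated group, ratios to the homecage baseline are formed at the
transcription level (group-mean total RPKM) and the translation level
(group-mean TE), and called with the fold-change rule

    up:   ratio > 1.5        down:  ratio < 0.667      (strict; boundary = unchanged)

Differentially expressed (DEG) and differentially translated (DTG) sets are
then intersected across the two stimulated groups: same-direction calls in
both are "shared", and the association-specific lists are CFC minus shared.

Around this core: footprint QC (length distribution, P-site offsets,
reading-frame fractions, metagene 3-nt periodicity, replicate R², PCA +
complete-linkage clustering), UTR characterization of the called sets
(length, GC%, a Nussinov-style folding minimum free energy, uORF/TOP and a
configurable motif registry, with t-test and two-way ANOVA group
statistics), and validation-assay analytics (polysome-trace
polysome/monosome area ratios, heavy/light polysome qPCR with luciferase
spike-in normalization, ΔΔCt fold changes with FC = 2^(−ΔΔCt), freezing
percentages with ANOVA/Tukey).

## Worked example

Simulate the full study design (1000 genes, 3 groups × 2 replicates, 10⁶
reads per library), quantify, and call translation-level contrasts:

```r
library(ribocontrast)

cfg <- sim_config(n_genes = 1000, seed = 1)
tx  <- generate_transcriptome(cfg)
cm  <- simulate_counts(tx$genes, tx$truth, cfg)

expr_fp <- normalize_libraries(compute_rpkm(cm$footprint,  tx$genes), "quantile")
expr_to <- normalize_libraries(compute_rpkm(cm$total_mrna, tx$genes), "quantile")
tt <- compute_te(list(expr_fp, expr_to))

calls_cfc   <- call_changes(condition_ratio(tt, "cfc",             level = "translation"))
calls_shock <- call_changes(condition_ratio(tt, "immediate_shock", level = "translation"))
contrast_sets(calls_cfc, calls_shock, labels = c("cfc", "shock"))
#> contrast_result (cfc vs shock)
#>  direction     region  n
#>         up   cfc_only 30
#>         up shock_only 27
#>         up     shared  1
#>       down   cfc_only 23
#>       down shock_only 28
#>       down     shared  0

min(replicate_correlation(expr_to)$r_squared)
#> [1] 0.992
```

The Venn table reads directly against the planted truth: the generator
plants 25 up and ~25 down TE-perturbed genes exclusively in each stimulated
group (plus a shared mRNA-level IEG class that does not move TE), and the
caller recovers them with a handful of boundary cases. Replicate log2-RPKM
correlation sits at R² ≈ 0.99, the data quality the simulated design
emulates.

A single call runs every stage (simulation → write/read of the plain-file
inputs → quantification/QC → contrasts → UTR features → assay analytics)
into a run directory with per-stage TSVs, `summary.json` and a log:

```r
run_pipeline(run_config(seed = 1), "run1/")
```

A thin command-line wrapper with `simulate` and `run-all` subcommands is
installed at `inst/scripts/ribocontrast-cli.R`.

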