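---
title: "Methods: separating stimulus-only from association-specific gene regulation with paired ribosome profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: separating stimulus-only from association-specific gene regulation with paired ribosome profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis problem

A footshock delivered to a rodent changes hippocampal gene expression whether
or not the animal can associate the shock with its context. Studies that
compare a conditioned group only against naive animals therefore conflate
genes driven by the aversive stimulus itself with genes specific to
associative memory formation. The design this package analyses separates the
two with three groups — homecage (naive), immediate shock (stimulus without
association) and contextual fear conditioning (CFC; stimulus paired with
context) — each profiled with paired ribosome-footprint and total-mRNA
libraries, so that both transcription (mRNA abundance) and translation
(ribosome occupancy) can be contrasted against the naive baseline and the
stimulus-only response subtracted from the association response.

`ribocontrast` implements the full desk-side analysis: quantification and
quality control, fold-change differential calling with contrast set algebra,
UTR sequence characterization of the called gene sets, and the analytics for
the wet-lab validation assays (polysome profiles, qPCR, freezing behaviour).
A synthetic-data module with planted ground truth stands in for the
animal-derived sequencing data, so every stage is testable end to end.

## Quantification model

For gene $g$ in library $\ell$ with transcript length $L_g$ (nt) and library
size $N_\ell$ (column sum of the count matrix),

$$\mathrm{RPKM}_{g\ell} = \frac{10^9 \, c_{g\ell}}{L_g N_\ell},$$

and translational efficiency per replicate pair is the ratio of matched
footprint to total-mRNA values,

$$\mathrm{TE}_{g,r} = \frac{\mathrm{RPKM}^{\mathrm{fp}}_{g,r}}
                           {\mathrm{RPKM}^{\mathrm{total}}_{g,r}}.$$

Any pair in which either RPKM is zero is *undefined* and flagged — never
encoded as a sentinel value — and undefined genes are excluded from
downstream log-scale analyses. Group TE is the mean of the defined replicate
TEs on the natural scale (a log-scale mean is available via
`compute_te(log_scale = TRUE)`); one representative transcript per gene is
used throughout, since isoform deconvolution is out of scope.

Counts are normalized across libraries within each assay before TE is
formed. The default is quantile normalization (`limma::normalizeQuantiles`),
which forces identical value distributions across libraries; a median-ratio
scaling (per-library median of ratios to the per-gene geometric mean) is the
alternative. Both are rank-preserving within a library, and the choice is
recorded in the run summary. Normalization is not cosmetic here: the
generator (like a sequencer) hands every library the same read budget, so a
group with many up-regulated genes has its remaining genes compressed — a
compositional bias of roughly 0.1 log2 units at the default effect sizes
that median-ratio scaling removes and quantile normalization strongly
attenuates.

## Differential calling and contrast algebra

Per stimulated group, each gene's ratio to the homecage baseline is formed
at two levels: group-mean total-mRNA RPKM (transcription) and group-mean TE
(translation). Calls use a plain fold-change rule with strict inequalities:

* up if ratio $> 1.5$,
* down if ratio $< 0.667$,
* otherwise unchanged; a ratio exactly at a cutoff is unchanged.

With two replicates per group, no per-gene variance test is attempted —
calls are ratio-only by design. "Shared" genes are those called in the
*same direction* in both stimulated groups; the association-specific sets
are the CFC calls minus those shared calls (and symmetrically for
immediate shock). Cross-condition agreement is summarized as the squared
Pearson correlation of the two groups' log2 ratios over jointly defined
genes.

## The synthetic-data generator

The generator emulates the study design — 3 groups × 2 replicates × 2
assays = 12 libraries — with known per-gene truth:

* **Classes** (default proportions): a shared immediate-early-gene class
  induced at the mRNA level in both stimulated groups (5%); group-exclusive
  mRNA-level (DEG) and TE-level (DTG) classes (5% each, signs split up/down
  except IEGs, which are induced); short-transcript ribosomal-protein genes
  with a constant −0.5 log2 TE shift in *all* groups (5%), exercising the
  length-matched TE comparison without creating differential calls; and
  null genes (70%).
* **Effects**: planted |log2 fold change| of 1 — above the log2 1.5 cutoff
  with margin. Footprint abundance couples mRNA and TE effects
  multiplicatively (footprint = mRNA × TE by construction), so a TE-only
  gene moves in the footprint libraries but not the total libraries.
* **Counts**: expected count ∝ baseline × 2^effects × length, scaled to the
  library size; negative-binomial with a single dispersion knob
  (`dispersion = Inf` gives the Poisson limit). Baselines are log-normal
  (meanlog log 100, sdlog 1), spanning roughly three orders of magnitude.
  The default dispersion (size 1000) was calibrated once so the simulated
  replicate correlation of log2 RPKM sits at R² ≈ 0.99, matching the
  reported quality of the data the design emulates; that calibration is the
  documented purpose of the knob.
* **Sequences**: CDS = AUG + non-stop codons + stop. uORF-planted 5' UTRs
  receive a complete AUG…in-frame-stop entirely inside the UTR (length
  regenerated if the drawn UTR cannot host it); *all other* 5' UTRs are
  scrubbed free of AUG triplets, and non-TOP transcripts are scrubbed of
  chance 5'-terminal pyrimidine tracts, so uORF/TOP content equals the
  planted truth exactly — recovery tests need no tolerance. TOP-planted
  transcripts start with C plus 4–12 pyrimidines.
* **Footprints**: read lengths on 26–34 nt with mode 29; the 5' end is
  placed so the P-site (5' end + offset, default 12 nt) lands on CDS frame
  0 with probability `frame_fidelity` (default 0.85), otherwise uniformly
  on the other two frames, uniformly along the CDS.
* **Assay data**: polysome traces as sums of Gaussian peaks with analytic
  areas as truth; qPCR tables built by inverting the ΔΔCt relation
  (Ct = base − log2 abundance + noise); freezing scores Bernoulli per 5-s
  interval over a 5-min session (60 intervals), with a default CFC freezing
  probability of 0.7 matching the behavioural read-out the design emulates.

Everything is a pure function of the configuration and one global seed;
per-component child seeds (`child_seed`) make stages individually
reproducible.

What the generator does **not** emulate: rRNA/tRNA contamination, adapter
and alignment artefacts, multi-isoform structure, UMI/duplication
structure, or the pooling of 5–6 animals per replicate (a single dispersion
knob stands in for the biological-plus-pooling variance decomposition).
Passing recovery tests therefore demonstrates correctness of the analysis
chain under idealized sampling, not robustness to alignment-level
artefacts.

## Footprint quality control

* **Length distribution** and the fraction of reads in the canonical
  28–32 nt window.
* **P-site offsets** per read length: the offset in 10–15 nt maximizing
  meta-coverage at the first nucleotide of the CDS start codon; ties break
  toward the canonical 12 nt, and lengths with fewer than 100 reads fall
  back to 12 with a warning.
* **Frame fractions** over P-sites inside the CDS only.
* **Periodicity score**: on the mean-centred metagene coverage downstream
  of the CDS start, the spectral power at period 3 divided by the total
  power at periods 2–6. A perfect 3-periodic profile scores ≈ 1; an
  unstructured profile scores 1/5 *on average* — the single-profile score
  of noise is Dirichlet-like with substantial spread, so calibration checks
  average over independent simulations. An exactly constant profile has no
  power at any probed period and returns NA with a warning.
* **Replicate correlation**: squared Pearson correlation of log2 RPKM per
  assay and group over genes positive in both replicates.
* **Ordination**: genes with any undefined log2 value are excluded, each
  gene is standardized to mean 0 / SD 1 (zero-variance genes excluded with
  a count), then PCA on samples and complete-linkage clustering on
  Euclidean distances of the same standardized matrix.
* **Gene-class TE**: ribosomal-protein versus all protein-coding genes and
  versus a length-matched set — the non-ribosomal genes whose transcript
  length falls within the [min, max] range of the ribosomal-protein
  transcripts.

## UTR characterization

Per region (5' and 3' UTR): length, GC% (undefined for empty regions), and
a folding minimum free energy. The MFE is a deliberately simple
base-pair-sum model solved exactly by Nussinov-style dynamic programming
(G–C −3, A–U −2, G–U −1 kcal/mol; nested structures; minimum hairpin loop
of 3 nt; compiled kernel). It is a stand-in for nearest-neighbour engines:
group *differences* in structural potential are meaningful, absolute
energies are not. One property worth noting: the model is exactly invariant
under sequence reversal (the pair multiset is preserved), but *not* under
complement-reversal in general, because a G–U wobble pair maps to an
unpairable A–C.

Motifs come from a configurable registry recorded in the run summary. The
defaults are 4 motif types for the 5' UTR (uORF, TOP, a PAS-like AAUAAA,
and a ≥8 nt pyrimidine-rich element) and 9 for the 3' UTR (PAS, AU-rich
element requiring ≥2 AUUUA copies, CPE, Musashi element, Brd-box, K-box,
GY-box, a 15-LOX-DICE-like element, and a ≥6 nt UA-rich element) — sizes
chosen to reproduce the degrees of freedom of the published motif-type
ANOVA (F with 3 and 9, and 8 and 24 degrees of freedom respectively); the
exact published motif sets are not named, so this membership is a
documented choice, not an assertion.

* A **uORF** is an AUG in the 5' UTR with an in-frame stop codon ending
  inside the UTR, at least 2 codons long including the stop; each AUG pairs
  with its first in-frame stop, and overlapping/nested uORFs are all
  reported. uORFs whose stop would fall in the CDS are not counted.
* A **TOP** transcript starts with C followed by ≥ 4 uninterrupted
  pyrimidines.

Group statistics follow the published analysis: two-sided equal-variance
t-tests for length/GC/MFE between group pairs, and per region a two-way
ANOVA of motif presence *percentage* (presence/absence, not hit counts)
with factors motif type × experimental group. With one percentage per
motif × group cell the model is additive (no replication), so with $m$
motifs and $k$ groups the motif factor has $(m-1, (m-1)(k-1))$ degrees of
freedom; post-hoc group contrasts use the residual mean square with
Bonferroni correction.

## Validation-assay analytics

* **Polysome/monosome ratio**: trapezoidal area of the baseline-subtracted
  A254 trace between boundaries b→c (polysomes) over a→b (80S monosome).
  Trapezoids are exact on piecewise-linear traces and grid-converged well
  below 0.1% at the default grid. Boundaries are detected on a
  moving-average-smoothed copy (window 11 samples, configurable): a is the
  valley between the 60S and 80S peaks, b the valley between 80S and the
  first polysome peak, c the end of the trace; fewer than 4 detected peaks
  is an error instructing manual boundaries, and a manual override is
  returned verbatim and recorded.
* **Heavy/light polysome qPCR**: per fraction, relative abundance
  $2^{\mathrm{Ct}_{\mathrm{spike}} - \mathrm{Ct}_{\mathrm{gene}}}$ times a
  per-fraction total-RNA balance factor (an explicit input column); the
  statistic is heavy/light abundance per gene, averaged over replicates
  with SEM. Any recovery loss shifting gene and spike-in equally cancels.
* **ΔΔCt**: $\Delta Ct = Ct_{\mathrm{gene}} - Ct_{\mathrm{LC}}$ per
  condition, $\Delta\Delta Ct$ against the reference condition, fold
  change $2^{-\Delta\Delta Ct}$; PCR efficiency is fixed at 2 (a
  standard-curve efficiency correction is deliberately out of scope, with
  the flag reserved).
* **Freezing**: 100 × frozen intervals / total intervals; group comparisons
  via one-way ANOVA with Tukey or Bonferroni post-hoc, or an
  equal-variance t-test for two groups.

## Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open; annotation files are 1-based
  inclusive. The internal alphabet is RNA; T is normalized to U on input.
* Longest-UTR selection per gene takes the 5' and 3' UTR independently from
  the transcripts maximizing each, with ties broken by lexicographically
  smallest transcript id; the CDS comes from the longest-CDS transcript.
* A CDS whose length is not a multiple of 3 is flagged and excluded from
  frame logic with a warning, not an error.
* Boundary ratios exactly at a cutoff are unchanged (strict inequalities).
* Degenerate statistics (constant vectors, zero variance, fewer than 3
  shared genes) yield NA with a warning rather than an error wherever the
  quantity is a summary; hard errors are reserved for structural problems
  (unpaired libraries, missing spike-ins or loading controls, non-positive
  monosome areas).

## Problem sizes used by the test suite

The packaged tests run the full design at 1000 genes × 10⁶ reads per
library for recovery checks, 10⁵ simulated footprints for QC recovery, 200
random sequences of ≤ 12 nt against an exhaustive folding enumerator, 1000
random UTRs against brute-force motif enumerators, and two 120–150 gene
end-to-end pipeline runs for byte-identical determinism — sizes chosen so
the whole suite exercises every claim in about a minute on one CPU.

## Known limitations

* The fold-change caller makes no error-rate statement; with n = 2 it is a
  deliberate reproduction of the cutoff rule, not a substitute for
  count-based differential tests.
* The MFE model ignores stacking, loop entropies and temperature; only
  relative comparisons are meaningful.
* The default motif registry beyond uORF/TOP is a documented guess at an
  unnamed published set.
* Quantification is per representative transcript; genes whose signal is
  dominated by minor isoforms will be mis-lengthed.
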