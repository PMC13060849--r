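---
title: "Methods: from surface-capture LFQ to actionable MPNST targets"
author: "surfkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from surface-capture LFQ to actionable MPNST targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfkit)
```

# Scope

`surfkit` implements the downstream analysis chain for cell-surface-capture
proteomics of malignant peripheral nerve sheath tumor (MPNST) model
systems: starting from a label-free quantitation (LFQ) protein intensity
matrix it selects a consensus surfaceome across sample groups, quantifies
PRC2-conditional differential surface abundance, relates protein to RNA
abundance, converts flow-cytometry fluorescence into antigens per cell via
bead calibration, and extracts IC50s from viability screens of
antibody-drug conjugates (ADCs). Upstream steps — spectral processing and
LFQ extraction, read alignment and RNA quantification, differential RNA
expression — are out of scope; the package consumes their outputs
(intensity tables, TPM matrices, externally produced log2-fold-change
tables).

# The data model

The central container, `LFQExperiment`, extends `SummarizedExperiment`
with a single linear-scale `intensity` assay. A protein not detected in a
sample is an explicit `NA`, never 0: zero is not a legal LFQ intensity
under any convention, and keeping missingness explicit makes the
detection-based filters unambiguous. All downstream log transforms use
log2 for abundances and fold changes and log10 for the fluorescence
calibration, matching the reporting conventions of the field.

# Contaminants and normalization

Contaminant filtering (case-insensitive gene-symbol match against a
cRAP-style list; no alias resolution, which is catalog-dependent) runs
*before* median normalization. The order matters: mass-spectrometry
contaminants such as HSPA5, HSPA9 or KRT1 sit at high abundance,
especially in PDX material with residual stroma, and would otherwise
distort per-sample medians.

Median normalization rescales each sample multiplicatively so its median
present intensity equals a reference — by default the grand median of the
per-sample medians, which is invariant to sample order. Multiplicative
scaling on the linear scale (an additive shift in log space) is the
standard reading of "median-normalized" for LFQ and preserves
nonnegativity, within-sample ranks and missingness. The operation is
idempotent. All present values per sample enter the median; restricting to
proteins shared across samples is a defensible alternative we did not
adopt because it couples a sample's scale factor to the detection pattern
of the others.

# Consensus surfaceome selection

Within each sample group (e.g. PDX and cell line), in order:

1. **Detected in all** — keep proteins with a present value in every
   sample of the group.
2. **Top half of expression** — summarize each candidate as its median
   intensity across the group's samples and discard candidates strictly
   below the median of those summaries. Ties at the median are retained:
   "discard what is below the median" implies a strict-less cut. We read
   "group-wise median intensity" as the median of per-protein summaries
   (the natural reading of "top half of expression" over proteins); the
   pooled-all-values alternative is available as
   `medianMode = "pooled"`.
3. **Surface evidence** — intersect with a Cell Surface Protein
   Atlas-style catalog of high-confidence surface proteins
   (case-insensitive). Confidence-level filtering of the catalog is
   exposed in `readSurfaceCatalog()` since catalogs differ in how they
   grade evidence.

The cross-group consensus is the strict intersection of the per-group
surface sets. `buildConsensus()` records every stage's before/after counts
in a provenance table, so the funnel is auditable. Counts are reported
exactly as computed; no attempt is made to reproduce any particular
published list, which would require the underlying raw data.

# Differential surface abundance under PRC2 modulation

For an isogenic pair profiled with and without PRC2 activity, each
protein's log2 fold change is the mean log2 intensity difference
(inactive minus active) over present values. The test is a two-sample
t-test on log2 intensities, Welch by default: with 2–4 replicates per
condition and no variance moderation, assuming equal variances is the
riskier choice, and Welch is the conservative standard for
small-replicate LFQ (a pooled-variance switch exists). Multiple testing
uses Benjamini–Hochberg throughout. The default significance thresholds —
log2FC ≥ 1, FDR ≤ 0.05 — mirror the conventional RNA differential
expression cuts and are configurable.

Proteins detected in only one condition have an infinite raw fold change.
They are retained with a capped value (the largest finite |log2FC| plus
one, signed) and a `one_condition_only` flag instead of being dropped:
presence/absence proteins are biologically the most interesting candidates
and must stay visible in volcano-style outputs, but they carry no p-value
and are excluded from fold-change correlation analyses.

The cross-model step is a plain intersection of the two models' up-sets.
Pathway enrichment is a hypergeometric over-representation test (upper
tail, inclusive of the observed overlap) of the up-set against GMT gene
sets within the tested universe, with BH across sets. A ranked GSEA was
deliberately not re-implemented: the input here is an unranked
"more-abundant-when-PRC2-inactive" set, for which the set-based test is
the exact, enumerable analogue.

The t-statistics are computed vectorized across protein rows for speed;
the unit tests verify the vectorized p-values against `stats::t.test`
row by row. Under an all-null simulation the Welch p-values are only
approximately uniform (the Satterthwaite degrees of freedom are an
approximation at n = 3), which is visible to a Kolmogorov–Smirnov check
on 1000 proteins in a small fraction of runs; the validation thresholds
account for this known property.

# RNA–protein concordance

Concordance is computed on gene-level summaries: median present log2
intensity against log2(TPM + 1) (the pseudocount keeps zero-TPM genes
finite; log-log is the only scale on which LFQ/TPM correlation is
conventionally computed). A `minTPM` filter exposes the "remove
low-abundance RNA" analysis; no particular threshold is claimed to match
any published analysis since none is stated there. Decile binning ranks
genes by surface intensity ascending — decile 10 holds the most abundant
surface proteins — and splits them into bins whose sizes differ by at
most one, the larger bins at the low end, with ties broken by stable
lexicographic gene order so results are reproducible. Replicate structure
is summarized by a pairwise sample correlation matrix over proteins
detected in both samples of each pair.

# Bead-calibrated antigen density

A 4-peak PE bead panel defines an ordinary least-squares line of
log10(MFI) on log10(PE molecules per bead); inverting the line converts a
sample's median fluorescence into PE molecules per cell. Antigen density
is (stained PE − isotype PE) / (PE per antibody). Two decisions here were
genuinely open:

* **Where to subtract the isotype control.** We subtract on the
  PE-molecule scale, after calibration, because PE molecules are the
  physically additive quantity (specific plus nonspecific binding);
  subtracting raw MFIs would be wrong whenever the calibration slope
  differs from 1. Subtraction is on by default and switchable, and the
  choice is recorded in the output.
* **PE per antibody** defaults to 1, the 1:1 conjugation convention for
  this bead system, and is always explicit in the output.

Negative densities (isotype exceeding stained signal) are floored at zero
with a warning. Event-level flow data (FCS), gating and compensation are
out of scope; the module consumes per-sample median summaries.

# Dose-response and the density–potency relationship

Viability processing follows the screen design: every well is shifted by
the mean of the plate's media-only wells, and viability is the ratio of a
drug well's shifted intensity to the mean shifted intensity of the
zero-drug wells. This makes the pipeline invariant to plate-wide affine
intensity transforms with positive gain. Replicate wells enter the fit
individually — pre-averaging would hide the quadruplicate error
structure — and viabilities are not clipped to [0, 1], which would bias
the asymptotes.

The model is the four-parameter log-logistic in the LL.4 convention,

$$f(x) = c + \frac{d - c}{1 + \exp\!\big(b(\ln x - \ln e)\big)},$$

so the midpoint $e$ is the IC50 on the dose scale (molar). Fitting is
Levenberg–Marquardt least squares with data-driven starts: $d$ from the
top and $c$ from the bottom of the mean responses, $e$ from the dose
nearest the half-range crossing, and the sign of $b$ from the
dose–response trend. A fit is reported as non-converged — with no IC50,
rather than an error, so screens containing inactive drugs complete —
when the optimizer fails, or when the fitted curve fails basic
plausibility: it must reduce the residual sum of squares of the flat
(constant-mean) model by at least half, keep a response amplitude
$|d - c| \ge 0.1$, and keep $e$ within three decades of the tested dose
range. These guards exist to prevent a flat plate from yielding a
spurious IC50; their values are deliberately permissive so that any real
sigmoid at screen noise levels passes.

The density–potency analysis is a Spearman correlation between antigens
per cell and IC50 over matched pairs with converged fits; the p-value is
the exact permutation distribution for n < 10 without ties and the
asymptotic approximation otherwise (the behavior of `cor.test`). A
negative rho is the expected direction: denser antigens need less ADC.

# What the synthetic generator emulates — and what it does not

Every stage is validated on synthetic data with known ground truth,
generated by `syntheticConfig()` and the `simulate*` family:

* **LFQ intensities** are log-normal per protein (log2 mean 23, sd 2 —
  the scale and spread typical of LFQ output), with per-sample
  multiplicative distortions (log2 sd 0.25) and intensity-dependent
  missingness: the dropout probability is a decreasing logistic in true
  log2 intensity (midpoint 19, steepness 1.5, giving a few percent
  missingness concentrated at low abundance). The real missingness
  mechanism of LFQ is unknown; the logistic model is an assumption and is
  parameterized, not fixed.
* **Contaminants** are spiked as extra rows drawn from the upper quartile
  of the intensity distribution, to exercise exactly the failure mode in
  which abundant contaminants would pass every abundance filter.
* **The PRC2 pair** plants a 5% subset of proteins with log2 fold changes
  from N(3, 0.5) in the inactive condition and applies independent
  multiplicative replicate noise (CV 0.1) — technical-replicate regime,
  no dropout, since the pair emulates deep replicate runs of one line.
* **Matched RNA** uses a Gaussian-copula construction so the population
  correlation between log RNA and log protein equals a requested rho
  (default 0.12, a deliberately weak coupling: RNA abundance is a poor
  proxy for surface protein abundance, which is the point of the
  concordance module).
* **Bead panels and viability plates** follow their measurement models
  exactly: a log-log line with optional multiplicative noise, and
  plate intensities `background + signal · 4PL(dose)` with media-only
  and zero-drug wells, 8 of each, quadruplicate drug wells, 5%
  multiplicative noise at the screen design.
* **The density–potency panel** couples IC50 ∝ 1/density with 10%
  lognormal noise across 12 lines.

One master seed drives a per-operation seed sequence, so each generator
is independently reproducible and a fixed seed gives bit-identical
outputs.

The generator does **not** emulate raw mass spectra, peptide-to-protein
inference, shared-peptide ambiguity, batch effects beyond a scalar
per-sample distortion, FCS event-level structure (e.g. bimodal
subpopulations), plate-edge or drift effects, or mouse/human read
deconvolution in PDX material. Tests passing on synthetic data therefore
certify the *computational* contracts — the filters, the statistics, the
calibrations and their error behavior — not robustness to every artifact
of real acquisitions.

# Validation design and problem sizes

The test suite checks each operation against an independent oracle
(brute-force set logic for the consensus rules, exhaustive enumeration
for hypergeometric p-values, per-row `t.test` for the vectorized Welch
statistics, step-by-step arithmetic for antigen densities, bisection on
the fitted curve for the IC50 midpoint property) and exercises the
planted-truth recoveries at these sizes, chosen to give stable pass/fail
behavior at small multiple-testing burden: 100 random toy matrices for
the consensus oracle; 1000 proteins × 3 replicates × 50 seeds for
differential recall/FDR and null p-value uniformity; 5000 genes × 100
seeds per coupling for concordance; 100 noiseless bead panels; 100
simulated plates at the screen design for IC50 recovery; 100 screens of
12 lines for the density–potency direction. `scripts/acceptance.R` reruns
the same computations from scratch at comparable sizes and writes the
headline numbers as JSON.

# Known limitations

* No imputation, protein inference or batch correction beyond median
  scaling; these belong upstream or to specialized tools.
* The Welch test is unmoderated; with very few replicates a variance-
  moderated test (as in limma) would gain power. The module boundary
  makes swapping the test straightforward.
* Identifier matching is exact (case-insensitive) on gene symbols;
  cross-catalog alias resolution is intentionally not attempted.
* Absolute reproduction of published headline values (specific consensus
  list sizes, specific IC50s, the r = 0.12 top-decile figure) requires
  the corresponding raw study data and is not attempted here; the package
  reproduces the *procedures* and validates them on planted ground truth.
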