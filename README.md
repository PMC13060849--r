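# surfkit

Analysis toolkit for **cell-surface-capture proteomics of malignant
peripheral nerve sheath tumor (MPNST) models**.

MPNSTs are aggressive sarcomas in which loss of the polycomb repressive
complex 2 (PRC2) derepresses many genes, some of which encode cell-surface
proteins that could be attacked with antibody-drug conjugates (ADCs),
bispecific engagers or CAR constructs. Identifying those targets from
surface-capture LFQ (label-free quantitation) mass-spectrometry data takes
a chain of well-defined steps, and `surfkit` implements that chain as
tested, reusable functions for proteomics analysts working with PDX and
cell-line panels:

* **LFQ core** — contaminant filtering (cRAP-style lists) and
  multiplicative median normalization of protein × sample intensity
  matrices (`filterContaminants()`, `medianNormalize()`), with explicit
  `NA` missingness on a `SummarizedExperiment`-based container
  (`LFQExperiment`).
* **Consensus surfaceome** — per group: proteins detected in *every*
  sample, in the top half of expression (per-protein median summary at or
  above the group-wise median; ties retained), and present in a Cell
  Surface Protein Atlas-style catalog; then the strict intersection
  across groups, with full provenance counts (`buildConsensus()`).
* **PRC2 differential abundance** — Welch t-tests on log2 intensities
  with Benjamini–Hochberg FDR, capped presence/absence fold changes,
  cross-model intersection of up-sets, and hypergeometric
  over-representation analysis against GMT gene sets
  (`differentialAbundance()`, `significantUpSet()`, `oraEnrichment()`).
* **RNA–protein concordance** — gene-level Pearson correlation of
  log2(TPM + 1) vs log2 intensity, low-TPM filtering, decile binning by
  surface abundance, fold-change concordance and replicate correlation
  matrices (`correlateAbundance()`, `decileBinning()`).
* **Antigen density** — 4-peak PE bead calibration by ordinary least
  squares of log10(MFI) on log10(PE), inversion of the line, isotype
  subtraction on the PE scale and conversion to antigens per cell
  (`fitBeadCurve()`, `antigenDensity()`).
* **Dose response** — media-well background shift, zero-drug viability
  normalization, four-parameter log-logistic fitting
  (LL.4: `f(x) = c + (d−c)/(1+exp(b(ln x − ln e)))`, so the midpoint `e`
  is the IC50) and the antigen-density vs potency Spearman correlation
  (`fit4PL()`, `densityPotencyCorrelation()`).
* **Synthetic data** — generators with known ground truth for every
  input (LFQ matrices with logistic dropout, PRC2 pairs with planted
  fold changes, coupled RNA, bead panels, viability plates), so the whole
  pipeline is testable without access to raw study data
  (`syntheticConfig()`, `simulate*()`), plus an end-to-end orchestrator
  with a reproducibility manifest (`runPipeline()`).

## Worked example

Everything below runs on synthetic data with planted ground truth.

```r
library(surfkit)

cfg <- syntheticConfig(n_proteins = 500, seed = 42)
sim <- simulateLFQ(cfg)
sim$experiment
#> LFQExperiment: 525 proteins x 6 samples
#>   missing cells: 133 (4.2%)
#>   groups: cell_line (n=3), PDX (n=3)

res <- buildConsensus(sim$experiment,
                      catalog = sim$truth$surface_set,
                      contaminants = sim$truth$contaminant_set)
res
#> ConsensusResult over 2 group(s): PDX, cell_line
#>   PDX: detected-in-all 456 -> above-median 228 -> surface 74
#>   cell_line: detected-in-all 454 -> above-median 227 -> surface 70
#>   consensus: 68 proteins
```

The funnel reads: of 525 proteins (500 + 25 spiked contaminants), 456
were detected in every PDX sample, 228 sit in the top half of expression,
74 of those have surface evidence; intersecting the two groups' surface
sets leaves 68 consensus surfaceome proteins. No contaminant survives
(they are removed before any abundance filter sees them).

```r
pair <- simulatePRC2Pair(cfg)
dt <- differentialAbundance(pair$active, pair$inactive)
up <- significantUpSet(dt, lfcMin = 1, fdrMax = 0.05)
length(up)                                           # 25 proteins up
sum(names(pair$truth$planted_up_set) %in% up)        # all 25 planted
```

All 25 proteins planted as PRC2-derepressed (log2FC ~ N(3, 0.5), CV 0.1,
n = 3 per condition) are recovered with no false positives at
log2FC ≥ 1, FDR ≤ 0.05.

```r
panel <- simulateBeadPanel(slope = 0.98, intercept = 0.2)
cal <- fitBeadCurve(panel$mfi, panel$pe_per_bead)
cal
#> BeadCalibration: 4 peaks; log10(MFI) = 0.2000 + 0.9800 log10(PE); R^2 = 1.0000

flow <- data.frame(sample = "S462TY", antigen = "PTK7",
                   stained_mfi = 52000, isotype_mfi = 310,
                   pe_per_antibody = 1)
antigenDensity(cal, flow)
#>   sample antigen antigens_per_cell pe_per_antibody background_subtracted
#> 1 S462TY    PTK7          40348.59               1                  TRUE
```

A stained MFI of 52,000 against an isotype MFI of 310 corresponds to about
40,000 PTK7 antigens per cell under this calibration.

```r
truth <- doseResponseFit(b = 1.5, c = 0, d = 1, e = 2e-9, drug = "PTK7-ADC")
plate <- simulateViabilityPlate(truth,
                                doses = 2e-9 * 10^seq(2, -2, length.out = 8),
                                noise_sd = 0.05, seed = 42, drug = "PTK7-ADC")
fit <- fit4PL(normalizeViability(plate))
fit
#> DoseResponseFit [PTK7-ADC]: IC50 = 1.89e-09, b = 1.67, c = 0.00375, d = 1.03 (rss 0.0204, n 32)
```

The quadruplicate 8-dose plate with 5% noise recovers the true 2 nM IC50
within 6%. A full synthetic run of every stage, with per-file checksums:

```r
runPipeline(defaultRunConfig(seed = 1), "out/")
```

See the methods vignette (`vignettes/surfkit-methods.Rmd`) for the models,
the selection rules, the fitting and calibration choices, and what the
synthetic generators do and do not emulate.

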