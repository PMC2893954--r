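# drgfpScreen

Hit calling and phenotype classification for genome-scale RNAi screens
that use the DR-GFP reporter to measure homologous-recombination-mediated
double-strand-break repair (HR-DSBR).

In a DR-GFP screen, cells carry two non-functional GFP alleles; an
I-SceI-induced double-strand break repaired by homologous recombination
reconstitutes functional GFP, so the percent of GFP-positive cells per
384-well plate well (measured by FACS) is a quantitative readout of
HR-DSBR frequency. Knocking down a gene with an esiRNA and watching the
GFP+ fraction fall or rise identifies repair factors. This package
implements the full downstream analysis of such a screen:

- **Plate model and I/O** — 384-well layouts with the fixed control map
  (4 positive-control wells targeting Rad51 at C3, C21, M5, M18; 12
  negative-control Rluc wells), CSV readout tables, esiRNA library maps.
- **z-scoring** — `z = (x − μ)/σ` per well, with `μ`, `σ` from all sample
  wells of the plate (primary screen) or from the negative-control wells
  (validation), sample (n−1) standard deviation, replicate averaging.
- **Hit calling** — primary hits at average `|z| > 2`; validated hits
  need two independent silencing triggers, one beyond `|z| > 2` and the
  second beyond `|z| > 1.5`, in the same direction (single-trigger genes
  only at `|z| > 4`); a GFP-level counterscreen excludes knockdowns that
  dim the reporter itself; a viability filter removes severely toxic
  knockdowns before secondary assays.
- **Phenotype grading** — arrow grades for HR z-scores (±1.5/2/4),
  viability and double-normalized drug/IR sensitivity grades
  (10/30/40 %), and gamma-H2AX removal kinetics annotated by two-sample
  Student's t tests at each post-irradiation timepoint.
- **Category enrichment** — fold enrichment `(k/n)/(K/N)` with an exact
  upper-tail hypergeometric test and optional Benjamini–Hochberg
  adjustment.
- **AP-MS filters** — confident identifications (≥3 peptides with ions
  score > 20 per experiment) and common-background exclusion (present in
  > 15 % of 193 control immunoprecipitations, baits exempt).
- **Coding-indel consequences** — HGVS-style c. indels applied to a CDS,
  translation, and frameshift protein nomenclature
  (`p.<ref><pos><alt>fsX<k>`), including stop-position arithmetic.
- **Synthetic screens** — a seeded generator (binomial cell sampling at
  ~2000 cells/well around a 5 % baseline GFP+ fraction, log-normal plate
  effects, per-gene fold effects) with ground truth, so every stage is
  testable end to end without raw FACS data.

## Worked example

The bundled candidate table (`candidatePhenotypes()`) holds the 62
dual-trigger candidate genes of a published genome-scale DR-GFP screen
with their per-trigger HR grades, counterscreen, viability, sensitivity
and gamma-H2AX columns. Re-running the funnel from the grades alone:

```r
library(drgfpScreen)
funnel <- candidateFunnel()
funnel$counts
#>                validated                decreased                increased
#>                       62                       45                       17
#>      after_counterscreen decreasers_characterized       viability_excluded
#>                       61                       44                       13
#>         secondary_cohort
#>                       31
funnel$excludedByCounterscreen$gene_id
#> [1] "MKNK2"
```

45 knockdowns decrease and 17 increase HR-DSBR; one gene (MKNK2) is
excluded because it dims GFP itself; 13 of the remaining 44 decreasers
are too toxic for secondary assays, leaving 31 characterized genes.

A synthetic knockdown is recovered quantitatively:

```r
cfg <- syntheticScreenConfig(plateEffectSd = 0, replicateCount = 4L,
                             seed = 42L,
                             effectTable = data.frame(gene = "kd", fold = 3.4))
scr <- generateValidationScreen(cfg)
estimateFoldChange(scr$readouts, scr$libraryMap, "kd")
#> [1] 3.568794
```

and frameshift arithmetic locates a premature stop:

```r
stopPositionFromFs("p.L471LfsX56")
#> [1] 527
```

See `vignettes/drgfp-screen-methods.Rmd` for the statistical model, the
grading conventions and the design decisions.

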