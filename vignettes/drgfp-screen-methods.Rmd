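---
title: "Screen statistics and design decisions in drgfpScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screen statistics and design decisions in drgfpScreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drgfpScreen)
```

## The assay and its readout

The DR-GFP reporter carries two non-functional GFP alleles. An
I-SceI-induced double-strand break, when repaired by homologous
recombination (HR-DSBR), reconstitutes a functional GFP gene, so the
percentage of GFP-positive cells in a well — summarized from FACS — is a
per-well measure of repair frequency. A genome-scale screen arrays one
esiRNA per well on 384-well plates with a fixed control map: four
positive-control wells (esiRNA against Rad51, a core HR factor, at C3,
C21, M5, M18) and twelve negative-control wells (esiRNA against renilla
luciferase, Rluc, at C4, D3, D4, C22, D21, D22, M6, N5, N6, M19, N18,
N19). All other 368 wells are samples. The package models exactly this
structure (`defaultControlLayout()`); layouts are configurable per plate
map, since control schemes differ between published figure captions and
protocol descriptions — the explicit twelve-address list is adopted as
authoritative.

Upstream gating and FCS parsing are out of scope: inputs are already
summarized percent-positive values in [0, 100].

## Normalization: two z-score schemes

Both schemes standardize a well value $x$ as

$$ z = \frac{x - \mu}{\sigma}. $$

*Plate mode* (primary screen): $\mu$ and $\sigma$ are the mean and
standard deviation over all **sample** wells of that plate, excluding
controls. Control wells still receive z values for QC but never
influence the statistics. By construction the sample wells of every
plate then have mean 0 and sd 1 (the suite checks this to 1e−9), and z
is invariant to affine rescaling of a plate — which is the point of
plate-wise normalization: multiplicative batch effects cancel.

*Control mode* (validation): $\mu$ and $\sigma$ come from the
negative-control (Rluc) wells of the same replicate. This anchors z to
the biological null rather than to a sample population that is enriched
for true effects after re-arraying candidate genes.

The sample (n−1) standard deviation is used throughout. The choice is
conventional for screen statistics rather than dictated by the source
protocol, which does not specify it; it is recorded in output metadata,
and with 368 sample wells (or 12 controls) the difference to the
population sd is far below the decision thresholds.

Replicates are z-scored first and averaged afterwards (`avg_z`), with
the number of contributing replicates recorded; a missing replicate
flows through as partial data rather than dropping the gene, because
real candidate tables contain single-trigger entries.

## The hit funnel

- **Primary hits**: average `z < −2` or `z > 2`, strictly. Boundary
  values never call — the rules are worded as "below"/"over", and
  boundaries are measure-zero for continuous data.
- **Validated hits**: each gene is re-screened with two independent,
  non-overlapping esiRNAs ("triggers") in 4 replicates. Validation
  requires one trigger beyond the strong cut-off (2.0) and the other
  beyond the weak one (1.5), either assignment, and **in the same
  direction**. The same-direction requirement is imposed here although
  the selection rule's wording does not state it: opposite-signed
  triggers cannot support a single phenotype, and no mixed-direction
  candidate appears in the published summary table.
- **Single-trigger genes** (the second esiRNA unavailable, "n.a.")
  validate only at `|z| > 4`, the most extreme grade. This reproduces
  the published candidate count without weakening the two-trigger rule.
- **Counterscreen**: esiRNAs that reduce GFP levels in constitutively
  GFP-expressing cells (counterscreen `z < −4`, strictly) score in the
  reporter assay without touching repair and are excluded. Only the
  decreasing direction excludes — the confound is loss of GFP signal;
  increased GFP levels are reported but retained. Genes without a
  counterscreen measurement are flagged `untested` and retained.
- **Viability filter**: validated decreasers graded "++" for viability
  (see below) are excluded from secondary assays.

Each decision function is checked against a brute-force transcription of
its rule on a dense z grid (step 0.25 over [−6, 6]²).

## Grade scales

HR arrow grades follow the strongest satisfied cut-off, strictly:
`z < −4, −2, −1.5` give ↓↓↓, ↓↓, ↓; `z > 1.5, 2, 4` give ↑, ↑↑, ↑↑↑;
otherwise "−". When a printed grade must be transcribed back into a
number (`hrGradeToZ()`), interior grades map to the midpoint of their
interval (e.g. ↓↓ → −3) and the unbounded extreme grades to |z| = 5.

**Viability** is graded on the relative decrease in untreated cell
numbers versus Rluc, $r = 1 - \bar{n}_\text{gene}/\bar{n}_\text{Rluc}$:
$r > 0.50$ → "++", $r > 0.25$ → "+". Read as absolute remaining
viability the published wording ("below 50% and 25% … ++ and +") would
make "+" more severe than "++" while "+" genes continued to secondary
assays; the relative-decrease reading is the only internally consistent
one (all "++" genes, and only those, were excluded) and is the one
implemented.

**Drug/IR sensitivity** is double-normalized:

$$ d = 1 - \frac{\bar{n}^{\text{gene}}_{\text{treated}} / \bar{n}^{\text{gene}}_{\text{untreated}}}
              {\bar{n}^{\text{Rluc}}_{\text{treated}} / \bar{n}^{\text{Rluc}}_{\text{untreated}}} $$

so that a baseline viability defect does not masquerade as drug-specific
sensitivity; $d \ge 0.40, 0.30, 0.10$ grade "+++", "++", "+"
(inclusive boundaries, per the "by 40%" wording, with a 1e−9 guard
absorbing floating-point noise of the double ratio). The double ratio
itself is a design decision — the protocol only says counts were
"compared to Rluc transfections" — and is recorded in output metadata.

**Gamma-H2AX kinetics**: at each post-irradiation timepoint (1 h, 6 h),
percent gamma-H2AX-positive cells (3 replicates) are compared to Rluc by
a two-sided two-sample Student's t test with pooled variance (df = 4);
p < 0.05 annotates an arrow with the sign of the mean difference.
Whether the original calls were one- or two-sided is not stated;
two-sided is adopted as the conservative default, with Welch's test
available by flag. The p-value path is tested against an independent
pooled-variance oracle at 1e−10.

## Enrichment

Fold enrichment of a category among hits is $(k/n)/(K/N)$ with an exact
upper-tail hypergeometric p (computed in log space via `phyper`). The
background universe is a required explicit argument — published fold
values depend on the annotation database and universe and are therefore
not reproducible quantities. Benjamini–Hochberg adjustment is applied
across categories by default (the original analysis reported none; an
off-switch is provided). The test suite checks the p-value against
exhaustive enumeration of all draws for universes up to N = 12.

## AP-MS filters

Identifications are confident when an experiment yields at least three
peptides with ions score strictly above 20; the rule is applied per
experiment, not pooled across immunoprecipitations of a bait. Proteins
seen in strictly more than 15 % of the 193 independent control
immunoprecipitations are common background; at that denominator the
boundary falls between counts 28 (14.5 %, retained) and 29 (15.0 %,
excluded). Baits are exempt from the background filter.

## Coding-indel consequences

c. coordinates are 1-based and inclusive. A complex allele written as a
bracketed deletion-plus-insertion (e.g. a 4-base deletion with a 22-base
insertion across the same positions) is normalized to a single
replacement of the deleted span by the insertion — the only executable
reading — and the normalization is recorded in the variant label.
Translation uses the standard code and stops at the first stop codon.

Frameshift nomenclature uses single-letter amino acids with "X" for the
termination codon (`p.L471LfsX56` style). Stop-position arithmetic
follows the standard convention: a retained anchor (ref == alt) puts the
stop at `pos + offset`; a substituted anchor at `pos + offset − 1`.
Published descriptions occasionally count substituted anchors as
`pos + offset`; the parser warns when it applies the standard convention
to a substituted anchor. When consequences are derived from a CDS and a
variant, the exact net length change decides frameshift versus in-frame
kinds; from protein pairs alone, in-frame re-alignment is inferred from
a matching suffix (a documented heuristic).

## The synthetic-screen generator

The generator emulates the statistical structure the analysis assumes,
nothing more. Per well, the positive-cell count is

$$ C \sim \mathrm{Binomial}\!\left(m,\; \mathrm{clamp}\!\left(\pi_0 \cdot e_p / f_g\right)\right),
\qquad x = 100\,C/m $$

with $m$ = 2000 cells/well, baseline GFP+ fraction $\pi_0$ = 0.05,
log-normal plate effect $e_p = \exp(\mathcal{N}(0, \sigma_p))$ with
$\sigma_p = 0.1$ by default, and per-gene fold $f_g$ (positive controls
use a 5-fold depletion, negative controls fold 1). These defaults are
free parameters of the generator — the true dispersion of the original
raw FACS data is unpublished — chosen as plausible for a FACS readout at
this cell number; they live in the configuration, never hard-coded in
analysis code. Genes are scattered over plates with a seeded
permutation, as arrayed libraries are, so planted effects do not cluster
on one plate and distort its statistics. Each plate × replicate draws
from its own generator stream derived from the master seed, making
output byte-identical under a fixed configuration and stable under
partial regeneration.

Secondary assays are emulated with Poisson cell counts (Rluc plates
1000 cells untreated, treated/untreated survival 0.7) and Gaussian
percent-gamma-H2AX values (means 5 %, 60 %, 20 % at no-IR, 1 h, 6 h; sd
3 percentage points; 3 replicates), again free parameters documented
here and configurable.

What the generator does **not** emulate: transfection chemistry,
cell-cycle structure, spatial plate artifacts (edge effects,
dispenser gradients), image-level data, or heavy-tailed well failures.
Passing tests therefore demonstrate the correctness and calibration of
the statistical pipeline under its own model assumptions, not
robustness to every artifact of real screening data.

### Fold-change recovery

The pipeline's fold estimate for a gene is the pooled negative-control
mean divided by the pooled mean over **all wells targeting the gene**
(both triggers, all replicates). In the validation design (two triggers
× 4 replicates at 2000 cells/well, 5 % baseline) a 3.4-fold knockdown
yields ≈ 235 expected positive cells, hence a ≈ 6.6 % relative standard
error of the estimate, and recovery within ±15 % in ≈ 97–98 % of runs —
simple binomial arithmetic that the stochastic acceptance check (200
seeded runs) confirms. A single 4-well trigger alone carries ≈ 9 %
relative error, which is why the estimator is defined at the gene level.

## Numerical choices and degenerate inputs

- Plates with fewer than two measured sample wells, or zero sample-well
  standard deviation, raise a degenerate-plate error naming the plate;
  degenerate negative controls likewise.
- Zero untreated means make sensitivity/viability ratios undefined and
  raise errors rather than propagating infinities.
- All strict/inclusive boundary conventions follow the wording of the
  corresponding rule ("below −2" strict; "by 40%" inclusive).
- Readout CSV round trips are value-exact (17 significant digits).

## The bundled candidate table

`candidatePhenotypes()` ships the 62-gene candidate summary used by the
worked example and the acceptance checks. One weak-trigger grade (gene
AIP) was reconciled from one to two arrows during transcription: as
printed, its two single-arrow grades are mutually inconsistent with the
screen's own dual-trigger selection rule and with the stated candidate
counts, while every other row is consistent — a single-glyph
transcription artifact is the most plausible explanation, and the
reconciliation is the minimal change restoring internal consistency.

## Problem sizes in the test suite

The suite runs entirely on generated data: dense-grid oracle checks at
2401 z pairs; 40–60 seeded screens for calibration and recovery rates;
500 null t tests for the uniformity check; 1000 random CDS/indel pairs
for the frameshift round trip; 200 seeded validation screens for the
fold-recovery criterion. These sizes keep Monte-Carlo standard errors
well inside the asserted margins while the whole suite stays fast.

## Known limitations

- No B-score/median-polish or robust-z variants; the pipeline
  implements plain mean/sd z-scoring, as the analysis it reproduces did.
- No FDR machinery for hit calling (fixed z cut-offs are faithful to the
  source analysis; the enrichment module's BH correction is the only
  multiple-testing adjustment).
- Enrichment ships no annotation database; users must supply annotation
  and universe.
- Variant consequences handle CDS-level indels only: no genomic-to-CDS
  projection, splice-site prediction, or population-frequency logic.
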