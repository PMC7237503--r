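---
title: "Methods behind ResistOmics: models, parameters and design choices"
author: "ResistOmics authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind ResistOmics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ResistOmics)
```

## Scope

ResistOmics re-implements, as reusable and tested components, the
computational analyses that typically accompany a multi-omics study of
anti-androgen-resistant prostate cancer cells: selection of a protein
signature that is consistently modulated across several resistant
derivatives and culture formats; natural-abundance correction and labelling
metrics for ¹³C-glucose tracing; lipid shorthand parsing with
saturation-class profiling; a hyperspectral Raman tissue-map QC and
band-ratio pipeline; and expression-based survival stratification. Because
the raw instrument data behind such studies are rarely re-analysable at desk
scale, every module is paired with a synthetic-data generator that plants a
known ground truth, so the statistical behaviour of each procedure can be
measured rather than assumed.

## Differential signature selection

Abundances are modelled on the log2 scale. For each non-reference group and
each culture format, `differentialTable()` computes the log2 fold change as
the difference of group means of log2 intensities and a two-sided Welch
t-test p-value, then Benjamini–Hochberg q-values across features within each
comparison. Features with fewer than two finite values in a compared group
are dropped from that comparison rather than imputed: with three or four
replicates any imputation model would dominate the result.

The panel rule implemented by `selectConsistent()` retains a feature if it
passes both `|log2FC| >= log2(fcThreshold)` and the significance threshold
in at least `kOfN` comparisons, with one consistent sign across the
qualifying comparisons. `intersectContexts()` then intersects per-format
selections. The default significance measure for panel selection is the raw
p-value at 0.05 together with the 1.5-fold threshold, which is the printed
rule for this kind of consistency panel; q-value selection (`useQ = TRUE`)
and a label-permutation mode (`method = "permutation"`, pooled null across
features, seeded) are available for stricter error control of a single
comparison. With four replicates per group the per-comparison Welch test has
roughly six degrees of freedom; requiring a q < 0.05 hit in all six
comparisons simultaneously would drive sensitivity to a few percent, whereas
the raw-p consistency rule measured on the synthetic study conditions
(2000 proteins, 5% signature, |log2FC| in [1, 2], noise SD 0.3 on log2,
20 seeds) achieves mean sensitivity above 0.9 with zero observed false
discoveries — the intersection across six comparisons is itself a powerful
multiplicity filter.

A note on monotonicity: tightening the fold-change, significance or count
threshold can never add features when sign consistency is off. With sign
consistency on, shrinking a mixed-sign qualifying set can make it
consistent, so strict monotonicity holds only for the threshold/count rule.

`dunnettTest()` provides the classical many-to-one comparison against the
reference group under a pooled-variance model. Family-wise adjusted
p-values come from the Monte Carlo null distribution of the maximum
absolute statistic (`dunnettNull()`, 100,000 draws by default, seeded),
floored at the unadjusted p-value so the family-wise p never undercuts the
marginal one; there is no closed form for unequal group sizes, and a seeded
Monte Carlo null is directly testable. Measured on 2000 null features the
procedure rejects at 4–6% at the nominal 5% level.

## Isotope-tracing correction

For a compound with C carbons, the measured isotopologue vector
(M+0 … M+C) mixes tracer incorporation with naturally occurring heavy
isotopes. `correctionMatrix()` builds the forward operator column by
column: a molecule with j tracer carbons contributes a mass-shift
distribution equal to the binomial ¹³C distribution over its C − j
unlabelled carbons, convolved with the tracer-purity binomial over the j
labelled positions and, in `"all-elements"` mode, with the +1/+2 shift
distributions of natural H, N, O, S and Si isotopes (relevant for
nominal-mass GC-MS of FAME/TMS derivatives). In `"carbon-only"` mode (high
resolution instruments where only ¹³C is isobaric with the tracer shift)
the operator is lower triangular. Distributions are truncated at shift C —
measured vectors stop at M+C — and columns renormalised. Isotope
abundances default to IUPAC representative values (¹³C 0.0107, ²H 0.000115,
¹⁵N 0.00364, ¹⁷O 0.00038, ¹⁸O 0.00205, ³³S 0.0075, ³⁴S 0.0425, ²⁹Si 0.0468,
³⁰Si 0.0310) and are overridable; tracer purity defaults to 1 with 0.99
matching typical commercial U-¹³C glucose.

`correctMid()` inverts the operator by non-negative least squares
(an in-package Lawson–Hanson active-set solver, `nnlsSolve()`): plain
matrix inversion can return negative isotopologue fractions on noisy data,
and the non-negativity constraint is the physically meaningful estimator.
The corrected distribution is normalised to sum 1 and reported with the
total corrected signal. The forward generator `simTracingSamples()` uses
the same operator, which gives a strict round-trip identity at zero noise
(recovery below 1e-9 L1 for formulas up to C30) and puts the labelled
fraction of a simulated unlabelled standard below 0.005 after correction.
Under 5% multiplicative noise per isotopologue the median L1 recovery error
is about 0.04 — the intrinsic noise-propagation scale of the inverse
problem, not a solver artefact. `enrichmentMetrics()` reports the labelled
fraction 1 − x₀ and the fractional enrichment Σ i·xᵢ / C;
`normalizeAbundance()` applies internal-standard and protein/cell-number
normalisation.

## Lipidomics

`parseLipidName()` implements the species grammar `CLASS C:DB` and the
chain grammar `CLASS c1:d1/c2:d2[/...]` (chains summed; sphingoid `d`
prefix tolerated) for the classes Cer, CL, DG, LysoPC, PC, PE, PG, PI, PS,
SM, TG and BMP. Ether/oxidised notations (`PC O-34:2`) are rejected
explicitly rather than misparsed. "Saturation level" is read as the total
double-bond count of the species name; `classifySaturation()` splits
lipidomes at more than two double bonds (`high_unsat`) versus two or fewer
(`low_unsat`), and `faClassTotals()` uses the standard per-fatty-acid
definition (SFA 0, MUFA 1, PUFA ≥ 2 double bonds). `lipidDiffMatrix()`
applies the consistency-selection semantics to a lipidome and returns
heatmap values as natural-log fold changes (the convention of the figures
this reproduces; log2 by argument) or per-species z-scores. Hierarchical
clustering of the heatmap is left to the caller (e.g. `pheatmap`), since
linkage and distance choices are presentation, not inference.

## Raman tissue maps

The pipeline order is fixed and logged on the object: despike → polynomial
baseline → crop to 2800–3020 cm⁻¹ → intensity-based tissue mask → QC
stage 1 (absolute floor 60,000 counts) → QC stage 2 (one SD from the mean)
→ min–max scaling plus anchor normalisation at 2933 cm⁻¹ → band ratios
I(2845)/I(2935) (lipid CH₂ vs protein CH₃) and I(2880)/I(2935)
(cholesterol-associated).

Numerical choices worth recording:

* **Despiking** replaces points that exceed the running median (window 5)
  by more than 5 local MADs. The threshold is floored at the larger of the
  high-frequency noise estimate and 5% of the spectral range: smooth band
  apexes produce locally zero MADs, and without the floor they would be
  falsely clipped. Cosmic rays dwarf both floors.
* **Baseline**: an 11th-order polynomial fitted by iterative peak
  exclusion — after each least-squares fit, points more than 1.5 noise SDs
  above the fit are excluded and the fit repeated. A plain least-squares
  polynomial absorbs a large fraction of the CH-stretch band envelope
  (bands and an 11th-order polynomial overlap in function space on a
  600 cm⁻¹ axis), which both biases band ratios and collapses
  total-intensity QC; exclusion-based fitting is how practical Raman
  baseline routines avoid this. A spectrum that is exactly an order-11
  polynomial is removed to numerical zero.
* **QC stage 2** interprets "one standard deviation from the mean" as the
  Euclidean distance of each spectrum to the mean spectrum, dropping pixels
  beyond mean + 1 SD of those distances; a total-intensity variant is
  available (`metric = "total"`), since the prose definition is ambiguous.
* **Anchor**: the normalisation anchor defaults to 2933 cm⁻¹ with the
  ratio denominators at 2935 cm⁻¹; intensities are read at the nearest
  axis point without interpolation. Min–max scaling followed by anchor
  division makes the result invariant to any positive affine transform of
  the raw spectrum, so end-to-end ratios are invariant to rescaling up to
  pixels crossing the absolute intensity floor — the floor is therefore
  configurable in the units of the input.
* **Group comparison** uses a two-sided Mann–Whitney test on per-map mean
  ratios: the experimental unit is the map (one animal/section), not the
  pixel.

The generator `simRamanMap()` emulates: Gaussian bands at 2845/2880/2935
cm⁻¹ (SD 8 cm⁻¹) on a 2600–3200 cm⁻¹ axis at 2 cm⁻¹ steps, a smooth
low-order polynomial baseline, additive Gaussian noise, near-zero
background pixels and single-channel cosmic spikes at recorded positions.
The default band amplitude (4000 counts) places tissue band integrals over
the cropped window at roughly 80,000–120,000 counts — above the 60,000
vendor-scale floor, as tissue must be — while background totals stay near
zero; this implements the generator's contract that planted background
falls below the QC floor. It does not emulate real tissue heterogeneity,
fluorescence saturation, detector nonlinearity or spatial correlation, so
passing tests demonstrate correctness of the pipeline's operations, not
performance on real tissue. The planted 2845/2935 amplitude difference of
0.3 between conditions is recovered by the full pipeline within a few
percent and detected by the Mann–Whitney comparison with 6 maps per group
in ≥ 95% of seeded replicate studies.

## Survival stratification

`stratifyKmeans()` mean-centres expression and clusters it into k = 3
strata. The default engine is multi-start Hartigan–Wong k-means (seeded);
`method = "exact"` computes the provably optimal 1-D clustering by dynamic
programming over the sorted values (optimal 1-D clusters are contiguous),
which serves as the verifiable reference — the multi-start heuristic
attains the DP optimum on the cohort sizes used here. Strata are labelled
low/mid/high by ascending centroid, so labels are invariant to input order
and initialisation. `kmCurve()` is the product-limit estimator and
`logrankTest()` the k-sample logrank test (hypergeometric variance for
ties), both via the survival package; the package's own tests verify them
against closed forms and textbook O−E/V computations. The module is
outcome-agnostic: disease-free versus overall survival semantics belong to
the caller.

`wilcoxonSignedRank()` handles the paired pre/post histoscore design:
zero differences dropped, tie-averaged ranks, and an exact two-sided
p-value for up to 25 non-zero pairs computed from the full sign-assignment
distribution via a generating-function convolution on the half-rank grid
(ties included); larger n uses a normal approximation with continuity and
tie corrections. Fourteen uniformly positive differences give the exact
two-sided p of 2/2¹⁴ ≈ 1.22e-4.

`simCohort()` draws expression from a three-component location mixture and
event times from exponential distributions with per-component hazard
multipliers and independent exponential censoring. Under equal hazards the
logrank p-values are calibrated (type-I error 4–6% at the 5% level over
2000 null cohorts); with a hazard ratio of 2 between extreme components at
n = 300 the stratified analysis detects the effect in the majority of
seeded cohorts.

## Synthetic study conditions and seeds

The generators' defaults are the study conditions used throughout the test
suite: proteomes with four groups (reference plus three resistant lines) in
two formats, four replicates, log-normal intensities with log2-scale noise
SD 0.3, 5% signature features with |log2FC| in [1, 2] applied with one
consistent sign in every comparison and format; lipidomes whose
knockout effect multiplies species with more than two double bonds by the
effect size and divides the rest by it; Raman maps and cohorts as described
above. Every generator takes one integer seed and is bit-reproducible;
`runPipeline()` splits a single global seed into per-stage seeds. Test and
simulation sizes (e.g. 2000-feature proteomes over 20 seeds, 100 seeded
Raman studies of 12 six-by-six maps, 2000-replicate calibration runs) were
chosen so the whole suite runs in a few minutes on a single core while
keeping Monte Carlo error well inside the asserted margins.

## Worked example: the bundled resistance panel

The package ships the six-comparison log2 fold-change matrix of the
13-protein resistance panel as a plain-text fixture. Applying the
consistency filter at its standard thresholds to the fixture plus 20
decoy rows (each failing the fold-change threshold in at least one
comparison) retains exactly the 13 panel proteins:

```{r}
out <- table1PanelCount(fcThreshold = 1.5, nDecoys = 20, seed = 1)
out$nRetained
out$retained
```

## Known limitations

* The differential engine assumes log-normal-ish intensities with
  replicate-level independence; it implements no peptide-to-protein
  roll-up, normalisation between samples, or batch correction.
* The correction matrix covers C, H, N, O, S and Si; derivatisation atoms
  are included only if the caller passes the derivatised formula.
* The lipid grammar is species-level: no sn-position, ether/oxidised
  species, or MS/MS identity handling.
* The Raman pipeline reads band intensities at fixed positions (a local
  maximum search is deliberately not the default) and models no
  fluorescence or instrument response.
* Survival stratification is marginal k-means on one gene's expression; no
  multivariable or proportional-hazards modelling is provided.
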