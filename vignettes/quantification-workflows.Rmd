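---
title: "Quantification workflows for pollen tube heat-stress multi-omics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification workflows for pollen tube heat-stress multi-omics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollenomics)
```

This vignette explains the models and procedures the package implements,
the parameters that matter, what the synthetic-data generator does and
does not emulate, and the design decisions taken where more than one
reasonable choice existed.

## The measurement model

### Lipid species and the subclass registry

Lipid species are named in shorthand nomenclature: a subclass code
followed by the chain part — `"PC 34:2"` (sum composition), `"PC
16:0_18:2"` (molecular species), `"HexCer 18:1(d4);O2/24:0;O"`
(sphingolipid: sphingoid base / amide-linked fatty acid), `"SE
cholesterol/16:0"` (sterol conjugate). The parser captures positional
annotations where the chemistry resolves them — base double bonds at the
d4/d8 positions, C4 hydroxylation of trihydroxy bases (structurally
exclusive with the d4 double bond), C2 hydroxylation of the amide-linked
acyl — and records them as *unresolved* otherwise. Unresolved never means
absent: downstream modification profiles exclude unresolved species from
numerators and report their share separately, rather than imputing.

Subclass chemistry lives in an editable TSV registry
(`inst/extdata/subclass_registry.tsv`): category, chain count, ionization
mode, and the elemental composition of backbone and headgroup as free
molecules. A species formula is assembled as backbone + headgroup + chain
residues + (steryl residue) − one water per condensation bond; for
sphingolipids the base *is* the backbone and contributes no water. Sum
compositions are evaluated on a canonical n-acyl skeleton — elementally
this is exact, because a fatty acid with $c$ carbons and $d$ double bonds
contributes $C_cH_{2c-2d}O_2$ regardless of how a sum composition is
split across chains. Sterols that co-elute at the same mass (the M398 and
M412 groups) are modeled as single grouped residues.

### Isotopic correction

The only physics in the pipeline: a species with $n_C$ carbons has
monoisotopic fraction $(1-p)^{n_C}$ under an independent-atoms binomial
model with natural ¹³C abundance $p = 0.0107$, so measured monoisotopic
areas are multiplied by $\mathrm{icf} = (1-p)^{-n_C}$. This is a type-I
(M0-only) correction; deconvolution of M+2 overlap between species two
mass units apart is deliberately out of scope, as is any adduct or
fragment-ion chemistry. The correction is applied per transition before
summation — since the factor depends only on the species, correcting
before or after transition summation is algebraically identical, so the
choice is inconsequential; per-transition keeps the corrected table
auditable. `p13c` is a parameter everywhere it appears.

### The quantification procedure

Stages run strictly in order: (1) icf correction of raw areas; (2)
summation of corrected areas over the mass transitions of each species;
(3) subclass totals per sample and normalization to the mean total of the
reference-condition replicates (RT3), putting the reference mean at
exactly 1; then mol% species profiles, saturation fractions, and
modification occurrence. Missing transitions are treated as zero areas,
and zeros propagate; a subclass with a zero reference total is flagged
rather than silently dividing by zero.

Two aggregation choices were genuinely open:

* **Reference normalization** divides by the *mean* of the reference
  replicates (pairing replicates across conditions would be arbitrary
  here, since replicates are not matched).
* **Modification occurrence** is *abundance-weighted* by default (the
  share of subclass signal carried by species bearing the modification);
  a `weight = "count"` flag gives the species-count interpretation, since
  published phrasings of such percentages are ambiguous between the two.

"mol%" treats corrected peak areas as proportional to molar amounts with
no per-species response factors; that is the convention the profiles
reproduce and it is an approximation — ionization efficiency differs
between species, so mol% values are comparative, not absolute.

The major-species rule masks species whose condition-mean mol% never
exceeds 1% in any condition; the threshold is strict (`> 1%`), so a
species sitting exactly at 1% is minor. The same strictness is used for
every other published cutoff (CPM > 0.5, |log₂FC| > 1, FDR < 0.005).

## Absolute quantification

GC-FID FAME areas are converted to masses through the spiked 0.05 mg
triheptadecanoate standard assuming a mass-proportional, FA-independent
FID response (no theoretical response-factor correction; the carbon-count
corrections matter at the few-percent level and the quantities reported
are comparative). TG per mg dry pollen is the sum of analyte FA masses —
FAME-equivalent mass, without reconstructing the glycerol backbone —
scaled by the 20 mg dry-pollen input. Metabolite responses are
quantifier-ion areas over the 0.0125 mg *allo*-inositol standard, with an
optional per-row dilution factor for analytes measured on diluted runs
(sucrose in the design this emulates), folded to the RT3 mean.

## Condition statistics

One-way ANOVA uses the classical between/within decomposition; the post
hoc test is Tukey HSD in its Tukey–Kramer form for unbalanced groups,
with p-values from the studentized-range distribution (`stats::ptukey`,
which performs the required numerical integration). The compact letter
display is built by insert-and-absorb: start with one letter covering all
groups; for each significant pair, split every letter containing both;
absorb letters that become subsets of others. The result satisfies, by
construction, "two groups share a letter iff not significantly
different", which the tests verify by brute force against random p
matrices. Letters are ordered a, b, c, … over groups sorted by descending
mean, ties broken by input order.

Two-sample comparisons use Student's pooled-variance t by default (Welch
by flag), with stars coded \*P < 0.05, \*\*P < 0.01, \*\*\*P < 0.005.
Degenerate inputs are defined rather than left to NaN: zero pooled
variance with equal means gives t = 0, p = 1; with unequal means p = 0;
an all-constant ANOVA is flagged and its letters collapse to "a".

## Transcript aggregation

CPM and RPKM are the plain formulas (count / library-size × 10⁶;
additionally per gene kb for RPKM), with library sizes defaulting to
column sums of the supplied counts. The detection filter retains genes
with CPM strictly above 0.5 in at least two libraries and is idempotent.
GO terms are quantified by summing member-gene RPKMs per sample;
per-condition means of these scores give log₂FC (earlier condition in
the denominator) and a Student's t on the per-sample scores gives the
p-value (n = replicates per condition, not n = genes). Differential
expression itself is *not* fitted here — DE flags arrive as an input
table and are only tallied per GO term or gene set with the strict
thresholds above. Genes in a set but absent from the DE table are
reported as missing, not counted.

## The synthetic-data generator

The generator produces inputs with the statistical structure the analysis
assumes, with every injected parameter recorded:

* **Design.** Five regimes (RT3, RT6, HS3+3, HS3+6, HSR) × 5 replicates
  for lipids, FAMEs and metabolites; three regimes × 3 replicates for
  counts.
* **Noise.** Mean-preserving multiplicative lognormal noise with CV 0.15
  by default — areas are positive and right-skewed, so additive Gaussian
  noise would be the wrong model; `cv = 0` gives the noise-free limit in
  which every injected effect must be recovered exactly.
* **Lipidome effects.** Per-subclass per-condition fold trajectories
  (defaults encode the magnitudes the workflow is designed to resolve: a
  5.8-fold SPBP jump at HS3+3 over RT6 and 2.8-fold for extended stress
  over relief, a 30% HexCer increase, roughly doubled TG, decreasing
  sterol esters, increasing sterylglycosides); a saturation shift that
  moves mass from polyunsaturated to saturated species (+15 points under
  heat stress) while preserving the subclass total, so abundance and
  saturation effects stay independently testable; and a d4-to-C4-OH mass
  transfer in hexosylceramides (9.3 points, i.e. +31% on the 30%
  baseline).
* **Panels.** Species are drawn from the enumerated target universe
  (sphingolipids from a positionally annotated base pool, so
  modification features are resolved). For subclasses carrying a
  saturation or modification effect, the draw is stratified so the panel
  composition matches the imposed baseline (25/25/50 saturation classes;
  60/30/10 d4/C4-OH/other), as a measured panel would — otherwise the
  universe's own composition (mostly polyunsaturated combinations) would
  leave the minority classes represented by one or two species and the
  class fractions dominated by single-species noise. Species weights are
  lognormal with log-SD 0.5 (moderate dominance); 12 species per subclass
  by default, with richer panels (40) used for the abundant membrane
  subclass in recovery simulations.
* **Counts.** Negative-binomial counts (dispersion 0.05) around
  lognormal gene means scaled to 2 × 10⁶ reads, 8% DE genes shifted
  ±2 log₂ units under heat stress, GO terms of which a few are enriched
  in upshifted genes, and a 10% trace-expression tail (~0.1 expected
  counts) so the CPM filter has something to remove — about 92% of genes
  survive the filter, matching the regime of real pollen tube libraries
  (~90%).
* **Determinism.** All draws derive from one integer seed; the same seed
  reproduces tables byte-identically, and the generator restores the
  caller's RNG state.

What the generator does **not** emulate: chromatographic artifacts,
retention-time or mass drift, species-correlated noise, batch effects,
censoring at the detection limit, response-factor differences between
species, and count overdispersion heterogeneity. Passing recovery tests
therefore demonstrate that the computations are correct and calibrated
under the stated noise model — not that the workflow is robust to every
failure mode of real acquisitions.

## Numerical choices and problem sizes

Tolerances: conservation laws (mol% summing to 100, fractions to 1) are
checked to 10⁻⁹ relative; noise-free recoveries to 10⁻⁸ or better;
statistical cross-checks against independent implementations to 10⁻⁸.
Recovery simulations use 200 seeded runs of a three-subclass panel
(40-species membrane subclass, the five base phosphates, 24 annotated
hexosylceramides), which puts the saturation- and modification-shift
estimators within ±2 percentage points of truth in ≥95% of runs at n = 5
and CV 0.15. Null calibration of the ANOVA uses 10,000 three-group
simulations (5,000 in the acceptance script), with the rejection rate
required to sit in 0.05 ± 0.01. These sizes keep the full suite at a few
minutes on one core.

## Known limitations

* Type-II isotopic overlap (M+2 leakage between species differing by one
  double bond) is not deconvoluted; profiles of heavily co-eluting
  species inherit that bias.
* mol% and FID-based TG masses assume uniform response factors.
* The registry ships the subclasses of this workflow's scope; adding a
  subclass means adding one registry row (and, for new categories,
  deciding its condensation-bond rule).
* GO-term p-values from t tests on n = 3 summed-RPKM scores have the low
  power and fragile normality any such small-n test has; they are
  reported because that is the statistic this workflow defines, not
  because they are recommended for discovery.
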