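---
title: "Defining a denitrification regulon: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Defining a denitrification regulon: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulonkit)
library(dplyr)
library(tibble)
```

regulonkit implements the computational side of a classical bacterial
regulon study: wild-type and regulator-deletion cultures are profiled under
denitrifying conditions (anoxia plus nitrate), differential expression is
filtered through replicate detection calls, the induced and
regulator-dependent gene sets are intersected, and candidate direct targets
are followed up with operon context, promoter box scanning,
transcription-start-site (TSS) mapping from primer-extension product
lengths, and reporter/qPCR quantification. This vignette explains each
model, its assumptions, and the choices made where the method leaves room.

## Differential expression on detection-called microarrays

The input is a linear-scale signal matrix plus a parallel matrix of
per-replicate detection calls ("present", "marginal", "absent") and a
sample sheet assigning each array to a strain × condition group with at
least four biological replicates.

Three filters define a differentially expressed gene between groups A
(numerator) and B:

1. **Detection.** The gene must be called present or marginal in at least
   75% of the replicates of *at least one* of the two groups. Reading "each
   experiment" as *either group suffices* is a deliberate choice: requiring
   detection in both groups would silently discard genes that are fully off
   in one condition — exactly the strongly induced genes the analysis is
   after. The fraction uses a `>=` comparison, so 3 of 4 replicates passes.
2. **Test.** A two-sided Welch (unequal-variance) t-test on log2 signals
   with raw P <= 0.025. The original analysis names only a "student t-test";
   Welch on the log scale is the robust default for 4-replicate microarray
   groups, where variance heterogeneity between strains is the rule. No
   multiple-testing correction is applied: the method's operating point is
   the joint raw-P *and* fold-change criterion, which is conservative in
   itself (see the null property below). If both groups have zero variance
   the p-value is defined as 0 when the means differ and 1 otherwise.
3. **Effect size.** A signed fold change of magnitude >= 2, computed on
   linear-scale group means (not a back-transformed log mean). Ratios below
   1 are reported as negative reciprocals, so the scale is symmetric: -4
   means four-fold lower. In the mutant-versus-wild-type contrast the
   mutant is the numerator, so *negative* fold change means the gene needs
   the regulator (positive control).

Chip-level normalization of the original platform is out of scope; a
per-sample median scaling to the global median (`median_normalize()`,
`normalize = TRUE` in `differential_test()`) is available as a documented,
deliberately simple stand-in for data that need it. The simulated data are
generated on a common scale, so tests run without it.

## The regulon intersection

`build_regulon_report()` reproduces the two-circle logic: the **induced**
set is up-only in the wild-type anoxic-versus-oxic contrast; the
**mutant-differential** set takes either direction. Their overlap is the
candidate regulon, partitioned by the sign of the mutant-contrast fold
change. A high-confidence subset is cut at |FC| >= 5 in the mutant
contrast, and the percentage of it under positive control
(`percent_positive`) summarizes whether the regulator acts mainly as an
activator. With an empty high-confidence set the percentage is reported as
`NA`, never as 0. The headline counts of the original study (hundreds of
genes per set) are not reproducible without the original microarray series
and its chip normalization; on synthetic data with planted truth the
package instead demonstrates the *properties* those counts rely on:
recovery >= 90% of planted effects at log2 fold change 3, noise SD 0.25 and
n = 4, near-zero false calls under the null, and a positive-control
percentage within a few points of the planted proportion.

## Operon reconstruction

Adjacent genes are joined into an operon-like unit when they run in the
same direction and the intergenic gap — defined as the number of bases
strictly between the annotated end and the next start, `start - end - 1` —
is **less than 32 bp**. The bound is strict because the rule is stated as
"less than"; the companion rule, which enlarges the distance to **100 bp
when the first three letters of the gene names match** (norC/norB), is
taken as inclusive (`<= 100`) because it is stated as a bound that the
distance was "enlarged to". Both are configurable. Only mnemonic names
participate in the prefix rule: locus tags (bll4130, blr0314) share
three-letter prefixes vacuously and would chain most of the genome. The
name comparison is case-insensitive. Transitive closure of pairwise joins
yields the operons; single genes are not reported. Members are listed in
genomic order regardless of transcription direction. Equivalence with an
O(n²) pairwise-closure oracle is asserted over randomized annotations in
the test suite.

## The regulator box model and scanner

The binding site is modeled as a spaced dyad: a 6-nt first half site whose
positions 2, 4 and 6 must be G, G and C (the leading base belongs to the
box as reported but is unconstrained), a spacer, and a 3-nt second half
site with G and C at positions 1 and 3. A window scores one point per
matching conserved position (5 total) and is a hit at `min_matches` (default
5). This model is *induced from the published site collection*
(`regr_box_sites()`, ten sites upstream of six promoters) — the source
describes the box only by highlighting conserved nucleotides, never
algebraically — so the package also ships `fit_box_model()`, which
re-derives the model from any annotated site collection.

Two facts about the published collection drove the defaults, both
established by exhaustive enumeration of every (start, spacer) window:

* one perfect site (upstream of the FixK-type regulator gene) needs a
  spacer of 7 nt, so the default spacer range is 2–7 rather than the 2–6
  that the other sites would suggest;
* one norC site matches at only 4 of 5 conserved positions however it is
  framed (consistent with its own annotation, which highlights only four
  bases), so it is found at `min_matches = 4` but not 5.

`fit_box_model()` picks each site's best-scoring window, preferring windows
that agree with the site's annotated conserved positions (this matters for
one site containing an internal GGCC repeat that otherwise admits a
spacer-0 reading), and returns a model whose spacer range spans the
observed spacers and whose `min_matches` is the worst site's score — fitted
on the full collection: spacer 3–7, 4 of 5 matches. Every input site then
rescans as a hit (the closure property, asserted in the tests).

Overlapping hits with different spacers are deduplicated to the highest
score, then the shortest spacer, then the leftmost start — an invented but
documented convention, switchable with `dedup = FALSE`. Scanning is
forward-strand-only by default, since published sites are reported on the
displayed strand; `revcomp = TRUE` scans the mirror. Ambiguity codes score
as mismatches with a warning.

## Coordinates: the axis with no zero

All promoter positions are relative to the translation start: +1 is the
first base of the start codon, -1 the base immediately upstream, and **no
position 0 exists**. Every piece of position arithmetic lives in three
helpers (`fragment_index_to_offset()`, `offset_to_index()`,
`promoter_distance()`) so the zero skip is implemented exactly once.

Primer-extension (FLOE) products are converted by `tss_offset()`: the cDNA
runs from the primer's 5'-end base back to the transcript's first base,
*both included*. With the norC reverse primer at +53..+31, products of 88
and 74 nt map to starts 35 and 21 bp upstream of the start codon, 14 bp
apart — the inclusive-endpoints convention is forced by this arithmetic
(88 = 35 + 53). One source statement gives the second start as "about 22 bp"
upstream; the package follows the exact 35/14/21 arithmetic and treats the
22 as rounding. Peak sizes from raw electropherogram units are assigned by
piecewise-linear interpolation between flanking ladder markers
(`calibrate_sizes()`), rounded to whole nucleotides, with out-of-range
peaks extrapolated and flagged. Peaks in two traces are "the same
transcript" when calibrated sizes agree within 1 nt — the sources are
silent here, and 1 nt is the resolution a capillary ladder supports.

## Assay arithmetic

`miller_units()` uses the standard reporter-assay formula
1000 × (A420 − 1.75 × A550) / (t × v × A600); the 1.75 scattering
correction and the factor 1000 come from the canonical method description,
which the regulon studies cite rather than restate. A negative corrected
A420 is clamped to 0 and flagged. "About n-fold" statements are reproduced
by rounding the raw ratio to the nearest integer, with the raw ratio always
reported alongside. `pfaffl_ratio()` computes the efficiency-corrected
qPCR ratio E_target^dCt_target / E_ref^dCt_ref with dCt oriented as
control − treated, so values above 1 mean induction in the treated sample.

## What the synthetic data do and do not show

`simulate_expression()` draws log-normal signals: per-gene baselines
uniform on log2 6–10, planted induction effects added to all
anoxic-condition groups, planted regulator effects added to the mutant
group, Gaussian log2 noise (default SD 0.25), and detection calls drawn
independently of signal with a configurable dropout rate (default 0.05).
Independence of calls and signal is the simplest model that exercises the
75% filter; real detection calls correlate with intensity. The generator
does not model probe-level effects, intensity-dependent variance, chip
normalization artifacts, or correlated noise between genes — so green
tests demonstrate the *logic* of the pipeline (filters, conventions, set
algebra, coordinate arithmetic), not its robustness to platform-specific
noise. Annotation, promoter, and trace generators plant their truth
directly (exact gaps, box offsets, TSS offsets), making every downstream
stage testable against enumeration oracles. All generators are
deterministic given a seed.

Test and acceptance runs use 200–500 genes, 3 groups × 4 replicates,
randomized annotations up to 200 genes, and fragments up to 300 nt — sizes
chosen so each property is established in seconds while keeping at least
an order of magnitude more null genes than planted ones.

## The pipeline

`run_pipeline()` chains the stages — simulate, two differential contrasts,
regulon intersection, operon reconstruction, operon extension, box scan,
TSS calling/trace comparison, reporter summaries — through plain files
(CSV/TSV/FASTA/JSON) in one output directory, so any stage can be rerun or
replaced independently. A disabled stage makes dependents fail fast with a
dependency error. The run manifest records the seed and the md5 of every
output; identical configurations give byte-identical outputs.

```{r pipeline, eval = FALSE}
manifest <- run_pipeline(pipeline_config(seed = 1), "pipeline_out")
```

## Known limitations

* The headline set sizes of the motivating study require its original
  microarray series; the package validates properties, not those counts.
* The box model is a conserved-position count, not a PWM; it has no
  information-content weighting and finds no sites the half-site anchors
  miss. De novo motif discovery is out of scope.
* FixK-type box positions are consumed as user input in promoter
  architectures, never predicted.
* Absolute Miller units depend on per-well reaction time and volume;
  only ratios are reproducible from a published activity table.
* Operon prediction is purely annotation-based; expression-correlation
  evidence is not used.
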