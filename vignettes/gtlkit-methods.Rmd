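---
title: "Methods: spectral-library construction, RT calibration and protein summarization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral-library construction, RT calibration and protein summarization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtlkit)
```

This vignette documents the models and procedures `gtlkit` implements, the
parameters that matter, the choices made where the design was genuinely
open, and what the synthetic-data tests do and do not demonstrate.

## Peptide and fragment masses

All masses are monoisotopic. The residue table covers the 20 standard amino
acids; fixed modifications are additive deltas, with carbamidomethylated
cysteine (+57.021464 Da) applied by default, matching
iodoacetamide-alkylated samples. Constants are proton 1.007276466 Da and
water 18.0105646 Da. For a peptide r_1..r_n:

* neutral mass `M = Σ m(r_i) + m_H2O`,
* `b_k = (Σ_{i≤k} m(r_i) + z·m_H+) / z`,
* `y_k = (Σ_{i>n−k} m(r_i) + m_H2O + z·m_H+) / z`,

which gives the complementarity identity `b_k(1+) + y_{n−k}(1+) = M +
2·m_H+`, asserted to 1e-9 Da in the tests. Only y and b series are
enumerated — the dominant ions under beam-type CID — and fragment charges
default to {1, 2}; the original extraction's charge coverage is not
documented, so it is a configuration field rather than a constant.

Digestion follows the dominant trypsin convention: cut C-terminal to K or
R unless the next residue is proline. Base fragments are maximal runs
between allowed sites; missed-cleavage peptides join up to `missed`
adjacent fragments; length bounds (default 5–50) apply last so positions
remain exact. I and L are distinct residues by default; `equate_il()`
collapses them for mass-uniqueness checks, since the two are isobaric.

## Consensus spectra and transition extraction

Spectral clustering itself happens upstream; the package consumes a
spectrum-to-cluster assignment. Consensus construction is not standardized
anywhere, so the package uses the simplest defensible rule: within a
cluster, peaks are merged greedily left-to-right whenever the next peak
lies within `merge_tol` (default 0.02 Da) of the current group's
intensity-weighted mean m/z; the merged peak takes the weighted-mean m/z
and the mean intensity, and the consensus RT is the median member RT.
Singleton clusters pass through unchanged.

PSM selection keeps, per peptide group (sequence + charge — the unit
libraries are counted in), the match with the smallest q-value, provided it
is below 0.10. Ties break by higher search score, then lexicographic
spectrum id, so output is deterministic.

Transition extraction matches each theoretical y/b ion against the
consensus peak list within a *relative* tolerance of 1 ppm (|obs − theo| ≤
theo × 1e-6). When several peaks fall inside the window the closest wins,
then the more intense. All matched transitions are kept by default; a
`top_n` intensity cap exists because some library workflows prune, but the
original behavior is undocumented, so keep-all is the default.

## Endogenous RT anchors and the lasso model

Anchor candidates must satisfy four per-observation filters, with boundary
semantics chosen to match their natural phrasing: RT deviation **at most**
600 s (inclusive), peak width **strictly less than** 16.5 s, intensity
**at least** 1e5 (inclusive), and qualifying observations in **at least**
20 runs (peptides in fewer are discarded). The run count counts qualifying
observations by default; `count_qualifying = FALSE` counts any detection,
since the original criterion is ambiguous on this point.

Candidates are spread across the gradient by binning library RT into 20
equal-width half-open bins `[lo, hi)` (last bin closed) over the configured
gradient span and subsampling each bin to at most 100 peptides with a fixed
seed.

The RT model is an L1-penalized (lasso) regression of observed on library
RT over a polynomial basis, degree 1 by default and configurable to 3 —
the method is named lasso upstream but its features are not, and an affine
map captures the dominant drift between LC runs. λ is chosen by 5-fold
cross-validation over a grid reaching effectively unpenalized values, so a
strong linear signal is not shrunk noticeably. One numerical detail:
`glmnet` requires at least two design columns, so the basis always carries
a second polynomial column whose coefficient is constrained to zero when
the requested degree is 1.

The iteration loop filters, bins, fits one model per run, re-aligns every
feature against its run model's prediction, and recounts identifications —
defined here as features whose model-corrected |ΔRT| is within 600 s. This
definition deliberately isolates the selection logic from any external
peak-scoring engine; on real data the identification counts come from the
DIA scorer. The loop stops after 5 iterations or when the identified count
changes by under 0.5%, reflecting the plateau this scheme reaches in
practice.

## Multi-library combination and FDR

Combination applies three precedence rules per peptide group: the own
library's record if present; otherwise the only quantifying library's
record; otherwise the minimum-p record among externals (ties break by
library id for determinism). With more than two external libraries the
third rule generalizes to the global external minimum. The chosen
library's per-sample quantities are carried unchanged — reconciling
quantities across libraries is not defined upstream, and averaging records
from different libraries would mix incompatible normalizations.

q-values use Benjamini–Hochberg step-up adjustment. This is a deliberate,
documented stand-in for semi-supervised rescoring (PyProphet-style), which
operates on score distributions this package does not model.

## Quantification matrices

* `median_scale` divides each sample by its observed median, making every
  column's median 1.
* `log2_center_scale` standardizes each row over observed values; constant
  rows become centered zeros with a warning rather than NaN.
* `filter_missingness` keeps rows with strictly less than 30% missing.
* Protein summarization reads "a subgroup whose members correlate ≥ 0.7
  among them" as **pairwise**, i.e. a clique, not a connected component —
  "among them" implies all pairs. Cliques are found exactly via
  `igraph::largest_cliques` up to 30 peptides and by a greedy
  degeneracy-ordered heuristic beyond (exactness there would be
  exponential); ties prefer the subgroup with larger total intensity.
  Pairwise correlations require at least 6 shared observed samples, a
  pragmatic floor below which Spearman on missing-rich data is noise.
  Member intensities are summed per sample over observed members; a sample
  where every member is missing stays missing. Proteins without a
  qualifying clique are dropped by default (`fallback = "sum_all"` is
  available).
* Spearman correlations use average ranks for ties and a p-value from the
  t-approximation `t = ρ√((n−2)/(1−ρ²))` with n−2 degrees of freedom,
  computed over pairwise-complete samples (minimum 3, else the pair is
  reported with a note).

## SAAV and isoform libraries

Variant calls (already in protein coordinates — variant-effect prediction
is upstream) are filtered to ≥ 2 supporting reads and ≥ 10 total coverage,
both inclusive. Each surviving call is applied as a single-residue
substitution after checking the reference residue; the identifying
peptides are the variant digest minus the reference digest, compared by
string equality against the *parent* protein's digest (a whole-proteome
exclusion mode exists for stricter uniqueness). Substitutions creating a
K/R site yield two identifying peptides; destroying one yields a merged
peptide — both covered by digest-both oracle tests. The SAAV FASTA
concatenates identifying peptides per variant, and a sidecar table records
each member peptide's coordinates inside the record, so transition
building never sees junction-spanning artifacts. An `equate_il` option
treats I→L-type events as non-identifying, since they are mass-silent.

The isoform library digests every isoform, maps each peptide of length ≥ 5
to the exact set of isoforms containing it, and emits one mock protein per
distinct isoform set, peptides ordered by position in the
lexicographically smallest member isoform for determinism. The groups
partition the retained peptide universe by construction, and the tests
verify the partition against a brute-force digest of every isoform.

## Synthetic data: what it emulates, and what it does not

The generators produce clustered spectra (all theoretical y/b peaks with
Gaussian ppm jitter plus uniform noise peaks), drifting RT runs (affine
drift plus Gaussian noise, with designated fractions violating exactly one
anchor filter each), log-normal protein abundances with correlated true
peptides and independent decoy peptides, transcripts coupled or decoupled
from their protein, MNAR missingness (censoring below an intensity
quantile — the dominant missingness mode in MS), variant calls with
controllable cleavage-site effects, and isoform families assembled from
shared and unique tryptic blocks.

Default simulation scales used by the tests and the acceptance script:
spectra for tens of peptides at 0.3 ppm jitter and 20% noise peaks; RT
runs with 300–500 peptides × 25 runs, slope 1.05, intercept 180 s, noise
6 s; quantification sets of 100 proteins × 30 samples with peptide-level
log2 noise 0.2 and 10% censoring. These sizes give stable statistics in
seconds while exercising every code path.

What passing these tests shows: the selection logic, boundary semantics,
mass arithmetic, clique selection and library bookkeeping are correct
against independent oracles, and parameters planted in the simulation are
recovered at the stated tolerances. What they do not show: performance on
real chromatography (no peak-shape or co-elution modeling), real spectral
noise structure (noise here is uniform, not chemically structured), search
-engine score distributions (PSM q-values are drawn, not computed from
spectra), or cohort-scale biology. Numbers obtained on real data depend on
the upstream clustering, search and scoring tools this package
deliberately treats as inputs.

## Degenerate inputs and numerical choices

Empty sequences, unknown residues (unless skipping is requested),
assignments to unknown spectra, all-missing sample columns, non-positive
values before log2, constant library RTs, and duplicate peptide-group keys
all raise immediate errors naming the offending item. Subsampling and
cross-validation folds derive from explicit seeds; every generator
restores the caller's RNG state. m/z values are written to 6 decimals
(sub-ppm at any fragment mass), and GTL round-trips are byte-stable.
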