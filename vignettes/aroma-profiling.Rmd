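---
title: "Methods: differential volatile profiling and aroma-activity scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential volatile profiling and aroma-activity scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aromascreen)
```

# The analysis in brief

`aromascreen` models the common two-group headspace GC-MS contrast: the
same volatile panel measured in a handful of biological replicates per
group (typically three), with the questions being (i) which compounds
differ between groups, and (ii) which of those differences a human nose
would plausibly notice. The pipeline starts from an integrated peak table
— peak detection, integration, and spectral library matching are upstream
instrument-software steps — and carries it through retention-index
annotation, relative quantification, supervised and unsupervised
chemometrics, a VIP/p screen, and odor-activity scoring.

# Data model and conventions

A `peak_table` stores compounds × samples raw areas together with a
parallel logical `detected` matrix. A peak absent from a sample is stored
as **area 0 with `detected = FALSE`**, not as `NA`: the multivariate
steps need a complete matrix, zero is the natural "not present"
abundance, and detection counts read the flag rather than the value. The
group structure is a named map sample → label; every differential
operation requires exactly two groups and fails loudly otherwise.

CSV IO uses one fixed dialect (UTF-8, comma, `.` decimal, header row).
The wide format — one numeric column per sample plus a companion
`sample_id, group` file — is canonical; a long-format reader is provided
as a convenience. Empty area cells become undetected zeros, and
non-numeric cells are reported with their exact row/column coordinates.

# Retention indices and the identification filter

Retention indices are linear interpolations between bracketing ladder
alkanes on the 100·carbon scale. Two deliberate choices:

* **No extrapolation.** The index is defined only between bracketing
  alkanes; a query outside the ladder span is an error, not a guess. A
  C7–C27 ladder covers any sensible fruit-volatile panel, so an
  out-of-span query almost always signals a unit or ladder mistake.
* **Exact self-indices.** A query equal to a ladder retention time
  returns exactly 100·n (guarded against floating-point drift), so the
  invariant "every ladder rung self-indexes" holds bit-exactly.

The identification filter retains compounds whose **library match score**
strictly exceeds 80. Workflows sometimes describe this cut-off loosely as
a retention filter, but a retention index of 80 is physically impossible
for C7+ volatiles (the scale starts at 700), so the package implements
the only coherent reading: a match-quality filter on the 0–100 library
score. Compounds with missing scores — e.g. panels transcribed from
literature tables — are retained with a warning; `strict = TRUE` makes
this an error.

# Relative quantification

Relative content is each compound's percent of its sample's total area.
Group summaries are the **mean of per-sample percentages** (with n − 1
SDs), not the percentage of mean areas; this matches the usual
"mean ± SD" presentation of such tables and is what the class totals sum
over. Published panels that tabulate only rounded group-mean percentages
can be wrapped directly via `relative_content_table()`, whose per-sample
sum check takes a tolerance precisely because rounded values do not sum
to exactly 100 (the built-in *Docynia* panel deviates by ≤ 0.03%).
The computing path `relative_content()` always renormalises exactly.

# Chemometrics

**Z-scoring** standardises each compound across all samples (n − 1 SD);
a constant compound carries no contrast and maps to zeros rather than
NaN. Z-scoring is idempotent on non-constant rows.

**Cluster ordering** for heat maps is average-linkage (UPGMA)
agglomeration on Euclidean distances via `stats::hclust`, returning the
deterministic dendrogram leaf order. The test suite cross-checks the
merge sequence against a naive O(n³) agglomeration written from first
principles.

**PCA** is the SVD of the column-centred samples × variables matrix;
explained fractions are squared singular values over total variance.

**OPLS-DA** is written for exactly two classes: labels are dummy-coded
and centred, `k_ortho` components orthogonal to the class contrast are
removed by orthogonal signal correction, then one predictive PLS
component is fitted on the filtered matrix. Statistics follow the usual
conventions: R²X is the X-variance captured by all extracted components,
R²Y the explained label variance, Q² = 1 − PRESS/SS from cross-validation
in which the whole extraction — orthogonal filtering included — is
refitted per fold. Choices that matter at n = 6:

* **Folds** default to 7 (the common chemometrics-software convention)
  but reduce to leave-one-out whenever n_samples < folds, so a 3 + 3
  design is LOO de facto. Fold assignment is stratified and fixed by the
  seed; a split that would lose an entire class from training is refused.
* **k_ortho = "auto"** adds orthogonal components while cross-validated
  Q² improves by more than 0.01, capped at min(n − 3, 5) to prevent
  degenerate fits in tiny designs.
* **Scaling** is unit-variance by default, consistent with a Z-score
  pipeline; it can be disabled for pre-scaled input.
* **VIP** uses the standard formula with components weighted by the
  label variance they explain; the mean of squared VIPs is 1 by algebraic
  identity, checked on every fitted model. The default flavor sums over
  predictive + orthogonal components jointly; since orthogonal components
  explain essentially no label variance, it coincides in practice with
  the predictive-only flavor, which is available by flag.
* **Permutation validation** refits the model under random label
  permutations with identical hyperparameters, recording |Pearson
  correlation| between permuted and original dummy labels against R²Y
  and Q²; the unpermuted model enters as the reference point at
  correlation 1, and the reported intercepts come from least-squares
  lines through all points.

**t-tests** are two-sided on **raw peak areas**, pooled-variance by
default ("equal variances assumed"); Welch is available by flag. Note
that z-scoring a compound across both groups rescales but does not
reorder pooled-t p-values, so testing raw areas keeps the screen
consistent with the Z-scored multivariate view. **No multiple-testing
correction is applied in the screening path** — the classical VIP/p
screen uses raw p < 0.05 — but a Benjamini–Hochberg column is emitted for
users who want it.

# Screening and rOAV

The key-compound screen is the strict double criterion VIP > 1 **and**
p < 0.05; boundary values are excluded on both sides. rOAV is

$$\mathrm{rOAV}_i = 100 \cdot \frac{C_i}{C_\mathrm{ref}} \cdot
  \frac{T_\mathrm{ref}}{T_i}$$

with the reference chosen per group as the compound maximising
content/threshold among compounds with known thresholds (ties broken by
compound order). The normalising threshold is **the reference compound's
threshold** — under this reading, and only this one, the most
odor-active compound scores exactly 100 by construction and no compound
can exceed 100. rOAV is computed from group-mean relative contents (the
ratio form makes it invariant to any common rescaling); compounds
without thresholds are excluded with an explicit note, never silently.
Categories are critical (rOAV ≥ 1, inclusive), modifying
(0.1 < rOAV < 1), negligible (≤ 0.1). Aroma-type profiles sum the rOAV
of critical + modifying compounds over their descriptor terms.

# The synthetic-data generator

`simulate_volatile_experiment()` emulates the statistical structure the
analysis assumes: log-normal peak areas (positive, right-skewed), a
differential subset multiplied by a fold change in group 2, and a
dropout subset absent from group 1, mirroring maturity-specific
volatiles. Defaults are fixed at the study scale: 42 compounds, 2 groups
× 3 replicates, log-scale SD 0.3 (~30% CV), 10 differential compounds at
log2 fold change 2 (fold 4), 6 dropouts, thresholds log-uniform on
[10⁻⁴, 10] mg/kg, a C7–C27 ladder. The generator does **not** emulate
chromatographic realities — co-elution, peak-shape distortion,
between-batch drift, correlated compound families — so passing recovery
tests demonstrate statistical behaviour under the assumed model, not
robustness to instrument artefacts.

# Problem sizes and runtime choices

The test suite exercises the pipeline at the study scale (42 × 6) and
uses 20 generator seeds for recovery rates, 50 refits for the
permuted-label Q² property, 15–25 permutations in permutation-plot
tests, and 5–8 random instances per oracle comparison; these sizes give
stable checks while keeping the full suite in seconds.

# Known limitations

* **Screen power at n = 3 + 3 sits at the 0.9 knife edge.** At fold
  change 4 and log-SD 0.3, the per-compound recovery of the VIP ∧ p
  screen hovers around 0.89–0.91 over seed sets: the pooled t-test at
  three replicates is the binding constraint. Recovery is strongly
  monotone in effect size (≈ 0.05 at fold 1, ≈ 0.55 at fold 2).
* **VIP ranks are unstable at small n.** VIP > 1 captures nearly all
  injected compounds, but the *top-d* ranks contain only ~85–90% of
  them, since null compounds can by chance align with the class contrast
  across six samples.
* **Rounded published contents limit rOAV precision.** When contents
  enter at two decimals, the ~0.5–2% relative error propagates through
  the content ratios; small rOAVs reproduce tabulated values at two
  decimals, while values of magnitude 10–100 can differ by a few tenths
  to ~1 unit from figures computed on unrounded replicate-level data.
* **One pseudo-replicate per group supports no inference.** The built-in
  reference panel allows every ratio-based quantity but neither t-tests
  nor OPLS-DA; the pipeline refuses to pretend otherwise and takes
  external VIP/p columns instead.
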