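---
title: "From taste chemistry to consumer response: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From taste chemistry to consumer response: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umamipanel)
```

`umamipanel` implements a complete flavoromics-to-consumer pipeline for
the Chinese mitten crab (*Eriocheir sinensis*): chemical taste scoring of
three edible parts (abdomen meat M, hepatopancreas H, gonad G) from two
farming origins and two selected varieties, check-all-that-apply (CATA)
emoji sensometrics for a 93-consumer panel, group-level correlation by
multiple factor analysis (MFA) and the RV coefficient, and a small
feed-forward network predicting hedonic preference from six flavor
compounds. This vignette explains the models, the tunable parameters, the
synthetic-panel generator, and the design decisions that were genuinely
open.

## The study design and its data objects

Nine samples exist: parts {M, H, G} crossed with origin-variety
combinations {C-JH, T-JH, T-CJ} (Chongming reared only the Jianghai 21
variety; Taixing reared Jianghai 21 and Yangtze II). The raw chemical
observable is a replicate-level concentration table (`compound_table`):
26 compounds — 17 free amino acids (FAAs), the 5'-nucleotide-related
compounds GMP, IMP, AMP, Hx, HxR, and the ions Na⁺, K⁺, Mg²⁺, Ca²⁺ — in
mg/100 g with three replicates per cell. Raw replicates were never
deposited for this system; the package ships the published per-cell
mean ± SD (`load_crab_compounds()`) and regenerates replicates
synthetically when replicate-level data are needed. Below-detection cells
(`"ND"`, e.g. hepatopancreas GMP/IMP/AMP) are stored as zero with
`detected = FALSE`: they contribute nothing to sums or umami scoring,
which is the only defensible numeric reading of a value below the
detection limit.

### Taste categories: two schemes on purpose

FAAs group into umami, sweet and bitter categories. The published
summary rows are reproduced (to within the ±0.05 mg/100 g rounding of
printed means — a property the test suite checks on all nine samples)
only by the membership umami = {Asp, Glu}, sweet = {Thr, Ser, Gly, Ala,
Pro, Arg}, bitter = {Val, Leu, Tyr, Phe, Lys, His, Ile}, with Met and Cys
uncategorized. The accompanying narrative instead lists Met as bitter and
omits Arg from sweet. Both conventions are defensible sensory chemistry
(Arg is ambivalently sweet-bitter; Met is usually called bitter), so both
ship as `faa_categories("table")` and `faa_categories("text")`; `"table"`
is the default because the printed sums are the verifiable ground truth.
Neither is asserted as "correct".

## Taste scoring

**TAV.** The taste activity value is `content / threshold`; TAV > 1
flags a compound as taste-active. Thresholds are matrix- and
panel-dependent and the source study does not print its threshold table,
so the packaged registry (`default_thresholds()`) anchors only arginine,
at 50 mg/100 g — the value that back-derives the reported Arg TAV range
12.89–13.47 from the Arg concentrations — and fills the other entries
with documented literature placeholders that users should replace via
`read_thresholds()`. With the placeholder registry, the taste-active set
in abdomen meat is exactly the eight FAAs reported for that part (Glu,
Gly, Ala, Arg, Pro, Met, Lys, His) and K⁺ is the only active ion, so the
placeholders are at least qualitatively faithful; still, only the Arg
entry is treated as quantitative.

**EUC.** The equivalent umami concentration aggregates umami amino acids
and synergistic nucleotides into g MSG/100 g:

$$\mathrm{EUC} = \sum_i a_i b_i \;+\; 1218\Big(\sum_i a_i b_i\Big)\Big(\sum_j a_j b_j\Big)$$

with relative umami concentrations $b$ of Glu 1, Asp 0.077 (amino acids,
relative to MSG) and IMP 1, GMP 2.3, AMP 0.18 (nucleotides, relative to
IMP), concentrations in g/100 g, and the bilinear synergy constant 1218.
Two numeric caveats are documented rather than hidden:

* Because EUC is nonlinear, evaluating it at per-cell *means* is not the
  same as averaging per-replicate EUCs. At the coefficients of variation
  of this data the difference is below 0.5% for meat and gonads, which is
  why the package's EUC checks use a 1% relative tolerance.
* The published hepatopancreas EUC values (0.32, 0.01, 0.01) cannot be
  derived from the published hepatopancreas concentrations by the formula
  above (which gives ≈0.38, 0.065, 0.063 with non-detects as zero — an
  inconsistency in the source material with no stated explanation).
  `euc_table()` reports the formula's value; the hepatopancreas cells are
  simply not used as reproduction anchors.

**Contrast conventions.** `pct_more(a, b) = (a − b)/a × 100` uses the
*reference* (first, larger) argument as denominator. This is contrary to
the everyday reading of "X% more than b" (denominator `b`) but is the
convention under which the published umami contrasts (29.92%, 32.66%)
reproduce; it is therefore the implemented and prominently documented
one. `share_of_total()` is the ordinary percentage of a total.

## CATA emoji statistics

Selections are a binary consumer × sample × emoji tensor in a complete
block design (every consumer rated all nine samples against 23 emojis:
13 positive, 8 negative, 2 neutral).

**Cochran's Q** tests equality of selection proportions across the nine
samples per emoji; the default p-value is the chi-square asymptote with
k − 1 degrees of freedom (the variant in standard sensometrics software).
For very small panels `cochran_q(..., method = "exact")` enumerates every
within-row rearrangement — the exact permutation null of the block design
— and the test suite pins it against an independently coded brute-force
enumeration. At a 4 × 3 toy instance the exact p (0.296) is nearly twice
the asymptotic one (0.174), a useful reminder that the asymptotic flavor
is a large-panel tool.

**Pairwise McNemar** follows the significant Q: all 36 pairs at
Bonferroni level α/36. The test flavor switches at the conventional
point: exact binomial when discordant pairs b + c < 25, chi-square
without continuity correction otherwise. Results are summarised as a
compact letter display via insert-and-absorb over the significance graph
(ties broken by study sample order); the lettering algorithm used in the
original analysis software is not documented anywhere, so any agreement
is on the partition, not on letter names.

**Correspondence analysis** is the classical chi-square decomposition:
correspondence matrix $P$, masses $r, c$, standardized residuals
$S = (P - rc')/\sqrt{rc'}$, SVD, principal coordinates scaled by singular
values. Two design notes:

* The two never-selected emojis have zero mass and are mathematically
  inadmissible as active rows; `load_emoji_frequencies()` drops them by
  default, leaving the 21 × 9 table.
* Percent tables are used directly: CA inertia *proportions* are
  invariant to global rescaling, so reconstructing counts from
  percentages is unnecessary (a property the tests verify).

The packaged frequency table stores integer percentages. On that table
the recomputed first two dimensions carry ≈72.0% of inertia (dimension 2
≈17.7%), not the ≈74.3%/20.5% reported for the original analysis; the
computed decomposition is verified against an independent CA
implementation (`vegan::cca`), and no aggregation variant of the printed
table (count reconstruction at n = 93, CATA table doubling, significant-
emoji subsets) reproduces the reported pair. The likely cause is that the
original analysis ran on unrounded frequencies that were never deposited.
The package reports what the available table yields rather than tuning
toward the reported number.

## MFA and RV

For group-level correlation the samples × variables data are split into
groups (FAAs, nucleotides, ions, sensory intensities, enjoyment, emoji
frequencies). Continuous groups are z-scored; frequency groups get the
CA (chi-square) standardized-residual transform so mixed data types are
comparable. Each block is weighted by the inverse of its first singular
value — the classical MFA balancing that stops any one group from
dominating dimension 1 — and the concatenation is decomposed by a global
PCA. Group association uses Escoufier's RV,

$$RV = \frac{\operatorname{tr}(XX'YY')}{\sqrt{\operatorname{tr}((XX')^2)\operatorname{tr}((YY')^2)}} \in [0, 1],$$

with the study's reading bands: < 0.6 low, 0.6–0.7 moderate, > 0.7 high
(`rv_band()`), and `export_network()` writes node/edge CSVs and a SIF
file for Cytoscape-style viewers. The original MFA input matrix (which
per-sample sensory means entered, and whether Hx/HxR sat with the
nucleotides) is not published, so the reported variance shares and RV
values are not reproduction targets; MFA/RV are instead validated by
their mathematical invariances (rotation/scale invariance, group-order
invariance, reduction to PCA for one group) and by planted-latent-factor
recovery on synthetic data. Note RV's positive small-sample bias: at
nine samples, two genuinely independent five-variable groups typically
show a clearly nonzero RV, and the test suite asserts only that the
large majority of such draws stay below the 0.6 band — worth remembering
when reading "low" RV values at panel-study sample sizes.

## The preference network

A single-hidden-layer feed-forward network maps the six
preference-relevant compounds (Arg, Ala, Gly, Pro, K⁺, Ca²⁺) to hedonic
preference. Choices, with rationale:

* **Normalization** (`fit_scaler()`): min-max to [0, 1] per variable,
  inverted exactly on prediction.
* **Split** (`split_data()`): 70/15/15 train/validation/test with
  largest-remainder rounding (27 rows → 19/4/4) and a seeded permutation.
* **Fitting**: `nnet::nnet` (full-batch BFGS backpropagation, logistic
  hidden units, linear output), the standard R implementation of exactly
  this architecture. The logistic hidden activation is representationally
  equivalent to tanh up to an affine reparameterisation of the weights;
  the package's contracts are on metrics, not weight trajectories.
* **Validation use**: `nnet` exposes no epoch callback, so instead of
  epoch-level early stopping the validation set selects among several
  seeded random initializations (5 by default), which serves the same
  purpose — guarding against a poor local optimum or an overfit run — in
  a way that is exactly reproducible under a seed.
* **Metrics**: R² is the squared Pearson correlation between predicted
  and observed preference over all rows (the regression-of-outputs
  convention used with such scans); MSE is on the normalized scale.
  R² conventions differ enough across software that this is worth
  stating exactly.
* **Sizing** (`neuron_scan()`): hidden sizes 1–10 by trial and error,
  reporting R²/MSE per size. The reported R²/MSE values of the original
  scan depend on unpublished consumer-level data and on stochastic
  training, and are not reproduction targets; the scan is instead
  validated by parameter recovery on synthetic data with a planted
  relation (best R² ≥ 0.9 at 200 observations, noise SD 0.05).

## The synthetic panel generator

The generator exists because no raw consumer or replicate data are
deposited; its defaults *are* the study conditions:

* `gen_compound_replicates()`: truncated-normal draws (lower bound 0) at
  the published per-cell mean ± SD, n = 3. Truncation matters only for
  high-CV cells (gonad K⁺, 129 ± 54) and protects against negative
  concentrations.
* `gen_cata()`: independent Bernoulli selections at the published
  per-(emoji, sample) frequencies for 93 consumers. Only marginal
  frequencies are published, so no emoji co-selection structure is
  modeled — synthetic panels will underestimate correlations between
  emoji columns, and passing CATA tests demonstrate engine correctness,
  not realism of consumer covariance.
* `gen_hedonic()`: integer 9-point scores as rounded, clipped normals.
  Per-sample means are only published as a range (4.69–6.30, all above
  5.00 except H-C-JH); the defaults spread the nine means across that
  range with H-C-JH at the minimum and abdomen meat most liked, matching
  the qualitative preference ordering. These are design-time choices,
  fixed once.
* `gen_preference_dataset()`: plants a known monotone link from the six
  normalized compounds to preference for network-recovery tests. The
  `"saturating"` link passes each input through a tanh ramp centered at a
  compound-specific half-saturation point (slope 6 on the normalized
  scale): taste intensity saturates with concentration and each compound
  saturates at its own level. A sum of six axis-aligned ramps firing at
  different points is deliberately *not* a single ridge function, so one
  hidden unit underfits it while three suffice — the basis of the
  nonlinearity-recovery property.

All generators are pure functions of (spec, seed), restore the caller's
RNG state, and are byte-reproducible.

## Problem sizes and runtime

The shipped tests run the neuron scan at 200 observations and 10 hidden
sizes, CATA convergence checks at 5 000 synthetic consumers, moment
checks at 10 000 draws, and the exact Cochran enumeration at 4 × 3
(81 arrangements); the whole suite completes in well under a minute on a
single core, and the headline-quantity script is pure linear algebra on
the packaged tables.

## Known limitations

* Thresholds other than arginine's are placeholders; TAV tables computed
  from them are qualitative.
* The hepatopancreas EUC inconsistency and the CA inertia gap described
  above are properties of the available published tables, not of the
  implementation; both are surfaced in documentation rather than patched.
* Synthetic CATA data lack co-selection structure; synthetic hedonic
  scores are homoscedastic across samples.
* The MFA/network stages are validated structurally and on synthetic
  recovery, not against the original (unpublished) consumer-level data.
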