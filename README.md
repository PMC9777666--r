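# umamipanel

Taste-compound scoring and consumer emotion analytics for crustacean
flavor panels, built around the Chinese mitten crab (*Eriocheir
sinensis*).

Flavor chemists and sensometricians who profile an aquatic product
usually hold two disconnected data sets: a chemical table (free amino
acids, 5'-nucleotides, metal ions, in mg/100 g) and a consumer panel
(9-point hedonic scores, taste-intensity ratings, and check-all-that-apply
"CATA" emotion ballots). `umamipanel` implements the full pipeline that
connects them for a nine-sample crab design (abdomen meat,
hepatopancreas and gonad of crabs from two farms and two selected
varieties):

* **Taste scoring** — taste activity values (TAV = C/T, with T the taste
  threshold) and the equivalent umami concentration with nucleotide
  synergy,

  EUC = Σᵢaᵢbᵢ + 1218 (Σᵢaᵢbᵢ)(Σⱼaⱼbⱼ)  [g MSG/100 g],

  where the aᵢ are Glu/Asp and the aⱼ are IMP/GMP/AMP concentrations
  (g/100 g) and the b are relative umami concentrations (Glu 1,
  Asp 0.077; IMP 1, GMP 2.3, AMP 0.18). Category accounting (umami /
  sweet / bitter FAA sums) and the compositional contrasts used to
  compare parts and origins are included.
* **CATA emoji statistics** — emoji × sample frequency tables, Cochran's
  Q across the nine samples (asymptotic, plus an exact permutation
  variant for small panels), all-pairs McNemar tests with Bonferroni
  correction and a compact letter display, and chi-square correspondence
  analysis (CA) with principal coordinates and inertia decomposition.
* **Group correlation** — multiple factor analysis (MFA) over variable
  groups with the classical inverse-first-singular-value weighting, and
  Escoufier's RV coefficient with the low/moderate/high banding at
  0.6/0.7, exportable as network files for Cytoscape-style viewers.
* **Preference prediction** — a 6 → h → 1 feed-forward network (min-max
  normalization, 70/15/15 split, hidden sizes scanned 1–10) predicting
  hedonic preference from Arg, Ala, Gly, Pro, K⁺ and Ca²⁺.
* **Synthetic panel generator** — replicate-level compound tables,
  93-consumer CATA tensors and hedonic scores with the statistical
  structure of the study design, so the whole pipeline is testable
  although no raw consumer data were ever deposited.

The packaged data (`load_crab_compounds()`, `load_emoji_frequencies()`,
`default_thresholds()`) transcribe the published per-cell summary tables
of the source study; replicate- and consumer-level data are always
synthetic. See the methods vignette
(`vignettes/umamipanel-methods.Rmd`) for the models, parameter choices
and known limitations.

## Worked example

```r
library(umamipanel)
s <- load_crab_compounds()          # 9 samples x 26 compounds, mean/sd/n

category_sums(s)[, 1:4]             # FAA category accounting, mg/100 g
#>        category  M-C-JH  M-T-JH  M-T-CJ
#> 1         umami   73.24   57.29   75.21
#> 2         sweet 2175.61 2266.50 2070.48
#> 3        bitter  158.37  219.27  256.86
#> 4 uncategorized   28.13   49.63   61.49
#> 5         total 2435.35 2592.69 2464.04

et <- euc_table(s)                  # umami intensity, g MSG/100 g
data.frame(sample = et$sample, euc = round(et$euc, 2))
#>   sample    euc
#> 1 M-C-JH   9.04
#> 2 M-T-JH   6.22
#> 3 M-T-CJ   7.39
#> 4 H-C-JH   0.38
#> 5 H-T-JH   0.07
#> 6 H-T-CJ   0.06
#> 7 G-C-JH 128.70
#> 8 G-T-JH 165.42
#> 9 G-T-CJ 108.78

correspondence_analysis(load_emoji_frequencies())
#> Correspondence analysis: 21 rows x 9 columns
#> Total inertia (chi-square / N): 0.142898
#> Inertia by dimension (%): 54.30 17.67 9.36 8.92 4.34 2.23 1.80 1.39
```

The category sums reconstruct the published summary rows to within the
rounding of the printed means. The EUC column shows the umami hierarchy
of the parts: gonads two orders of magnitude above meat (IMP/GMP-driven
synergy), hepatopancreas lowest; among meats, the Chongming Jianghai 21
sample (M-C-JH, 9.04 g MSG/100 g) leads. The CA decomposition of the
21 × 9 emoji frequency table puts 54.3% + 17.7% of the chi-square inertia
on the first two dimensions, which separate positive from negative
emotions (dimension 1) and, more weakly, arousal level (dimension 2).

A preference model on synthetic data with a planted compound–preference
relation:

```r
ds <- gen_preference_dataset(n_rows = 200, link = "saturating", seed = 1)
scan <- neuron_scan(ds$X, ds$y, h_range = 1:10, seed = 1)
attr(scan, "best")        # hidden-layer size with the best fit
#> [1] 3
round(max(scan$r_squared), 3)
#> [1] 0.984
```

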