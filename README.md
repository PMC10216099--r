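# eegnets

Resting-state EEG coherence networks of spatial attention: a tested R
implementation of the full analysis chain used to compare children with
nonverbal learning disability (NVLD) against typically developing (TD)
peers from source-level resting EEG — and to validate every stage on
synthetic cohorts with known ground truth.

## Who this is for

Clinical neurophysiology and EEG network-neuroscience groups who want a
reproducible pipeline for band-wise functional connectivity in networks
of interest (dorsal and ventral attention networks, DAN/VAN), with
machine-learning discrimination, brain-to-behavior prediction, and
weighted-graph topology backed by Bayesian inference — without
hand-assembled toolbox scripts.

## The core quantities

- **Magnitude squared coherence** per frequency band, from Welch
  cross-spectra (2-s Hann windows, 50% overlap by default):

  MSC_xy(f) = |S_xy(f)|² / (S_xx(f) · S_yy(f)) ∈ [0, 1],

  band value = mean of per-bin MSC over bins inside delta 2–4, theta
  5–7, alpha 8–12, beta 13–29 or gamma 30–59 Hz.
- **Leave-one-subject-out linear SVM** accuracy per network ×
  hemisphere × band (chance 50%), and **LOO ε-SVR** prediction of the
  visuospatial composite (mean of Rey figure copy and recall z-scores),
  summarized by the Pearson r of held-out predictions and filtered by
  r > 0 and correlation BF₁₀ ≥ 3.
- **Weighted graph metrics** on top-10% thresholded, max-normalized
  coherence graphs: degree, strength, Onnela clustering, global
  efficiency E = mean over pairs of 1/d_ij with edge length 1/w,
  strength assortativity, Louvain modularity Q.
- **Bayes factors**: JZS t-test (Cauchy prior on effect size, default
  width 0.707) and Pearson-correlation test (stretched-beta prior,
  default width 0.5), with prior-width robustness curves and the
  conventional evidence scale (moderate ≥ 3, strong ≥ 10, very strong
  ≥ 30, extreme ≥ 100).

## Worked example

Bayes factors straight from published-style group summaries:

```r
library(eegnets)
jzsTtestBF(m1 = -4.93, sd1 = 2.69, n1 = 16,   # NVLD copy z-scores
           m2 = -0.88, sd2 = 1.27, n2 = 16)   # TD copy z-scores
#> BF10 = 2235 (extreme evidence; cauchy_on_effect_size prior,
#>              width 0.707107, two_sided; t = 5.446, df = 30)

bayesCorrelationBF(0.55, 16)
#> BF10 = 3.249 (moderate evidence; stretched_beta_on_correlation prior,
#>               width 0.5, two_sided; r = 0.550, n = 16)

anovaFromSummary(-4.93, 2.69, 16, -0.88, 1.27, 16)[c("F", "etaPSquared")]
#> $F            29.65759
#> $etaPSquared  0.4971302
```

The t = 5.446 implied by the copy summaries is a very large effect
(Cohen's d ≈ 1.9), hence the "extreme" category; the r = 0.55
correlation at n = 16 only reaches "moderate" evidence.

A full synthetic study — simulate a 16 + 16 cohort (24 DAN/VAN ROIs,
256 Hz, 240 s) with a gamma-band DAN coupling difference and a
delta-band right-DAN behavior linkage in the NVLD-like group, then run
every stage:

```r
report <- runFullStudy(runConfig(cohort = demoCohortConfig(seed = 0),
                                 graphBands = "gamma"))
report$accuracy$byBand
#>    band nCells      mean         se informative
#> 1 alpha      4 0.5937500 0.11121957        TRUE
#> 2  beta      4 0.4531250 0.11796616       FALSE
#> 3 delta      4 0.6484375 0.10393855        TRUE
#> 4 gamma      4 0.7812500 0.14768174        TRUE
#> 5 theta      4 0.5234375 0.04302789        TRUE

report$predictions$reported
#>     roi  band group  n         r         bf10 evidence
#> 1 DAN-R delta  NVLD 16 0.9882306 1.495030e+08  extreme
#> 2 VAN-R theta  NVLD 16 0.8073202 1.402736e+02  extreme
```

Reading this: the gamma band — the only band with an injected group
difference in both hemispheres — discriminates the groups (DAN cells hit
100% accuracy; the band mean of 78% averages over the uncoupled VAN
cells), untouched bands hover near chance, and the injected right-DAN
delta linkage is recovered as a reported brain-to-behavior prediction
for the NVLD-like group (the VAN-R theta row is a false positive of the
kind the 20-seed acceptance test quantifies). Nodal group comparisons in
`report$graphStats$nodal` flag the IPS hub nodes with degree/strength
BF₁₀ well above 3 in gamma.

Individual stages are exported too — `generateCohort()`,
`welchCrossSpectra()`, `mscBand()`, `buildFeatures()`, `loocvSvm()`,
`loocvSvr()`, `buildGraph()`, `nodalMetrics()`, `globalMetrics()`,
`compareGroupsGraphMetrics()` — and a YAML-driven command-line wrapper
lives at `inst/scripts/run_full_study.R`.

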