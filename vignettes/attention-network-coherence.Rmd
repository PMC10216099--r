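---
title: "Resting-state coherence networks of spatial attention: models and methods"
author: "eegnets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting-state coherence networks of spatial attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(eegnets)
```

## The scientific problem

Nonverbal learning disability (NVLD) presents with visuospatial deficits
alongside spared verbal skills, and a long-standing hypothesis places its
neural basis in right-hemisphere connectivity. A natural way to probe this
is resting-state EEG functional connectivity inside the two spatial
attention systems — the dorsal attention network (DAN: frontal eye fields,
FEF, and intraparietal sulcus, IPS) and the ventral attention network
(VAN: ventral prefrontal cortex, VPFC, and temporo-parietal junction,
TPJ) — estimated at the cortical-source level and compared between NVLD
and typically developing (TD) children.

`eegnets` implements that analysis chain as reusable, tested components:

1. band-wise **magnitude squared coherence** (MSC) from Welch
   cross-spectra,
2. **leave-one-subject-out (LOO) linear SVM** discrimination of group
   membership from network coherence patterns,
3. **LOO support-vector regression** predicting a visuospatial composite
   (the mean of Rey–Osterrieth complex figure copy and recall z-scores)
   from the same patterns, filtered by a Bayesian-correlation evidence
   rule,
4. **weighted graph topology** (degree, strength, Onnela clustering,
   global efficiency, assortativity, Louvain modularity) on thresholded,
   max-normalized coherence graphs, and
5. **Bayes-factor inference** (JZS t-tests, stretched-beta correlation
   tests) with prior-robustness curves.

Because no raw recordings are publicly deposited for this kind of cohort,
the package ships a first-class synthetic-cohort generator whose coupling
structure is known exactly, so every downstream stage can be validated by
parameter recovery.

## Coherence model

For channels $x$ and $y$ with cross-spectrum $S_{xy}(f)$ and auto-spectra
$S_{xx}(f)$, $S_{yy}(f)$, the magnitude squared coherence is

$$\mathrm{MSC}_{xy}(f) \;=\; \frac{|S_{xy}(f)|^2}{S_{xx}(f)\,S_{yy}(f)} \in [0, 1].$$

Spectra are estimated by Welch averaging: 2-s Hann-tapered segments with
50% overlap (both configurable), per-segment mean removal, no further
detrending. At 256 Hz and 240 s this gives $K = 239$ averaged segments
and a 0.5-Hz frequency resolution. The band summary is the arithmetic
mean of per-bin MSC over bins whose center frequency falls inside the
band, closed at both integer edges (delta 2–4, theta 5–7, alpha 8–12,
beta 13–29, gamma 30–59 Hz). Averaging per-bin coherence (rather than
taking coherence of band-averaged spectra) is the common
coherence-toolbox convention and is recorded in the output metadata.

Two estimator facts matter for interpretation and are asserted in the
test suite: MSC of independent channels is biased upward by roughly
$1/K$ (so 240 s of data put the noise floor near 0.004), and MSC is
invariant to separate rescaling of either channel.

## The synthetic cohort

Each subject is a 24-ROI (up to 148), 256-Hz, 240-s source-level
recording. Every ROI series is a sum over the five bands of
unit-variance band-limited processes, so the variance target per series
equals the number of bands. Band-limiting uses the squared-magnitude
response of a 4th-order digital Butterworth band-pass applied with zero
phase in the spectral domain — the same transfer function a
forward–backward (filtfilt) pass applies, chosen because it is exactly
linear-phase-free, spectrally flat in band, reproducible, and an order of
magnitude faster at cohort scale. The flat in-band spectrum is a modeling
choice; resting EEG has 1/f structure that the generator does not
emulate, which is irrelevant to MSC (a spectral ratio) but means absolute
PSD shapes should not be read off these simulations.

Coupling is injected per (group, network, hemisphere-scope, band,
anatomical-role) row: each row spawns one shared band-limited source
$s$, and a covered ROI mixes it as
$x_i = a\, s + \sqrt{1 - a^2}\, n_i$ with independent noise $n_i$.
Two covered ROIs then have asymptotic band MSC $a^4$ (additivity across
several rows goes through the summed cross-amplitude). The mixing
coefficient is jittered per subject (truncated Gaussian) to create
inter-subject variability; a per-node cap keeps the summed source power
below 1. Group effects enter **only** through couplings, never through
amplitude, so any successful classification reflects connectivity alone.

The behavioral composite is an affine function of the subject's true
mean pairwise coherence in a designated network/hemisphere/band scope,
plus Gaussian noise; with zero noise the linkage is exact, which the
tests assert. A separate helper draws copy/recall z-scores at the
published group means and SDs for exercising the Bayesian t-test stage
at realistic effect sizes.

Seeding: one master seed spawns per-subject substreams keyed by group
and within-group index, so enlarging the cohort never perturbs existing
subjects, and identical configs are byte-identical.

The demonstration configuration (`demoCohortConfig()`) encodes the
study conditions used throughout the acceptance suite: 16 + 16 subjects;
a gamma-band DAN source with squared coupling 0.30 present only in the
NVLD-like group, concentrated further on IPS so parietal hubs emerge in
the graphs; and a delta-band right-DAN source whose per-subject strength
drives the composite (behavior weight 10, noise SD 0.3).

## Networks and features

The parcel-to-network assignment is a convention, not an anatomical
ground truth, so it ships as an editable JSON: six
Destrieux-style parcels per network per hemisphere (FEF/IPS for DAN,
VPFC/TPJ for VAN), twelve bilateral nodes per network. Node order is
fixed (anterior roles first, left before right, alphabetical within
role) so that feature vectors are reproducible. A network submatrix is
the principal submatrix in definition order; its strict upper triangle
in row-major order is the feature vector, $n(n-1)/2$ values for $n$
nodes (66 for a bilateral network, 15 per hemisphere).

## Machine learning protocol

Classification uses a linear soft-margin SVM with the library default
box constraint $C = 1$ and no kernel scaling; regression uses
$\varepsilon$-SVR with $C = 1$, $\varepsilon = 0.1$. Both run
leave-one-subject-out: features are standardized with training-fold
means/SDs (applied to the held-out subject; constant features get unit
scale with a warning), SVR targets are centered per fold. This per-fold
standardization prevents information leakage and is toggleable.
Accuracy is the fraction of correct held-out labels — necessarily a
multiple of $1/n$ — with a 50% chance level for balanced groups; a
decision value of exactly zero resolves deterministically (training-fold
majority, then "NVLD"). Regression quality is the Pearson correlation
between pooled held-out predictions and observations, pooled rather than
averaged per fold because single-subject folds have no within-fold
correlation.

The prediction report keeps only rows with $r > 0$ (a negative LOO
correlation indicates a failed fit, not an inverse association) and
correlation BF$_{10} \ge 3$; filtering is idempotent and the test suite
checks both the rule and its null behavior.

## Graphs and topology

Per subject, network scope and band: keep the
$m = \lceil 0.10 \cdot n(n-1)/2 \rceil$ strongest connections with their
values (no binarization; ties at the cutoff are all kept and flagged,
which keeps the rule deterministic without arbitrary tie-breaking), zero
the rest, then divide by the maximum weight so the strongest edge is
exactly 1. Normalization must precede the metrics; the functions enforce
this. The "keep the top fraction" reading of the threshold, the ceil
rounding, and the fraction itself are all config keys.

Global measures are computed on single-hemisphere graphs, nodal measures
on bilateral graphs. Definitions:

- **degree** — count of retained incident edges; **strength** — sum of
  normalized incident weights (with normalized weights, strength never
  exceeds degree);
- **clustering** — Onnela's weighted coefficient
  $C_i = \tfrac{2}{k_i(k_i-1)} \sum_{j<h} (\hat w_{ij}\hat w_{ih}\hat w_{jh})^{1/3}$,
  zero for degree < 2;
- **global efficiency** — mean inverse shortest-path length over ordered
  pairs with edge lengths $1/w$, disconnected pairs contributing zero;
- **assortativity** — Pearson correlation of endpoint strengths over
  edges (reported missing when degenerate);
- **modularity** — best Louvain $Q$ over 100 seeded restarts at
  resolution 1.

All of these are checked against exhaustive oracles on $\le 7$-node
fixtures (Floyd–Warshall shortest paths, explicit triangle enumeration,
brute force over all node partitions), including the worked values:
path-of-3 efficiency $5/6$, reweighted-triangle clustering $0.5$,
two-clique modularity $0.5$.

## Bayesian inference

**JZS t-test.** The pooled-variance $t$ is computed from raw samples or
printed summaries (the two modes agree exactly when summaries come from
the samples). BF$_{10}$ integrates the noncentral-$t$ likelihood over a
Cauchy prior on the standardized effect size (adaptive quadrature,
relative tolerance $10^{-9}$); one-sided variants truncate the prior.
The quadrature is dual-checked in the tests against the $g$-prior
integral representation and a Monte-Carlo prior-sampling estimate.

**Correlation test.** BF$_{10}$ for a Pearson $r$ under a stretched-beta
prior on $\rho$ — beta$(1/w, 1/w)$ rescaled to $(-1, 1)$ — using the
exact sampling density of $r$ through its
$\int_0^\infty (\cosh u - \rho r)^{-(n-1)}\,du$ representation.

**Prior conventions.** The default width is 0.707 for t-tests and 0.5
for correlations, both exposed. Where the published analysis is
ambiguous about sidedness and width, the package documents a sweep over
widths $\{0.5, 0.707, 1\}$ and sidedness $\{$two-sided, directional$\}$
and resolves it to the two-sided defaults: that convention reproduces
the published recall-trial t-test BF to about 1% and all three published
correlation BFs within a factor of 2, which identifies it as the
convention actually used. Two published values resist recomputation and
are documented rather than asserted: the copy-trial BF$_{10}$ of
44,791.26 is unreachable from the printed group summaries (the implied
$t = 5.45$ caps any effect-size-prior BF near $4\times 10^3$–$5\times
10^3$; even the maximum likelihood ratio over all priors is
$\sim 4\times 10^4$), and the gender $\chi^2(1) = 0.183$ does not follow
from the printed 12:4 / 14:2 counts (direct computation gives 0.82
uncorrected, 0.21 Yates-corrected; both are reported).

Evidence categories follow the conventional scale — anecdotal < 3,
moderate [3, 10), strong [10, 30), very strong [30, 100), extreme
$\ge$ 100 — and every BF can carry a robustness curve over a prior-width
grid; the curve reproduces the single-call BF at its own width to
$10^{-9}$. Robustness of the recall-trial t-test stays above 100 for
widths $\gtrsim 0.15$ but drops to "very strong" (66.6) at width 0.1.

## Numerical choices and degenerate inputs

- Band membership is by bin center, closed at both edges — deterministic
  for integer band edges on a 0.5-Hz grid.
- MSC is clip-free: Cauchy–Schwarz guarantees $[0,1]$ for averaged
  spectra, and a violation would be a bug, not something to clamp.
- Silent channels (zero in-band auto-spectrum) raise an error naming the
  channel; empty bands, Nyquist-crossing bands, too-short recordings,
  all-zero graphs, zero pooled variances, $|r| = 1$ and single-class
  folds all raise descriptive errors asserted in the tests.
- `dt(..., ncp)` carries roughly $10^{-8}$ relative accuracy; that is
  orders of magnitude inside the factor-level tolerances used for BFs.
- Louvain is stochastic; all modularity values are computed under a
  fixed seed with the best-of-100 rule, making reports byte-identical
  across runs.

## What the validation shows — and what it does not

The acceptance suite reruns the full pipeline on 20 fresh demo cohorts
(16 + 16 subjects, 240 s each; sizes chosen to mirror the study
conditions): gamma-DAN classification recovers the injected group
difference (median accuracy at or above 0.75) while untouched bands stay
at chance; the right-DAN/delta behavior linkage is reported for the
NVLD-like group and not for controls in the majority of seeds; and DAN
degree/strength group BFs exceed 3 in the affected band with IPS hubs
more connected in the NVLD-like group. Passing these recovery tests
shows the chain is statistically faithful to its own generative model.
It does not show that real resting EEG satisfies that model: the
generator has no 1/f background, no artifacts, no volume
conduction/source-leakage (the package deliberately implements plain
MSC, not leakage-corrected measures), and its group effects are cleaner
than nature's. Results on real data inherit those caveats.

## Known limitations

- Phase-based connectivity (PLV, imaginary coherence) and leakage
  correction are out of scope by design.
- Only DAN/VAN node sets ship; other networks require a user-supplied
  definition file.
- Nodal local efficiency is not part of the canonical measure set here;
  clustering serves as the segregation proxy.
- The 148-ROI mode exists but the default 24-ROI layout keeps the full
  pipeline at desk scale (a single full study runs in under a minute on
  one core).
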