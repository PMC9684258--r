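---
title: "Microstate analysis of resting-state EEG: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate analysis of resting-state EEG: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microvolt)
```

## The model

Resting-state EEG alternates between a small number of quasi-stable scalp
potential topographies — microstates — each persisting for roughly 40–100 ms
before switching. `microvolt` implements the standard analysis chain for
low-density (19-channel 10/20) clinical recordings:

1. **Global field power (GFP)** is the per-instant population standard
   deviation of the potential across electrodes. Its peaks mark the moments
   of strongest, most stable topography; only the scalp maps at GFP peaks
   enter template estimation.
2. **Polarity-invariant clustering** (the "modified k-means") groups peak
   maps by topographic shape, treating a map and its sign-flip as
   identical. Each map joins the template with the highest absolute spatial
   correlation; each template is re-estimated as the first principal
   direction of its members — the orientation-invariant analogue of the
   cluster mean, which is the right estimator because the sign of a
   microstate field is physiologically arbitrary.
3. **Model selection** uses the Krzanowski–Lai (KL) criterion on the
   within-cluster dispersion curve $W(k)$ over $k = 2\dots12$.
4. **Condition comparison** uses the global map dissimilarity
   $GD_{u,v} = \sqrt{\tfrac1N \sum_i (u_i/GFP_u - v_i/GFP_v)^2}$
   inside a paired-permutation TANOVA.
5. **Backfitting** assigns every GFP peak to its best-correlated (absolute
   value) global template, extends labels to all samples by the nearest-peak
   midpoint rule, and summarizes the resulting segment sequence as mean
   duration (ms), occurrence (1/s), coverage (%) and directional
   predominance between template pairs (percentage points).
6. **Group statistics** use the aligned rank transform (ART) factorial
   ANOVA with ART-C contrasts, the nonparametric repeated-measures workhorse
   for Condition × Template (× Side) designs, with Bonferroni-corrected
   post-hoc tests and Pearson chi-square for clinical contingency tables.

All analysis operates on average-referenced data; re-referencing is applied
on load. This is not cosmetic: with a zero-mean field the algebraic identity
$GD^2 = 2(1 - r)$ between dissimilarity and spatial correlation $r$ is
exact, and GFP computed with divisor $N$ makes the identity hold to machine
precision. The test suite asserts it at $10^{-10}$ on a thousand random map
pairs.

## Key quantities and defaults

| Parameter | Default | Unit | Why |
|---|---|---|---|
| GFP peak separation | 10 | ms | below the shortest credible microstate segment; the source studies leave it unstated |
| GFP smoothing | off | ms | eyes-closed alpha EEG has well-defined peaks |
| band-pass | 1–40 | Hz | conventional resting-state band; artifact cleaning is the user's job |
| k range | 2–12 | – | the conventional scan range for template counts |
| restarts | 20 (fit), 8 (scan) | – | diversified inits (maps and random partitions) plus a warm start from the k−1 solution |
| scan subsample | 8000 | maps | model selection on a seeded subsample; the final fit uses all peak maps |
| TANOVA permutations | 999 | – | add-one p estimator, so p ≥ 1/1000 |
| minimum-duration smoothing | off | ms | no segment rejection unless requested |

Explained variance is GFP-weighted,
$EV = \sum_i (GFP_i\,|r_i|)^2 / \sum_i GFP_i^2$, and the dispersion used for
model selection is its complement $W(k) = \sum_i (1 - r_i^2)\,GFP_i^2$ — an
orientation-invariant residual that is non-increasing in $k$ and equals the
residual sum of squares divided by the electrode count.

## The KL rule

$DIFF(k) = (k-1)^{2/p}W(k-1) - k^{2/p}W(k)$ with $p = 19$ electrodes, and
$KL(k) = |DIFF(k)|/|DIFF(k+1)|$. Practitioners describe the optimum as "the
second KL maximum" because the raw curve carries a trivial maximum at its
small-k boundary. We make that cleaning explicit instead of positional:
boundary values of the curve are never peaks, and any $k$ with
$DIFF(k) \le 0$ is discarded — past the elbow the penalized dispersion no
longer improves, and ratios of those near-zero differences produce
arbitrarily large spurious KL values (on simulated four-template EEG the
uncleaned "second-largest maximum" reading lands on k between 7 and 10
essentially always, which no practitioner would accept). The chosen $k$ is
the largest remaining interior local maximum; if the curve has none (e.g.
exactly geometric $W$), the global maximum over improving $k$ is used and
the result is flagged. On simulated 10-minute recordings with four planted
templates this rule selects $k=4$ in 20/20 seeded runs (the acceptance
script recomputes this rate).

## What the generator emulates

`simulate_microstates()` plants ground truth for every downstream stage:

* a semi-Markov label sequence: geometric run lengths matched to the
  configured per-template mean duration (default 70 ms, the middle of the
  40–100 ms band), next template drawn from a zero-diagonal row-stochastic
  transition matrix (uniform by default; asymmetric matrices plant known
  directional predominance);
* polarity indifference: each run's sign is flipped with probability 1/2;
* a rectified-sinusoid GFP profile restarting at each run, 10 Hz and 10 µV
  by default — the alpha-dominant eyes-closed regime. Runs shorter than one
  half-period get a single rescaled arch so that every run carries one
  well-defined GFP peak; without this, sub-25 ms runs are invisible to the
  peak finder, neighbouring segments merge, and recovered durations inflate
  by ~15% — an artifact of the amplitude model, not of the estimator being
  validated;
* spatially white electrode noise, average-referenced, with SD
  `noise_sigma` relative to the unit-norm template at peak amplitude (0.3
  by default, i.e. per-channel SNR ≈ 3 at GFP peaks).

It does **not** emulate volume-conducted 1/f background, ocular or muscle
artifacts, alpha reactivity, or electrode drift. Passing recovery tests on
this generator therefore demonstrates the correctness of the estimators
under the microstate model's own assumptions, not robustness to real-world
contamination — cleaning remains the user's responsibility.

`simulate_cohort()` wraps the generator into a paired pre/post design with
log-normal between-subject duration jitter and an optional fractional
reduction of templates B and D in the post condition, the synthetic
analogue of a treatment that destabilizes specific microstates.

## Statistical design

The ART ANOVA fits a single residual error stratum on the aligned ranks, so
with a complete factorial on $n$ observations the denominator df is $n$
minus the number of cells: the 27-subject, 2-condition, 4-template design
gives $F(1, 208)$ for Condition, adding Side gives 200, and the 6-pair
directional-predominance design gives 312 and 300. Covariates (clinical
outcome, structural aetiology) enter as additional crossing factors, which
preserves those dfs. Alignment uses cell/marginal means
(inclusion–exclusion over the factor subsets); ties get midranks.

Because the error stratum ignores subjects, the test is exactly calibrated
under exchangeable errors and conservative when a subject random effect
dominates — a property of the published design itself, which we verify
rather than repair: type-I error for Condition over 500 exchangeable-null
replicates lands in the nominal band, and power to detect a 20% duration
reduction of templates B and D under 10% noise exceeds 90% at the same
design size. The single-factor ART reduces exactly to an ANOVA on ranks,
and only in that case is the F statistic invariant to monotone response
transforms — multifactor alignment happens on the raw scale.

The TANOVA statistic is the GD between condition mean maps after
sign-aligning every subject map to a reference (templates are
sign-arbitrary; without alignment, arbitrary flips dominate the mean), with
subject-wise condition swaps as the permutation group and the add-one
p-value estimator.

## Numerical choices

* Clustering convergence: assignment stability or relative EV change below
  `tol` (default 1e-6); empty clusters are re-seeded at the worst-fitted
  map; exact |corr| ties go to the lower template index and are counted.
* Restarts alternate between map-sampled centers and principal directions
  of random partitions; on small instances this reaches the enumeration
  optimum (the acceptance battery checks 50 instances of up to 8 maps
  against brute force over all bipartitions).
* GFP peak plateaus take the first sample; recording endpoints are never
  peaks.
* Degenerate inputs error early: zero-GFP maps, absorbing transition rows,
  missing design cells (reported by name), unpaired TANOVA groups.
* Problem sizes used in the validation experiments — 10-minute recordings
  at 256 Hz for recovery, 500/200 replicates for calibration/power, 20
  seeded runs for model selection, scan subsample of 5000 peaks — were
  chosen as the smallest sizes at which the Monte-Carlo error is clearly
  below the tolerance being asserted.

## Known limitations

* Backfitting is peak-interval based (winner-take-all at GFP peaks with
  midpoint interpolation); sample-wise backfitting is out of scope.
* Transition statistics are first-order; no syntax, entropy or Hurst
  analyses.
* The KL fallback on elbow-free dispersion curves is a convention; when it
  fires, inspect the quality curves (`summary()` prints them) rather than
  trusting the chosen k.
* EDF support covers the common 16-bit single-rate case, not EDF+
  annotations or per-channel rates.
* The canonical A–D labeling is a greedy match against built-in reference
  shapes; with k > 4 the extra templates are labeled E, F, … in residual
  order and carry no canonical meaning.
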