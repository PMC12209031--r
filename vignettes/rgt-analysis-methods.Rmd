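---
title: "Methods: behavioral and neural analysis of the rodent gambling task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioral and neural analysis of the rodent gambling task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgtpipe)
```

## The experimental paradigm

In the rodent gambling task (rGT) a food-restricted rat chooses on each
trial between two levers with balanced expected value: a **low-risk**
lever paying 1 pellet with probability 0.9, and a **high-risk** lever
paying 3 pellets with probability 0.3. A probe session comprises 90
trials; a trial with no press within the 15-s limit is an **omission**,
and completed trials are classified by lever and outcome into four
response classes — LR, LNo, HR, HNo (low/high risk, rewarded or not).
Orbitofrontal cortex (OFC) units are recorded extracellularly during
the session, and each lever press is an event to which spike trains
are time-locked.

`rgtpipe` implements the full analysis chain for such experiments —
behavior, event-locked electrophysiology, response clustering, and
delta-Ct expression — together with a seeded synthetic-data generator,
so that every stage has a ground truth to be tested against.

## Behavioral metrics

The **choice preference index** (CPI) of a set of trials is

$$\mathrm{CPI} = \frac{n_{\text{low}} - n_{\text{high}}}{n_{\text{low}} + n_{\text{high}}},$$

where counts are completed presses only. The printed form of this
formula is ambiguous about parenthesization; the stated range
$[-1, 1]$ forces the difference-over-completed reading implemented
here, and likewise forces omissions out of the denominator. +1 is
exclusive low-risk (risk-averse) choice, −1 exclusive high-risk
(risk-prone) choice. The per-session curve computes the CPI on each
block of 10 *consecutive* trials — omissions occupy block positions
but do not enter the ratio; a block with no completed trial has an
undefined CPI rendered as a gap (`NA`), and a trailing partial block
is kept and flagged rather than dropped (sessions are 90 trials by
design, but synthetic sessions need not be).

Curves are smoothed with a 3-point centered moving mean whose window
shrinks at the edges, preserving curve length; undefined entries stay
undefined and are excluded from their neighbours' means. Smoothing is
exposed for any numeric series (`smooth_curve()`), so it can be
applied to per-block CPI (the default used by `preference_curve()`)
or to a per-trial preference signal if preferred — both readings of a
"3-point" smoother are supported.

`detect_preference_switch()` reports the first block whose smoothed
CPI drops below zero, which localizes a mid-session shift from
risk-averse to risk-prone choice to within about one block.

## Peri-event time histograms and Z-scoring

`compute_peth()` bins spikes relative to each lever press of one
response class into half-open 50-ms bins `[t, t + 0.05)` over a window
from 5 s before to 10 s after the press (press = 0; a spike exactly at
the press falls in the first post-press bin; these conventions are
stated once and applied everywhere). The per-bin mean rate is total
count over events divided by `n_events × bin_width`, and raw counts
are retained so that count conservation can be asserted exactly.
Overlapping event windows are allowed — each event contributes
independently, as is standard for PETHs. A class with no events yields
an explicit empty marker rather than silent zeros.

The "width of 3 points" Gaussian smoother is implemented as a
normalized Gaussian kernel truncated to 3 bins with σ = 1 bin — width
is the only stated parameter, so σ is a configurable choice; kernel
weights sum to 1 (a constant PETH is a fixed point) and edges are
renormalized over the available bins.

Z-scoring standardizes each bin as $Z = (x - m)/SD$ with $m$ and $SD$
the mean and sample standard deviation of the *baseline* bins — the
5-s pre-press window of the same PETH, per unit and per response class.
Whether baselines should pool across classes is not dictated by the
analysis definition; per-class baselines were chosen because the
activity-ratio standardization that feeds the clustering uses the same
per-class 5-s window, and pooling is exposed through the `baseline`
argument. A baseline with zero variance flags the unit
`degenerate_baseline` and removes it from Z-based summaries instead of
fabricating zero Z-scores for silent units.

## Clustering of response profiles

Each unit's feature vector is its **activity ratio** per response
class: mean rate 5 s after the press divided by mean rate 5 s before
it, from raw (unsmoothed) PETHs. Ratios are undefined for silent
baselines (excluded, reason `zero_baseline`); a unit lacking trials of
some class is excluded with reason `missing_class` rather than imputed
— imputation would fabricate a response profile, and scarce low-risk
non-rewarded trials are a real feature of sessions dominated by the
low-risk lever. Units with session-wide firing below 0.5 Hz are
excluded first (kept if exactly at the threshold: "below" excludes
strictly-below). The same workflow has also been described with a
1-Hz cutoff; `min_rate_hz` exposes both, and the default follows the
0.5-Hz convention.

Agglomeration is average linkage on Euclidean distances, implemented
via the Lance–Williams update with a deterministic tie-break (lowest
pair of cluster positions, which coincides with the lowest minimum
member index), so dendrograms are identical across platforms. Average
linkage is reducible, hence merge heights are non-decreasing; the code
asserts this and warns if floating-point noise ever violates it. The
merge tree converts to a standard `hclust` object for plotting.

The **cut rule** formalizes "largest increase in distance below a
linkage threshold of 3": among successive merge distances strictly
below the threshold, find the largest gap between consecutive merges
and cut immediately below the merge that opens it (earliest gap wins
ties). Two degenerate regimes are defined explicitly: if no merge is
below the threshold every unit stays a singleton, and if all
sub-threshold gaps are (numerically) zero — e.g. all pairwise
distances equal — there is no informative gap and every sub-threshold
merge is applied, leaving one cluster. The threshold is interpreted as
an absolute linkage distance (not a link count); on the natural scale
of activity ratios near 1, profiles differing by a planted gain of 3
in one class sit at pairwise distance ≈ 2.8, below the threshold, so
the gap rule — not the threshold itself — separates planted clusters.

Per-cluster response magnitude is the mean over member units of each
unit's mean Z in the 5-s post-press window, per class. The
**flexibility score** quantifies, per cluster, how many of the four
response classes it encodes: the count of classes with |mean Z| ≥
1.96 (the two-sided 5% normal bound, configurable). This turns the
qualitative notion of clusters "encoding multiple responses" into a
number in 0–4 that simulations can verify.

## Delta-Ct expression

Relative expression uses the delta-Ct method with a housekeeping gene
(GAPDH by convention): replicate Ct values (triplicates by default)
are averaged per sample and gene, $\Delta C_t = C_t^{target} -
C_t^{housekeeping}$, and relative expression is $2^{-\Delta C_t}$ —
1 when both genes amplify at the same cycle, halved per extra target
cycle, invariant to any global Ct shift. ΔCt (not ΔΔCt) is
deliberate: group-level fold changes are reported descriptively, and
group comparisons delegate to the two-sided Mann–Whitney rank-sum
test (`stats::wilcox.test`). Replicate aggregation is the arithmetic
mean with no outlier handling by default, since none is part of the
protocol being modeled.

## The synthetic-data generator

The generator exists to emulate the *structure* of the study's data,
and its defaults are the study conditions: 90-trial sessions under
the 0.9/1-pellet vs 0.3/3-pellet contingency, 15-s trial limit, 10-s
inter-trial interval, triplicate Ct tables. Where the emulated design
prints no value, defaults were chosen once on field-realism grounds:
press latencies truncated-normal with mean 2 s and SD 1 s on (0, 15]
(latencies cannot exceed the trial limit), omission probability 0.05
(observed omission rates are low), baseline firing 8 Hz for planted
units (mid-range for cortical units and safely above both exclusion
thresholds), and a 5-s post-press modulation window mirroring the
analysis window. The behavioral agent decides omission first, then
lever (matching the task definition in which an omission is the
absence of any press), supports a linear drift and a two-regime
switch in its low-risk preference, and is calibrated only to
aggregate preference levels since per-trial reward draws of the
original sessions are not available.

Spike trains are inhomogeneous Poisson with piecewise-constant
intensity — baseline everywhere, baseline × gain in the 5-s
post-event window of the event's class; overlapping windows resolve
in favour of the later event with a warning. All randomness flows
through one explicitly seeded generator (`withr::with_seed`), with no
global state: identical configurations are bit-identical, which the
pipeline verifies by hashing its own outputs.

What the generator does **not** emulate — and what passing tests
therefore cannot show about real data: no bursting, refractoriness or
non-Poisson spike statistics; no slow drift in excitability or
electrode stability; no within-session learning beyond the planted
preference dynamics; no correlated noise across units (planted
clusters are spherical in feature space); no amplification-efficiency
differences between qPCR primers. Recovery results on planted
structure are upper bounds on what identically parameterized real
populations would give.

## Numerical choices and degenerate inputs

* Bins are half-open `[t, t + Δ)`; windows must be integer multiples
  of the bin width (checked to 1e−9).
* Sample (n−1) SD throughout, so a Z-scored baseline has exactly mean
  0 and SD 1.
* CPI of a block with no completed trials, latency summaries of
  all-omission sessions, and cluster/class cells with no Z-valid unit
  are `NA` markers, never errors and never zeros.
* Clustering refuses fewer than 2 complete units; exclusions always
  carry machine-readable reasons (`low_firing`, `zero_baseline`,
  `missing_class`).
* Equal-distance merges are broken toward the lowest pair indices;
  sub-threshold gap ties are broken toward the earliest merge; both
  policies are documented above and fixed, not configurable chance.

## Period comparison

Control and pain (or any two) periods are clustered independently, so
their clusters carry no intrinsic correspondence.
`compare_periods()` matches each second-period cluster to the
first-period cluster with the nearest mean-Z profile (Euclidean),
which is an artifact convention — flagged with a warning when cluster
counts differ — and then reports per-cluster, per-class ΔZ. When
clusters are well separated this recovers the identity matching; when
they are not, matched pairs should be inspected before interpreting
deltas.

## Problem sizes used in validation

The packaged tests and the acceptance script validate on: 90-trial
sessions (10,000 trials for binomial calibration of the agent);
homogeneous 10-Hz units with 500 events for PETH calibration (every
50-ms bin within 3 SE of truth); brute-force oracle equivalence for
all merge trees up to 7 units across 100 random matrices; planted
2- and 4-cluster populations of 20 units per cluster on a balanced
20-events-per-class scaffold, recovered at adjusted Rand index ≥ 0.9
over repeated seeds; and flexibility recovery for planted k-class
responders, k = 1..4. These sizes were chosen as the smallest at
which the sampling error of each check is comfortably below its
acceptance margin.

## Known limitations

* Only average linkage is implemented; the cut rule is defined on its
  non-decreasing merge heights and would need a guard under
  non-reducible linkages.
* The flexibility threshold 1.96 treats per-class mean Z as
  approximately standard normal under no modulation; with very few
  events per class the bin-level noise is Poisson-skewed and the
  score becomes conservative.
* The profile-based period matching can mis-pair clusters whose
  response profiles change drastically between periods; deltas are
  only as meaningful as the matching.
* The agent is memoryless (no reinforcement learning); it reproduces
  preference levels and shifts, not trial-by-trial choice dynamics.
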