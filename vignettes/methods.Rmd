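---
title: "Models and methods: expressivity, social networks and the synthetic study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(maqsoc)
```

This vignette is the package's account of its science: the measures it
computes, the assumptions behind them, the choices made where the design
was genuinely open, and what the synthetic-data generator does and does
not emulate. Nothing here states an empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

## The observational design being modelled

The setting is a colony of single-male rhesus macaque groups housed in
identical two-room enclosures (a 3.5 × 8 m main room plus a smaller
annex; 6 m is the greatest distance at which two animals can be seen
apart). Data streams per group:

* **Focal follows** of up to 10 min per adult with grooming bouts
  recorded continuously, about 3.4 h per individual.
* **Proximity scans** every 2 min within a follow: estimated 2-D
  coordinates and room for every group member (~100 scans received per
  individual).
* **Ad libitum agonistic records**: winner, loser, and whether the event
  was contact aggression, non-contact aggression or a displacement.
* **Close-up video of the male only** (~2 h raw), coded with MaqFACS: 17
  action units with onset and offset, behavioural context, out-of-sight
  (`AUX`) and feeding (`AD50a`) markers, and `AU43` (eyes closed).

Only adults enter the social analysis; each group has exactly one adult
male, who is the expressivity subject.

## Dyadic sociality

Mean dyadic distance uses the scans conducted on either member of the
dyad; cross-room pairs contribute the 6 m maximum, and same-room
Euclidean distances are capped at 6 m as well — the cap is a visibility
constraint of the enclosure, not a property of the room geometry, so it
is global (and it keeps the reversal `6 − distance` non-negative even
though the room diagonal exceeds 6 m). Scans by a third individual that
happen to show both members are not counted: the stated denominator is
"scans conducted on A + B", and mixing in third-party scans would change
numerator and denominator asymmetrically.

Grooming is symmetrized (given + received pooled) because the index is
defined on unordered dyads; if the same bout is logged from both
partners' follows it is summed — the definition is "total summed time",
and deduplicating would require bout identity information the format does
not carry.

The DSI divides each measure by its across-dyad mean and averages the
two, so the group mean DSI is exactly 1: values are relative to the
average dyad *of that group*. A measure that is identically zero across
dyads (no grooming observed at all) cannot be mean-normalized; it is
dropped with a warning and the divisor reduced, which reduces the index
to the remaining measure rather than poisoning it with 0/0.

## Network metrics

All graph computations use `igraph`, with DSI edge weights treated as
affinities. Two decisions deserve flagging:

* **Betweenness on affinity weights.** Shortest-path betweenness needs
  distances; affinities are not distances. We use `1/weight` as edge
  length, the standard conversion, but note that an analysis that passed
  raw affinities as "weights" to a shortest-path routine would get
  different (and hard-to-interpret) values. This is the single most
  likely source of divergence from any reference analysis of the same
  data.
* **Centralization.** We compute eigenvector centralization as
  `sum(max(c) − c)` normalized by the same sum on the equally-sized star
  graph — the most centralized topology — giving 1 for a star and 0 for
  any regular graph. igraph's own `centr_eigen(normalized = TRUE)`
  normalizes by `n − 1` instead and gives ≈0.69 for a star; we prefer the
  star-normalized scale because its endpoints are interpretable and
  comparable across group sizes. Degree centralization is a plausible
  alternative reading of the construct; the eigenvector version matches
  the rest of the centrality analysis.

Walktrap community detection runs with the conventional 4-step walks;
modularity is weighted Newman Q. On disconnected input, eigenvector
scores are computed per component and max-normalized globally (with a
warning); centralization refuses disconnected graphs outright.

## Dominance

Ratings are classical sequential Elo (start 1000, k = 100, logistic
scale 400), a deterministic substitute for Bayesian Elo-based steepness
estimators: it shares the core quantity (expected winning probability as
a logistic function of the rating gap) but has no posterior uncertainty
and is sensitive to event order. Summed winning probabilities are exact
functions of the final ratings and satisfy Σᵢ SWPᵢ = n(n−1)/2
identically; steepness regresses sorted SWP/(n−1) on normalized rank so
its scale is [0, 1] regardless of group size. Displacements count as
wins — they are part of the agonistic ethogram. Group size n in the SWP
and aggression normalizations counts adults only, consistent with the
scope of the social analysis.

## Expressivity

The ledger is pure interval arithmetic per subject × context:

* true observation time t = context footage − `AUX` overlap;
* events are assigned to the context active at their **onset** (context
  changes mid-event do not split events — the simplest defensible rule);
* event durations are truncated at `AUX` boundaries; events entirely out
  of sight are dropped;
* `AU43` never counts; during `AD50a` intervals, events whose code is in
  the mastication mask (default `AU25`, `AU26` — configurable, since the
  source convention is only exemplified, not enumerated) are dropped
  while other AUs count as normal.

AU duration is the literal *sum* of AU durations over t, so overlapping
AUs can push it past 100%; a union-of-intervals variant bounded by 100%
is available (`duration_method = "union"`). Diversity uses natural-log
Shannon entropy exponentiated to effective numbers; any log base works if
the exponentiation matches, and effective numbers are the interpretable
scale (1 = one AU used, 17 = all used evenly). Contexts with zero events
have undefined entropy and are skipped in the diversity average (they
still contribute rate 0 and duration 0 if observed); treating them as
D = 0 would conflate "no facial behaviour" with "maximally uneven
behaviour". Final scores are unweighted means across contexts so that
unequal context exposure cannot masquerade as expressivity differences.
AU proportions are pooled across contexts rather than context-averaged:
the proportion is defined directly on overall AU frequency, without the
per-context machinery the other three measures specify.

## The GLM/LRT surface

Gaussian GLM with one predictor ≡ OLS; the likelihood-ratio statistic
with maximum-likelihood variance has the closed form χ² =
n·ln(RSS₀/RSS₁) = −n·ln(1−R²), tested against χ²(1). AICc uses k = 3
(intercept, slope, variance), consistent with the likelihood in the LRT.
The asymptotic χ² reference is anticonservative at small n: by the exact
F mapping, the nominal 5% test has true size ≈9.5% at n = 9 and ≈5.4% at
n = 50. The calibration suite therefore checks the type-I rate at the
50-group setting, where the asymptotics are serviceable; at nine groups
per study the p-values should be read as descriptive. No multiplicity
adjustment is applied across the 33-cell grid — the analysis is
exploratory, and the report says so prominently.

k-means on AU proportions treats each AU as a point in male-space
(its proportion in every male's repertoire), k-means++-style multi-restart
(50 restarts, fixed seed 42) over k = 2–17, mean silhouette width with
Euclidean distance, ties broken toward the smaller k. k equal to the
number of AUs (every AU a singleton) is assigned silhouette 0 by the
usual convention rather than fitted. Cluster membership then aggregates
proportions by summation, which conserves each male's total mass of 1.

## The synthetic study generator

`sim_params()` defaults *are* the study conditions: nine groups sized
(9, 8, 8, 7, 7, 7, 7, 7, 6) — 66 adults, mean 7.33, range 6–9 — ~22
follows per individual (~3.4 h, five scans per full follow, ~100 scans),
120 ± 15 min of footage per male with ~27% out of sight (≈87 min true
observation), an AU emission rate centred on 0.2155 events/s (≈1130
events per male), exponential AU durations (mean 1.5 s), six behavioural
contexts with male-specific Dirichlet exposure imbalance (so the
per-context weighting is genuinely exercised), a ~12% feeding-time
fraction, occasional `AU43`, and ~4 agonistic events per observation
hour under a despotic (logistic scale 2) hierarchy.

Each male's AU usage is a categorical draw from a symmetric Dirichlet
whose log-concentration (standardized: the latent z) is the **diversity
latent**; his emission rate has an independent log-normal latent. The
coupling β routes z into the social layer through four channels: group
spatial dispersion σ ∝ e^(−0.4βz) (cohesion), the male's own dispersion
around the attractor ∝ e^(−0.8βz) (his spatial centrality), his grooming
participation ∝ e^(βz), and the evenness of dyadic affinities (Gamma
shape ∝ e^(0.5βz), flattening centralization). β = 0 severs expressivity
from sociality exactly — the calibration null. The default β = 0.5 is a
moderate positive coupling; β = 1.5 is the "strong coupling" profile used
by the power check, chosen so the latent chain yields a realized
diversity–centrality correlation around 0.4 at 50 groups.

What the generator does *not* emulate: kinship/matriline structure,
temporal autocorrelation of behaviour, directed grooming asymmetries,
behaviourally structured interaction sequences, juveniles, and any
distributional realism of within-context AU composition beyond the
Dirichlet-categorical convenience. Passing tests therefore demonstrate
that the *pipeline* measures what it claims under a known generative
model — not that real macaque data satisfy that model.

## Problem sizes and numerical choices

Monte-Carlo checks run at sizes chosen to keep the whole suite fast on a
single CPU while leaving their estimates far more precise than the bands
they check: 400 replicates for the null calibration of the grid
(pooled-rate SE ≈ 0.3 percentage points against a ±2-point band) and 250
replicates for the power check (SE ≈ 2 points against a ≥80% bound), both
at 50 groups with a reduced observation-effort profile (4 follows per
individual, 10–12 min of footage per male) — effort scales measurement
noise but not the null distribution of the test. Smaller property loops
(oracle comparisons on ≤6-node graphs, ledger sweeps, Elo conservation)
use 20–200 seeded cases each.

Numerical tie-breaks and degenerate inputs: constant predictors yield
χ² = 0 with a warning; perfect fits are flagged with χ² = ∞ rather than a
spurious finite value; identical AU profiles make clustering refuse;
zero-weight networks refuse centrality; dyads never co-observed are
errors unless missingness is explicitly allowed. Interval arithmetic uses
half-open intervals with 1e−9 slack; the DSI mean-of-1 identity is exact
to 1e−12 and tested at that tolerance.
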