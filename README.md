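# maqsoc

Facial expressivity of dominant male macaques and the social structure of
their groups: an analysis pipeline in R.

## The problem

In single-male groups of rhesus macaques (*Macaca mulatta*), the adult
male's behaviour shapes the whole group's social organisation. This
package implements a quantitative pipeline asking whether a male's
**facial expressivity** — how much, how long and how diversely he moves
his face, measured from MaqFACS-coded action units (AUs) — predicts his
own position in the group's affiliation network and group-level cohesion.
It is aimed at behavioural ecologists working with focal-follow, scan and
ad libitum observation data plus FACS-coded video.

The pipeline has five stages, each exposed as package functions and driven
by the numbered scripts under `analysis/`:

1. **Sociality** — dyadic matrices from observations. Proximity for dyad
   AB is the summed inter-individual distance over all scans conducted on
   A or B divided by the number of those scans (individuals in different
   rooms count the 6 m maximum visible distance). Grooming for AB is the
   summed grooming time over both individuals' follows divided by their
   summed focal time. These combine into the **Dyadic Sociality Index**

   DSI_ab = (1/d) Σᵢ f_i,ab / f̄ᵢ,  d = 2,

   where each measure f (grooming, reversed proximity `6 − distance`) is
   divided by its mean across dyads, so the average dyad scores exactly 1.
2. **Networks** — from the weighted DSI graph: eigenvector and
   betweenness centrality of the male, nodal and network strength (from
   the raw, non-standardized matrices), walktrap community detection with
   Newman modularity Q, and eigenvector centralization normalized by the
   star-graph maximum so groups of different size are comparable
   (star = 1, complete graph = 0). All graph machinery is `igraph`.
3. **Dominance** — sequential Elo ratings over the time-ordered agonistic
   record; each male's **summed winning probability** SWPᵢ = Σⱼ 1/(1 +
   10^((Rⱼ−Rᵢ)/400)) normalized by group size, hierarchy **steepness**
   (absolute OLS slope of sorted SWP/(n−1) against normalized rank, 1 =
   despotic, 0 = egalitarian) and the aggression rate per observation
   hour per individual.
4. **Expressivity** — per-context measures from AU event streams with
   true observation time (footage minus out-of-sight `AUX` time), `AU43`
   (eyes closed) excluded and mastication-related codes dropped during
   feeding (`AD50a`) intervals: AU rate f/t, AU duration 100·d/t, AU
   diversity D = exp(H) with H the Shannon entropy of AU usage (the
   "effective number" of action units), and per-AU proportions. Final
   scores average the per-context values so every context carries equal
   weight; a robustness variant excludes contexts under 60 s.
5. **Inference** — single-predictor Gaussian GLMs against intercept-only
   nulls compared by likelihood-ratio test (χ² = n·ln(RSS₀/RSS₁), df = 1)
   over the 3 expressivity × 11 social-attribute grid; per-AU exploratory
   models of eigenvector centrality ranked by AICc (k = 3, small-sample
   correction); and k-means clustering of AU proportions in male-space
   with silhouette-scanned k ∈ 2–17, followed by cluster-level models.
   P-values are deliberately unadjusted (exploratory analysis).

A **synthetic-data generator** (`simulate_study()`) produces complete
observation sets with the study's structure — nine single-male groups, 66
adults, ~3.4 h focal follows and ~100 scans per individual, ~2 h of video
per male yielding ~87 min of true observation and ~1130 AU events — with
a tunable coupling `beta` between male expressivity and group cohesion,
so calibration (type-I error at `beta = 0`) and power (detection under
strong coupling) are testable end to end.

## Worked example

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_sociality_networks.R
Rscript analysis/03_dominance.R
Rscript analysis/04_expressivity.R
Rscript analysis/05_models.R
```

Output of a full run (seed 42):

```
groups: 9 | adults: 66 (mean 7.33/group)
focal hours/individual: 3.68 | AU events/male: 1074
DSI dyad mean per group: 1 1 1 1 1 1 1 1 1 (identically 1 by construction)
male eigenvector centrality: 0.73-1.00 | centralization: 0.16-0.39
steepness: 0.60-0.81 | male normalized SWP: 0.38-0.80
true observation: 84.5 min/male on average
AU rate 0.116-0.316 /s | AU diversity 6.6-12.9 effective AUs
robustness (exclude <60s contexts): r = 1.00, 1.00, 1.00
model grid: 33 tests, 2 with p < 0.05 (no adjustment)
silhouette-optimal k = 6
```

Reading this: every group's DSI normalizes correctly; the nine males span
a realistic range of expressivity (0.12–0.32 facial movements per second,
6.6–12.9 effective AUs out of 17); excluding thin contexts leaves the
scores essentially unchanged (r = 1.00); and at the default moderate
coupling a 9-group study yields only scattered significant cells in the
33-test grid — a reminder of how little power nine males give, which is
exactly what the calibration suite quantifies at larger group counts.

Equivalent calls in R: `run_pipeline("out", seed = 42)` runs all stages
and writes a manifest with file digests for bit-for-bit reproducibility.

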