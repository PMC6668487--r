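---
title: "Structural connectome group analysis: models, choices and limitations"
author: "psdnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural connectome group analysis: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psdnet)
```

## The analysis

psdnet reimplements, as tested library code, the standard graph-theoretical
pipeline used to compare structural brain networks between a depressed
(PSD) and a non-depressed (PSND) post-stroke cohort and to relate network
topology to depression severity (17-item HAMD). The pipeline starts where
tractography ends: a 90×90 symmetric matrix of streamline (fiber) counts
per subject on an AAL-style parcellation (45 regions per hemisphere,
cerebellum excluded). Everything upstream — image acquisition, tensor
fitting, tracking, registration — is out of scope.

Per subject the chain is:

1. **Threshold** raw fiber counts at a minimum of `wMin = 10` fibers
   (boundary kept: an edge with exactly 10 fibers survives, since 10 is a
   *minimum*). Thresholding acts on raw counts, before any normalization,
   because a fiber-count cutoff is only meaningful on counts. Robustness is
   assessed by re-running the analysis over thresholds 5..15
   (`thresholdSweep()`).
2. **Orient** hemispheres so "ipsilesional" is a consistent set of matrix
   indices: subjects with right-sided lesions have each homotopic
   left/right region pair swapped (rows and columns). The flip is a pure
   permutation, so the multiset of all metric values is unchanged; global
   metrics are orientation-invariant. Subjects with unknown lesion side
   cannot enter lateralized analyses and are left unflipped.
3. **Normalize** the matrix to its largest entry (maximum weight exactly
   1), reducing between-subject differences in overall connectivity
   strength.
4. **Measure.** With weights $w_{ij} \in [0,1]$ and edge lengths
   $1/w_{ij}$:
   - Onnela weighted clustering
     $C_i = \frac{1}{k_i(k_i-1)} \sum_{j,h} (w_{ij} w_{ih} w_{jh})^{1/3}$,
     0 when the binary degree $k_i < 2$;
   - characteristic path length $L$: mean shortest-path distance over
     ordered pairs, finite entries only (the count of excluded infinite
     pairs is reported);
   - global efficiency
     $E_{glob} = \frac{1}{n(n-1)}\sum_{i \ne j} 1/d_{ij}$ with
     $1/\infty = 0$, so disconnection needs no special casing;
   - nodal efficiency $E_{nodal}(i) = \frac{1}{n-1}\sum_{j\ne i} 1/d_{ij}$
     (its mean is exactly $E_{glob}$, asserted to $10^{-12}$ in tests);
   - local efficiency $E_{loc}(i)$: global efficiency of the subnetwork
     induced by $i$'s neighbors, weights retained;
   - binary degree, strength, and Brandes betweenness on $1/w$ lengths
     with fractional credit for tied geodesics.

   The source publications for this kind of analysis name these measures
   but do not print formulas; they cite the Brain Connectivity Toolbox, so
   psdnet adopts that toolbox's standard weighted definitions (Onnela
   clustering, inverse-weight distances, neighbor-subgraph local
   efficiency). Betweenness is weighted by default with a `binary` switch,
   since published work often leaves the choice unstated.
5. **Small-world normalization.** Each network's $C$ and $L$ are divided
   by their means over 100 degree-preserving random surrogates:
   $\gamma = C/\bar C_{rand}$, $\lambda = L/\bar L_{rand}$,
   $\sigma = \gamma/\lambda$. Surrogates are built by weighted double-edge
   swaps (10 successful swaps per edge, bounded attempts): topology is
   randomized while the node count, edge count, per-node binary degree and
   the multiset of edge weights are preserved exactly; each weight travels
   with its moved edge. The verdict "small-world" requires $\gamma > 1$,
   $|\lambda - 1| \le 0.25$ and $\sigma > 1$. The $\lambda$ tolerance is
   deliberately wide enough that the $\lambda \approx 1.2$ typical of
   structural brain networks counts as "close to one"; it is configurable.

## Inference

Group comparisons residualize each metric on the covariates (age, sex,
infarct size, hypertension, diabetes, serum total cholesterol) by ordinary
least squares — the covariate-adjustment mechanism is rarely stated in
applied papers; residualization is the transparent choice and is exposed
as `adjustCovariates()`. The adjusted values then enter

- a Welch two-sample t-test (group SDs of clinical scores can differ more
  than two-fold, so a pooled-variance test would be wrong), and
- a label-permutation test: 5,000 shuffles preserving group sizes, the
  95th percentile of the null as critical value, empirical p with the +1
  correction. Because the tail is usually not fixed a priori, the default
  tests the observed direction and doubles the p-value; strict one-tailed
  testing against the 95th percentile is available via `direction=`.

Bonferroni families: the four global metrics form one family; each nodal
metric forms a 90-region family; all metric × score correlations tested
form one family. Correlations with the functional scores use Spearman
ranks; with covariates both sides are rank-transformed, residualized, and
the Pearson correlation of residuals is taken (a partial Spearman), with
the t-approximation at $n - 2 - k$ degrees of freedom.

Numerical details worth knowing: permutation tie comparisons use a
spread-relative tolerance ($10^{-9}$ of the null range) so p-values are
exactly invariant under positive affine rescaling of a metric; constant
covariate columns are absorbed into the intercept rather than raising a
collinearity error; genuinely collinear covariates are refused by name.

## The synthetic cohort generator

No subject-level data are deposited for studies of this design, so the
package ships a seeded generator whose *defaults are the study
conditions*: 31 PSD-like and 23 PSND-like subjects, 90 regions. It is
first-class, tested code — every analysis stage runs end-to-end on it with
no download.

**Base networks.** Nodes split into two hemispheres of 45 with mirrored
modules (3 per hemisphere, 15 regions each). Edges appear with probability
0.6 within a module, 0.06 between modules, 0.9 for homotopic pairs.
Fiber counts are log-normal (meanlog 3.4, sdlog 0.6) rounded to integers;
homotopic connections are drawn stronger and tighter (meanlog 5.2, sdlog
0.2), emulating the consistently heavy interhemispheric tracts. This has a
second, deliberate consequence: the maximum entry — the normalization
denominator — is a homotopic edge of low between-subject variability, so
max-normalized metrics are stable across subjects. Draws are retried
(bounded) until the network is connected at threshold 10. These networks
come out small-world without any tuning toward published values
($\gamma \approx 2.4$–$2.8$, $\lambda \approx 1.2$–$1.33$).

**Planted group effect.** PSD-like subjects get (i) long-range
(non-homotopic inter-module) weights multiplied by $1 - 0.5$, (ii) new
intra-module connections added with probability 0.5 per absent pair
(weights from the fiber-count model), and (iii) rows/columns of three
designated "lesioned" regions scaled by $1 - 0.3$ (these regions gain no
new connections). The design is a lattice-like reorganization: weakened
long-range integration lowers global efficiency, denser modules raise
clustering and local efficiency. A purely multiplicative boost of
intra-module *weights* cannot produce the latter — max-normalization
divides it straight back out — which is why the local effect is planted as
densification. Homotopic edges are exempt from the long-range reduction so
the normalization denominator stays comparable across groups. Effect
magnitudes were fixed during generator design so the planted
reorganization is as pronounced as such studies report (group p-values
near $10^{-3}$ at these sample sizes imply standardized differences around
1.5; paired calibration of these defaults gave $d \approx -1.7$ for global
and $+2.1$ for local efficiency).

**Clinical table.** HAMD is drawn per group from the published moments
(8.5 ± 1.8 and 3.7 ± 0.8), truncated/resampled to respect the diagnostic
rule (PSD ≥ 7, PSND < 7). Within the PSD-like group, HAMD is rank-coupled
to each subject's local efficiency through a Gaussian copula with
correlation 0.79 — chosen because a copula correlation $\rho$ yields a
population Spearman of $(6/\pi)\arcsin(\rho/2)$, and $\rho = 0.79$ plants
exactly the reported association strength of about 0.78. The coupling uses
the truncated-normal inverse CDF, so the monotone link survives the
diagnostic truncation. Ages, sex, lesion side, vascular covariates and the
optional functional scores are drawn per group from the published
demographic table; infarct volume uses a moment-matched log-normal
(5.6 ± 10.1 cm³ — a normal with SD > mean would mass-produce negative
volumes). All randomness derives from the master seed via fixed per-subject
derivations; an identical spec reproduces a byte-identical cohort tree.

**What the generator does not emulate.** Tractography physics, spatially
structured lesions, distance-dependent connection probability, realistic
hub architecture, missing data, or site effects. Passing tests therefore
show that the *pipeline* is correct and calibrated — that it recovers
effects of the planted kind at the study's sample sizes, with controlled
type-I error — not that the biological claims would replicate on real
cohorts.

## Problem sizes and reproducibility

The shipped test-suite and acceptance runs use: brute-force oracle checks
at $n \le 7$ nodes (exhaustive path/triple enumeration); 100 surrogates
for null-model invariants; permutation calibration with 500 replicates of
1,000 permutations; planted-effect recovery on 20 full-size cohorts
(31+23 subjects, 90 regions) at 1,000 permutations; and one full study run
at the canonical 100 surrogates and 5,000 permutations. Unit tests use a
reduced cohort (30 regions, 6+5 subjects). Every stochastic routine takes
an explicit seed, sets it locally and restores the caller's RNG state;
derived child seeds stay within R's 32-bit integer range.

## Known limitations

- Characteristic path length averages finite pairs only; on heavily
  fragmented networks it describes the largest communicating part, while
  efficiency (which handles $1/\infty = 0$ natively) is the safer metric.
  Both conventions are logged.
- The double-edge-swap sampler is best-effort on very constrained degree
  sequences (it warns and reports the achieved swap count); a triangle,
  for instance, cannot be rewired at all.
- The generator's modules are equal-sized and mirrored; real parcellations
  have heterogeneous community structure.
- "Degree" on a thresholded weighted network is the suprathreshold edge
  count; strength is reported alongside for the weighted analogue.
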