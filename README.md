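# psdnet

Graph-theoretical analysis of weighted structural brain connectomes for
two-group clinical studies, modelled on post-stroke depression (PSD vs
PSND) cohorts.

Structural connectomes arrive as 90×90 symmetric matrices of white-matter
streamline (fiber) counts on an AAL-style parcellation, one per subject.
psdnet covers everything that happens after tractography:

- **Preprocessing** — minimum fiber-count threshold (default
  $w_{ij} \ge 10$, sweepable over 5..15), ipsilesional hemisphere
  orientation via homotopic region pairing, normalization to the largest
  entry.
- **Network measures** — Onnela weighted clustering
  $C_i = \frac{1}{k_i(k_i-1)}\sum_{j,h}(w_{ij}w_{ih}w_{jh})^{1/3}$,
  characteristic path length $L$ and betweenness on inverse-weight
  distances, global efficiency
  $E_{glob} = \frac{1}{n(n-1)}\sum_{i\ne j} 1/d_{ij}$, nodal and local
  efficiency, degree and strength.
- **Small-world normalization** — $\gamma = C/\bar C_{rand}$,
  $\lambda = L/\bar L_{rand}$, $\sigma = \gamma/\lambda$ against 100
  degree-preserving random surrogates built by weighted double-edge swaps
  (edge count, per-node degree and the weight multiset preserved exactly).
- **Group inference** — covariate residualization (age, sex, infarct
  size, vascular risk factors), Welch t-tests, 5,000-shuffle permutation
  tests with the 95th-percentile critical-value rule, Bonferroni
  correction, and covariate-adjusted Spearman correlations of network
  metrics with depression severity (HAMD).
- **A seeded synthetic cohort generator** (31 + 23 subjects by default)
  producing modular small-world fiber-count networks with planted group
  effects — lower global efficiency and higher local efficiency in the
  PSD-like group, degraded "lesioned" regions — and clinical tables whose
  HAMD scores are rank-coupled to each subject's local efficiency, so the
  whole pipeline runs and validates end-to-end with no external data.

The methods vignette (`vignettes/psdnet-methods.Rmd`) documents the model
choices, the generator's design and what it does and does not emulate.

## Worked example

```r
library(psdnet)

## one synthetic subject: raw fiber counts -> processed network -> metrics
x <- generateBaseConnectome(cohortSpec(masterSeed = 7), 1)
x
#> Connectome 'base': 90 regions, 614 edges, state=raw, lesion side=unknown
#>   weight range: [6, 242] over edges

y <- preprocessConnectome(x)        # threshold 10, normalize to max
computeMetrics(y)$global
#>  subject_id clustering_C path_length_L eff_global  eff_local
#>        base   0.03784306      9.244393  0.1259412 0.07631546

smallWorldParams(y, nRandom = 100, seed = 7)
#> small-world normalization over 100 surrogates (0 excluded)
#>   gamma = 1.6746  lambda = 1.0408  sigma = 1.6089
```

γ > 1 with λ near 1 says the network is far more clustered than
degree-matched random networks while keeping comparably short paths — the
small-world regime expected of a brain network (σ > 1).

A full study replica — simulate a 31 + 23 cohort, compute all metrics,
compare groups and correlate with HAMD — is one call:

```r
st <- runStudy(spec = cohortSpec(masterSeed = 1), nRandom = 100, B = 5000,
               seed = 1, outDir = "results/study")
st   # prints per-group gamma/lambda/sigma, adjusted group differences,
     # and the significant HAMD correlations
```

Interpreting the group table: `observed_diff` is the covariate-adjusted
PSD − PSND mean difference; a negative value for `eff_global` with
`p_perm_adj < 0.05` reproduces the signature finding of reduced network
integration in depressed patients, alongside increased `eff_local`
(segregation) that correlates positively with HAMD within the PSD group.

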