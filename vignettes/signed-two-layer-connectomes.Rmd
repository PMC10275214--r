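---
title: "Signed two-layer connectome analysis: models, measures and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signed two-layer connectome analysis: models, measures and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duplexnet)
```

## The problem

Resting-state functional connectivity between brain networks is summarized,
per subject, as a square matrix of signed temporal correlations (a typical
dimension is 21 nodes, one per independent-component network). Positive
entries reflect co-activation; negative entries (anticorrelations) reflect
inhibition-like coupling and carry behaviourally relevant information that
is lost when analyses keep only positive edges or average over signs.

`duplexnet` treats the signed connectome as a *two-layer* network: a
positive layer holding the weights $w > 0$ and a negative layer holding
$|w|$ for $w < 0$ (graph measures are undefined for negative weights, so
the negative layer stores magnitudes and its provenance is flagged). Zero
entries belong to neither layer, so the positive layer minus the negative
layer reconstructs the signed matrix exactly. The package then
characterizes each layer alone, the two layers coupled replica-to-replica
(multiplex), and the two layers coupled all-to-all (multilayer), and
provides the statistics used to compare such measures between groups in a
cross-sectional aging cohort.

## Thresholding and density integration

Connection-level statistics (`Conn-Ave`, `PosConn-Ave`, `NegConn-Ave`,
`NegConn-No`) are computed on the unthresholded weighted network. All
*topological* measures are computed on proportionally thresholded graphs:
at density $d$ the top $k = \lfloor d \, n(n-1)/2 \rfloor$ edges ranked by
$|w|$ are retained with their signed weights. The floor rule keeps the
realized density at or below the target (within one edge); ties at the cut
are broken toward the lexicographically smaller node pair, which makes
thresholding deterministic across platforms and keeps the retained edge
sets nested across densities.

Because there is no consensus density, every topological measure is
computed across the default grid 6 %–33 % in 1 % steps and integrated over
density with the trapezoidal rule (AUC), giving one threshold-robust scalar
per measure per subject. Below about 6 % a 21-node network has fewer edges
than nodes and fragments; 33 % is the largest density that sparse negative
layers typically still support — `max_common_density()` validates the upper
bound against a cohort, and the per-subject pipeline refuses to sweep past
it, naming the offending subject.

## Single-layer measures

Edge lengths are inversely proportional to weights, $l_{ij} = 1/w_{ij}$
(not $-\log w$: lengths are stated as inversely proportional). With
$d_{ij}$ the shortest weighted path length (Dijkstra, via igraph),

$$\mathrm{SL\text{-}Ge}_i = \frac{1}{n-1} \sum_{j \ne i} d_{ij}^{-1},$$

with disconnected pairs contributing zero. The weighted clustering
coefficient uses the geometric mean of triangle edge weights,

$$t_i = \tfrac12 \sum_{j,h} (w_{ij} w_{jh} w_{hi})^{1/3}, \qquad
\mathrm{SL\text{-}CC}_i = \frac{2 t_i}{k_i (k_i - 1)},$$

where the degree $k_i$ counts edges regardless of weight and nodes with
$k_i \le 1$ score zero. Network values are plain means over nodes. Both
measures are homogeneous of degree one in the weights, which the tests
exploit as a property check; both are verified against brute-force
path/triangle enumeration oracles on small random graphs.

## Multiplex measures

The multiplex supra-adjacency places the two thresholded layers on the
block diagonal and couples each node only to its own replica (unit weight).
The participation coefficient measures how evenly a node's intralayer
strength $s_{i\alpha}$ (replica couplings excluded — they are structural)
splits across the $L = 2$ layers:

$$\mathrm{MP\text{-}Pt}_i = \frac{L}{L-1}
  \left(1 - \sum_\alpha \left(\frac{s_{i\alpha}}{o_i}\right)^2\right),
  \qquad o_i = \sum_\alpha s_{i\alpha},$$

ranging from 0 (one-layer concentration) to 1 (perfect balance), with
$o_i = 0$ mapped to 0. The multiplex clustering coefficient counts
triangles made of one edge in one layer and two in the other,

$$\mathrm{MP\text{-}CC}_i =
  \frac{\sum_\alpha \sum_{\beta \ne \alpha} \sum_{j \ne m}
        (w_{ij\alpha} w_{jm\beta} w_{mi\alpha})^{1/3}}
       {(M-1) \sum_\alpha k_{i\alpha}(k_{i\alpha} - 1)},$$

with ordered pairs $(j, m)$, $j, m \ne i$. The ordered-pair convention is
the one under which two stacked unit triangles score exactly 1, which the
tests assert; interpretation of multiplex clustering on correlation
networks warrants caution in general.

## Multilayer measures

The multilayer construction couples *every* cross-layer node pair with one
uniform weight

$$w_{\mathrm{inter}} = \sigma \cdot \max(w^{\max}_\alpha, w^{\max}_\beta),
  \qquad \sigma \in (0, 1],$$

a fraction of the subject's strongest absolute connection, so the coupling
is anchored to each subject's own scale. The default $\sigma$ grid is 0.05
to 1 in steps of 0.05; $\sigma = 0.2$ (efficiency) and $\sigma = 0.7$
(clustering) are tagged as the headline couplings in the summary outputs.
Since proportional thresholds are nested from the top, the thresholded
layer maximum equals the unthresholded maximum at every grid density.

For a node $i$ of layer $\alpha$, an augmented network of size $n + 1$ is
built from $i$ plus all nodes and edges of layer $\beta$, with $i$
connected to every $\beta$-node at weight $w_{\mathrm{inter}}$. The
opposite-layer efficiency is the mean inverse distance from $i$ to the $n$
opposite nodes; the opposite-layer clustering applies the weighted
clustering formula to $i$ in that augmented network
($k_i = n$, triangles formed by two interlayer wings and one $\beta$
edge, so the value scales as $w_{\mathrm{inter}}^{2/3}$). The multilayer
measures are the differences

$$\mathrm{ML\text{-}Ge}_i(\sigma) =
  \mathrm{OppL\text{-}Ge}_i(\sigma) - \mathrm{SameL\text{-}Ge}_i, \qquad
\mathrm{ML\text{-}CC}_i(\sigma) =
  \mathrm{OppL\text{-}CC}_i(\sigma) - \mathrm{SameL\text{-}CC}_i,$$

and the network values average over all $2n$ replicas, which makes the
result symmetric in the layer labels.

Two analytical facts are worth recording. First, with uniform coupling and
the $1/w$ length map, the direct interlayer edge is always a weakly
shortest path, so $\mathrm{OppL\text{-}Ge}_i(\sigma) = w_{\mathrm{inter}}$
identically; the implementation nevertheless computes it by Dijkstra on
the augmented network (the defined procedure), and the tests assert both
the identity and agreement with a path-enumeration oracle. Monotonicity of
$\mathrm{ML\text{-}Ge}$ in $\sigma$ follows. Second, the opposite-layer
*efficiency* denominator is read as the number of opposite-layer targets
$n$ (equivalently $(n+1)-1$ in the augmented network).

Degenerate inputs: when one layer has no edges, its opposite-layer terms
are set to 0 and flagged rather than left undefined, so cohort sweeps
remain total; a replica facing an empty opposite layer therefore scores
$-\mathrm{SameL}$ value. The low-level `opposite_layer_*()` operations,
which take an explicit coupling weight, still evaluate the augmented
network faithfully (an edgeless opposite layer then yields exactly
$w_{\mathrm{inter}}$ for efficiency and 0 for clustering).

## The synthetic cohort generator

Real cohorts of this kind are access-restricted, so the generator exists
as first-class, tested code that emulates the *structure* such data would
have. Per subject it draws each of the $N = n(n-1)/2$ edges independently:
negative with probability $\kappa(\mathrm{age}, \mathrm{sex})/N$, weight
$-|\mathcal N(\mu_-, s)|$, otherwise $+|\mathcal N(\mu_+, s)|$, clipped to
$[-1, 1]$. Per-edge Bernoulli signs make the negative-connection count
binomial around $\kappa$ — the variance a cohort needs for permutation
tests and for unbiased parameter-recovery checks. The three curves
($\mu_+$, $\mu_-$, $\kappa$) are quadratics in centered age, per sex — the
same basis the analysis models fit, so recovery is well-posed.

The reference spec (`aging_cohort_spec()`) uses 21 nodes, ages 47–79, 50
subjects per (age, sex) cell (3,300 subjects), noise sd 0.12, and, with
$a = \mathrm{age} - 63$:

| curve | female | male |
|---|---|---|
| $\mu_+$ | $0.30 + 0.0015a$ | same |
| $\mu_-$ | $0.25$ | same |
| $\kappa$ | $97 - 0.3125a - 0.01a^2$ | $103 - 0.6875a - 0.01a^2$ |

These values were fixed once, by design: the $\kappa$ gap (12 edges at age
47) closes linearly to zero at 79, so men have more negative connections —
hence lower average connectivity — at mid-age, and the sexes converge at
old age; mean positive/negative strengths carry no sex effect, so
`PosConn-Ave` and `NegConn-Ave` are null contrasts; $\kappa$ stays near
89–112 so both layers always support the 33 % density bound; and positive
connectivity drifts up with age while negative connections decline, the
canonical aging direction. What the generator does *not* emulate: block
structure among resting-state networks, topologically targeted negative
edges (they concentrate between specific networks in real data; placement
here is uniform), subject-level trait stability across sessions, and any
hemodynamic forward model. Passing recovery tests therefore demonstrate
that the pipeline detects the injected kind of signal at realistic sizes —
not that real connectomes behave this way. Optional projection to the
nearest correlation-structured matrix (`psd_project`, via `Matrix::nearPD`)
is off by default since no downstream measure requires positive
semidefiniteness.

## Group statistics

*Permutation tests.* The statistic is the difference of group means (a
t-like statistic would also be defensible; the mean difference is the
simpler documented choice), with two-tailed p-values under the add-one
convention $p = (1 + \#\{|T^\pi| \ge |T|\})/(n_{\mathrm{perm}} + 1)$,
which never returns zero and keeps the test valid at any permutation
count. The default is 10,000 permutations. Within each age the group
values are sorted before permuting so results do not depend on row order.
BH-FDR at $q < 0.05$ is applied per measure *across* age groups.

*Age/sex models.* Measures are first averaged within each (age, sex) cell;
the models are fit on these cell means. Age is centered before the
polynomial expansion (collinearity control; coefficients are reported on
the centered scale) and sex coded female = 0, male = 1 so coefficient
signs are reproducible. All $2^5$ subsets of {age, sex, age², age×sex,
age²×sex} are enumerated — exact minimum-AIC at trivial cost, with no
hierarchy constraint — and the best subset's $R^2$, AIC, MSE and overall
F-test are reported.

*PLS / VIP.* A NIPALS PLS1 factorization relates the 12 connectivity
measures to an outcome; the number of latent variables is chosen from
2–12 by BIC with naive degrees of freedom (LVs + 1) — the literature's
estimated-degrees-of-freedom corrections are not uniquely specified, so
the naive count is used and stated. Variable importance in projection is
$\mathrm{VIP}_j = \sqrt{p \sum_a \mathrm{SSY}_a w_{ja}^2 / \sum_a
\mathrm{SSY}_a}$ (unit-norm weight vectors), so $\overline{\mathrm{VIP}^2}
= 1$ identically and VIP > 1 flags above-average contributors. Outcomes
can be residualized on covariates (e.g., a diagnosis-to-scan interval)
before the fit. The factorization is cross-checked against an independent
PLS implementation (mixOmics) in the tests.

*Reliability and reproducibility.* `icc_test_retest()` implements
ICC(A,1) — two-way random effects, absolute agreement, single measurement
— from closed-form ANOVA mean squares with the McGraw–Wong F-based
confidence interval (reported test-retest ICCs for measures of this kind
are around 0.4–0.65). `subsample_reproducibility()` re-runs the
permutation + FDR analysis on per-cell subsamples over a grid of
fractions and reports detection proportions; at fraction 1 it reproduces
the full-cohort pattern exactly because permutation seeds are shared.

## Numerical choices and problem sizes

Symmetrization tolerance is 1e-6 (correlation matrices are symmetric by
construction; tiny asymmetries are averaged, larger ones are errors);
weights marginally past 1 (within 1e-9) are clipped with a warning.
The density grid is built from integer percentages to avoid floating-point
drift, so a constant curve integrates to exactly $0.27c$. Measure tables
are written with 15 significant digits, making write/read round trips
lossless well past the documented 1e-12.

The test suite verifies the measures against enumeration oracles on graphs
of up to 8 nodes (200 random graphs for distances, with triangle, multiplex
and augmented-network oracles alongside), monotonicity over 100 random
two-layer fixtures crossed with the full $\sigma$ grid, statistical
calibration over 500 null simulations at 1,000 permutations each, and
pattern recovery over 20 cohort seeds at 2,000 permutations per age — sizes
chosen to give stable pass/fail decisions on a single CPU. The
demonstration cohort uses the full 3,300 subjects but only the connection
measures, where the injected contrasts live; full topological sweeps
(28 densities × 20 couplings) are run on subject samples.

## Known limitations

- Strictly two layers; no more-general multilayer stacks and no
  variable-strength interlayer couplings (a documented future direction).
- Weighted metrics only; the thresholded graphs retain weights and no
  binary-metric variants are computed.
- The analytic collapse of opposite-layer efficiency to
  $w_{\mathrm{inter}}$ means ML-Ge differences between groups are driven
  by the same-layer term and the subjects' maximum weights; the measure is
  implemented as defined, but users should be aware of this structure.
- No spatial or network-block realism in the generator (see above), and
  no estimation of connectomes from time series — matrices are consumed
  as given, without Fisher transformation.
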