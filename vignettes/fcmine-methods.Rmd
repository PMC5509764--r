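---
title: "fcmine: methods, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fcmine: methods, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcmine)
```

`fcmine` analyzes within-subject (pre/post) resting-state functional
connectivity with two complementary arms — conventional nodal network
metrics (CNM) and frequent subgraph mining (FSM) — plus a permutation/FDR
inference layer and a synthetic cohort generator used to validate the whole
chain. This vignette explains the models and conventions the package
commits to, why, and what its green test suite does and does not establish.

## 1. The analysis model

### Networks

Each subject-session contributes a matrix of T timepoints × N regional
signals (AAL-90 labels by default). After discarding initial volumes
(scanner equilibration; default 10 of 212) and regressing nuisance signals
(intercept plus any supplied confound columns, e.g. the six motion
parameters), the N × N Pearson correlation matrix is computed.

Binarization is by **sparsity**, not by a correlation cut: at sparsity S
the network keeps exactly `round(S · N(N−1)/2)` edges, the pairs with the
largest |r|. This guarantees every subject has identical edge counts at a
given S, which is the point of thresholding by sparsity — group differences
then reflect topology, not overall correlation level. Conventions:

* **Ranking by |r|** (default). The binary-topology metrics ignore sign,
  and absolute-value ranking is the dominant convention in
  sparsity-thresholded connectome studies. Signed ranking
  (`rank_by = "positive"`) is available since the original choice is
  usually unstated in publications.
* **Deterministic tie-breaking** by ascending (row, column) index, so
  results are bit-reproducible and the edge set at sparsity S is always a
  subset of the edge set at S′ > S.
* The default threshold space is S ∈ {5%, 6%, …, 40%} (36 levels): below
  ~5% a 90-node graph fragments badly; above ~40% topology approaches the
  complete graph and metrics lose discrimination.

### Nodal metrics and AUC

For every threshold, three per-node metrics: degree `k_i`; betweenness
centrality `b_i = Σ_{s<t, s≠i≠t} σ_st(i)/σ_st`, normalized by
`(N−1)(N−2)/2` so it lies in [0, 1]; and nodal efficiency
`e_i = (1/(N−1)) Σ_{j≠i} 1/d_ij`, with unreachable pairs contributing 0.
The normalization of betweenness is presentation-only — the sign-flip
permutation test is invariant to a common positive scale factor. Each
(node, metric) curve over the threshold space is summarized by its
trapezoidal area under the curve (AUC), the quantity entering group
statistics; integrating over S avoids committing to one arbitrary
threshold.

Hubs are regions whose group-mean degree summary is at least one standard
deviation above the across-node mean. Two conventions are fixed here
deliberately: the degree summary is the AUC of the group-mean degree curve
(the same summary device used everywhere else), and the SD uses divisor N
(population form) because the 90 regions are the entire population of
nodes, not a sample. The boundary is inclusive (≥). Both choices are
configurable and documented because published hub rules rarely state them.

### Frequent subgraph mining

Each subject's binary network (at a single, configurable sparsity — default
0.10) becomes a transaction: an undirected graph whose vertices are labeled
with region names (one uniform edge label). The miner is a from-scratch
gSpan:

* A pattern is identified by its **minimum DFS code** — the
  lexicographically smallest depth-first traversal code under the gSpan
  edge order (backward edges before forward ones, deeper forward origins
  first, then vertex labels, compared bytewise so results cannot depend on
  the session locale). Equal minimum codes ⇔ isomorphic patterns; the test
  suite verifies this exhaustively for all labeled graphs with ≤ 4 nodes
  and verifies the code against explicit enumeration of every DFS
  traversal.
* Patterns grow by rightmost-path extension; candidates whose code is not
  the minimum code of their own graph are pruned (they are generated
  elsewhere in canonical form). Support is **transaction-level** (a pattern
  counts once per subject regardless of embeddings), matching the
  question "how many subjects share this sub-network".
* Although region labels are unique within any one transaction here, the
  miner never assumes label uniqueness; embeddings are vertex-injective,
  label-preserving subgraph isomorphisms.

Defaults the literature leaves open, fixed here as config knobs: minimum
support = ⌈0.8 · #subjects⌉ (a "frequent" sub-network should be present in
most of the group); pattern sizes 2–6 edges (single edges are tracked
separately for the appeared/disappeared connection report); mining at
S = 0.10 (dense enough to carry structure, sparse enough that patterns stay
interpretable). Pre/post comparison is set algebra on canonical keys:
appeared = post∖pre, disappeared = pre∖post, persistent = intersection,
valid only when both sessions were mined with identical parameters
(enforced).

### Inference

* **Paired sign-flip permutation test.** The design is within-subject, so
  the null distribution flips the sign of each subject's AUC difference
  (post − pre) independently; the statistic is the mean difference and the
  two-sided p uses the add-one estimator `(1 + #{|null| ≥ |obs|})/(1 + B)`
  (never zero; all-zero differences give p = 1 by convention). Default
  B = 10,000. One shared set of sign patterns is used across the 270 tests
  of a run, which preserves each test's marginal validity.
* **FDR.** Benjamini–Hochberg step-up, by default across the whole
  3 × N family at once (per-metric families of N tests are available).
  Significant / marginal labels use strict inequalities: adjusted p < 0.05
  and < 0.1, so exactly 0.05 is marginal.
* **Covariates.** Age and sex are removed by least-squares residualization.
  In the *correlation* stage both the metric change and the score change
  are residualized before computing Pearson r (with p from the exact t
  transform and effect size d = 2|r|/√(1−r²)). In the *permutation* stage
  the pipeline tests raw within-subject differences: age and sex are
  constant within subject, so they cancel in post − pre, whereas
  residualizing the differences would force the mean-difference statistic
  to zero identically. (Published descriptions of this adjustment sometimes
  state the regression with dependent and independent variables swapped;
  `fcmine` always residualizes the measure on the covariates.)
* **Behavioral helpers.** Pooled-variance two-sample t (computable directly
  from printed group summaries), classic mean-centered Levene test
  (Brown–Forsythe median centering available), and a 2 × 2 between-subjects
  Treatment × Time ANOVA with type-II sums of squares. A repeated-measures
  ANOVA would match the design more closely but is out of scope; the
  between-subjects form mirrors how such results are commonly reported.

## 2. The synthetic cohort: what it emulates, what it does not

`generate_cohort()` draws, for each treated subject, pre- and post-session
series from multivariate normal distributions sharing a **block-modular
correlation base** (default: 5 equal modules, r = 0.4 within, 0.1 between
— enough community structure to produce realistic hubs and mining targets
without external data). Defaults mirror a typical single-group intervention
design: 30 treated subjects, 90 regions, 212 volumes with 10 discarded,
plus 21 behavioral-only controls (`n_controls`) so the Treatment × Time
ANOVA has a data source.

**Effect injection.** The post-session correlation raises every
off-diagonal entry touching the chosen effect nodes by `effect_delta`
(clipped to a valid range). The incremented matrix is generally indefinite
— the increment is a high-rank perturbation — so it must be repaired. A
single eigenvalue-clipping pass systematically under-delivers the injected
effect (at delta = 0.3 on two nodes of the default base it realizes only
~0.22), so the package instead uses **over-relaxed alternating projections**
between the PSD cone and the affine set fixing the target entries and unit
diagonal (`inject_effect_correlation()`, relaxation 1.9, tolerance 1e-4,
memoized). For feasible targets — delta = 0.3 on two nodes of the default
base is feasible — this converges to a correlation matrix realizing the
increment essentially exactly, so "injected" means what it says; for
infeasible targets the attained deviation is reported in an attribute
rather than silently absorbed.

**Behavior.** Each scale's post − pre change is
`behavior_beta × (subject's realized mean empirical correlation change on
the affected edges) + N(0, behavior_noise_sd²)`; controls get pure noise.
Baselines are drawn at plausible levels (full-scale quotients ~N(120, 9–10),
subtests on the scaled-score scale ~N(10, 3)). The coupling is linear with
Gaussian noise — the minimal model that exercises the Pearson-correlation
stage.

**Motion.** Traces are slow drift plus jitter; exactly
`round(motion_exceed_fraction × n_subjects)` subjects get a post-session
trace rescaled to peak between 2.6 and 3.5 mm. Exclusion uses strictly
greater-than 2.5 mm on the maximum absolute translation in any session
("exceeded" read as strict); rotations are generated but do not enter the
rule, matching the stated criterion. Whether a baseline-only spike should
also exclude is a policy question; the rule here excludes on any session,
and per-session peaks are available to implement other policies.

**What a green test does not establish.** The generator is stationary
multivariate normal: no hemodynamics, no autocorrelation, no scanner drift,
no spatially structured noise, no motion-correlated artifacts (motion and
signal are independent by construction), and the effect is a clean additive
correlation shift. Passing the recovery tests shows the *pipeline machinery*
detects the effects it defines; it says nothing about sensitivity to
realistic fMRI confounds, and specific group-level regional findings from
any real study are not reproducible from synthetic data.

## 3. Numerical and reproducibility choices

* All randomness flows from explicit integer seeds (`cohort_config(seed=)`,
  `pipeline_config(seed=)`; the permutation seed is derived
  deterministically from the pipeline seed). Identical config + seed gives
  byte-identical cohorts and reports; reports carry a config fingerprint
  (FNV-1a hash of the serialized config) and the package version.
* Thresholding requires `k ≥ 1` retained edges and errors otherwise;
  the threshold-space constructor rejects spans that are not an integral
  number of steps (tolerance 1e-9).
* Permutation p-value comparisons use a relative 1e-12 tolerance when
  counting `|null| ≥ |obs|` so floating-point ties do not flip decisions.
* `correlation_table()` clamps |r| away from 1 by 1e-15 before the t
  transform; a genuinely perfect correlation in
  `metric_cognition_correlation()` warns and reports an infinite d.
* DFS-code label comparisons are bytewise (C locale) everywhere.

## 4. Known limitations

* gSpan is pure R; databases whose frequent-edge sets are large and
  overlapping (e.g. strong injected effects mined at permissive support)
  generate many patterns and mining cost grows with the pattern count.
  The defaults keep this tractable; `max_edges`, `support_fraction` and the
  mining sparsity are the relevant dials.
* The ANOVA helper is between-subjects; mixed-effects or repeated-measures
  models are out of scope.
* No weighted-network metrics, no Fisher z step, no global metrics
  (path length, clustering, small-worldness): the analysis is deliberately
  limited to the three nodal metrics plus FSM.
* Adjusted p-values for correlation tables depend on the FDR family, which
  published tables rarely state; the package fixes its family (all
  node-metric × scale pairs) and documents it rather than trying to match
  any particular printed table.
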