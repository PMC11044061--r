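---
title: "Morphometric similarity networks and disinhibition: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric similarity networks and disinhibition: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msnet)
```

## The scientific question

Disinhibition — socially inappropriate behaviour measured by the
Neuropsychiatric Inventory Questionnaire's dedicated item — occurs in both
behavioural variant frontotemporal dementia (bvFTD) and dementia of the
Alzheimer's type (DAT). The analysis this package implements asks whether the
symptom, across diagnoses, is associated with reduced structural integrity of
two functional subnetworks: the salience network (SN) and the cognitive
control network (CCN). Structure is summarised per subject as a
*morphometric similarity network* (MSN): a graph over cortical parcels whose
edge weights are Pearson correlations between the parcels' vectors of seven
FreeSurfer-derived grey-matter features (grey matter volume, surface area,
cortical thickness, intrinsic curvature, mean curvature, curved index,
folding index).

## The MSN construction, step by step

1. **Feature standardisation.** Each of the 7 feature columns is z-scored
   across the subject's 360 regions (`standardize_features()`). The features
   live on incommensurate scales (mm^3 to dimensionless indices); without
   standardisation the correlations would be dominated by the widest-ranging
   feature. This is the originating MSN convention; it is exposed as a switch
   (`build_msn(standardize = )`, default on).
2. **Similarity.** Pairwise Pearson correlation of the regions' 7-feature
   vectors gives a 360 × 360 symmetric matrix; self-correlations (diagonal)
   and negative correlations are removed, i.e. set to zero
   (`build_msn()`). A region whose standardized feature vector is constant
   has no defined correlation; its edges are set to 0 with a warning rather
   than aborting a large simulated run.
3. **Subnetwork extraction.** The SN (56 Cingulo-opercular + 6
   Orbito-affective parcels, 62 nodes) and CCN (23 Dorsal attention + 50
   Frontoparietal parcels, 73 nodes) are taken as induced subgraphs
   (`extract_subnetwork()`).
4. **Density thresholding.** At each density d in {0.25, 0.30, 0.35, 0.40,
   0.45} exactly `round(d * n(n-1)/2)` largest-weight edges are kept
   (round half up; ties broken by ascending node-index pair so results are
   bit-reproducible), and retained weights are divided by their maximum
   (`threshold_density()`).

Two construction orders are defensible: threshold the whole-brain matrix and
then extract subnetworks, or extract first and threshold within the
subnetwork. The package defaults to the latter so that the *analysed* network
has exactly the nominal density — the quantity the within-subject factor
sweeps — and because disconnection behaviour is reported per subnetwork.
Thresholding the whole-brain matrix first remains available by calling
`threshold_density()` before `extract_subnetwork()`.

The normalisation step is likewise under-determined in common practice; the
package divides by the maximum retained weight (the usual weighted-network
convention, making weights interpretable as fractions of the strongest edge)
and offers mean-normalisation as an option.

## Graph measures

All measures treat the network as weighted and undirected, with weights in
[0, 1] after normalisation; they are implemented from first principles and
tested against brute-force oracles (triple loops; independent Dijkstra).

* **Transitivity** (segregation): with $W^{1/3}$ the elementwise cube root
  and $k_i$ the binary degree,
  $T = \sum_i [(W^{1/3})^3]_{ii} \big/ \sum_i k_i(k_i-1)$ — the
  whole-network weighted triangle density, robust to poorly connected nodes.
* **Global efficiency** (integration):
  $E = \frac{1}{n(n-1)} \sum_{i \neq j} 1/d_{ij}$, where $d_{ij}$ is the
  shortest path length with edge length $1/w$ (strong similarity = short
  edge, the standard convention for similarity-weighted connectomes, stated
  explicitly here because it is often left implicit). Unreachable pairs
  contribute 0, so the measure degrades gracefully on disconnected graphs.
* **Characteristic path length** and the **weighted clustering coefficient**
  $c_i = [(W^{1/3})^3]_{ii} / (k_i(k_i-1))$ support the small-world
  coefficient.
* **Small-worldness** $\sigma = (C/C_{rand}) / (L/L_{rand})$, with $C$ the
  mean weighted clustering coefficient and $L$ the characteristic path
  length. The null model is degree-preserving Maslov–Sneppen edge rewiring
  retaining the empirical weight multiset (weights reassigned at random to
  the rewired edges), averaged over `n_null = 10` realisations by default.
  Neither the clustering definition nor the null model is canonical across
  toolboxes; this combination is the common weighted-toolbox recipe, and the
  choice is recorded here because reported σ values are not comparable
  across recipes. Shortest paths use dense Floyd–Warshall in compiled code:
  the analysed networks are small (62–73 nodes) and near-complete, where the
  dense algorithm beats heap-based alternatives.

## The repeated-measures ANCOVA

For each subnetwork × metric, the design is 2 (disinhibition presence) × 2
(diagnosis) × 5 (density). Density is a within-subject factor included to
show results are not threshold-specific; the scientific conclusions rest on
the between-subject effects. `rm_ancova()` tests those on the per-subject
mean across the five densities — in a balanced repeated design with
subject-constant covariates this reduction is *exact* for between-subject
effects (the between-subject sums of squares of the mixed-model decomposition
are those of the reduced model), so no sphericity machinery is needed.
Within-subject (density) means are reported descriptively.

Sums of squares are Type III with sum-to-zero contrasts for the crossed
factors, the convention matching the commercial-software defaults this kind
of clinical analysis usually reports. Covariates: age, sex, total
intracranial volume, days between MRI and symptom assessment, dementia
severity (CDR-SB), scanner make (dummy coded, Siemens reference) and
education. With all covariates and n = 186 the denominator df is 174 (13
between-subject parameters); the package reports its own df rather than
forcing agreement with any published value. Each effect gets F, df, p,
partial $\eta^2 = SS_{eff}/(SS_{eff}+SS_{err})$, and (for the two-level
factors) an adjusted contrast estimate whose sign gives the direction. No
multiple-testing correction is applied across the four models, matching the
analysis convention the package mirrors.

The demographic table (`demographics_table()`) uses a pooled two-sample t by
default, switches to Welch when an F variance-ratio screen rejects equal
variances at α = 0.05, and uses the uncorrected Pearson χ² for categorical
variables. The summary-statistic forms (`pooled_t_test()` etc.) exist so the
published group summaries themselves can be used as inputs.

## The synthetic cohort generator

Real MRI cohorts behind this kind of analysis are access-restricted, so the
package ships a generator (`sim_config()`, `simulate_cohort()`,
`simulate_morphometry()`) that makes every downstream stage runnable and
testable. Cohort defaults emulate the published two-group structure:
111 DAT / 75 bvFTD, disinhibition rates 27/111 and 62/75, severity
distribution 15/27/20 over grades 1–3 among the disinhibited, and per-group
means/SDs for age, education, CDR-SB, days-to-assessment and scanner/sex
proportions. TIV defaults to 1.45 × 10⁶ (SD 1.4 × 10⁵) mm³ — a typical
adult value, invented because no summary is published. Subject records are
drawn from per-subject RNG sub-streams, so a subject's data do not depend on
cohort size or order.

Morphometric tables follow an additive generative model chosen because it
yields tunable inter-regional Pearson correlations — exactly what MSN
construction consumes:

$$x_{r\cdot} = a_r + \lambda_r\, u_{g(r)} + \varepsilon_r$$

* $a_r$ — a fixed region archetype (SD 1), drawn once per configuration;
* $u_{g(r)}$ — a subject-specific latent 7-vector shared by all regions of
  region r's functional network, with correlation `network_coupling` (0.5)
  between the latents of networks forming one analysis subnetwork (e.g.
  Cingulo-opercular and Orbito-affective within the SN), so a subnetwork is
  not two unrelated blocks;
* $\varepsilon_r$ — independent Gaussian noise (SD 0.75);
* $\lambda_r$ — the latent loading (1 by default), multiplied by
  (1 − attenuation) in the regions of a targeted network for subjects
  matching an `effect_map` entry. The default map attenuates CCN similarity
  by 0.5 for disinhibited subjects: the ground-truth effect the
  parameter-recovery tests must find, and must *not* find in the SN.

Structural direction vectors are drawn on the sphere (fixed norm, random
direction). With only 7 features, a raw Gaussian draw's *norm* is highly
variable, and a region or network that drew a short vector would be weakly
correlated with everything, for every subject — a fixture artefact, not a
property being modelled. A global (all-region) latent is deliberately absent:
any region-constant component is removed exactly by the feature z-scoring
step, so it could never influence an MSN.

An optional smooth profile-gradient component (`archetype_coupling`, default
off) lets regions of one network trace an arc between two anchor profiles,
emulating within-network cytoarchitectonic gradients; it is off by default
because the latent-dominant configuration reproduces the analysis-relevant
behaviour (detectable, network-localised group effects) more faithfully.

A final per-feature affine map gives the exported tables FreeSurfer-like
locations and scales (thickness ≈ 2.45 mm, and so on); affine maps are
removed again by standardisation, so they affect only file realism.

### What the generator does and does not emulate

It reproduces: the two-diagnosis covariate structure, network-localised
similarity deficits of configurable size, 7-feature sampling noise (the
dominant noise source in real MSNs — correlations estimated from 7 numbers
are *very* noisy, and the generator inherits that honestly), and
density-dependent disconnection (disconnected thresholded subnetworks become
common below density 0.25 and are flagged, not fatal). It does not emulate:
spatial autocorrelation on the cortical sheet, atrophy gradients coupled to
diagnosis, scanner- or site-specific feature biases, or realistic whole-brain
(outside SN/CCN) organisation. Synthetic thresholded subnetworks disconnect
somewhat more often at density 0.25 than real cortical data appear to.
Passing parameter-recovery tests therefore shows the *pipeline* recovers the
effects the generator injects under realistic noise — not that the published
cohort results are reproduced; those depend on restricted data.

### Simulation sizes used by the test suite

Parameter recovery uses balanced 50 + 50 cohorts over 20 generator seeds;
inferential calibration uses 500 null replicates of n = 100 with the
rejection rate of each between-subject effect required to sit in 3–7% at
α = 0.05; generator-level exchangeability and monotonicity checks use 20
seeds each. These sizes give the binomial comparisons enough resolution for
their acceptance bands while keeping a complete run of the suite on one CPU
within ordinary interactive patience.

## Numerical and degenerate-input policy

* Edge-count rounding is half-up; weight ties break by ascending (i, j), so
  thresholded edge sets nest across increasing densities and runs are
  bit-identical across platforms.
* `build_msn()` output is clamped to [0, 1]; no NaN/Inf survives any public
  function.
* Disconnected thresholded networks: efficiency counts unreachable pairs as
  zero contribution; characteristic path length averages reachable pairs
  with a warning; small-worldness refuses disconnected input (the caller —
  `compute_metrics()` — records NA and flags the row instead).
* Degenerate regions (zero feature variance) get zero-weight edges and a
  warning; zero-variance feature *columns* are an error naming the column.
* All randomness flows from explicit seeds: cohort/morphometry from
  per-subject sub-streams of the master seed; small-world null ensembles
  from per-graph derived seeds. Identical configurations give byte-identical
  pipeline outputs.

## Known limitations

* The fixture atlas reproduces the published network *cardinalities* (56/6,
  23/50 of 360), not the real parcel assignments, which are not
  redistributable here; `load_atlas()` accepts a user-supplied assignment
  table in the same three-column schema.
* Between-subject inference only; threshold (within-subject) effects are
  descriptive. No mixed-effects alternative is provided.
* Small-worldness values depend on the null-model recipe; compare σ across
  studies only when the recipe matches.
* The race variable and its exact test are not implemented; r × c exact
  tests on this table are ambiguous from summary data alone.
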