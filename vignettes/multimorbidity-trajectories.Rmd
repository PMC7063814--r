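---
title: "Modelling multimorbidity patterns and disease trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling multimorbidity patterns and disease trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mmtraj` models the long-term disease progression of a hospital population.
This vignette is the package's account of the underlying statistical model,
the choices made where the design was genuinely open, and the limits of what
the synthetic test bed can show.

## The model

### Health states as cumulative binary vectors

Each patient's health state at the end of calendar year $t$ is a binary
vector $x \in \{0,1\}^D$ over $D$ diagnosis blocks (by default the 131 WHO
blocks of ICD-10 chapters A00–N99, e.g. I10–I15 *hypertensive diseases*).
Component $b$ is 1 iff any hospital stay admitted up to 31 December of $t$
carried a level-3 code mapping into block $b$. The encoding is deliberately
cumulative: inpatient data does not reliably reveal cures, so the vector
records the complete observed diagnosis history. Consequently vectors are
componentwise non-decreasing in time, which gives the downstream transition
model its one-way (acyclic) structure.

A washout window standardises the initial state: only patients with no
A00–N99 diagnosis during the washout years (default 1997–2002) enter the
cohort, and states are built for the observation years (default 2003–2014)
up to and including the year of in-hospital death.

### Monothetic divisive clustering

The observed vectors are partitioned into $K$ clusters by recursive
single-variable splits. For a cluster with members $x_1,\dots,x_n$ and
centroid $\bar x$, the inertia is $I = \sum_i \lVert x_i - \bar x\rVert^2$;
splitting on variable $v$ into the $x_v{=}0$ and $x_v{=}1$ subsets yields a
gain $I - I_0 - I_1 \ge 0$. At every step the (cluster, variable) pair with
the maximal gain is executed, until $K$ leaves exist or no positive gain
remains. Each leaf is then described by *inclusion criteria* (blocks
answered 1 on its path) and *exclusion criteria* (blocks answered 0), which
is what makes the patterns clinically readable. For binary data the inertia
reduces to counts — with per-variable totals $s_v$, $I = \sum_v
(s_v - s_v^2/n)$ — so gains for all variables come from one sparse
cross-product, and duplicate vectors are weighted by multiplicity rather
than enumerated.

Numerical choices:

* **Tie-breaking.** Gains within `1e-12` of the maximum are tied; ties go to
  the earliest-created leaf and then the lowest variable index, so fits are
  deterministic and independent of input order.
* **Labels.** Final clusters are numbered by inclusion-set size, then
  lexicographically; the leaf whose path answers are all zero — the
  "healthy cluster" holding the all-zero vector — is always cluster 0.
* **Degenerate inputs.** A cluster of identical vectors emits a no-split
  signal; requesting more clusters than achievable returns the maximal
  model with a warning and an `underfull` flag.
* **Choice of K.** `choose_k_diagnostic()` compares the inertia curve
  against null data with independently permuted columns (marginals kept,
  correlations destroyed). $K$ itself stays a configuration parameter; the
  pipeline default of 12–20 matches the synthetic registry's planted
  structure, and larger registries support larger $K$.

### The multilayer transition network

The cohort is stratified by sex $g$ and 10-year age group $a$. For source
cluster $k$ and target $j$, the yearly transition rate
$q_{g,a,k,j}$ is the fraction of the layer's at-risk patient-years in $k$
found in $j$ one year later; the layer is taken from the *source* year,
because risk statements condition on current age. Every at-risk
patient-year has exactly one outcome — a cluster, in-hospital death, or
censoring by the window end — so rates, death rate and censor rate sum to 1
(checked to `1e-9`).

**Death attribution.** Registry data records a health state in the death
year (the fatal stay exists), so the death-year row is kept as the terminal
record of the trajectory, but it is *not* an at-risk source year: the death
outcome is attributed to the preceding year. This makes the estimated
kernel unbiased — terminal rows cannot transition anywhere, and counting
them as self-loop sources would deflate every outgoing rate. Cluster
*profile* mortality intentionally uses the other convention (fraction of a
cluster's patient-years that end in in-hospital death), which matches how
annual cluster mortality is usually reported; the two notions coincide
unless the fatal stay moves the patient to a new cluster.

Because vectors only grow, a patient can never step from a cluster where a
block is an inclusion criterion to one where it is an exclusion criterion;
`acyclicity_check()` verifies the observed inter-cluster graph is a DAG and
exhibits an explicit cycle if not. Links are drawn only when robust:
rate above 0.5% (the printed default) *and* at least `min_count`
(default 100) observed transitions. Sink states are clusters with no
outgoing inter-cluster links — death and self-loops do not count.
Elderly clusters are labelled into mortality regions by bands (defaults
0.2–0.3%, 0.3–1%, 2–11%, minimum mean age 55); bands are half-open
$[\mathrm{lo}, \mathrm{hi})$ where they share a boundary, and clusters in
the printed gaps stay unlabelled.

### Trajectories, risks, comparisons

The *reduced* trajectory removes consecutive repeats from the yearly
cluster sequence; its length counts distinct successive health states.
Modal reduced trajectories of length $L$ are tallied in two modes: `exact`
(default; the full reduced trajectory has length exactly $L$) and `prefix`
(the first $L$ entries of longer trajectories count too, matching how
figure captions often count patients "stepping through" a prefix). Both
are exposed because published summaries are ambiguous between them.

Region-entry risks use a patient-year design: every year a patient spends
in the source cluster is one at-risk trial, an event is entry into the
region within the horizon (default 1 year), and patient-years with
incomplete follow-up and no event are excluded. The baseline is either all
same-stratum patient-years not already in the region, or the healthy
cluster's patient-years. The 95% CI on the relative risk is the Katz
log-normal interval, $\mathrm{SE} = \sqrt{1/e_1 - 1/n_1 + 1/e_0 - 1/n_0}$,
validated against a nonparametric bootstrap in the test suite; reports give
the full interval plus its half-width because published "±" values can be
read either way. *Progredient* patients are those found outside a cluster
set (optionally: inside a target region) three years after their first year
in it; comorbidity differences between progredient and stable patients use
the two-sided Fisher exact test (hypergeometric point-probability
summation, vectorised; equal to `stats::fisher.test` to the standard
`1e-7` relative convention) with Bonferroni adjustment over tested items.
The sex-bias screen applies the same test per (age group, source, target)
move; self-loops are the complement of the tested move and are not tested
separately.

The simulator evolves a cohort through the estimated kernel, conditioning
out censoring; ages advance yearly, layers switch at band boundaries, the
oldest band absorbs ages, and a sampled death makes the following year the
terminal record — exactly mirroring the estimator, which is what makes the
round trip (estimate → simulate → re-estimate) close. Trajectories that
are logically impossible under monotone histories can occur in principle
(a cluster sequence re-excluding a previously included block); strata
without at-risk data make patients stay put, and both situations are
counted in `n_undefined`-style diagnostics rather than hidden.
Single-disease benchmark models label each patient-year by its most
recently acquired or least prevalent block; model quality is compared by
total-variation distance between real and simulated reduced-length and
final-occupancy distributions, each model evaluated in its own label
space. Total variation was chosen because it is bounded, interpretable,
and indifferent to the differing label spaces. On held-out synthetic data
the cluster model's *combined* divergence and its final-occupancy
divergence are both clearly smaller than either benchmark's; the
reduced-length statistic alone does not separate the cluster model from
the least-frequent benchmark reliably — both are close to the sampling
noise floor on that statistic — so the package's acceptance checks compare
the combined divergence, not the length statistic in isolation.

## The synthetic registry

No national hospital registry is publicly available, so the package ships
a generator with known ground truth. It emulates, per patient: sex, a
birth year placing ages 0–90 at the start of the registry window
(1997–2014 by default); a latent multimorbidity process over nested block
sets (each latent state adds one or two blocks, so the latent graph is
acyclic by construction) with yearly progression rates rising with age,
mild sex differences, and in-hospital death probabilities rising with
latent severity and age; Poisson hospital stays (mean 0.3 per person-year,
the order of magnitude of national inpatient registries), with a stay
forced in acquisition and death years; diagnosis noise (one random acute
block on 10% of stays) that enters the cumulative vector, as acute codes
do in real data; and chapter O–Z placeholder codes for stays with nothing
chronic to report. A quarter of patients never acquire an A00–N99 code,
mirroring the roughly one-in-four share of cohort patients that never
leave the healthy cluster in large registries. Identical configurations
reproduce output bit for bit.

What the generator does **not** emulate: realistic ICD-10 code
frequencies, lengths of stay, outpatient care, cures, coding-practice
artifacts, or correlated comorbidity structure beyond the nested chains.
Green tests therefore demonstrate that the estimators recover the dynamics
they target under a faithful data-generating process of this family — not
that any clinical finding transfers to a particular real registry.

## Problem sizes and reproducibility

The test suite exercises parameter recovery on a 50,000-patient synthetic
registry (≈380,000 patient-years), clustering-oracle equivalence on 50
small random instances against an exhaustive greedy-tree implementation,
the Fisher test against full hypergeometric enumeration on all 2×2 tables
with margins ≤ 30, and hazard recovery over 25 replicate registries of
20,000 patients — sizes chosen so the whole suite runs comfortably on one
CPU while keeping every binomial check well-powered.
`scripts/acceptance.R` reruns the main computations at 20,000 patients
from a single `--seed` and writes the resulting quantities as JSON. All
randomness flows through explicit seeds; rerunning any stage with the same
configuration reproduces identical artifacts (the pipeline manifest
records MD5 checksums to make this checkable).

## Known limitations

* The Markov assumption — next state depends only on sex, age and current
  cluster — is inherited from the model, not tested against real data.
* The monothetic tree is greedy; it matches stepwise-optimal splits (and
  the brute-force oracle) but is not a globally optimal $K$-partition.
* Mortality-region labels are threshold rules on profile mortality and
  mean age; region definitions that also use inclusion criteria must be
  supplied by the user.
* Relative risks are stratified by sex and age only; no further
  confounder adjustment is attempted.
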