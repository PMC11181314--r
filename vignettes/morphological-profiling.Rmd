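---
title: "Morphological profiling with cellpaintr: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphological profiling with cellpaintr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellpaintr)
library(dplyr)
```

## The problem

Cell Painting assays stain several cellular compartments of (typically U2OS)
cells treated with compounds on 384-well plates, image each well at multiple
microscope sites, and extract on the order of 1,700 morphological features per
site with CellProfiler. Compared against DMSO control wells, the feature
profile of a compound is a phenotypic fingerprint: compounds with similar
profiles tend to share a mechanism of action, and a compound's overall
departure from the controls measures its bioactivity without committing to a
target. `cellpaintr` implements the downstream analysis of such screens —
everything after feature extraction — plus a synthetic-data generator so that
every stage can be exercised and validated with known ground truth.

## The model

### Aggregation

Site-level values are collapsed to wells by the per-feature median
(`aggregate_wells()`), and replicate plates may then be collapsed by median
(`aggregate_replicates()`). Medians are used throughout because image-derived
features are heavy-tailed and outlier sites (debris, focus failures) are
common. When replicates are collapsed, test rows are grouped per
(compound, concentration) but control rows are grouped per well position, so
that a collapsed pseudo-plate still carries one control row per original
control well and the control-matching rule below still has a population of
control wells to estimate from.

### Robust Z-scores

For a test well value $x_f$ of feature $f$, with control wells on the same
plate at the same DMSO load,

$$ z_f = \frac{x_f - \mathrm{median}(c_f)}{\mathrm{MAD}(c_f)} $$

where $\mathrm{MAD}$ is the *raw* median absolute deviation
(`mad_raw()`, no 1.4826 Gaussian consistency factor; the factor can be
restored via `mad_constant`). Controls are matched strictly by plate and
`dmso_percent`; if no matching controls exist the function errors rather than
silently pooling across plates, because plate effects are the dominant
nuisance in high-content screens. A feature whose control MAD is zero gets a
floor of $\max(\varepsilon_{abs}, \varepsilon_{rel}\,|\mathrm{median}|)$
(defaults $10^{-6}$ each) and is reported in a diagnostics table; Z-scores are
never infinite.

### Induction and the activity call

Induction is the percentage of features with $|z_f| \ge$ cutoff. The cutoff
defaults to 3 in raw-MAD units and is exposed everywhere as a parameter.
A compound is *active* when induction $\ge$ 5% (inclusive).

Two consequences of the raw-MAD convention are worth stating explicitly,
because they shape every downstream threshold. First, for Gaussian noise
$|z| \ge 3$ in raw-MAD units corresponds to about $2.02$ standard deviations,
so a completely inactive profile has an expected induction around
$2\,(1-\Phi(3\,q_{0.75})) \approx 4.3\%$ — just below the 5% activity
threshold — rather than the $0.27\%$ a 3-sigma rule would give. Second, the
MAD of a finite control sample is noisy, which inflates that tail further:
simulation gives roughly 10% expected null induction with 16 control wells
but ~5.4% with 64. The package therefore treats the 5% activity call as what
it is in practice: a liberal first-pass screen, with the 10% threshold used
where a decision must be reliable (retest selection and confirmation, below).
This is also why the synthetic plates default to the 384-well format with
one-sixth (64) DMSO wells: it matches the assay plate format and gives the
control estimators enough data that the null induction stays near its
asymptotic value.

### Biosimilarity

Profile similarity is derived from the correlation distance between two
Z-score vectors:

$$ \mathrm{biosim}(x, y) = \max\big(0, \; r_{xy}\big) \times 100, $$

the Pearson correlation of the two profiles, clipped at zero and expressed in
percent. Anti-correlated profiles are "0% similar", not negatively similar.
Constant vectors have undefined correlation and raise an error; callers that
can tolerate the condition (feature selection, cluster scoring) catch it and
drop or mark the case.

### Robust feature selection

Following the reference-plate procedure, each feature's whole-plate profile
(its value across wells in fixed row-major order A01…P24) is computed in two
biological repeats of one reference plate; the feature is kept when the
cross-repeat biosimilarity is at least 80 (i.e. correlation $\ge 0.8$,
inclusive). Features that are constant in either repeat are excluded with a
message. In the published screen this once-only procedure kept 579 of 1716
features; the synthetic default therefore uses 579 features.

### Replicate concordance and confirmation

`replicate_concordance()` matches two runs by compound, computes per-compound
cross-run biosimilarity, and summarises: Pearson $r$ and $r^2$ of induction,
median biosimilarity, the fraction of compounds with biosimilarity $\ge$ 80%,
and the confirmed-active fraction. The confirmation rule was a genuinely open
design point (the screen retested compounds with induction $\ge 10\%$ and
confirmed 370 of 549): `cellpaintr`'s pipeline default confirms at induction
$\ge 10\%$ in the second run, for the reason given above — with the raw-MAD
convention an effect-free profile sits near 5% induction, so a 5% confirmation
rule would "confirm" a majority of truly dead (e.g. precipitated) compounds by
noise alone, and the confirmed fraction could not track the planted
precipitation rate. Both thresholds are configuration keys.

### Cluster subprofiles and assignment

A bioactivity cluster is defined by a set of member profiles. For each
feature, count strictly positive and strictly negative values across the
defining profiles; the feature enters the cluster subprofile when
$\max(n^+, n^-) / n_{\mathrm{def}} \ge 0.85$ (inclusive; zeros count in the
denominator only — a conservative reading of "same sign for 85% of the
defining profiles"). The subprofile value is the per-feature median over the
defining profiles. Compounds are assigned to every cluster whose subprofile
biosimilarity reaches 80% — higher than the 75% full-profile convention
because subprofiles are shorter. The residual structure outside a cluster's
features can be explored with `cluster_residual()`, which clusters profiles
hierarchically on the complement feature set with correlation distance
(1 − Pearson) and average linkage; neither choice is prescribed by the
source procedure, and both are arguments.

## The curation funnel

`standardize_compounds()` keeps the largest fragment of each structure (ties
broken by heavy-atom count, then molecular weight, then canonical SMILES
order, so results are stable), attaches the standard InChIKey, and computes
MW, heavy-atom count, logP, TPSA, FrCsp3 and H-bond donor/acceptor counts.
Unparseable structures and failed keys are kept with missing values and
counted, never silently dropped. `apply_funnel()` then applies the ordered
stages: availability ($\ge 2$ mg, missing amounts fail), size (heavy atoms
$\ge 25$, so 25 itself is kept), and overlap removal by full-string,
case-exact InChIKey comparison against a reference key set.
`select_diverse()` performs MaxMin (greedy farthest-point) picking on
Tanimoto distance over extended-connectivity fingerprints (OpenBabel ECFP4,
the radius-2 circular-fingerprint family); the starting compound is drawn
from a mandatory seed and every later pick is deterministic with ties broken
by record order. `flag_pains()` matches a hand-curated catalog of canonical
pan-assay-interference substructure families (rhodanines, hydroxyphenyl
hydrazones, catechols, quinones, alkylidene barbiturates, isothiazolones,
aryl azos) — a representative subset of the published alert sets, not the
full catalog, shipped as a plain SMARTS table that users can replace.
`flag_lysosomotropic()` applies the physicochemical heuristic logP $> 2$
(strict) and basic pKa in $[6.5, 11]$ (inclusive); pKa values are inputs,
not predictions.

## The synthetic generator

`synth_spec()` / `synth_run()` emulate the data model of a profiling screen:

* per-feature baselines with log-uniform medians ($10^{[0,2]}$) and MADs
  (10–20% of the median), so features are not scale-homogeneous;
* cluster effect templates: sign patterns ($\pm 1$ on a random 15% of
  features, 0 elsewhere). An active compound shifts each touched feature by
  `effect_size` control-MADs in the template direction. Templates are sign
  patterns rather than unit-norm directions so that `effect_size` has the
  stated per-feature meaning — an effect of 4 produces $|z| \approx 4$ on
  touched features, and an effect of 5 on 20% of features produces induction
  near 20%;
* independent Gaussian well noise scaled so its raw MAD equals `noise_sd`
  (a heavy-tailed Student-$t_3$ option exists, since real Cell Painting
  features are not Gaussian), plus smaller site-level jitter collapsed by the
  median of `n_sites` sites;
* replicate pairs sharing baseline, compounds and truth but with independent
  noise, and a precipitation failure mode: a seeded fraction
  (default 9.6%) of the active compounds has its effect zeroed in run 2,
  emulating compounds that precipitate after a freeze–thaw cycle;
* a toy SDF library with salts, duplicates, small fragments and an
  `available` field, exercising every curation stage with construction-known
  counts (8 → 6 → 4 → 3 through the funnel).

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: spatial plate effects (edge wells, gradients),
feature–feature correlation structure (real CellProfiler features are highly
collinear; synthetic features are independent given the effect template),
dose–response behaviour, cytotoxicity-driven profile collapse, and batch
effects between runs beyond independent noise. Results on synthetic data
validate the *statistics*, not the biology.

## Worked example

```{r example, eval = FALSE}
library(cellpaintr)

cfg <- pipeline_config(seed = 1)
res <- run_pipeline(cfg)

glance(res$concordance)
res$cluster_counts
res$funnel$stages
autoplot(res$concordance)
```

On the default conditions (60 compounds, 30% active across three clusters,
effect 4 MAD on 15% of 579 features, unit noise, 9.6% precipitation) the run
retests the compounds with first-run induction $\ge$ 10%, confirms all
non-precipitated ones, assigns every confirmed active to its true cluster,
and reproduces the toy funnel counts exactly.

## Numerical choices and degenerate inputs

* Median of an even count: mean of the two central values (R's default).
* Missing feature values are excluded pairwise from medians and correlations;
  a profile missing more than 5% of the robust features is rejected with a
  diagnostic rather than scored.
* Zero-variance vectors: undefined correlation is an error at the
  `biosimilarity()` level; feature selection converts it to exclusion,
  cluster scoring to a missing (unassignable) value.
* All boundary comparisons (induction 5%, similarity 0.8, consistency 0.85,
  cluster threshold 80%, 2 mg, 25 heavy atoms) are inclusive.
* Every stochastic element — generator noise, precipitation draws, the MaxMin
  starting pick, pipeline compound assignments — derives from an explicit
  seed, and seeded runs are bit-reproducible (the toy SDF writer even scrubs
  the timestamp OpenBabel embeds in molblocks).

## Problem sizes in the test suite

The packaged tests run the full statistics at the study scale where it
matters (579 features; 384-well plates; 200 compounds for the
precipitation-recovery check; 10 generator seeds for cluster-label recovery)
and smaller scales (96–150 features, 3 sites) where only correctness of the
wiring is at stake. These sizes are the package's own validation choices and
complete in well under a minute each.

## Known limitations

* The PAINS catalog is a curated family subset; screening-grade filtering
  should load the full published SMARTS set via the `catalog` argument.
* Cheminformatics is delegated to OpenBabel: descriptor values (logP, TPSA)
  and canonicalization follow OpenBabel's models and may differ numerically
  from other toolkits; InChIKeys follow the standard InChI and are portable.
* `aggregate_replicates()` assumes replicate plates share well positions for
  controls; fully scrambled layouts should be collapsed after Z-scoring
  instead.
* The pipeline's headline 5% activity call is liberal under the raw-MAD
  convention (see above); treat single-run activity near the threshold as
  provisional until confirmed in a replicate.
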