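---
title: "Correlation-weight QSAR models from SMILES optimal descriptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation-weight QSAR models from SMILES optimal descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cwqsar)
```

## The model

`cwqsar` fits one-variable regression models of the CORAL family for
continuous toxicity endpoints such as the NOAEL and LOAEL of sub-chronic
repeated-dose studies (log10 mg/kg bw/day). The model is

$$\mathrm{Endpoint} = C_0 + C_1 \cdot \mathrm{DCW}(T, N)$$

where the *descriptor of correlation weights* DCW is the sum, over the
molecular features of a compound, of a learned real-valued *correlation
weight* per feature. The features come from four families:

* **SMILES n-grams** (`S`, `SS`, `SSS`): windows of one, two or three
  adjacent SMILES tokens. Two- and three-token windows are compared with
  their reversal and the lexicographically smaller orientation is kept, so a
  string and its mirror image yield the same keys. These are *string*
  features by design: two SMILES spellings of the same molecule may differ.
* **Morgan extended connectivity** (`EC1`–`EC3`): element-tagged
  connectivity codes on the hydrogen-suppressed molecular graph. The
  order-0 value of a vertex is its degree; the order-$k$ value is the sum of
  the order-$(k-1)$ values of its neighbours. Order-0 codes are computed but
  not emitted as features.
* **Nearest-neighbour codes** (`NNC`): one code per atom, the element plus
  the sorted multiset of neighbour elements (e.g. `C/N[C,O]`). The exact
  historical definition of this family is not fixed in the literature we
  follow; the element + sorted-neighbour-multiset code is this package's
  concrete definition.
* **Atom-pair proportions** (`APP`): one key per pair of symbols from
  `{F, Cl, Br, N, O, S, P, =, #}` recording the joint counts, e.g.
  `(Cl.N)..1.2` for one chlorine and two nitrogens. `=` and `#` are counted
  as bond-token occurrences. The `delta` block runs over the upper triangle
  of the 9 × 9 symbol matrix in the fixed alphabet order; the `gamma` block
  is the four chlorine pairs, individually gated. When both blocks are
  enabled a key appearing in both is kept once — the blocks gate which
  pairs are *eligible*, and a proportion is a single fact about a molecule.

Which families enter the descriptor is controlled by a `cw_config`
([model_config()]): blocks `alpha` (n-grams, gated by `x1`–`x3`), `beta`
(EC + NNC), `gamma` and `delta` (APP), mirroring the eight published model
configurations available via `preset_config("M1")` … `preset_config("M8")`.

## Training procedure

The dataset is split uniformly at random (seeded) into four disjoint
subsets with distinct roles:

* the **active training** set drives the weight updates and the final
  least-squares calibration of $(C_0, C_1)$;
* the **passive training** set only enters the target function through its
  correlation, guarding against weights that fit the active compounds only;
* the **calibration** set detects overtraining: the per-epoch snapshot with
  the best calibration $R^2$ is the one retained, and the IIC/CII terms of
  the target function are evaluated on it;
* the **validation** set is never touched during training and supplies the
  external statistics.

Subset sizes are `floor(fraction * n)` for the first three subsets with the
remainder in validation, so 561 records at equal fractions give
140/140/140/141.

The optimiser is a Monte Carlo hill climb. Attributes seen in fewer than
`T` active-training molecules are *blocked* (frequency counts molecules
containing the feature, so `T = 1` blocks nothing that has been seen);
blocked features never contribute to the descriptor, and features entirely
unseen at training time contribute 0 at prediction time while raising the
applicability-domain defect. All active weights start at 1 — an
intentionally scale-free start under which DCW is proportional to the
attribute count. For `N` epochs the active attributes are visited in seeded
random order; each visit proposes a uniform perturbation on
$[-0.1, +0.1]$ and accepts it only if the target function

$$tf = r_{AT} + r_{PT} - w_{bal}\,|r_{AT} - r_{PT}|
      + w_{IIC}\,\mathrm{IIC}_C + w_{CII}\,\mathrm{CII}_C$$

strictly increases ($r$ are Pearson correlations between DCW and endpoint).
The base balance-of-correlations form with `tf_balance` default 0.1 is the
standard form for this model family; the published work states only the
IIC/CII weighting, so the base form and both knobs are exposed as
configuration. An *epoch* is one full pass over all active attributes: this
keeps epoch counts comparable across dataset sizes, which matches the small
published epoch optima (4–33). The initial weight state participates in
snapshot selection as an epoch-0 baseline, so an optimisation that degrades
calibration quality can never beat the start.

Several quantities worth naming exactly:

* $R^2$ is the squared Pearson correlation between observed and predicted
  values (not $1 - RSS/TSS$); this convention is what makes the published
  F-ratios reconstructable from the published $R^2$ and $n$.
* $Q^2$ is the leave-one-out cross-validated coefficient of the
  one-variable fit, computed with the closed-form leverage identity.
* $Q^2_{F3}$ scales the external mean squared error by the *active
  training* variance of the endpoint. Which training variance anchors the
  statistic is a known ambiguity in the literature; the active training set
  is the choice here because it is the only subset that parameterises the
  model.
* **IIC** multiplies the correlation by the ratio of the smaller to the
  larger of the mean absolute residuals of the two residual signs. When all
  residuals have one sign the index is 0 by convention — in practice a
  calibration set always straddles the fitted line.
* **CII** is $1 - \sum_k \max(0, R^2_{-k} - R^2)$ over single-compound
  removals, with the refit recomputed per exclusion (the stricter reading;
  under the squared-Pearson convention the refit $R^2$ equals the squared
  correlation on the remaining points).

## Applicability domain

The domain is probabilistic, based on the *statistical SMILES defect*. Per
attribute,

$$d_k = \frac{|P(S_k) - P'(S_k)|}{N(S_k) + N'(S_k)}$$

with $P, N$ the probability and frequency of the attribute in the active
training set and $P', N'$ in the calibration set. The source prints this
formula without a visible fraction bar; division by $N + N'$ is the only
reading under which features frequent in both sets are low-defect, and is
what this package implements. Probabilities and frequencies are
molecule-presence counts (matching the blocking convention), an attribute
absent from both sets has defect 1 (maximal novelty), and a molecule's
defect is the sum over its *distinct* non-blocked attributes. A prediction
is in domain when its defect is strictly below $2\bar D$, the threshold
stored in the model file ($\bar D$ = mean defect of the active-training
compounds). Features present only in the calibration set use the same
formula rather than a separate penalty.

## The synthetic-data generator

Because the published datasets ship as supplementary material, the package
carries a generator so every stage is testable from code alone.
`generate_library()` assembles unique SMILES from templates — linear and
branched alkanes, halogenated alkanes, amines, ethers, thioethers,
phosphates, alkenes, alkynes, nitriles and substituted benzenes — covering
every symbol of the atom-pair alphabet. Template assembly (rather than
random grammar walks) guarantees parseability without a chemistry toolkit.
Aromatic chemistry is drawn with elevated probability (about a third of
random draws): organic toxicity datasets are aromatic-rich, and broad
support for the correlated block of aromatic attributes keeps every
attribute family represented in random training subsets of the default
library size.

`plant_and_label()` draws a true weight per library attribute uniformly in
$[0.5, 2.5]$ and scales the affine map so noise-free labels span $[-1,
4.3]$ — the log10 range of real sub-chronic endpoint datasets. The default
library size of 200 mirrors the organ-specific dataset scale (roughly
90–280 compounds). The generator emulates attribute-driven linear
structure, seeded determinism and range; it does **not** emulate the
property distributions, activity cliffs, measurement heterogeneity or
assay-design variability of real repeated-dose data, so passing recovery
tests demonstrate correctness of the machinery, not real-data predictivity.

`make_ad_challenge()` pairs a halogen-free library with perhalogenated
molecules whose attributes are guaranteed unseen, exercising the domain
machinery.

## Numerical choices and degenerate inputs

* Ties in the hyperparameter grid (`select_hyperparams()`) break towards
  the smaller threshold, then the smaller epoch count — preferring models
  that use more features for fewer optimisation passes.
* A constant descriptor on a training subset (identical molecules, or
  everything blocked) raises an error advising a lower `T` rather than
  returning a meaningless fit.
* Zero-variance guards inside the optimiser score IIC/CII as 0 for the
  affected proposal instead of erroring mid-run.
* Model JSON is written with 17 significant digits, which round-trips IEEE
  doubles exactly: a saved and reloaded model reproduces predictions
  bit-for-bit.
* Aromatic bonds count as order 1 for degrees and Morgan connectivity, and
  lowercase aromatic atoms keep their lowercase symbol in attribute keys,
  keeping the string and graph alphabets aligned; element counts for
  atom-pair proportions map aromatic atoms to their uppercase element.
* Duplicate records are collapsed by CAS when present, otherwise by the
  exact SMILES string — no canonicalisation engine is involved, matching a
  2D-level duplicate check without importing a chemistry toolkit. The
  curation rule for low-frequency endpoint values (an optional trim of
  sparse histogram-tail bins, default off) is a policy knob: no published
  threshold exists for that step.

## Problem sizes used in the tests

The test-suite experiments run at the generator's default scale: libraries
of 200 molecules (50 per subset) for recovery and domain experiments, 120
for noise-degradation curves, and about 100 small molecules for the
brute-force attribute oracles. Parameter-recovery experiments use the
SMILES 1- and 2-gram configuration with a pure correlation target
(`iic_w = cii_w = 0`), threshold `T = 1` and `N = 30` epochs: recovery of a
planted linear truth is a property of the optimiser, so the experiment uses
the plainest identifiable configuration rather than the IIC/CII-weighted
variants used for real endpoints.

## Known limitations

* SMILES support is a Daylight-style subset: stereo markers are preserved
  as tokens but carry no graph semantics, and bracket atoms contribute the
  bare element.
* The n-gram families are spelling-sensitive by construction; models should
  be trained and applied on consistently written SMILES.
* One Monte Carlo run yields one model; no multi-run consensus averaging is
  provided.
* The domain criterion is semi-qualitative: it flags unfamiliar feature
  distributions, not prediction-error bounds.
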