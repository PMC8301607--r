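---
title: "Methods: weighted molecular views, toxicity generators, and AggE activity calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted molecular views, toxicity generators, and AggE activity calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viewtox)
```

## The problem

High-throughput zebrafish embryo screens record, for each chemical, the
incidence of 18 developmental endpoints (mortality and morphological
defects at 120 hours post-fertilization) across 32 replicate embryos at the
highest tested concentration. Most registered chemicals have never been
screened. `viewtox` implements a structure-to-toxicity pipeline for this
setting: a 3D structure is vectorized into a weighted set of local-frame
"views", a deep-network generator maps the views to a predicted 18-endpoint
incidence matrix, the matrix is condensed to a single aggregate-entropy
(AggE) score in bits, and the chemical is called active when AggE reaches
the 9.35-bit threshold. Two generators are provided: Go-ZT, trained by
plain mean-squared-error regression, and GAN-ZT, the same generator shape
trained adversarially against a discriminator that judges (chemical
features, toxicity matrix) pairs.

## The views vectorization

Each atom of a molecule contributes one *view*: a local coordinate frame
centered on that atom, whose rows are `[period, group, x, y, z]` — the
atom's periodic-table position (IUPAC 18-column groups) plus its position
relative to the center. Rows are ordered by distance from the center, up to
a configurable `max_atoms_per_view`; shorter views are zero-padded when
converted to fixed-shape arrays (period = group = 0 is an unambiguous
sentinel because no real atom has group 0).

The frame is canonical: the center maps to the origin, the designated
nearest atom to the +x axis, the nearest non-collinear atom into the
half-plane y > 0, and z completes a right-handed frame, after which the
first off-plane atom in distance order is required to have z > 0 (a
reflection is applied if needed). Consequences worth knowing:

* **Rigid-motion invariance.** Translating or rotating the input
  coordinates changes nothing, which the test suite checks at 1e-6 over
  100 molecules.
* **Enantiomers collapse.** The reflection rule means mirror-image
  molecules produce identical views. This is a deliberate representational
  limit: without it, the frame would be ill-defined for achiral molecules.
* **Tie-splitting.** When k atoms tie (within `tie_tol`, default 1e-3 Å)
  for a center's *nearest-neighbor* position, the axis is ambiguous, and
  the view splits into k views, one per tied atom, sharing the center's
  unit weight equally. Ties at later positions are broken deterministically
  (by period, group, then canonical-frame coordinates) without splitting,
  bounding the view count. Splitting only at the axis-defining position is
  the rule that makes methyl isothiocyanate — whose methyl carbon sees
  three equidistant hydrogens — come out at exactly nine all-atom views:

```{r}
vs <- build_views(fixture_molecule("methyl_isothiocyanate"), view_config())
length(vs$views)
sum(vs$weights)
```

* **Weights.** Every center contributes base weight 1, divided over its
  split views and finally normalized so the molecule's weights sum to 1.
  Normalization makes the pooled representation (below) comparable across
  molecules of different atom counts.

Ordering ties among *candidate* reference atoms are resolved with
rotation-invariant keys only (distance to center, period, group, distance
to the designated nearest, then the atom's full sorted distance profile).
Atoms that all these keys cannot separate are exact symmetry mates, for
which either choice yields the same view; this is what makes the output
independent of the order atoms appear in the file. Sort keys are quantized
at 1e-6 Å so floating-point jitter below the tolerance cannot reorder rows.

A `carbon_only` centers mode starts views only from carbons (falling back
to all atoms for carbon-free molecules). Under the pinned splitting rule
methyl isothiocyanate has 4 carbon-only views (3 from the split methyl
carbon + 1 from the other carbon), not 3; the all-atom count is the one
this package treats as normative, and the carbon-only mode is provided as
an option without a count guarantee.

## The generators

Both generators share one shape. A feature network *f* (default: 3 hidden
layers) reads each flattened padded view; the chemical's representation is
the weighted sum *s* = Σᵢ f(vᵢ)·wᵢ over its views — exact, order-invariant
pooling, checked against a brute-force summation oracle at 1e-6. A
toxicity network *g* (default: 11 hidden layers) maps *s* to the
18-endpoint incidence vector. All hidden *and* output layers use swish
activation, with batch normalization between layers, Gaussian weight
initialization, and no dropout. Since swish is unbounded, raw regression
outputs are clipped into [0, 1] only at the AggE interface; the raw values
remain available.

**Go-ZT** minimizes mean squared error against the empirical incidence
vectors with mini-batch SGD (batch 32) for 75 epochs. **GAN-ZT** trains the
same generator adversarially in the least-squares-GAN form: the
discriminator — a fully-connected network on the concatenation of *s* and a
toxicity matrix — is pushed toward score 1 on real pairs and 0 on generated
pairs (Adam optimizer), while the generator is pushed to make its pairs
score 1 (SGD), one discriminator step per generator step. The conditioning
information is the weighted-sum feature vector *s* itself, shared by
generator and discriminator; gradients flow to the feature network through
both the toxicity path and the conditioning path. Batch-normalization
statistics are taken per mini-batch during training and frozen (running
averages) at evaluation; during the generator step the discriminator is
evaluated with its frozen statistics.

Defaults and their provenance:

| parameter | default | why |
|---|---|---|
| feature hidden layers | 3 | published final architecture |
| toxicity hidden layers | 11 | published final architecture |
| hidden width | 128 | not published (tuned by random search there); 128 here, exposed to `random_search()` |
| feature dimension D | 32 | not published; package choice |
| atoms per view | 10 | "user-defined limit"; covers the synthetic chains |
| Go-ZT epochs | 75 | published |
| GAN-ZT epochs | 2000 | published (tests use 200; see below) |
| SGD learning rate | 0.1 | not published; chosen once for stable convergence of the default width |
| batch size | 32 | not published; package choice |

Training is deterministic given the seed: identical seeds give bit-identical
loss histories and predictions. A diverging run (non-finite or > 1e8 loss)
aborts with a learning-rate diagnostic rather than returning garbage.

## AggE scoring and activity calls

The screen's own summary statistic, aggregate entropy, was defined in
earlier work on these data and is not restated in the source for this
package; what is fixed is its scale (bits), its threshold (9.35 at the
highest concentration), and its intent — summarize 18 incidences without
double counting correlated endpoints. `viewtox` therefore pins a
transparent stand-in with those properties and isolates it in one function
(`agg_entropy()`) so a different definition can be swapped in:

* endpoints are pooled within correlation groups by max (default: 18
  singleton groups, configurable via `endpoint_panel()`);
* each group incidence q is scored s(q) = H₂(q) for q ≤ ½ and 2 − H₂(q)
  above, H₂ the binary entropy in bits — continuous, monotone, with
  s(0) = 0, s(½) = 1, s(1) = 2;
* AggE is the sum of group scores, so singleton grouping spans [0, 36] and
  the 9.35 threshold sits inside the attainable range.

Entropy alone is not monotone in incidence (it falls beyond ½); the folded
form restores monotonicity, which is what a *toxicity* summary needs:
raising any endpoint incidence never lowers AggE, and pooling into fewer
groups can only lower it. Calls use ≥ at the threshold; the threshold is
configurable because it is concentration dependent.

## Evaluation

With ~16% active prevalence, accuracy is uninformative; the package centers
evaluation on Cohen's kappa and PPV, with SE/SP reported in percent.
"AUROC" for thresholded binary calls is computed as (SE + SP)/2 — balanced
accuracy, the ROC area of a single operating point — and labelled as such
in every report; a threshold-sweep ROC is deliberately not offered for
AggE-thresholded calls. Metrics with zero denominators are reported as
explicitly undefined (`NA`), never as 0.

Cross-validation is implemented as k repeats of a randomized 80:20
subsample ("10-fold cross-validation using a randomized 80:20 split" is
internally inconsistent — true 10-fold would be 90:10 — and the quoted
split ratio plus mean±SD reporting match repeated subsampling). Splits are
stratified by class by default so the minority class appears in every
validation set; an unstratified switch resamples degenerate splits with a
logged message. `random_search()` tunes hyperparameters against the
cross-validated mean kappa. `shuffle_null()` permutes truth labels against
fixed predictions (1000 times by default); its kappa and AUROC concentrate
at 0 and 0.5, which the acceptance tests check within ±0.05.
`consensus_and()` implements the two-model consensus: active only where
both models agree, which can only remove positive calls, trading
sensitivity for PPV. `prioritization_estimate()` carries a PPV into
screening-list arithmetic (expected actives rounded to the nearest 10).

## The domain-of-applicability filter

Predictions are refused, with a named reason, for structure classes outside
the generators' domain: perfluorinated chains longer than nine carbons,
chloroperfluoro compounds, and betaine-motif compounds (quaternary N⁺ with
a carboxylate in the same molecule). Connectivity is inferred from
distances (bond when d < 1.2 × sum of covalent radii) because PDB inputs
need not carry CONECT records; a disconnected inferred graph is an error,
never a silent acceptance. Filter decisions depend only on element
identities and connectivity, hence are invariant to atom order and rigid
motion.

## Synthetic data: what it emulates and what it does not

No screen data ships with the package. The `synth` module generates the
*statistical shape* of the empirical setting so the pipeline is testable
end to end: 18 binary endpoints, 32 replicates, and a target active
prevalence of 0.16 mirroring the 159/1003 training imbalance. Molecules
are random acyclic heavy-atom chains over a C/N/O/S/Cl alphabet (frequency
0.60/0.10/0.15/0.08/0.07, lengths 3–9), embedded as idealized tetrahedral
zigzags with bond lengths equal to covalent-radius sums (C–C = 1.54 Å). The
planted signal acts only through 3D-derivable descriptors — atom count,
heteroatom fraction, S presence, Cl presence, mean coordination — via
per-endpoint logistic models p_e = logistic(α_e + β·d + ε), with Gaussian
logit noise (SD 0.25) and binomial sampling at 32 replicates. The global
intercept is calibrated by bisection so the noise-free active rate matches
the target prevalence to the nearest achievable count. Effect sizes default
to β = (0.8, 1.0, 2.5, 1.5, 0.5) — strong enough that activity is largely
determined by composition (the noise-free labels agree with the sampled
labels at kappa ≈ 0.94), which makes held-out recovery a fair test of the
whole views → generator → AggE chain; β = 0 plants an exact null.

What passing tests on these data do *not* show: performance on real
chemistry. The generator makes no rings, no stereochemistry, no tautomers,
no hydrogens, and its signal is low-dimensional by construction. Synthetic
results certify that the pipeline can recover a recoverable signal and
reports chance on a null — not that any particular kappa transfers to a
real screen.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run desk-scale studies chosen
to finish in minutes on one CPU: signal recovery uses 200 chemicals, an
80:20 split, the default 75-epoch Go-ZT at full width 128, averaged over 3
seeds; adversarial stability uses 200 epochs (a tenth of the published
2000) at width 64, checking that both losses stay bounded and the
discriminator loss does not collapse to 0. Invariance suites use 100
molecules. Other numerics: batch-norm ε = 1e-5 with momentum 0.9;
coordinate comparisons at 1e-6 Å; tie tolerance 1e-3 Å; weight
normalization checked at 1e-9; the AggE stand-in uses 0·log 0 = 0.
Degenerate inputs are defined rather than accidental: a single-atom
molecule yields one center-only view of weight 1; a fully collinear
molecule gets y = z = 0 for every row; an endpoint with zero evaluable
replicates is an error naming the endpoint.

## Known limitations

* The AggE form is a pinned stand-in (scale, monotonicity and threshold
  compatibility are guaranteed; the historical formula is not).
* Enantiomers are indistinguishable by construction.
* Carbon-only view counts are not normative (see above).
* Bond order and charge are not represented; the domain filter and the
  betaine rule operate on inferred connectivity only.
* One toxicity matrix per chemical (highest concentration);
  concentration–response modeling is out of scope.
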