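---
title: "Methods: harmonized GHS acute toxicity labels and heterogeneous descriptor models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: harmonized GHS acute toxicity labels and heterogeneous descriptor models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Regulatory agencies publish acute toxicity classifications under the
Globally Harmonized System (GHS): for each exposure route a compound is
assigned to one of five categories defined by LD50 intervals, category 1
being the most severe. Several partially overlapping public inventories
state such classifications (authoritative lists), and industrial
self-classification notifications add per-category submission counts.
`ghstox` implements a pipeline that pools these heterogeneous statements
into one harmonized per-route label per compound, derives a binary acute
oral toxicity endpoint, and relates it to three descriptor domains —
2D molecular descriptors, predicted protein-target bioactivity
probabilities, and qHTS assay scores — through structural-alert
enrichment, class-separation analyses and Random Forest classification
over three deliberately different train/test split designs.

Because the regulatory inventories themselves cannot be redistributed, the
package ships a synthetic-study generator with a fully known generative
model; every stage of the pipeline is tested against that ground truth.

## Label harmonization

**Authoritative tier.** For one compound and route, sources may state a
category (1–5) or merely list the compound without an acute-toxicity
category. Presence without a category is read as *implied nontoxicity*,
encoded as a hypothetical category 6: GHS records are intended to be a
complete hazard summary, so absence of an acute-toxicity entry in a source
that covers the compound is informative. Conflicting categories between
authoritative sources are resolved to the most severe (numerically lowest)
category. This conflict policy is a design choice of the package —
hazard-conservative and in line with how regulators aggregate discordant
evidence; disagreements between sources do occur at the observed noise
levels, so *some* policy is unavoidable.

**Notification tier.** Notification tables give counts per category plus
"no classification". A category `c` qualifies when at least 10% of all
notifications are at `c` or a more severe level (cumulative rule); the most
severe qualifying category is taken. The comparison is done in exact
integer arithmetic (counts against a rational threshold) so that a
boundary case such as exactly 10% is never decided by floating-point
rounding. When no category qualifies, the compound is treated as implied
nontoxic — the same completeness rationale as above, applied to the
notification tier; this is configurable because the tier's semantics for
that corner are genuinely underdetermined.

**Merging.** Authoritative labels always take precedence; the notification
label is a fallback only. The binary endpoint maps categories 1–3 (the
"toxic" pictogram classes) to *toxic*, category 5 and implied nontoxicity
(no pictogram) to *nontoxic*, and excludes the marginal category 4 from
binary analyses.

Diagnostics: pairwise source overlap is intersection-over-union on compound
sets; label agreement is the fraction of identical categories on common
compounds, with implied nontoxics participating as category 6.

## Structure pipeline

Standardization retains the largest fragment, neutralizes charges, and
emits OpenBabel canonical SMILES. The canonical writer fixes one
deterministic mesomer/tautomer representation; this is a documented
dialect — no claim of equivalence with any proprietary standardizer is
made, and the operation is idempotent, which the tests assert across the
whole synthetic library. Structure identity for deduplication is the
standard InChI.

The small-organic filter discards records typed as mixtures, polymers or
macromolecules, structures without carbon, structures containing elements
of atomic number 21–32, 36–52 or above 53, and structures failing the
molecular-weight rule. The weight rule is configurable in direction:
the default discards MW < 100 Da (reading the bound as a floor on small
fragments and salts); the alternative reading (discard MW > a ceiling,
e.g. 1000 Da) is selectable because the printed form of this rule in the
regulatory-modelling literature is ambiguous and the two readings differ
materially.

Deduplication by InChI: singletons pass; within a duplicate group,
unannotated members are dropped; if several annotated members remain, the
group survives only when exactly one member's raw SMILES already equals its
standardized SMILES (that member is the closest representation of the
annotated substance); otherwise the whole group is discarded as
unresolvable.

## Descriptor blocks

**Molecular block.** An open set of about 160 raw 2D descriptors per compound (typically just over 100 survive constant-dropping on a given library):
constitutional counts, bond/ring statistics, topological indices (Wiener,
Randić, Zagreb, Kier kappa shapes, graph diameter and radius),
electronegativity-based charge proxies, OpenBabel physicochemical
properties (MW, logP, TPSA, molar refractivity, H-bond donors/acceptors),
sixteen functional-group SMARTS counts, and 96 hashed radius-1
atom-environment counts. Feature names are namespaced (`const_`, `topo_`,
`fg_`, …) precisely so that no report implies equivalence with any
proprietary descriptor package. Constant columns are dropped and logged.

**Target block.** Per-target ensemble-of-trees classifiers are fitted on
2048-bit circular fingerprints of radius 2. The fingerprints are the
package's own Morgan-style implementation on the molecular graph: the
initial atom invariant combines atomic number, degree, valence (bond-order
sum) and ring-framework membership; two rounds of order-invariant
neighbourhood hashing extend each environment to radius 2, and every
(atom, radius) environment sets one bit of the folded vector. Models are
Platt-calibrated on out-of-fold scores (5-fold). A model's output is only used as a descriptor
when it passes both reliability criteria: recall on the overlap of its
training actives with the query set of at least 0.5 (a known active counts
as recalled when its calibrated out-of-fold probability exceeds 0.5), and a
mean nearest-neighbour Tanimoto similarity of the training set to the query
set strictly above 0.25. Recall is computed from out-of-fold predictions so
that training-set memorization cannot let an unreliable model pass. Known
active (compound, target) pairs are overridden to probability exactly 1.
Known *inactives* are not overridden — only the active override has a
defensible certainty semantics.

**Assay block.** Assays flagged as counter-screens, autofluorescence
screens or superseded confirmatory screens are dropped first; repeated
(compound, assay) measurements collapse to the median; absent cells are
assumed inactive and scored 0. Scores outside [0, 100] are rejected as
input errors. Because all-zero rows are common in this sparse block, its
distance metric is cosine with two conventions: the distance of a zero
vector to anything non-zero is 1 (orthogonality convention) and to another
zero vector is 0. The molecular block uses Euclidean distance after
centring/scaling; the target and assay blocks are already on a common
scale.

## Toxicophore screening

The packaged alert set contains five reactive chemotypes written as SMARTS
(P=S bond, thiourea, N-nitroso, thiocarbonyl, gem-dichloro carbon) with
high/moderate severities; user alert files with the same schema are
accepted. The three-way outcome policy is: any high-severity hit rejects,
otherwise any moderate hit is intermediate, otherwise accepted. Per-alert
enrichment uses the 2×2 table against the binary classes, a two-sided
Fisher exact test with Bonferroni correction over the number of alerts
tested, and the odds ratio ad/bc with the Haldane–Anscombe +0.5 correction
when a cell is zero (the correction can be disabled). Significant alerts
are ranked by descending odds ratio, ties broken lexicographically so the
ranking is a total order.

## Class separation

For each compound the nearest neighbour in its own class (self excluded)
and in the other class is found under the block's metric; the paired t
test on (inter − intra) and Cohen's *d* with the equal-n pooled SD
`sqrt((s1² + s2²)/2)` summarize neighbourhood behaviour. Positive *d*
means inter-class neighbours are farther, i.e. the classes clump.

Per-feature tests use a two-sample Welch t test and a two-sample
Kolmogorov–Smirnov test; a feature is significant when the *larger* of the
two p values clears the Bonferroni threshold. These are deliberately
two-sample tests: the classes have unequal sizes, so a paired design is
not available, and the package does not guess one. Cohen's *d* here uses
the Bessel-corrected pooled SD and is positive when the toxic mean is
higher.

The linear discriminant is the two-class Fisher direction
`w = Σ⁻¹(μ_toxic − μ_nontoxic)` with an eigenvalue floor on the pooled
within-class covariance at `1e-6 × trace/p`. The floor keeps the
near-singular assay block (many identical zero rows) invertible and makes
the analysis defined even when n ≤ p; up to that regularization the
projected effect size is invariant to affine rescaling of individual
features, which the tests assert. The unpaired t test and pooled-SD
Cohen's *d* on the projection quantify separability; weights are reported
ranked by absolute value.

## Predictive modelling

Three split designs define the evaluation:

* *random* — class-stratified 20% test subsample (per-class quota rounded
  half-up);
* *rare scaffolds* — all compounds whose Murcko framework occurs at most
  twice in the modelling set (deterministic, not repeatable by design);
* *single source* — a class-stratified 20% subsample drawn only from
  compounds covered by exactly one authoritative source; if that pool
  cannot fill a class quota the split fails loudly rather than silently
  relaxing the constraint.

Murcko frameworks are computed by iteratively pruning terminal atoms of
the molecular graph and canonicalizing the remaining ring-and-linker
subgraph; acyclic molecules share the empty scaffold string `""`, which in
practice puts them in the training set (their shared "scaffold" is
common). Classifiers are Random Forests of 200 gini trees with sqrt(p)
features per split and unlimited depth; the predicted probability is the
fraction of trees voting toxic. The decision threshold is chosen by
5-fold stratified cross-validation within the training set: out-of-fold
probabilities are pooled, candidate thresholds are the midpoints of sorted
unique pooled probabilities plus 0 and 1, and the threshold maximizing CCR
(balanced accuracy, the mean of sensitivity and specificity) is selected,
ties broken toward the smallest threshold (favouring sensitivity). The
pooled-predictions variant was chosen over per-fold threshold averaging
because it uses every out-of-fold prediction in a single decision problem;
the boundary rule is *toxic iff p ≥ threshold*. ROC AUC is computed by the
trapezoidal rule (equal to the Mann–Whitney formulation, which the tests
assert), average precision as the step-sum of precision × Δrecall.
Randomized split designs can be repeated (20 repeats by default in the
run configuration) with seeds derived as base + index; means and
Bessel-corrected SDs are reported. Feature importances are normalized
impurity (mean Gini decrease) importances; the disagreement analysis
restricts to compounds classified differently by two models and reports
per-class fractions correct.

## The synthetic study generator

The generator emulates the *shape* of the real data landscape, not its
chemistry: a compound library assembled from a packaged grammar (15 ring
scaffolds × 30 substituents, with 5 toxicophore fragments plantable at a
second substitution site), several authoritative sources with partial,
overlapping coverage and ±1-category label noise (clamped to 1–5; implied
nontoxics are noise-free), an ECHA-style notification count table with
multinomial noise, a sparse assay matrix with the 0 / (0,40) / [40,100]
score semantics, 11% missing cells and 36% duplicated measurements, and
per-target training sets designed so that linked targets pass the
reliability filter while a dissimilar-chemistry target fails the Tanimoto
criterion and a chemotype-mismatched target fails the recall criterion —
making the filter's selectivity assertable by construction.

Ground truth follows a logistic link: P(toxic) =
plogis(intercept + Σ βᵢxᵢ) over planted fragment indicators and target
activity indicators; the class is a Bernoulli draw and the GHS category is
drawn conditional on the class (toxic → 1–3; nontoxic → 5 or implied
nontoxic; category 4 arises only through observation noise). The default
coefficients (+8 structural, +6 target-mediated, intercept −3.5, fragment
rates 0.06) were fixed once at design time by enumerating the
Bayes-optimal AUC of the latent model over all feature combinations
(≈ 0.99, toxic prevalence ≈ one third): a consistent learner must be able
to approach that ceiling, so planted-signal recovery (random-split RF
AUC ≥ 0.9) is a property of the generator, not of a tuned test. Under a
Bernoulli class draw, weaker coefficients (|β| ≈ 3) cap the Bayes AUC
near 0.89 irrespective of the learner, which is why the reference study
uses strong ones.

What the generator does **not** emulate: real pharmacology (no LD50 is
modelled — the pipeline consumes categories, and a latent-dose model would
add nothing it can see), realistic chemical diversity (a closed grammar of
valid products), 3D structure, or the noise structure of real notification
data (the multinomial model is a stand-in, not a claim about any agency's
data). Consequently, green tests demonstrate correctness of the
*computations* and recoverability of *planted* signal; they say nothing
about the predictability of real acute toxicity.

## Problem sizes and determinism

The test suite runs the generator at 100–400 compounds for unit checks and
at 2000 for the end-to-end signal-recovery and null-calibration checks;
the brute-force nearest-neighbour oracle runs at n = 300, the discriminant
recovery check at n = 5000 Gaussian points, and the permutation null for
enrichment at 200 relabellings — sizes at which each property is sharp
while the suite stays quick. All randomness flows from explicit seeds:
one master seed is split into per-stage substreams by hashing the stage
name, so any stage can be reproduced in isolation and two runs of the
pipeline with the same configuration produce byte-identical manifests
(asserted in the tests). `scripts/acceptance.R` re-runs the full analysis
at n = 2000 from a command-line seed.

## Known limitations

* OpenBabel's neutralize/canonicalization differs from proprietary
  standardizers; InChI-level identity absorbs most but not all of the
  difference.
* The Murcko convention here prunes exocyclic multiply-bonded atoms
  (pure framework); toolkits that retain them would split a few molecules
  differently.
* The descriptor set is open and namespaced; models trained on it are not
  comparable coefficient-for-coefficient with proprietary descriptor
  models.
* Fisher-exact enrichment with the +0.5 correction biases odds ratios of
  empty cells toward finite values by construction; the uncorrected
  estimator is available where exact reproduction of a zero-cell
  convention matters.
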