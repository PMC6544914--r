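# ghstox

Pooling regulatory GHS acute-toxicity annotations and modelling them with
heterogeneous descriptors.

## The problem

Public inventories publish acute toxicity classifications under the
Globally Harmonized System (GHS): per exposure route, a compound falls in
category 1 (most severe) through 5, defined by LD50 intervals. Several
authoritative sources overlap only partially and sometimes disagree, and
industrial notification tables add per-category submission counts rather
than a single label. `ghstox` is for computational toxicologists who want
to (a) pool these statements into one harmonized per-route label per
compound, (b) derive a binary acute **oral** toxicity endpoint, and (c)
ask how well that endpoint is carried by three descriptor domains —
2D molecular descriptors, predicted protein-target bioactivity
probabilities, and qHTS assay scores — via structural-alert enrichment,
class-separation analyses, and Random Forest classifiers evaluated over
three train/test split designs of increasing difficulty.

The core rules, in the field's notation:

* **Implied nontoxicity** — presence in an authoritative GHS source with
  no acute-toxicity category for the route is read as nontoxic for that
  route (hypothetical category 6).
* **Notification rule** — category *c* qualifies iff the cumulative
  fraction of notifications at *c* or more severe is ≥ 10%; the most
  severe qualifying category is used, and authoritative labels always take
  precedence.
* **Binary endpoint** — categories 1–3 → toxic; 5 and implied nontoxic →
  nontoxic; category 4 → excluded.
* **Target descriptors** — per-target tree ensembles on 2048-bit circular
  fingerprints, Platt-calibrated; a model is used only if recall on its
  training/query overlap ≥ 0.5 and the training set's mean
  nearest-neighbour Tanimoto to the query set > 0.25; known actives are
  set to probability 1.
* **qHTS features** — per (compound, assay) activity score in [0, 100]
  (0 inactive, 40–100 active, between inconclusive), median over repeats,
  missing → 0, cosine distances.
* **Models** — Random Forests (200 gini trees, √p features per split);
  decision threshold maximizing CCR = (sensitivity + specificity)/2,
  chosen by 5-fold cross-validation within the training set; splits:
  class-stratified *random* 20%, *rare scaffolds* (Murcko framework
  frequency ≤ 2), and *single source* (compounds covered by exactly one
  authoritative source).

Real regulatory extracts cannot be shipped, so the package includes a
synthetic-study generator with a known logistic ground truth (planted
toxicophore fragments and target activities); every pipeline stage is
validated against it. See the methods vignette
(`vignettes/ghstox-methods.Rmd`) for the model and all conventions.

## Worked example

Generate a small synthetic study, harmonize its GHS observations, and train
a molecular-descriptor Random Forest on the random split:

```r
library(ghstox)

study  <- generate_study(generator_config(n_compounds = 300, seed = 42))
labels <- harmonize_labels(study$observations)
oral   <- labels[labels$route == "oral", ]
bin    <- binarize_oral(oral$category)
y      <- setNames(bin, oral$compound_key)[bin != "excluded"]

smiles <- setNames(study$library$smiles, study$library$compound_key)[names(y)]
std    <- setNames(smiles_standardize(smiles), names(smiles))
mol    <- compute_molecular_block(std)

split  <- random_split(y[rownames(mol$values)], 0.2, seed = 7)
fit    <- run_split_model(mol$values, y[rownames(mol$values)], split,
                          "molecular", ntree = 200, seed = 7)
fit
```

```
<ghs_model_report> random / molecular
  threshold 0.600 | ROC AUC 0.940 | AP 0.944 | sens 0.889 | spec 0.846 | CCR 0.868
```

The threshold is the CV-selected CCR optimum on the training side; ROC AUC
and average precision summarize ranking quality on the held-out test side,
and sensitivity/specificity/CCR are evaluated at that threshold. On this
synthetic study the toxicity signal is planted (strong logistic
coefficients on five toxicophore fragments and two target activities), so
an AUC near 0.9 means the pipeline recovered the planted structure-toxicity
relationship from descriptors alone; with all generative coefficients set
to zero the same pipeline yields AUC ≈ 0.5.

The full pipeline — collation, structure standardization and filtering,
descriptor assembly, toxicophore enrichment, class separation, and all
split × descriptor-combination models — runs as one call and writes a
report bundle (CSV tables plus a `manifest.json` with seeds, a config hash
and per-stage counts):

```r
res <- run_pipeline(run_config(generator = generator_config(n_compounds = 300,
                                                            seed = 42),
                               out_dir = "ghstox_out", seed = 42))
res$reports[res$reports$descriptor_combo == "molecular",
            c("split_name", "roc_auc", "ccr")]
```

```
      split_name   roc_auc       ccr
1         random 0.9658120 0.9059829
5 rare_scaffolds 0.8172269 0.7531513
9  single_source 0.9985755 0.9622507
```

A thin command-line wrapper is included at `inst/scripts/ghstox.R`
(`generate` and `run` subcommands over a YAML config).

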