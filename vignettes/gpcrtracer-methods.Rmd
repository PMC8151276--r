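---
title: "Models and methods behind gpcrtracer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gpcrtracer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Competitive NanoBRET ligand-engagement assays read out binding between a
fluorescent tracer and a HiBiT-tagged GPCR as a drop in BRET when the
unmodified parental compound displaces the tracer. Because the signal is
restricted to the tagged receptor, one *promiscuous* tracer scaffold can
power assays across many receptors — if such scaffolds can be found.
`gpcrtracer` implements an in-silico-first workflow: learn, from a large
corpus of known ligand–family associations, which fingerprint patterns
characterize each GPCR family; read the classifier's full probability
distribution as a promiscuity prediction for candidate scaffolds; and
score those predictions against empirical competitive-screen data.

# Dataset construction

Raw association tables aggregate heterogeneous sources and are heavily
redundant: the same molecule appears under many receptors and species,
and popular scaffolds recur with minor spelling differences. The pipeline
therefore proceeds:

1. **Ingestion filter** — keep human-annotated records with a compound
   identifier and a parseable SMILES (parse failures are counted and
   dropped). Structures are canonicalized at this step.
2. **Deduplication** — one record per (canonical structure, family) pair.
   Keying on the canonical form, not the string, is what makes two
   spellings of phenol collapse. A compound associated with *k* families
   deliberately keeps *k* records: multi-family membership is signal, not
   redundancy, in this task.
3. **Family-size threshold** — families with fewer than 700 unique
   compounds are removed; below that, a family contributes too little
   chemical diversity to learn from.
4. **Balanced selection** — exactly 530 compounds per family, uniformly
   at random without replacement, to remove class imbalance while
   retaining most diversity. With 45 families this yields 23,850 records.
5. **Stratified split** — per family, `floor(0.7·n)` records to training
   (371 of 530) and the rest to test (159), so the class balance is exact
   in both partitions.

All random draws flow from one documented integer seed; the split is a
partition (train ∩ test = ∅, |train| + |test| = |selected|).

An *open point we had to decide*: when a compound recurs across receptors
within one family, the balanced selection operates on unique
compound–family pairs (dedupe first), not on raw interaction rows. The
counts above are only consistent under that reading.

# Fingerprint encoding

Each molecule becomes one numeric vector of **758 positions**, three
blocks concatenated in fixed order:

| block | positions | content |
|---|---|---|
| MACCS | 1–167 | binary structural keys; position 1 is the reserved key of the public 167-key indexing convention and is always 0 |
| E-State | 168–246 | integer atom-type counts over the complete 79-type electrotopological scheme |
| functional groups | 247–758 | 512 binary substructure slots |

The arithmetic wrinkle: 166 + 79 + 512 = 757. The stated total of 758 is
honoured by carrying the MACCS block with its reserved position 1, the
usual public-key convention; we flag this as an inference rather than
assert it as intent.

The 512-slot block is defined by a SMARTS dialect shipped with the
package (`extdata/fgfp_smarts_synthetic.tsv`, 150 named functional-group
patterns; unassigned slots stay 0). The historical Open Babel FP4 pattern
file could not be redistributed or computed offline, so this dialect is a
**synthetic stand-in**, frozen with the package so that encodings are
stable. It preserves the block's role (functional-group presence bits) but
not the exact historical bit assignments.

Parsing, canonicalization, MACCS keys, E-State typing and SMARTS matching
are delegated to RDKit via a bundled Python helper; encodings are
deterministic and invariant to SMILES spelling.

**Near-zero-variance filter.** Fingerprint positions that are constant or
almost constant carry no signal and slow training. Fit on training rows
only, a column is removed iff it has a single unique value, or its
frequency ratio (most common value count / second most common) exceeds
`freq_cut = 95/5 = 19` while its percent of unique values
(100·distinct/rows) is below `unique_cut = 10`. These are the defaults of
the framework that popularized the rule; we keep them. The resulting mask
is applied unchanged to test data — it never consults test rows. On an
8-family synthetic training set the mask typically retains ~180 of 758
positions; the exact count is data-dependent.

# Family classifier

A 500-tree random forest maps masked fingerprints to family labels.
The only tuned hyperparameter is features-per-split (`mtry`), selected by
mean accuracy over stratified 5-fold cross-validation repeated 10 times
on a 3-value grid centred on √p, then refit on the full training set.
Five hundred trees and a √p-centred grid mirror common defaults for this
model family; centering/scaling is omitted because forests are invariant
to monotone feature rescaling. Training runs in scikit-learn with a
single thread and a fixed seed, so fits are reproducible.

Evaluation builds the K×K confusion matrix (rows true, columns
predicted). Per family, one-vs-rest counts give

* Accuracy = (TP + TN) / (TP + FN + TN + FP)
* Sensitivity = TP / (TP + FN)
* Specificity = TN / (TN + FP)

on the percent scale; overall accuracy is the trace over the total. With
~44 negative families per positive one, specificity is structurally
biased high — worth remembering when reading per-family tables.

Top-1 prediction is the probability argmax with a deterministic
tie-break: the first family in the model's class-label order.

**Randomized-label control.** Permuting labels, retraining, and scoring
on a held-out 30% should drop accuracy to chance (1/K); the acceptance
suite checks the control lands inside the 99% binomial CI of 1/8 on the
8-family fixture. We treat a reported control accuracy of "0.02%" in the
literature for a 45-class task as a scale typo — chance there is ≈2.2% —
and assert ≈1/K.

# Promiscuity profiles

Class probabilities are rescaled to 0–100% (each compound's profile sums
to 100). Every family with probability **≥ 4%** — inclusive — is a
predicted interaction. Two modes are deliberately distinct: top-1
classification always returns a family, while the promiscuity screen may
return an empty set when nothing clears the threshold; forcing the top
class there would manufacture false positives. Raising the threshold can
only remove calls (monotonicity), which the sweep tests rely on.

# Chemical-space map

For visual/quantitative cluster analysis the MACCS block alone is
embedded to 2-D with UMAP. Binary structural keys call for Jaccard
(Tanimoto) distance; since the R UMAP backend lacks a Jaccard metric, we
compute the distance matrix directly and embed it. Defaults: 50
neighbours (the setting that balanced spread against family clustering in
a 10–400 sweep), `min_dist` 0.1 (library default; the method source does
not state one), single-threaded SGD under a fixed seed for bitwise
reproducibility. Silhouette of family labels on the embedded coordinates
is the quantitative readout; on two single-scaffold synthetic families it
exceeds 0.5, and it always beats label-permuted silhouette.

# Screen statistics

* **BRET ratio** = acceptor emission (600 nm long-pass) / donor emission
  (450 nm). Donor must be positive; negative acceptor values are rejected.
* **Fold response** = BRET of tracer-alone wells / BRET of paired
  tracer-plus-competitor wells, after averaging replicate wells per
  condition (the source protocol does not say whether single wells or
  duplicate means were used; we average). Positive iff fold ≥ 1.5,
  inclusive, with a 1e-12 relative epsilon so decimal-exact boundary
  cases such as 0.15/0.10 are not lost to binary floating point.
* **Signal/noise** = (BRET_tracer − mean(controls)) / SD(controls), with
  the *sample* (n−1) standard deviation — the spreadsheet convention the
  original STDEV most likely denotes. Zero-spread controls yield NA with
  a warning rather than an infinite score.
* **Screen summary** reports, per (construct, tracer, concentration),
  both BRET values, fold, signal/noise and the call; the profile
  attribute lists constructs positive at each concentration and those
  *retained* — positive at the lowest tested concentration (0.1 µM in
  the reference protocol), the stricter and more assay-predictive call.
* **Saturation binding**: tracer-alone BRET minus paired
  competitor-blocked BRET gives the specific signal, fit by least squares
  to the one-site hyperbola `B(c) = Bmax·c/(EC50+c)` (no Hill slope —
  the reference data show simple saturation). The port algorithm with
  positivity bounds is used; non-convergence or an all-negative corrected
  signal returns a `converged = FALSE` result, never an error.

# Concordance

Predictions (scaffold × family calls at ≥ 4%) are compared cell-wise with
screen confirmations consolidated by the **any-member rule**: a family is
confirmed for a scaffold iff any member construct showed fold ≥ 1.5 for
any tracer candidate at any tested concentration. The 2×2 tally uses the
same three formulas as the classifier metrics, plus the
positive-confirmation rate TP/(TP+FP). The threshold sweep recomputes the
table per candidate threshold and reports the maximizer of **balanced
accuracy** — the stated selection criterion in the source is qualitative
("best balance between accuracy and false predictions"), so we made the
criterion explicit and configurable. Manual verifications obtained by
cross-displacement of other tracers enter the confirmation matrix as
curated overrides supplied by the user, not computed calls.

A worked identity the acceptance suite pins down: with 612 cells, 82
predicted positives of which 56 confirmed, and 530 predicted negatives of
which 512 confirmed, overall accuracy is (56+512)/612 = 92.8% and the
positive-confirmation rate 56/82 = 68.3%. The companion printed values
97.2% (vs 512/530 = 96.6%) and sensitivity/specificity 76.7%/94.9% do not
reconcile with those counts under the stated formulas; the package
reports formula-consistent values only.

# The synthetic-data world

The generator states one fixed world; its defaults are not tuned against
test outcomes.

* **Chemistry**: 19 verified drug-like scaffold templates, two open
  positions each, decorated from a pool of 21 small substituents.
  Families own disjoint template subsets while the library lasts (beyond
  19 assignments templates recycle with a warning). Compounds are drawn
  *without replacement* from a family's template × substituent² space, so
  within-family structures are unique by construction and within-family
  Tanimoto similarity exceeds between-family similarity — the clustered
  structure real family-specific SAR series produce.
* **Artifacts**: `promiscuous_fraction = 0.05` of compounds gain a second
  family record (promiscuity is rare by construction);
  `duplicate_rate = 0.10` exact duplicates and `nonhuman_rate = 0.15`
  non-human re-reports emulate aggregation redundancy. The source
  corpus's redundancy is described only anecdotally (a most frequent
  molecule occurring 120 times), so these two rates are free choices,
  fixed once.
* **Plates**: donor fixed at 10⁶ counts, acceptor = BRET × donor with
  Gaussian noise on the acceptor channel — any decomposition consistent
  with the ratio is acceptable, and this one is the simplest.
  `background_bret = 0.1`, `true_fold_response = 2.0`, and
  `noise_sd = 0.007`, calibrated so that a 1.5-fold response corresponds
  to ≈7-fold signal over noise, the empirical relationship reported for
  the reference screen. Triplicate wells by default.
* **Saturation**: Bmax 0.2 BRET units, EC50 50 nM (mid-range of the
  1–600 nM reference span), eight 2-fold dilutions from 1000 nM.

What the generator does **not** emulate: real structure–activity
relationships (labels follow scaffolds, not pharmacology), peptide/lipid
ligands, inter-plate drift, dye photophysics, or nonspecific-background
pathologies. A green classifier test therefore establishes that the
pipeline learns family-specific chemical signal when it exists and not
when labels are permuted — it does not predict accuracy on real corpora,
where published figures are far below the synthetic 100%.

# Numerical choices and degenerate inputs

* Inclusive thresholds throughout (≥ 4%, ≥ 1.5-fold), with the epsilon
  guard noted above only where a ratio crosses the decimal boundary.
* Argmax ties break to the first class label; sweep ties break to the
  first threshold attaining the maximum.
* All-zero feature rows predict (they land wherever the forest's priors
  put them) rather than erroring; empty profiles are legal outputs.
* The NZV filter is monotone in `freq_cut` (raising it never removes more
  columns) — a property test, since off-by-one comparisons at the 19
  boundary are an easy bug.
* CV in the acceptance test runs 5 folds × 2 repeats instead of × 10
  purely for wall-clock budget; defaults keep 5 × 10.

# Known limitations

* The functional-group block is a package-defined dialect, not the
  historical FP4 bit assignment; models trained here are not
  fingerprint-compatible with encodings from that toolchain.
* The Python backend is a process boundary: large matrices cross it as
  CSV, which is robust but not fast; at the package's synthetic scales
  (≤ a few thousand compounds) this is seconds.
* The UMAP step materializes an n × n distance matrix; fine to a few
  thousand compounds, not to corpus scale.
* Published corpus-scale figures (e.g. ~81% test accuracy over 45
  families, 758→187 feature reduction) depend on the external corpus and
  are documented context here, not reproduced claims.
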