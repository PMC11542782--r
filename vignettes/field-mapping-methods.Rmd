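---
title: "Metric-learning for eCRF-to-SDTM field mapping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metric-learning for eCRF-to-SDTM field mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Submitting clinical-trial data to regulators requires tabulating it in the
CDISC Standard Data Tabulation Model (SDTM). The data, however, are captured
in electronic data capture (EDC) systems whose forms are designed for site
usability, not for SDTM, so every study needs a curated mapping from each
electronic case report form (eCRF) field to its SDTM variable (e.g. the
"Date of Death" field of an `EXPIRATION` form maps to `DTHDTC`). Curators
work from four pieces of field metadata: the form identifier (FormOID), the
field identifier (FieldOID), the field prompt (PreText, possibly carrying
HTML markup) and its supplementary hint (PostText, typically a parenthesized
unit or format). That humans can map fields from this metadata alone
suggests the metadata suffices for a model to do the same.

The obstacle is the shape of the data: many target classes, few examples per
class, heavy class imbalance, OID jargon absent from general vocabularies,
and only partial vocabulary overlap between the studies one trains on and
the studies one must map. `crfmapr` addresses this with metric learning: a
Siamese network trained on *pairs* of fields, which turns N labeled records
into O(N²) training examples.

## Model

Each field's four metadata strings are HTML-stripped, concatenated in the
order FormOID, FieldOID, PreText, PostText, lowercased, tokenized on
whitespace (outer punctuation stripped, so `(mmHg)` becomes `mmhg` and
`DIAST_BP_VAL` stays one token), and dictionary-encoded: the first token
seen in the training stream is 1, the next new token 2, and so on, with 0
reserved for out-of-vocabulary tokens and padding. Sequences are padded or
truncated to a fixed length, by default the longest training sequence.

The shared subnetwork is

* a trainable token lookup table mapping the vocabulary to 256 dimensions
  (no pre-trained embeddings: OIDs and trial jargon are not in public
  corpora, which is precisely what pre-trained vectors fail on),
* an LSTM with 64 units and tanh cell activation returning its full state
  sequence (tanh keeps the embedding components centered on zero),
* a flattening of the per-position states,
* an affine projection to a 32-dimensional embedding.

Two copies of this subnetwork with one shared parameter set embed the two
members of a pair; the similarity head is the Euclidean distance
d = sqrt(Σᵢ (xᵢ − yᵢ)²) between the embeddings. The pair target is 0 for
same-class pairs and 1 for different-class pairs, so training pulls fields
that map to the same SDTM variable together and pushes others beyond unit
distance.

### Loss and head placement

The output activation is a sigmoid, but its exact placement relative to the
distance, and the loss, are genuinely open design points. We model the
output as s = sigmoid(γ·(d − 1)) with γ = 4 (`distance_scale`), regressed
toward the 0/1 target with binary cross-entropy. This centers the decision
boundary at d = 1 (s = 0.5), and at d = 0 gives s ≈ 0.02, so same-class
pairs saturate near zero loss once collapsed. A contrastive loss with
margin 1 — (1−t)·d² + t·max(0, 1−d)² — is available via
`siamese_config(loss = "contrastive")`; on the synthetic corpora both
separate classes, and the sigmoid/BCE head is the default because it
matches the published architecture's final activation.

### Training

Optimization is Adam at learning rate 1e-3 (a package convention — the
architecture prescribes no optimizer), 3 epochs, batch size 64, with 20
same-class and 20 different-class pairs per training record. Same-class
partners are drawn uniformly with replacement, never pairing a record with
itself; records whose label has no second member contribute no same-class
pairs and are reported. Both twins are evaluated as one stacked batch, so
the summed gradient is exactly the shared-weight gradient. Initialization
(Glorot uniform, forget-gate bias 1, lookup entries U(−0.05, 0.05)) and
epoch shuffles all derive from `config$seed`; training twice with one seed
reproduces embeddings bitwise. No masking is applied to index 0: padding
and OOV share one lookup row, the simplest consistent treatment.

Dimension note: descriptions of this architecture circulate with both a
32-dimensional and a 20-dimensional embedding; this package uses 32 (the
dense layer width), and `embedding_dim` is configurable for anyone who
prefers 20.

### Leakage discipline

The stratified holdout split happens **before** anything else. The
vocabulary, the encoded sequences, all training pairs, and the k-NN
reference index derive from the training side only; `train_field_mapper()`
receives only the training corpus, so deleting the held-out records cannot
change the trained encoder (a regression test asserts bitwise-identical
probe embeddings). Held-out records containing tokens unseen in training
encode those tokens to 0 — the out-of-vocabulary failure mode that caps
real-world holdout accuracy, exercised deliberately by the generator's
novel-token injection.

## Suggestion and evaluation

Prediction embeds a query field and runs an exact k-nearest-neighbour
search (k = 5) against the indexed training records, answering three
auto-suggest questions: is the true variable among the 5 neighbours
("contains"), is it the nearest neighbour's class ("nearest"), is it the
plurality class of the 5 ("majority"). Containment-mode accuracy dominates
the other two by construction, since both the nearest and majority labels
are members of the top-5 label set. Distance ties break by ascending record
reference and vote ties by the tied class with the nearest member — both
package conventions chosen for determinism.

Metrics are overall accuracy and macro-F1 (unweighted mean of per-class F1
over the classes present in the truth set, zero-division counted as 0), so
rare SDTM variables weigh as much as abundant ones. For the containment
mode, which returns a set rather than a label, macro-F1 scores the
effective prediction "true label if contained, else the nearest label" — a
package convention, documented here because macro-F1 needs a single label
per record. Held-out labels never seen in training count as misses in all
modes and are flagged in the per-class table rather than dropped, matching
deployment reality.

The headline protocol is a 20% stratified holdout; stratified k-fold
cross-validation (`cross_validate()`, default 5 folds, vocabulary and pairs
rebuilt per fold) is exposed separately, since the two protocols answer
different questions. `pca_project()` gives the
2-D principal-component view of the embedding space (sign fixed per
component by its largest loading) used for the cluster plots.

## The baseline

`evaluate_baseline()` is the traditional comparator: TF-IDF (document
frequency floor 2, natural term counts, smoothed idf log((1+N)/(1+df))+1,
L2 row normalization, the most common TF-IDF convention) over the *same*
concatenated, normalized text, classified
by multiclass gradient-boosted trees (xgboost, default max_depth 6, eta
0.3, 100 rounds, single-threaded, seeded). It shares the splitter, so a
run on the same seed is a controlled head-to-head comparison of
representations. A pre-trained-transformer comparator is deliberately out
of scope (it requires downloaded weights); its published protocol (batch
48, 100-word cap, 9 epochs) is noted here for anyone adding one.

## What the synthetic generator emulates

Real annotated-CRF corpora are proprietary, so `generate_corpus()` builds
labeled corpora with the structure the method's difficulties come from:

* **OID jargon**: UPPER_SNAKE FormOIDs/FieldOIDs that tokenize to single
  out-of-dictionary-style tokens, unique to a class;
* **source-form variants** (`variants_per_class`, default 6): each class's
  records arise from several variants with their own OIDs and a little
  variant-specific phrasing, emulating the same SDTM field collected on
  different forms across trials. This is what makes support matter: a
  class with few training records cannot cover its variants, so held-out
  records from uncovered variants carry only OOV OIDs;
* **natural-phrase PreText** from a class vocabulary mixed with shared
  form boilerplate at `shared_token_fraction` (default 0.3 — lower is
  easier; the dial demonstrably controls task difficulty);
* **parenthesized PostText format hints** (`(mmHg)`, `(MM/DD/YYYY)`, ...);
* **HTML wrappers** on a fraction of PreTexts (default 0.15), so the
  stripping path is exercised;
* **confusable groups**: classes sharing one PreText/PostText pool and
  differing only in OIDs — the cross-domain failure mode in which an
  adverse-event end date is mistaken for a medication end date;
* **class imbalance** via explicit supports or the `"figure4"` ladder
  {10, 25, 50, 100, 200};
* **partial train/test vocabulary disjointness** via `oov_injection_rate`:
  injected tokens are globally unique, so wherever those records land
  after splitting they are OOV to the other side.

What it does **not** emulate: real OID naming conventions of any vendor,
multi-domain pivoted/unpivoted table structure, composite or calculated
fields, multi-target mappings (composite labels like `AESTDTC/CMSTDTC` are
treated as opaque strings throughout), and realistic token frequency
distributions — the curated lexicon is arbitrary clinical-flavoured
vocabulary. Passing tests on these corpora show the pipeline learns the
intended invariances (OID memorization, phrase similarity, robustness to
markup and OOV); they do not certify accuracy on any proprietary corpus.

## Reference experiments and problem sizes

Test-suite and acceptance-script experiments run at desk scale, chosen so
the full default model (256/64/32, 3 epochs) trains in minutes on one CPU:

* **Balanced reference corpus**: 10 classes × 150 records,
  `shared_token_fraction` 0.3. The default pipeline reaches containment-mode
  accuracy ≥ 0.9 and nearest-mode accuracy ≥ 0.8 here, and classifies its
  own training pairs at ≥ 0.99 — the qualitative pattern of the published
  full-scale results, not a numeric reproduction of them, which the
  proprietary corpus makes impossible.
* **Support ladder**: supports {10, 25, 50, 100, 200} arranged in
  confusable pairs that span the ladder, with `variants_per_class` 12,
  `shared_token_fraction` 0.7 and 15% OOV injection. Twelve variants exceed
  what 8–20 training records can cover, so low-support classes are starved
  of exactly the information the confusable pairing makes necessary; high
  shared fraction keeps PreText from rescuing them. Per-class accuracy then
  rises with training support (positive Spearman correlation), the
  qualitative support-dependence of the full-scale study.
* **Stress comparison**: confusable pairs plus 20% OOV injection, where the
  embedding method must stay within 0.05 macro-F1 of the TF-IDF baseline
  under the identical split.

Choices of this kind (corpus sizes, the difficulty dials of each
experiment) are fixed once in the test code with fixed seeds and are not
tuned per run.

## Numerical and degenerate-input behavior

* Distances add 1e-12 under the square root during training, so collapsed
  pairs have a finite gradient; `pair_distance()` itself is exact.
* BCE probabilities are clamped to [1e-12, 1 − 1e-12]; a non-finite loss
  aborts training with the epoch in the error.
* All-zero (fully OOV) sequences are legal everywhere and embed to finite
  vectors.
* Corpora with a single label are rejected before pairing (no negative
  pairs exist); singleton-label records go to the training side with a
  warning and contribute only different-class pairs.
* Encoder archives carry a format stamp; truncated or foreign archives are
  rejected on load.

## Known limitations

* Pure-R training: the LSTM forward/backward is batched dense linear
  algebra, fast enough for corpora of a few thousand records but not for
  the 1827-token maximum sequences reported for real corpora — use
  `max_len_cap` there.
* The k-NN suggester is exact and O(n·q); appropriate at these corpus
  sizes, not for millions of reference rows.
* One field maps to one label; multi-target fields are only supported as
  composite opaque labels.
* Character-level encoding, two-step domain-then-field prediction and
  attention/Shapley interpretability are out of scope.
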