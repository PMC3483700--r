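---
title: "Predicting Enzyme Commission numbers from signature sets: model, metrics and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting Enzyme Commission numbers from signature sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecknn)
```

## The problem

Enzymatic function is classified by the Enzyme Commission (EC) nomenclature:
a four-field code such as `1.2.3.4`, where the leading fields give an
increasingly specific reaction class and the last the substrate class.
Manual curation of EC annotations cannot keep pace with sequencing, so
`ecknn` predicts the complete set of EC numbers of a protein from a purely
sequence-derived representation: the presence or absence of conserved
sequence signatures (InterPro-style domain and motif identifiers), one
binary attribute per signature. The task is *multi-label*: a protein can
carry several EC numbers (multiple catalytic sites or a regulated site), an
incomplete EC such as `1.2.-.-` (a legitimate class when the finer
classification is unresolved), or none at all — the non-enzyme outcome,
which also absorbs not-yet-characterised enzymes.

## Label model

Labels are canonical four-field strings (`"1.2.-.-"`). Three rules shape
the label space:

* **Hierarchical expansion at assembly time.** A stored annotation
  `1.2.3.4` becomes the chain {`1.-.-.-`, `1.2.-.-`, `1.2.3.-`, `1.2.3.4`}
  for training and truth alike. This lets an exact-match criterion reward
  partially specific predictions consistently and lets incomplete
  annotations contribute at their level; it also means a fully annotated
  enzyme typically carries about four labels.
* **Incomplete ECs are leaves of their own.** A protein annotated only
  `1.2.-.-` keeps that label as its most specific class.
* **Status remapping.** Nomenclature entries are active, deleted or
  transferred; deleted ECs are dropped from annotations and transferred
  ones substituted, transitively, by all their replacements (cyclic
  transfer tables are rejected). A complete EC absent from the status
  table is treated as active and passed through with a warning — the
  practical choice when the table is a partial export rather than the full
  nomenclature release.

Label spaces are hierarchically closed and ordered numerically
(lexicographic by components, ancestors first), which fixes the column
layout of exported files.

## The classifier

`brknn()` implements binary-relevance k-nearest-neighbour. Binary relevance
turns a q-label problem into q one-vs-rest decisions, but all q decisions
for a query reuse one distance computation — the whole point of the
algorithm on label spaces with thousands of classes. Over binary vectors
the Euclidean distance is `sqrt(|symmetric difference|)`, so squared
distances are integers; the implementation computes them blockwise from
sparse cross-products (`|a| + |b| - 2 a·b`).

Numerical and tie-handling conventions, chosen here and documented as this
package's contract:

* **Neighbour ties.** The neighbour set is the k nearest training
  instances *plus every instance tied with the k-th distance* (exact
  integer comparison, no epsilon). This makes predictions deterministic
  and independent of training-set order.
* **Decision threshold.** A label is predicted when its confidence — the
  fraction of the neighbour set carrying it — is at least 0.5. At k = 1
  without ties this reduces to copying the nearest neighbour's label set.
  The threshold is exposed (`threshold =`) for exploration.
* **Unknown query signatures** (absent from the training vocabulary) are
  ignored: under a binary attribute model they would add the same constant
  to every squared distance of that query, leaving the neighbour ranking
  unchanged. A warning reports how many occurrences were dropped.
* **Non-enzyme confidence.** The empty call is scored `1 - max` label
  confidence (1 when the neighbour set carries no labels at all), so
  downstream consumers can rank no-EC calls.
* **Unseen classes.** A lazy learner can only emit labels present in its
  training data; classes occurring only in a held-out set are never
  predicted, and the evaluation keeps them scoreable by fixing the label
  universe to the full dataset's space.

Two baselines frame the classifier. `zero_rule()` predicts the modal exact
label set of the training data for every instance (ties broken toward the
empty set, then lexicographically) — with a non-enzyme majority it scores
exactly the non-enzyme fraction. `transitive_mapper()` assigns the
expanded union of ECs mapped from a query's signatures through a
signature-to-EC list, with confidence 1.

## Evaluation

`subset_accuracy()` is the headline metric: the fraction of instances whose
predicted set exactly equals the true set; empty-vs-empty counts as a
match. `micro_macro_example_metrics()` adds micro averaging (pooled
confusion counts; frequent classes dominate), macro averaging (unweighted
per-label mean; rare classes weigh equally) and example-based averaging
(per-instance set overlaps). Undefined-ratio conventions: macro averages
skip labels with no true and no predicted occurrence in the evaluated set;
a label with positives but no predictions contributes precision 0 (and
symmetrically recall 0); an instance with empty truth and empty prediction
contributes 1.0 to the example metrics, consistent with subset accuracy
rewarding correct non-enzyme calls. Whether never-occurring labels should
instead enter macro averages as zeros is not decidable from the protocol
this package follows; the chosen convention is the one stated above.

`cross_evaluate()` runs seeded n-fold cross-evaluation: a seeded shuffle,
contiguous fold slicing (sizes differing by at most one), two independent
rounds by default for datasets under 40,000 instances (one above, both
overridable), and per-fold metrics with mean and standard deviation.
`leave_group_out()` is the jackknife protocol: hold out one group (for
example a species' proteome), train on the rest, score the group — or the
inverse, training on the group alone. `per_main_class_accuracy()` and
`digit_histogram()` give the per-main-class and depth breakdowns; the
digit histogram counts the deepest label of each chain once, so one 4-digit
annotation is one depth-4 count.

`significance()` compares two equal-length samples of fold metrics with a
one-sample t statistic, `t = (X - M) / (sd / sqrt(n))`, using only the
reference sample's standard deviation (no pooling), n − 1 degrees of
freedom, and a two-tailed p-value from the t distribution,
`p = 2 (1 - F(|t|))` — the spreadsheet-style convention in which the
t-density function is queried for a two-tailed tail probability. Samples
are declared different at the 5% level.

## File formats

Datasets travel as a sparse attribute-relation (ARFF) file plus a label
hierarchy XML document. The dialect is frozen by this package: every
attribute is declared `@attribute <name> {0,1}`, signature columns first
and label columns after; label attribute names are canonical EC strings
prefixed `EC_` with dots replaced by underscores; data rows are sparse
`{index value, …}` omitting zeros, `{}` for an all-zero instance; each row
is preceded by a `% <accession>` comment carrying the instance id (plain
ARFF parsers skip comments); UTF-8, `\n` line endings. Dense 0/1 rows are
accepted on input. The hierarchy document nests one `<label>` element per
EC label under its parent. Writing is byte-stable, and write→read→write is
byte-identical — the round-trip is enforced by tests. Annotation tables are
two-column delimited text (`protein,EC`, `protein,signature`,
`protein,group`, `member,representative`); an empty EC field marks a
non-enzyme record.

## The synthetic generator

`generate_dataset()` emulates the statistical structure of real enzyme
annotation databases so the whole pipeline can be exercised without
external downloads. Its defaults are the study conditions used throughout
the package's tests:

| parameter | default | rationale |
|---|---|---|
| `non_enzyme_fraction` | 0.45 | non-enzyme share of a doubly-curated protein set |
| `combo_length_mean` | 3.55 | mean signatures per protein |
| `zipf_exponent` | 1.0 | long-tail class frequencies (top 20% of classes carry ~70-90% of annotations) |
| `partial_label_fraction` | 0.09 | share of classes annotated only at 1-3 digits |
| `multi_ec_fraction` | 0.05 | enzymes carrying a second class |
| `empty_vector_fraction` | 0.007 | non-enzymes with no signatures (~0.3% of instances overall) |
| `combos_per_class` | 1-3 | distinct signature combinations per class |

Generative model: classes sharing a 3-digit family prefix share a small
family core of signatures (creating near-neighbour confusability between
related classes); each class owns a few distinct combinations, every
combination containing one *anchor* signature private to it. Non-enzymes
draw from a disjoint background pool or carry an empty vector. The anchor
construction guarantees that at zero noise the map from signature vector
to label set is a function — identical vectors never carry conflicting
labels — which is what makes noise-free recovery a meaningful correctness
bar; an internal assertion verifies it on every noise-free generation.
For the same reason, incomplete labels are modelled *per class* (a
truncated class is truncated for all its proteins) rather than per
protein: per-protein truncation would plant contradictory duplicates and
turn label incompleteness into irreducible label noise. Label noise is
available explicitly instead, via `corrupt_labels()`, which reassigns the
label sets of a seeded fraction of instances.

`noise_rate` corrupts the *vectors*: each signature present in an enzyme's
combination is dropped with that probability, and with the same
probability one spurious signature from the enzyme pool is added. (A flip
probability applied across the whole vocabulary would produce vectors with
hundreds of spurious signatures — nothing like the sparse 3-4 signature
instances being modelled.)

All stages draw from named sub-streams of one master seed, so a stage can
be regenerated independently and every output (including ARFF export) is
byte-identical across reruns.

What the generator does **not** model: real signature sets' full
subset/superset lattice (only family cores approximate it), taxonomic
structure beyond uniformly assigned group keys, correlated annotation
errors between databases, and the true vocabulary size (tens of thousands
of signatures). Passing tests on synthetic data therefore demonstrate the
correctness of the machinery — distances, ties, expansion, metrics,
protocols — not the accuracy the method attains on real UniProt/KEGG data,
which depends on structure the generator idealises.

## Problem sizes and numerical choices

The test suite and the acceptance script work at 5,000 instances, 200 leaf
classes and 10-fold cross-evaluation — large enough that class long tails,
ties and singleton combinations all occur, while a full run stays
comfortably interactive. Fold slicing uses seeded Mersenne-Twister
shuffles; distances are exact integers (no floating-point tie tolerance);
binomial coefficients for the signature-set combinatorics
(`count_combinations()`) are computed exactly at arbitrary precision with
the multiplicative formula over a base-10^7 big-integer representation,
because `choose(21178, 4)` already sits at the edge of double precision
and larger arguments overflow it entirely.

## Known limitations

* Exact nearest-neighbour search only — no indexing or approximate search;
  prediction is O(train × query) sparse products, practical into the
  hundreds of thousands of instances but not beyond without blocking.
* No learned weighting of signatures; every attribute counts equally in
  the distance.
* Classes absent from training are structurally unpredictable (inherent to
  the lazy learner), so recall against a held-out set with novel classes
  is bounded above by the label overlap.
* EC syntax is validated, but no nomenclature rule checking beyond syntax
  is attempted.
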