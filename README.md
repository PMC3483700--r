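# ecknn

Multi-label prediction of Enzyme Commission (EC) numbers for proteins
represented as sparse binary vectors of sequence-signature presence
(InterPro-style identifiers), with the complete evaluation protocol around
it: subset accuracy and micro/macro/example-based metrics, seeded
cross-evaluation, leave-species-out proteome reannotation, UniRef-style
redundancy reduction, Zero Rule and transitive-mapping baselines, a
significance test for comparing result sets, and a synthetic
annotation-database generator so everything is testable without access to
UniProt, KEGG or InterPro.

The intended users are bioinformaticians doing automatic enzyme function
annotation — assigning the reactions a protein catalyses as one of the first
steps of metabolic reconstruction — and anyone who needs a careful,
reproducible multi-label evaluation harness for hierarchical EC labels.

## The model

Each protein is an instance **x** ∈ {0,1}^p over a vocabulary of p
signatures, carrying a set Y of EC labels. Labels live in the four-level EC
hierarchy: an annotation `1.2.3.4` is stored hierarchically expanded as
{`1.-.-.-`, `1.2.-.-`, `1.2.3.-`, `1.2.3.4`}; incomplete ECs such as
`1.2.-.-` are legitimate classes of their own, and the empty set is the
non-enzyme outcome.

The classifier is **binary-relevance k-nearest-neighbour** (BR-kNN, default
k = 1): a lazy learner that stores the training instances and, per query,
computes the Euclidean distance to every training instance **once**, sharing
it across all per-label binary decisions. Over binary vectors,

    d(a, b) = sqrt(|a Δ b|)      (root symmetric-difference size)

so squared distances are integers and nearest-neighbour ties are exact. The
neighbour set is the k nearest instances plus everything tied with the k-th
distance; each label's confidence is the fraction of the neighbour set
carrying it, and labels with confidence ≥ 0.5 are predicted. At k = 1
without ties this copies the nearest neighbour's label set — the operative
case. The headline metric is **subset accuracy**: the fraction of instances
whose predicted label set is an *exact* match of the true set (predicting
3 of 4 labels of a chain scores zero for that instance).

## Worked example

```r
library(ecknn)

cfg <- synth_config(n_proteins = 1000, n_leaf_classes = 50, seed = 42)
gen <- generate_dataset(cfg)
d <- gen$dataset
d
#> ec_dataset: 1000 instances, 398 signatures, 83 EC labels
#>   550 enzymes (55.0%), 450 non-enzymes; 5 empty signature vectors
#>   group keys: species

folds <- make_folds(d, n_folds = 10, seed = 1)   # 2 rounds below 40,000 instances
cross_evaluate(d, folds)
#> multi-label evaluation over 1000 instance(s), 20 evaluation unit(s)
#>   subset_accuracy    0.9620 +/- 0.0199
#>   micro_precision    0.9982 +/- 0.0057
#>   micro_recall       0.9404 +/- 0.0270
#>   macro_precision    0.9556 +/- 0.0381
#>   macro_recall       0.9255 +/- 0.0443
#>   example_precision  0.9875 +/- 0.0149
#>   example_recall     0.9767 +/- 0.0144
#>   example_accuracy   0.9762 +/- 0.0150

model <- brknn(d, k = 1)
predict(model, subset_dataset(d, 1:3))
#> ec_predictions: 3 instances (1 enzyme calls, 2 non-enzyme calls)
#>   P000001 -> 3.-.-.-; 3.4.-.-; 3.4.3.-; 3.4.3.3
#>   P000002 -> (no EC)
#>   P000003 -> (no EC)

zero_rule(d)
#> zero rule baseline: predicts the non-enzyme outcome for every instance (majority fraction 0.450)
```

Reading: on a noise-free synthetic database with 45% non-enzymes the 1-NN
classifier recovers 96% of instances' exact label sets, against the 45%
majority baseline; micro precision (pooled over labels, dominated by
frequent classes) is near 1, while macro recall — where rare classes weigh
as much as frequent ones — is the lowest metric, as expected for a long-tail
class distribution. `significance()` compares two samples of fold metrics
and here declares the classifier/baseline gap significant at the 5% level
(t = 64.6 on 9 degrees of freedom, p ≈ 3e-13).

A command-line wrapper with `simulate`, `assemble`, `train`, `predict`,
`xval`, `jackknife`, `baseline` and `report` subcommands is installed at
`inst/cli/ecknn` (see `run_cli()`).

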