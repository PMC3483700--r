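# Multi-label evaluation: subset accuracy, micro/macro/example-based
# metrics, cross-evaluation and leave-group-out protocols, per-main-class
# and EC-digit breakdowns, and the one-sample t significance test used to
# compare result sets.

#' Subset accuracy
#'
#' The strictest multi-label accuracy: the fraction of instances whose
#' predicted label set is an exact match of the true set. A prediction that
#' misses even one of an instance's labels scores zero for that instance;
#' an empty prediction for an empty truth (a correct non-enzyme call)
#' counts as a match.
#'
#' @param truth,predicted lists of label sets (character vectors), equal
#'   length. An `ec_predictions` object is accepted for `predicted`.
#' @return fraction in `[0, 1]`.
#' @export
subset_accuracy <- function(truth, predicted) {
  predicted <- as_label_set_list(predicted)
  truth <- as_label_set_list(truth)
  if (length(truth) != length(predicted))
    stop("truth and predicted have different lengths", call. = FALSE)
  if (length(truth) == 0L) return(NaN)
  mean(mapply(function(t, p) setequal(t, p), truth, predicted))
}

as_label_set_list <- function(x) {
  if (inherits(x, "ec_predictions")) x$labels
  else if (inherits(x, "ec_dataset")) dataset_label_sets(x)
  else x
}

#' Per-label confusion counts
#'
#' @param truth,predicted lists of label sets, equal length.
#' @param labels label universe; defaults to all labels occurring in either.
#' @return data frame with columns `label`, `TP`, `FP`, `FN`, `TN`;
#'   `TP+FP+FN+TN` equals the instance count for every label.
#' @export
confusion_counts <- function(truth, predicted, labels = NULL) {
  truth <- as_label_set_list(truth); predicted <- as_label_set_list(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted have different lengths", call. = FALSE)
  if (is.null(labels))
    labels <- ec_sort(unique(c(unlist(truth, use.names = FALSE),
                               unlist(predicted, use.names = FALSE))))
  n <- length(truth)
  count_occ <- function(sets) {
    f <- factor(unlist(sets, use.names = FALSE), levels = labels)
    tabulate(f, nbins = length(labels))
  }
  tp <- count_occ(mapply(intersect, truth, predicted, SIMPLIFY = FALSE))
  t_tot <- count_occ(truth)
  p_tot <- count_occ(predicted)
  data.frame(label = labels, TP = tp, FP = p_tot - tp, FN = t_tot - tp,
             TN = n - t_tot - p_tot + tp, stringsAsFactors = FALSE)
}

#' Micro-, macro- and example-averaged multi-label metrics
#'
#' Micro averaging pools the confusion counts of all labels (weighting
#' frequent classes more); macro averaging takes the unweighted mean of
#' per-label precision and recall over labels with at least one true or
#' predicted occurrence (rare classes weigh as much as frequent ones);
#' example-based metrics average per-instance set overlaps
#' `|T∩P|/|P|`, `|T∩P|/|T|` and `|T∩P|/|T∪P|`.
#'
#' Conventions for undefined ratios: a label with positives but no
#' predictions contributes precision 0, and one with predictions but no
#' positives contributes recall 0; labels with neither are skipped. An
#' instance with empty truth and empty prediction (an agreeing non-enzyme)
#' contributes 1 to all three example-based metrics; an empty prediction
#' against non-empty truth (or vice versa) contributes 0.
#'
#' @inheritParams confusion_counts
#' @return named list: `micro_precision`, `micro_recall`, `macro_precision`,
#'   `macro_recall`, `example_precision`, `example_recall`,
#'   `example_accuracy`.
#' @export
micro_macro_example_metrics <- function(truth, predicted, labels = NULL) {
  truth <- as_label_set_list(truth); predicted <- as_label_set_list(predicted)
  cc <- confusion_counts(truth, predicted, labels)
  occ <- (cc$TP + cc$FN) > 0 | (cc$TP + cc$FP) > 0
  cc <- cc[occ, , drop = FALSE]
  ratio <- function(num, den) ifelse(den > 0, num / den, 0)
  micro_p <- ratio(sum(cc$TP), sum(cc$TP) + sum(cc$FP))
  micro_r <- ratio(sum(cc$TP), sum(cc$TP) + sum(cc$FN))
  macro_p <- if (nrow(cc)) mean(ratio(cc$TP, cc$TP + cc$FP)) else NaN
  macro_r <- if (nrow(cc)) mean(ratio(cc$TP, cc$TP + cc$FN)) else NaN
  ex <- mapply(function(t, p) {
    if (length(t) == 0L && length(p) == 0L) return(c(1, 1, 1))
    i <- length(intersect(t, p))
    c(ratio(i, length(p)), ratio(i, length(t)),
      ratio(i, length(union(t, p))))
  }, truth, predicted)
  if (length(truth) == 0L) ex <- matrix(NaN, 3, 0)
  list(micro_precision = micro_p, micro_recall = micro_r,
       macro_precision = macro_p, macro_recall = macro_r,
       example_precision = mean(ex[1, ]), example_recall = mean(ex[2, ]),
       example_accuracy = mean(ex[3, ]))
}

#' EC-digit histogram of label sets
#'
#' Counts the depth (number of specified EC digits) of the most specific
#' label of each hierarchical chain, so one 4-digit annotation contributes
#' one count at depth 4, not four counts at depths 1 to 4. An empty set
#' contributes nothing.
#'
#' @param label_sets list of (hierarchically closed) label sets, or an
#'   `ec_predictions` / `ec_dataset`.
#' @return named integer vector with entries `depth_1` .. `depth_4`.
#' @export
digit_histogram <- function(label_sets) {
  label_sets <- as_label_set_list(label_sets)
  leaves <- unlist(lapply(label_sets, leaf_labels), use.names = FALSE)
  d <- if (length(leaves)) ec_depth(leaves) else integer(0)
  stats::setNames(tabulate(d, nbins = 4L), paste0("depth_", 1:4))
}

#' Subset accuracy per main EC class
#'
#' Buckets evaluated instances by the main (first-digit) classes of their
#' true labels, with a `no-EC` bucket for instances with empty truth, and
#' reports the subset accuracy within each bucket. An instance whose true
#' labels span several main classes is counted in each of them.
#'
#' @inheritParams subset_accuracy
#' @return named numeric vector (`no-EC`, `EC1`, `EC2`, ...) of subset
#'   accuracies over the buckets present.
#' @export
per_main_class_accuracy <- function(truth, predicted) {
  truth <- as_label_set_list(truth); predicted <- as_label_set_list(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted have different lengths", call. = FALSE)
  mains <- lapply(truth, function(t) {
    if (length(t) == 0L) "no-EC"
    else paste0("EC", unique(vapply(ec_digits(t), `[`, integer(1), 1L)))
  })
  buckets <- sort(unique(unlist(mains)))
  out <- vapply(buckets, function(b) {
    idx <- which(vapply(mains, function(m) b %in% m, logical(1)))
    subset_accuracy(truth[idx], predicted[idx])
  }, numeric(1))
  out[order(match(names(out), c("no-EC", paste0("EC", 1:9))))]
}

# ---- Evaluation protocols ---------------------------------------------------

eval_metric_names <- c("subset_accuracy", "micro_precision", "micro_recall",
                       "macro_precision", "macro_recall", "example_precision",
                       "example_recall", "example_accuracy")

score_predictions <- function(truth, predicted, labels) {
  c(list(subset_accuracy = subset_accuracy(truth, predicted)),
    micro_macro_example_metrics(truth, predicted, labels))
}

#' Seeded cross-evaluation of a classifier
#'
#' For each round and fold, fits a model on the fold's complement, predicts
#' the held-out fold, and scores it; the label universe for per-label
#' metrics is fixed to the full dataset's label space, so classes occurring
#' only in a test fold remain scoreable. Identical seeds give identical
#' reports.
#'
#' @param dataset an [ec_dataset()].
#' @param folds an [make_folds()] assignment for `dataset`.
#' @param model_factory function taking a training [ec_dataset()] and
#'   returning a model with a `predict` method; default fits [brknn()] with
#'   `k`.
#' @param k neighbour count for the default factory.
#' @param threshold decision threshold passed to [predict.brknn()].
#' @return object of class `ec_eval`: `per_fold` (data frame of metric values
#'   per round and fold), `mean` and `sd` (named vectors over folds), `n`.
#' @export
cross_evaluate <- function(dataset, folds = make_folds(dataset, seed = 1),
                           model_factory = NULL, k = 1, threshold = 0.5) {
  stopifnot(inherits(dataset, "ec_dataset"), inherits(folds, "ec_folds"))
  if (folds$n != n_instances(dataset))
    stop("fold assignment does not match the dataset", call. = FALSE)
  if (is.null(model_factory))
    model_factory <- function(train) brknn(train, k = k)
  labels <- dataset$label_space$labels
  rows <- list()
  for (r in seq_len(folds$rounds)) {
    fold_of <- folds$assignment[[r]]
    for (f in seq_len(folds$n_folds)) {
      test_idx <- which(fold_of == f)
      train <- subset_dataset(dataset, which(fold_of != f))
      test <- subset_dataset(dataset, test_idx)
      model <- model_factory(train)
      preds <- if (inherits(model, "brknn"))
        predict(model, test, threshold = threshold) else predict(model, test)
      sc <- score_predictions(dataset_label_sets(test), preds$labels, labels)
      rows[[length(rows) + 1L]] <-
        c(list(round = r, fold = f, n_test = length(test_idx)), sc)
    }
  }
  per_fold <- do.call(rbind, lapply(rows, as.data.frame))
  new_ec_eval(per_fold, n = n_instances(dataset))
}

new_ec_eval <- function(per_fold, n) {
  vals <- per_fold[eval_metric_names]
  structure(list(per_fold = per_fold,
                 mean = vapply(vals, mean, numeric(1)),
                 sd = if (nrow(per_fold) > 1L)
                   vapply(vals, stats::sd, numeric(1)) else NULL,
                 n = n),
            class = "ec_eval")
}

#' @export
print.ec_eval <- function(x, digits = 4, ...) {
  cat(sprintf("multi-label evaluation over %d instance(s), %d evaluation unit(s)\n",
              x$n, nrow(x$per_fold)))
  for (m in eval_metric_names) {
    if (is.null(x$sd)) cat(sprintf("  %-18s %.*f\n", m, digits, x$mean[[m]]))
    else cat(sprintf("  %-18s %.*f +/- %.*f\n", m, digits, x$mean[[m]],
                     digits, x$sd[[m]]))
  }
  invisible(x)
}

#' Leave-group-out (jackknife) evaluation
#'
#' Holds out all instances with the given group value (for example one
#' species' proteome), trains on the remainder, and scores the predictions
#' for the held-out group — the protocol used to reannotate a proteome as if
#' it came from a newly sequenced genome. With `inverse = TRUE` the model is
#' trained on the group and evaluated on the complement.
#'
#' @param dataset an [ec_dataset()] with the group key in `groups`.
#' @param group_key group column name (e.g. `"species"`).
#' @param group_value value(s) defining the held-out group.
#' @inheritParams cross_evaluate
#' @param inverse train on the group and predict the complement instead.
#' @return an `ec_eval` report with a single evaluation unit.
#' @export
leave_group_out <- function(dataset, group_key, group_value,
                            model_factory = NULL, k = 1, threshold = 0.5,
                            inverse = FALSE) {
  parts <- partition_by_group(dataset, group_key, group_value)
  test <- if (inverse) parts$complement else parts$subset
  train <- if (inverse) parts$subset else parts$complement
  if (n_instances(test) == 0L) stop("held-out group is empty", call. = FALSE)
  if (n_instances(train) == 0L) stop("training part is empty", call. = FALSE)
  if (is.null(model_factory))
    model_factory <- function(tr) brknn(tr, k = k)
  model <- model_factory(train)
  preds <- if (inherits(model, "brknn"))
    predict(model, test, threshold = threshold) else predict(model, test)
  sc <- score_predictions(dataset_label_sets(test), preds$labels,
                          dataset$label_space$labels)
  per_fold <- as.data.frame(c(list(round = 1L, fold = 1L,
                                   n_test = n_instances(test)), sc))
  new_ec_eval(per_fold, n = n_instances(test))
}

#' Export an evaluation report as CSV
#'
#' Long layout: one row per evaluation unit per metric (`round`, `fold`,
#' `metric`, `value`), followed by `mean` and `sd` summary rows (fold column
#' empty).
#'
#' @param report an `ec_eval`.
#' @param path destination file.
#' @param header optional `#`-prefixed comment line(s).
#' @return the path, invisibly.
#' @export
write_evaluation_report <- function(report, path, header = NULL) {
  stopifnot(inherits(report, "ec_eval"))
  pf <- report$per_fold
  rows <- character(0)
  for (i in seq_len(nrow(pf)))
    for (m in eval_metric_names)
      rows <- c(rows, sprintf("%d,%d,%s,%.10g", pf$round[i], pf$fold[i], m,
                              pf[[m]][i]))
  for (m in eval_metric_names)
    rows <- c(rows, sprintf(",mean,%s,%.10g", m, report$mean[[m]]))
  if (!is.null(report$sd))
    for (m in eval_metric_names)
      rows <- c(rows, sprintf(",sd,%s,%.10g", m, report$sd[[m]]))
  con <- file(path, open = "wb")
  writeLines(c(if (!is.null(header)) paste0("# ", header),
               "round,fold,metric,value", rows), con, sep = "\n",
             useBytes = TRUE)
  close(con)
  invisible(path)
}

# ---- Significance test ------------------------------------------------------

#' One-sample t significance test between two result sets
#'
#' Computes `t = (X - M) / (sd / sqrt(n))` where `X` and `sd` are the mean
#' and standard deviation of the reference sample `a`, `M` is the mean of
#' sample `b`, and `n` is the common sample count; the two-tailed p-value is
#' taken from the t distribution with `n - 1` degrees of freedom,
#' `p = 2 * (1 - F(|t|))`. Only the reference sample's spread enters the
#' statistic (no pooling). Samples are declared significantly different at
#' the 5% level.
#'
#' @param a reference sample of metric values (length n >= 2, sd > 0).
#' @param b comparison sample, same length.
#' @param alpha significance level (default 0.05).
#' @return list with `t`, `df`, `p_value`, `significant`.
#' @export
significance <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b))
    stop("samples must have the same length", call. = FALSE)
  n <- length(a)
  if (n < 2L) stop("need at least two values per sample", call. = FALSE)
  s <- stats::sd(a)
  if (s == 0) stop("reference sample has zero standard deviation",
                   call. = FALSE)
  t <- (mean(a) - mean(b)) / (s / sqrt(n))
  df <- n - 1L
  p <- 2 * stats::pt(abs(t), df = df, lower.tail = FALSE)
  list(t = t, df = df, p_value = p, significant = p < alpha)
}
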