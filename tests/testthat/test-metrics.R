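# Multi-label metrics, evaluation protocols, and the significance test.

test_that("subset accuracy requires an exact match of the whole label set", {
  truth <- list(c("1.-.-.-", "1.2.-.-", "1.2.3.-", "1.2.3.4"))
  miss_one <- list(c("1.-.-.-", "1.2.-.-", "1.2.3.-"))
  expect_equal(subset_accuracy(truth, miss_one), 0)   # completely incorrect
  expect_equal(subset_accuracy(truth, truth), 1)
  expect_equal(subset_accuracy(list(character(0)), list(character(0))), 1)
  mixed_t <- c(truth, list(character(0)), list("2.-.-.-"))
  mixed_p <- c(truth, list(character(0)), list(character(0)))
  expect_equal(subset_accuracy(mixed_t, mixed_p), 2 / 3)
  expect_error(subset_accuracy(truth, c(truth, truth)), "lengths")
})

test_that("micro, macro and example averaging follow their definitions", {
  perfect <- list(c("1.1.1.1", "1.1.1.-"), character(0))
  m0 <- micro_macro_example_metrics(perfect, perfect)
  expect_true(all(unlist(m0) == 1))
  # label A: TP=1 FP=1; label B: TP=0 FN=1  (hand-computed expectations)
  truth <- list(c("1.1.1.1"), c("2.2.2.2"), character(0))
  pred <- list(c("1.1.1.1"), character(0), c("1.1.1.1"))
  m <- micro_macro_example_metrics(truth, pred)
  expect_equal(m$micro_precision, 0.5)
  expect_equal(m$micro_recall, 0.5)
  expect_equal(m$macro_precision, 0.25)
  expect_equal(m$macro_recall, 0.5)
  # example-based overlap: truth {x}, predicted {x,y}
  m2 <- micro_macro_example_metrics(list("1.1.1.1"),
                                    list(c("1.1.1.1", "2.2.2.2")))
  expect_equal(m2$example_precision, 0.5)
  expect_equal(m2$example_recall, 1)
  expect_equal(m2$example_accuracy, 0.5)
  # empty/empty instance contributes 1.0 to the example metrics
  m3 <- micro_macro_example_metrics(list("1.1.1.1", character(0)),
                                    list("1.1.1.1", character(0)))
  expect_equal(m3$example_accuracy, 1)
})

test_that("micro averages equal an independent per-label loop", {
  for (seed in c(2, 11)) {
    truth <- random_label_sets(30, seed = seed)
    pred <- random_label_sets(30, seed = seed + 100)
    m <- micro_macro_example_metrics(truth, pred)
    orc <- oracle_micro(truth, pred)
    expect_equal(m$micro_precision, unname(orc["precision"]))
    expect_equal(m$micro_recall, unname(orc["recall"]))
    # subset accuracy is the strictest criterion
    expect_lte(subset_accuracy(truth, pred), m$example_accuracy + 1e-12)
  }
})

test_that("confusion counts partition the instance set for every label", {
  truth <- random_label_sets(25, seed = 9)
  pred <- random_label_sets(25, seed = 10)
  cc <- confusion_counts(truth, pred)
  expect_true(all(cc$TP + cc$FP + cc$FN + cc$TN == 25))
  expect_true(all(cc$TP >= 0 & cc$FP >= 0 & cc$FN >= 0 & cc$TN >= 0))
})

test_that("the EC-digit histogram counts the deepest label of each chain", {
  h1 <- digit_histogram(list(c("1.-.-.-", "1.2.-.-", "1.2.3.-", "1.2.3.4")))
  expect_identical(unname(h1), c(0L, 0L, 0L, 1L))
  expect_identical(unname(digit_histogram(list(character(0)))), rep(0L, 4))
  h2 <- digit_histogram(list("1.2.-.-", "2.-.-.-"))
  expect_identical(unname(h2), c(1L, 1L, 0L, 0L))
  # two chains in one instance: one count each
  h3 <- digit_histogram(list(expand_label_set(c("1.2.3.4", "2.3.-.-"))))
  expect_identical(unname(h3), c(0L, 1L, 0L, 1L))
})

test_that("per-main-class accuracy equals a filter-then-score oracle", {
  truth <- list(expand_label_set("1.1.1.1"), expand_label_set("2.3.1.12"),
                character(0), expand_label_set(c("1.2.3.4", "6.1.1.1")))
  pred_perfect <- truth
  expect_true(all(per_main_class_accuracy(truth, pred_perfect) == 1))
  all_wrong <- list(expand_label_set("3.1.1.1"), expand_label_set("3.1.1.1"),
                    expand_label_set("3.1.1.1"), expand_label_set("3.1.1.1"))
  pm <- per_main_class_accuracy(truth, all_wrong)
  expect_equal(unname(pm["no-EC"]), 0)
  # mixed predictions: compare each bucket against manual filtering
  pred <- list(expand_label_set("1.1.1.1"), character(0),
               character(0), expand_label_set("1.2.3.4"))
  pm2 <- per_main_class_accuracy(truth, pred)
  expect_equal(unname(pm2["EC1"]),
               subset_accuracy(truth[c(1, 4)], pred[c(1, 4)]))
  expect_equal(unname(pm2["EC2"]), 0)
  expect_equal(unname(pm2["EC6"]), 0)   # instance 4 counted in EC1 and EC6
  expect_equal(unname(pm2["no-EC"]), 1)
})

test_that("cross-evaluation is reproducible and scores each fold once", {
  d <- generate_dataset(synth_config(n_proteins = 200, n_leaf_classes = 12,
                                     seed = 8))$dataset
  f <- make_folds(d, n_folds = 5, rounds = 2, seed = 21)
  r1 <- cross_evaluate(d, f)
  r2 <- cross_evaluate(d, f)
  expect_identical(r1, r2)
  expect_identical(nrow(r1$per_fold), 10L)
  expect_identical(sum(r1$per_fold$n_test), 2L * n_instances(d))
  expect_true(all(r1$per_fold$subset_accuracy >= 0 &
                    r1$per_fold$subset_accuracy <= 1))
  expect_false(is.null(r1$sd))
  # zero-rule factory: accuracy equals the per-fold non-enzyme fraction
  rz <- cross_evaluate(d, f, model_factory = function(tr) zero_rule(tr))
  expect_equal(rz$mean[["subset_accuracy"]],
               mean(sapply(1:2, function(r) sapply(1:5, function(fd) {
                 test <- dataset_label_sets(
                   subset_dataset(d, which(f$assignment[[r]] == fd)))
                 mean(lengths(test) == 0)
               }))))
})

test_that("leave-group-out reannotation behaves like a jackknife", {
  # held-out group duplicates vectors in the complement -> perfect score
  d <- ec_dataset(sprintf("P%d", 1:6),
                  list(c("a", "b"), c("c", "d"), "e",
                       c("a", "b"), c("c", "d"), "e"),
                  list("1.1.1.1", "2.2.2.2", character(0),
                       "1.1.1.1", "2.2.2.2", character(0)),
                  groups = data.frame(species = rep(c("eco", "hsa"),
                                                    each = 3)))
  r <- leave_group_out(d, "species", "eco")
  expect_equal(r$mean[["subset_accuracy"]], 1)
  expect_identical(r$n, 3L)
  # classes absent from the complement can never be predicted
  d2 <- ec_dataset(sprintf("P%d", 1:4),
                   list(c("a", "b"), c("a", "c"), "d", "e"),
                   list("3.3.3.3", "4.4.4.4", character(0), character(0)),
                   groups = data.frame(species = c("x", "y", "y", "y")))
  r2 <- leave_group_out(d2, "species", "x")
  expect_lt(r2$mean[["micro_recall"]], 1)
  expect_equal(r2$mean[["subset_accuracy"]], 0)
  # inverse mode trains on the group and scores the complement
  r3 <- leave_group_out(d, "species", "eco", inverse = TRUE)
  expect_identical(r3$n, 3L)
  expect_equal(r3$mean[["subset_accuracy"]], 1)
  expect_error(leave_group_out(d, "species", "none"), "empty")
})

test_that("the t statistic uses the reference sample's spread only", {
  s1 <- significance(c(1, 2, 3), c(1, 2, 3))
  expect_equal(s1$t, 0)
  expect_equal(s1$p_value, 1)
  expect_false(s1$significant)
  s2 <- significance(c(1, 2, 3), c(101, 102, 103))
  expect_lt(s2$p_value, 1e-3)   # |t| is huge but df = 2 tails are heavy
  expect_true(s2$significant)
  # X = 0.9, sd = 0.01, n = 10, M = 0.88  ->  t = 0.02 / (0.01/sqrt(10))
  a <- c(0.88557, 0.89557, 0.90557, 0.91557, 0.89045, 0.90955,
         0.89497, 0.90503, 0.89833, 0.91939)
  a <- 0.9 + 0.01 * scale(a)[, 1]   # exact mean 0.9, sd 0.01
  b <- rep(0.88, 10)
  s3 <- significance(a, b)
  expect_equal(s3$t, 0.02 / (0.01 / sqrt(10)), tolerance = 1e-12)
  expect_equal(s3$t, 6.3245, tolerance = 1e-4)
  expect_equal(s3$p_value, oracle_t_pvalue(s3$t, 9), tolerance = 1e-6)
  expect_error(significance(1:3, 1:4), "same length")
  expect_error(significance(c(1, 1), c(0, 2)), "zero standard deviation")
})

test_that("p-values are proper, symmetric in sign, and monotone in |t|", {
  for (df in c(1, 5, 9, 30)) {
    prev <- 1.1
    for (tt in c(0, 0.5, 1, 2, 4, 8)) {
      p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
      a <- seq_len(df + 1); a <- a / stats::sd(a)     # sd 1, n = df + 1
      b <- a - tt / sqrt(df + 1)                      # shifts mean by t*sd/sqrt(n)
      s <- significance(a, b)
      expect_equal(s$t, tt, tolerance = 1e-9)
      expect_equal(s$p_value, p, tolerance = 1e-12)
      expect_equal(significance(b, a)$p_value, s$p_value, tolerance = 1e-9)
      expect_true(s$p_value > 0 && s$p_value <= 1)
      expect_lte(s$p_value, prev)
      prev <- s$p_value
    }
  }
})

test_that("evaluation reports export and summarise as CSV", {
  d <- generate_dataset(synth_config(n_proteins = 120, n_leaf_classes = 8,
                                     seed = 14))$dataset
  r <- cross_evaluate(d, make_folds(d, 4, rounds = 1, seed = 2))
  f <- tempfile(fileext = ".csv")
  write_evaluation_report(r, f, header = "test run")
  df <- read.csv(f, comment.char = "#", stringsAsFactors = FALSE)
  expect_setequal(unique(df$metric),
                  c("subset_accuracy", "micro_precision", "micro_recall",
                    "macro_precision", "macro_recall", "example_precision",
                    "example_recall", "example_accuracy"))
  mean_row <- df[df$fold == "mean" & df$metric == "subset_accuracy", ]
  expect_equal(as.numeric(mean_row$value), r$mean[["subset_accuracy"]],
               tolerance = 1e-9)
})
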