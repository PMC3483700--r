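# Dataset assembly, joining, partitioning, folds, summaries, combinatorics.

test_that("assemble parses, remaps and expands annotations", {
  tabs <- list(
    ec = list(P1 = "2.6.99.2", P2 = character(0), P3 = "9.9.9.9"),
    signatures = list(P1 = c("a", "b", "c", "d", "e")),
    groups = c(P1 = "eco", P2 = "eco", P3 = "hsa"))
  status <- ec_status_table("9.9.9.9", "deleted")
  expect_warning(d <- assemble(tabs, status), "not in status table")
  expect_identical(d$ids, c("P1", "P2", "P3"))
  i <- match("P1", d$ids)
  expect_length(dataset_signature_sets(d)[[i]], 5)   # five attributes
  expect_length(dataset_label_sets(d)[[i]], 4)       # four expanded labels
  # P2: empty vector, empty label set is a legal instance
  expect_identical(dataset_signature_sets(d)[[2]], character(0))
  expect_identical(dataset_label_sets(d)[[2]], character(0))
  # P3's only EC was deleted -> non-enzyme instance
  expect_identical(dataset_label_sets(d)[[3]], character(0))
  expect_identical(d$groups$species, c("eco", "eco", "hsa"))
})

test_that("join_agreeing keeps exactly the couples present in both sources", {
  a <- list(P = c("1.1.1.1", "2.2.2.2"), Q = character(0),
            R = "1.1.1.1", S = "3.3.3.3")
  b <- list(P = "1.1.1.1", Q = character(0), R = "2.2.2.2", T = "1.1.1.1")
  j <- join_agreeing(a, b)
  expect_identical(j[["P"]], "1.1.1.1")      # partial overlap keeps couple
  expect_identical(j[["Q"]], character(0))   # agreeing non-enzyme retained
  expect_false("R" %in% names(j))            # full disagreement dropped
  expect_false("S" %in% names(j))            # absent from one source
  expect_false("T" %in% names(j))
  # symmetric, and result couples are a subset of the couple intersection
  j2 <- join_agreeing(b, a)
  expect_identical(j[order(names(j))], j2[order(names(j2))])
  for (p in names(j))
    expect_true(all(j[[p]] %in% intersect(a[[p]], b[[p]])))
})

test_that("group partitions are disjoint and exhaustive", {
  d <- tiny_dataset()
  parts <- partition_by_group(d, "species", "eco")
  expect_identical(parts$subset$ids, c("P1", "P2"))
  expect_identical(parts$complement$ids, c("P3", "P4", "P5"))
  expect_identical(parts$subset$signatures, d$signatures)
  expect_identical(parts$subset$label_space$labels, d$label_space$labels)
  all_values <- unique(d$groups$species)
  expect_identical(n_instances(partition_by_group(d, "species",
                                                  all_values)$complement), 0L)
  expect_identical(n_instances(partition_by_group(d, "species",
                                                  character(0))$subset), 0L)
  expect_error(partition_by_group(d, "taxon", "eco"), "unknown group key")
})

test_that("random subsets are seeded and bounded", {
  d <- tiny_dataset()
  expect_identical(random_subset(d, 5, seed = 1)$ids, d$ids)
  expect_identical(n_instances(random_subset(d, 0, seed = 1)), 0L)
  expect_identical(random_subset(d, 3, seed = 9)$ids,
                   random_subset(d, 3, seed = 9)$ids)
  expect_error(random_subset(d, 6, seed = 1), "exceeds")
})

test_that("redundancy reduction keeps one instance per cluster", {
  d <- tiny_dataset()
  ident <- setNames(d$ids, d$ids)
  expect_identical(reduce_to_representatives(d, ident)$ids, d$ids)
  cmap <- c(P1 = "P1", P2 = "P1", P3 = "P3", P4 = "P3", P5 = "P5")
  r <- reduce_to_representatives(d, cmap)
  expect_identical(r$ids, c("P1", "P3", "P5"))
  expect_error(reduce_to_representatives(d, c(P1 = "PX", P2 = "P1",
                                              P3 = "P3", P4 = "P3",
                                              P5 = "P5")),
               "not present")
  expect_error(reduce_to_representatives(d, cmap[-1]), "does not cover")
})

test_that("fold assignment is balanced, seeded, and a partition", {
  cfg <- synth_config(n_proteins = 101, n_leaf_classes = 10, seed = 4)
  d <- generate_dataset(cfg)$dataset
  f <- make_folds(d, n_folds = 10, rounds = 2, seed = 3)
  for (r in 1:2) {
    sizes <- tabulate(f$assignment[[r]], nbins = 10)
    expect_identical(sort(sizes), c(rep(10L, 9), 11L))
    expect_identical(sum(sizes), 101L)
  }
  expect_identical(make_folds(d, 10, 2, seed = 3)$assignment, f$assignment)
  expect_false(identical(f$assignment[[1]], f$assignment[[2]]))
  d100 <- subset_dataset(d, 1:100)
  expect_true(all(tabulate(make_folds(d100, 10, 1, seed = 1)$assignment[[1]],
                           10) == 10L))
  # round policy: two rounds below the threshold, one above
  expect_identical(make_folds(d, 10, seed = 1)$rounds, 2L)
  expect_identical(make_folds(d, 10, seed = 1, small_threshold = 50)$rounds, 1L)
  expect_error(make_folds(subset_dataset(d, 1:5), 10, seed = 1), "fewer")
})

test_that("cumulative EC distribution is non-decreasing and ends at 100%", {
  one <- ec_dataset(c("P1", "P2"), list("s1", "s2"),
                    list("1.1.1.1", "1.1.1.1"))
  c1 <- ec_cumulative_distribution(one)
  expect_identical(nrow(c1), 1L)
  expect_equal(c1$cumulative_fraction, 100)
  # two classes at 90/10
  d <- ec_dataset(sprintf("P%02d", 1:10),
                  rep(list("s1"), 10),
                  c(rep(list("1.1.1.1"), 9), list("2.2.2.2")))
  cv <- ec_cumulative_distribution(d)
  expect_equal(cv$rank_fraction, c(50, 100))
  expect_equal(cv$cumulative_fraction, c(90, 100))
  # long-tail synthetic curve: non-decreasing, above the diagonal, ends at 100
  g <- generate_dataset(synth_config(n_proteins = 800, n_leaf_classes = 40,
                                     seed = 12))$dataset
  cz <- ec_cumulative_distribution(g)
  expect_true(all(diff(cz$cumulative_fraction) >= 0))
  expect_equal(cz$cumulative_fraction[nrow(cz)], 100)
  expect_true(all(cz$cumulative_fraction >= cz$rank_fraction - 1e-9))
  # expanded ancestors are not double-counted: total leaf counts match a
  # direct census of per-instance leaf labels
  gl <- dataset_label_sets(g)
  expect_identical(sum(cz$count),
                   length(unlist(lapply(gl[lengths(gl) > 0], leafs_of))))
  # no enzymes -> empty curve
  expect_identical(nrow(ec_cumulative_distribution(
    ec_dataset("P1", list("s1"), list(character(0))))), 0L)
})

test_that("signature-set census matches a brute-force subset oracle", {
  d <- ec_dataset(c("P1", "P2", "P3"),
                  list(c("a", "b"), c("a", "b"), "a"),
                  rep(list(character(0)), 3))
  st <- signature_set_stats(d)
  expect_identical(st$n_distinct, 2L)
  expect_equal(st$mean_size, 1.5)
  expect_identical(st$n_maximal, 1L)
  all_empty <- ec_dataset(c("P1", "P2"), list(character(0), character(0)),
                          list(character(0), character(0)))
  expect_identical(signature_set_stats(all_empty)$n_distinct, 1L)
  # random fixture vs O(n^2) oracle
  set.seed(31)
  sets <- replicate(40, sort(sample(letters[1:8], sample(0:5, 1))),
                    simplify = FALSE)
  d2 <- ec_dataset(sprintf("P%02d", 1:40), sets,
                   rep(list(character(0)), 40))
  st2 <- signature_set_stats(d2)
  keys <- sapply(sets, paste, collapse = "|")
  distinct <- sets[!duplicated(keys)]
  n_max <- sum(sapply(seq_along(distinct), function(i) {
    !any(sapply(seq_along(distinct), function(j) {
      j != i && length(distinct[[j]]) > length(distinct[[i]]) &&
        all(distinct[[i]] %in% distinct[[j]])
    }))
  }))
  expect_identical(st2$n_distinct, length(distinct))
  expect_equal(st2$mean_size, mean(lengths(distinct)))
  expect_identical(st2$n_maximal, n_max)
})

test_that("binomial coefficients are exact at arbitrary precision", {
  expect_identical(as.character(count_combinations(21178, 3)),
                   "1582858375176")
  expect_equal(signif(as.numeric(count_combinations(21178, 4)), 2), 8.4e15)
  expect_identical(as.character(count_combinations(5, 0)), "1")
  expect_identical(as.character(count_combinations(52, 5)),
                   format(choose(52, 5), scientific = FALSE))
  # a value far beyond double precision stays exact: check the last digits
  # against the Pascal recurrence C(300,150) = C(299,149) + C(299,150)
  add_tail <- function(a, b, k) {  # last k digits of a+b
    ta <- as.numeric(substr(a, nchar(a) - k + 1, nchar(a)))
    tb <- as.numeric(substr(b, nchar(b) - k + 1, nchar(b)))
    sprintf(paste0("%0", k, ".0f"), (ta + tb) %% 10^k)
  }
  big <- as.character(count_combinations(300, 150))
  expect_gt(nchar(big), 17)
  expect_identical(substr(big, nchar(big) - 7, nchar(big)),
                   add_tail(as.character(count_combinations(299, 149)),
                            as.character(count_combinations(299, 150)), 8))
  expect_error(count_combinations(3, 4), "k must not exceed n")
})
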