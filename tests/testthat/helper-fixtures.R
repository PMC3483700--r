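# Shared fixtures and independent oracles for the test suite.

# Small hand-built dataset: two enzyme classes plus non-enzymes.
tiny_dataset <- function() {
  ec_dataset(
    ids = c("P1", "P2", "P3", "P4", "P5"),
    signature_sets = list(c("sA", "sB"), c("sA", "sB"), c("sC", "sD", "sE"),
                          "sF", character(0)),
    label_sets = list("1.1.1.1", "1.1.1.1", c("2.3.1.12", "2.3.1.13"),
                      character(0), character(0)),
    groups = data.frame(species = c("eco", "eco", "hsa", "hsa", "mmu"),
                        stringsAsFactors = FALSE))
}

# Random label sets over a small EC universe (for property tests).
random_label_sets <- function(n, seed) {
  universe <- c("1.1.1.1", "1.1.1.2", "1.2.3.4", "2.3.1.12", "2.7.1.1",
                "3.4.21.1", "1.2.-.-", "6.3.4.-")
  with_seed <- function(s, code) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(s); force(code)
  }
  with_seed(seed, replicate(n, sample(universe, sample(0:4, 1)),
                            simplify = FALSE))
}

# Brute-force nearest-neighbour oracle: dense 0/1 vectors, exhaustive
# pairwise Euclidean distances, the same tie/threshold contract as the
# classifier but computed independently of its sparse-matrix path.
oracle_knn_predict <- function(train_sets, train_labels, query_sets, vocab,
                               k = 1, threshold = 0.5) {
  dense <- function(s) as.numeric(vocab %in% s)
  Xt <- vapply(train_sets, dense, numeric(length(vocab)))  # p x n
  lapply(query_sets, function(q) {
    qv <- dense(q)
    d <- sqrt(colSums((Xt - qv)^2))
    kd <- sort(d)[min(k, length(d))]
    nb <- which(d <= kd + 1e-9)
    labs <- unlist(train_labels[nb], use.names = FALSE)
    if (length(labs) == 0L) return(character(0))
    tab <- table(labs) / length(nb)
    sort(names(tab)[tab >= threshold])
  })
}

# Independent per-label loop for micro averaging.
oracle_micro <- function(truth, predicted) {
  labels <- unique(c(unlist(truth), unlist(predicted)))
  tp <- fp <- fn <- 0
  for (l in labels) {
    for (i in seq_along(truth)) {
      t_has <- l %in% truth[[i]]; p_has <- l %in% predicted[[i]]
      tp <- tp + (t_has && p_has)
      fp <- fp + (!t_has && p_has)
      fn <- fn + (t_has && !p_has)
    }
  }
  c(precision = tp / (tp + fp), recall = tp / (tp + fn))
}

# High-precision quadrature of the t density for two-tailed p-values.
oracle_t_pvalue <- function(t, df) {
  dens <- function(x) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  2 * stats::integrate(dens, abs(t), Inf, rel.tol = 1e-12)$value
}

file_bytes <- function(path) readBin(path, "raw", file.info(path)$size)

# Most specific labels of a closed set, recomputed from exported primitives.
leafs_of <- function(s) setdiff(s, unlist(lapply(s, ec_ancestors)))
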