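# Annotated datasets: instances x signature vocabulary x EC label space.
#
# Instances are proteins; attributes are binary presence of sequence
# signatures (InterPro-style identifiers); each instance carries a
# hierarchically closed set of EC labels (empty = non-enzyme) and optional
# group keys (species, taxon, cluster representative). Presence matrices are
# stored as sparse pattern matrices from the Matrix package.

#' Construct an annotated dataset
#'
#' @param ids character vector of unique instance identifiers (protein
#'   accessions).
#' @param signature_sets list of character vectors: the signatures present in
#'   each instance (may be empty).
#' @param label_sets list of character vectors of canonical EC labels; sets
#'   are hierarchically expanded on construction (an empty set is the no-EC,
#'   non-enzyme outcome).
#' @param signatures signature vocabulary (ordered character vector). Defaults
#'   to the sorted union of observed signatures.
#' @param labels an [ec_label_space()] or character vector of labels fixing
#'   the label space. Defaults to the closure of observed labels.
#' @param groups optional data frame of group keys (one row per instance),
#'   e.g. a `species` or `cluster` column.
#' @return object of class `ec_dataset` with elements `ids`, `signatures`,
#'   `label_space`, sparse pattern matrices `X` (instances x signatures) and
#'   `Y` (instances x labels), and `groups`.
#' @examples
#' d <- ec_dataset(c("P1", "P2"),
#'                 list(c("IPR1", "IPR2"), character(0)),
#'                 list("1.1.1.1", character(0)))
#' d
#' @export
ec_dataset <- function(ids, signature_sets, label_sets,
                       signatures = NULL, labels = NULL, groups = NULL) {
  n <- length(ids)
  stopifnot(is.character(ids), length(signature_sets) == n,
            length(label_sets) == n)
  if (anyDuplicated(ids))
    stop("instance ids must be unique", call. = FALSE)
  label_sets <- lapply(label_sets, expand_label_set)
  if (is.null(signatures))
    signatures <- sort(unique(unlist(signature_sets, use.names = FALSE)))
  if (is.null(labels)) {
    space <- build_label_space(label_sets)
  } else if (inherits(labels, "ec_label_space")) {
    space <- labels
  } else {
    space <- label_space(labels)
  }
  X <- incidence_matrix(signature_sets, signatures, ids, "signature")
  Y <- incidence_matrix(label_sets, space$labels, ids, "label")
  if (!is.null(groups)) {
    groups <- as.data.frame(groups, stringsAsFactors = FALSE)
    if (nrow(groups) != n)
      stop("groups must have one row per instance", call. = FALSE)
    rownames(groups) <- ids
  }
  structure(list(ids = ids, signatures = signatures, label_space = space,
                 X = X, Y = Y, groups = groups),
            class = "ec_dataset")
}

incidence_matrix <- function(sets, vocab, ids, what) {
  lens <- lengths(sets)
  items <- unlist(sets, use.names = FALSE)
  j <- match(items, vocab)
  if (anyNA(j)) {
    miss <- unique(items[is.na(j)])
    stop(sprintf("%s(s) outside the vocabulary: %s", what,
                 paste(utils::head(miss, 5), collapse = ", ")), call. = FALSE)
  }
  i <- rep.int(seq_along(sets), lens)
  dup <- duplicated(cbind(i, j))
  Matrix::sparseMatrix(i = i[!dup], j = j[!dup],
                       dims = c(length(sets), length(vocab)),
                       dimnames = list(ids, vocab))
}

#' @export
print.ec_dataset <- function(x, ...) {
  nl <- length(x$label_space$labels)
  enz <- sum(Matrix::rowSums(x$Y) > 0)
  cat(sprintf("ec_dataset: %d instances, %d signatures, %d EC labels\n",
              length(x$ids), length(x$signatures), nl))
  cat(sprintf("  %d enzymes (%.1f%%), %d non-enzymes; %d empty signature vectors\n",
              enz, 100 * enz / max(1, length(x$ids)),
              length(x$ids) - enz, sum(Matrix::rowSums(x$X) == 0)))
  if (!is.null(x$groups))
    cat("  group keys:", paste(names(x$groups), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.ec_dataset <- function(object, ...) {
  ls <- dataset_label_sets(object)
  out <- list(
    n = length(object$ids),
    n_signatures = length(object$signatures),
    n_labels = length(object$label_space$labels),
    enzyme_fraction = mean(lengths(ls) > 0),
    mean_signatures = mean(Matrix::rowSums(object$X)),
    mean_labels = mean(lengths(ls)[lengths(ls) > 0]))
  class(out) <- "summary.ec_dataset"
  out
}

#' @export
print.summary.ec_dataset <- function(x, ...) {
  cat(sprintf(paste0(
    "%d instances, %d signatures, %d EC labels\n",
    "enzyme fraction %.3f; mean signatures/instance %.2f; ",
    "mean labels/enzyme %.2f\n"),
    x$n, x$n_signatures, x$n_labels, x$enzyme_fraction,
    x$mean_signatures, x$mean_labels))
  invisible(x)
}

#' Dataset accessors
#'
#' `dataset_signature_sets()` and `dataset_label_sets()` return per-instance
#' sets as lists of character vectors; `n_instances()` the instance count.
#'
#' @param dataset an [ec_dataset()].
#' @return list of character vectors (or an integer for `n_instances()`).
#' @export
dataset_signature_sets <- function(dataset) {
  row_sets(dataset$X, dataset$signatures)
}

#' @rdname dataset_signature_sets
#' @export
dataset_label_sets <- function(dataset) {
  row_sets(dataset$Y, dataset$label_space$labels)
}

#' @rdname dataset_signature_sets
#' @export
n_instances <- function(dataset) length(dataset$ids)

row_sets <- function(M, vocab) {
  if (ncol(M) == 0L) return(rep(list(character(0)), nrow(M)))
  Mt <- as(as(M, "TsparseMatrix"), "nMatrix")
  out <- split(vocab[Mt@j + 1L], factor(Mt@i + 1L, levels = seq_len(nrow(M))))
  unname(lapply(out, function(v) v))
}

#' Subset a dataset by instance index
#'
#' Keeps the parent signature vocabulary and label space.
#'
#' @param dataset an [ec_dataset()].
#' @param idx integer, logical, or character (id) index of instances to keep.
#' @return an [ec_dataset()].
#' @export
subset_dataset <- function(dataset, idx) {
  if (is.character(idx)) idx <- match(idx, dataset$ids)
  if (is.logical(idx)) idx <- which(idx)
  if (anyNA(idx) || (length(idx) > 0 && (max(idx) > length(dataset$ids) || min(idx) < 1)))
    stop("instance index out of range", call. = FALSE)
  structure(list(
    ids = dataset$ids[idx],
    signatures = dataset$signatures,
    label_space = dataset$label_space,
    X = dataset$X[idx, , drop = FALSE],
    Y = dataset$Y[idx, , drop = FALSE],
    groups = if (!is.null(dataset$groups)) dataset$groups[idx, , drop = FALSE]),
    class = "ec_dataset")
}

# ---- Assembly from annotation tables ---------------------------------------

#' Assemble a dataset from annotation tables
#'
#' Joins protein-to-EC and protein-to-signature maps into an annotated
#' dataset: EC strings are parsed, remapped through the status table (deleted
#' numbers dropped, transferred numbers substituted), and hierarchically
#' expanded; the signature vocabulary and label space are built
#' deterministically. Proteins present in only one table get empty sets in
#' the other; proteins with no signatures are retained (their vector is
#' empty), and a protein whose only EC was deleted becomes a non-enzyme
#' instance.
#'
#' @param tables a list as returned by [read_annotation_tables()]: `ec`
#'   (named list protein -> EC strings), `signatures` (named list protein ->
#'   signature ids), optional `groups` (named character vector protein ->
#'   group key).
#' @param status_table optional [ec_status_table()] for remapping.
#' @param group_name column name used for the group key (default
#'   `"species"`).
#' @return an [ec_dataset()].
#' @export
assemble <- function(tables, status_table = NULL, group_name = "species") {
  ids <- sort(unique(c(names(tables$ec), names(tables$signatures))))
  ec_sets <- lapply(ids, function(p) {
    raw <- tables$ec[[p]] %||% character(0)
    if (length(raw) == 0L) return(character(0))
    expand_label_set(remap_annotations(parse_ec(raw), status_table))
  })
  sig_sets <- lapply(ids, function(p) {
    s <- tables$signatures[[p]] %||% character(0)
    sort(unique(s))
  })
  groups <- NULL
  if (!is.null(tables$groups)) {
    g <- unname(tables$groups[ids])
    groups <- stats::setNames(data.frame(g, stringsAsFactors = FALSE),
                              group_name)
  }
  ec_dataset(ids, sig_sets, ec_sets, groups = groups)
}

#' Keep only annotations that agree between two sources
#'
#' An annotation is a (protein, EC) couple. The join keeps exactly the
#' couples present in both sources. A protein appears in the result if it has
#' at least one agreeing couple, or if both sources record it with an empty
#' EC set (an agreeing non-enzyme). Proteins absent from either source, or
#' with non-empty but fully disagreeing annotation, are dropped.
#'
#' @param a,b named lists mapping protein id to a character vector of raw
#'   (unexpanded) EC strings; an empty vector marks a non-enzyme record.
#' @return named list protein -> agreeing EC set.
#' @export
join_agreeing <- function(a, b) {
  shared <- intersect(names(a), names(b))
  out <- list()
  for (p in shared) {
    ea <- unique(parse_ec(as.character(a[[p]])))
    eb <- unique(parse_ec(as.character(b[[p]])))
    common <- intersect(ea, eb)
    if (length(common) > 0L) {
      out[[p]] <- ec_sort(common)
    } else if (length(ea) == 0L && length(eb) == 0L) {
      out[[p]] <- character(0)
    }
  }
  out
}

# ---- Partitioning and redundancy reduction ---------------------------------

#' Split a dataset by a group key
#'
#' @param dataset an [ec_dataset()] whose `groups` carry `group_key`.
#' @param group_key name of the group column (e.g. `"species"`).
#' @param values group values defining the subset.
#' @return list with elements `subset` (instances whose group value is in
#'   `values`) and `complement`; both share the parent vocabulary and label
#'   space, and together partition the parent instances.
#' @export
partition_by_group <- function(dataset, group_key, values) {
  if (is.null(dataset$groups) || !group_key %in% names(dataset$groups))
    stop(sprintf("unknown group key '%s'", group_key), call. = FALSE)
  g <- dataset$groups[[group_key]]
  sel <- !is.na(g) & g %in% values
  list(subset = subset_dataset(dataset, which(sel)),
       complement = subset_dataset(dataset, which(!sel)))
}

#' Uniform random subset of instances
#'
#' @param dataset an [ec_dataset()].
#' @param n number of instances to sample without replacement.
#' @param seed integer seed; the same seed reproduces the same subset.
#' @return an [ec_dataset()] over the parent vocabulary and label space.
#' @export
random_subset <- function(dataset, n, seed) {
  N <- n_instances(dataset)
  if (n > N) stop("n exceeds the number of instances", call. = FALSE)
  idx <- with_seed(stream_seed(seed, "random_subset"),
                   sort(sample.int(N, n)))
  subset_dataset(dataset, idx)
}

#' Reduce a dataset to cluster representatives
#'
#' Emulates UniRef-style redundancy reduction: given a member-to-
#' representative map covering every instance, keeps exactly the instances
#' that are their own representative (one per cluster).
#'
#' @param dataset an [ec_dataset()].
#' @param cluster_map named character vector mapping member id to
#'   representative id; singletons map to themselves.
#' @return an [ec_dataset()] with one instance per cluster.
#' @export
reduce_to_representatives <- function(dataset, cluster_map) {
  miss <- setdiff(dataset$ids, names(cluster_map))
  if (length(miss) > 0L)
    stop("cluster map does not cover instance(s): ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  reps <- unname(cluster_map[dataset$ids])
  absent <- setdiff(unique(reps), dataset$ids)
  if (length(absent) > 0L)
    stop("representative(s) not present in dataset: ",
         paste(utils::head(absent, 5), collapse = ", "), call. = FALSE)
  subset_dataset(dataset, which(dataset$ids == reps))
}

# ---- Cross-evaluation folds -------------------------------------------------

#' Seeded fold assignment for cross-evaluation
#'
#' Instances are shuffled with the seed and sliced contiguously into
#' `n_folds` folds whose sizes differ by at most one. By default datasets
#' with fewer than 40,000 instances get two independent rounds of fold
#' assignment, larger ones a single round.
#'
#' @param dataset an [ec_dataset()].
#' @param n_folds number of folds (>= 2).
#' @param rounds number of cross-evaluation rounds; `NULL` selects 2 when the
#'   dataset has fewer than `small_threshold` instances, else 1.
#' @param seed integer seed.
#' @param small_threshold instance count below which two rounds are used by
#'   default (40,000).
#' @return object of class `ec_folds`: `n_folds`, `rounds`, `seed`, and
#'   `assignment`, a list (one per round) of integer fold ids per instance.
#' @export
make_folds <- function(dataset, n_folds = 10, rounds = NULL, seed = 1,
                       small_threshold = 40000) {
  N <- n_instances(dataset)
  if (n_folds < 2) stop("n_folds must be at least 2", call. = FALSE)
  if (N < n_folds) stop("fewer instances than folds", call. = FALSE)
  if (is.null(rounds)) rounds <- if (N < small_threshold) 2L else 1L
  sizes <- rep(N %/% n_folds, n_folds)
  extra <- N %% n_folds
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  assignment <- lapply(seq_len(rounds), function(r) {
    perm <- with_seed(stream_seed(seed, paste0("folds_round_", r)),
                      sample.int(N))
    fold <- integer(N)
    fold[perm] <- rep.int(seq_len(n_folds), sizes)
    fold
  })
  structure(list(n_folds = as.integer(n_folds), rounds = as.integer(rounds),
                 seed = seed, n = N, assignment = assignment),
            class = "ec_folds")
}

#' @export
print.ec_folds <- function(x, ...) {
  cat(sprintf("fold assignment: %d round(s) of %d folds over %d instances (seed %s)\n",
              x$rounds, x$n_folds, x$n, format(x$seed)))
  invisible(x)
}

# ---- Distribution and combinatorics summaries -------------------------------

#' Cumulative EC class frequency curve
#'
#' Ranks the most specific (leaf) EC labels of each enzyme instance by
#' descending frequency and accumulates the fraction of enzyme annotations
#' covered, reproducing the long-tail view of class frequencies. Non-enzymes
#' are excluded from the denominator; expanded ancestor labels are not
#' counted (only the leaves of each instance's label set), so one annotation
#' contributes one count.
#'
#' @param dataset an [ec_dataset()].
#' @return data frame with columns `label`, `count`, `rank_fraction` and
#'   `cumulative_fraction` (both in percent); the curve is non-decreasing and
#'   ends at 100. Zero rows if the dataset has no enzymes.
#' @export
ec_cumulative_distribution <- function(dataset) {
  ls <- dataset_label_sets(dataset)
  leaves <- unlist(lapply(ls, leaf_labels), use.names = FALSE)
  if (length(leaves) == 0L)
    return(data.frame(label = character(0), count = integer(0),
                      rank_fraction = numeric(0),
                      cumulative_fraction = numeric(0)))
  tab <- sort(table(leaves), decreasing = TRUE)
  counts <- as.integer(tab)
  data.frame(label = names(tab), count = counts,
             rank_fraction = 100 * seq_along(counts) / length(counts),
             cumulative_fraction = 100 * cumsum(counts) / sum(counts),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Most specific labels of a hierarchically closed set: members that are not
# a proper prefix (ancestor) of another member.
leaf_labels <- function(labels) {
  if (length(labels) <= 1L) return(labels)
  anc <- unique(unlist(lapply(labels, ec_ancestors), use.names = FALSE))
  setdiff(labels, anc)
}

#' Census of distinct signature sets
#'
#' Summarises how compactly the instances are described by unordered
#' signature sets: the number of distinct sets, their mean size, and how
#' many are maximal (not a proper subset of another distinct set present).
#'
#' @param dataset an [ec_dataset()].
#' @return list with `n_distinct`, `mean_size`, `n_maximal`.
#' @export
signature_set_stats <- function(dataset) {
  sets <- dataset_signature_sets(dataset)
  keys <- vapply(sets, paste, character(1), collapse = "\x1f")
  distinct <- sets[!duplicated(keys)]
  sizes <- lengths(distinct)
  ord <- order(sizes)  # ascending: a proper superset must be strictly larger
  n_max <- 0L
  for (ii in seq_along(ord)) {
    s <- distinct[[ord[ii]]]
    is_sub <- FALSE
    for (jj in seq_along(ord)) {
      if (sizes[ord[jj]] <= sizes[ord[ii]]) next
      if (all(s %in% distinct[[ord[jj]]])) { is_sub <- TRUE; break }
    }
    if (!is_sub) n_max <- n_max + 1L
  }
  list(n_distinct = length(distinct),
       mean_size = if (length(distinct)) mean(sizes) else NaN,
       n_maximal = n_max)
}

#' Exact binomial coefficient
#'
#' Computes `choose(n, k)` exactly at arbitrary precision using the
#' multiplicative formula over an internal big-integer representation, for
#' combinatorial arguments far beyond double precision (e.g. the number of
#' unordered signature triples over a vocabulary of tens of thousands).
#'
#' @param n,k non-negative integers with `k <= n`.
#' @return object of class `bigint`; convert with `as.character()` (exact
#'   decimal digits) or `as.numeric()`.
#' @examples
#' as.character(count_combinations(21178, 3))
#' @export
count_combinations <- function(n, k) {
  stopifnot(length(n) == 1L, length(k) == 1L, n >= 0, k >= 0)
  if (k > n) stop("k must not exceed n", call. = FALSE)
  k <- min(k, n - k)
  acc <- big_from_int(1)
  for (i in seq_len(k)) {
    acc <- big_mul_small(acc, n - k + i)
    acc <- big_div_small(acc, i)  # exact: running value is C(n-k+i, i)
  }
  acc
}

# Big integers as little-endian base-1e7 digit vectors.
BIG_BASE <- 1e7

big_from_int <- function(x) {
  stopifnot(x >= 0, x < 2^53)
  d <- numeric(0)
  repeat {
    d <- c(d, x %% BIG_BASE)
    x <- x %/% BIG_BASE
    if (x == 0) break
  }
  structure(list(d = d), class = "bigint")
}

big_mul_small <- function(b, m) {
  stopifnot(m >= 0, m < 2^31)
  d <- b$d * m
  carry <- 0
  for (i in seq_along(d)) {
    v <- d[i] + carry
    d[i] <- v %% BIG_BASE
    carry <- v %/% BIG_BASE
  }
  while (carry > 0) {
    d <- c(d, carry %% BIG_BASE)
    carry <- carry %/% BIG_BASE
  }
  b$d <- d
  b
}

big_div_small <- function(b, m) {
  stopifnot(m >= 1, m < 2^31)
  d <- b$d
  rem <- 0
  for (i in rev(seq_along(d))) {
    v <- rem * BIG_BASE + d[i]
    d[i] <- v %/% m
    rem <- v %% m
  }
  if (rem != 0) stop("inexact big-integer division", call. = FALSE)
  while (length(d) > 1L && d[length(d)] == 0) d <- d[-length(d)]
  b$d <- d
  b
}

#' @export
as.character.bigint <- function(x, ...) {
  d <- rev(x$d)
  paste0(format(d[1], scientific = FALSE),
         paste(sprintf("%07.0f", d[-1]), collapse = ""))
}

#' @export
as.double.bigint <- function(x, ...) sum(x$d * BIG_BASE^(seq_along(x$d) - 1))

#' @export
format.bigint <- function(x, ...) as.character(x)

#' @export
print.bigint <- function(x, ...) {
  cat(as.character(x), "\n")
  invisible(x)
}
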