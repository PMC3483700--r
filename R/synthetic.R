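# Synthetic annotation databases.
#
# Generates datasets with the statistical structure of real enzyme
# annotation data: long-tail (Zipf) EC class frequencies, a small number of
# signature combinations per class, a non-enzyme majority drawn from a
# disjoint background signature pool, incomplete (partial) EC labels,
# multi-EC proteins and empty-attribute instances — so every pipeline stage
# is testable without downloading any external database.
#
# Generative model: each leaf EC class owns a few distinct signature
# combinations. Classes sharing a 3-digit family prefix share a small family
# core of signatures (creating realistic near-neighbour confusability);
# every combination additionally contains one anchor signature private to
# its class and combination, which guarantees that, at zero noise, the map
# from signature vector to label set is a function (no cross-class
# collisions).

#' Synthetic generator configuration
#'
#' @param n_proteins number of protein instances.
#' @param n_leaf_classes number of 4-digit leaf EC classes.
#' @param zipf_exponent exponent s of the rank-frequency law
#'   (class weight proportional to rank^-s); larger values concentrate mass
#'   on the top classes.
#' @param combos_per_class integer range `c(min, max)` of distinct signature
#'   combinations owned by each class.
#' @param combo_length_mean mean signatures per combination (shifted Poisson,
#'   capped at `combo_length_max`).
#' @param combo_length_max cap on combination length.
#' @param non_enzyme_fraction fraction of instances with no EC annotation.
#' @param empty_vector_fraction fraction of non-enzymes with an empty
#'   signature vector.
#' @param multi_ec_fraction fraction of enzymes carrying a second EC class.
#' @param partial_label_fraction fraction of classes annotated only at a
#'   truncated (1-3 digit) depth; their proteins carry incomplete EC labels.
#' @param noise_rate per-signature corruption probability: each signature
#'   present in an enzyme's combination is dropped with this probability,
#'   and with the same probability one spurious signature is added.
#' @param n_signatures signature vocabulary size, or `NULL` to size the
#'   vocabulary automatically from the class structure.
#' @param n_groups number of group (species-like) keys assigned uniformly.
#' @param seed mandatory integer seed; all stages derive named sub-streams
#'   from it.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_proteins = 5000, n_leaf_classes = 200,
                         zipf_exponent = 1.0, combos_per_class = c(1L, 3L),
                         combo_length_mean = 3.55, combo_length_max = 12L,
                         non_enzyme_fraction = 0.45,
                         empty_vector_fraction = 0.007,
                         multi_ec_fraction = 0.05,
                         partial_label_fraction = 0.09,
                         noise_rate = 0, n_signatures = NULL,
                         n_groups = 6L, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  fr <- c(non_enzyme_fraction, empty_vector_fraction, multi_ec_fraction,
          partial_label_fraction, noise_rate)
  if (any(fr < 0 | fr > 1))
    stop("all fractions must lie in [0, 1]", call. = FALSE)
  if (zipf_exponent <= 0) stop("zipf_exponent must be positive", call. = FALSE)
  stopifnot(n_proteins >= 1, n_leaf_classes >= 1,
            length(combos_per_class) == 2L,
            combos_per_class[1] >= 1, combos_per_class[2] >= combos_per_class[1],
            combo_length_mean >= 1, n_groups >= 1)
  structure(list(n_proteins = as.integer(n_proteins),
                 n_leaf_classes = as.integer(n_leaf_classes),
                 zipf_exponent = zipf_exponent,
                 combos_per_class = as.integer(combos_per_class),
                 combo_length_mean = combo_length_mean,
                 combo_length_max = as.integer(combo_length_max),
                 non_enzyme_fraction = non_enzyme_fraction,
                 empty_vector_fraction = empty_vector_fraction,
                 multi_ec_fraction = multi_ec_fraction,
                 partial_label_fraction = partial_label_fraction,
                 noise_rate = noise_rate,
                 n_signatures = if (is.null(n_signatures)) NULL
                                else as.integer(n_signatures),
                 n_groups = as.integer(n_groups),
                 seed = seed),
            class = "synth_config")
}

#' Generate a synthetic EC label space with long-tail class weights
#'
#' Creates `n_leaf_classes` 4-digit classes organised under a plausible
#' number of shared 1/2/3-digit family prefixes (about one family per three
#' leaves, under main classes 1-6), and assigns each leaf a Zipf weight
#' proportional to `rank^-zipf_exponent`. Deterministic from the seed.
#'
#' @param config a [synth_config()].
#' @return list with `space` (an `ec_label_space`), `leaves` (4-digit class
#'   labels in rank order, most frequent first) and `weights` (named,
#'   summing to 1).
#' @export
generate_label_space <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_leaf_classes
  with_seed(stream_seed(config$seed, "label_space"), {
    n_fam <- max(1L, ceiling(n / 3))
    sub_max <- 8L
    subsub_max <- max(12L, ceiling(n_fam / (6 * sub_max)) + 12L)
    grid <- expand.grid(main = 1:6, sub = seq_len(sub_max),
                        subsub = seq_len(subsub_max))
    fam_rows <- grid[sample.int(nrow(grid), n_fam), , drop = FALSE]
    fam_of_leaf <- sort(rep_len(seq_len(n_fam), n))
    serial <- stats::ave(fam_of_leaf, fam_of_leaf, FUN = seq_along)
    leaves <- sprintf("%d.%d.%d.%d", fam_rows$main[fam_of_leaf],
                      fam_rows$sub[fam_of_leaf], fam_rows$subsub[fam_of_leaf],
                      serial)
    leaves <- sample(leaves)  # rank order decoupled from family order
  })
  w <- seq_len(n)^(-config$zipf_exponent)
  w <- w / sum(w)
  list(space = label_space(leaves), leaves = leaves,
       weights = stats::setNames(w, leaves))
}

#' Generate a synthetic annotated dataset
#'
#' Draws proteins from the generative model described above: each enzyme
#' picks a class by Zipf weight and one of the class's signature
#' combinations uniformly; multi-EC proteins union a second class's
#' combination; classes designated partial are annotated only at a
#' truncated depth; non-enzymes draw from a disjoint background pool or, for
#' a small fraction, carry an empty signature vector. Labels are stored
#' hierarchically expanded. Reproducible from the seed.
#'
#' @param config a [synth_config()].
#' @return list with `dataset` (an [ec_dataset()] with a `species` group
#'   key), `truth` (data frame of generator records: instance id, class(es),
#'   combination index, enzyme flag, group) and `classes` (per-class
#'   definitions: label set and combinations).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  ls <- generate_label_space(config)
  n_leaf <- config$n_leaf_classes
  fam_key <- vapply(ls$leaves, function(l)
    paste(ec_digits(l)[[1]][1:3], collapse = "."), character(1))
  fams <- unique(fam_key)

  # --- signature pool allocation (deterministic layout) ---
  combos_n <- with_seed(stream_seed(config$seed, "combo_counts"),
    sample(seq(config$combos_per_class[1], config$combos_per_class[2]),
           n_leaf, replace = TRUE))
  core_sizes <- with_seed(stream_seed(config$seed, "core_sizes"),
                          sample(1:2, length(fams), replace = TRUE))
  # private pool: one anchor per combination plus filler so combination
  # lengths are not starved below the configured mean
  priv_sizes <- combos_n + 4L
  used <- sum(core_sizes) + sum(priv_sizes)
  bg_size <- if (is.null(config$n_signatures))
    max(30L, ceiling(0.25 * used)) else config$n_signatures - used
  if (bg_size < 10L)
    stop(sprintf("n_signatures too small: class structure needs %d signatures plus a background pool",
                 used), call. = FALSE)
  total_sig <- used + bg_size
  sig_ids <- sprintf("S%06d", seq_len(total_sig))
  core_pool <- split(sig_ids[seq_len(sum(core_sizes))],
                     rep.int(seq_along(fams), core_sizes))
  names(core_pool) <- fams
  off <- sum(core_sizes)
  priv_pool <- split(sig_ids[off + seq_len(sum(priv_sizes))],
                     rep.int(seq_len(n_leaf), priv_sizes))
  bg_pool <- sig_ids[(off + sum(priv_sizes)) + seq_len(bg_size)]

  # --- per-class label sets (partial classes truncated) ---
  part <- with_seed(stream_seed(config$seed, "partial"), {
    is_part <- stats::runif(n_leaf) < config$partial_label_fraction
    depth <- sample(1:3, n_leaf, replace = TRUE)
    list(is_part = is_part, depth = depth)
  })
  class_labels <- lapply(seq_len(n_leaf), function(i) {
    l <- ls$leaves[i]
    if (part$is_part[i])
      l <- ec_render(ec_digits(l)[[1]][seq_len(part$depth[i])])
    expand_label_set(l)
  })

  # --- combinations: anchor private signature + family core + filler ---
  rlen <- function(n, lambda)
    pmin(config$combo_length_max, 1L + stats::rpois(n, max(0, lambda - 1)))
  combos <- with_seed(stream_seed(config$seed, "combos"), {
    lapply(seq_len(n_leaf), function(i) {
      core <- core_pool[[fam_key[i]]]
      priv <- priv_pool[[i]]
      lens <- rlen(combos_n[i], config$combo_length_mean)
      lapply(seq_len(combos_n[i]), function(j) {
        anchor <- priv[j]
        filler_pool <- c(core, setdiff(priv, anchor))
        extra <- min(lens[j] - 1L, length(filler_pool))
        sort(c(anchor, if (extra > 0) sample(filler_pool, extra)))
      })
    })
  })

  # --- instances ---
  n <- config$n_proteins
  n_non <- round(n * config$non_enzyme_fraction)
  n_enz <- n - n_non
  ids <- sprintf("P%06d", seq_len(n))
  is_enz <- with_seed(stream_seed(config$seed, "roles"),
                      sample(rep(c(TRUE, FALSE), c(n_enz, n_non))))
  sig_sets <- vector("list", n)
  lab_sets <- vector("list", n)
  rec_class <- character(n); rec_combo <- integer(n)
  with_seed(stream_seed(config$seed, "instances"), {
    for (i in seq_len(n)) {
      if (is_enz[i]) {
        cl <- sample.int(n_leaf, 1L, prob = ls$weights)
        cb <- sample.int(combos_n[cl], 1L)
        vec <- combos[[cl]][[cb]]
        labs <- class_labels[[cl]]
        cls_rec <- ls$leaves[cl]
        if (stats::runif(1) < config$multi_ec_fraction && n_leaf > 1L) {
          repeat {
            cl2 <- sample.int(n_leaf, 1L, prob = ls$weights)
            if (cl2 != cl) break
          }
          cb2 <- sample.int(combos_n[cl2], 1L)
          vec <- sort(union(vec, combos[[cl2]][[cb2]]))
          labs <- ec_sort(union(labs, class_labels[[cl2]]))
          cls_rec <- paste(cls_rec, ls$leaves[cl2], sep = ";")
        }
        if (config$noise_rate > 0) {
          keep <- stats::runif(length(vec)) >= config$noise_rate
          vec <- vec[keep]
          if (stats::runif(1) < config$noise_rate)
            vec <- sort(union(vec, sample(sig_ids[seq_len(used)], 1L)))
        }
        sig_sets[[i]] <- vec
        lab_sets[[i]] <- labs
        rec_class[i] <- cls_rec
        rec_combo[i] <- cb
      } else {
        if (stats::runif(1) < config$empty_vector_fraction) {
          sig_sets[[i]] <- character(0)
        } else {
          L <- min(rlen(1L, config$combo_length_mean), length(bg_pool))
          sig_sets[[i]] <- sort(sample(bg_pool, L))
        }
        lab_sets[[i]] <- character(0)
        rec_class[i] <- ""
        rec_combo[i] <- NA_integer_
      }
    }
  })
  groups <- with_seed(stream_seed(config$seed, "groups"),
                      sprintf("sp%02d", sample.int(config$n_groups, n,
                                                   replace = TRUE)))
  space <- build_label_space(class_labels)
  dataset <- ec_dataset(ids, sig_sets, lab_sets, signatures = sig_ids,
                        labels = space,
                        groups = data.frame(species = groups,
                                            stringsAsFactors = FALSE))
  if (config$noise_rate == 0) assert_consistent_mapping(dataset)
  truth <- data.frame(id = ids, class = rec_class, combo = rec_combo,
                      is_enzyme = is_enz, species = groups,
                      stringsAsFactors = FALSE)
  list(dataset = dataset, truth = truth,
       classes = list(leaves = ls$leaves, weights = ls$weights,
                      labels = class_labels, combos = combos))
}

# At zero noise the vector -> label-set map must be a function; the anchor
# construction guarantees it, so a violation is an internal error.
assert_consistent_mapping <- function(dataset) {
  vk <- vapply(dataset_signature_sets(dataset), paste, character(1),
               collapse = "\x1f")
  lk <- vapply(dataset_label_sets(dataset), paste, character(1),
               collapse = "\x1f")
  bad <- tapply(lk, vk, function(x) length(unique(x)) > 1L)
  if (any(bad))
    stop("internal error: identical signature vectors with different label sets at zero noise",
         call. = FALSE)
  invisible(TRUE)
}

#' Reassign labels of a random subset of instances
#'
#' Supports robustness experiments: a `flip_fraction` of instances
#' (seeded, without replacement) have their label set replaced by a
#' different exact label set drawn from those present in the dataset
#' (possibly the empty, non-enzyme set). `flip_fraction = 0` is the
#' identity; at 1 no instance keeps its original exact set.
#'
#' @param dataset an [ec_dataset()].
#' @param flip_fraction fraction of instances to relabel, in `[0, 1]`.
#' @param seed integer seed.
#' @return a relabelled [ec_dataset()] over the same vocabulary, label space
#'   and groups.
#' @export
corrupt_labels <- function(dataset, flip_fraction, seed) {
  stopifnot(flip_fraction >= 0, flip_fraction <= 1)
  n <- n_instances(dataset)
  if (flip_fraction == 0 || n == 0L) return(dataset)
  labs <- dataset_label_sets(dataset)
  keys <- vapply(labs, paste, character(1), collapse = "\x1f")
  pool <- labs[!duplicated(keys)]
  pool_keys <- keys[!duplicated(keys)]
  with_seed(stream_seed(seed, "corrupt"), {
    m <- round(flip_fraction * n)
    picks <- sample.int(n, m)
    for (i in picks) {
      alt <- which(pool_keys != keys[i])
      labs[[i]] <- if (length(alt) == 0L) character(0)
                   else pool[[if (length(alt) == 1L) alt else sample(alt, 1L)]]
    }
  })
  ec_dataset(dataset$ids, dataset_signature_sets(dataset), labs,
             signatures = dataset$signatures, labels = dataset$label_space,
             groups = dataset$groups)
}

#' Duplicate-collapse cluster map
#'
#' Maps every instance to the first instance (in dataset order) with an
#' identical signature vector — a UniRef100-style clustering where clusters
#' are exact duplicates.
#'
#' @param dataset an [ec_dataset()].
#' @return named character vector member id -> representative id.
#' @seealso [reduce_to_representatives()]
#' @export
duplicate_collapse_map <- function(dataset) {
  vk <- vapply(dataset_signature_sets(dataset), paste, character(1),
               collapse = "\x1f")
  reps <- dataset$ids[match(vk, vk)]
  stats::setNames(reps, dataset$ids)
}

#' Export a dataset as delimited annotation tables
#'
#' Writes the protein-EC, protein-signature and (if present) protein-group
#' tables, plus optionally a cluster map and a ground-truth record table,
#' in the formats read by [read_annotation_tables()] and
#' [read_cluster_map()]. EC rows carry the most specific (leaf) labels
#' only; non-enzymes get one row with an empty EC field.
#'
#' @param dataset an [ec_dataset()].
#' @param dir destination directory (created if needed).
#' @param prefix file name prefix.
#' @param cluster_map optional named character vector to write as
#'   `<prefix>clusters.csv`.
#' @param truth optional data frame written as `<prefix>truth.csv`.
#' @return character vector of the files written, invisibly.
#' @export
export_annotation_tables <- function(dataset, dir, prefix = "",
                                     cluster_map = NULL, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(name) file.path(dir, paste0(prefix, name))
  labs <- dataset_label_sets(dataset)
  sigs <- dataset_signature_sets(dataset)
  ec_rows <- unlist(lapply(seq_along(dataset$ids), function(i) {
    leaves <- leaf_labels(labs[[i]])
    if (length(leaves) == 0L) paste0(dataset$ids[i], ",")
    else paste(dataset$ids[i], leaves, sep = ",")
  }), use.names = FALSE)
  sig_rows <- unlist(lapply(seq_along(dataset$ids), function(i) {
    if (length(sigs[[i]]) == 0L) character(0)
    else paste(dataset$ids[i], sigs[[i]], sep = ",")
  }), use.names = FALSE)
  write_lines_lf(ec_rows, f("proteins_ec.csv"))
  write_lines_lf(sig_rows, f("proteins_signatures.csv"))
  written <- c(f("proteins_ec.csv"), f("proteins_signatures.csv"))
  if (!is.null(dataset$groups)) {
    g <- dataset$groups[[1]]
    write_lines_lf(paste(dataset$ids, g, sep = ","), f("proteins_groups.csv"))
    written <- c(written, f("proteins_groups.csv"))
  }
  if (!is.null(cluster_map)) {
    write_lines_lf(paste(names(cluster_map), cluster_map, sep = ","),
                   f("clusters.csv"))
    written <- c(written, f("clusters.csv"))
  }
  if (!is.null(truth)) {
    utils::write.csv(truth, f("truth.csv"), row.names = FALSE, quote = FALSE)
    written <- c(written, f("truth.csv"))
  }
  invisible(written)
}

write_lines_lf <- function(lines, path) {
  con <- file(path, open = "wb")
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  close(con)
  invisible(path)
}
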