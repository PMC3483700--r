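# Binary-relevance k-nearest-neighbour multi-label classifier.
#
# The model is a lazy learner: fitting stores the training instances; at
# prediction time the Euclidean distance from each query to every stored
# instance is computed once and shared across all per-label (binary
# relevance) decisions. Over binary signature vectors the Euclidean distance
# is sqrt(|symmetric difference|), so squared distances are integers and
# nearest-neighbour ties are exact.

#' Euclidean distance between binary signature vectors
#'
#' For presence sets over a common vocabulary the Euclidean distance equals
#' the square root of the size of the symmetric difference. It is zero iff
#' the sets are equal, symmetric, and satisfies the triangle inequality.
#'
#' @param a,b character (or integer index) vectors: the signatures present.
#' @return non-negative numeric distance.
#' @examples
#' signature_distance(c("s1", "s2"), c("s2", "s3", "s4"))  # sqrt(3)
#' @export
signature_distance <- function(a, b) {
  a <- unique(a); b <- unique(b)
  sqrt(length(setdiff(a, b)) + length(setdiff(b, a)))
}

#' Fit a binary-relevance k-nearest-neighbour EC classifier
#'
#' Stores the training instances verbatim (no label is dropped, including
#' classes with a single example). Prediction copies the label sets of the
#' nearest training neighbours: with the default `k = 1` and no distance
#' ties this reduces to copying the nearest neighbour's (hierarchically
#' closed) label set; the empty prediction is the non-enzyme call.
#'
#' @param dataset an [ec_dataset()] of training instances (non-empty).
#' @param k number of neighbours (>= 1; the operative choice is 1).
#' @return object of class `brknn` with `predict`, `print` and `summary`
#'   methods.
#' @examples
#' d <- ec_dataset(c("P1", "P2"),
#'                 list(c("s1", "s2"), "s3"),
#'                 list("1.1.1.1", character(0)))
#' m <- brknn(d)
#' predict(m, list(c("s1", "s2")))
#' @export
brknn <- function(dataset, k = 1) {
  stopifnot(inherits(dataset, "ec_dataset"))
  if (n_instances(dataset) == 0L)
    stop("training dataset is empty", call. = FALSE)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop("k must be a positive integer", call. = FALSE)
  if (k > n_instances(dataset))
    stop("k exceeds the number of training instances", call. = FALSE)
  structure(list(X = dataset$X,
                 ids = dataset$ids,
                 signatures = dataset$signatures,
                 label_sets = dataset_label_sets(dataset),
                 label_space = dataset$label_space,
                 k = as.integer(k)),
            class = "brknn")
}

#' @export
print.brknn <- function(x, ...) {
  cat(sprintf("brknn model: k = %d, %d training instances, %d signatures, %d EC labels\n",
              x$k, length(x$ids), length(x$signatures),
              length(x$label_space$labels)))
  invisible(x)
}

#' @export
summary.brknn <- function(object, ...) {
  enz <- sum(lengths(object$label_sets) > 0)
  cat(sprintf(paste0("brknn model (binary-relevance %d-nearest-neighbour)\n",
                     "  training instances: %d (%d enzymes, %d non-enzymes)\n",
                     "  signature vocabulary: %d\n",
                     "  EC label space: %d labels\n"),
              object$k, length(object$ids), enz, length(object$ids) - enz,
              length(object$signatures), length(object$label_space$labels)))
  invisible(object)
}

#' Predict EC label sets with a fitted brknn model
#'
#' For each query the distance to every training instance is computed once.
#' The neighbour set is the `k` nearest training instances, extended to all
#' instances tied with the k-th distance (exact integer tie detection). The
#' confidence of each label is the fraction of the neighbour set carrying
#' it; labels with confidence at or above `threshold` are predicted. Query
#' signatures outside the training vocabulary are ignored (they shift all
#' distances equally and cannot change the neighbour ranking); a warning
#' reports how many were dropped.
#'
#' @param object a [brknn()] model.
#' @param newdata an [ec_dataset()], a list of character vectors (signature
#'   sets), or a sparse pattern matrix over the training vocabulary.
#' @param threshold decision threshold on label confidence (default 0.5).
#' @param chunk_size queries per distance block (memory/speed trade-off).
#' @param ... unused.
#' @return object of class `ec_predictions`: `ids`, `labels` (list of
#'   predicted label sets, canonically sorted), `confidence` (list of named
#'   numeric vectors for the predicted labels), `no_ec_confidence`
#'   (1 - max label confidence; 1 for an empty prediction with no
#'   competitors), and `label_space`.
#' @export
predict.brknn <- function(object, newdata, threshold = 0.5,
                          chunk_size = 1024L, ...) {
  q <- as_query_matrix(newdata, object$signatures)
  n_train <- length(object$ids)
  Xd <- as(object$X, "dMatrix")  # numeric: pattern matrices multiply as Boolean
  Qd <- as(q$Q, "dMatrix")
  rx <- Matrix::rowSums(object$X)
  m <- nrow(q$Q)
  labels_out <- vector("list", m)
  conf_out <- vector("list", m)
  no_ec <- numeric(m)
  k <- object$k
  for (start in seq(1L, length.out = ceiling(m / chunk_size),
                    by = chunk_size)) {
    rows <- start:min(start + chunk_size - 1L, m)
    Qc <- Qd[rows, , drop = FALSE]
    S <- as.matrix(Matrix::tcrossprod(Qc, Xd))  # shared dot products
    rq <- Matrix::rowSums(Qc)
    for (ii in seq_along(rows)) {
      d2 <- rq[ii] + rx - 2 * S[ii, ]  # integer squared distances
      kth <- if (k >= n_train) max(d2) else sort(d2, partial = k)[k]
      nb <- which(d2 <= kth)
      res <- neighbour_vote(object$label_sets[nb], threshold)
      i <- rows[ii]
      labels_out[[i]] <- res$labels
      conf_out[[i]] <- res$confidence
      no_ec[i] <- res$no_ec
    }
  }
  new_ec_predictions(q$ids, labels_out, conf_out, no_ec,
                     object$label_space$labels)
}

neighbour_vote <- function(neighbour_label_sets, threshold) {
  nn <- length(neighbour_label_sets)
  if (nn == 1L) {
    labs <- neighbour_label_sets[[1]]
    conf <- stats::setNames(rep(1, length(labs)), labs)
  } else {
    all <- unlist(neighbour_label_sets, use.names = FALSE)
    conf <- if (length(all) == 0L) stats::setNames(numeric(0), character(0))
            else {
              tab <- table(all) / nn
              stats::setNames(as.numeric(tab), names(tab))
            }
    labs <- ec_sort(names(conf)[conf >= threshold])
  }
  # no-EC confidence: complement of the strongest label vote
  no_ec <- if (length(conf) == 0L) 1 else 1 - max(conf)
  list(labels = labs, confidence = conf[labs], no_ec = no_ec)
}

as_query_matrix <- function(newdata, signatures) {
  if (inherits(newdata, "ec_dataset")) {
    if (identical(newdata$signatures, signatures))
      return(list(Q = newdata$X, ids = newdata$ids))
    sets <- dataset_signature_sets(newdata)
    ids <- newdata$ids
  } else if (is.list(newdata)) {
    sets <- lapply(newdata, as.character)
    ids <- names(newdata) %||% sprintf("query_%05d", seq_along(sets))
  } else if (inherits(newdata, "Matrix") || is.matrix(newdata)) {
    if (ncol(newdata) != length(signatures))
      stop("query matrix does not match the training vocabulary",
           call. = FALSE)
    M <- as(Matrix::Matrix(newdata, sparse = TRUE), "nMatrix")
    return(list(Q = M,
                ids = rownames(newdata) %||%
                  sprintf("query_%05d", seq_len(nrow(newdata)))))
  } else {
    stop("unsupported query type", call. = FALSE)
  }
  known <- lapply(sets, function(s) s[s %in% signatures])
  dropped <- sum(lengths(sets)) - sum(lengths(known))
  if (dropped > 0L)
    warning(sprintf("%d query signature occurrence(s) outside the training vocabulary were ignored",
                    dropped), call. = FALSE)
  list(Q = incidence_matrix(known, signatures, ids, "signature"), ids = ids)
}

new_ec_predictions <- function(ids, labels, confidence, no_ec_confidence,
                               label_space) {
  structure(list(ids = ids, labels = labels, confidence = confidence,
                 no_ec_confidence = no_ec_confidence,
                 label_space = label_space),
            class = "ec_predictions")
}

#' @export
print.ec_predictions <- function(x, n = 10L, ...) {
  m <- length(x$ids)
  enz <- sum(lengths(x$labels) > 0)
  cat(sprintf("ec_predictions: %d instances (%d enzyme calls, %d non-enzyme calls)\n",
              m, enz, m - enz))
  for (i in seq_len(min(n, m))) {
    cat(sprintf("  %s -> %s\n", x$ids[i],
                if (length(x$labels[[i]]) == 0L) "(no EC)"
                else paste(x$labels[[i]], collapse = "; ")))
  }
  if (m > n) cat(sprintf("  ... %d more\n", m - n))
  invisible(x)
}

#' @export
length.ec_predictions <- function(x) length(x$ids)

# ---- Baselines --------------------------------------------------------------

#' Zero Rule baseline
#'
#' Fits the majority-outcome baseline: every query is assigned the modal
#' exact label set of the training data (typically the empty, non-enzyme
#' set). Ties are broken toward the empty set, then by lexicographic order
#' of the label-set key.
#'
#' @param dataset an [ec_dataset()] of training instances.
#' @return object of class `zero_rule` with a `predict` method; element
#'   `majority_fraction` is the training frequency of the modal set.
#' @export
zero_rule <- function(dataset) {
  stopifnot(inherits(dataset, "ec_dataset"))
  sets <- dataset_label_sets(dataset)
  keys <- vapply(sets, paste, character(1), collapse = ";")
  tab <- table(keys)
  top <- names(tab)[tab == max(tab)]
  key <- if ("" %in% top) "" else sort(top)[1]
  modal <- sets[[match(key, keys)]]
  structure(list(modal_set = modal,
                 majority_fraction = as.numeric(max(tab)) / length(sets),
                 label_space = dataset$label_space),
            class = "zero_rule")
}

#' @export
print.zero_rule <- function(x, ...) {
  cat(sprintf("zero rule baseline: predicts %s for every instance (majority fraction %.3f)\n",
              if (length(x$modal_set) == 0L) "the non-enzyme outcome"
              else paste(x$modal_set, collapse = "; "),
              x$majority_fraction))
  invisible(x)
}

#' @export
predict.zero_rule <- function(object, newdata, ...) {
  ids <- query_ids(newdata)
  m <- length(ids)
  labs <- object$modal_set
  conf <- stats::setNames(rep(1, length(labs)), labs)
  new_ec_predictions(ids, rep(list(labs), m), rep(list(conf), m),
                     rep(if (length(labs) == 0L) 1 else 0, m),
                     object$label_space$labels)
}

query_ids <- function(newdata) {
  if (inherits(newdata, "ec_dataset")) newdata$ids
  else if (is.list(newdata))
    names(newdata) %||% sprintf("query_%05d", seq_along(newdata))
  else if (!is.null(nrow(newdata)))
    rownames(newdata) %||% sprintf("query_%05d", seq_len(nrow(newdata)))
  else stop("unsupported query type", call. = FALSE)
}

#' Transitive signature-to-EC mapping baseline
#'
#' Assigns EC labels directly from a signature-to-EC mapping table (the
#' composition of InterPro-to-GO and GO-to-EC style lists): the prediction
#' for a query is the hierarchical expansion of the union of the ECs mapped
#' by its signatures, each with confidence 1. Queries with no mapping hit
#' get the empty (non-enzyme) prediction.
#'
#' @param map named list mapping signature id to a character vector of EC
#'   strings, or the path of a two-column delimited file `signature,EC`.
#' @param label_space optional [label_space()]; defaults to the closure of
#'   all mapped ECs.
#' @return object of class `transitive_ec` with a `predict` method.
#' @export
transitive_mapper <- function(map, label_space = NULL) {
  if (is.character(map) && length(map) == 1L) {
    df <- parse_two_col(map, what = "signature-EC")
    map <- lapply(split(df$value, df$key), function(v) unique(v[nzchar(v)]))
  }
  stopifnot(is.list(map), !is.null(names(map)))
  map <- lapply(map, function(v) ec_sort(unique(parse_ec(as.character(v)))))
  space <- if (is.null(label_space))
    build_label_space(map) else label_space
  structure(list(map = map, label_space = space), class = "transitive_ec")
}

#' @export
print.transitive_ec <- function(x, ...) {
  cat(sprintf("transitive signature-to-EC mapper: %d signatures mapped, %d EC labels\n",
              length(x$map), length(x$label_space$labels)))
  invisible(x)
}

#' @export
predict.transitive_ec <- function(object, newdata, ...) {
  sets <- if (inherits(newdata, "ec_dataset")) dataset_signature_sets(newdata)
          else if (is.list(newdata)) lapply(newdata, as.character)
          else stop("unsupported query type", call. = FALSE)
  ids <- query_ids(newdata)
  labels <- lapply(sets, function(s) {
    hits <- unlist(object$map[intersect(s, names(object$map))],
                   use.names = FALSE)
    expand_label_set(unique(hits %||% character(0)))
  })
  conf <- lapply(labels, function(l) stats::setNames(rep(1, length(l)), l))
  new_ec_predictions(ids, labels, conf,
                     ifelse(lengths(labels) == 0L, 1, 0),
                     object$label_space$labels)
}
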