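# EC numbers: parsing, hierarchy, canonical ordering, status remapping.
#
# An EC label is represented throughout the package as its canonical text
# form: four dot-separated fields, unspecified trailing fields rendered as
# "-", e.g. "1.2.-.-". Label sets are plain character vectors of canonical
# strings, so set algebra is ordinary vector algebra.

#' Parse Enzyme Commission numbers
#'
#' Parses EC number strings into their canonical four-field text form.
#' An EC number has one to four dot-separated components, each a positive
#' integer; trailing components may be unspecified and are written `-`
#' (an incomplete, or partial, EC such as `1.2.-.-` is a legitimate class
#' label of its own). An optional `EC ` prefix is accepted.
#'
#' @param x character vector of EC strings, e.g. `"2.6.99.2"`, `"EC 1.2.-.-"`,
#'   `"1.2"` (short forms are padded with `-`).
#' @return character vector of canonical EC labels, always four dot-separated
#'   fields (`"1.2.-.-"`). Parsing then rendering is the identity on
#'   canonical labels.
#' @examples
#' parse_ec("2.6.99.2")
#' parse_ec("EC 1.2")     # -> "1.2.-.-"
#' ec_depth("1.2.-.-")    # -> 2
#' @seealso [ec_ancestors()], [expand_label_set()]
#' @export
parse_ec <- function(x) {
  stopifnot(is.character(x))
  vapply(x, parse_ec1, character(1), USE.NAMES = FALSE)
}

parse_ec1 <- function(text) {
  raw <- text
  text <- sub("^\\s*EC\\s+", "", trimws(text), ignore.case = TRUE)
  if (!nzchar(text))
    stop("empty EC string", call. = FALSE)
  fields <- strsplit(text, ".", fixed = TRUE)[[1]]
  if (length(fields) < 1L || length(fields) > 4L)
    stop(sprintf("malformed EC '%s': expected 1-4 dot-separated fields", raw),
         call. = FALSE)
  fields <- c(fields, rep("-", 4L - length(fields)))
  digits <- integer(0)
  seen_wild <- FALSE
  for (i in seq_len(4L)) {
    f <- trimws(fields[i])
    if (identical(f, "-")) {
      seen_wild <- TRUE
    } else {
      if (seen_wild)
        stop(sprintf("malformed EC '%s': field %d ('%s') specified after an unspecified field",
                     raw, i, f), call. = FALSE)
      if (!grepl("^[0-9]+$", f))
        stop(sprintf("malformed EC '%s': field %d ('%s') is not a positive integer",
                     raw, i, f), call. = FALSE)
      v <- suppressWarnings(as.integer(f))
      if (is.na(v) || v <= 0L)
        stop(sprintf("malformed EC '%s': field %d ('%s') must be a positive integer",
                     raw, i, f), call. = FALSE)
      digits <- c(digits, v)
    }
  }
  if (length(digits) == 0L)
    stop(sprintf("malformed EC '%s': no specified fields", raw), call. = FALSE)
  ec_render(digits)
}

ec_render <- function(digits) {
  paste(c(as.character(digits), rep("-", 4L - length(digits))), collapse = ".")
}

ec_fields <- function(labels) {
  # 4-column character matrix of fields for canonical labels
  m <- matrix("-", nrow = length(labels), ncol = 4L)
  sp <- strsplit(labels, ".", fixed = TRUE)
  for (i in seq_along(sp)) m[i, seq_along(sp[[i]])] <- sp[[i]]
  m
}

#' @rdname parse_ec
#' @param labels character vector of canonical EC labels.
#' @return `ec_depth()`: integer vector of depths in 1..4 (number of
#'   specified fields).
#' @export
ec_depth <- function(labels) {
  if (length(labels) == 0L) return(integer(0))
  m <- ec_fields(labels)
  rowSums(m != "-")
}

#' @rdname parse_ec
#' @return `ec_digits()`: list of integer vectors, the specified components
#'   of each label.
#' @export
ec_digits <- function(labels) {
  m <- ec_fields(labels)
  lapply(seq_along(labels), function(i) {
    f <- m[i, m[i, ] != "-"]
    as.integer(f)
  })
}

#' Sort EC labels in canonical (numeric lexicographic) order
#'
#' Orders labels component-wise by numeric value, with an unspecified field
#' sorting before any specified one, so every label follows its ancestors
#' (`1.-.-.-` < `1.2.-.-` < `1.2.3.-` < `1.2.3.4` < `1.10.-.-`). This
#' ordering fixes attribute and label column indices in exported files.
#'
#' @param labels character vector of canonical EC labels.
#' @return the sorted vector.
#' @export
ec_sort <- function(labels) {
  if (length(labels) <= 1L) return(labels)
  m <- ec_fields(labels)
  keys <- matrix(0, nrow = length(labels), ncol = 4L)
  spec <- m != "-"
  keys[spec] <- as.numeric(m[spec])  # wildcard sorts first as 0
  labels[order(keys[, 1], keys[, 2], keys[, 3], keys[, 4])]
}

#' EC label ancestors and hierarchical closure
#'
#' `ec_ancestors()` returns the proper prefixes of one EC label in increasing
#' depth; `expand_label_set()` closes a label set under the ancestor
#' relation, so an annotation `1.2.3.4` expands to
#' `{1.-.-.-, 1.2.-.-, 1.2.3.-, 1.2.3.4}`. Expansion is idempotent and
#' monotone, and the empty set (a non-enzyme) expands to itself.
#'
#' @param label one canonical EC label.
#' @return `ec_ancestors()`: character vector of the depth-1..depth-1
#'   prefixes (empty for a depth-1 label).
#' @examples
#' ec_ancestors("1.2.3.4")
#' expand_label_set(c("1.2.3.4", "1.2.4.-"))
#' @export
ec_ancestors <- function(label) {
  stopifnot(length(label) == 1L)
  d <- ec_digits(label)[[1]]
  if (length(d) <= 1L) return(character(0))
  vapply(seq_len(length(d) - 1L), function(k) ec_render(d[seq_len(k)]),
         character(1))
}

#' @rdname ec_ancestors
#' @param labels character vector (a label set), possibly empty.
#' @return `expand_label_set()`: the hierarchically closed set, sorted
#'   canonically.
#' @export
expand_label_set <- function(labels) {
  if (length(labels) == 0L) return(character(0))
  out <- unique(c(labels, unlist(lapply(labels, ec_ancestors),
                                 use.names = FALSE)))
  ec_sort(out)
}

# ---- EC status table (active / deleted / transferred) ----------------------

#' EC status table with transfer resolution
#'
#' Enzyme nomenclature entries are active, deleted, or transferred to one or
#' more replacement EC numbers. `ec_status_table()` builds a resolved table:
#' transfers are followed transitively to their active endpoints and cycles
#' are rejected, so remapping is a single lookup.
#'
#' @param ec character vector of 4-digit EC strings.
#' @param status character vector, each one of `"active"`, `"deleted"`,
#'   `"transferred"`.
#' @param replacements character vector parallel to `ec`; for transferred
#'   entries a semicolon-separated list of replacement EC strings, otherwise
#'   empty (`""` or `NA`).
#' @return an object of class `ec_status_table`.
#' @examples
#' tab <- ec_status_table(c("1.1.1.1", "1.1.1.2"),
#'                        c("transferred", "active"), c("1.1.1.2", ""))
#' remap_annotations(c("1.1.1.1"), tab)
#' @export
ec_status_table <- function(ec, status, replacements = character(length(ec))) {
  stopifnot(length(ec) == length(status), length(ec) == length(replacements))
  ec <- parse_ec(ec)
  if (anyDuplicated(ec))
    stop("duplicate EC entries in status table", call. = FALSE)
  if (any(ec_depth(ec) != 4L))
    stop("status table entries must be complete 4-digit EC numbers",
         call. = FALSE)
  status <- tolower(status)
  bad <- setdiff(unique(status), c("active", "deleted", "transferred"))
  if (length(bad) > 0L)
    stop("unknown EC status: ", paste(bad, collapse = ", "), call. = FALSE)
  replacements[is.na(replacements)] <- ""
  repl <- lapply(seq_along(ec), function(i) {
    if (status[i] != "transferred") return(character(0))
    r <- strsplit(replacements[i], ";", fixed = TRUE)[[1]]
    r <- trimws(r[nzchar(trimws(r))])
    if (length(r) == 0L)
      stop(sprintf("transferred EC %s has no replacement", ec[i]),
           call. = FALSE)
    parse_ec(r)
  })
  names(repl) <- ec
  names(status) <- ec
  resolved <- resolve_ec_status(ec, status, repl)
  structure(list(ec = ec, status = status, replacements = repl,
                 resolved = resolved),
            class = "ec_status_table")
}

# Follow transfer chains to active endpoints; deleted endpoints vanish.
# Depth-first with an on-stack mark to reject cycles.
resolve_ec_status <- function(ec, status, repl) {
  resolved <- vector("list", length(ec))
  names(resolved) <- ec
  state <- structure(integer(length(ec)), names = ec)  # 0 new, 1 open, 2 done
  resolve1 <- function(e) {
    if (!e %in% ec) return(e)  # unknown label: treated as active downstream
    if (state[[e]] == 1L)
      stop(sprintf("cyclic EC transfer chain involving %s", e), call. = FALSE)
    if (state[[e]] == 2L) return(resolved[[e]])
    state[[e]] <<- 1L
    out <- switch(status[[e]],
      active = e,
      deleted = character(0),
      transferred = unique(unlist(lapply(repl[[e]], resolve1),
                                  use.names = FALSE)))
    state[[e]] <<- 2L
    resolved[[e]] <<- out
    out
  }
  for (e in ec) resolve1(e)
  resolved
}

#' @export
print.ec_status_table <- function(x, ...) {
  cat(sprintf("EC status table: %d entries (%d active, %d deleted, %d transferred)\n",
              length(x$ec), sum(x$status == "active"),
              sum(x$status == "deleted"), sum(x$status == "transferred")))
  invisible(x)
}

#' Read an ENZYME-style EC status table
#'
#' Reads a delimited text file with columns `ec`, `status`, `replacements`
#' (semicolon-separated EC strings for transferred entries).
#'
#' @param path file path.
#' @param sep field delimiter, default comma.
#' @return an [ec_status_table()].
#' @export
read_ec_status <- function(path, sep = ",") {
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", quote = "\"",
                          comment.char = "", fill = TRUE)
  need <- c("ec", "status")
  if (!all(need %in% names(df)))
    stop("status table must have columns ec, status[, replacements]",
         call. = FALSE)
  if (!"replacements" %in% names(df)) df$replacements <- ""
  ec_status_table(df$ec, df$status, df$replacements)
}

#' Remap EC annotations through a status table
#'
#' Applies the nomenclature bookkeeping to an annotation set: deleted EC
#' numbers are dropped, transferred numbers are substituted (transitively) by
#' all their replacements, active numbers pass through. Partial labels are
#' never remapped. A complete 4-digit label absent from the table is treated
#' as active and passed through with a warning.
#'
#' @param labels character vector of canonical EC labels (one annotation set).
#' @param table an [ec_status_table()], or `NULL` for a no-op.
#' @return the remapped, deduplicated, canonically sorted label set.
#' @export
remap_annotations <- function(labels, table = NULL) {
  if (length(labels) == 0L) return(character(0))
  if (is.null(table)) return(ec_sort(unique(labels)))
  stopifnot(inherits(table, "ec_status_table"))
  out <- lapply(labels, function(l) {
    if (ec_depth(l) < 4L) return(l)
    r <- table$resolved[[l]]
    if (is.null(r)) {
      warning(sprintf("EC %s not in status table; treated as active", l),
              call. = FALSE)
      return(l)
    }
    r
  })
  ec_sort(unique(unlist(out, use.names = FALSE)))
}

# ---- Label space -----------------------------------------------------------

#' Build the label space of a dataset
#'
#' The label space is the hierarchically closed, canonically ordered union of
#' all EC labels observed across instances, plus the implicit no-EC outcome
#' (the empty label set). Parent links connect each label of depth d > 1 to
#' its depth d-1 prefix.
#'
#' @param annotation_sets a list of label sets (character vectors of canonical
#'   EC labels), typically already remapped and expanded.
#' @return an object of class `ec_label_space` with elements `labels`
#'   (ordered character vector) and `parent` (named character vector, `NA`
#'   for depth-1 labels).
#' @export
build_label_space <- function(annotation_sets) {
  all <- unique(unlist(annotation_sets, use.names = FALSE))
  label_space(if (is.null(all)) character(0) else all)
}

#' @rdname build_label_space
#' @param labels character vector of EC labels; closed under ancestors if not
#'   already.
#' @export
label_space <- function(labels) {
  labels <- expand_label_set(unique(labels))
  parent <- vapply(labels, function(l) {
    a <- ec_ancestors(l)
    if (length(a) == 0L) NA_character_ else a[length(a)]
  }, character(1))
  structure(list(labels = labels, parent = parent), class = "ec_label_space")
}

#' @export
print.ec_label_space <- function(x, ...) {
  cat(sprintf("EC label space: %d labels (%d at depth 4) plus the no-EC outcome\n",
              length(x$labels), sum(ec_depth(x$labels) == 4L)))
  invisible(x)
}

#' @export
length.ec_label_space <- function(x) length(x$labels)
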