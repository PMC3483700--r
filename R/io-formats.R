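# File formats: sparse attribute-relation (ARFF) files with a companion
# label-hierarchy XML document, and delimited annotation tables.
#
# Frozen dialect: every attribute is binary, declared as
# "@attribute <name> {0,1}"; signature attribute columns come first, label
# columns follow; label attribute names are canonical EC strings prefixed
# "EC_" with dots replaced by underscores (EC_1_2_-_-). Data rows use the
# sparse "{index value, ...}" form omitting zeros; an all-zero instance is
# "{}". Each data row is preceded by a "% <instance id>" comment carrying the
# protein accession. Encoding UTF-8, line ending "\n".

label_to_attr <- function(labels) paste0("EC_", gsub(".", "_", labels, fixed = TRUE))
attr_to_label <- function(attrs) gsub("_", ".", sub("^EC_", "", attrs), fixed = TRUE)

#' Write a dataset as a sparse ARFF file with a label-hierarchy document
#'
#' Writes the instances-by-signatures-by-labels dataset in the sparse
#' attribute-relation dialect described in the package vignette, together
#' with a companion XML file mirroring the EC label hierarchy. Output is
#' byte-stable for a fixed dataset.
#'
#' @param dataset an [ec_dataset()].
#' @param arff_path destination for the ARFF file.
#' @param xml_path destination for the hierarchy XML; defaults to
#'   `arff_path` with extension `.xml`.
#' @param relation relation name written in the header.
#' @return invisibly, `c(arff_path, xml_path)`.
#' @seealso [read_sparse_arff()]
#' @export
write_sparse_arff <- function(dataset, arff_path, xml_path = NULL,
                              relation = "ec_dataset") {
  stopifnot(inherits(dataset, "ec_dataset"))
  if (is.null(xml_path)) xml_path <- sub("\\.[^.]*$", ".xml", arff_path)
  labels <- dataset$label_space$labels
  header <- c(
    paste0("@relation ", relation),
    paste0("@attribute ", dataset$signatures, " {0,1}"),
    paste0("@attribute ", label_to_attr(labels), " {0,1}"),
    "@data")
  p <- length(dataset$signatures)
  Xi <- row_index_list(dataset$X)
  Yi <- row_index_list(dataset$Y)
  rows <- vapply(seq_along(dataset$ids), function(i) {
    idx <- c(Xi[[i]] - 1L, Yi[[i]] - 1L + p)  # zero-based column indices
    if (length(idx) == 0L) "{}" else
      paste0("{", paste0(idx, " 1", collapse = ", "), "}")
  }, character(1))
  body <- if (length(dataset$ids) == 0L) character(0)
          else as.vector(rbind(paste0("% ", dataset$ids), rows))
  con <- file(arff_path, open = "wb")
  writeLines(c(header, body), con, sep = "\n", useBytes = TRUE)
  close(con)
  write_label_hierarchy(dataset$label_space, xml_path)
  invisible(c(arff_path, xml_path))
}

# per-row 1-based column indices of a sparse pattern matrix, ascending
row_index_list <- function(M) {
  Mt <- as(M, "TsparseMatrix")
  split(Mt@j + 1L, factor(Mt@i + 1L, levels = seq_len(nrow(M))))
}

#' Write / read the label-hierarchy XML document
#'
#' The hierarchy document nests one `<label>` element per EC label under its
#' parent label, mirroring the label space (Mulan-style
#' `<labels xmlns=...>` root).
#'
#' @param space an [label_space()].
#' @param path file path.
#' @return `write_label_hierarchy()`: the path, invisibly;
#'   `read_label_hierarchy()`: an `ec_label_space`.
#' @export
write_label_hierarchy <- function(space, path) {
  doc <- xml2::xml_new_root("labels",
                            xmlns = "http://mulan.sourceforge.net/labels")
  add_children <- function(node, parent_label) {
    kids <- if (is.na(parent_label)) space$labels[is.na(space$parent)]
            else space$labels[!is.na(space$parent) &
                                space$parent == parent_label]
    for (l in kids) {
      child <- xml2::xml_add_child(node, "label", name = label_to_attr(l))
      add_children(child, l)
    }
  }
  add_children(doc, NA_character_)
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname write_label_hierarchy
#' @export
read_label_hierarchy <- function(path) {
  doc <- xml2::read_xml(path)
  names <- xml2::xml_attr(xml2::xml_find_all(doc, ".//*[local-name()='label']"),
                          "name")
  labels <- attr_to_label(names)
  bad <- labels[is.na(suppressWarnings(vapply(labels, function(l)
    tryCatch(parse_ec(l), error = function(e) NA_character_), character(1))))]
  if (length(bad) > 0L)
    stop("hierarchy file contains non-EC label name(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  label_space(labels)
}

#' Read a sparse ARFF file and its hierarchy document
#'
#' Accepts the dialect written by [write_sparse_arff()]; dense data rows
#' (comma-separated 0/1 values) are also accepted. The hierarchy file
#' determines which trailing attribute columns are labels; its label set
#' must match the ARFF label columns.
#'
#' @param arff_path path to the ARFF file.
#' @param xml_path path to the hierarchy XML; defaults to `arff_path` with
#'   extension `.xml`.
#' @return an [ec_dataset()]. Reading a written dataset reproduces it
#'   exactly (same vocabularies, instances, labels, order).
#' @export
read_sparse_arff <- function(arff_path, xml_path = NULL) {
  if (is.null(xml_path)) xml_path <- sub("\\.[^.]*$", ".xml", arff_path)
  space <- read_label_hierarchy(xml_path)
  lines <- readLines(arff_path, encoding = "UTF-8")
  attrs <- character(0)
  data_at <- NA_integer_
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "%")) next
    low <- tolower(ln)
    if (startsWith(low, "@relation")) next
    if (startsWith(low, "@attribute")) {
      m <- regmatches(ln, regexec("^@attribute\\s+(\\S+)\\s+\\{0,1\\}\\s*$",
                                  ln, ignore.case = TRUE))[[1]]
      if (length(m) != 2L)
        stop(sprintf("line %d: only binary '{0,1}' attributes are supported", i),
             call. = FALSE)
      attrs <- c(attrs, m[2])
      next
    }
    if (startsWith(low, "@data")) { data_at <- i; break }
    stop(sprintf("line %d: unexpected header line '%s'", i, ln), call. = FALSE)
  }
  if (is.na(data_at)) stop("no @data section found", call. = FALSE)
  label_attrs <- label_to_attr(space$labels)
  n_lab <- length(label_attrs)
  n_sig <- length(attrs) - n_lab
  if (n_sig < 0L ||
      !identical(attrs[seq_len(n_lab) + n_sig], label_attrs))
    stop("label columns in ARFF do not match the hierarchy document",
         call. = FALSE)
  signatures <- attrs[seq_len(n_sig)]
  total <- n_sig + n_lab

  ids <- character(0); sig_sets <- list(); lab_sets <- list()
  pending_id <- NULL
  for (i in seq((data_at + 1L), length.out = max(0L, length(lines) - data_at))) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, "%")) { pending_id <- trimws(sub("^%", "", ln)); next }
    on <- parse_arff_row(ln, i, total)
    sig_on <- on[on <= n_sig]
    lab_on <- on[on > n_sig] - n_sig
    ids <- c(ids, pending_id %||% sprintf("instance_%05d", length(ids) + 1L))
    pending_id <- NULL
    sig_sets[[length(ids)]] <- signatures[sig_on]
    lab_sets[[length(ids)]] <- space$labels[lab_on]
  }
  ec_dataset(ids, sig_sets, lab_sets, signatures = signatures, labels = space)
}

# one data row -> ascending 1-based indices of columns set to 1
parse_arff_row <- function(ln, lineno, total) {
  if (startsWith(ln, "{")) {
    if (!endsWith(ln, "}"))
      stop(sprintf("line %d: unterminated sparse row", lineno), call. = FALSE)
    inner <- trimws(substr(ln, 2L, nchar(ln) - 1L))
    if (!nzchar(inner)) return(integer(0))
    parts <- trimws(strsplit(inner, ",", fixed = TRUE)[[1]])
    on <- integer(0)
    for (p in parts) {
      kv <- strsplit(p, "\\s+")[[1]]
      if (length(kv) != 2L || !grepl("^[0-9]+$", kv[1]))
        stop(sprintf("line %d: malformed sparse entry '%s'", lineno, p),
             call. = FALSE)
      idx <- as.integer(kv[1]) + 1L
      if (idx > total)
        stop(sprintf("line %d: attribute index %s out of bounds", lineno, kv[1]),
             call. = FALSE)
      if (!kv[2] %in% c("0", "1"))
        stop(sprintf("line %d: non-binary value '%s'", lineno, kv[2]),
             call. = FALSE)
      if (kv[2] == "1") on <- c(on, idx)
    }
    sort(unique(on))
  } else {
    vals <- trimws(strsplit(ln, ",", fixed = TRUE)[[1]])
    if (length(vals) != total)
      stop(sprintf("line %d: dense row has %d values, expected %d",
                   lineno, length(vals), total), call. = FALSE)
    if (!all(vals %in% c("0", "1")))
      stop(sprintf("line %d: non-binary value in dense row", lineno),
           call. = FALSE)
    which(vals == "1")
  }
}

# ---- Delimited annotation tables --------------------------------------------

parse_two_col <- function(path, sep = ",", what = "annotation") {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  out_k <- character(0); out_v <- character(0)
  for (i in which(keep)) {
    parts <- strsplit(lines[i], sep, fixed = TRUE)[[1]]
    if (endsWith(lines[i], sep)) parts <- c(parts, "")
    if (length(parts) == 1L) parts <- c(parts, "")
    if (length(parts) != 2L || !nzchar(trimws(parts[1])))
      stop(sprintf("%s table %s: malformed row %d: '%s'", what,
                   basename(path), i, lines[i]), call. = FALSE)
    out_k <- c(out_k, trimws(parts[1]))
    out_v <- c(out_v, trimws(parts[2]))
  }
  data.frame(key = out_k, value = out_v, stringsAsFactors = FALSE)
}

#' Read delimited annotation tables
#'
#' Reads (protein, value) pair tables: protein-to-EC, protein-to-signature
#' and optionally protein-to-group (species/taxon). One pair per row, no
#' header; an empty EC value marks the protein as a non-enzyme; duplicate
#' rows are deduplicated; lines starting with `#` are ignored.
#'
#' @param ec_path path to the protein,EC table.
#' @param signature_path path to the protein,signature table.
#' @param group_path optional path to the protein,group table.
#' @param sep field delimiter, default comma.
#' @return list with `ec` (named list protein -> character vector of EC
#'   strings), `signatures` (named list protein -> signature ids) and
#'   `groups` (named character vector or `NULL`). Proteins present in only
#'   one table get empty sets elsewhere at assembly time.
#' @seealso [assemble()]
#' @export
read_annotation_tables <- function(ec_path, signature_path, group_path = NULL,
                                   sep = ",") {
  ecs <- parse_two_col(ec_path, sep, "protein-EC")
  sigs <- parse_two_col(signature_path, sep, "protein-signature")
  ec_map <- lapply(split(ecs$value, ecs$key),
                   function(v) unique(v[nzchar(v)]))
  sig_map <- lapply(split(sigs$value, sigs$key),
                    function(v) unique(v[nzchar(v)]))
  groups <- NULL
  if (!is.null(group_path)) {
    g <- parse_two_col(group_path, sep, "protein-group")
    g <- g[!duplicated(g$key), , drop = FALSE]
    groups <- stats::setNames(g$value, g$key)
  }
  list(ec = ec_map, signatures = sig_map, groups = groups)
}

#' Read a cluster-membership map
#'
#' Two-column delimited text `member,representative` (UniRef-style).
#'
#' @param path file path.
#' @param sep field delimiter.
#' @return named character vector mapping member id to representative id.
#' @seealso [reduce_to_representatives()]
#' @export
read_cluster_map <- function(path, sep = ",") {
  df <- parse_two_col(path, sep, "cluster")
  df <- df[!duplicated(df$key), , drop = FALSE]
  stats::setNames(df$value, df$key)
}

#' Export predictions as CSV
#'
#' One row per instance: protein id, semicolon-separated predicted EC labels,
#' semicolon-separated per-label confidences (aligned), and the confidence of
#' the no-EC call.
#'
#' @param predictions an `ec_predictions` object from [predict.brknn()] or a
#'   baseline model.
#' @param path destination file.
#' @param header optional comment line(s) written before the column header,
#'   each prefixed `#`.
#' @return the path, invisibly.
#' @export
write_predictions <- function(predictions, path, header = NULL) {
  stopifnot(inherits(predictions, "ec_predictions"))
  rows <- vapply(seq_along(predictions$ids), function(i) {
    labs <- predictions$labels[[i]]
    conf <- predictions$confidence[[i]]
    paste(predictions$ids[i],
          paste(labs, collapse = ";"),
          paste(formatC(conf, digits = 6, format = "g"), collapse = ";"),
          formatC(predictions$no_ec_confidence[i], digits = 6, format = "g"),
          sep = ",")
  }, character(1))
  con <- file(path, open = "wb")
  writeLines(c(if (!is.null(header)) paste0("# ", header),
               "protein,predicted_ec,confidence,no_ec_confidence", rows),
             con, sep = "\n", useBytes = TRUE)
  close(con)
  invisible(path)
}
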