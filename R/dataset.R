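#' Tabular sample-sheet datasets
#'
#' A dataset is the meta-information table that makes a directory of data
#' files self-describing: one row per sample, one column per
#' characteristic, with tagged headers (see [col_header()]). On disk it is
#' a plain `dataset.tsv`; in memory it is a `dataset` object holding the
#' ordered column headers and a character-only table. Cell values are raw
#' strings: the framework imposes no vocabulary or type on them — their
#' semantics belong to the applications that consume them.
#'
#' Structural invariants enforced by the constructor:
#' * column base names are unique (case-sensitive);
#' * every row has exactly one cell per column;
#' * if a `Name` column exists its values are unique and non-empty
#'   (applications and grouping address samples by `Name`).
#'
#' @param headers List of [col_header()] objects, in column order.
#' @param table Data frame of character columns, one per header, with
#'   column names equal to the header base names. May have zero rows.
#' @param name Optional dataset name (used for result-directory naming).
#' @param source_path Optional path of the file the dataset was read from.
#' @return An object of class `dataset` with fields `name`, `headers`,
#'   `table` and `source_path`.
#' @seealso [read_dataset()], [write_dataset()], [dataset_from_frame()]
#' @export
new_dataset <- function(headers, table, name = NULL, source_path = NULL) {
  if (!is.list(headers) || !all(vapply(headers, inherits, TRUE, "col_header")))
    pf_stop("headers must be a list of col_header objects")
  bases <- vapply(headers, function(h) h$base_name, "")
  if (anyDuplicated(bases))
    pf_stop("duplicate column base name %s",
            dQuote(bases[duplicated(bases)][1L]))
  if (!is.data.frame(table))
    pf_stop("table must be a data frame")
  table <- as.data.frame(lapply(table, as.character),
                         check.names = FALSE, stringsAsFactors = FALSE,
                         optional = TRUE)
  if (ncol(table) != length(headers))
    pf_stop("table has %d columns but %d headers were given",
            ncol(table), length(headers))
  names(table) <- bases
  rownames(table) <- NULL
  if ("Name" %in% bases && nrow(table) > 0L) {
    nm <- table[["Name"]]
    if (any(!nzchar(nm)))
      pf_stop("empty value in the Name column (row %d)", which(!nzchar(nm))[1L])
    if (anyDuplicated(nm))
      pf_stop("duplicate Name value %s", dQuote(nm[duplicated(nm)][1L]))
  }
  structure(list(name = name, headers = headers, table = table,
                 source_path = source_path),
            class = "dataset")
}

#' Build a dataset from a data frame with tagged column names
#'
#' Convenience constructor: the data frame's column names are full header
#' strings (e.g. `"Read1 [File]"`) that are parsed with [parse_header()].
#'
#' @param df Data frame; all columns are coerced to character.
#' @inheritParams new_dataset
#' @return A `dataset`.
#' @examples
#' ds <- dataset_from_frame(data.frame(
#'   Name = c("s1", "s2"),
#'   `Read1 [File]` = c("reads/s1.fastq.gz", "reads/s2.fastq.gz"),
#'   check.names = FALSE))
#' dataset_colnames(ds)
#' @export
dataset_from_frame <- function(df, name = NULL) {
  headers <- lapply(names(df), parse_header)
  names(df) <- vapply(headers, function(h) h$base_name, "")
  new_dataset(headers, df, name = name)
}

#' @export
print.dataset <- function(x, ...) {
  cat(sprintf("<dataset%s: %d sample%s x %d column%s>\n",
              if (is.null(x$name)) "" else paste0(" ", dQuote(x$name)),
              nrow(x$table), if (nrow(x$table) == 1L) "" else "s",
              length(x$headers), if (length(x$headers) == 1L) "" else "s"))
  hdr <- vapply(x$headers, format_header, "")
  cat("  columns: ", paste(hdr, collapse = ", "), "\n", sep = "")
  if (nrow(x$table) > 0L) {
    shown <- utils::head(x$table, 6L)
    print(shown, row.names = FALSE)
    if (nrow(x$table) > 6L) cat("  ...", nrow(x$table) - 6L, "more rows\n")
  }
  invisible(x)
}

#' Column base names of a dataset
#' @param dataset A `dataset`.
#' @return Character vector in column order.
#' @export
dataset_colnames <- function(dataset) {
  stopifnot(inherits(dataset, "dataset"))
  vapply(dataset$headers, function(h) h$base_name, "")
}

#' Sample names of a dataset
#' @param dataset A `dataset` with a `Name` column.
#' @return Character vector of the `Name` column, in row order.
#' @export
sample_names <- function(dataset) {
  stopifnot(inherits(dataset, "dataset"))
  if (!"Name" %in% dataset_colnames(dataset))
    pf_stop("dataset has no Name column")
  dataset$table[["Name"]]
}

#' Datasets are compared on content, not provenance
#' @keywords internal
#' @noRd
dataset_equal <- function(a, b) {
  identical(lapply(a$headers, unclass), lapply(b$headers, unclass)) &&
    identical(a$table, b$table)
}

#' Read a dataset.tsv file
#'
#' Parses a tab-separated sample sheet whose first line is the header row.
#' Cells are kept as raw strings with no type coercion; empty lines are
#' skipped. The TSV dialect is deliberately quote-free so the file stays
#' greppable: a tab or newline can never occur inside a cell.
#'
#' @param path Path to the tsv file.
#' @param name Optional dataset name; defaults to the parent directory's
#'   name, which for result datasets is the run directory.
#' @return A [new_dataset()] with `source_path` set.
#' @export
read_dataset <- function(path, name = NULL) {
  if (!file.exists(path))
    pf_stop("dataset file %s does not exist", dQuote(path))
  lines <- read_text_lines(path)
  if (length(lines) == 0L || !nzchar(trimws(lines[1L])))
    pf_stop("%s: empty file (missing header row)", path)
  header_cells <- split_tsv_line(lines[1L])
  headers <- vector("list", length(header_cells))
  for (i in seq_along(header_cells)) {
    headers[[i]] <- tryCatch(parse_header(header_cells[i]),
                             error = function(e)
                               pf_stop("%s: line 1: %s", path, conditionMessage(e)))
  }
  bases <- vapply(headers, function(h) h$base_name, "")
  if (anyDuplicated(bases))
    pf_stop("%s: line 1: duplicate column base name %s",
            path, dQuote(bases[duplicated(bases)][1L]))
  body_idx <- which(seq_along(lines) > 1L & nzchar(lines))
  cells <- lapply(lines[body_idx], split_tsv_line)
  n_col <- length(headers)
  for (k in seq_along(cells)) {
    if (length(cells[[k]]) != n_col)
      pf_stop("%s: line %d: expected %d cells, found %d",
              path, body_idx[k], n_col, length(cells[[k]]))
  }
  table <- as.data.frame(
    stats::setNames(lapply(seq_len(n_col), function(j)
      vapply(cells, `[[`, "", j)), bases),
    check.names = FALSE, stringsAsFactors = FALSE)
  if (length(cells) == 0L)
    table <- as.data.frame(stats::setNames(rep(list(character()), n_col), bases),
                           check.names = FALSE, stringsAsFactors = FALSE)
  if ("Name" %in% bases && nrow(table) > 0L) {
    nm <- table[["Name"]]
    dup <- which(duplicated(nm))
    if (length(dup))
      pf_stop("%s: line %d: duplicate Name value %s",
              path, body_idx[dup[1L]], dQuote(nm[dup[1L]]))
    if (any(!nzchar(nm)))
      pf_stop("%s: line %d: empty Name value",
              path, body_idx[which(!nzchar(nm))[1L]])
  }
  if (is.null(name))
    name <- basename(dirname(abs_path(path)))
  new_dataset(headers, table, name = name, source_path = abs_path(path))
}

#' Write a dataset to a dataset.tsv file
#'
#' Canonical serialization: UTF-8, LF line endings, header row of
#' canonically formatted tagged headers, cells joined by single tabs.
#' `read_dataset(write_dataset(d, p))` reproduces `d`'s columns and rows
#' exactly. Because the dialect has no quoting, a cell containing a tab,
#' newline or carriage return is a serialization error.
#'
#' @param dataset A `dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "dataset"))
  cells <- unlist(dataset$table, use.names = FALSE)
  bad <- grepl("[\t\n\r]", cells)
  if (any(bad))
    pf_stop("cell value %s contains a tab or newline; the tsv dialect cannot quote it",
            dQuote(cells[bad][1L]))
  header_line <- paste(vapply(dataset$headers, format_header, ""),
                       collapse = "\t")
  body <- if (nrow(dataset$table) == 0L) character() else
    do.call(paste, c(unname(as.list(dataset$table)), sep = "\t"))
  write_lines_lf(c(header_line, body), path)
}

#' Columns carrying a given tag
#'
#' @param dataset A `dataset`.
#' @param tag Tag token, matched case-sensitively.
#' @return Base names of the columns whose tag list contains `tag`, in
#'   column order.
#' @examples
#' ds <- dataset_from_frame(data.frame(
#'   Name = "s1", `Read1 [File]` = "r.fastq.gz", check.names = FALSE))
#' columns_with_tag(ds, "File")
#' @export
columns_with_tag <- function(dataset, tag) {
  stopifnot(inherits(dataset, "dataset"))
  keep <- vapply(dataset$headers, function(h) tag %in% h$tags, TRUE)
  dataset_colnames(dataset)[keep]
}

#' Group samples by experimental factors
#'
#' Partitions the samples by the tuple of their values in all
#' `Factor`-tagged columns (in column order) — the grouping a differential
#' comparison needs. With no `Factor` column all samples form one group
#' keyed by the empty tuple. An empty factor cell is treated as the level
#' `""`, i.e. it forms its own group rather than being dropped.
#'
#' @param dataset A `dataset` with a `Name` column.
#' @return A list of groups ordered by key; each group is a list with
#'   `key` (character vector of factor values, one per Factor column) and
#'   `samples` (sample names in row order). The groups partition the
#'   sample set.
#' @export
factor_groups <- function(dataset) {
  nms <- sample_names(dataset)
  fcols <- columns_with_tag(dataset, "Factor")
  if (length(fcols) == 0L) {
    return(list(list(key = character(), samples = nms)))
  }
  keymat <- dataset$table[fcols]
  id <- do.call(paste, c(unname(as.list(keymat)), sep = "\x1f"))
  uniq <- sort(unique(id), method = "radix")
  lapply(uniq, function(u) {
    rows <- which(id == u)
    list(key = as.character(unlist(keymat[rows[1L], ], use.names = FALSE)),
         samples = nms[rows])
  })
}

#' Known header tags that trigger framework behaviour
#' @keywords internal
#' @noRd
KNOWN_TAGS <- c("File", "Link", "Factor", "Characteristics")

#' Validate a dataset against its data files
#'
#' Checks the contract a sample sheet makes about the file system: every
#' non-empty cell of every `File`-tagged column, interpreted as a path
#' relative to `data_root`, must exist. Tags outside the four recognised
#' ones (`File`, `Link`, `Factor`, `Characteristics`) are reported as
#' warnings only — column semantics are user-extensible, so an unknown tag
#' is never an error. Absolute paths in File cells are accepted but flagged
#' because they break portability of the directory. The check is pure: it
#' modifies neither the dataset nor the file system.
#'
#' @param dataset A `dataset`.
#' @param data_root Directory against which File cells are resolved.
#' @return A `validation_report` with fields `missing_files` (data frame:
#'   name, column, path), `duplicate_names`, `unknown_tags` (data frame:
#'   column, tag), `absolute_paths` and `ok`. `ok` is `TRUE` iff there are
#'   no missing files and no duplicate names.
#' @export
validate_dataset <- function(dataset, data_root) {
  stopifnot(inherits(dataset, "dataset"))
  if (!dir.exists(data_root))
    pf_stop("data_root %s does not exist", dQuote(data_root))
  bases <- dataset_colnames(dataset)
  row_label <- if ("Name" %in% bases && nrow(dataset$table) > 0L)
    dataset$table[["Name"]] else as.character(seq_len(nrow(dataset$table)))

  missing <- list()
  absolute <- character()
  for (col in columns_with_tag(dataset, "File")) {
    vals <- dataset$table[[col]]
    for (i in seq_along(vals)) {
      cell <- vals[i]
      if (!nzchar(cell)) next
      if (is_abs_path(cell)) {
        absolute <- c(absolute, cell)
        resolved <- cell
      } else {
        resolved <- file.path(data_root, cell)
      }
      if (!file.exists(resolved))
        missing[[length(missing) + 1L]] <-
          data.frame(name = row_label[i], column = col, path = cell,
                     stringsAsFactors = FALSE)
    }
  }
  missing_files <- if (length(missing)) do.call(rbind, missing) else
    data.frame(name = character(), column = character(), path = character(),
               stringsAsFactors = FALSE)

  dup <- character()
  if ("Name" %in% bases) {
    nm <- dataset$table[["Name"]]
    dup <- unique(nm[duplicated(nm)])
  }

  unknown <- list()
  for (h in dataset$headers) {
    for (tg in setdiff(h$tags, KNOWN_TAGS))
      unknown[[length(unknown) + 1L]] <-
        data.frame(column = h$base_name, tag = tg, stringsAsFactors = FALSE)
  }
  unknown_tags <- if (length(unknown)) do.call(rbind, unknown) else
    data.frame(column = character(), tag = character(), stringsAsFactors = FALSE)

  structure(list(missing_files = missing_files,
                 duplicate_names = dup,
                 unknown_tags = unknown_tags,
                 absolute_paths = unique(absolute),
                 ok = nrow(missing_files) == 0L && length(dup) == 0L),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(if (x$ok) "dataset OK" else "dataset INVALID", "\n")
  if (nrow(x$missing_files)) {
    cat("missing files:\n")
    print(x$missing_files, row.names = FALSE)
  }
  if (length(x$duplicate_names))
    cat("duplicate sample names:", paste(x$duplicate_names, collapse = ", "), "\n")
  if (nrow(x$unknown_tags)) {
    cat("warnings: unknown tags:",
        paste(sprintf("%s [%s]", x$unknown_tags$column, x$unknown_tags$tag),
              collapse = ", "), "\n")
  }
  if (length(x$absolute_paths))
    cat("warnings: absolute File paths reduce portability:",
        paste(x$absolute_paths, collapse = ", "), "\n")
  invisible(x)
}
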