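#' Column headers with bracketed tags
#'
#' Sample-sheet columns carry a base name plus an optional, ordered list of
#' tags written as a comma-separated group in square brackets, e.g.
#' `"Read1 [File]"` or `"X [Factor,Link]"`. The base name identifies the
#' column; tags annotate how the framework should treat its values. Four
#' tags trigger behaviour (`File`, `Link`, `Factor`, `Characteristics`);
#' any other tag is preserved verbatim and reported as a warning during
#' validation, never rejected.
#'
#' @param base_name Column name; must not contain brackets, tabs or
#'   newlines. Surrounding whitespace is stripped.
#' @param tags Character vector of tag tokens (possibly empty). Tokens must
#'   be non-empty and free of brackets and commas; duplicates are rejected.
#' @return An object of class `col_header` with fields `base_name` and
#'   `tags`.
#' @examples
#' h <- col_header("Read1", "File")
#' format_header(h)
#' parse_header("Genotype [Factor]")
#' @export
col_header <- function(base_name, tags = character()) {
  if (!is.character(base_name) || length(base_name) != 1L || is.na(base_name))
    pf_stop("column base name must be a single string")
  base_name <- trimws(base_name)
  if (!nzchar(base_name))
    pf_stop("column base name must be non-empty")
  if (grepl("[][]", base_name))
    pf_stop("column base name %s must not contain brackets", dQuote(base_name))
  if (grepl("[\t\n\r]", base_name))
    pf_stop("column base name must not contain tabs or newlines")
  tags <- trimws(as.character(tags))
  if (any(!nzchar(tags) | is.na(tags)))
    pf_stop("column %s: empty tag token", dQuote(base_name))
  bad <- grepl("[][,\t\n\r]", tags)
  if (any(bad))
    pf_stop("column %s: tag %s contains brackets or commas",
            dQuote(base_name), dQuote(tags[bad][1L]))
  if (anyDuplicated(tags))
    pf_stop("column %s: duplicate tag %s",
            dQuote(base_name), dQuote(tags[duplicated(tags)][1L]))
  structure(list(base_name = base_name, tags = tags), class = "col_header")
}

#' Parse a tagged column header
#'
#' Splits a header such as `"Genotype [Factor]"` into its base name and tag
#' list. A header is either a bare name or a name followed by exactly one
#' trailing bracketed tag group; text after the bracket group, unbalanced
#' brackets, empty tag tokens and duplicate tags are parse errors.
#'
#' @param header_text Header string, e.g. `"Read1 [File]"`.
#' @return A [col_header()].
#' @export
parse_header <- function(header_text) {
  if (!is.character(header_text) || length(header_text) != 1L)
    pf_stop("header must be a single string")
  raw <- trimws(header_text)
  if (!nzchar(raw))
    pf_stop("empty column header")
  m <- regmatches(raw, regexec("^([^][]+?)\\s*\\[([^][]*)\\]$", raw))[[1L]]
  if (length(m) == 3L) {
    base <- m[2L]
    tag_text <- m[3L]
    n_commas <- length(regmatches(tag_text,
                                  gregexpr(",", tag_text, fixed = TRUE))[[1L]])
    n_expected <- n_commas + 1L
    tags <- strsplit(tag_text, ",", fixed = TRUE)[[1L]]
    length(tags) <- n_expected          # keep trailing empty tokens visible
    tags[is.na(tags)] <- ""
    if (any(!nzchar(trimws(tags))))
      pf_stop("header %s: empty tag token", dQuote(raw))
    return(col_header(base, tags))
  }
  if (grepl("[][]", raw))
    pf_stop("header %s: malformed bracket group", dQuote(raw))
  col_header(raw)
}

#' Canonical text form of a column header
#'
#' Inverse of [parse_header()]: `"base [t1,t2]"` with a single space before
#' the bracket and no spaces inside, or just the base name when the tag
#' list is empty.
#'
#' @param header A [col_header()].
#' @return A single string.
#' @export
format_header <- function(header) {
  stopifnot(inherits(header, "col_header"))
  if (length(header$tags) == 0L) return(header$base_name)
  paste0(header$base_name, " [", paste(header$tags, collapse = ","), "]")
}

#' @export
format.col_header <- function(x, ...) format_header(x)

#' @export
print.col_header <- function(x, ...) {
  cat("<column> ", format_header(x), "\n", sep = "")
  invisible(x)
}

#' @export
`==.col_header` <- function(e1, e2) {
  identical(e1$base_name, e2$base_name) && identical(e1$tags, e2$tags)
}
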