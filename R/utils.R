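`%||%` <- function(x, y) if (is.null(x)) y else x

## User-facing errors carry the class "pf_error" so the command-line
## driver can distinguish them (exit 1) from internal faults (exit 2).
pf_stop <- function(...) {
  stop(errorCondition(sprintf(...), class = c("pf_error", "error", "condition")))
}

## Split one TSV line into cells, preserving trailing empty fields
## (strsplit() drops them).
split_tsv_line <- function(line) {
  tabs <- gregexpr("\t", line, fixed = TRUE)[[1L]]
  n <- if (tabs[1L] == -1L) 1L else length(tabs) + 1L
  cells <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  length(cells) <- n
  cells[is.na(cells)] <- ""
  cells
}

## Write lines with LF endings regardless of platform.
write_lines_lf <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

read_text_lines <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sub("\r$", "", lines)
}

iso_utc <- function(time) {
  format(as.POSIXct(time, tz = "UTC"), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

stamp_utc <- function(time) {
  format(as.POSIXct(time, tz = "UTC"), "%Y%m%d-%H%M%S", tz = "UTC")
}

is_abs_path <- function(path) {
  grepl("^(/|~|[A-Za-z]:[/\\\\])", path)
}

## Absolute, symlink-resolved form of a path that may not exist yet.
abs_path <- function(path) {
  if (file.exists(path)) return(normalizePath(path, winslash = "/"))
  parent <- dirname(path)
  if (parent == path) return(path)
  file.path(abs_path(parent), basename(path))
}

## Path of `path` relative to `root`, or NULL when it lies outside root.
path_relative_to <- function(path, root) {
  p <- abs_path(path)
  r <- abs_path(root)
  if (identical(p, r)) return(".")
  prefix <- paste0(r, "/")
  if (startsWith(p, prefix)) substring(p, nchar(prefix) + 1L) else NULL
}

## A filesystem-safe token for directory names.
sanitize_token <- function(x) {
  x <- gsub("[^A-Za-z0-9._-]+", "_", x)
  x <- gsub("^_+|_+$", "", x)
  if (!nzchar(x)) "dataset" else x
}

## Run code with a private, restorable RNG state so generators do not
## disturb the caller's random stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}
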