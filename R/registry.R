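REGISTRY_COLUMNS <- c("id", "name", "tsv_path", "parent_id", "app_name",
                      "created_at")

empty_registry_frame <- function() {
  data.frame(id = integer(), name = character(), tsv_path = character(),
             parent_id = integer(), app_name = character(),
             created_at = character(), stringsAsFactors = FALSE)
}

#' Create an empty dataset registry
#'
#' The registry is the project's lineage index: one record per dataset,
#' each derived dataset pointing at the dataset it was computed from and
#' the application that produced it. It replaces a database with a single
#' tab-separated file in the project root, so the whole project history
#' stays greppable and travels with the directory.
#'
#' @param path File the registry persists to.
#' @return A `registry` object (`records` data frame, `next_id`, `path`).
#' @export
new_registry <- function(path) {
  structure(list(records = empty_registry_frame(), next_id = 1L,
                 path = path),
            class = "registry")
}

check_registry_frame <- function(records) {
  if (anyDuplicated(records$id))
    pf_stop("registry: duplicate id %d", records$id[duplicated(records$id)][1L])
  for (i in seq_len(nrow(records))) {
    p <- records$parent_id[i]
    if (!is.na(p)) {
      if (!p %in% records$id)
        pf_stop("registry: record %d references unknown parent %d",
                records$id[i], p)
      if (p >= records$id[i])
        pf_stop("registry: record %d has parent %d with a non-smaller id (cycle risk)",
                records$id[i], p)
    }
  }
  invisible(records)
}

#' Load a registry file
#'
#' @param path Registry file; a missing file yields an empty registry.
#' @return A `registry`.
#' @export
registry_load <- function(path) {
  if (!file.exists(path)) return(new_registry(path))
  lines <- read_text_lines(path)
  if (!length(lines)) return(new_registry(path))
  header <- split_tsv_line(lines[1L])
  if (!identical(header, REGISTRY_COLUMNS))
    pf_stop("%s: unexpected registry header", path)
  body <- lines[-1L]
  body <- body[nzchar(body)]
  cells <- lapply(body, split_tsv_line)
  bad <- which(vapply(cells, length, 0L) != length(REGISTRY_COLUMNS))
  if (length(bad))
    pf_stop("%s: line %d: malformed registry row", path, bad[1L] + 1L)
  col <- function(j) vapply(cells, `[[`, "", j)
  records <- data.frame(
    id = as.integer(col(1L)), name = col(2L), tsv_path = col(3L),
    parent_id = suppressWarnings(as.integer(ifelse(col(4L) == "", NA, col(4L)))),
    app_name = ifelse(col(5L) == "", NA_character_, col(5L)),
    created_at = col(6L), stringsAsFactors = FALSE)
  if (length(cells) == 0L) records <- empty_registry_frame()
  check_registry_frame(records)
  structure(list(records = records,
                 next_id = if (nrow(records)) max(records$id) + 1L else 1L,
                 path = path),
            class = "registry")
}

#' Persist a registry to its file
#' @param registry A `registry`.
#' @return The registry path, invisibly.
#' @export
registry_save <- function(registry) {
  stopifnot(inherits(registry, "registry"))
  r <- registry$records
  body <- if (nrow(r) == 0L) character() else
    paste(r$id, r$name, r$tsv_path,
          ifelse(is.na(r$parent_id), "", r$parent_id),
          ifelse(is.na(r$app_name), "", r$app_name),
          r$created_at, sep = "\t")
  write_lines_lf(c(paste(REGISTRY_COLUMNS, collapse = "\t"), body),
                 registry$path)
}

append_record <- function(registry, name, tsv_path, parent_id = NA_integer_,
                          app_name = NA_character_, now = Sys.time()) {
  rec <- data.frame(id = registry$next_id, name = name, tsv_path = tsv_path,
                    parent_id = parent_id, app_name = app_name,
                    created_at = iso_utc(now), stringsAsFactors = FALSE)
  registry$records <- rbind(registry$records, rec)
  check_registry_frame(registry$records)
  registry$next_id <- registry$next_id + 1L
  registry_save(registry)
  list(registry = registry, record = as.list(rec))
}

#' Import an existing dataset as a lineage root
#'
#' Validates the sample sheet against the project's data root (every
#' `File` cell must exist) and, if valid, appends a parentless record and
#' persists the registry. Invalid datasets are refused with the report
#' attached to the error.
#'
#' @param tsv_path Path of the dataset.tsv (absolute, or relative to the
#'   project root).
#' @param name Dataset name recorded in the registry.
#' @param registry A `registry`.
#' @param config A [project_config()].
#' @param now Timestamp (injectable).
#' @return List with the updated `registry` and the new `record`.
#' @export
import_dataset <- function(tsv_path, name, registry, config,
                           now = Sys.time()) {
  stopifnot(inherits(registry, "registry"), inherits(config, "project_config"))
  full <- if (is_abs_path(tsv_path)) tsv_path else
    file.path(config$root, tsv_path)
  ds <- read_dataset(full, name = name)
  report <- validate_dataset(ds, config$data_root)
  if (!report$ok) {
    cond <- errorCondition(
      sprintf("refusing to import %s: %d missing file(s), %d duplicate name(s)",
              tsv_path, nrow(report$missing_files),
              length(report$duplicate_names)),
      class = c("pf_error", "error", "condition"))
    cond$report <- report
    stop(cond)
  }
  stored <- path_relative_to(full, config$root) %||% abs_path(full)
  append_record(registry, name = name, tsv_path = stored, now = now)
}

#' Register the dataset produced by a run
#'
#' Appends a child record whose parent is the run's input dataset and
#' whose application is the one that generated it — one edge of the
#' lineage forest.
#'
#' @param plan A `run_plan` from [prepare_run()].
#' @param parent_id Registry id of the input dataset.
#' @param registry A `registry`.
#' @param config A [project_config()].
#' @param now Timestamp (injectable).
#' @return List with the updated `registry` and the new `record`.
#' @export
register_result <- function(plan, parent_id, registry, config,
                            now = Sys.time()) {
  stopifnot(inherits(plan, "run_plan"), inherits(registry, "registry"))
  parent_id <- as.integer(parent_id)
  if (!parent_id %in% registry$records$id)
    pf_stop("unknown parent dataset id %d", parent_id)
  if (!dir.exists(plan$result_dir))
    pf_stop("result directory %s does not exist", plan$result_dir)
  tsv <- file.path(plan$result_dir, "dataset.tsv")
  stored <- path_relative_to(tsv, config$root) %||% abs_path(tsv)
  append_record(registry, name = basename(plan$result_dir),
                tsv_path = stored, parent_id = parent_id,
                app_name = plan$app_name, now = now)
}

#' The dataset lineage forest
#'
#' Builds the parent/child forest from the registry and renders it two
#' ways: an indented tree (`name (app)` per node, children in id order)
#' and a flat chronological table (id order equals creation order).
#'
#' @param registry A `registry`.
#' @return A `dataset_tree`: `roots` (nested lists with `record` and
#'   `children`), `text` (character vector of rendered tree lines) and
#'   `table` (the records data frame).
#' @export
dataset_tree <- function(registry) {
  stopifnot(inherits(registry, "registry"))
  r <- registry$records
  build <- function(id) {
    rec <- as.list(r[r$id == id, , drop = FALSE])
    kids <- sort(r$id[!is.na(r$parent_id) & r$parent_id == id])
    list(record = rec, children = lapply(kids, build))
  }
  roots <- lapply(sort(r$id[is.na(r$parent_id)]), build)
  render <- function(node, depth) {
    rec <- node$record
    label <- paste0(strrep("  ", depth), rec$name,
                    if (!is.na(rec$app_name)) paste0(" (", rec$app_name, ")")
                    else "")
    c(label, unlist(lapply(node$children, render, depth = depth + 1L)))
  }
  text <- unlist(lapply(roots, render, depth = 0L)) %||% character()
  structure(list(roots = roots, text = as.character(text), table = r),
            class = "dataset_tree")
}

#' @export
print.dataset_tree <- function(x, ...) {
  if (length(x$text)) cat(x$text, sep = "\n") else cat("(no datasets)\n")
  invisible(x)
}

#' Discover application definitions in a directory
#'
#' Each definition lives in its own `.R` file that evaluates to a single
#' [app_spec()] (the file's last expression). Files are sourced in an
#' isolated environment with this package's functions in scope, so a
#' definition reads as a declarative spec: required columns, parameters
#' with defaults, and the two builder functions.
#'
#' @param applications_dir Directory of definition files.
#' @return List of `app_spec` objects in stable name order.
#' @export
discover_apps <- function(applications_dir) {
  if (!dir.exists(applications_dir))
    pf_stop("applications directory %s does not exist", dQuote(applications_dir))
  files <- sort(list.files(applications_dir, pattern = "\\.[rR]$",
                           full.names = TRUE), method = "radix")
  apps <- list()
  for (f in files) {
    env <- new.env(parent = asNamespace("provflow"))
    app <- tryCatch(source(f, local = env)$value,
                    error = function(e)
                      pf_stop("malformed application definition %s: %s",
                              dQuote(f), conditionMessage(e)))
    if (!inherits(app, "app_spec"))
      pf_stop("application definition %s did not evaluate to an app_spec",
              dQuote(f))
    if (app$name %in% names(apps))
      pf_stop("duplicate application name %s (second definition in %s)",
              dQuote(app$name), dQuote(f))
    apps[[app$name]] <- app
  }
  if (length(apps) == 0L) return(list())
  apps[order(names(apps), method = "radix")]
}

#' The example applications bundled with the package
#'
#' Loads the definitions shipped under `inst/apps`: `FastqStats`
#' (per-sample read statistics), `BarcodeCount` (per-sample feature
#' counting), `GroupCompare` (dataset-level two-group comparison) and
#' `FastqcReport` (wraps a real `fastqc` binary, if one is on the PATH).
#'
#' @return Named list of `app_spec` objects.
#' @export
builtin_apps <- function() {
  discover_apps(system.file("apps", package = "provflow"))
}
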