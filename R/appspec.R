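#' Declare an analysis application (a meta-process)
#'
#' An application here never computes data itself. It is a meta-process:
#' from an input dataset and resolved parameters it declares (a) the
#' output dataset — columns and cell contents, including the promised
#' `File` paths — and (b) the shell command lines that will later produce
#' those files. The framework turns these declarations into a
#' self-contained result directory (see [prepare_run()]); the commands
#' are executed afterwards by any POSIX shell.
#'
#' The two builder contracts:
#'
#' * `output_columns(input, params, result_dir_name)` returns a
#'   [new_dataset()] describing the result. It must include a `Name`
#'   column; `File`-tagged cells should be paths inside
#'   `result_dir_name` (which is relative to the project data root).
#'   Per-sample apps must return one row per input row.
#' * `commands(x, params)` returns the command lines for one job as a
#'   character vector. For `granularity = "per_sample"`, `x` is a named
#'   character vector (the sample row) and one job script is generated
#'   per sample; for `"per_dataset"`, `x` is the whole input dataset and
#'   a single script is generated. Command lines refer to input files and
#'   the output directory through the shell variables that the generator
#'   defines (see [shell_var()], `RESULT_DIR`, `DATA_ROOT`,
#'   `INPUT_DATASET`); they may call any non-interactive command-line
#'   tool whose results are representable as files.
#'
#' Applications are only offered for compatible datasets: every entry of
#' `required_columns` must match a column base name of the input (tags
#' are ignored — they annotate type, not identity).
#'
#' @param name Application name; used as a directory-name token.
#' @param analysis_category Grouping label (e.g. `"QC"`, `"Count"`).
#' @param required_columns Non-empty character vector of column base
#'   names the input dataset must possess.
#' @param output_columns,commands The two builder functions (above).
#' @param params List of [param_spec()] objects.
#' @param granularity `"per_sample"` or `"per_dataset"`.
#' @param description Free-text description.
#' @param version Optional tool/app version string recorded in script
#'   headers.
#' @return An `app_spec` object.
#' @export
app_spec <- function(name, analysis_category, required_columns,
                     output_columns, commands,
                     params = list(),
                     granularity = c("per_sample", "per_dataset"),
                     description = "", version = NULL) {
  if (!is.character(name) || length(name) != 1L ||
      !grepl("^[A-Za-z][A-Za-z0-9_.-]*$", name))
    pf_stop("application name %s is not a valid directory-name token",
            dQuote(as.character(name)[1L]))
  granularity <- match.arg(granularity)
  if (!is.character(required_columns) || length(required_columns) == 0L ||
      any(!nzchar(required_columns)))
    pf_stop("application %s: required_columns must be a non-empty character vector",
            name)
  if (!is.function(output_columns) || !is.function(commands))
    pf_stop("application %s: output_columns and commands must be functions", name)
  if (inherits(params, "param_spec")) params <- list(params)
  if (!all(vapply(params, inherits, TRUE, "param_spec")))
    pf_stop("application %s: params must be a list of param_spec objects", name)
  keys <- vapply(params, function(p) p$key, "")
  if (anyDuplicated(keys))
    pf_stop("application %s: duplicate parameter key %s", name,
            dQuote(keys[duplicated(keys)][1L]))
  structure(list(name = name, analysis_category = analysis_category,
                 description = description,
                 required_columns = required_columns,
                 params = params, granularity = granularity,
                 output_columns = output_columns, commands = commands,
                 version = version),
            class = "app_spec")
}

#' @export
print.app_spec <- function(x, ...) {
  cat(sprintf("<application %s> (%s, %s)\n", x$name, x$analysis_category,
              x$granularity))
  cat("  requires columns:", paste(x$required_columns, collapse = ", "), "\n")
  if (length(x$params)) {
    cat("  parameters:\n")
    for (p in x$params)
      cat(sprintf("    %s (%s%s)%s\n", p$key, p$type,
                  if (p$required) ", required"
                  else paste0(", default ",
                              format_param_value(param_default_value(p))),
                  if (is.null(p$description)) "" else paste0(" — ", p$description)))
  }
  invisible(x)
}

#' Is an application applicable to a dataset?
#'
#' The compatibility guarantee: an application is offered for a dataset
#' iff every required column base name is present among the dataset's
#' column base names. Tags are ignored.
#'
#' @param app An [app_spec()].
#' @param dataset A `dataset`.
#' @return `TRUE` or `FALSE`.
#' @export
check_compatibility <- function(app, dataset) {
  stopifnot(inherits(app, "app_spec"), inherits(dataset, "dataset"))
  all(app$required_columns %in% dataset_colnames(dataset))
}

#' Required columns missing from a dataset
#' @keywords internal
#' @noRd
missing_required <- function(app, dataset) {
  setdiff(app$required_columns, dataset_colnames(dataset))
}

#' List applications compatible with a dataset
#'
#' @param apps List of [app_spec()] objects.
#' @param dataset A `dataset`.
#' @return A data frame with columns `category` and `name`, containing
#'   exactly the compatible apps, ordered by category then name.
#' @export
list_compatible <- function(apps, dataset) {
  keep <- vapply(apps, check_compatibility, TRUE, dataset = dataset)
  apps <- apps[keep]
  out <- data.frame(
    category = vapply(apps, function(a) a$analysis_category, ""),
    name = vapply(apps, function(a) a$name, ""),
    stringsAsFactors = FALSE)
  out <- out[order(out$category, out$name, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the output dataset an application promises
#'
#' Invokes the app's `output_columns` builder and enforces its contract:
#' the result is a dataset with a `Name` column, and per-sample apps
#' yield exactly one output row per input row.
#'
#' @param app An [app_spec()].
#' @param input Input `dataset` (must be compatible).
#' @param params A resolved `parameter_set`.
#' @param result_dir_name Result directory path relative to the data
#'   root; `File` cells of the output should point inside it.
#' @return The output `dataset`.
#' @export
build_output_dataset <- function(app, input, params, result_dir_name) {
  stopifnot(inherits(app, "app_spec"), inherits(input, "dataset"),
            inherits(params, "parameter_set"))
  if (!check_compatibility(app, input))
    pf_stop("application %s is not compatible with the dataset (missing: %s)",
            app$name, paste(missing_required(app, input), collapse = ", "))
  out <- app$output_columns(input, params$values, result_dir_name)
  if (!inherits(out, "dataset"))
    pf_stop("application %s: output_columns must return a dataset", app$name)
  if (!"Name" %in% dataset_colnames(out))
    pf_stop("application %s: output dataset must include a Name column", app$name)
  if (app$granularity == "per_sample" && nrow(out$table) != nrow(input$table))
    pf_stop("application %s: per-sample app must yield one output row per input row",
            app$name)
  out$name <- result_dir_name
  out
}
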