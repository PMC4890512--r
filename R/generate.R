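RESERVED_SHELL_VARS <- c("RESULT_DIR", "DATA_ROOT", "INPUT_DATASET")

#' Shell variable name for an input file column
#'
#' Job scripts never contain the runner; instead, the generator resolves
#' every `File`-tagged input cell to an absolute path and binds it to a
#' shell variable that the application's command lines reference.
#' Per-sample scripts bind one variable per File column (`Read1` →
#' `$READ1`); per-dataset scripts bind one per sample and column
#' (`Count`, sample `Mut1` → `$COUNT_MUT1`). `RESULT_DIR`, `DATA_ROOT`
#' and (for per-dataset jobs) `INPUT_DATASET` are always defined.
#'
#' @param column Column base name.
#' @param sample Sample name, for per-dataset jobs; `NULL` otherwise.
#' @return The variable name (without the `$`).
#' @examples
#' shell_var("Read1")
#' shell_var("Count", "Mut1")
#' @export
shell_var <- function(column, sample = NULL) {
  token <- function(x) {
    x <- gsub("[^A-Za-z0-9]+", "_", toupper(x))
    x <- gsub("^_+|_+$", "", x)
    if (grepl("^[0-9]", x)) x <- paste0("V", x)
    x
  }
  v <- if (is.null(sample)) token(column)
       else paste(token(column), token(sample), sep = "_")
  if (v %in% RESERVED_SHELL_VARS)
    pf_stop("column %s maps to the reserved shell variable %s", column, v)
  v
}

sh_assign <- function(var, value) {
  paste0(var, "=", shQuote(value))
}

script_header <- function(app, params, job_name, input_dataset_path,
                          created_at) {
  c("#!/bin/sh",
    paste0("# job: ", job_name),
    paste0("# application: ", app$name),
    paste0("# generator_version: ",
           as.character(utils::packageVersion("provflow"))),
    if (!is.null(app$version)) paste0("# app_version: ", app$version),
    paste0("# input_dataset: ", input_dataset_path),
    paste0("# created: ", iso_utc(created_at)),
    vapply(names(params$values), function(k)
      paste0("# param ", k, "=", format_param_value(params$values[[k]])),
      ""),
    "set -e")
}

file_var_bindings <- function(input, data_root, per_sample_row = NULL) {
  file_cols <- columns_with_tag(input, "File")
  bindings <- character()
  nms <- if ("Name" %in% dataset_colnames(input)) input$table[["Name"]]
         else as.character(seq_len(nrow(input$table)))
  resolve <- function(cell) {
    if (is_abs_path(cell)) cell else file.path(abs_path(data_root), cell)
  }
  if (!is.null(per_sample_row)) {
    row <- input$table[per_sample_row, , drop = FALSE]
    for (col in file_cols) {
      cell <- row[[col]]
      if (!nzchar(cell))
        pf_stop("sample %s: File column %s is empty; cannot generate its job script",
                dQuote(nms[per_sample_row]), dQuote(col))
      v <- shell_var(col)
      bindings[v] <- sh_assign(v, resolve(cell))
    }
  } else {
    for (col in file_cols) {
      for (i in seq_len(nrow(input$table))) {
        cell <- input$table[i, col]
        if (!nzchar(cell))
          pf_stop("sample %s: File column %s is empty; cannot generate the job script",
                  dQuote(nms[i]), dQuote(col))
        v <- shell_var(col, nms[i])
        if (v %in% names(bindings))
          pf_stop("shell variable collision: %s (columns/samples differ only in punctuation)", v)
        bindings[v] <- sh_assign(v, resolve(cell))
      }
    }
  }
  unname(bindings)
}

#' Generate the standalone job scripts of a run (pure)
#'
#' Builds, without writing anything, the POSIX shell scripts that will
#' produce the run's data files. Each script is self-contained: a comment
#' header records the application, generator version, input dataset,
#' creation time and every resolved parameter; `set -e` makes failures
#' fatal; all paths are bound as absolute shell variables so the script
#' can be executed from any working directory by any POSIX shell. The
#' scripts reference only the shell, the tools the application calls and
#' the file system — never this package.
#'
#' @param app An [app_spec()].
#' @param input Compatible input `dataset`.
#' @param params Resolved `parameter_set`.
#' @param result_dir Absolute path of the result directory.
#' @param data_root Absolute path File cells resolve against.
#' @param created_at Timestamp recorded in the headers (injectable so
#'   that regeneration is byte-reproducible).
#' @return A list of `job_script` objects (`job_name`, `script_path`
#'   relative to `result_dir`, `body`).
#' @export
generate_scripts <- function(app, input, params, result_dir, data_root,
                             created_at = Sys.time()) {
  stopifnot(inherits(app, "app_spec"), inherits(input, "dataset"),
            inherits(params, "parameter_set"))
  if (!check_compatibility(app, input))
    pf_stop("application %s is not compatible with the dataset (missing: %s)",
            app$name, paste(missing_required(app, input), collapse = ", "))
  result_dir <- abs_path(result_dir)
  input_ds_path <- file.path(result_dir, "input_dataset.tsv")
  common <- c(sh_assign("RESULT_DIR", result_dir),
              sh_assign("DATA_ROOT", abs_path(data_root)))

  one_script <- function(job_name, bindings, cmd_lines) {
    body <- paste(c(script_header(app, params, job_name, input_ds_path,
                                  created_at),
                    common, bindings, "", cmd_lines, ""),
                  collapse = "\n")
    structure(list(job_name = job_name,
                   script_path = file.path("scripts",
                                           paste0(job_name, ".sh")),
                   body = body),
              class = "job_script")
  }

  if (app$granularity == "per_sample") {
    if (!"Name" %in% dataset_colnames(input))
      pf_stop("per-sample application %s needs a Name column", app$name)
    lapply(seq_len(nrow(input$table)), function(i) {
      row <- vapply(input$table[i, , drop = FALSE], as.character, "")
      names(row) <- dataset_colnames(input)
      job <- paste0(app$name, "__", sanitize_token(row[["Name"]]))
      one_script(job, file_var_bindings(input, data_root, i),
                 app$commands(row, params$values))
    })
  } else {
    bindings <- c(sh_assign("INPUT_DATASET", input_ds_path),
                  file_var_bindings(input, data_root))
    list(one_script(app$name, bindings, app$commands(input, params$values)))
  }
}

#' Prepare a run: Step 1 of the two-phase contract
#'
#' Creates the self-contained result directory for one application run.
#' Only meta-information is written — no data file exists yet:
#'
#' * `input_dataset.tsv` — verbatim copy of the input sample sheet;
#' * `parameters.tsv` — the resolved parameters, `key<TAB>value`;
#' * `dataset.tsv` — the *promised* output dataset (its `File` cells
#'   name files that Step 2 will create);
#' * `scripts/*.sh` — standalone job scripts (executable);
#' * `logs/` — empty, filled by the runner.
#'
#' The directory is named `<App>_<dataset id>_<UTC yyyymmdd-HHMMSS>` under
#' the project's `result_root`. Preparation refuses incompatible
#' datasets, inputs whose File cells do not all exist, and name
#' collisions. With the same inputs, parameters and injected timestamp
#' the directory content is byte-identical.
#'
#' @param app An [app_spec()].
#' @param input Input `dataset` (validated against `config$data_root`).
#' @param overrides Named character vector of parameter overrides.
#' @param config A [project_config()].
#' @param dataset_id Token identifying the input dataset in the directory
#'   name; defaults to the input's `name`.
#' @param now Timestamp used for the directory name and script headers
#'   (injectable for reproducibility tests).
#' @return A `run_plan`: `result_dir`, `app_name`, `input_dataset_path`,
#'   `output_dataset`, `parameter_file_path`, `scripts`, `created_at`.
#' @export
prepare_run <- function(app, input, overrides = character(), config,
                        dataset_id = NULL, now = Sys.time()) {
  stopifnot(inherits(app, "app_spec"), inherits(input, "dataset"),
            inherits(config, "project_config"))
  if (!check_compatibility(app, input))
    pf_stop("application %s requires column(s) %s that the dataset lacks",
            app$name, paste(missing_required(app, input), collapse = ", "))
  report <- validate_dataset(input, config$data_root)
  if (!report$ok)
    pf_stop("input dataset failed validation: %d missing file(s)%s",
            nrow(report$missing_files),
            if (nrow(report$missing_files))
              paste0(" (first: ", report$missing_files$path[1L], ")") else "")
  params <- resolve_params(app, overrides)
  id_token <- sanitize_token(dataset_id %||% input$name %||% "dataset")
  dir_name <- paste(app$name, id_token, stamp_utc(now), sep = "_")
  result_dir <- file.path(config$result_root, dir_name)
  if (dir.exists(result_dir))
    pf_stop("result directory %s already exists", result_dir)
  rel_dir <- path_relative_to(result_dir, config$data_root)
  if (is.null(rel_dir)) {
    warning("result_root lies outside data_root; output File cells will be absolute",
            call. = FALSE)
    rel_dir <- abs_path(result_dir)
  }

  ## Build everything before touching the file system, so a failing
  ## builder leaves no half-made directory behind.
  output <- build_output_dataset(app, input, params, rel_dir)
  scripts <- generate_scripts(app, input, params, result_dir,
                              config$data_root, created_at = now)

  dir.create(result_dir, recursive = TRUE)
  dir.create(file.path(result_dir, "scripts"))
  dir.create(file.path(result_dir, "logs"))
  input_ds_path <- file.path(result_dir, "input_dataset.tsv")
  if (!is.null(input$source_path) && file.exists(input$source_path)) {
    file.copy(input$source_path, input_ds_path)
  } else {
    write_dataset(input, input_ds_path)
  }
  param_path <- file.path(result_dir, "parameters.tsv")
  param_text <- render_parameter_file(params)
  con <- file(param_path, open = "wb")
  if (nzchar(param_text)) writeChar(param_text, con, eos = NULL)
  close(con)
  write_dataset(output, file.path(result_dir, "dataset.tsv"))
  for (s in scripts) {
    p <- file.path(result_dir, s$script_path)
    write_lines_lf(strsplit(s$body, "\n", fixed = TRUE)[[1L]], p)
    Sys.chmod(p, mode = "0755")
  }
  structure(list(result_dir = result_dir,
                 app_name = app$name,
                 input_dataset_path = input_ds_path,
                 output_dataset = output,
                 parameter_file_path = param_path,
                 scripts = scripts,
                 created_at = as.POSIXct(now, tz = "UTC")),
            class = "run_plan")
}

#' @export
print.run_plan <- function(x, ...) {
  cat(sprintf("<run plan: %s>\n  result_dir: %s\n  jobs: %d\n",
              x$app_name, x$result_dir, length(x$scripts)))
  invisible(x)
}
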