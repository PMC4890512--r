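#' Step 2: execute one job script
#'
#' Runs a generated job script as a child `sh` process with stdin closed
#' (jobs must never require interactive input), captures stdout and
#' stderr to `<job>.out` / `<job>.err` in `logs_dir`, and persists the
#' outcome to `<job>.status` (`success <code>` or `failed <code>`, plus
#' start/finish timestamps). A nonzero exit is a recorded failure, not
#' an R error.
#'
#' @param script_path Path of the script (job name = file name without
#'   `.sh`).
#' @param logs_dir Directory for the log and status files.
#' @return A `run_record`: `job_name`, `exit_code`, `started_at`,
#'   `finished_at`, `stdout_log`, `stderr_log`, `status`.
#' @export
execute_script <- function(script_path, logs_dir) {
  if (!file.exists(script_path))
    pf_stop("job script %s does not exist", dQuote(script_path))
  if (!dir.exists(logs_dir))
    dir.create(logs_dir, recursive = TRUE)
  job <- sub("\\.sh$", "", basename(script_path))
  out <- file.path(logs_dir, paste0(job, ".out"))
  err <- file.path(logs_dir, paste0(job, ".err"))
  started <- Sys.time()
  code <- suppressWarnings(
    system2("sh", shQuote(abs_path(script_path)),
            stdout = out, stderr = err, stdin = nullfile()))
  finished <- Sys.time()
  status <- if (code == 0L) "success" else "failed"
  write_lines_lf(c(paste(status, code),
                   paste("started", iso_utc(started)),
                   paste("finished", iso_utc(finished))),
                 file.path(logs_dir, paste0(job, ".status")))
  structure(list(job_name = job, exit_code = as.integer(code),
                 started_at = started, finished_at = finished,
                 stdout_log = out, stderr_log = err, status = status),
            class = "run_record")
}

read_status_file <- function(path) {
  if (!file.exists(path)) return(NULL)
  lines <- read_text_lines(path)
  if (!length(lines)) return(NULL)
  first <- strsplit(lines[1L], " ", fixed = TRUE)[[1L]]
  if (length(first) < 2L || !first[1L] %in% c("success", "failed")) return(NULL)
  list(status = first[1L], exit_code = suppressWarnings(as.integer(first[2L])))
}

plan_scripts <- function(result_dir) {
  scripts_dir <- file.path(result_dir, "scripts")
  if (!dir.exists(scripts_dir))
    pf_stop("%s has no scripts/ directory; not a prepared result directory",
            result_dir)
  sort(list.files(scripts_dir, pattern = "\\.sh$", full.names = TRUE),
       method = "radix")
}

summarize_records <- function(records) {
  statuses <- vapply(records, function(r) r$status, "")
  counts <- table(factor(statuses,
                         levels = c("created", "running", "success", "failed")))
  ran <- statuses %in% c("success", "failed")
  overall <- if (length(records) == 0L || !any(ran)) "pending"
             else if (all(statuses == "success")) "success"
             else if (all(ran) && all(statuses == "failed")) "failed"
             else "partial"
  structure(list(records = records,
                 counts = as.list(as.integer(counts)) |>
                   stats::setNames(names(counts)),
                 overall = overall),
            class = "status_summary")
}

#' Run (or resume) all jobs of a prepared result directory
#'
#' Executes every job script that has not already succeeded, at most
#' `max_parallel` at a time. Rerunning is idempotent: succeeded jobs are
#' skipped, so after a partial failure only the failed jobs are retried.
#' Jobs are independent; no ordering between them is guaranteed.
#'
#' @param result_dir A Step-1 result directory (see [prepare_run()]).
#' @param max_parallel Maximum concurrent jobs (default 1).
#' @return A `status_summary` (see [plan_status()]).
#' @export
run_plan <- function(result_dir, max_parallel = 1L) {
  scripts <- plan_scripts(result_dir)
  logs_dir <- file.path(result_dir, "logs")
  todo <- Filter(function(s) {
    st <- read_status_file(file.path(logs_dir,
                                     paste0(sub("\\.sh$", "", basename(s)),
                                            ".status")))
    is.null(st) || st$status != "success"
  }, scripts)
  if (length(todo)) {
    if (max_parallel > 1L && length(todo) > 1L) {
      parallel::mclapply(todo, execute_script, logs_dir = logs_dir,
                         mc.cores = min(max_parallel, length(todo)))
    } else {
      lapply(todo, execute_script, logs_dir = logs_dir)
    }
  }
  plan_status(result_dir)
}

#' Reconstruct run status from the logs directory
#'
#' A pure read of `logs/*.status`: jobs without a status file are
#' `created`; the summary is `pending` before any job has run, `success`
#' when all jobs succeeded, `failed` when all ran and failed, otherwise
#' `partial`.
#'
#' @param result_dir A Step-1 result directory.
#' @return A `status_summary` with per-job `records`, `counts` and
#'   `overall`.
#' @export
plan_status <- function(result_dir) {
  scripts <- plan_scripts(result_dir)
  logs_dir <- file.path(result_dir, "logs")
  records <- lapply(scripts, function(s) {
    job <- sub("\\.sh$", "", basename(s))
    st <- read_status_file(file.path(logs_dir, paste0(job, ".status")))
    structure(list(job_name = job,
                   exit_code = if (is.null(st)) NA_integer_ else st$exit_code,
                   started_at = NULL, finished_at = NULL,
                   stdout_log = file.path(logs_dir, paste0(job, ".out")),
                   stderr_log = file.path(logs_dir, paste0(job, ".err")),
                   status = if (is.null(st)) "created" else st$status),
              class = "run_record")
  })
  summarize_records(records)
}

#' Check the Step-1 promise after Step 2
#'
#' A prepared directory's `dataset.tsv` names output files before they
#' exist; after execution, every `File` cell must resolve to a real
#' file. This simply applies [validate_dataset()] to the result's
#' `dataset.tsv`.
#'
#' @param result_dir A Step-1 result directory.
#' @param data_root Root against which File cells resolve.
#' @return A `validation_report`; `ok = TRUE` iff all promised files
#'   exist.
#' @export
verify_outputs <- function(result_dir, data_root) {
  ds_path <- file.path(result_dir, "dataset.tsv")
  if (!file.exists(ds_path))
    pf_stop("%s has no dataset.tsv", result_dir)
  validate_dataset(read_dataset(ds_path), data_root)
}

#' @export
print.status_summary <- function(x, ...) {
  cat(sprintf("<run status: %s> (%d job%s)\n", x$overall, length(x$records),
              if (length(x$records) == 1L) "" else "s"))
  for (r in x$records)
    cat(sprintf("  %-30s %s%s\n", r$job_name, r$status,
                if (!is.na(r$exit_code) && r$exit_code != 0L)
                  paste0(" (exit ", r$exit_code, ")") else ""))
  invisible(x)
}
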