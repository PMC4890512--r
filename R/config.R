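CONFIG_FILENAME <- "provflow.conf"

#' Project configuration
#'
#' A project is a directory holding a plain-text config file
#' (`provflow.conf`, `key: value` lines), the data files, the result
#' directories and the lineage registry. Relative paths in the config are
#' resolved against the config file's directory.
#'
#' Keys (with defaults relative to the project root):
#' * `data_root` (`.`) — root against which all `File` cells resolve;
#' * `result_root` (`results`) — where run directories are created; must
#'   lie under `data_root` so that result files remain addressable by
#'   relative paths;
#' * `applications_dir` (`apps`) — application definition files;
#' * `registry_path` (`datasets.tsv`) — the lineage index;
#' * `max_parallel` (`1`) — local runner concurrency.
#'
#' @param root Project root directory.
#' @param data_root,result_root,applications_dir,registry_path,max_parallel
#'   Overrides for the individual settings.
#' @return A `project_config` object with absolute paths.
#' @export
project_config <- function(root,
                           data_root = ".",
                           result_root = "results",
                           applications_dir = "apps",
                           registry_path = "datasets.tsv",
                           max_parallel = 1L) {
  if (!dir.exists(root))
    pf_stop("project root %s does not exist", dQuote(root))
  root <- abs_path(root)
  resolve <- function(p) if (is_abs_path(p)) p else file.path(root, p)
  cfg <- structure(list(root = root,
                        data_root = abs_path(resolve(data_root)),
                        result_root = abs_path(resolve(result_root)),
                        applications_dir = abs_path(resolve(applications_dir)),
                        registry_path = abs_path(resolve(registry_path)),
                        max_parallel = as.integer(max_parallel)),
                   class = "project_config")
  if (is.na(cfg$max_parallel) || cfg$max_parallel < 1L)
    pf_stop("max_parallel must be a positive integer")
  cfg
}

#' Write a skeleton project
#'
#' Creates the config file, the `results/` and `apps/` directories and an
#' empty registry, and copies the bundled example application definitions
#' into `apps/`.
#'
#' @param root Project root (created if absent).
#' @param copy_apps Copy the bundled example app definitions?
#' @return The [project_config()], invisibly.
#' @export
init_project <- function(root, copy_apps = TRUE) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(root, CONFIG_FILENAME)
  if (file.exists(cfg_path))
    pf_stop("%s already exists", cfg_path)
  write_lines_lf(c("data_root: .",
                   "result_root: results",
                   "applications_dir: apps",
                   "registry_path: datasets.tsv",
                   "max_parallel: 1"),
                 cfg_path)
  dir.create(file.path(root, "results"), showWarnings = FALSE)
  dir.create(file.path(root, "apps"), showWarnings = FALSE)
  if (copy_apps) {
    bundled <- list.files(system.file("apps", package = "provflow"),
                          pattern = "\\.[rR]$", full.names = TRUE)
    file.copy(bundled, file.path(root, "apps"))
  }
  cfg <- load_config(cfg_path)
  registry_save(new_registry(cfg$registry_path))
  invisible(cfg)
}

#' Read a project config file
#'
#' @param path Path to a `provflow.conf` file.
#' @return A [project_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    pf_stop("config file %s does not exist", dQuote(path))
  lines <- read_text_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z_]+)\\s*:\\s*(.*?)\\s*$", lines))
  bad <- vapply(kv, length, 0L) != 3L
  if (any(bad))
    pf_stop("%s: malformed config line %s", path, dQuote(lines[bad][1L]))
  vals <- stats::setNames(vapply(kv, `[[`, "", 3L), vapply(kv, `[[`, "", 2L))
  known <- c("data_root", "result_root", "applications_dir",
             "registry_path", "max_parallel")
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    pf_stop("%s: unknown config key %s", path, dQuote(unknown[1L]))
  args <- as.list(vals)
  do.call(project_config, c(list(root = dirname(abs_path(path))), args))
}

#' Locate the project config by upward search
#'
#' @param start Directory to start from (default: working directory).
#' @return Path of the nearest `provflow.conf` in `start` or an ancestor.
#' @export
find_config <- function(start = ".") {
  dir <- abs_path(start)
  repeat {
    cand <- file.path(dir, CONFIG_FILENAME)
    if (file.exists(cand)) return(cand)
    parent <- dirname(dir)
    if (parent == dir)
      pf_stop("no %s found in %s or any parent directory",
              CONFIG_FILENAME, dQuote(abs_path(start)))
    dir <- parent
  }
}

#' @export
print.project_config <- function(x, ...) {
  cat("<project at ", x$root, ">\n", sep = "")
  for (k in c("data_root", "result_root", "applications_dir",
              "registry_path", "max_parallel"))
    cat(sprintf("  %s: %s\n", k, x[[k]]))
  invisible(x)
}
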