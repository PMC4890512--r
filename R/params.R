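#' Declare an application parameter
#'
#' Parameter typing is inferred from the default literal: an integer,
#' double, logical or string default gives an integer/real/boolean/string
#' parameter; a character vector of length > 1 declares an enumerated
#' choice whose first element is the default. A `required` parameter has
#' no usable default and must be supplied when a run is prepared; its
#' coercion type is given by `type`.
#'
#' @param key Parameter name.
#' @param default Default literal, or `NULL` for a required parameter.
#' @param description Optional one-line description.
#' @param required Logical; must the user supply a value?
#' @param type Coercion type for required parameters
#'   (`"string"`, `"integer"`, `"real"`, `"boolean"`).
#' @return A `param_spec` object.
#' @examples
#' param_spec("cores", 4L, "number of threads")
#' param_spec("mode", c("fast", "thorough"))  # choice, default "fast"
#' @export
param_spec <- function(key, default = NULL, description = NULL,
                       required = FALSE,
                       type = c("string", "integer", "real", "boolean")) {
  if (!is.character(key) || length(key) != 1L || !nzchar(key))
    pf_stop("parameter key must be a non-empty string")
  if (grepl("[\t\n=]", key))
    pf_stop("parameter key %s must not contain tabs, newlines or '='", dQuote(key))
  if (required) {
    type <- match.arg(type)
    default <- NULL
  } else {
    if (is.null(default))
      pf_stop("parameter %s: a non-required parameter needs a default", dQuote(key))
    type <- infer_param_type(key, default)
    if (type == "integer") default <- as.integer(default)
  }
  structure(list(key = key, default = default, description = description,
                 required = required, type = type,
                 choices = if (!required && is.character(default) &&
                               length(default) > 1L) default else NULL),
            class = "param_spec")
}

infer_param_type <- function(key, default) {
  if (is.logical(default) && length(default) == 1L) return("boolean")
  if (is.numeric(default) && length(default) == 1L) {
    if (is.integer(default) || isTRUE(all.equal(default, round(default))))
      return("integer")
    return("real")
  }
  if (is.character(default)) {
    if (length(default) == 1L) return("string")
    if (anyDuplicated(default))
      pf_stop("parameter %s: duplicate choice values", dQuote(key))
    return("choice")
  }
  pf_stop("parameter %s: unsupported default type %s", dQuote(key),
          class(default)[1L])
}

coerce_param <- function(spec, value) {
  stopifnot(is.character(value), length(value) == 1L)
  switch(spec$type,
    string = value,
    choice = {
      if (!value %in% spec$choices)
        pf_stop("parameter %s: value %s is not one of {%s}",
                dQuote(spec$key), dQuote(value),
                paste(spec$choices, collapse = ", "))
      value
    },
    integer = {
      if (!grepl("^[+-]?[0-9]+$", trimws(value)))
        pf_stop("parameter %s: %s is not an integer", dQuote(spec$key),
                dQuote(value))
      as.integer(trimws(value))
    },
    real = {
      x <- suppressWarnings(as.numeric(trimws(value)))
      if (is.na(x))
        pf_stop("parameter %s: %s is not a number", dQuote(spec$key),
                dQuote(value))
      x
    },
    boolean = {
      v <- trimws(value)
      if (!v %in% c("true", "false"))
        pf_stop("parameter %s: %s is not true/false", dQuote(spec$key),
                dQuote(value))
      v == "true"
    },
    pf_stop("parameter %s: unknown type", dQuote(spec$key)))
}

param_default_value <- function(spec) {
  if (spec$type == "choice") spec$choices[1L] else spec$default
}

#' Resolve application parameters against user overrides
#'
#' Starts from each parameter's default and applies the string-valued
#' overrides (as received from a command line or a parameter file),
#' coercing every override to the parameter's declared type. Choice
#' parameters must receive one of their enumerated values; required
#' parameters without an override are an error, as are unknown keys.
#'
#' @param app An [app_spec()].
#' @param overrides Named character vector or named list of strings.
#' @return A `parameter_set`: list with `values` (named, typed) and
#'   `provenance` (`"default"` or `"user"` per key), in the app's declared
#'   parameter order.
#' @export
resolve_params <- function(app, overrides = character()) {
  stopifnot(inherits(app, "app_spec"))
  overrides <- as.list(overrides)
  if (length(overrides) && (is.null(names(overrides)) ||
                            any(!nzchar(names(overrides)))))
    pf_stop("parameter overrides must be named")
  keys <- vapply(app$params, function(p) p$key, "")
  unknown <- setdiff(names(overrides), keys)
  if (length(unknown))
    pf_stop("unknown parameter %s for application %s",
            dQuote(unknown[1L]), app$name)
  values <- list()
  provenance <- character()
  for (p in app$params) {
    if (p$key %in% names(overrides)) {
      values[[p$key]] <- coerce_param(p, as.character(overrides[[p$key]]))
      provenance[p$key] <- "user"
    } else if (p$required) {
      pf_stop("required parameter %s was not supplied", dQuote(p$key))
    } else {
      values[[p$key]] <- param_default_value(p)
      provenance[p$key] <- "default"
    }
  }
  structure(list(values = values, provenance = provenance, app_name = app$name),
            class = "parameter_set")
}

format_param_value <- function(v) {
  if (is.logical(v)) return(if (v) "true" else "false")
  if (is.integer(v)) return(as.character(v))
  if (is.double(v)) return(format(v, digits = 15, scientific = FALSE))
  as.character(v)
}

#' Serialize a parameter set to parameter-file text
#'
#' One `key<TAB>value` line per parameter, in the application's declared
#' order; booleans render as `true`/`false`. The text parses back to an
#' identical set via [parse_parameter_file()] given the same app spec.
#'
#' @param params A `parameter_set` from [resolve_params()].
#' @return A character scalar (possibly `""` for a parameterless app).
#' @export
render_parameter_file <- function(params) {
  stopifnot(inherits(params, "parameter_set"))
  if (length(params$values) == 0L) return("")
  paste0(paste(names(params$values),
               vapply(params$values, format_param_value, ""),
               sep = "\t", collapse = "\n"), "\n")
}

#' Read a parameter file back into a parameter set
#'
#' @param app The [app_spec()] that defines the parameter types.
#' @param path_or_text Path of a `parameters.tsv` file, or its literal
#'   text.
#' @return A `parameter_set`.
#' @export
parse_parameter_file <- function(app, path_or_text) {
  is_path <- !grepl("\n", path_or_text, fixed = TRUE) &&
    file.exists(path_or_text)
  lines <- if (is_path) read_text_lines(path_or_text)
           else strsplit(path_or_text, "\n", fixed = TRUE)[[1L]]
  lines <- lines[nzchar(lines)]
  kv <- lapply(lines, split_tsv_line)
  bad <- vapply(kv, function(x) length(x) != 2L, TRUE)
  if (any(bad))
    pf_stop("malformed parameter line %s", dQuote(lines[bad][1L]))
  overrides <- stats::setNames(vapply(kv, `[[`, "", 2L),
                               vapply(kv, `[[`, "", 1L))
  resolve_params(app, overrides)
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameters for ", x$app_name, ">\n", sep = "")
  for (k in names(x$values))
    cat(sprintf("  %s = %s (%s)\n", k, format_param_value(x$values[[k]]),
                x$provenance[[k]]))
  invisible(x)
}
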