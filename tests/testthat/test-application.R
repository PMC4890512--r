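## A tiny app used across these tests: per-sample copy of a File column.
toy_app <- function(name = "ToyCopy", required = c("Name", "Read1"),
                    granularity = "per_sample",
                    params = list(param_spec("cores", 4L))) {
  app_spec(
    name = name, analysis_category = "Misc",
    required_columns = required, params = params,
    granularity = granularity,
    output_columns = function(input, params, rd) {
      nm <- sample_names(input)
      new_dataset(list(col_header("Name"), col_header("Out", "File")),
                  data.frame(Name = nm,
                             Out = file.path(rd, paste0(nm, ".txt")),
                             check.names = FALSE))
    },
    commands = function(sample, params)
      sprintf('cp "$READ1" "$RESULT_DIR/%s.txt"', sample[["Name"]]))
}

reads_frame <- function(n = 2L) {
  data.frame(Name = sprintf("s%d", seq_len(n)),
             `Read1 [File]` = sprintf("reads/s%d.fastq.gz", seq_len(n)),
             check.names = FALSE)
}

test_that("compatibility matches on base names only, ignoring tags", {
  app <- toy_app()
  expect_true(check_compatibility(app, dataset_from_frame(reads_frame())))
  ## the example sheet names its column "Read", not "Read1"
  expect_false(check_compatibility(app, table1_dataset()))
  only_name <- dataset_from_frame(data.frame(Name = character(),
                                             check.names = FALSE))
  expect_true(check_compatibility(toy_app(required = "Name"), only_name))
  expect_error(toy_app(required = character()), "required_columns")
})

test_that("list_compatible equals brute-force required-column filtering", {
  expect_identical(nrow(list_compatible(list(), table1_dataset())), 0L)
  set.seed(13)
  pool <- c("Name", "Read1", "Read2", "Count", "Stats", "Genotype", "Zzz")
  for (i in 1:20) {
    apps <- lapply(seq_len(sample(1:6, 1)), function(j)
      toy_app(name = paste0("App", j),
              required = sample(pool, sample(1:4, 1)),
              granularity = "per_sample"))
    cols <- unique(c("Name", sample(pool, sample(1:6, 1))))
    df <- as.data.frame(stats::setNames(
      lapply(cols, function(cn) if (cn == "Name") "s1" else "v"), cols),
      check.names = FALSE)
    ds <- dataset_from_frame(df)
    got <- list_compatible(apps, ds)$name
    brute <- sort(unlist(lapply(apps, function(a)
      if (all(a$required_columns %in% cols)) a$name else NULL)))
    expect_identical(sort(got), as.character(brute))
  }
})

test_that("parameter resolution: defaults, coercion, and errors by key", {
  app <- builtin_apps()$FastqStats
  ps <- resolve_params(app, character())
  expect_identical(ps$values$cores, 4L)
  expect_identical(unname(ps$provenance["cores"]), "default")

  ps8 <- resolve_params(app, c(cores = "8"))
  expect_identical(ps8$values$cores, 8L)
  expect_identical(unname(ps8$provenance["cores"]), "user")

  expect_error(resolve_params(app, c(corez = "8")), "corez")
  expect_error(resolve_params(app, c(cores = "eight")), "not an integer")

  rich <- app_spec("Rich", "Misc", "Name",
                   output_columns = function(i, p, r) i,
                   commands = function(s, p) "true",
                   params = list(
                     param_spec("alpha", 0.5),
                     param_spec("verbose", FALSE),
                     param_spec("mode", c("fast", "slow")),
                     param_spec("label", "x"),
                     param_spec("genome", required = TRUE)))
  ps <- resolve_params(rich, c(genome = "mm10"))
  expect_identical(ps$values$mode, "fast")     # first choice is the default
  expect_identical(ps$values$verbose, FALSE)
  expect_identical(ps$values$genome, "mm10")
  ps2 <- resolve_params(rich, c(genome = "hg38", verbose = "true",
                                mode = "slow", alpha = "0.25"))
  expect_identical(ps2$values$verbose, TRUE)
  expect_identical(ps2$values$alpha, 0.25)
  expect_error(resolve_params(rich, c(genome = "x", mode = "medium")),
               "mode")
  expect_error(resolve_params(rich, character()), "genome")
})

test_that("parameter files render in declared order and round-trip", {
  app <- builtin_apps()$FastqStats
  expect_identical(render_parameter_file(resolve_params(app)), "cores\t4\n")
  paramless <- app_spec("Bare", "Misc", "Name",
                        output_columns = function(i, p, r) i,
                        commands = function(s, p) "true")
  expect_identical(render_parameter_file(resolve_params(paramless)), "")

  rich <- app_spec("Rich", "Misc", "Name",
                   output_columns = function(i, p, r) i,
                   commands = function(s, p) "true",
                   params = list(param_spec("alpha", 0.5),
                                 param_spec("verbose", FALSE),
                                 param_spec("mode", c("fast", "slow")),
                                 param_spec("n", 3L)))
  set.seed(3)
  for (i in 1:10) {
    ov <- c(alpha = format(runif(1), digits = 10),
            verbose = sample(c("true", "false"), 1),
            mode = sample(c("fast", "slow"), 1),
            n = as.character(sample.int(100, 1)))
    ov <- ov[sample(c(TRUE, FALSE), 4, replace = TRUE)]
    ps <- resolve_params(rich, ov)
    back <- parse_parameter_file(rich, render_parameter_file(ps))
    expect_identical(back$values, ps$values)
  }
})

test_that("output datasets follow the per-sample pattern and carry metadata", {
  root <- withr::local_tempdir()
  df <- table1_frame()
  names(df)[2] <- "Read1 [File]"      # the app requires Read1
  ds <- dataset_from_frame(df, name = "ventricles")
  app <- builtin_apps()$FastqStats
  ps <- resolve_params(app)
  out <- build_output_dataset(app, ds, ps, "results/FastqStats_x")
  expect_identical(nrow(out$table), 4L)
  expect_identical(out$table$Stats[1], "results/FastqStats_x/Mut1.stats.tsv")
  expect_identical(out$table$Species[1], "Mus musculus")
  expect_identical(out$table$Genotype[1], "Mutant")
  expect_true("Factor" %in%
                out$headers[[which(dataset_colnames(out) == "Genotype")]]$tags)

  empty <- dataset_from_frame(reads_frame(0L))
  out0 <- build_output_dataset(app, empty, ps, "results/x")
  expect_identical(nrow(out0$table), 0L)

  bad <- app_spec("NoName", "Misc", "Name",
                  output_columns = function(i, p, r)
                    dataset_from_frame(data.frame(X = "1", check.names = FALSE)),
                  commands = function(s, p) "true",
                  granularity = "per_dataset")
  expect_error(build_output_dataset(bad, ds, resolve_params(bad), "r"),
               "Name column")
})

test_that("generated scripts are self-contained POSIX shell", {
  root <- withr::local_tempdir()
  touch_files(root, paste0("reads/s", 1:4, ".fastq.gz"))
  ds <- dataset_from_frame(reads_frame(4L))
  app <- toy_app()
  ps <- resolve_params(app, c(cores = "2"))
  scripts <- generate_scripts(app, ds, ps, file.path(root, "results/r1"),
                              root, created_at = as.POSIXct("2024-01-02 03:04:05", tz = "UTC"))
  expect_identical(length(scripts), 4L)
  expect_identical(vapply(scripts, `[[`, "", "job_name"),
                   paste0("ToyCopy__s", 1:4))
  body <- scripts[[1]]$body
  expect_match(body, "^#!/bin/sh\n", fixed = FALSE)
  expect_match(body, "\nset -e\n", fixed = TRUE)
  expect_match(body, "# param cores=2", fixed = TRUE)
  expect_match(body, "# created: 2024-01-02T03:04:05Z", fixed = TRUE)
  expect_match(body, sprintf("READ1='%s/reads/s1.fastq.gz'",
                             normalizePath(root, winslash = "/")),
               fixed = TRUE)
  ## no back reference to the generating package
  for (s in scripts) {
    expect_false(grepl("provflow", s$body, ignore.case = TRUE))
    expect_false(any(vapply(.libPaths(), grepl, TRUE, x = s$body,
                            fixed = TRUE)))
  }

  ## empty File cell: generation error naming sample and column
  df <- reads_frame(2L)
  df$`Read1 [File]`[2] <- ""
  expect_error(
    generate_scripts(app, dataset_from_frame(df), ps,
                     file.path(root, "results/r2"), root),
    "s2.*Read1")
})

test_that("the external-tool QC wrapper emits the canonical command line", {
  root <- withr::local_tempdir()
  touch_files(root, "reads/mut1_R1.fastq.gz")
  ds <- dataset_from_frame(data.frame(
    Name = "Mut1", `Read1 [File]` = "reads/mut1_R1.fastq.gz",
    check.names = FALSE))
  app <- builtin_apps()$FastqcReport
  sc <- generate_scripts(app, ds, resolve_params(app),
                         file.path(root, "results/q"), root)
  expect_match(sc[[1]]$body,
               'fastqc --extract -o "$RESULT_DIR" -t 4 "$READ1"',
               fixed = TRUE)
})

test_that("prepare_run writes only the five meta entries (Step-1 purity)", {
  prj <- make_project(n_reads = 20L, seed = 5L)
  t0 <- as.POSIXct("2024-06-01 12:00:00", tz = "UTC")
  plan <- prepare_run(prj$apps$FastqStats, prj$dataset, character(),
                      prj$config, dataset_id = "1", now = t0)
  listing <- sort(list.files(plan$result_dir, all.files = TRUE,
                             no.. = TRUE, include.dirs = TRUE))
  expect_identical(listing, c("dataset.tsv", "input_dataset.tsv", "logs",
                              "parameters.tsv", "scripts"))
  expect_identical(list.files(file.path(plan$result_dir, "logs")),
                   character())
  expect_identical(length(list.files(file.path(plan$result_dir, "scripts"))),
                   4L)
  ## input copy is verbatim
  expect_identical(readBin(plan$input_dataset_path, "raw",
                           file.size(plan$input_dataset_path)),
                   readBin(prj$tsv, "raw", file.size(prj$tsv)))
  ## same second -> name collision
  expect_error(prepare_run(prj$apps$FastqStats, prj$dataset, character(),
                           prj$config, dataset_id = "1", now = t0),
               "already exists")
})

test_that("preparation is byte-deterministic under an injected timestamp", {
  prj <- make_project(n_reads = 20L, seed = 5L)
  t1 <- as.POSIXct("2024-06-01 12:00:00", tz = "UTC")
  snapshot <- function(dir) {
    files <- sort(list.files(dir, recursive = TRUE))
    stats::setNames(lapply(files, function(f) {
      p <- file.path(dir, f)
      readBin(p, "raw", file.size(p))
    }), files)
  }
  p1 <- prepare_run(prj$apps$BarcodeCount, prj$dataset, character(),
                    prj$config, dataset_id = "1", now = t1)
  snap1 <- snapshot(p1$result_dir)
  unlink(p1$result_dir, recursive = TRUE)
  p2 <- prepare_run(prj$apps$BarcodeCount, prj$dataset, character(),
                    prj$config, dataset_id = "1", now = t1)
  expect_identical(p2$result_dir, p1$result_dir)
  expect_identical(snapshot(p2$result_dir), snap1)
})

test_that("prepare_run refuses incompatible or invalid inputs", {
  prj <- make_project(n_reads = 10L)
  expect_error(prepare_run(prj$apps$GroupCompare, prj$dataset, character(),
                           prj$config),
               "Count")
  ## delete one fastq: validation failure stops Step 1
  file.remove(file.path(prj$config$data_root,
                        prj$dataset$table$Read1[1]))
  expect_error(prepare_run(prj$apps$FastqStats, prj$dataset, character(),
                           prj$config),
               "validation")
})
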