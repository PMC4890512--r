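## Shared fixtures: all built in code at test time.

## The published example sample sheet: 4 mouse ventricle samples,
## Mutant vs Wildtype.
table1_frame <- function() {
  data.frame(
    Name = c("Mut1", "Mut2", "Wt1", "Wt2"),
    `Read [File]` = c("P1001/ventricles/mut1_R1.fastq.gz",
                      "P1001/ventricles/mut2_R1.fastq.gz",
                      "P1001/ventricles/wt1_R1.fastq.gz",
                      "P1001/ventricles/wt2_R1.fastq.gz"),
    Species = rep("Mus musculus", 4L),
    `Genotype [Factor]` = c("Mutant", "Mutant", "Wildtype", "Wildtype"),
    check.names = FALSE, stringsAsFactors = FALSE)
}

table1_dataset <- function() dataset_from_frame(table1_frame(), name = "ventricles")

table1_path <- function() {
  system.file("extdata", "mouse_ventricles.tsv", package = "provflow")
}

## Create empty placeholder files under root for the given relative paths.
touch_files <- function(root, rels) {
  for (r in rels) {
    dir.create(file.path(root, dirname(r)), recursive = TRUE,
               showWarnings = FALSE)
    file.create(file.path(root, r))
  }
  invisible(root)
}

## A throwaway project with a simulated read dataset imported as id 1.
make_project <- function(n_reads = 100L, seed = 1L,
                         group_names = c("Mutant", "Wildtype"),
                         n_samples_per_group = 2L,
                         barcode_set = c("ACTG", "CAGT", "GTCA", "TGAC"),
                         gc_content = 0.5, read_length = 50L) {
  root <- tempfile("proj")
  cfg <- init_project(root)
  spec <- synthetic_read_spec(
    n_samples_per_group = n_samples_per_group, group_names = group_names,
    n_reads = n_reads, read_length = read_length, gc_content = gc_content,
    barcode_set = barcode_set, seed = seed)
  tsv <- generate_read_dataset(cfg$data_root, spec)
  reg <- registry_load(cfg$registry_path)
  imp <- import_dataset(tsv, "reads", reg, cfg)
  list(config = cfg, registry = imp$registry, record = imp$record,
       dataset = read_dataset(tsv, name = "reads"), tsv = tsv,
       spec = spec, apps = builtin_apps())
}

## Independent naive FASTQ reader (oracle for the generated scripts).
oracle_read_fastq <- function(path) {
  lines <- readLines(gzfile(path))
  if (length(lines) %% 4L != 0L) stop("truncated FASTQ")
  lines[seq_along(lines) %% 4L == 2L]
}

## Random valid dataset for round-trip property tests.
random_dataset <- function(n_rows, n_cols, with_name = TRUE) {
  rand_token <- function(n, min_len = 3L, max_len = 8L) {
    vapply(seq_len(n), function(i)
      paste(sample(c(letters, LETTERS, 0:9),
                   sample(min_len:max_len, 1L), replace = TRUE),
            collapse = ""), "")
  }
  bases <- unique(rand_token(n_cols * 2L))[seq_len(n_cols)]
  tag_pool <- c("File", "Link", "Factor", "Characteristics", "Custom")
  headers <- lapply(seq_len(n_cols), function(j) {
    if (with_name && j == 1L) return(col_header("Name"))
    n_tags <- sample(0:2, 1L)
    col_header(bases[j], sample(tag_pool, n_tags))
  })
  cols <- lapply(seq_len(n_cols), function(j) {
    if (with_name && j == 1L)
      return(paste0("s", seq_len(n_rows), "_", rand_token(n_rows, 2L, 4L)))
    vals <- rand_token(n_rows, 0L, 6L)
    vals[sample(c(TRUE, FALSE), n_rows, replace = TRUE, prob = c(.2, .8))] <- ""
    vals
  })
  table <- as.data.frame(stats::setNames(cols, vapply(headers, function(h)
    h$base_name, "")), check.names = FALSE, stringsAsFactors = FALSE)
  new_dataset(headers, table, name = "random")
}
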