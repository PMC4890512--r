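#' Specification of a synthetic sequencing-read dataset
#'
#' The fixture generator emulates the convention for a sequencing-read
#' sample sheet: per-sample gzipped FASTQ files accompanied by a
#' `dataset.tsv` with `Name`, `Read1 [File]`, `Adapter1`, `Species`,
#' `StrandMode`, `Enrichment Kit`, `Read Count` and a `Genotype [Factor]`
#' column. Reads carry a leading 4-mer barcode drawn from `barcode_set`;
#' barcodes act as exactly countable stand-in features for the toy
#' counting and comparison applications. The remaining positions are
#' i.i.d. bases with `P(G or C) = gc_content`.
#'
#' @param n_samples_per_group Samples per factor level (default 2,
#'   giving the classic Mut1/Mut2/Wt1/Wt2 design).
#' @param group_names Factor levels (default Mutant/Wildtype).
#' @param n_reads Reads per sample.
#' @param read_length Read length in bases (>= barcode length 4).
#' @param gc_content Probability of G or C outside the barcode, in
#'   \[0, 1\].
#' @param barcode_set Unique 4-mers over ACGT.
#' @param seed Integer seed; the whole fixture is a pure function of the
#'   spec, so equal specs give bit-identical files.
#' @return A `synthetic_read_spec` object.
#' @export
synthetic_read_spec <- function(n_samples_per_group = 2L,
                                group_names = c("Mutant", "Wildtype"),
                                n_reads = 100L,
                                read_length = 50L,
                                gc_content = 0.5,
                                barcode_set = c("ACTG", "CAGT", "GTCA", "TGAC"),
                                seed = 1L) {
  n_reads <- as.integer(n_reads)
  if (is.na(n_reads) || n_reads < 0L) pf_stop("n_reads must be >= 0")
  if (gc_content < 0 || gc_content > 1)
    pf_stop("gc_content must be in [0, 1]")
  if (length(barcode_set) == 0L || anyDuplicated(barcode_set) ||
      any(!grepl("^[ACGT]{4}$", barcode_set)))
    pf_stop("barcode_set must be unique 4-mers over ACGT")
  if (as.integer(read_length) < 4L)
    pf_stop("read_length must be at least the barcode length (4)")
  if (as.integer(n_samples_per_group) < 1L || length(group_names) < 1L)
    pf_stop("need at least one sample in at least one group")
  structure(list(n_samples_per_group = as.integer(n_samples_per_group),
                 group_names = as.character(group_names),
                 n_reads = n_reads,
                 read_length = as.integer(read_length),
                 gc_content = as.numeric(gc_content),
                 barcode_set = as.character(barcode_set),
                 seed = as.integer(seed)),
            class = "synthetic_read_spec")
}

#' Write one synthetic gzipped FASTQ file
#'
#' Standard 4-line records; read `i` is named `@read_i`, starts with a
#' barcode drawn uniformly from `barcode_set`, continues with
#' i.i.d. bases at the requested GC content, and carries a constant
#' quality string of `I`. Deterministic: the same arguments always
#' produce a byte-identical file (the generator uses a private RNG
#' stream and gzip output carries no timestamp).
#'
#' @param path Output path (`.fastq.gz`).
#' @param n_reads Number of records.
#' @param read_length Bases per read.
#' @param gc_content P(G or C) for non-barcode positions.
#' @param barcode_set Unique 4-mers; the leading barcode is sampled
#'   uniformly from this set.
#' @param seed Integer seed.
#' @return The number of reads written, invisibly.
#' @export
generate_fastq <- function(path, n_reads, read_length = 50L,
                           gc_content = 0.5,
                           barcode_set = c("ACTG", "CAGT", "GTCA", "TGAC"),
                           seed = 1L) {
  n_reads <- as.integer(n_reads)
  if (is.na(n_reads) || n_reads < 0L) pf_stop("n_reads must be >= 0")
  if (length(barcode_set) == 0L) pf_stop("barcode_set must be non-empty")
  read_length <- as.integer(read_length)
  tail_len <- read_length - 4L
  seqs <- with_seed(seed, {
    barcodes <- barcode_set[sample.int(length(barcode_set), n_reads,
                                       replace = TRUE)]
    if (tail_len > 0L && n_reads > 0L) {
      p <- c(gc_content / 2, gc_content / 2,
             (1 - gc_content) / 2, (1 - gc_content) / 2)
      draws <- sample(c("G", "C", "A", "T"), n_reads * tail_len,
                      replace = TRUE, prob = p)
      tails <- apply(matrix(draws, nrow = tail_len), 2L, paste, collapse = "")
      paste0(barcodes, tails)
    } else barcodes
  })
  qual <- strrep("I", read_length)
  con <- gzfile(path, open = "wb")
  on.exit(close(con))
  if (n_reads > 0L) {
    records <- rbind(paste0("@read_", seq_len(n_reads)), seqs, "+", qual)
    writeLines(as.vector(records), con, sep = "\n", useBytes = TRUE)
  }
  invisible(n_reads)
}

group_prefix <- function(group) {
  switch(group, Mutant = "Mut", Wildtype = "Wt", sanitize_token(group))
}

#' Generate a complete synthetic read dataset
#'
#' Writes one gzipped FASTQ per sample under `data_root/reads/` and the
#' accompanying `dataset.tsv` following the read-sheet convention. Sample
#' names are `<prefix><i>` per group (Mutant -> Mut1, Mut2, ...;
#' Wildtype -> Wt1, ...). The `Read Count` cells record the true number
#' of generated reads; `Adapter1`, `Species`, `StrandMode` and
#' `Enrichment Kit` are filled with realistic free-text metadata that the
#' framework carries but never interprets. Each sample uses a distinct
#' seed derived from `spec$seed`, so the whole dataset is reproducible.
#'
#' @param data_root Project data root (must be writable).
#' @param spec A [synthetic_read_spec()].
#' @param force Overwrite existing files? Without it an existing FASTQ or
#'   dataset.tsv is an error.
#' @return The path of the written `dataset.tsv`, invisibly.
#' @export
generate_read_dataset <- function(data_root, spec = synthetic_read_spec(),
                                  force = FALSE) {
  stopifnot(inherits(spec, "synthetic_read_spec"))
  if (!dir.exists(data_root))
    pf_stop("data_root %s does not exist", dQuote(data_root))
  reads_dir <- file.path(data_root, "reads")
  dir.create(reads_dir, showWarnings = FALSE)
  samples <- list()
  idx <- 0L
  for (g in spec$group_names) {
    for (i in seq_len(spec$n_samples_per_group)) {
      idx <- idx + 1L
      name <- paste0(group_prefix(g), i)
      rel <- file.path("reads", paste0(name, "_R1.fastq.gz"))
      full <- file.path(data_root, rel)
      if (file.exists(full) && !force)
        pf_stop("%s already exists (use force = TRUE to overwrite)", full)
      n <- generate_fastq(full, spec$n_reads, spec$read_length,
                          spec$gc_content, spec$barcode_set,
                          seed = spec$seed + idx)
      samples[[idx]] <- data.frame(
        Name = name, Read1 = rel, Adapter1 = "AGATCGGAAGAGC",
        Species = "Mus musculus", StrandMode = "unstranded",
        `Enrichment Kit` = "polyA", `Read Count` = as.character(n),
        Genotype = g, check.names = FALSE, stringsAsFactors = FALSE)
    }
  }
  table <- do.call(rbind, samples)
  headers <- list(col_header("Name"), col_header("Read1", "File"),
                  col_header("Adapter1"), col_header("Species"),
                  col_header("StrandMode"), col_header("Enrichment Kit"),
                  col_header("Read Count"), col_header("Genotype", "Factor"))
  ds <- new_dataset(headers, table, name = "reads")
  tsv <- file.path(reads_dir, "dataset.tsv")
  if (file.exists(tsv) && !force)
    pf_stop("%s already exists (use force = TRUE to overwrite)", tsv)
  write_dataset(ds, tsv)
  invisible(tsv)
}
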