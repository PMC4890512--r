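# provflow

Self-documented dataset directories and two-phase analysis workflows for
sequence data.

Bioinformatic analyses chain standalone command-line tools, and the real
maintenance burden is administrative: which files belong to which
samples, which parameters produced which result, and whether a result
directory still makes sense — and can be re-run — on a machine where the
workflow system is not installed. provflow addresses this with a
file-based recipe:

* **Datasets.** Every input and every result is a *dataset*: a directory
  of data files plus a plain-text sample sheet, `dataset.tsv` (rows =
  samples, columns = characteristics). Column headers carry optional
  bracketed tags — `Read1 [File]`, `Genotype [Factor]` — that trigger
  framework behaviour (file-existence checks, factor grouping) without
  constraining the values themselves. No ontology is imposed; semantics
  belong to the user and the applications.
* **Applications as meta-processes.** An application declares its
  required input columns, its typed parameters with defaults, the output
  sheet it will produce, and the shell commands that will produce it.
  Running it is two-phase: **Step 1** generates a self-contained result
  directory holding *only* meta-information (`input_dataset.tsv`,
  `parameters.tsv`, the promised output `dataset.tsv`, standalone
  `scripts/*.sh`, empty `logs/`); **Step 2** executes the scripts —
  through the bundled local runner or, equivalently, any POSIX shell.
  Generated scripts contain no reference back to this package, so
  results remain reproducible if it is uninstalled.
* **Lineage.** A flat tab-separated registry links each derived dataset
  to its parent and generating application, forming a browsable forest.
* **Fixtures.** A seeded synthetic-read generator (gzipped FASTQ with
  leading 4-mer barcodes as exactly countable stand-in features) and
  three pure sh/awk example applications — `FastqStats`, `BarcodeCount`,
  `GroupCompare` (per-barcode group means and
  `log2((mean_A + p)/(mean_B + p))`) — reproduce a toy
  QC → counting → two-group comparison pipeline with no external tools.

## Worked example

```r
library(provflow)
cfg  <- init_project("myproj")
tsv  <- generate_read_dataset(cfg$data_root,
                              synthetic_read_spec(n_reads = 100, seed = 1))
reg  <- registry_load(cfg$registry_path)
reg  <- import_dataset(tsv, "reads", reg, cfg)$registry
reads <- read_dataset(tsv, name = "reads")

apps <- builtin_apps()
list_compatible(apps, reads)
#>   category         name
#> 1    Count BarcodeCount
#> 2       QC   FastqStats
#> 3       QC FastqcReport

plan <- prepare_run(apps$FastqStats, reads, c(cores = "2"), cfg,
                    dataset_id = "1")
list.files(plan$result_dir, recursive = TRUE, include.dirs = TRUE)
#> [1] "dataset.tsv"                 "input_dataset.tsv"
#> [3] "logs"                        "parameters.tsv"
#> [5] "scripts"                     "scripts/FastqStats__Mut1.sh"
#> [7] "scripts/FastqStats__Mut2.sh" "scripts/FastqStats__Wt1.sh"
#> [9] "scripts/FastqStats__Wt2.sh"
```

After Step 1 the directory holds only meta-information — the promised
output files do not exist yet. Step 2 creates them:

```r
run_plan(plan$result_dir)
#> <run status: success> (4 jobs)
#>   FastqStats__Mut1               success
#>   FastqStats__Mut2               success
#>   FastqStats__Wt1                success
#>   FastqStats__Wt2                success

readLines(file.path(plan$result_dir, "Mut1.stats.tsv"))
#> read_count        100
#> gc_fraction       0.503800
#> mean_read_length  50.000000

verify_outputs(plan$result_dir, cfg$data_root)$ok
#> [1] TRUE

reg <- register_result(plan, 1, reg, cfg)$registry
dataset_tree(reg)
#> reads
#>   FastqStats_1_20260920-201544 (FastqStats)
```

`read_count` is exactly the generator's `n_reads`; `gc_fraction` is the
empirical GC over all bases (the 0.5-GC simulation gives 0.5038 at this
seed); `verify_outputs()` confirms every `File` cell promised by Step 1
now exists. The same pipeline is scriptable from a shell via the
installed `exec/provflow` wrapper (`init`, `simulate`, `import`, `apps`,
`run`, `exec`, `status`, `validate`, `datasets`, `tree`).

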