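---
title: "Self-documented dataset directories and two-phase workflows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-documented dataset directories and two-phase workflows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(provflow)
```

## The model

High-throughput sequence analysis is usually a chain of standalone
command-line tools, and the hard part is rarely the tools: it is keeping
track of which files belong to which samples, which parameters produced
which result, and whether a result directory handed to a collaborator can
be understood — and re-run — without the system that produced it.

provflow organises everything around one idea: **every input and every
analysis result is a dataset**, a directory of data files made
self-describing by a plain-text sample sheet, `dataset.tsv`. Rows are
samples; columns are characteristics; a column header may carry bracketed
tags — `Read1 [File]`, `Genotype [Factor]`, `X [Factor,Link]` — that tell
the framework *how* to treat the values without constraining *what* they
mean:

* `File` — the cell is a path (relative to the project data root);
  existence is checked at validation time;
* `Factor` — the column is an experimental factor used to group samples
  (e.g. for a two-group comparison);
* `Link`, `Characteristics` — carried and displayed, never interpreted.

Any other tag is preserved verbatim and reported as a warning, never an
error: column semantics are deliberately delegated to the user and to the
applications. No ontology or controlled vocabulary is imposed.

Analysis applications are **meta-processes** (`app_spec()`). An
application never computes data when invoked; given an input dataset and
parameters it *declares* its output dataset (including the file paths it
promises to create) and the shell command lines that will create them.
The framework then runs in two phases:

* **Step 1** (`prepare_run()`) writes a result directory containing only
  meta-information: `input_dataset.tsv` (verbatim copy),
  `parameters.tsv`, `dataset.tsv` (the promised output sheet),
  `scripts/*.sh`, and an empty `logs/`.
* **Step 2** (`run_plan()`, or any POSIX shell) executes the scripts,
  producing the data and log files. `verify_outputs()` then checks that
  every promised `File` cell exists.

The scripts are fully self-contained — absolute paths bound as shell
variables, `set -e`, a comment header recording application, parameters,
input sheet and creation time — and contain **no reference back to this
package**. If the package is uninstalled, every result remains
reproducible with `sh scripts/*.sh`; the test suite asserts that a bare
shell reproduces the runner's output byte for byte.

Lineage is tracked in a flat tab-separated registry: each derived dataset
records its parent dataset and the generating application, giving a
forest whose rendering (`dataset_tree()`) shows how every result was
derived. The registry deliberately replaces a database with one greppable
file so the whole project history travels with the directory.

## A worked toy pipeline

```{r, eval = FALSE}
cfg <- init_project("myproj")
tsv <- generate_read_dataset(cfg$data_root,
                             synthetic_read_spec(n_reads = 100, seed = 1))
reg <- registry_load(cfg$registry_path)
reg <- import_dataset(tsv, "reads", reg, cfg)$registry
reads <- read_dataset(tsv, name = "reads")
apps <- builtin_apps()

plan <- prepare_run(apps$FastqStats, reads, c(cores = "2"), cfg,
                    dataset_id = "1")
run_plan(plan$result_dir)
verify_outputs(plan$result_dir, cfg$data_root)
```

The same pipeline is available from a shell through the thin
command-line wrapper (`exec/provflow` once installed): `init`,
`simulate`, `import`, `apps`, `run`, `exec`, `status`, `validate`,
`datasets`, `tree`.

## Parameters

Parameter typing is inferred from the default literal (`param_spec()`):
integer, real, boolean (`true`/`false` on the command line and in
`parameters.tsv`), string, or an enumerated choice when the default is a
character vector (first element is the default — the analogue of a
selector widget). Required parameters have no default and must be
supplied at preparation. `parameters.tsv` is `key<TAB>value` in declared
order and parses back to an identical set, so a result directory always
records exactly the parameters that produced it. The conventional
resource keys (`cores`, `ram`, `scratch`) are ordinary integers with no
scheduling semantics in the local runner; the bundled QC application
defaults to `cores = 4`.

## The sample-sheet dialect

`dataset.tsv` is UTF-8, LF, tab-separated, with no quoting or escaping:
a tab or newline inside a cell is a serialization error rather than
something to quote. This is a deliberate trade — the sheet stays exactly
`grep`/`cut`/`awk`-able, which is worth more in practice than exotic cell
content. Headers are canonicalised on write (`Base [t1,t2]`, one space,
no inner spaces), so write→read→write is byte-identical; tests enforce
the round trip on randomized tables. Other conventions:

* column base names and tags match case-sensitively; determinism beats
  convenience;
* a `Name` column, when present, must be unique and non-empty — samples
  are addressed by name everywhere;
* empty cells are legal except under `Name`; an empty `Factor` cell is
  treated as the level `""` (its own group), not as missing;
* `File` cells are POSIX relative paths; absolute paths are accepted but
  flagged, because they break portability of the directory;
* text after a tag group (`"Read1 [File] extra"`) is rejected — headers
  are either a name or a name plus one trailing tag group.

## Compatibility and generation-time checks

An application lists `required_columns`; it is offered for a dataset iff
every required base name is present (tags are ignored — they annotate
type, not identity, which is why a sheet can satisfy `Read1` with the
column `Read1 [File]`). `list_compatible()` is equivalent to brute-force
filtering, and `prepare_run()` refuses exactly the incompatible pairs —
both properties are asserted on randomized app/dataset pairs in the test
suite.

Two checks happen earlier than a runtime-scripting system would place
them, because commands are baked at generation time from the input
sheet:

* an **empty `File` cell** in any File-tagged column aborts script
  generation, naming the sample and column. Since command builders are
  opaque shell constructors, the framework cannot know which columns a
  command actually uses and conservatively binds them all;
* the two-group comparison's **level count** (`grouping_column` must
  hold exactly two values) is enforced when the run is prepared, not
  when the script runs — the generator already knows the levels, so
  failing at Step 1 is strictly earlier and cheaper than a nonzero exit
  at Step 2.

Result directories are named `<App>_<dataset id>_<UTC yyyymmdd-HHMMSS>`;
the timestamp is injectable, and with a fixed timestamp preparation is
byte-deterministic. `result_root` should live under `data_root` (the
default layout puts `results/` beneath the project root) so that output
`File` cells remain relative; configuring it elsewhere falls back to
absolute cells with a warning.

## The runner

`execute_script()` runs each script via `sh` with **stdin closed**,
enforcing — not merely trusting — the rule that tools must not require
interactive input. Exit status, stdout and stderr are persisted per job
as `logs/<job>.{status,out,err}`, so `plan_status()` is a pure function
of the logs directory and the directory stays self-describing without
any database. `run_plan()` is idempotent: succeeded jobs are never
re-executed, so a rerun after a partial failure retries only the failed
jobs. Jobs are independent; `max_parallel` (default 1) bounds
concurrency; there is no retry policy, no walltime handling, and nothing
is ever cleaned up automatically — a failed job's partial output is
simply overwritten by the rerun.

## The synthetic fixtures and what they do (not) show

`generate_read_dataset()` emulates a sequencing-read sample sheet: per
sample a gzipped FASTQ plus the conventional columns (`Name`,
`Read1 [File]`, `Adapter1`, `Species`, `StrandMode`, `Enrichment Kit`,
`Read Count`, `Genotype [Factor]`). Defaults are the classic 2×2 design
(Mut1, Mut2, Wt1, Wt2), 100 reads × 50 bp per sample, GC 0.5 — small
enough that every downstream quantity is exactly checkable by a naive
oracle, which is the point of the fixture tier. Reads carry a leading
4-mer barcode drawn uniformly from `barcode_set`; barcodes are exactly
countable stand-in "genes". Qualities are a constant `I`, because
quality simulation exercises nothing in the framework. `StrandMode` and
`Enrichment Kit` are filled with plausible free text
(`unstranded`, `polyA`); the metadata convention does not define value
vocabularies and the framework never interprets them. The generator is a
pure function of its spec: it uses a private RNG stream (the caller's
`.Random.seed` is untouched) and equal specs yield bit-identical files.

The three bundled applications are pure sh/awk stand-ins for a real
QC → count → differential-expression chain: `FastqStats` (read count,
GC fraction, mean length), `BarcodeCount` (reads per leading barcode),
and `GroupCompare` (per-barcode group means and
`log2((meanA + p) / (meanB + p))` with pseudocount `p`, levels in
lexicographic order). The comparison is deliberately a mean ratio, not a
dispersion model — it makes the stage deterministic and desk-checkable
and claims no statistical inference. A fourth definition wraps a real
`fastqc` binary for users who have one; the test suite does not touch
it.

Passing tests therefore demonstrate the *framework's* contracts —
meta-only Step 1, self-contained scripts, exact conservation of counts,
lineage bookkeeping — on data whose every property is known. They say
nothing about real reads (no quality structure, no adapters inside
reads, no alignment) and nothing about the statistical behaviour of a
real differential-expression method.

## Problem sizes and numerical choices

The test suite and the acceptance script run the pipeline at fixture
scale — 4 samples, 10–200 reads of 30–50 bp, ≤ 25 randomized
property-test iterations — chosen so every expected value can be
verified by brute force and the whole suite stays interactive. Numeric
cells in the stand-in outputs are printed with six decimals (`%.6f`
from awk); tests compare them at `1e-6`. `log2` is computed in awk as
`log(x)/log(2)`. Sorting everywhere (barcodes, script names, registry
ids, group levels) is bytewise (`LC_ALL=C` / radix) so output order
never depends on locale.

## Known limitations

* No grid or cloud execution, no resource scheduling, no DAG language:
  pipelines are chained by feeding one run's `dataset.tsv` to the next
  application, which is exactly how the lineage forest arises.
* The registry is append-only from the package's perspective; there is
  no delete or archive operation.
* The TSV dialect cannot represent cells containing tabs or newlines,
  by design.
* Level names containing commas or shell metacharacters would break the
  baked comparison command; fixture-style tokens are assumed.
* The runner deletes nothing; temporary-data cleanup is the
  application's own business.
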