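## FastqStats -- per-sample read statistics over a gzipped FASTQ.
## A pure stand-in for a QC report generator: the job script needs only
## sh, gzip and awk, and writes <Name>.stats.tsv with read_count,
## gc_fraction and mean_read_length as key<TAB>value lines.

app_spec(
  name = "FastqStats",
  analysis_category = "QC",
  description = "Read count, GC fraction and mean read length per sample.",
  required_columns = c("Name", "Read1"),
  params = list(
    param_spec("cores", 4L, "number of cores used for multi-threading")),
  granularity = "per_sample",
  output_columns = function(input, params, result_dir_name) {
    nm <- sample_names(input)
    carried <- intersect(c("Read Count", "Species"), dataset_colnames(input))
    fcols <- columns_with_tag(input, "Factor")
    headers <- c(list(col_header("Name"), col_header("Stats", "File")),
                 lapply(carried, col_header),
                 lapply(fcols, function(cn) col_header(cn, "Factor")))
    table <- data.frame(
      Name = nm,
      Stats = sprintf("%s/%s.stats.tsv", result_dir_name, nm),
      check.names = FALSE, stringsAsFactors = FALSE)
    for (cn in c(carried, fcols)) table[[cn]] <- input$table[[cn]]
    new_dataset(headers, table)
  },
  commands = function(sample, params) {
    c('gzip -t "$READ1"',
      sprintf('OUT="$RESULT_DIR/%s.stats.tsv"', sample[["Name"]]),
      'gzip -dc "$READ1" | awk \'',
      "  NR % 4 == 2 { n++; len += length($0); gc += gsub(/[GCgc]/, \"\") }",
      "  END {",
      "    printf \"read_count\\t%d\\n\", n",
      "    printf \"gc_fraction\\t%.6f\\n\", (len > 0 ? gc / len : 0)",
      "    printf \"mean_read_length\\t%.6f\\n\", (n > 0 ? len / n : 0)",
      "  }' > \"$OUT\"")
  })
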