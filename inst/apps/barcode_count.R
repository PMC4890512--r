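## BarcodeCount -- per-sample feature counting, with the leading 4-mer
## barcode of each read standing in for a gene. Writes
## <Name>.counts.tsv (barcode<TAB>count, barcode-sorted); counts below
## min_count are dropped. Needs only sh, gzip, awk and sort.

app_spec(
  name = "BarcodeCount",
  analysis_category = "Count",
  description = "Count reads per leading 4-mer barcode feature.",
  required_columns = c("Name", "Read1"),
  params = list(
    param_spec("min_count", 0L, "drop barcodes with fewer reads than this")),
  granularity = "per_sample",
  output_columns = function(input, params, result_dir_name) {
    nm <- sample_names(input)
    fcols <- columns_with_tag(input, "Factor")
    headers <- c(list(col_header("Name"), col_header("Count", "File")),
                 lapply(fcols, function(cn) col_header(cn, "Factor")))
    table <- data.frame(
      Name = nm,
      Count = sprintf("%s/%s.counts.tsv", result_dir_name, nm),
      check.names = FALSE, stringsAsFactors = FALSE)
    for (cn in fcols) table[[cn]] <- input$table[[cn]]
    new_dataset(headers, table)
  },
  commands = function(sample, params) {
    c('gzip -t "$READ1"',
      sprintf('OUT="$RESULT_DIR/%s.counts.tsv"', sample[["Name"]]),
      sprintf('gzip -dc "$READ1" | awk -v min=%d \'', params$min_count),
      "  NR % 4 == 2 { c[substr($0, 1, 4)]++ }",
      "  END { for (b in c) if (c[b] >= min) printf \"%s\\t%d\\n\", b, c[b] }",
      "' | LC_ALL=C sort > \"$OUT\"")
  })
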