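## FastqcReport -- wraps a real `fastqc` binary, when one is installed
## on the execution host. Kept minimal: single-end reads, one report
## archive per sample, named the way fastqc names it
## (<reads>_fastqc.zip). Not exercised by the test suite, which relies
## only on the pure stand-in applications.

app_spec(
  name = "FastqcReport",
  analysis_category = "QC",
  description = "FastQC quality-control report per sample (external tool).",
  required_columns = c("Name", "Read1"),
  params = list(
    param_spec("cores", 4L, "number of cores used for multi-threading")),
  granularity = "per_sample",
  version = "fastqc (external, version as installed)",
  output_columns = function(input, params, result_dir_name) {
    nm <- sample_names(input)
    stem <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(input$table[["Read1"]]))
    fcols <- columns_with_tag(input, "Factor")
    headers <- c(list(col_header("Name"), col_header("Report", "File")),
                 lapply(fcols, function(cn) col_header(cn, "Factor")))
    table <- data.frame(
      Name = nm,
      Report = sprintf("%s/%s_fastqc.zip", result_dir_name, stem),
      check.names = FALSE, stringsAsFactors = FALSE)
    for (cn in fcols) table[[cn]] <- input$table[[cn]]
    new_dataset(headers, table)
  },
  commands = function(sample, params) {
    sprintf('fastqc --extract -o "$RESULT_DIR" -t %d "$READ1"',
            params$cores)
  })
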