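## GroupCompare -- dataset-level two-group comparison of barcode count
## tables. Merges the per-sample counts (missing barcode counts as 0),
## computes each group's mean count per barcode and the log2 ratio
## between the two levels (lexicographic order, with a pseudocount), and
## writes a headered, barcode-sorted compare.tsv. Deliberately a plain
## mean-ratio, not a dispersion model: the stage exists to exercise
## factor grouping and dataset chaining, not to claim statistics.

app_spec(
  name = "GroupCompare",
  analysis_category = "Compare",
  description = "Mean count per factor level and log2 ratio per barcode.",
  required_columns = c("Name", "Count"),
  params = list(
    param_spec("grouping_column", "Genotype",
               "Factor column that defines the two groups"),
    param_spec("pseudocount", 1L, "added to both means before the ratio")),
  granularity = "per_dataset",
  output_columns = function(input, params, result_dir_name) {
    lv <- compare_levels(input, params$grouping_column)
    new_dataset(
      list(col_header("Name"), col_header("Result", "File")),
      data.frame(Name = paste0(lv[1L], "_vs_", lv[2L]),
                 Result = file.path(result_dir_name, "compare.tsv"),
                 check.names = FALSE, stringsAsFactors = FALSE))
  },
  commands = function(input, params) {
    lv <- compare_levels(input, params$grouping_column)
    groups <- input$table[[params$grouping_column]]
    vars <- vapply(sample_names(input), function(nm) shell_var("Count", nm), "")
    file_args <- paste(sprintf('"$%s"', vars), collapse = " ")
    c("{",
      sprintf("printf 'barcode\\tmean_%s\\tmean_%s\\tlog2_ratio\\n'",
              lv[1L], lv[2L]),
      sprintf("awk -F'\\t' -v groups='%s' -v la='%s' -v lb='%s' -v pseudo='%s' '",
              paste(groups, collapse = ","), lv[1L], lv[2L],
              format_param_value(params$pseudocount)),
      "  BEGIN {",
      "    n = split(groups, g, \",\")",
      "    for (i = 1; i <= n; i++) ng[g[i]]++",
      "    for (i = 1; i <= n; i++) {",
      "      f = ARGV[i]",
      "      while ((getline line < f) > 0) {",
      "        split(line, a, \"\\t\")",
      "        sum[a[1] SUBSEP g[i]] += a[2]",
      "        seen[a[1]] = 1",
      "      }",
      "      close(f)",
      "    }",
      "    for (b in seen) {",
      "      ma = sum[b SUBSEP la] / ng[la]",
      "      mb = sum[b SUBSEP lb] / ng[lb]",
      "      printf \"%s\\t%.6f\\t%.6f\\t%.6f\\n\", b, ma, mb, log((ma + pseudo) / (mb + pseudo)) / log(2)",
      "    }",
      "  }",
      sprintf("' %s | LC_ALL=C sort", file_args),
      '} > "$RESULT_DIR/compare.tsv"')
  })
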