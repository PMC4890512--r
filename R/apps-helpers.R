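#' The two factor levels of a comparison's grouping column
#'
#' Helper for two-group comparison applications: returns the sorted
#' (lexicographic) pair of distinct values in `grouping_column`, erroring
#' when the column is absent or does not hold exactly two levels. The
#' first element is the ratio's numerator level.
#'
#' @param input Input `dataset`.
#' @param grouping_column Column base name holding the group labels.
#' @return Character vector of length 2, sorted.
#' @export
compare_levels <- function(input, grouping_column) {
  stopifnot(inherits(input, "dataset"))
  if (!grouping_column %in% dataset_colnames(input))
    pf_stop("grouping column %s is not present in the input dataset",
            dQuote(grouping_column))
  lv <- sort(unique(input$table[[grouping_column]]), method = "radix")
  if (length(lv) != 2L)
    pf_stop("grouping column %s must hold exactly two levels, found %d (%s)",
            dQuote(grouping_column), length(lv),
            paste(utils::head(lv, 5L), collapse = ", "))
  lv
}
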