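#' Pool the two strands of each CpG
#'
#' By default the pipeline treats the cytosines on the two strands of a CpG
#' as independent measurements. This opt-in transformation maps each minus-
#' strand call onto the plus-strand C of the same CpG (position - 1) and
#' pools the per-sample observations: coverages add, methylation becomes the
#' coverage-weighted mean of the non-missing strand calls.
#'
#' @param calls Merged calls tibble.
#' @return A calls tibble on the `+` strand only.
#' @export
collapse_strands <- function(calls) {
  pooled <- calls |>
    dplyr::mutate(start = ifelse(.data$strand == "-", .data$start - 1L, .data$start)) |>
    dplyr::group_by(.data$sample, .data$group, .data$chrom, .data$start) |>
    dplyr::summarise(
      meth_pct = {
        w <- .data$coverage[!is.na(.data$meth_pct)]
        m <- .data$meth_pct[!is.na(.data$meth_pct)]
        if (length(m) && sum(w) > 0) sum(w * m) / sum(w) else NA_real_
      },
      coverage = sum(.data$coverage),
      .groups = "drop"
    ) |>
    dplyr::mutate(end = .data$start + 1L, strand = "+")
  out <- pooled[c("sample", "chrom", "start", "end", "strand", "coverage",
                  "meth_pct", "group")]
  manifest <- attr(calls, "manifest")
  if (is.null(manifest)) manifest <- dplyr::distinct(calls, .data$sample, .data$group)
  sort_calls(out[setdiff(names(out), "group")], manifest)
}
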