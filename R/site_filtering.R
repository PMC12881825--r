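#' Filter 1: positions unmethylated and covered in controls
#'
#' A position (chrom, pos, strand) survives iff
#' (a) at least `ceiling(min_ctrls_frac * n_controls)` control samples are
#' assessable there (coverage >= `min_ctrl_cov`), and
#' (b) no assessable control shows methylation strictly above
#' `max_ctrl_meth` percent.
#' Controls below the coverage gate contribute no methylation evidence: an
#' unassessable value can neither veto nor support a position.
#'
#' @param calls Merged calls tibble (with `group` column), see
#'   [merge_bedmethyl()].
#' @param params [msp_params()].
#' @return Tibble of surviving positions (`chrom`, `start`, `strand`).
#' @export
filter_control_sites <- function(calls, params = msp_params()) {
  n_controls <- dplyr::n_distinct(calls$sample[calls$group == "control"])
  if (n_controls == 0L) usage_error("Filter 1 needs at least one control sample.")
  need_ctrls <- ceiling(params$min_ctrls_frac * n_controls)

  ctrl <- calls |>
    dplyr::filter(.data$group == "control") |>
    dplyr::mutate(assessable = .data$coverage >= params$min_ctrl_cov) |>
    dplyr::group_by(.data$chrom, .data$start, .data$strand) |>
    dplyr::summarise(
      n_assessable = sum(.data$assessable),
      veto = any(.data$assessable & !is.na(.data$meth_pct) &
                   .data$meth_pct > params$max_ctrl_meth),
      .groups = "drop"
    )

  calls |>
    dplyr::distinct(.data$chrom, .data$start, .data$strand) |>
    dplyr::left_join(ctrl, by = c("chrom", "start", "strand")) |>
    dplyr::mutate(
      n_assessable = dplyr::coalesce(.data$n_assessable, 0L),
      veto = dplyr::coalesce(.data$veto, FALSE)
    ) |>
    dplyr::filter(.data$n_assessable >= need_ctrls, !.data$veto) |>
    dplyr::select("chrom", "start", "strand") |>
    dplyr::arrange(chrom_factor(.data$chrom), .data$start, .data$strand)
}

#' Five-number boxplot summary with whisker-bounded extremes
#'
#' Computes the per-group statistic used at every position: the 25th/50th/75th
#' percentiles by linear interpolation between order statistics (type 7, the
#' convention of numpy's `nanpercentile` and R's default `quantile`), and in
#' place of the raw extremes the whisker ends: the 0th percentile is the
#' smallest value at or above `p25 - 1.5 * iqr`, the 100th percentile the
#' largest value at or below `p75 + 1.5 * iqr`. Values beyond the fences are
#' outliers and do not move the whiskers. Missing values are dropped first.
#'
#' @param values Numeric vector of percent methylation (may contain `NA`).
#' @return A one-row tibble with `p0`, `p25`, `p50`, `p75`, `p100`, `iqr`,
#'   `n`; all statistics `NA` when no non-missing value remains.
#' @examples
#' boxplot_stats(c(0, 0, 0, 100))  # p100 is 0: the 100 is an outlier
#' @export
boxplot_stats <- function(values) {
  v <- values[!is.na(values)]
  n <- length(v)
  if (n == 0L) {
    return(tibble::tibble(p0 = NA_real_, p25 = NA_real_, p50 = NA_real_,
                          p75 = NA_real_, p100 = NA_real_, iqr = NA_real_, n = 0L))
  }
  q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  p25 <- q[1]; p75 <- q[2]
  iqr <- p75 - p25
  in_lo <- v[v >= p25 - 1.5 * iqr]
  in_hi <- v[v <= p75 + 1.5 * iqr]
  tibble::tibble(
    p0 = min(in_lo), p25 = p25, p50 = stats::median(v), p75 = p75,
    p100 = max(in_hi), iqr = iqr, n = n
  )
}

#' Per-position, per-group boxplot statistics
#'
#' For every position that passed Filter 1, aggregates the methylation values
#' of each group (observations with coverage >= 1 and a non-missing
#' methylation call) into the [boxplot_stats()] summary. This is the table
#' behind `boxplotData.tsv`.
#'
#' @param calls Merged calls tibble.
#' @param positions Tibble of positions (`chrom`, `start`, `strand`), e.g.
#'   from [filter_control_sites()].
#' @return Tibble with one row per position and group: `chrom`, `start`,
#'   `end`, `strand`, `group`, `p0`, `p25`, `p50`, `p75`, `p100`, `iqr`, `n`.
#' @export
site_statistics <- function(calls, positions) {
  obs <- calls |>
    dplyr::semi_join(positions, by = c("chrom", "start", "strand")) |>
    dplyr::filter(.data$coverage >= 1L)
  grid <- positions |>
    tidyr::crossing(group = c("control", "disease"))
  stats <- obs |>
    dplyr::group_by(.data$chrom, .data$start, .data$strand, .data$group) |>
    dplyr::summarise(stats = boxplot_stats(.data$meth_pct), .groups = "drop") |>
    tidyr::unnest("stats")
  grid |>
    dplyr::left_join(stats, by = c("chrom", "start", "strand", "group")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L), end = .data$start + 1L) |>
    dplyr::select("chrom", "start", "end", "strand", "group",
                  "p0", "p25", "p50", "p75", "p100", "iqr", "n") |>
    dplyr::arrange(chrom_factor(.data$chrom), .data$start, .data$strand, .data$group)
}

#' Filter 2: differentiating CpGs
#'
#' A Filter-1-surviving position is a differentiating CpG ("CpG of interest")
#' iff the disease median methylation is strictly above the control 100th
#' percentile (upper whisker) and at least one disease observation exists.
#' Ties fail: moderate elevation is not enough for an MSP biomarker.
#'
#' @param stats Per-position statistics from [site_statistics()].
#' @return Tibble of differentiating positions with `chrom`, `start`,
#'   `strand`, `ctrl_p100`, `disease_p50`.
#' @export
differentiating_sites <- function(stats) {
  wide <- stats |>
    dplyr::select("chrom", "start", "strand", "group", "p50", "p100", "n") |>
    tidyr::pivot_wider(names_from = "group",
                       values_from = c("p50", "p100", "n"),
                       names_sep = "_")
  for (col in c("p50_disease", "p100_control", "n_disease", "n_control")) {
    if (!col %in% names(wide)) wide[[col]] <- if (startsWith(col, "n_")) 0L else NA_real_
  }
  wide |>
    dplyr::filter(
      .data$n_disease >= 1L, .data$n_control >= 1L,
      !is.na(.data$p50_disease), !is.na(.data$p100_control),
      .data$p50_disease > .data$p100_control
    ) |>
    dplyr::transmute(
      .data$chrom, .data$start, .data$strand,
      ctrl_p100 = .data$p100_control, disease_p50 = .data$p50_disease
    ) |>
    dplyr::arrange(chrom_factor(.data$chrom), .data$start, .data$strand)
}
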