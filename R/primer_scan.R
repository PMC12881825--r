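#' Filter 3: enumerate candidate primer windows
#'
#' Screens each chromosome and strand for primer-length windows dense in
#' differentiating CpGs. Windows are left-anchored at differentiating sites:
#' for every site position `p` and every length `L` in
#' `[min_primer_len, max_primer_len]`, the window `[p, p + L)` is a candidate
#' iff it fully contains at least `min_cpgs` differentiating CpG
#' dinucleotides — a CpG at `s` counts only when both the C and the following
#' G fit, i.e. `s >= p` and `s + 2 <= p + L`.
#'
#' @param sites Differentiating sites tibble (`chrom`, `start`, `strand`),
#'   e.g. from [differentiating_sites()].
#' @param params [msp_params()].
#' @return Tibble of candidate primers: `chrom`, `start`, `end`, `strand`,
#'   `length`, `n_cpgs`, `cpg_positions` (comma-joined starts), sorted by
#'   (chrom, start, end, strand).
#' @export
enumerate_primers <- function(sites, params = msp_params()) {
  empty <- tibble::tibble(
    chrom = character(), start = integer(), end = integer(),
    strand = character(), length = integer(), n_cpgs = integer(),
    cpg_positions = character()
  )
  if (nrow(sites) == 0L) return(empty)
  out <- sites |>
    dplyr::group_by(.data$chrom, .data$strand) |>
    dplyr::group_map(function(df, key) {
      pos <- sort(unique(df$start))
      res <- purrr::map(params$min_primer_len:params$max_primer_len, function(L) {
        # sites s with s >= pos[i] and s + 2 <= pos[i] + L; pos is sorted so the
        # members of window i are pos[i..hi[i]]
        hi <- findInterval(pos + L - 2L, pos)
        n <- hi - seq_along(pos) + 1L
        keep <- which(n >= params$min_cpgs)
        if (!length(keep)) return(NULL)
        tibble::tibble(
          chrom = key$chrom, start = pos[keep], end = pos[keep] + L,
          strand = key$strand, length = L, n_cpgs = n[keep],
          cpg_positions = vapply(keep, function(i) {
            paste(pos[i:hi[i]], collapse = ",")
          }, character(1))
        )
      })
      purrr::list_rbind(purrr::compact(res))
    }) |>
    purrr::list_rbind()
  if (nrow(out) == 0L) return(empty)
  out |>
    dplyr::distinct(.data$chrom, .data$start, .data$end, .data$strand,
                    .keep_all = TRUE) |>
    dplyr::arrange(chrom_factor(.data$chrom), .data$start, .data$end, .data$strand)
}

#' Per-disease-sample coverage normalisers
#'
#' For every disease sample, collects the coverages at all differentiating
#' sites where the sample has data (coverage >= 1) and reduces them to the
#' normaliser used by [score_primers()]: their mean (default; a score term
#' then weighs methylation by the site's coverage relative to the sample's
#' typical coverage, comparable across samples of different depth) or their
#' plain sum. A disease sample with no data at any differentiating site gets
#' a missing normaliser, contributes zero to every score, and triggers a
#' warning.
#'
#' @param calls Merged calls tibble.
#' @param sites Differentiating sites tibble (`chrom`, `start`, `strand`).
#' @param params [msp_params()]; `norm_mode` selects `"mean"` or `"sum"`.
#' @return Tibble with one row per disease sample: `sample`, `k_sites`,
#'   `norm`.
#' @export
sample_norms <- function(calls, sites, params = msp_params()) {
  disease <- sort(unique(calls$sample[calls$group == "disease"]))
  obs <- calls |>
    dplyr::filter(.data$group == "disease", .data$coverage >= 1L) |>
    dplyr::semi_join(sites, by = c("chrom", "start", "strand"))
  agg <- obs |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(
      k_sites = dplyr::n(),
      norm = if (params$norm_mode == "mean") mean(.data$coverage) else sum(.data$coverage),
      .groups = "drop"
    )
  out <- tibble::tibble(sample = disease) |>
    dplyr::left_join(agg, by = "sample") |>
    dplyr::mutate(k_sites = dplyr::coalesce(.data$k_sites, 0L))
  if (nrow(sites) > 0L && any(out$k_sites == 0L)) {
    rlang::warn(paste0(
      "Disease sample(s) without data at any differentiating site: ",
      paste(out$sample[out$k_sites == 0L], collapse = ", "),
      "; they contribute 0 to all primer scores."
    ))
  }
  out
}

#' Score candidate primers by coverage-weighted disease methylation
#'
#' The primer score sums, over all disease samples and all differentiating
#' CpGs inside the window, the coverage-normalised methylation
#' `(cov / norm) * meth`, with methylation in percent. Terms with a missing
#' coverage, methylation or normaliser contribute zero. High scores mean
#' well-covered, strongly methylated windows in the disease group.
#'
#' @param primers Candidate primers from [enumerate_primers()].
#' @param calls Merged calls tibble.
#' @param norms Normaliser table from [sample_norms()].
#' @return `primers` with a `score` column appended.
#' @export
score_primers <- function(primers, calls, norms) {
  if (nrow(primers) == 0L) {
    return(dplyr::mutate(primers, score = double()))
  }
  terms <- calls |>
    dplyr::filter(.data$group == "disease", .data$coverage >= 1L,
                  !is.na(.data$meth_pct)) |>
    dplyr::inner_join(norms[!is.na(norms$norm), c("sample", "norm")], by = "sample") |>
    dplyr::mutate(term = .data$coverage / .data$norm * .data$meth_pct) |>
    dplyr::group_by(.data$chrom, .data$start, .data$strand) |>
    dplyr::summarise(site_score = sum(.data$term), .groups = "drop")
  site_key <- paste(terms$chrom, terms$start, terms$strand)
  site_score <- stats::setNames(terms$site_score, site_key)
  primers |>
    dplyr::mutate(score = purrr::pmap_dbl(
      list(.data$chrom, .data$cpg_positions, .data$strand),
      function(chrom, cpgs, strand) {
        keys <- paste(chrom, strsplit(cpgs, ",", fixed = TRUE)[[1]], strand)
        sum(site_score[keys], na.rm = TRUE)
      }
    ))
}
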