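#' Pair primers into MSP regions
#'
#' Forms every ordered pair of candidate primers (A, B) on the same
#' chromosome with non-overlapping windows (`A.end <= B.start`) whose spanned
#' amplicon — left primer start to right primer end, primers included — has a
#' length within `[min_amplicon_len, max_amplicon_len]`. Distinct pairs may
#' overlap each other; overlapping alternatives are desired so the downstream
#' assay designer can trade off annealing temperature and other constraints.
#' The region score is exactly the sum of the two primer scores; a single
#' global best region (highest score, ties broken by smallest start then
#' smallest length) is flagged.
#'
#' @param primers Scored candidate primers from [score_primers()].
#' @param params [msp_params()].
#' @param calls Optional merged calls tibble; when given, each region also
#'   carries `mean_coverage` (mean disease coverage over both primers'
#'   differentiating sites) and `mean_meth_diff` (mean disease minus mean
#'   control methylation over those sites).
#' @return Tibble of MSP regions sorted by (chrom, start, end), score
#'   descending within ties: `chrom`, `start`, `end`, `length`, `left_start`,
#'   `left_end`, `right_start`, `right_end`, `score`, `cpg_positions`,
#'   `mean_coverage`, `mean_meth_diff`, `is_best`.
#' @export
pair_primers <- function(primers, params = msp_params(), calls = NULL) {
  empty <- tibble::tibble(
    chrom = character(), start = integer(), end = integer(), length = integer(),
    left_start = integer(), left_end = integer(),
    right_start = integer(), right_end = integer(),
    score = double(), cpg_positions = character(),
    mean_coverage = double(), mean_meth_diff = double(), is_best = logical()
  )
  if (nrow(primers) == 0L) return(empty)
  left <- primers |>
    dplyr::select("chrom", left_start = "start", left_end = "end",
                  left_score = "score", left_cpgs = "cpg_positions")
  right <- primers |>
    dplyr::select("chrom", right_start = "start", right_end = "end",
                  right_score = "score", right_cpgs = "cpg_positions")
  pairs <- dplyr::inner_join(left, right, by = "chrom",
                             relationship = "many-to-many") |>
    dplyr::filter(
      .data$left_end <= .data$right_start,
      .data$right_end - .data$left_start >= params$min_amplicon_len,
      .data$right_end - .data$left_start <= params$max_amplicon_len
    )
  if (nrow(pairs) == 0L) return(empty)
  regions <- pairs |>
    dplyr::transmute(
      .data$chrom, start = .data$left_start, end = .data$right_end,
      length = .data$right_end - .data$left_start,
      .data$left_start, .data$left_end, .data$right_start, .data$right_end,
      score = .data$left_score + .data$right_score,
      cpg_positions = paste(.data$left_cpgs, .data$right_cpgs, sep = ",")
    ) |>
    dplyr::distinct(.data$chrom, .data$left_start, .data$left_end,
                    .data$right_start, .data$right_end, .keep_all = TRUE)
  regions <- region_site_summaries(regions, calls)
  best <- regions |>
    dplyr::arrange(dplyr::desc(.data$score), .data$start, .data$length) |>
    dplyr::slice(1)
  regions |>
    dplyr::mutate(is_best = .data$chrom == best$chrom &
                    .data$left_start == best$left_start &
                    .data$left_end == best$left_end &
                    .data$right_start == best$right_start &
                    .data$right_end == best$right_end) |>
    dplyr::arrange(chrom_factor(.data$chrom), .data$start, .data$end,
                   dplyr::desc(.data$score))
}

# mean disease coverage and disease-vs-control methylation difference over
# the (deduplicated) differentiating sites of both primers
region_site_summaries <- function(regions, calls) {
  if (is.null(calls)) {
    return(dplyr::mutate(regions, mean_coverage = NA_real_,
                         mean_meth_diff = NA_real_))
  }
  obs <- calls |>
    dplyr::filter(.data$coverage >= 1L, !is.na(.data$meth_pct))
  summaries <- purrr::pmap(
    list(regions$chrom, regions$cpg_positions),
    function(chrom, cpgs) {
      pos <- unique(as.integer(strsplit(cpgs, ",", fixed = TRUE)[[1]]))
      o <- obs[obs$chrom == chrom & obs$start %in% pos, ]
      d <- o[o$group == "disease", ]
      c_ <- o[o$group == "control", ]
      tibble::tibble(
        mean_coverage = if (nrow(d)) mean(d$coverage) else NA_real_,
        mean_meth_diff = if (nrow(d) && nrow(c_)) {
          mean(d$meth_pct) - mean(c_$meth_pct)
        } else NA_real_
      )
    }
  ) |> purrr::list_rbind()
  dplyr::bind_cols(regions, summaries)
}

#' Select the best MSP region
#'
#' The best region carries the maximal summed primer score; ties are broken
#' by the smallest start, then the smallest length.
#'
#' @param regions Regions tibble from [pair_primers()].
#' @return The single best row.
#' @export
best_region <- function(regions) {
  if (nrow(regions) == 0L) data_error("No MSP regions to choose from.")
  regions |>
    dplyr::arrange(dplyr::desc(.data$score), .data$start, .data$length) |>
    dplyr::slice(1)
}

#' GC content of a sequence
#'
#' `100 * (#G + #C) / length`, case-insensitive; ambiguity codes (N etc.)
#' count in the denominator only.
#'
#' @param sequence Character vector of non-empty DNA sequences.
#' @return Numeric vector of GC percentages.
#' @examples
#' gc_content(c("GCGC", "ACGT", "ACGN"))
#' @export
gc_content <- function(sequence) {
  if (any(!nzchar(sequence)) || any(is.na(sequence))) {
    usage_error("GC content of an empty sequence is undefined.")
  }
  gc <- stringr::str_count(toupper(sequence), "[GC]")
  100 * gc / nchar(sequence)
}

#' Extract a plus-strand reference subsequence
#'
#' @param reference A [Biostrings::DNAStringSet] (see [read_reference()]).
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @return Uppercase sequence string of `[start, end)`.
#' @export
extract_region_sequence <- function(reference, chrom, start, end) {
  if (!chrom %in% names(reference)) {
    data_error("Chromosome '{chrom}' ({chrom}:{start}-{end}) absent from the reference.")
  }
  len <- Biostrings::width(reference[chrom])
  if (start < 0 || end > len || start >= end) {
    data_error("Region {chrom}:{start}-{end} out of range (chromosome length {len}).")
  }
  toupper(as.character(Biostrings::subseq(reference[[chrom]], start + 1L, end)))
}

# appends `sequence` and `gc_pct` columns to any interval tibble
add_sequences <- function(x, reference) {
  if (is.null(reference) || nrow(x) == 0L) {
    return(dplyr::mutate(x, gc_pct = NA_real_, sequence = NA_character_))
  }
  seqs <- purrr::pmap_chr(list(x$chrom, x$start, x$end),
                          function(chrom, start, end) {
                            extract_region_sequence(reference, chrom, start, end)
                          })
  dplyr::mutate(x, gc_pct = gc_content(seqs), sequence = seqs)
}

#' Gene context of MSP regions
#'
#' Attaches the names of all gene bodies overlapping each region by at least
#' one nucleotide and classifies the locus: `gene` when any gene body
#' overlaps; otherwise `upstream500` when the region overlaps the 500 nt
#' upstream of any gene's transcription start (strand-aware: upstream of
#' `start` for `+` genes, of `end` for `-` genes, clipped at position 0);
#' otherwise `intergenic`.
#'
#' @param regions Regions tibble (needs `chrom`, `start`, `end`).
#' @param genes Gene models from [read_gene_annotation()].
#' @param upstream Width of the upstream window in nt.
#' @return `regions` with `genes` (comma-joined names, `""` when none) and
#'   `locus_class` columns.
#' @export
annotate_regions <- function(regions, genes, upstream = 500L) {
  if (nrow(regions) == 0L) {
    return(dplyr::mutate(regions, genes = character(), locus_class = character()))
  }
  if (is.null(genes) || nrow(genes) == 0L) {
    return(dplyr::mutate(regions, genes = NA_character_, locus_class = NA_character_))
  }
  rg <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start + 1L, regions$end)
  )
  gg <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end)
  )
  hits <- GenomicRanges::findOverlaps(rg, gg, ignore.strand = TRUE)
  gene_lists <- split(genes$gene_name[S4Vectors::subjectHits(hits)],
                      factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(regions))))
  gene_str <- vapply(gene_lists, function(g) paste(sort(unique(g)), collapse = ","),
                     character(1))
  up_start <- ifelse(genes$strand == "+", pmax(genes$start - upstream, 0L), genes$end)
  up_end <- ifelse(genes$strand == "+", genes$start, genes$end + upstream)
  ok <- up_start < up_end
  ug <- GenomicRanges::GRanges(
    genes$chrom[ok], IRanges::IRanges(up_start[ok] + 1L, up_end[ok])
  )
  up_hit <- GenomicRanges::countOverlaps(rg, ug, ignore.strand = TRUE) > 0L
  dplyr::mutate(
    regions,
    genes = unname(gene_str),
    locus_class = dplyr::case_when(
      nzchar(.data$genes) ~ "gene",
      up_hit ~ "upstream500",
      TRUE ~ "intergenic"
    )
  )
}
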