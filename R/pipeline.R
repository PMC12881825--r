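#' Run the full MSP biomarker discovery pipeline
#'
#' Chains the whole workflow on a merged multi-sample methylation table:
#' Filter 1 (controls unmethylated and sufficiently covered), per-position
#' boxplot statistics, Filter 2 (disease median above the control upper
#' whisker), primer window enumeration (Filter 3), coverage-normalised
#' scoring, and amplicon pairing; optionally attaches sequences/GC from a
#' reference and gene context from an annotation.
#'
#' @param calls Merged calls tibble from [merge_bedmethyl()] (or
#'   [simulate_methylome()]'s `calls`).
#' @param params [msp_params()].
#' @param reference Optional [Biostrings::DNAStringSet] or FASTA path.
#' @param annotation Optional gene-model tibble from
#'   [read_gene_annotation()] or GTF/GFF3 path.
#' @param verbose Log per-stage counts to stderr.
#' @return An object of class `msp_result`: a list with elements `stats`
#'   (per-position boxplot table), `sites` (differentiating CpGs), `norms`,
#'   `primers`, `regions`, `params` and `counts`.
#' @examples
#' sim <- simulate_methylome(sim_config(seed = 1))
#' res <- find_msp_regions(sim$calls)
#' glance(res)
#' @export
find_msp_regions <- function(calls, params = msp_params(), reference = NULL,
                             annotation = NULL, verbose = FALSE) {
  if (is.character(reference)) reference <- read_reference(reference)
  if (is.character(annotation)) annotation <- read_gene_annotation(annotation)
  say <- function(...) if (verbose) message(sprintf(...))

  n_pos <- nrow(dplyr::distinct(calls, .data$chrom, .data$start, .data$strand))
  say("positions in: %d", n_pos)

  kept <- filter_control_sites(calls, params)
  say("surviving Filter 1 (control gate): %d", nrow(kept))

  stats <- site_statistics(calls, kept)
  sites <- differentiating_sites(stats)
  say("surviving Filter 2 (differentiating CpGs): %d", nrow(sites))

  norms <- sample_norms(calls, sites, params)
  primers <- enumerate_primers(sites, params) |>
    score_primers(calls, norms) |>
    add_sequences(reference)
  say("candidate primers: %d", nrow(primers))

  regions <- pair_primers(primers[setdiff(names(primers), c("gc_pct", "sequence"))],
                          params, calls) |>
    add_sequences(reference) |>
    annotate_regions(annotation)
  say("MSP regions: %d", nrow(regions))
  if (nrow(regions) == 0L) {
    rlang::warn("No MSP region found under the current parameters.")
  }

  interesting <- calls |>
    dplyr::semi_join(sites, by = c("chrom", "start", "strand")) |>
    dplyr::arrange(chrom_factor(.data$chrom), .data$start, .data$strand, .data$sample)

  structure(
    list(
      stats = stats, sites = sites, interesting = interesting, norms = norms,
      primers = primers, regions = regions, params = params,
      has_reference = !is.null(reference), has_annotation = !is.null(annotation),
      counts = tibble::tibble(
        n_positions = n_pos, n_filter1 = nrow(kept), n_sites = nrow(sites),
        n_primers = nrow(primers), n_regions = nrow(regions)
      )
    ),
    class = "msp_result"
  )
}

#' @export
print.msp_result <- function(x, ...) {
  cat("<msp_result>\n")
  cat(sprintf("  positions:             %d\n", x$counts$n_positions))
  cat(sprintf("  pass Filter 1:         %d\n", x$counts$n_filter1))
  cat(sprintf("  differentiating CpGs:  %d\n", x$counts$n_sites))
  cat(sprintf("  candidate primers:     %d\n", x$counts$n_primers))
  cat(sprintf("  MSP regions:           %d\n", x$counts$n_regions))
  if (x$counts$n_regions > 0) {
    b <- best_region(x$regions)
    cat(sprintf("  best region:           %s:%d-%d (length %d, score %.2f)\n",
                b$chrom, b$start, b$end, b$length, b$score))
  }
  invisible(x)
}

#' Tidy the MSP regions of a pipeline result
#'
#' @param x An `msp_result`.
#' @param ... Unused.
#' @return The regions tibble, one row per candidate MSP region.
#' @importFrom generics tidy
#' @export
tidy.msp_result <- function(x, ...) x$regions

#' One-row pipeline summary
#'
#' @param x An `msp_result`.
#' @param ... Unused.
#' @return A one-row tibble with stage counts, the best region score and the
#'   median region length.
#' @importFrom generics glance
#' @export
glance.msp_result <- function(x, ...) {
  dplyr::mutate(
    x$counts,
    best_score = if (nrow(x$regions)) max(x$regions$score) else NA_real_,
    median_region_length = if (nrow(x$regions)) {
      stats::median(x$regions$length)
    } else NA_real_
  )
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
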