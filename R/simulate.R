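#' Configuration of the synthetic methylome generator
#'
#' Describes a single-chromosome multi-sample methylome with sparse
#' background CpGs (essentially unmethylated in both groups) and planted
#' clusters of CpGs hypermethylated in the disease group — the regime an MSP
#' biomarker screen is designed for. Clusters are planted in consecutive
#' pairs spaced so that the two clusters of a pair fall within the default
#' amplicon bounds, giving known truth amplicons for recovery checks.
#'
#' Defaults emulate a small clinical cohort: three control and three disease
#' samples, ~20x mean coverage, background CpGs every ~100 nt with control
#' methylation noise up to 5 percent, and clusters of three CpGs spaced 8 nt
#' apart (span 18 nt, so a 18-24 nt primer window can hold all three) with
#' 90 percent disease methylation.
#'
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param chrom Chromosome name.
#' @param chrom_length Chromosome length in nt.
#' @param n_control,n_disease Sample counts per group.
#' @param cpg_spacing Mean background inter-CpG gap (geometric, minimum 2 nt).
#' @param coverage_lambda Mean of the Poisson per-site, per-sample coverage.
#' @param control_meth_noise Upper bound (percent) of the uniform background
#'   methylation noise in controls (and of disease background methylation).
#' @param clusters Tibble of planted clusters with columns `anchor`,
#'   `n_cpgs`, `spacing`, `disease_meth`, `control_meth`; consecutive rows
#'   are paired into truth amplicons when within `max_amplicon_len`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom = "chrSim",
                       chrom_length = 13000L,
                       n_control = 3L,
                       n_disease = 3L,
                       cpg_spacing = 100,
                       coverage_lambda = 20,
                       control_meth_noise = 5,
                       clusters = default_clusters()) {
  clusters <- tibble::as_tibble(clusters)
  stopifnot(all(c("anchor", "n_cpgs", "spacing", "disease_meth", "control_meth")
                %in% names(clusters)))
  span_end <- clusters$anchor + clusters$spacing * (clusters$n_cpgs - 1L) + 2L
  o <- order(clusters$anchor)
  if (any(span_end[o][-length(o)] > clusters$anchor[o][-1])) {
    usage_error("Planted clusters overlap.")
  }
  if (any(span_end > chrom_length)) usage_error("Planted clusters exceed `chrom_length`.")
  structure(
    list(seed = as.integer(seed), chrom = chrom,
         chrom_length = as.integer(chrom_length),
         n_control = as.integer(n_control), n_disease = as.integer(n_disease),
         cpg_spacing = cpg_spacing, coverage_lambda = coverage_lambda,
         control_meth_noise = control_meth_noise, clusters = clusters),
    class = "sim_config"
  )
}

#' Default planted-cluster layout
#'
#' Pairs of CpG clusters in primer-window geometry: each cluster holds
#' `n_cpgs` CpGs `spacing` nt apart (so its span fits a maximum-length
#' primer), the two clusters of a pair sit `pair_gap` nt apart (an amplicon
#' within the default 60-400 nt bounds), and pairs are separated by
#' `between_pairs` nt so no cross-pair amplicon is possible.
#'
#' @param disease_meth,control_meth Planted methylation (percent) at cluster
#'   CpGs per group.
#' @param n_pairs Number of cluster pairs (truth amplicons).
#' @param pair_gap Distance between the anchors of a pair, nt.
#' @param between_pairs Distance between consecutive pairs, nt.
#' @param first_anchor Anchor of the first cluster, nt.
#' @param n_cpgs,spacing CpGs per cluster and their spacing, nt.
#' @return A cluster tibble for [sim_config()].
#' @export
default_clusters <- function(disease_meth = 90, control_meth = 0,
                             n_pairs = 3L, pair_gap = 150L, between_pairs = 4000L,
                             first_anchor = 2000L, n_cpgs = 3L, spacing = 8L) {
  anchors <- as.vector(vapply(seq_len(n_pairs), function(i) {
    a <- first_anchor + (i - 1L) * between_pairs
    c(a, a + pair_gap)
  }, integer(2)))
  tibble::tibble(anchor = anchors, n_cpgs = n_cpgs, spacing = spacing,
                 disease_meth = disease_meth, control_meth = control_meth)
}

#' Generate a synthetic multi-sample methylome
#'
#' Draws plus-strand CpG positions (background gaps geometric with mean
#' `cpg_spacing`, planted cluster positions fixed by the config), then per
#' sample and site an integer coverage from Poisson(`coverage_lambda`) and a
#' methylation percentage: uniform background noise in `[0,
#' control_meth_noise]` for controls everywhere and for disease samples
#' outside clusters, and the planted disease methylation (plus or minus
#' bounded noise, clipped to `[0, 100]`) at cluster CpGs. Sites with coverage
#' 0 carry a missing methylation call.
#'
#' @param config A [sim_config()].
#' @return A list with `calls` (merged, sorted calls tibble ready for
#'   [find_msp_regions()]), `manifest`, `truth` (tibble `chrom`, `start`,
#'   `end`, `kind` with one `primer_cluster` row per cluster and one
#'   `amplicon` row per in-bounds consecutive cluster pair) and `config`.
#' @export
simulate_methylome <- function(config = sim_config()) {
  withr::with_seed(config$seed, {
    cl <- config$clusters
    cluster_pos <- unlist(purrr::pmap(
      list(cl$anchor, cl$n_cpgs, cl$spacing),
      function(anchor, n, sp) anchor + sp * (0:(n - 1L))
    ))
    gaps <- 2L + stats::rgeom(ceiling(config$chrom_length / max(config$cpg_spacing, 2) * 2) + 50L,
                              prob = 1 / max(config$cpg_spacing - 1, 1))
    background <- cumsum(c(50L, gaps))
    background <- background[background < config$chrom_length - 2L]
    background <- setdiff(background, cluster_pos)
    pos <- sort(c(background, cluster_pos))
    planted <- stats::setNames(rep(NA_real_, length(pos)), pos)
    planted_ctrl <- planted
    for (i in seq_len(nrow(cl))) {
      p <- cl$anchor[i] + cl$spacing[i] * (0:(cl$n_cpgs[i] - 1L))
      planted[as.character(p)] <- cl$disease_meth[i]
      planted_ctrl[as.character(p)] <- cl$control_meth[i]
    }

    manifest <- tibble::tibble(
      sample = c(sprintf("ctrl%d", seq_len(config$n_control)),
                 sprintf("dis%d", seq_len(config$n_disease))),
      group = rep(c("control", "disease"), c(config$n_control, config$n_disease))
    )
    noise <- config$control_meth_noise
    calls <- purrr::pmap(manifest, function(sample, group) {
      coverage <- stats::rpois(length(pos), config$coverage_lambda)
      meth <- if (group == "control") {
        base <- ifelse(is.na(planted_ctrl), 0, planted_ctrl)
        pmin(pmax(base + stats::runif(length(pos), 0, max(noise, 0)), 0), 100)
      } else {
        base <- planted
        bg <- stats::runif(length(pos), 0, max(noise, 0))
        sig <- pmin(pmax(base + stats::runif(length(pos), -noise, noise), 0), 100)
        ifelse(is.na(base), bg, sig)
      }
      meth <- unname(meth)
      meth[coverage == 0L] <- NA_real_
      tibble::tibble(sample = sample, chrom = config$chrom, start = as.integer(pos),
                     end = as.integer(pos) + 1L, strand = "+",
                     coverage = as.integer(coverage), meth_pct = meth)
    }) |> purrr::list_rbind()

    cluster_truth <- tibble::tibble(
      chrom = config$chrom,
      start = cl$anchor,
      end = cl$anchor + cl$spacing * (cl$n_cpgs - 1L) + 2L,
      kind = "primer_cluster"
    )
    o <- order(cl$anchor)
    amp <- NULL
    if (nrow(cl) >= 2L) {
      i1 <- o[seq(1, nrow(cl) - 1, by = 2)]
      i2 <- o[seq(2, nrow(cl), by = 2)]
      amp <- tibble::tibble(
        chrom = config$chrom,
        start = cluster_truth$start[i1],
        end = cluster_truth$end[i2],
        kind = "amplicon"
      )
    }
    list(
      calls = sort_calls(calls, manifest),
      manifest = manifest,
      truth = dplyr::bind_rows(cluster_truth, amp) |>
        dplyr::arrange(.data$start, .data$kind),
      config = config
    )
  })
}

#' Write a simulated methylome as bedmethyl files
#'
#' Emits one BED9+2 bedmethyl file per sample (the dialect
#' [read_bedmethyl()] expects), a `manifest.tsv` (`path`, `sample`, `group`)
#' and the planted truth intervals as BED6 `truth.bed`.
#'
#' @param sim Output of [simulate_methylome()].
#' @param dir Output directory.
#' @return Named list of written paths, invisibly.
#' @export
write_simulated_bedmethyl <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- purrr::pmap_chr(sim$manifest, function(sample, group) {
    f <- file.path(dir, paste0(sample, ".bed"))
    df <- sim$calls[sim$calls$sample == sample, ]
    meth <- ifelse(is.na(df$meth_pct), "nan", sprintf("%.2f", df$meth_pct))
    readr::write_lines(sprintf(
      "%s\t%d\t%d\t5mC\t%d\t%s\t%d\t%d\t0,0,0\t%d\t%s",
      df$chrom, df$start, df$end, pmin(df$coverage, 1000L), df$strand,
      df$start, df$end, df$coverage, meth
    ), f)
    f
  })
  # paths are stored relative to the manifest so the directory is relocatable
  manifest_path <- file.path(dir, "manifest.tsv")
  readr::write_tsv(dplyr::mutate(sim$manifest, path = basename(paths),
                                 .before = "sample"), manifest_path)
  truth_path <- file.path(dir, "truth.bed")
  readr::write_lines(sprintf("%s\t%d\t%d\t%s\t0\t+", sim$truth$chrom,
                             sim$truth$start, sim$truth$end, sim$truth$kind),
                     truth_path)
  invisible(list(bedmethyl = paths, manifest = manifest_path, truth = truth_path))
}

#' Compare predicted MSP regions against planted truth
#'
#' A truth amplicon counts as recovered when some predicted region overlaps
#' it reciprocally by at least `min_overlap` (overlap length >= the fraction
#' of both intervals). A prediction not overlapping any truth amplicon by a
#' single nucleotide is a false positive.
#'
#' @param truth Truth tibble from [simulate_methylome()] (rows with
#'   `kind == "amplicon"` are used; a plain interval tibble works too).
#' @param regions Predicted regions tibble (`chrom`, `start`, `end`).
#' @param min_overlap Reciprocal overlap fraction required for recovery.
#' @return One-row tibble: `n_truth`, `n_recovered`, `recall`,
#'   `n_predictions`, `false_positives`.
#' @export
evaluate_recovery <- function(truth, regions, min_overlap = 0.5) {
  if ("kind" %in% names(truth)) truth <- truth[truth$kind == "amplicon", ]
  n_truth <- nrow(truth)
  n_pred <- nrow(regions)
  if (n_truth == 0L) {
    return(tibble::tibble(n_truth = 0L, n_recovered = 0L, recall = NA_real_,
                          n_predictions = n_pred, false_positives = n_pred))
  }
  ov <- function(ts, te, ps, pe) pmax(0L, pmin(te, pe) - pmax(ts, ps))
  recovered <- vapply(seq_len(n_truth), function(i) {
    if (n_pred == 0L) return(FALSE)
    same <- regions$chrom == truth$chrom[i]
    o <- ov(truth$start[i], truth$end[i], regions$start, regions$end)
    any(same &
          o >= min_overlap * (truth$end[i] - truth$start[i]) &
          o >= min_overlap * (regions$end - regions$start))
  }, logical(1))
  fp <- if (n_pred == 0L) 0L else sum(vapply(seq_len(n_pred), function(j) {
    same <- truth$chrom == regions$chrom[j]
    all(!same | ov(truth$start, truth$end, regions$start[j], regions$end[j]) == 0L)
  }, logical(1)))
  tibble::tibble(
    n_truth = n_truth, n_recovered = sum(recovered),
    recall = sum(recovered) / n_truth,
    n_predictions = n_pred, false_positives = fp
  )
}
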