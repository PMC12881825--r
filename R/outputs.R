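#' Write all pipeline output files
#'
#' Writes the four standard TSVs into `outdir` (created if absent, existing
#' files overwritten): `boxplotData.tsv` (per-position, per-group boxplot
#' statistics), `interestingCpGs.tsv` (raw observations at differentiating
#' CpGs), `primerData.tsv` (scored candidate primers) and `pcrProduct.tsv`
#' (MSP regions). When the pipeline ran with a reference, primers and regions
#' carry `gc_pct`/`sequence` columns and the region sequences are additionally
#' written to `mspRegions.fa`; with an annotation, regions carry
#' `genes`/`locus_class`. All files are tab-separated, UTF-8, LF-terminated,
#' with percentages and scores rendered with two decimals, and byte-identical
#' across repeated runs on identical input.
#'
#' @param result An `msp_result` from [find_msp_regions()].
#' @param outdir Output directory.
#' @return Named character vector of written paths, invisibly.
#' @export
write_msp_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) data_error("Cannot create output directory '{outdir}'.")
  paths <- c(
    boxplot = file.path(outdir, "boxplotData.tsv"),
    cpgs = file.path(outdir, "interestingCpGs.tsv"),
    primers = file.path(outdir, "primerData.tsv"),
    regions = file.path(outdir, "pcrProduct.tsv")
  )

  # like interestingCpGs.tsv, the boxplot table is restricted to the
  # differentiating cytosines (Filters 1 and 2); result$stats keeps all
  # Filter-1 survivors for inspection
  box <- result$stats |>
    dplyr::semi_join(result$sites, by = c("chrom", "start", "strand")) |>
    dplyr::select("chrom", "start", "end", "strand", "group",
                  "p0", "p25", "p50", "p75", "p100", "n") |>
    dplyr::mutate(dplyr::across(c("p0", "p25", "p50", "p75", "p100"), fmt2))
  write_tsv_lf(box, paths["boxplot"])

  cpgs <- result$interesting |>
    dplyr::select("chrom", "start", "end", "strand", "sample", "group",
                  "coverage", "meth_pct") |>
    dplyr::mutate(meth_pct = fmt2(.data$meth_pct))
  write_tsv_lf(cpgs, paths["cpgs"])

  primer_cols <- c("chrom", "start", "end", "strand", "length", "n_cpgs",
                   "cpg_positions", "score")
  if (result$has_reference) primer_cols <- c(primer_cols, "gc_pct", "sequence")
  primers <- result$primers[intersect(primer_cols, names(result$primers))] |>
    dplyr::mutate(score = fmt2(.data$score))
  if (result$has_reference) primers$gc_pct <- fmt2(as.numeric(primers$gc_pct))
  write_tsv_lf(primers, paths["primers"])

  region_cols <- c("chrom", "start", "end", "length", "left_start", "left_end",
                   "right_start", "right_end", "score", "mean_coverage")
  if (result$has_reference) region_cols <- c(region_cols, "gc_pct")
  if (result$has_annotation) region_cols <- c(region_cols, "genes", "locus_class")
  region_cols <- c(region_cols, "is_best")
  regions <- result$regions[intersect(region_cols, names(result$regions))] |>
    dplyr::mutate(score = fmt2(.data$score),
                  mean_coverage = fmt2(.data$mean_coverage))
  if (result$has_reference) regions$gc_pct <- fmt2(as.numeric(regions$gc_pct))
  write_tsv_lf(regions, paths["regions"])

  if (result$has_reference) {
    fa <- file.path(outdir, "mspRegions.fa")
    seqs <- result$regions$sequence
    ids <- sprintf("%s:%d-%d", result$regions$chrom, result$regions$start,
                   result$regions$end)
    keep <- !duplicated(ids)
    dna <- Biostrings::DNAStringSet(stats::setNames(seqs[keep], ids[keep]))
    Biostrings::writeXStringSet(dna, fa)
    paths <- c(paths, fasta = fa)
  }
  invisible(paths)
}

fmt2 <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.2f", x))

write_tsv_lf <- function(df, path) {
  readr::write_tsv(df, path, na = "NA", eol = "\n")
}

#' Command-line entry point
#'
#' Runs the whole pipeline from command-line style arguments. Inputs are
#' given either as repeatable `--bedmethyl path=sample:group` options or as a
#' `--manifest` TSV with columns `path`, `sample`, `group` (flags win when
#' both name a sample). See `run_cli(c("--help"))` for the flag inventory;
#' the Filter-1 methylation threshold is `--max-ctrl-meth` and the primer
#' CpG-count threshold `--minCpGs`.
#'
#' @param args Character vector of arguments (default: the process command
#'   line).
#' @return Exit status, invisibly: 0 on success (including zero regions
#'   found, with a warning), 1 on data errors, 2 on usage errors.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    cfg <- parse_cli(args)
    if (is.null(cfg)) return(invisible(0L))  # --help
    calls <- merge_bedmethyl(cfg$files, cfg$manifest)
    if (cfg$collapse_strands) calls <- collapse_strands(calls)
    message(sprintf("samples: %d control, %d disease",
                    sum(cfg$manifest$group == "control"),
                    sum(cfg$manifest$group == "disease")))
    res <- find_msp_regions(calls, cfg$params, reference = cfg$reference,
                            annotation = cfg$annotation, verbose = TRUE)
    paths <- write_msp_outputs(res, cfg$outdir)
    message(sprintf("wrote %d file(s) to %s", length(paths), cfg$outdir))
    0L
  },
  methmsp_usage_error = function(e) {
    message("usage error: ", conditionMessage(e))
    2L
  },
  error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

parse_cli <- function(args) {
  # optparse has no append action; collect repeatable --bedmethyl first
  bed <- character()
  rest <- character()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (a == "--bedmethyl") {
      if (i == length(args)) usage_error("--bedmethyl needs a value (path=sample:group).")
      bed <- c(bed, args[i + 1L]); i <- i + 2L
    } else if (startsWith(a, "--bedmethyl=")) {
      bed <- c(bed, sub("^--bedmethyl=", "", a)); i <- i + 1L
    } else {
      rest <- c(rest, a); i <- i + 1L
    }
  }

  spec <- list(
    optparse::make_option("--manifest", type = "character", default = NULL,
                          help = "TSV with columns path, sample, group"),
    optparse::make_option("--max-ctrl-meth", type = "double", default = 10,
                          dest = "max_ctrl_meth",
                          help = "Filter 1: max methylation [%%] in any assessable control [default %default]"),
    optparse::make_option("--minCtrCov", type = "integer", default = 3,
                          dest = "min_ctrl_cov",
                          help = "min coverage for a control to be assessable [default %default]"),
    optparse::make_option("--minCtrls", type = "double", default = 0.5,
                          dest = "min_ctrls_frac",
                          help = "min fraction of assessable controls [default %default]"),
    optparse::make_option("--minPrimerLength", type = "integer", default = 18,
                          dest = "min_primer_len",
                          help = "min primer length [nt, default %default]"),
    optparse::make_option("--maxPrimerLength", type = "integer", default = 24,
                          dest = "max_primer_len",
                          help = "max primer length [nt, default %default]"),
    optparse::make_option("--minCpGs", type = "integer", default = 3,
                          dest = "min_cpgs",
                          help = "min differentiating CpGs per primer [default %default]"),
    optparse::make_option("--minAmpliconLength", type = "integer", default = 60,
                          dest = "min_amplicon_len",
                          help = "min MSP region length [nt, default %default]"),
    optparse::make_option("--maxAmpliconLength", type = "integer", default = 400,
                          dest = "max_amplicon_len",
                          help = "max MSP region length [nt, default %default]"),
    optparse::make_option("--norm-mode", type = "character", default = "mean",
                          dest = "norm_mode", help = "coverage normaliser: mean or sum"),
    optparse::make_option("--collapse-strands", action = "store_true",
                          default = FALSE, dest = "collapse_strands",
                          help = "pool each CpG's +/- strand calls before filtering"),
    optparse::make_option("--reference", type = "character", default = NULL,
                          help = "genome FASTA (enables sequence/GC output)"),
    optparse::make_option("--annotation", type = "character", default = NULL,
                          help = "Ensembl-style GTF/GFF3 (enables gene context)"),
    optparse::make_option("--outdir", type = "character", default = "methmsp_out",
                          help = "output directory [default %default]")
  )
  parser <- optparse::OptionParser(
    usage = "methmsp --bedmethyl f1.bed=ctrl1:control --bedmethyl f2.bed=pat1:disease [options]",
    option_list = spec
  )
  if (any(rest %in% c("-h", "--help"))) {
    optparse::print_help(parser)
    return(NULL)
  }
  opt <- tryCatch(
    optparse::parse_args(parser, args = rest),
    error = function(e) usage_error(paste0("bad arguments: ", conditionMessage(e)))
  )

  files <- character(); groups <- character()
  if (length(bed)) {
    m <- regmatches(bed, regexec("^(.*)=([^=:]+):(control|disease)$", bed))
    bad <- lengths(m) != 4L
    if (any(bad)) {
      usage_error(paste0("--bedmethyl value '", bed[bad][1],
                         "' is not of the form path=sample:group."))
    }
    files <- stats::setNames(vapply(m, `[[`, character(1), 2L),
                             vapply(m, `[[`, character(1), 3L))
    groups <- stats::setNames(vapply(m, `[[`, character(1), 4L), names(files))
  }
  if (!is.null(opt$manifest)) {
    mf <- readr::read_tsv(opt$manifest, col_types = readr::cols(.default = "c"))
    if (!all(c("path", "sample", "group") %in% names(mf))) {
      usage_error("--manifest file needs columns path, sample, group.")
    }
    # paths may be given relative to the manifest's own directory
    mf$path <- ifelse(file.exists(mf$path), mf$path,
                      file.path(dirname(opt$manifest), mf$path))
    new <- !mf$sample %in% names(files)
    files <- c(files, stats::setNames(mf$path[new], mf$sample[new]))
    groups <- c(groups, stats::setNames(mf$group[new], mf$sample[new]))
  }
  if (!length(files)) usage_error("No input samples: give --bedmethyl and/or --manifest.")
  missing <- files[!file.exists(files)]
  if (length(missing)) usage_error("Input file(s) not found: {missing}.")

  params <- msp_params(
    max_ctrl_meth = opt$max_ctrl_meth, min_ctrl_cov = opt$min_ctrl_cov,
    min_ctrls_frac = opt$min_ctrls_frac, min_primer_len = opt$min_primer_len,
    max_primer_len = opt$max_primer_len, min_cpgs = opt$min_cpgs,
    min_amplicon_len = opt$min_amplicon_len,
    max_amplicon_len = opt$max_amplicon_len,
    norm_mode = if (opt$norm_mode %in% c("mean", "sum")) opt$norm_mode else {
      usage_error("--norm-mode must be 'mean' or 'sum'.")
    }
  )
  list(
    files = files,
    manifest = tibble::tibble(sample = names(files), group = unname(groups[names(files)])),
    params = params,
    collapse_strands = opt$collapse_strands,
    reference = opt$reference,
    annotation = opt$annotation,
    outdir = opt$outdir
  )
}
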