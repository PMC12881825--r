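#' Read one sample's bedmethyl file
#'
#' Parses the 11+-column BED9+2 bedmethyl dialect produced by per-read
#' modification aggregators (e.g. modbam2bed, modkit): columns 1-3 are
#' chrom/start/end of the cytosine (0-based half-open, so end = start + 1),
#' column 6 the strand, column 10 the read coverage and column 11 the percent
#' methylation. Other dialects can be mapped via `columns`.
#'
#' Rows with coverage 0, or with a non-numeric methylation field (e.g.
#' `"nan"`), are kept but carry a missing `meth_pct`: downstream filters
#' treat them as absent observations. Strand must be `+` or `-`; `.` is
#' rejected because the filters and primer windows are strand-aware.
#'
#' @param path Path to a tab-separated bedmethyl file (no header).
#' @param sample_id Sample identifier attached to every row.
#' @param columns Named integer vector mapping the fields `chrom`, `start`,
#'   `end`, `strand`, `coverage`, `meth_pct` to 1-based column indices;
#'   defaults to the BED9+2 layout `c(1, 2, 3, 6, 10, 11)`.
#' @return A tibble with columns `sample`, `chrom`, `start`, `end`,
#'   `strand`, `coverage`, `meth_pct`.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t101\t5mC\t15\t+\t100\t101\t0,0,0\t15\t80.0", f)
#' read_bedmethyl(f, "d1")
#' @export
read_bedmethyl <- function(path, sample_id,
                           columns = c(chrom = 1L, start = 2L, end = 3L,
                                       strand = 6L, coverage = 10L, meth_pct = 11L)) {
  stopifnot(is.character(path), length(path) == 1L)
  need <- c("chrom", "start", "end", "strand", "coverage", "meth_pct")
  if (!all(need %in% names(columns))) {
    usage_error("`columns` must name all of: {need}.")
  }
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(empty_calls())
  }
  fields <- stringr::str_split(lines, stringr::fixed("\t"))
  nf <- lengths(fields)
  min_cols <- max(columns)
  bad <- which(nf < min_cols)
  if (length(bad)) {
    data_error("{path}: line {bad[1]} has {nf[bad[1]]} columns; >= {min_cols} required.")
  }
  pick <- function(i) vapply(fields, `[[`, character(1), columns[[i]])
  start <- suppressWarnings(as.integer(pick("start")))
  end <- suppressWarnings(as.integer(pick("end")))
  cov <- suppressWarnings(as.integer(pick("coverage")))
  bad <- which(is.na(start) | is.na(end) | is.na(cov))
  if (length(bad)) {
    data_error("{path}: line {bad[1]}: start/end/coverage must be integers.")
  }
  bad <- which(end != start + 1L)
  if (length(bad)) {
    data_error("{path}: line {bad[1]}: interval is not a single cytosine (end != start + 1).")
  }
  bad <- which(start < 0L | cov < 0L)
  if (length(bad)) {
    data_error("{path}: line {bad[1]}: negative start or coverage.")
  }
  strand <- pick("strand")
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad)) {
    data_error(paste0("{path}: line {bad[1]}: strand '", strand[bad[1]],
                      "' not allowed; '+' or '-' required."))
  }
  meth_raw <- pick("meth_pct")
  meth <- suppressWarnings(as.numeric(meth_raw))
  # "nan"/"NA"/"." are missing observations, anything else non-numeric is malformed
  missing_ok <- tolower(meth_raw) %in% c("nan", "na", ".", "")
  bad <- which(is.na(meth) & !missing_ok)
  if (length(bad)) {
    data_error(paste0("{path}: line {bad[1]}: methylation '", meth_raw[bad[1]],
                      "' is not numeric."))
  }
  bad <- which(!is.na(meth) & (meth < 0 | meth > 100))
  if (length(bad)) {
    data_error("{path}: line {bad[1]}: methylation outside [0, 100].")
  }
  meth[cov == 0L | is.nan(meth)] <- NA_real_
  tibble::tibble(
    sample = sample_id, chrom = pick("chrom"), start = start, end = end,
    strand = strand, coverage = cov, meth_pct = meth
  )
}

empty_calls <- function() {
  tibble::tibble(
    sample = character(), chrom = character(), start = integer(),
    end = integer(), strand = character(), coverage = integer(),
    meth_pct = double()
  )
}

#' Merge per-sample bedmethyl files into one sorted table
#'
#' Reads every file, attaches the sample of origin as a column, checks the
#' manifest, and sorts by (chromosome, position, strand, sample) with natural
#' chromosome order (`chr2` before `chr10`). The result is independent of the
#' order in which files are listed.
#'
#' @param files Named character vector of bedmethyl paths; names are sample
#'   ids. Alternatively a tibble with columns `sample` and `path`.
#' @param manifest Tibble with columns `sample` and `group`; `group` must be
#'   `"control"` or `"disease"`, with at least one sample of each.
#' @return A tibble of calls (`sample`, `chrom`, `start`, `end`, `strand`,
#'   `coverage`, `meth_pct`, `group`) with the manifest attached as attribute
#'   `"manifest"`.
#' @export
merge_bedmethyl <- function(files, manifest) {
  if (is.data.frame(files)) {
    stopifnot(all(c("sample", "path") %in% names(files)))
    paths <- stats::setNames(files$path, files$sample)
  } else {
    paths <- files
  }
  if (is.null(names(paths)) || any(!nzchar(names(paths)))) {
    usage_error("`files` must be named by sample id.")
  }
  if (anyDuplicated(names(paths))) {
    usage_error("Duplicate sample ids in `files`: {unique(names(paths)[duplicated(names(paths))])}.")
  }
  manifest <- validate_manifest(manifest)
  missing <- setdiff(names(paths), manifest$sample)
  if (length(missing)) {
    usage_error("Samples absent from the manifest: {missing}.")
  }
  calls <- purrr::map2(unname(paths), names(paths), read_bedmethyl) |>
    purrr::list_rbind()
  sort_calls(calls, manifest)
}

validate_manifest <- function(manifest) {
  if (!is.data.frame(manifest) || !all(c("sample", "group") %in% names(manifest))) {
    usage_error("The manifest needs columns `sample` and `group`.")
  }
  manifest <- tibble::as_tibble(manifest[c("sample", "group")])
  bad <- setdiff(unique(manifest$group), c("control", "disease"))
  if (length(bad)) {
    usage_error("Unknown group(s) {bad}; groups must be 'control' or 'disease'.")
  }
  if (anyDuplicated(manifest$sample)) {
    usage_error("Duplicate sample ids in the manifest.")
  }
  if (!any(manifest$group == "control") || !any(manifest$group == "disease")) {
    usage_error("The manifest needs at least one control and one disease sample.")
  }
  manifest
}

sort_calls <- function(calls, manifest) {
  key <- paste(calls$sample, calls$chrom, calls$start, calls$strand)
  if (anyDuplicated(key)) {
    k <- key[duplicated(key)][1]
    data_error(paste0("Duplicate methylation call for (sample, chrom, pos, strand) = (", k, ")."))
  }
  out <- calls |>
    dplyr::left_join(manifest, by = "sample") |>
    dplyr::arrange(chrom_factor(.data$chrom), .data$start, .data$strand, .data$sample)
  attr(out, "manifest") <- manifest
  out
}

#' Write / re-read a merged methylation table
#'
#' The merged table TSV has a single header line with columns `chrom`,
#' `start`, `end`, `strand`, `coverage`, `meth_pct`, `sample`. Writing and
#' re-reading with the same manifest round-trips exactly.
#'
#' @param calls Merged calls tibble from [merge_bedmethyl()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_merged_table <- function(calls, path) {
  out <- calls[c("chrom", "start", "end", "strand", "coverage", "meth_pct", "sample")]
  readr::write_tsv(out, path, na = "NA")
  invisible(path)
}

#' @rdname write_merged_table
#' @param manifest Sample manifest tibble (`sample`, `group`).
#' @export
read_merged_table <- function(path, manifest) {
  manifest <- validate_manifest(manifest)
  calls <- readr::read_tsv(
    path,
    col_types = readr::cols(
      chrom = readr::col_character(), start = readr::col_integer(),
      end = readr::col_integer(), strand = readr::col_character(),
      coverage = readr::col_integer(), meth_pct = readr::col_double(),
      sample = readr::col_character()
    )
  )
  missing <- setdiff(unique(calls$sample), manifest$sample)
  if (length(missing)) usage_error("Samples absent from the manifest: {missing}.")
  sort_calls(calls[c("sample", "chrom", "start", "end", "strand", "coverage", "meth_pct")],
             manifest)
}

#' Read gene models from a GTF/GFF3 annotation
#'
#' Imports the annotation with `rtracklayer`, keeps feature type `gene` rows
#' and converts the 1-based inclusive coordinates to 0-based half-open. Gene
#' names fall back to the gene id when absent; GFF3 `gene:` id prefixes are
#' stripped.
#'
#' @param path GTF or GFF3 file.
#' @return Tibble with columns `gene_id`, `gene_name`, `chrom`, `start`,
#'   `end`, `strand`; zero rows (with a warning) when the file holds no gene
#'   features.
#' @export
read_gene_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  m <- S4Vectors::mcols(gr)
  type <- as.character(m$type)
  keep <- !is.na(type) & type == "gene"
  gr <- gr[keep]
  m <- S4Vectors::mcols(gr)
  if (length(gr) == 0L) {
    rlang::warn("No `gene` features found in the annotation; gene context disabled.")
    return(tibble::tibble(gene_id = character(), gene_name = character(),
                          chrom = character(), start = integer(),
                          end = integer(), strand = character()))
  }
  gene_id <- if ("gene_id" %in% names(m)) as.character(m$gene_id) else NA_character_
  alt_id <- if ("ID" %in% names(m)) sub("^gene:", "", as.character(m$ID)) else NA_character_
  gene_id <- dplyr::coalesce(gene_id, alt_id)
  gene_name <- NA_character_
  for (nm in c("gene_name", "Name")) {
    if (nm %in% names(m)) gene_name <- dplyr::coalesce(gene_name, as.character(m[[nm]]))
  }
  tibble::tibble(
    gene_id = gene_id,
    gene_name = dplyr::coalesce(gene_name, gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  ) |>
    dplyr::filter(.data$strand %in% c("+", "-")) |>
    dplyr::arrange(chrom_factor(.data$chrom), .data$start)
}

#' Read a reference genome FASTA
#'
#' @param path FASTA file (optionally gzipped).
#' @return A [Biostrings::DNAStringSet]; record ids are truncated at the
#'   first whitespace to match chromosome names.
#' @export
read_reference <- function(path) {
  ref <- Biostrings::readDNAStringSet(path)
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}
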