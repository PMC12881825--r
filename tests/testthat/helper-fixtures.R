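# in-code fixture builders shared across test files

# a calls tibble from compact per-row specs:
# make_calls("c1", "control", chrom, start, cov, meth, strand = "+")
make_calls <- function(...) {
  rows <- list(...)
  df <- purrr::map(rows, function(r) {
    tibble::tibble(
      sample = r[[1]], group = r[[2]], chrom = r[[3]],
      start = as.integer(r[[4]]), end = as.integer(r[[4]]) + 1L,
      strand = if (length(r) >= 7) r[[7]] else "+",
      coverage = as.integer(r[[5]]),
      meth_pct = as.numeric(r[[6]])
    )
  }) |> purrr::list_rbind()
  df[c("sample", "chrom", "start", "end", "strand", "coverage", "meth_pct", "group")]
}

# a valid BED9+2 bedmethyl line
bed_line <- function(chrom, start, cov, meth, strand = "+") {
  meth_str <- if (is.na(meth)) "nan" else format(meth)
  sprintf("%s\t%d\t%d\t5mC\t%d\t%s\t%d\t%d\t0,0,0\t%d\t%s",
          chrom, start, start + 1L, min(cov, 1000L), strand, start, start + 1L,
          cov, meth_str)
}

write_bed <- function(lines, path = withr::local_tempfile(fileext = ".bed",
                                                          .local_envir = parent.frame())) {
  writeLines(lines, path)
  path
}

# a candidate-primer tibble for pairing tests
make_primers <- function(chrom, start, end, score = 1) {
  tibble::tibble(
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    strand = "+", length = as.integer(end - start),
    n_cpgs = 3L,
    cpg_positions = paste(start, start + 4L, start + 8L, sep = ","),
    score = as.numeric(score)
  )
}

# reference FASTA + matching DNAStringSet built in code
write_fasta <- function(seqs, path = withr::local_tempfile(fileext = ".fa",
                                                           .local_envir = parent.frame())) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  path
}
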