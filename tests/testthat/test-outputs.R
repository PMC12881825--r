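cli_fixture <- function(dir, seed = 5, ...) {
  sim <- simulate_methylome(sim_config(seed = seed, ...))
  paths <- write_simulated_bedmethyl(sim, dir)
  list(sim = sim, manifest = paths$manifest, dir = dir)
}

random_fasta <- function(path, chrom = "chrSim", len = 13000, seed = 99) {
  withr::with_seed(seed, {
    seq <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  })
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(stats::setNames(seq, chrom)), path)
  path
}

test_that("a default CLI run writes the four TSVs and no FASTA", {
  fx <- cli_fixture(withr::local_tempdir())
  out <- withr::local_tempdir()
  status <- suppressMessages(run_cli(c("--manifest", fx$manifest, "--outdir", out)))
  expect_equal(status, 0L)
  expect_setequal(list.files(out),
                  c("boxplotData.tsv", "interestingCpGs.tsv",
                    "primerData.tsv", "pcrProduct.tsv"))
  primers <- readr::read_tsv(file.path(out, "primerData.tsv"),
                             show_col_types = FALSE)
  expect_false(any(c("gc_pct", "sequence") %in% names(primers)))
  regions <- readr::read_tsv(file.path(out, "pcrProduct.tsv"),
                             show_col_types = FALSE)
  expect_false(any(c("genes", "locus_class") %in% names(regions)))
  expect_equal(sum(regions$is_best), 1L)
})

test_that("a reference adds sequence columns and mspRegions.fa; annotation adds gene context", {
  fx <- cli_fixture(withr::local_tempdir())
  ref <- random_fasta(withr::local_tempfile(fileext = ".fa"))
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(paste0("chrSim\tens\tgene\t1901\t2500\t.\t+\t.\t",
                    'gene_id "ENSG1"; gene_name "MARK1";'), gtf)
  out <- withr::local_tempdir()
  status <- suppressMessages(run_cli(c(
    "--manifest", fx$manifest, "--outdir", out,
    "--reference", ref, "--annotation", gtf
  )))
  expect_equal(status, 0L)
  expect_true(file.exists(file.path(out, "mspRegions.fa")))
  primers <- readr::read_tsv(file.path(out, "primerData.tsv"),
                             show_col_types = FALSE)
  expect_true(all(c("gc_pct", "sequence") %in% names(primers)))
  expect_true(all(nchar(primers$sequence) == primers$length))
  regions <- readr::read_tsv(file.path(out, "pcrProduct.tsv"),
                             show_col_types = FALSE)
  expect_true(all(c("genes", "locus_class") %in% names(regions)))
  # the first planted cluster pair sits inside the annotated gene
  expect_true(any(regions$locus_class == "gene"))
  fa <- Biostrings::readDNAStringSet(file.path(out, "mspRegions.fa"))
  expect_true(all(grepl("^chrSim:\\d+-\\d+$", names(fa))))
})

test_that("usage errors exit 2 without writing anything", {
  fx <- cli_fixture(withr::local_tempdir())
  out <- file.path(withr::local_tempdir(), "never")
  expect_equal(suppressMessages(run_cli(c(
    "--manifest", fx$manifest, "--outdir", out,
    "--minPrimerLength", "30", "--maxPrimerLength", "24"
  ))), 2L)
  expect_false(dir.exists(out))
  expect_equal(suppressMessages(run_cli(c("--outdir", out))), 2L)
  expect_equal(suppressMessages(run_cli(c(
    "--bedmethyl", "nonsense-value", "--outdir", out
  ))), 2L)
})

test_that("runs without any discovered region still exit 0 with header-only tables", {
  fx <- cli_fixture(withr::local_tempdir(), seed = 8, control_meth_noise = 0,
                    clusters = default_clusters(disease_meth = 0))
  out <- withr::local_tempdir()
  suppressMessages(
    expect_warning(status <- run_cli(c("--manifest", fx$manifest, "--outdir", out)),
                   "No MSP region")
  )
  expect_equal(status, 0L)
  for (f in c("interestingCpGs.tsv", "primerData.tsv", "pcrProduct.tsv")) {
    expect_equal(nrow(readr::read_tsv(file.path(out, f), show_col_types = FALSE)),
                 0L, label = f)
  }
})

test_that("output tables cross-reference consistently", {
  fx <- cli_fixture(withr::local_tempdir())
  out <- withr::local_tempdir()
  suppressMessages(run_cli(c("--manifest", fx$manifest, "--outdir", out)))
  box <- readr::read_tsv(file.path(out, "boxplotData.tsv"), show_col_types = FALSE)
  cpgs <- readr::read_tsv(file.path(out, "interestingCpGs.tsv"), show_col_types = FALSE)
  primers <- readr::read_tsv(file.path(out, "primerData.tsv"), show_col_types = FALSE)
  regions <- readr::read_tsv(file.path(out, "pcrProduct.tsv"), show_col_types = FALSE)

  # identical position sets in the two per-CpG tables
  expect_setequal(unique(paste(box$chrom, box$start, box$strand)),
                  unique(paste(cpgs$chrom, cpgs$start, cpgs$strand)))
  # every region's primers exist in the primer table
  pk <- paste(primers$chrom, primers$start, primers$end)
  expect_true(all(paste(regions$chrom, regions$left_start, regions$left_end) %in% pk))
  expect_true(all(paste(regions$chrom, regions$right_start, regions$right_end) %in% pk))
  # region score is exactly the sum of its primer scores (2-decimal rendering)
  score_of <- stats::setNames(primers$score, pk)
  expect_equal(regions$score,
               round(score_of[paste(regions$chrom, regions$left_start, regions$left_end)] +
                       score_of[paste(regions$chrom, regions$right_start, regions$right_end)], 2),
               ignore_attr = TRUE, tolerance = 0.011)
})

test_that("strand pooling merges symmetric CpG calls", {
  calls <- make_calls(
    list("c1", "control", "chr1", 100, 4, 0),
    list("c1", "control", "chr1", 101, 6, 10, "-"),
    list("d1", "disease", "chr1", 100, 5, 80),
    list("d1", "disease", "chr1", 101, 5, 90, "-")
  )
  pooled <- collapse_strands(calls)
  expect_equal(nrow(pooled), 2L)
  expect_true(all(pooled$strand == "+"))
  expect_equal(pooled$coverage[pooled$sample == "c1"], 10L)
  expect_equal(pooled$meth_pct[pooled$sample == "c1"], 6)    # (4*0 + 6*10)/10
  expect_equal(pooled$meth_pct[pooled$sample == "d1"], 85)
})
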