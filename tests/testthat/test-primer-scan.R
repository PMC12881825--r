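sites_at <- function(pos, chrom = "chr1", strand = "+") {
  tibble::tibble(chrom = chrom, start = as.integer(pos), strand = strand)
}

test_that("primer window enumeration matches hand-derived layouts", {
  p <- msp_params()
  # three CpGs within 12 nt: every window anchored at the first site holds all
  # three, for each of the 7 lengths; later anchors hold too few
  got <- enumerate_primers(sites_at(c(100, 105, 110)), p)
  expect_equal(nrow(got), 7L)
  expect_equal(got$start, rep(100L, 7))
  expect_equal(got$end, 100L + 18:24)
  expect_equal(got$n_cpgs, rep(3L, 7))
  expect_equal(unique(got$cpg_positions), "100,105,110")

  # spacing beyond the maximum window: nothing
  expect_equal(nrow(enumerate_primers(sites_at(c(100, 160, 220)), p)), 0L)

  # a fourth site enters only the longer windows
  got <- enumerate_primers(sites_at(c(100, 102, 104, 120)), p)
  w24 <- got[got$length == 24, ]
  expect_equal(w24$n_cpgs[w24$start == 100], 4L)
  w18 <- got[got$length == 18, ]
  expect_equal(w18$n_cpgs[w18$start == 100], 3L)

  # a CpG counts only with its G inside the window: the site at 17 needs
  # end >= 19, so the 18 nt window misses it and only L >= 19 qualifies
  got <- enumerate_primers(sites_at(c(0, 8, 17)), msp_params())
  expect_equal(got$length, 19:24)
  expect_equal(got$start, rep(0L, 6))
  expect_equal(got$n_cpgs, rep(3L, 6))
})

test_that("enumeration agrees with the exhaustive (start, length) oracle", {
  set.seed(3)
  p <- msp_params()
  for (i in 1:40) {
    pos <- sort(sample(0:600, sample(3:15, 1)))
    got <- enumerate_primers(sites_at(pos), p)
    exp <- oracle_enumerate(pos, p)
    expect_equal(nrow(got), nrow(exp))
    expect_equal(got$start, exp$start)
    expect_equal(got$end, exp$end)
    expect_equal(got$n_cpgs, exp$n_cpgs)
    expect_equal(got$cpg_positions, exp$cpg_positions)
  }
})

test_that("strands are enumerated independently", {
  p <- msp_params()
  sites <- dplyr::bind_rows(sites_at(c(100, 105, 110), strand = "+"),
                            sites_at(c(100, 105), strand = "-"))
  got <- enumerate_primers(sites, p)
  expect_true(all(got$strand == "+"))
})

norm_fixture <- function() {
  make_calls(
    list("c1", "control", "chr1", 100, 5, 0),
    list("c1", "control", "chr1", 200, 5, 0),
    list("c1", "control", "chr1", 300, 5, 0),
    list("d1", "disease", "chr1", 100, 10, 80),
    list("d1", "disease", "chr1", 200, 20, 90),
    list("d1", "disease", "chr1", 300, 30, 100),
    list("d2", "disease", "chr1", 100, 0, NA)
  )
}

test_that("coverage normalisers: mean by default, literal sum on request, missing when no data", {
  calls <- norm_fixture()
  sites <- sites_at(c(100, 200, 300))
  expect_warning(nm <- sample_norms(calls, sites, msp_params()), "d2")
  expect_equal(nm$norm[nm$sample == "d1"], 20)
  expect_equal(nm$k_sites[nm$sample == "d1"], 3L)
  expect_true(is.na(nm$norm[nm$sample == "d2"]))

  expect_warning(ns <- sample_norms(calls, sites, msp_params(norm_mode = "sum")))
  expect_equal(ns$norm[ns$sample == "d1"], 60)
})

test_that("primer scores follow the coverage-normalised methylation sum", {
  # one disease sample, one site, cov 10, meth 80, norm 10 -> 80
  calls <- make_calls(
    list("c1", "control", "chr1", 100, 5, 0),
    list("d1", "disease", "chr1", 100, 10, 80)
  )
  sites <- sites_at(100)
  primers <- tibble::tibble(chrom = "chr1", start = 100L, end = 118L,
                            strand = "+", length = 18L, n_cpgs = 1L,
                            cpg_positions = "100")
  nm <- sample_norms(calls, sites, msp_params())
  expect_equal(score_primers(primers, calls, nm)$score, 80)

  # additivity over disease samples: a duplicated sample doubles the score
  calls2 <- dplyr::bind_rows(calls,
                             make_calls(list("d2", "disease", "chr1", 100, 10, 80)))
  nm2 <- sample_norms(calls2, sites, msp_params())
  expect_equal(score_primers(primers, calls2, nm2)$score, 160)

  # zero methylation annihilates
  calls0 <- make_calls(
    list("c1", "control", "chr1", 100, 5, 0),
    list("d1", "disease", "chr1", 100, 10, 0)
  )
  nm0 <- sample_norms(calls0, sites, msp_params())
  expect_equal(score_primers(primers, calls0, nm0)$score, 0)
})

test_that("score algebra: additivity over sites, scale invariance, sum-vs-mean factor", {
  calls <- norm_fixture()[1:6, ]  # drop the no-data sample
  sites <- sites_at(c(100, 200, 300))
  p2 <- tibble::tibble(chrom = "chr1", start = c(100L, 100L, 200L),
                       end = c(118L, 124L, 220L), strand = "+",
                       length = c(18L, 24L, 20L), n_cpgs = 1L,
                       cpg_positions = c("100", "100,200", "200,300"))
  nm <- sample_norms(calls, sites, msp_params())
  sc <- score_primers(p2, calls, nm)$score
  one_site <- function(pos) {
    score_primers(dplyr::mutate(p2[1, ], cpg_positions = as.character(pos)),
                  calls, nm)$score
  }
  expect_equal(sc[2], one_site(100) + one_site(200))
  expect_equal(sc[3], one_site(200) + one_site(300))
  expect_true(all(sc >= 0))

  # mean mode: scaling all coverages of one sample leaves its contribution alone
  scaled <- dplyr::mutate(calls,
                          coverage = ifelse(.data$sample == "d1",
                                            .data$coverage * 5L, .data$coverage))
  nm_s <- sample_norms(scaled, sites, msp_params())
  expect_equal(score_primers(p2, scaled, nm_s)$score, sc)

  # sum mode differs from mean mode exactly by 1/K per sample (K = 3 here)
  nm_sum <- sample_norms(calls, sites, msp_params(norm_mode = "sum"))
  expect_equal(score_primers(p2, calls, nm_sum)$score, sc / 3)

  # raising one site's methylation never lowers a score containing it
  raised <- dplyr::mutate(calls,
                          meth_pct = ifelse(.data$start == 200 & .data$group == "disease",
                                            pmin(.data$meth_pct * 1.1, 100), .data$meth_pct))
  nm_r <- sample_norms(raised, sites, msp_params())
  expect_true(all(score_primers(p2, raised, nm_r)$score >= sc - 1e-9))
})
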