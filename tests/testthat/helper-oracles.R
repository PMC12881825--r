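# Independent brute-force oracles. These deliberately avoid the package's
# code paths (stats::quantile, findInterval, joins) so agreement is evidence.

# five-number summary: manual sort + linear interpolation + fence scan
oracle_box_stats <- function(values) {
  v <- sort(values[!is.na(values)])
  n <- length(v)
  if (n == 0L) {
    return(list(p0 = NA_real_, p25 = NA_real_, p50 = NA_real_,
                p75 = NA_real_, p100 = NA_real_, iqr = NA_real_, n = 0L))
  }
  interp <- function(p) {
    h <- (n - 1) * p
    lo <- floor(h)
    v[lo + 1] + (h - lo) * (v[min(lo + 2, n)] - v[lo + 1])
  }
  p25 <- interp(0.25)
  p75 <- interp(0.75)
  p50 <- if (n %% 2 == 1L) v[(n + 1L) / 2L] else (v[n / 2L] + v[n / 2L + 1L]) / 2
  iqr <- p75 - p25
  p0 <- NA_real_
  for (x in v) if (x >= p25 - 1.5 * iqr) { p0 <- x; break }
  p100 <- NA_real_
  for (x in rev(v)) if (x <= p75 + 1.5 * iqr) { p100 <- x; break }
  list(p0 = p0, p25 = p25, p50 = p50, p75 = p75, p100 = p100, iqr = iqr, n = n)
}

# exhaustive (start, L) scan; a window is a candidate iff its start is a
# differentiating site and it fully contains >= min_cpgs CpG dinucleotides
oracle_enumerate <- function(pos, params) {
  pos <- sort(unique(pos))
  if (length(pos) == 0L) {
    return(data.frame(start = integer(), end = integer(), n_cpgs = integer(),
                      cpg_positions = character()))
  }
  starts <- (min(pos) - params$max_primer_len):max(pos)
  rows <- list()
  for (L in params$min_primer_len:params$max_primer_len) {
    # membership matrix: does site p (with its G at p+1) lie fully in [s, s+L)?
    inside <- outer(starts, pos, function(s, p) p >= s & p + 2 <= s + L)
    cnt <- rowSums(inside)
    for (k in which(cnt >= params$min_cpgs & starts %in% pos)) {
      rows[[length(rows) + 1L]] <- data.frame(
        start = starts[k], end = starts[k] + L, n_cpgs = cnt[k],
        cpg_positions = paste(pos[inside[k, ]], collapse = ",")
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(start = integer(), end = integer(), n_cpgs = integer(),
                      cpg_positions = character()))
  }
  out <- out[!duplicated(out[c("start", "end")]), ]
  out[order(out$start, out$end), , drop = FALSE]
}

# all-pairs double loop over candidate primers on one chromosome
oracle_pairs <- function(primers, params) {
  rows <- list()
  for (i in seq_len(nrow(primers))) {
    for (j in seq_len(nrow(primers))) {
      a <- primers[i, ]; b <- primers[j, ]
      if (a$chrom != b$chrom) next
      len <- b$end - a$start
      if (a$end <= b$start && len >= params$min_amplicon_len &&
          len <= params$max_amplicon_len) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = a$chrom, left_start = a$start, left_end = a$end,
          right_start = b$start, right_end = b$end, length = len,
          score = a$score + b$score
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(chrom = character(), left_start = integer(),
                      left_end = integer(), right_start = integer(),
                      right_end = integer(), length = integer(), score = double()))
  }
  out[order(out$left_start, out$left_end, out$right_start, out$right_end), ,
      drop = FALSE]
}
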