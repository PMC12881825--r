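#' Pipeline parameters
#'
#' Bundles every tunable threshold of the MSP-region discovery pipeline with
#' its default. Defaults correspond to standard MSP assay constraints:
#' primers of 18-24 nt carrying at least three discriminating CpGs, PCR
#' products of 60-400 nt, controls essentially unmethylated (<= 10 percent)
#' and assessable at >= 3x coverage in at least half of the control samples.
#'
#' @param max_ctrl_meth Maximum tolerated methylation (percent) in any
#'   assessable control sample; a single control strictly above this value
#'   removes the position (Filter 1).
#' @param min_ctrl_cov Minimum read coverage for a control sample to be
#'   considered assessable at a position.
#' @param min_ctrls_frac Minimum fraction of control samples that must be
#'   assessable at a position; the count is rounded up
#'   (`ceiling(min_ctrls_frac * n_controls)`).
#' @param min_primer_len,max_primer_len Primer window length bounds in nt.
#' @param min_cpgs Minimum number of differentiating CpGs a primer window
#'   must contain.
#' @param min_amplicon_len,max_amplicon_len MSP region (amplicon) length
#'   bounds in nt, measured from the left primer's start to the right
#'   primer's end (primers included).
#' @param norm_mode Per-disease-sample coverage normaliser: `"mean"`
#'   (default; mean coverage over the sample's differentiating sites, so a
#'   term becomes relative coverage times methylation) or `"sum"` (the plain
#'   coverage sum).
#'
#' @return A list of class `msp_params`.
#' @examples
#' p <- msp_params(min_cpgs = 4)
#' p$min_cpgs
#' @export
msp_params <- function(max_ctrl_meth = 10,
                       min_ctrl_cov = 3,
                       min_ctrls_frac = 0.5,
                       min_primer_len = 18,
                       max_primer_len = 24,
                       min_cpgs = 3,
                       min_amplicon_len = 60,
                       max_amplicon_len = 400,
                       norm_mode = c("mean", "sum")) {
  norm_mode <- match.arg(norm_mode)
  p <- list(
    max_ctrl_meth = as.numeric(max_ctrl_meth),
    min_ctrl_cov = as.integer(min_ctrl_cov),
    min_ctrls_frac = as.numeric(min_ctrls_frac),
    min_primer_len = as.integer(min_primer_len),
    max_primer_len = as.integer(max_primer_len),
    min_cpgs = as.integer(min_cpgs),
    min_amplicon_len = as.integer(min_amplicon_len),
    max_amplicon_len = as.integer(max_amplicon_len),
    norm_mode = norm_mode
  )
  validate_params(p)
  structure(p, class = "msp_params")
}

validate_params <- function(p) {
  if (p$min_primer_len > p$max_primer_len) {
    usage_error("`min_primer_len` ({p$min_primer_len}) must be <= `max_primer_len` ({p$max_primer_len}).")
  }
  if (p$min_amplicon_len > p$max_amplicon_len) {
    usage_error("`min_amplicon_len` ({p$min_amplicon_len}) must be <= `max_amplicon_len` ({p$max_amplicon_len}).")
  }
  if (2L * p$min_primer_len > p$max_amplicon_len) {
    usage_error("Two primers of `min_primer_len` do not fit in `max_amplicon_len`.")
  }
  if (p$min_cpgs < 1L) usage_error("`min_cpgs` must be >= 1.")
  if (p$min_ctrls_frac <= 0 || p$min_ctrls_frac > 1) {
    usage_error("`min_ctrls_frac` must be in (0, 1].")
  }
  if (p$max_ctrl_meth < 0 || p$max_ctrl_meth > 100) {
    usage_error("`max_ctrl_meth` must be a percentage in [0, 100].")
  }
  invisible(p)
}

#' @export
print.msp_params <- function(x, ...) {
  cat("<msp_params>\n")
  for (nm in names(x)) cat(sprintf("  %-17s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# classed conditions: usage errors exit 2 from the CLI, data errors exit 1
usage_error <- function(msg, ..., .envir = parent.frame()) {
  rlang::abort(glue_msg(msg, .envir = .envir), class = "methmsp_usage_error", ...)
}

data_error <- function(msg, ..., .envir = parent.frame()) {
  rlang::abort(glue_msg(msg, .envir = .envir), class = "methmsp_data_error", ...)
}

glue_msg <- function(msg, .envir) {
  as.character(glue_like(msg, .envir))
}

# minimal {var} interpolation so error messages stay readable without glue
glue_like <- function(template, envir) {
  m <- gregexpr("\\{[^{}]+\\}", template)[[1]]
  if (m[1] == -1) return(template)
  keys <- regmatches(template, gregexpr("\\{[^{}]+\\}", template))[[1]]
  vals <- vapply(keys, function(k) {
    expr <- substr(k, 2, nchar(k) - 1)
    paste(format(eval(parse(text = expr), envir = envir)), collapse = ", ")
  }, character(1))
  for (i in seq_along(keys)) template <- sub(keys[i], vals[i], template, fixed = TRUE)
  template
}

#' Order chromosome names naturally
#'
#' Natural (human-readable) chromosome order: `chr1 < chr2 < ... < chr10 <
#' ... < chr22 < chrM < chrX < chrY`. Used for every sorted output so runs
#' are deterministic.
#'
#' @param chrom Character vector of chromosome names.
#' @return A factor with naturally ordered levels.
#' @export
chrom_factor <- function(chrom) {
  lv <- stringr::str_sort(unique(chrom), numeric = TRUE)
  factor(chrom, levels = lv)
}
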