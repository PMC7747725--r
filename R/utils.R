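# internal helpers shared across modules

IMPACT_LEVELS <- c("HIGH", "MODERATE", "LOW", "MODIFIER", "NONE")
GROUP_LEVELS <- c("case", "crossbreed", "control")
PHENO_LEVELS <- c("curly", "straight", "unknown")

#' Round half away from zero
#'
#' Decimal rounding in which exact ties go up (0.0005 -> 0.001), matching the
#' convention of printed genotype-frequency tables.  `base::round()` rounds
#' ties to even and is not suitable for reproducing published 3-decimal cells.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# strongest impact among a character vector of impact labels; NONE if empty
max_impact <- function(x) {
  x <- x[x %in% IMPACT_LEVELS]
  if (length(x) == 0L) return("NONE")
  IMPACT_LEVELS[min(match(x, IMPACT_LEVELS))]
}

# stop() without the call, with sprintf-style formatting
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(ok, fmt, ...) if (!isTRUE(ok)) abort(fmt, ...)

# split a data.frame of intervals by chromosome preserving order
split_by_chrom <- function(df) split(df, factor(df$chrom, unique(df$chrom)))

# 1-based closed intervals -> IRanges
as_iranges <- function(start, end) IRanges::IRanges(start = start, end = end)
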