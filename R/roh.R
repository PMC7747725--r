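#' ROH sliding-window parameters
#'
#' Parameterization of the PLINK-style run-of-homozygosity scan.  A window
#' of `window_snps` consecutive SNPs "passes" when it contains at most
#' `window_het` heterozygous and `window_missing` missing calls.  Each SNP's
#' hit rate is the fraction of passing windows among all full windows that
#' contain it; SNPs with hit rate at least `hit_rate_threshold` are
#' run-eligible.  Maximal runs of eligible SNPs are split wherever adjacent
#' SNPs lie more than `max_gap_kb` apart, and a run is reported as a ROH
#' when it has at least `min_snps` SNPs, spans at least `min_length_kb`, and
#' averages at most `density_kb_per_snp` kb per SNP.
#'
#' `hit_rate_threshold` is the scanning tool's conventional default (0.05);
#' it is not part of the published parameter sets and is exposed here
#' explicitly.  With `truncated_window = TRUE` (default) a chromosome with
#' fewer SNPs than `window_snps` is evaluated as a single whole-chromosome
#' window instead of being silently skipped; set it to `FALSE` for strict
#' full-window-only behaviour.
#'
#' @param window_snps window size in SNPs.
#' @param window_het maximum heterozygous calls per window.
#' @param window_missing maximum missing calls per window.
#' @param hit_rate_threshold minimum fraction of passing windows per SNP.
#' @param min_snps minimum SNPs per reported run.
#' @param min_length_kb minimum run length (kb).
#' @param density_kb_per_snp maximum kb per SNP within a run.
#' @param max_gap_kb maximum distance between adjacent run SNPs (kb).
#' @param truncated_window evaluate short chromosomes as one truncated window.
#' @return a `roh_params` list.
#' @export
roh_params <- function(window_snps = 20, window_het = 3, window_missing = 5,
                       hit_rate_threshold = 0.05, min_snps = 20,
                       min_length_kb = 2.4, density_kb_per_snp = 0.12,
                       max_gap_kb = 100, truncated_window = TRUE) {
  assert_that(window_snps >= 1, "window_snps must be >= 1")
  assert_that(window_het < window_snps, "window_het must be < window_snps")
  assert_that(window_het >= 0 && window_missing >= 0, "window allowances must be >= 0")
  assert_that(hit_rate_threshold > 0 && hit_rate_threshold <= 1,
              "hit_rate_threshold must be in (0, 1]")
  assert_that(min_snps >= 1 && min_length_kb > 0 && density_kb_per_snp > 0 &&
                max_gap_kb > 0, "run thresholds must be positive")
  structure(list(window_snps = as.integer(window_snps),
                 window_het = as.integer(window_het),
                 window_missing = as.integer(window_missing),
                 hit_rate_threshold = hit_rate_threshold,
                 min_snps = as.integer(min_snps),
                 min_length_kb = min_length_kb,
                 density_kb_per_snp = density_kb_per_snp,
                 max_gap_kb = max_gap_kb,
                 truncated_window = isTRUE(truncated_window)),
            class = "roh_params")
}

#' Published ROH parameter presets
#'
#' `"wgs"`: windows of 20 SNPs with up to 3 heterozygous and 5 missing
#' calls; runs of at least 20 SNPs spanning at least 2.4 kb with a density
#' of at most 0.12 kb per SNP and gaps up to 100 kb — the whole-genome
#' sequencing parameter set.  `"chip"`: identical window allowances, runs of
#' at least 20 SNPs over at least 10 kb with at most 1000 kb per SNP — the
#' 50K SNP-chip parameter set.
#'
#' @param preset `"wgs"` or `"chip"`.
#' @param ... overrides passed to [roh_params()].
#' @return a `roh_params` list.
#' @export
roh_params_preset <- function(preset = c("wgs", "chip"), ...) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    wgs  = list(min_length_kb = 2.4, density_kb_per_snp = 0.12),
    chip = list(min_length_kb = 10, density_kb_per_snp = 1000))
  do.call(roh_params, utils::modifyList(defaults, list(...)))
}

#' Per-SNP window hit rates and run eligibility
#'
#' For one sample and one chromosome, computes for every SNP the fraction of
#' overlapping windows of exactly `window_snps` SNPs that contain at most
#' `window_het` heterozygous and `window_missing` missing calls, and flags
#' SNPs whose fraction reaches `hit_rate_threshold`.  SNPs near chromosome
#' ends use only the windows that exist; a chromosome shorter than the
#' window is evaluated as a single truncated window (see [roh_params()]).
#'
#' @param genos integer genotype vector (0/1/2/NA) ordered by position.
#' @param params a [roh_params()].
#' @return data.frame with `hit_rate` and logical `flag` per SNP.
#' @export
snp_hit_rates <- function(genos, params = roh_params()) {
  m <- length(genos)
  w <- params$window_snps
  if (m == 0L)
    return(data.frame(hit_rate = numeric(0), flag = logical(0)))
  het <- !is.na(genos) & genos == 1L
  miss <- is.na(genos)
  if (m < w) {
    if (!params$truncated_window)
      return(data.frame(hit_rate = rep(0, m), flag = rep(FALSE, m)))
    pass <- sum(het) <= params$window_het && sum(miss) <= params$window_missing
    return(data.frame(hit_rate = rep(as.numeric(pass), m),
                      flag = rep(pass & 1 >= params$hit_rate_threshold, m)))
  }
  H <- cumsum(het)
  M <- cumsum(miss)
  nw <- m - w + 1L
  win_het <- H[w:m] - c(0L, H[seq_len(m - w)])
  win_miss <- M[w:m] - c(0L, M[seq_len(m - w)])
  pass <- win_het <= params$window_het & win_miss <= params$window_missing
  P <- c(0L, cumsum(pass))
  i <- seq_len(m)
  lo <- pmax(1L, i - w + 1L)
  hi <- pmin(i, nw)
  rate <- (P[hi + 1L] - P[lo]) / (hi - lo + 1L)
  data.frame(hit_rate = rate, flag = rate >= params$hit_rate_threshold)
}

#' Assemble ROH segments from eligibility flags
#'
#' Maximal runs of flagged SNPs are split wherever adjacent SNPs lie more
#' than `max_gap_kb` apart; each resulting run is kept when it has at least
#' `min_snps` SNPs, spans at least `min_length_kb` and averages at most
#' `density_kb_per_snp` kb per SNP.  Segment endpoints are the bp positions
#' of the run's first and last SNP.
#'
#' @param flags logical eligibility per SNP (from [snp_hit_rates()]).
#' @param positions integer bp positions, same order.
#' @param genos genotype vector, used only to report per-segment
#'   heterozygous/missing totals.
#' @param params a [roh_params()].
#' @param chrom,sample_id labels attached to the output rows.
#' @return data.frame of segments: `sample_id`, `chrom`, `start_bp`,
#'   `end_bp`, `n_snps`, `n_het`, `n_missing`, `length_kb`.
#' @export
segments_from_flags <- function(flags, positions, genos, params = roh_params(),
                                chrom = "1", sample_id = "sample") {
  stopifnot(length(flags) == length(positions), length(genos) == length(flags))
  empty <- data.frame(sample_id = character(), chrom = character(),
                      start_bp = integer(), end_bp = integer(),
                      n_snps = integer(), n_het = integer(),
                      n_missing = integer(), length_kb = numeric(),
                      stringsAsFactors = FALSE)
  if (!any(flags)) return(empty)
  r <- rle(flags)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  out <- vector("list", sum(r$values))
  n_out <- 0L
  for (k in which(r$values)) {
    idx <- run_start[k]:run_end[k]
    # split at inter-SNP gaps exceeding max_gap_kb
    gaps <- which(diff(positions[idx]) > params$max_gap_kb * 1000)
    piece <- cumsum(c(1L, as.integer(seq_along(idx)[-1] %in% (gaps + 1L))))
    for (sub in split(idx, piece)) {
      n <- length(sub)
      len_kb <- (positions[sub[n]] - positions[sub[1]] + 1) / 1000
      if (n >= params$min_snps && len_kb >= params$min_length_kb &&
          len_kb / n <= params$density_kb_per_snp) {
        n_out <- n_out + 1L
        g <- genos[sub]
        out[[n_out]] <- data.frame(
          sample_id = sample_id, chrom = chrom,
          start_bp = positions[sub[1]], end_bp = positions[sub[n]],
          n_snps = n, n_het = sum(!is.na(g) & g == 1L),
          n_missing = sum(is.na(g)), length_kb = len_kb,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (n_out == 0L) return(empty)
  do.call(rbind, out[seq_len(n_out)])
}

#' Call runs of homozygosity for all samples and chromosomes
#'
#' Runs the sliding-window scan ([snp_hit_rates()] then
#' [segments_from_flags()]) per sample and chromosome and concatenates the
#' results.  Deterministic given its inputs.
#'
#' @param x a [genotype_matrix()].
#' @param params a [roh_params()] (see [roh_params_preset()]).
#' @param genome optional [genome_spec()]; when supplied, excluded
#'   chromosomes are not scanned.
#' @return data.frame of class `roh_segments` (one row per ROH; see
#'   [segments_from_flags()]), with the parameters attached as attribute
#'   `params`.
#' @export
call_roh <- function(x, params = roh_params(), genome = NULL) {
  if (params$window_snps > params$min_snps)
    warning("window_snps > min_snps: windows larger than the run minimum cannot flag short runs")
  chroms <- unique(x$sites$chrom)
  if (!is.null(genome)) chroms <- setdiff(chroms, genome$excluded_chroms)
  res <- list()
  for (chrom in chroms) {
    si <- which(x$sites$chrom == chrom)
    pos <- x$sites$pos[si]
    for (i in seq_len(n_samples(x))) {
      g <- x$geno[i, si]
      fl <- snp_hit_rates(g, params)$flag
      seg <- segments_from_flags(fl, pos, g, params, chrom = chrom,
                                 sample_id = x$samples$sample_id[i])
      if (nrow(seg)) res[[length(res) + 1L]] <- seg
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    segments_from_flags(logical(0), integer(0), integer(0), params)
  ord <- order(match(out$sample_id, x$samples$sample_id),
               factor(out$chrom, chroms), out$start_bp)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "params") <- params
  class(out) <- c("roh_segments", "data.frame")
  out
}

#' @export
summary.roh_segments <- function(object, ...) {
  by_sample <- split(object$length_kb, object$sample_id)
  n <- vapply(by_sample, length, integer(1))
  kb <- vapply(by_sample, sum, numeric(1))
  out <- data.frame(sample_id = names(by_sample), n_roh = as.integer(n),
                    total_kb = kb, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(list(per_sample = out,
                 mean_n_roh = mean(n), mean_total_kb = mean(kb)),
            class = "summary.roh_segments")
}

#' @export
print.summary.roh_segments <- function(x, ...) {
  cat(sprintf("ROH summary over %d samples: average number of ROHs %.2f, total mean length %.0f kb\n",
              nrow(x$per_sample), x$mean_n_roh, x$mean_total_kb))
  print(x$per_sample, row.names = FALSE)
  invisible(x)
}

#' @export
print.roh_segments <- function(x, ...) {
  cat(sprintf("roh_segments: %d segments, %d sample(s)\n",
              nrow(x), length(unique(x$sample_id))))
  print.data.frame(head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat(sprintf("... %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' Write ROH segments as TSV
#'
#' Columns: `sample chrom start end n_snps n_het n_missing length_kb`.
#'
#' @param segments a `roh_segments` data.frame.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_segments_tsv <- function(segments, path) {
  out <- data.frame(sample = segments$sample_id, chrom = segments$chrom,
                    start = segments$start_bp, end = segments$end_bp,
                    n_snps = segments$n_snps, n_het = segments$n_het,
                    n_missing = segments$n_missing,
                    length_kb = segments$length_kb)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
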