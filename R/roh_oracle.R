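#' Brute-force ROH caller (test oracle)
#'
#' A deliberately naive reimplementation of the sliding-window ROH scan:
#' every window is enumerated and counted explicitly, every SNP's hit rate
#' is computed window-by-window, and maximal runs are grown one SNP at a
#' time.  O(n * window) per sample; intended for small instances as an
#' independent check of [call_roh()], with which it must agree exactly.
#' Written without sharing any code with the production caller.
#'
#' @param x a [genotype_matrix()].
#' @param params a [roh_params()].
#' @return data.frame with the same columns as [call_roh()].
#' @export
brute_force_roh <- function(x, params = roh_params()) {
  assert_that(n_sites(x) <= 10000,
              "brute_force_roh is an oracle for small instances (<= 10,000 SNPs)")
  w <- params$window_snps
  rows <- list()
  for (chrom in unique(x$sites$chrom)) {
    si <- which(x$sites$chrom == chrom)
    pos <- x$sites$pos[si]
    m <- length(si)
    for (smp in seq_len(n_samples(x))) {
      g <- x$geno[smp, si]
      # --- per-SNP eligibility, one window at a time -------------------
      flag <- logical(m)
      if (m < w) {
        if (params$truncated_window) {
          nh <- 0L; nm <- 0L
          for (j in seq_len(m)) {
            if (is.na(g[j])) nm <- nm + 1L
            else if (g[j] == 1L) nh <- nh + 1L
          }
          ok <- nh <= params$window_het && nm <= params$window_missing
          if (ok && 1 >= params$hit_rate_threshold) flag[] <- TRUE
        }
      } else {
        for (i in seq_len(m)) {
          n_tot <- 0L; n_pass <- 0L
          for (s in seq_len(m - w + 1L)) {
            if (s > i || s + w - 1L < i) next
            n_tot <- n_tot + 1L
            nh <- 0L; nm <- 0L
            for (j in s:(s + w - 1L)) {
              if (is.na(g[j])) nm <- nm + 1L
              else if (g[j] == 1L) nh <- nh + 1L
            }
            if (nh <= params$window_het && nm <= params$window_missing)
              n_pass <- n_pass + 1L
          }
          if (n_pass / n_tot >= params$hit_rate_threshold) flag[i] <- TRUE
        }
      }
      # --- maximal runs, grown SNP by SNP ------------------------------
      run <- integer(0)
      flush <- function(run) {
        if (length(run) == 0L) return(NULL)
        n <- length(run)
        len_kb <- (pos[run[n]] - pos[run[1]] + 1) / 1000
        if (n >= params$min_snps && len_kb >= params$min_length_kb &&
            len_kb / n <= params$density_kb_per_snp) {
          gg <- g[run]
          data.frame(sample_id = x$samples$sample_id[smp], chrom = chrom,
                     start_bp = pos[run[1]], end_bp = pos[run[n]],
                     n_snps = n, n_het = sum(!is.na(gg) & gg == 1L),
                     n_missing = sum(is.na(gg)), length_kb = len_kb,
                     stringsAsFactors = FALSE)
        } else NULL
      }
      for (i in seq_len(m)) {
        if (flag[i]) {
          if (length(run) > 0L &&
              pos[i] - pos[run[length(run)]] > params$max_gap_kb * 1000) {
            rows[[length(rows) + 1L]] <- flush(run)
            run <- integer(0)
          }
          run <- c(run, i)
        } else {
          rows[[length(rows) + 1L]] <- flush(run)
          run <- integer(0)
        }
      }
      rows[[length(rows) + 1L]] <- flush(run)
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(data.frame(sample_id = character(), chrom = character(),
                      start_bp = integer(), end_bp = integer(),
                      n_snps = integer(), n_het = integer(),
                      n_missing = integer(), length_kb = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  ord <- order(match(out$sample_id, x$samples$sample_id),
               factor(out$chrom, unique(x$sites$chrom)), out$start_bp)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
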