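#' Depth-based QC parameters
#'
#' Defaults follow the whole-genome-sequencing filter set used for ROH
#' calling: genotypes with read depth outside \[3, 60\] are set missing,
#' sites with mean depth below 6 or with more than 30 missing genotypes are
#' removed.  For the candidate-variant dataset a stricter site mean depth of
#' 10 is conventional (`min_mean_dp = 10`); both are configurable.
#'
#' @param min_dp,max_dp per-genotype depth bounds (inclusive).
#' @param min_mean_dp minimum site mean depth over all individuals (missing
#'   depth counts as 0).
#' @param max_missing_count maximum missing genotypes tolerated per site.
#' @return a `depth_qc_params` list.
#' @export
depth_qc_params <- function(min_dp = 3, max_dp = 60, min_mean_dp = 6,
                            max_missing_count = 30) {
  assert_that(min_dp <= max_dp, "min_dp must be <= max_dp")
  assert_that(min_dp >= 0 && min_mean_dp >= 0 && max_missing_count >= 0,
              "depth QC parameters must be non-negative")
  structure(list(min_dp = min_dp, max_dp = max_dp, min_mean_dp = min_mean_dp,
                 max_missing_count = max_missing_count),
            class = "depth_qc_params")
}

#' Apply depth-based genotype and site QC
#'
#' Genotypes whose depth lies outside `[min_dp, max_dp]` are set missing;
#' sites with mean depth below `min_mean_dp` or more than
#' `max_missing_count` missing genotypes (counted after depth masking) are
#' removed.  Site order is preserved and the operation is idempotent.
#'
#' @param x a [genotype_matrix()] with depth.
#' @param params a [depth_qc_params()].
#' @return filtered [genotype_matrix()].
#' @export
apply_depth_qc <- function(x, params = depth_qc_params()) {
  assert_that(!is.null(x$depth),
              "matrix has no depth information; skip depth QC for this input")
  geno <- x$geno
  geno[x$depth < params$min_dp | x$depth > params$max_dp] <- NA_integer_
  dp0 <- x$depth
  dp0[is.na(dp0)] <- 0L
  keep <- colMeans(dp0) >= params$min_mean_dp &
    colSums(is.na(geno)) <= params$max_missing_count
  genotype_matrix(x$sites[keep, , drop = FALSE], x$samples,
                  geno[, keep, drop = FALSE],
                  x$depth[, keep, drop = FALSE])
}

#' SNP-chip QC parameters
#'
#' Defaults: per-site call rate at least 0.99, minor allele frequency at
#' least 0.05, sex chromosomes (and other excluded contigs) dropped.
#'
#' @param min_call_rate minimum fraction of called genotypes per site.
#' @param min_maf minimum minor allele frequency (computed on called
#'   genotypes).
#' @param drop_sex_chroms drop sites on the genome spec's excluded
#'   chromosomes.
#' @return a `chip_qc_params` list.
#' @export
chip_qc_params <- function(min_call_rate = 0.99, min_maf = 0.05,
                           drop_sex_chroms = TRUE) {
  assert_that(min_call_rate >= 0 && min_call_rate <= 1,
              "min_call_rate must be in [0, 1]")
  assert_that(min_maf >= 0 && min_maf <= 0.5, "min_maf must be in [0, 0.5]")
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 drop_sex_chroms = drop_sex_chroms),
            class = "chip_qc_params")
}

#' Apply SNP-chip site QC
#'
#' Removes sites failing call rate or minor-allele-frequency thresholds and
#' sites on excluded chromosomes.  Site order is preserved and the operation
#' is idempotent.  A one-line retention report is emitted as a message.
#'
#' @param x a [genotype_matrix()].
#' @param params a [chip_qc_params()].
#' @param genome a [genome_spec()] providing the excluded chromosomes.
#' @return filtered [genotype_matrix()].
#' @export
apply_chip_qc <- function(x, params = chip_qc_params(), genome = NULL) {
  n <- n_samples(x)
  called <- colSums(!is.na(x$geno))
  call_rate <- called / n
  alt_dose <- colSums(x$geno, na.rm = TRUE)
  p <- ifelse(called > 0, alt_dose / (2 * called), 0)
  maf <- pmin(p, 1 - p)
  keep <- call_rate >= params$min_call_rate & maf >= params$min_maf
  if (params$drop_sex_chroms && !is.null(genome))
    keep <- keep & !(x$sites$chrom %in% genome$excluded_chroms)
  message(sprintf("chip QC: %d of %d sites retained (call rate >= %.3g, MAF >= %.3g)",
                  sum(keep), n_sites(x), params$min_call_rate, params$min_maf))
  if (!any(keep)) warning("chip QC removed every site")
  subset_matrix(x, sites = keep)
}
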