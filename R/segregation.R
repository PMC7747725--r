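# resolve site references (indices, ids, or data.frame chrom+pos) to indices
match_sites <- function(x, sites) {
  if (is.numeric(sites)) {
    assert_that(all(sites >= 1 & sites <= n_sites(x)), "site index out of range")
    return(as.integer(sites))
  }
  if (is.character(sites)) {
    idx <- match(sites, x$sites$id)
    assert_that(!anyNA(idx), "site(s) absent from matrix: %s",
                paste(sites[is.na(idx)], collapse = ", "))
    return(idx)
  }
  key <- paste(x$sites$chrom, x$sites$pos)
  idx <- match(paste(sites$chrom, sites$pos), key)
  assert_that(!anyNA(idx), "site(s) absent from matrix: %s",
              paste(paste0(sites$chrom, ":", sites$pos)[is.na(idx)], collapse = ", "))
  idx
}

# phenotype cohorts used by the validation tables; unknowns are excluded
pheno_cohorts <- function(x) {
  unknown <- sum(x$samples$phenotype == "unknown")
  if (unknown > 0)
    message(sprintf("%d sample(s) with unknown phenotype excluded from cohort tables", unknown))
  list(curly = which(x$samples$phenotype == "curly"),
       straight = which(x$samples$phenotype == "straight"))
}

#' Genotype-frequency tables by phenotype cohort
#'
#' For each requested site, counts hom-ref / het / hom-alt / missing
#' genotypes within the curly and straight phenotype cohorts and derives
#' frequencies.  `denominator = "total_cohort"` (default) divides by the
#' full cohort size including missing — the convention of printed
#' validation tables — while `"called_only"` divides by called genotypes
#' (`NA` when a cohort has no calls).  Display frequencies are rounded
#' half-up to 3 decimals; raw fractions are retained.
#'
#' @param x a [genotype_matrix()].
#' @param sites site reference: indices, ids, or data.frame with
#'   `chrom`, `pos`.  An absent site is a hard error naming it.
#' @param denominator `"total_cohort"` or `"called_only"`.
#' @return data.frame, one row per site x cohort x genotype class:
#'   `id`, `chrom`, `pos`, `cohort`, `cohort_n`, `genotype`
#'   (hom_ref/het/hom_alt), `count`, `n_missing`, `freq`, `freq_display`.
#' @export
genotype_frequencies <- function(x, sites,
                                 denominator = c("total_cohort", "called_only")) {
  denominator <- match.arg(denominator)
  idx <- match_sites(x, sites)
  cohorts <- pheno_cohorts(x)
  rows <- list()
  for (j in idx) {
    for (co in names(cohorts)) {
      g <- x$geno[cohorts[[co]], j]
      counts <- c(hom_ref = sum(g == 0L, na.rm = TRUE),
                  het = sum(g == 1L, na.rm = TRUE),
                  hom_alt = sum(g == 2L, na.rm = TRUE))
      n_missing <- sum(is.na(g))
      denom <- switch(denominator,
                      total_cohort = length(g),
                      called_only = length(g) - n_missing)
      freq <- if (denom > 0) counts / denom else rep(NA_real_, 3)
      rows[[length(rows) + 1L]] <- data.frame(
        id = x$sites$id[j], chrom = x$sites$chrom[j], pos = x$sites$pos[j],
        cohort = co, cohort_n = length(g),
        genotype = names(counts), count = as.integer(counts),
        n_missing = n_missing, freq = as.numeric(freq),
        freq_display = round_half_up(as.numeric(freq), 3),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-locus combined genotype table
#'
#' Cross-tabulates genotypes at two loci (3 x 3 cells: 0/0, 0/1, 1/1 at
#' each) per phenotype cohort; individuals missing a call at either locus
#' are counted separately.
#'
#' @param x a [genotype_matrix()].
#' @param siteA,siteB site references (see [genotype_frequencies()]); must
#'   differ.
#' @return list of class `two_locus_table`: per cohort a 3 x 3 count matrix
#'   (rows = locus A, columns = locus B) plus `n_missing_either`.
#' @export
two_locus_table <- function(x, siteA, siteB) {
  a <- match_sites(x, siteA)
  b <- match_sites(x, siteB)
  assert_that(length(a) == 1 && length(b) == 1, "provide exactly one site each")
  assert_that(a != b, "siteA and siteB must differ")
  cohorts <- pheno_cohorts(x)
  lev <- c("0/0", "0/1", "1/1")
  out <- lapply(names(cohorts), function(co) {
    ga <- x$geno[cohorts[[co]], a]
    gb <- x$geno[cohorts[[co]], b]
    ok <- !is.na(ga) & !is.na(gb)
    tab <- table(factor(lev[ga[ok] + 1L], lev), factor(lev[gb[ok] + 1L], lev))
    list(counts = unclass(as.matrix(tab)), n_missing_either = sum(!ok),
         n = length(ga))
  })
  names(out) <- names(cohorts)
  structure(list(cohorts = out,
                 siteA = x$sites$id[a], siteB = x$sites$id[b]),
            class = "two_locus_table")
}

#' @export
print.two_locus_table <- function(x, ...) {
  cat(sprintf("Combined genotypes %s (rows) x %s (columns)\n", x$siteA, x$siteB))
  for (co in names(x$cohorts)) {
    cat(sprintf("\n%s (n = %d, missing at either locus: %d)\n", co,
                x$cohorts[[co]]$n, x$cohorts[[co]]$n_missing_either))
    print(x$cohorts[[co]]$counts)
  }
  invisible(x)
}

#' Autosomal-dominant consistency check
#'
#' Under a dominant model with full penetrance and no phenocopies, every
#' curly individual should carry at least one alternative allele at at
#' least one candidate site, and every straight individual none.  Returns
#' the discordant samples with their genotypes; samples with unknown
#' phenotype, or missing at every candidate site, are skipped.
#'
#' @param x a [genotype_matrix()].
#' @param candidate_sites site references (see [genotype_frequencies()]).
#' @return data.frame of discordant samples: `sample_id`, `breed`, `group`,
#'   `phenotype`, `carrier`, plus one genotype column per candidate site.
#' @export
dominance_consistency <- function(x, candidate_sites) {
  idx <- match_sites(x, candidate_sites)
  g <- x$geno[, idx, drop = FALSE]
  carrier <- rowSums(g >= 1L, na.rm = TRUE) > 0
  all_missing <- rowSums(!is.na(g)) == 0
  ph <- x$samples$phenotype
  discordant <- (ph == "curly" & !carrier & !all_missing) |
    (ph == "straight" & carrier)
  out <- cbind(x$samples[discordant, , drop = FALSE],
               carrier = carrier[discordant],
               as.data.frame(g[discordant, , drop = FALSE]))
  rownames(out) <- NULL
  out
}

#' Imputation error rate against assay genotypes
#'
#' Exact-match genotype comparison on the intersection of sites
#' (chromosome + position) and samples of an imputed and an
#' assay-validated genotype matrix.  Genotypes missing in either matrix
#' are excluded from the denominator.  The per-SNP error rate is the
#' fraction of discordant genotypes among compared ones; the summary error
#' is the mean over SNPs with at least one comparison.  Symmetric in its
#' two arguments.
#'
#' @param imputed,assay two [genotype_matrix()] objects.
#' @return list of class `error_rate_report`: `per_snp` (data.frame with
#'   `id`, `chrom`, `pos`, `n_compared`, `n_discordant`, `error_rate`),
#'   `mean_error`, `n_samples_compared`.
#' @export
imputation_error <- function(imputed, assay) {
  key_i <- paste(imputed$sites$chrom, imputed$sites$pos, imputed$sites$alt)
  key_a <- paste(assay$sites$chrom, assay$sites$pos, assay$sites$alt)
  si <- which(key_i %in% key_a)
  sa <- match(key_i[si], key_a)
  samples <- intersect(imputed$samples$sample_id, assay$samples$sample_id)
  assert_that(length(si) > 0 && length(samples) > 0,
              "imputed and assay matrices share no sites/samples")
  gi <- imputed$geno[match(samples, imputed$samples$sample_id), si, drop = FALSE]
  ga <- assay$geno[match(samples, assay$samples$sample_id), sa, drop = FALSE]
  both <- !is.na(gi) & !is.na(ga)
  n_comp <- colSums(both)
  n_disc <- colSums(both & (gi != ga), na.rm = TRUE)
  per_snp <- data.frame(
    id = imputed$sites$id[si], chrom = imputed$sites$chrom[si],
    pos = imputed$sites$pos[si],
    n_compared = as.integer(n_comp), n_discordant = as.integer(n_disc),
    error_rate = ifelse(n_comp > 0, n_disc / n_comp, NA_real_),
    stringsAsFactors = FALSE)
  rownames(per_snp) <- NULL
  structure(list(per_snp = per_snp,
                 mean_error = mean(per_snp$error_rate[per_snp$n_compared > 0]),
                 n_samples_compared = length(samples)),
            class = "error_rate_report")
}

#' @export
print.error_rate_report <- function(x, ...) {
  cat(sprintf("imputation error: mean %.4f over %d SNP(s), %d shared sample(s)\n",
              x$mean_error, nrow(x$per_snp), x$n_samples_compared))
  print(head(x$per_snp, 10), row.names = FALSE)
  invisible(x)
}
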