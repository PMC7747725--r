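#' Genotype matrix container
#'
#' The central in-memory model: an ordered site table, a sample metadata
#' table, and a samples x sites genotype matrix coded 0 = homozygous
#' reference, 1 = heterozygous, 2 = homozygous alternative, `NA` = missing.
#' An optional read-depth matrix of the same shape supports depth-based QC.
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based bp), `ref`,
#'   `alt`, and optionally `id`, `impact` (HIGH/MODERATE/LOW/MODIFIER/NONE),
#'   `var_class` (SNP/INDEL/SV) and `end` (for interval-typed records).
#'   Must be sorted by chromosome with strictly increasing positions within
#'   each chromosome.
#' @param samples data.frame with columns `sample_id`, `breed`, `group`
#'   (case/crossbreed/control), `phenotype` (curly/straight/unknown).
#' @param geno integer matrix, `nrow(samples)` x `nrow(sites)`.
#' @param depth optional non-negative integer matrix of the same shape.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, samples, geno, depth = NULL) {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  for (col in c("chrom", "pos", "ref", "alt"))
    assert_that(col %in% names(sites), "sites lacks column '%s'", col)
  if (is.null(sites$id))
    sites$id <- sprintf("%s_%d", sites$chrom, sites$pos)
  if (is.null(sites$impact)) sites$impact <- "NONE"
  if (is.null(sites$var_class)) sites$var_class <- "SNP"
  assert_that(all(sites$impact %in% IMPACT_LEVELS), "invalid impact label")
  assert_that(all(sites$pos >= 1), "site positions must be >= 1")
  assert_that(!any(sites$ref == sites$alt & sites$var_class != "SV"),
              "ref and alt allele identical at some site")
  for (col in c("sample_id", "breed", "group", "phenotype"))
    assert_that(col %in% names(samples), "samples lacks column '%s'", col)
  assert_that(!anyDuplicated(samples$sample_id),
              "duplicate sample_id in metadata")
  assert_that(all(samples$group %in% GROUP_LEVELS),
              "sample group must be one of %s", paste(GROUP_LEVELS, collapse = "/"))
  assert_that(all(samples$phenotype %in% PHENO_LEVELS),
              "phenotype must be one of %s", paste(PHENO_LEVELS, collapse = "/"))
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  assert_that(nrow(geno) == nrow(samples) && ncol(geno) == nrow(sites),
              "geno must be %d samples x %d sites", nrow(samples), nrow(sites))
  assert_that(all(geno %in% c(0L, 1L, 2L) | is.na(geno)),
              "genotype codes must be 0, 1, 2 or NA")
  # sites sorted within chromosome; equal positions only allowed for split
  # multi-allelic records (distinct alt), never full duplicates
  for (chunk in split(sites$pos, factor(sites$chrom, unique(sites$chrom))))
    assert_that(all(diff(chunk) >= 0),
                "sites must be position-sorted within each chrom")
  assert_that(!anyDuplicated(paste(sites$chrom, sites$pos, sites$alt)),
              "duplicate site (chrom, pos, alt)")
  sites$id <- make.unique(as.character(sites$id))
  dimnames(geno) <- list(samples$sample_id, sites$id)
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    storage.mode(depth) <- "integer"
    assert_that(all(dim(depth) == dim(geno)), "depth dimensions must match geno")
    assert_that(all(depth >= 0L, na.rm = TRUE), "depth must be non-negative")
    dimnames(depth) <- dimnames(geno)
  }
  structure(list(sites = sites, samples = samples, geno = geno, depth = depth),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  grp <- table(factor(x$samples$group, GROUP_LEVELS))
  cat(sprintf(
    "genotype_matrix: %d samples x %d sites (%d chrom%s)\n",
    nrow(x$samples), nrow(x$sites), length(unique(x$sites$chrom)),
    if (length(unique(x$sites$chrom)) == 1L) "" else "s"))
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s=%d", names(grp), grp), collapse = ", ")))
  cat(sprintf("  missing genotypes: %.2f%%; depth: %s\n",
              100 * mean(is.na(x$geno)),
              if (is.null(x$depth)) "absent" else "present"))
  invisible(x)
}

#' Number of samples / sites in a genotype matrix
#' @param x a `genotype_matrix`.
#' @return integer count.
#' @export
n_samples <- function(x) nrow(x$samples)

#' @rdname n_samples
#' @export
n_sites <- function(x) nrow(x$sites)

#' Subset a genotype matrix by sites or samples
#'
#' Site order is preserved; the result is revalidated.
#'
#' @param x a `genotype_matrix`.
#' @param sites logical or integer index over sites.
#' @param samples logical or integer index over samples, or sample ids.
#' @return a `genotype_matrix`.
#' @export
subset_matrix <- function(x, sites = NULL, samples = NULL) {
  si <- if (is.null(sites)) seq_len(n_sites(x)) else sites
  if (is.character(samples)) samples <- match(samples, x$samples$sample_id)
  sa <- if (is.null(samples)) seq_len(n_samples(x)) else samples
  genotype_matrix(x$sites[si, , drop = FALSE],
                  x$samples[sa, , drop = FALSE],
                  x$geno[sa, si, drop = FALSE],
                  if (is.null(x$depth)) NULL else x$depth[sa, si, drop = FALSE])
}

# row indices of samples belonging to a group
group_rows <- function(x, group) which(x$samples$group == group)
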