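#' Read sample metadata
#'
#' Tab-separated file with header `sample_id  breed  group  phenotype`.
#' `group` must be one of case/crossbreed/control and `phenotype` one of
#' curly/straight/unknown; group and phenotype are independent fields (a
#' crossbreed may be curly or straight).
#'
#' @param path file path.
#' @return data.frame of sample records.
#' @export
read_metadata <- function(path) {
  md <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character")
  for (col in c("sample_id", "breed", "group", "phenotype"))
    assert_that(col %in% names(md), "metadata lacks column '%s'", col)
  assert_that(!anyDuplicated(md$sample_id), "duplicate sample_id in metadata")
  assert_that(all(md$group %in% GROUP_LEVELS), "invalid group in metadata")
  assert_that(all(md$phenotype %in% PHENO_LEVELS), "invalid phenotype in metadata")
  md
}

#' Genome specification
#'
#' Chromosome lengths plus the autosomal genome size captured by the SNP set,
#' the denominator of F_ROH.  The default captured size (2,265,395,079 bp) is
#' the autosomal pig genome (Sscrofa11.1) captured by a whole-genome SNP set;
#' sex chromosomes, mitochondrion and unplaced scaffolds are excluded from
#' coverage and inbreeding arithmetic.
#'
#' @param chrom_lengths named numeric vector, chromosome -> length in bp.
#' @param autosomal_captured_bp denominator of F_ROH, in bp.
#' @param excluded_chroms chromosomes dropped from autosomal summaries.
#' @return an object of class `genome_spec`.
#' @export
genome_spec <- function(chrom_lengths,
                        autosomal_captured_bp = 2265395079,
                        excluded_chroms = c("X", "Y", "Mt", "Un")) {
  assert_that(length(chrom_lengths) > 0 && !is.null(names(chrom_lengths)),
              "chrom_lengths must be a named vector")
  assert_that(all(chrom_lengths > 0), "chromosome lengths must be positive")
  assert_that(autosomal_captured_bp > 0, "autosomal_captured_bp must be > 0")
  structure(list(chrom_lengths = chrom_lengths,
                 autosomal_captured_bp = as.numeric(autosomal_captured_bp),
                 excluded_chroms = excluded_chroms),
            class = "genome_spec")
}

#' @rdname genome_spec
#' @param path TSV with header `chrom  length`.
#' @param ... passed on to [genome_spec()].
#' @export
read_genome_spec <- function(path, ...) {
  gs <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  assert_that(all(c("chrom", "length") %in% names(gs)),
              "genome spec needs columns chrom, length")
  genome_spec(setNames(as.numeric(gs$length), as.character(gs$chrom)), ...)
}

# autosomes of a genome spec (chromosomes not excluded)
autosomes <- function(genome) {
  setdiff(names(genome$chrom_lengths), genome$excluded_chroms)
}

# ---- VCF ---------------------------------------------------------------

# GT string -> dosage of alt allele k; any "." allele -> NA
gt_to_code <- function(gt, k = 1L) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  out <- rep(NA_integer_, length(gt))
  ok <- !is.na(gt) & !grepl(".", gt, fixed = TRUE)
  if (any(ok)) {
    parts <- strsplit(gt[ok], "/", fixed = TRUE)
    out[ok] <- vapply(parts, function(a) sum(a == as.character(k)), integer(1))
  }
  out
}

# highest-severity impact from a SnpEff-style ANN INFO value
ann_impact <- function(info) {
  m <- regmatches(info, regexpr("ANN=[^;]*", info))
  if (length(m) == 0L) return("NONE")
  entries <- strsplit(sub("^ANN=", "", m), ",", fixed = TRUE)[[1]]
  imp <- vapply(strsplit(entries, "|", fixed = TRUE),
                function(f) if (length(f) >= 3L) f[3] else "NONE", character(1))
  max_impact(imp)
}

#' Read a multi-sample VCF into a genotype matrix
#'
#' Loads GT (and per-sample DP when present) from a VCF 4.x file.  Functional
#' impact is parsed from SnpEff-style `ANN` INFO annotations, taking the
#' highest severity across transcripts (HIGH > MODERATE > LOW > MODIFIER).
#' Multi-allelic records are split into one biallelic record per alternative
#' allele (sharing the position) or skipped, per `multiallelic`.
#'
#' @param path VCF file (plain text or gzipped).
#' @param metadata sample metadata data.frame (see [read_metadata()]) or a
#'   path to a metadata TSV; must cover every sample in the VCF.
#' @param multiallelic `"split"` (default) or `"skip"`.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path, metadata, multiallelic = c("split", "skip")) {
  multiallelic <- match.arg(multiallelic)
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  assert_that(nrow(fix) > 0, "VCF '%s' contains no variant records", path)
  vcf_samples <- colnames(vcf@gt)[-1]
  missing_md <- setdiff(vcf_samples, metadata$sample_id)
  assert_that(length(missing_md) == 0,
              "VCF sample(s) absent from metadata: %s",
              paste(missing_md, collapse = ", "))
  pos <- as.integer(fix[, "POS"])
  chrom <- fix[, "CHROM"]
  for (p in split(pos, factor(chrom, unique(chrom))))
    assert_that(all(diff(p) >= 0), "VCF is not sorted by position; sort it first")
  assert_that(!anyDuplicated(rle(chrom)$values),
              "VCF chromosome blocks are interleaved; sort the file first")

  gt <- vcfR::extract.gt(vcf, "GT")
  has_dp <- grepl("(^|:)DP(:|$)", vcf@gt[, "FORMAT"])
  dp <- if (any(has_dp)) suppressWarnings(vcfR::extract.gt(vcf, "DP", as.numeric = TRUE)) else NULL

  alt_list <- strsplit(ifelse(is.na(fix[, "ALT"]), ".", fix[, "ALT"]), ",", fixed = TRUE)
  info <- ifelse(is.na(fix[, "INFO"]), "", fix[, "INFO"])
  impacts <- vapply(info, ann_impact, character(1), USE.NAMES = FALSE)

  rec_site <- list(); rec_geno <- list(); rec_dp <- list()
  for (r in seq_len(nrow(fix))) {
    alts <- alt_list[[r]]
    if (length(alts) > 1L && multiallelic == "skip") next
    for (k in seq_along(alts)) {
      if (alts[k] %in% c(".", "")) next
      ref <- fix[r, "REF"]
      vc <- if (nchar(ref) != nchar(alts[k]) || nchar(ref) > 1) "INDEL" else "SNP"
      rec_site[[length(rec_site) + 1L]] <- data.frame(
        chrom = chrom[r], pos = pos[r],
        id = if (!is.na(fix[r, "ID"]) && fix[r, "ID"] != ".") fix[r, "ID"]
             else sprintf("%s_%d_%s", chrom[r], pos[r], alts[k]),
        ref = ref, alt = alts[k], impact = impacts[r], var_class = vc,
        stringsAsFactors = FALSE)
      rec_geno[[length(rec_geno) + 1L]] <- gt_to_code(gt[r, vcf_samples], k)
      if (!is.null(dp)) rec_dp[[length(rec_dp) + 1L]] <- dp[r, vcf_samples]
    }
  }
  assert_that(length(rec_site) > 0, "no usable records in VCF '%s'", path)
  sites <- do.call(rbind, rec_site)
  geno <- do.call(cbind, rec_geno)          # samples x sites
  depth <- if (length(rec_dp)) {
    d <- do.call(cbind, rec_dp)
    d[is.na(d)] <- 0
    round(d)
  } else NULL
  md <- metadata[match(vcf_samples, metadata$sample_id), , drop = FALSE]
  genotype_matrix(sites, md, geno, depth)
}

# ---- PLINK text --------------------------------------------------------

#' Read PLINK text MAP/PED genotypes
#'
#' Allele pairs are recoded against the major/minor alleles observed in the
#' file: homozygous major -> 0, heterozygous -> 1, homozygous minor -> 2,
#' `0 0` -> missing.  Allele-frequency ties are broken alphabetically.
#'
#' @param map_path MAP file: chrom, snp id, cM, bp.
#' @param ped_path PED file: 6 leading columns (family, individual, father,
#'   mother, sex, phenotype) then two allele columns per SNP.
#' @param metadata sample metadata covering all PED individual ids (data.frame
#'   or TSV path).
#' @return a [genotype_matrix()] (no depth).
#' @export
read_plink_text <- function(map_path, ped_path, metadata) {
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "id", "cM", "pos"),
                           colClasses = c("character", "character", "numeric", "integer"))
  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  toks <- strsplit(trimws(ped_lines), "[ \t]+")
  want <- 6L + 2L * nrow(map)
  bad <- which(lengths(toks) != want)
  assert_that(length(bad) == 0,
              "PED line %d has %d fields, expected %d (6 + 2 x %d MAP sites)",
              bad[1], length(toks[[bad[1]]]), want, nrow(map))
  ped <- do.call(rbind, toks)
  ids <- ped[, 2]
  missing_md <- setdiff(ids, metadata$sample_id)
  assert_that(length(missing_md) == 0, "PED sample(s) absent from metadata: %s",
              paste(missing_md, collapse = ", "))

  n <- length(ids)
  geno <- matrix(NA_integer_, n, nrow(map))
  ref <- alt <- character(nrow(map))
  for (j in seq_len(nrow(map))) {
    a1 <- ped[, 5L + 2L * j]
    a2 <- ped[, 6L + 2L * j]
    called <- a1 != "0" & a2 != "0"
    tab <- sort(table(c(a1[called], a2[called])), decreasing = TRUE)
    tab <- tab[order(-tab, names(tab))]          # tie -> alphabetical major
    major <- if (length(tab)) names(tab)[1] else "0"
    minor <- if (length(tab) >= 2) names(tab)[2] else "0"
    ref[j] <- major; alt[j] <- minor
    g <- (a1 != major) + (a2 != major)
    g[!called] <- NA_integer_
    geno[, j] <- as.integer(g)
  }
  ord <- order(factor(map$chrom, unique(map$chrom)), map$pos)
  sites <- data.frame(chrom = map$chrom, pos = map$pos, id = map$id,
                      ref = ref, alt = alt, impact = "NONE", var_class = "SNP",
                      stringsAsFactors = FALSE)[ord, , drop = FALSE]
  md <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  genotype_matrix(sites, md, geno[, ord, drop = FALSE])
}

# ---- BED ---------------------------------------------------------------

#' Write genomic intervals as BED
#'
#' Internal coordinates are 1-based fully closed; BED output is 0-based
#' half-open (`start - 1`, `end`).  Records are sorted by chromosome and
#' start; identical or overlapping records are written as-is (no merging).
#'
#' @param regions data.frame with `chrom`, `start`, `end` and optionally a
#'   `name` column written as the 4th BED field.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_intervals_bed <- function(regions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend", con)
  if (!is.null(regions) && nrow(regions) > 0) {
    regions <- regions[order(factor(regions$chrom, sort(unique(regions$chrom))),
                             regions$start), , drop = FALSE]
    lines <- sprintf("%s\t%d\t%d", regions$chrom,
                     as.integer(regions$start) - 1L, as.integer(regions$end))
    if (!is.null(regions$name))
      lines <- paste(lines, regions$name, sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a BED file as 1-based closed intervals
#'
#' @param path BED file (0-based half-open); `#` comment and `track` lines
#'   are skipped.
#' @return data.frame with `chrom`, `start`, `end` (1-based closed) and
#'   `name` when a 4th column is present.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0)
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  toks <- strsplit(lines, "\t", fixed = TRUE)
  out <- data.frame(chrom = vapply(toks, `[`, "", 1),
                    start = as.integer(vapply(toks, `[`, "", 2)) + 1L,
                    end = as.integer(vapply(toks, `[`, "", 3)),
                    stringsAsFactors = FALSE)
  if (all(lengths(toks) >= 4)) out$name <- vapply(toks, `[`, "", 4)
  out
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits VCF 4.2 with GT (and DP when depth is present) and a SnpEff-style
#' `ANN` INFO field carrying each site's impact class, so that the file
#' round-trips through [read_vcf()].
#'
#' @param x a [genotype_matrix()].
#' @param path output file.
#' @param genome optional [genome_spec()] used to emit `##contig` headers.
#' @return invisibly, the path.
#' @export
write_vcf <- function(x, path, genome = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=rohtrace",
           '##INFO=<ID=ANN,Number=.,Type=String,Description="Functional annotations: Allele|Annotation|Annotation_Impact|Gene_Name">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(x$depth))
    hdr <- c(hdr, '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">')
  if (!is.null(genome))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(genome$chrom_lengths),
                          as.integer(genome$chrom_lengths)))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", x$samples$sample_id), collapse = "\t"))
  writeLines(hdr, con)
  gt_str <- matrix(c("0/0", "0/1", "1/1")[x$geno + 1L], nrow = nrow(x$geno))
  gt_str[is.na(x$geno)] <- "./."
  fmt <- "GT"
  if (!is.null(x$depth)) {
    gt_str[] <- paste(gt_str, ifelse(is.na(x$depth), 0L, x$depth), sep = ":")
    fmt <- "GT:DP"
  }
  info <- ifelse(x$sites$impact == "NONE", ".",
                 sprintf("ANN=%s|custom|%s|gene", x$sites$alt, x$sites$impact))
  body <- data.frame(x$sites$chrom, x$sites$pos, x$sites$id, x$sites$ref,
                     x$sites$alt, ".", "PASS", info, fmt, t(gt_str),
                     stringsAsFactors = FALSE)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a genotype matrix as PLINK text MAP/PED
#'
#' @param x a [genotype_matrix()].
#' @param map_path,ped_path output files.
#' @return invisibly, `ped_path`.
#' @export
write_plink_text <- function(x, map_path, ped_path) {
  utils::write.table(
    data.frame(x$sites$chrom, x$sites$id, 0, x$sites$pos),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  ref <- x$sites$ref; alt <- x$sites$alt
  con <- file(ped_path, "w")
  on.exit(close(con))
  for (i in seq_len(n_samples(x))) {
    g <- x$geno[i, ]
    a1 <- ifelse(is.na(g), "0", ifelse(g == 2L, alt, ref))
    a2 <- ifelse(is.na(g), "0", ifelse(g >= 1L, alt, ref))
    writeLines(paste(c(x$samples$sample_id[i], x$samples$sample_id[i],
                       "0", "0", "0", "-9", rbind(a1, a2)), collapse = " "), con)
  }
  invisible(ped_path)
}
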