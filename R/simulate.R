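#' Simulation configuration
#'
#' Parameters of the synthetic cohort generator.  Defaults mirror the
#' whole-genome study design shrunk to desk scale: 9 case-breed animals,
#' 3 F1 crossbreeds (case x control) and 22 outbred controls on 2
#' chromosomes of 20 Mb, with a mean SNP spacing of 100 bp matching the
#' SNP density the whole-genome ROH parameter set presumes (about 1 SNP
#' per 0.1 kb).  Chip-like data use `mean_spacing_bp = 50000` and the
#' larger chip cohort (19/15/17).
#'
#' Outside planted tracts, case genotypes are heterozygous with probability
#' `background_het_rate` (default 0.5: maximally informative segregating
#' sites, so that non-autozygous background is not itself called as ROH);
#' control allele frequencies are drawn from a symmetric
#' Beta(`maf_beta_shape`, `maf_beta_shape`) and controls sampled under
#' Hardy-Weinberg.
#'
#' @param seed integer seed; identical config + seed gives identical output.
#' @param n_chroms,chrom_length_bp synthetic autosome count and length.
#' @param snp_spacing_mode `"uniform"` (spacing uniform on 1..2*mean-1) or
#'   `"exponential"`.
#' @param mean_spacing_bp mean inter-SNP distance.
#' @param n_case,n_cross,n_control cohort sizes.
#' @param n_consensus_tracts autozygosity tracts planted identically in
#'   every case sample (the consensus truth).
#' @param n_cross_shared_tracts how many consensus tracts are additionally
#'   made homozygous in every crossbreed (regions a breed-specific filter
#'   must remove).
#' @param n_planted_tracts additional per-sample tracts planted
#'   independently in each case animal.
#' @param tract_length_range log-uniform bounds of tract length in bp.
#' @param background_het_rate heterozygosity of case genomes outside tracts.
#' @param within_tract_het_leak probability of a stray heterozygous call
#'   inside a planted tract (genotyping noise; default 0).
#' @param n_private_variants breed-private variants planted (carried by
#'   >= 3 cases and >= 1 crossbreed, absent from controls), impacts drawn
#'   from `private_impact_mix`.
#' @param private_impact_mix named proportions over HIGH/MODERATE/LOW/MODIFIER.
#' @param n_decoy_variants HIGH/MODERATE variants planted with at least one
#'   control carrier (must be rejected by the funnel).
#' @param causal_site plant a dominant causal locus (cases homozygous
#'   alternative, crossbreeds heterozygous, controls reference); phenotype
#'   is curly iff an individual carries the alternative allele.
#' @param genotyping_missing_rate missingness injected into the observed
#'   matrix.
#' @param imputation_error_rate rate used to build the error-perturbed
#'   (imputed-like) matrix.
#' @param maf_beta_shape shape of the symmetric allele-frequency Beta.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_chroms = 2, chrom_length_bp = 2e7,
                       snp_spacing_mode = c("uniform", "exponential"),
                       mean_spacing_bp = 100,
                       n_case = 9, n_cross = 3, n_control = 22,
                       n_consensus_tracts = 5, n_cross_shared_tracts = 1,
                       n_planted_tracts = 2,
                       tract_length_range = c(2e5, 2e6),
                       background_het_rate = 0.5,
                       within_tract_het_leak = 0,
                       n_private_variants = 20,
                       private_impact_mix = c(HIGH = 0.25, MODERATE = 0.45,
                                              LOW = 0.15, MODIFIER = 0.15),
                       n_decoy_variants = 30,
                       causal_site = TRUE,
                       genotyping_missing_rate = 0.02,
                       imputation_error_rate = 0.1,
                       maf_beta_shape = 5) {
  snp_spacing_mode <- match.arg(snp_spacing_mode)
  rates <- c(background_het_rate, within_tract_het_leak,
             genotyping_missing_rate, imputation_error_rate)
  assert_that(all(rates >= 0 & rates <= 1), "rates must be in [0, 1]")
  assert_that(n_case >= 0 && n_cross >= 0 && n_control >= 0,
              "cohort sizes must be >= 0")
  assert_that(n_cross_shared_tracts <= n_consensus_tracts,
              "n_cross_shared_tracts cannot exceed n_consensus_tracts")
  assert_that(length(tract_length_range) == 2 &&
                tract_length_range[1] <= tract_length_range[2],
              "tract_length_range must be increasing bounds")
  assert_that(tract_length_range[2] <= chrom_length_bp,
              "tract longer than chromosome")
  assert_that(abs(sum(private_impact_mix) - 1) < 1e-8 &&
                all(names(private_impact_mix) %in% IMPACT_LEVELS),
              "private_impact_mix must be named proportions summing to 1")
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

# draw one tract not overlapping (within min_sep) intervals in `taken`
# (data.frame chrom/start/end); hard error when no placement is found
draw_tract <- function(chrom_lengths, range_bp, taken, min_sep = 1e5,
                       max_tries = 2000) {
  chroms <- names(chrom_lengths)
  for (tries in seq_len(max_tries)) {
    chrom <- sample(chroms, 1, prob = chrom_lengths)
    len <- round(exp(runif(1, log(range_bp[1]), log(range_bp[2]))))
    assert_that(len <= chrom_lengths[[chrom]], "tract longer than chromosome")
    start <- floor(runif(1, 1, chrom_lengths[[chrom]] - len + 1))
    end <- start + len - 1
    tk <- taken[taken$chrom == chrom, , drop = FALSE]
    if (nrow(tk) == 0 ||
        all(start > tk$end + min_sep | end < tk$start - min_sep))
      return(data.frame(chrom = chrom, start = start, end = end,
                        stringsAsFactors = FALSE))
  }
  abort("could not place a tract after %d tries; genome too crowded", max_tries)
}

# sample one transmitted allele per site from a parent genotype vector
transmit <- function(g) {
  a <- integer(length(g))
  a[g == 2L] <- 1L
  het <- g == 1L
  a[het] <- rbinom(sum(het), 1, 0.5)
  a
}

#' Generate a synthetic cohort with planted truth
#'
#' Builds a genotype dataset with the structure the ROH / private-variant
#' analysis assumes: an inbred case breed sharing long homozygous tracts
#' (consensus tracts planted identically in all cases, plus per-sample
#' tracts), F1 crossbreeds built from one transmitted case haplotype and
#' one control haplotype (heterozygous at case-fixed sites, no long
#' homozygosity except in deliberately cross-shared tracts), outbred
#' Hardy-Weinberg controls, breed-private coding variants with impact
#' classes, decoy high-impact variants carried by controls, and a dominant
#' causal locus determining the curly phenotype.  Genotyping missingness
#' and imputation-style errors are injected last; the clean pre-error
#' matrix is also returned.
#'
#' @param config a [sim_config()].
#' @return list of class `roh_simulation`: `genotypes` (observed matrix
#'   with missingness), `genotypes_clean` (pre-error), `genotypes_imputed`
#'   (clean with errors at `imputation_error_rate`), `truth` (consensus
#'   tracts, per-sample tracts, private variants, causal id, phenotypes;
#'   tract coordinates both raw and snapped to SNP positions), `genome`
#'   (a [genome_spec()] whose captured size is the synthetic autosome
#'   total), and `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  set.seed(config$seed)
  chrom_lengths <- setNames(rep(config$chrom_length_bp, config$n_chroms),
                            as.character(seq_len(config$n_chroms)))
  genome <- genome_spec(chrom_lengths,
                        autosomal_captured_bp = sum(chrom_lengths),
                        excluded_chroms = character(0))

  # --- SNP positions ----------------------------------------------------
  site_list <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    n_target <- ceiling(L / config$mean_spacing_bp * 1.3) + 10
    sp <- switch(config$snp_spacing_mode,
      uniform = sample.int(2L * config$mean_spacing_bp - 1L, n_target, replace = TRUE),
      exponential = pmax(1, round(rexp(n_target, 1 / config$mean_spacing_bp))))
    pos <- cumsum(sp)
    pos <- pos[pos <= L]
    data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, site_list)
  n_snp <- nrow(sites)
  sites$id <- sprintf("snp_%s_%d", sites$chrom, sites$pos)
  sites$ref <- "A"; sites$alt <- "C"
  sites$impact <- "NONE"; sites$var_class <- "SNP"

  # --- samples ----------------------------------------------------------
  samples <- data.frame(
    sample_id = c(sprintf("case_%02d", seq_len(config$n_case)),
                  sprintf("cross_%02d", seq_len(config$n_cross)),
                  sprintf("ctrl_%02d", seq_len(config$n_control))),
    breed = rep(c("caseBreed", "F1cross", "controlBreed"),
                c(config$n_case, config$n_cross, config$n_control)),
    group = rep(c("case", "crossbreed", "control"),
                c(config$n_case, config$n_cross, config$n_control)),
    phenotype = "unknown", stringsAsFactors = FALSE)
  is_case <- samples$group == "case"
  is_cross <- samples$group == "crossbreed"
  is_ctrl <- samples$group == "control"
  n_samp <- nrow(samples)

  p <- rbeta(n_snp, config$maf_beta_shape, config$maf_beta_shape)

  geno <- matrix(NA_integer_, n_samp, n_snp)
  for (i in which(is_ctrl))
    geno[i, ] <- rbinom(n_snp, 1, p) + rbinom(n_snp, 1, p)
  for (i in which(is_case)) {
    het <- runif(n_snp) < config$background_het_rate
    hom_alt <- runif(n_snp) < p
    geno[i, ] <- ifelse(het, 1L, 2L * hom_alt)
  }

  site_in <- function(tr) which(sites$chrom == tr$chrom &
                                  sites$pos >= tr$start & sites$pos <= tr$end)
  snap <- function(tr) {
    idx <- site_in(tr)
    if (length(idx) == 0)
      return(cbind(tr, snap_start = NA_integer_, snap_end = NA_integer_))
    cbind(tr, snap_start = min(sites$pos[idx]), snap_end = max(sites$pos[idx]))
  }
  plant <- function(row, tr, hap) {
    idx <- site_in(tr)
    g <- 2L * hap
    leak <- runif(length(idx)) < config$within_tract_het_leak
    g[leak] <- 1L
    geno[row, idx] <<- g
    invisible(NULL)
  }

  # --- consensus tracts (identical in all cases) ------------------------
  taken <- data.frame(chrom = character(), start = integer(), end = integer())
  cons <- list(); cons_haps <- list()
  for (t in seq_len(config$n_consensus_tracts)) {
    tr <- draw_tract(chrom_lengths, config$tract_length_range, taken)
    taken <- rbind(taken, tr)
    hap <- rbinom(length(site_in(tr)), 1, p[site_in(tr)])
    cons_haps[[t]] <- hap
    for (i in which(is_case)) plant(i, tr, hap)
    tr$tract_id <- sprintf("consensus_%02d", t)
    tr$cross_shared <- t <= config$n_cross_shared_tracts
    cons[[t]] <- tr
  }
  consensus_tracts <- if (length(cons)) do.call(rbind, cons) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               tract_id = character(), cross_shared = logical())

  # --- per-sample individual tracts ------------------------------------
  ind <- list()
  for (i in which(is_case)) {
    own <- taken[seq_len(config$n_consensus_tracts), , drop = FALSE]
    for (t in seq_len(config$n_planted_tracts)) {
      tr <- draw_tract(chrom_lengths, config$tract_length_range, own)
      own <- rbind(own, tr[c("chrom", "start", "end")])
      plant(i, tr, rbinom(length(site_in(tr)), 1, p[site_in(tr)]))
      tr$sample_id <- samples$sample_id[i]
      tr$tract_id <- sprintf("%s_ind_%02d", samples$sample_id[i], t)
      ind[[length(ind) + 1L]] <- tr
    }
  }

  # --- F1 crossbreeds: one case-transmitted + one control haplotype -----
  case1 <- which(is_case)[1]
  ctrl1 <- which(is_ctrl)[1]
  for (i in which(is_cross)) {
    a_case <- if (!is.na(case1)) transmit(geno[case1, ]) else rbinom(n_snp, 1, p)
    a_ctrl <- if (!is.na(ctrl1)) transmit(geno[ctrl1, ]) else rbinom(n_snp, 1, p)
    geno[i, ] <- a_case + a_ctrl
  }
  for (t in seq_len(config$n_cross_shared_tracts)) {
    for (i in which(is_cross)) plant(i, cons[[t]][c("chrom", "start", "end")],
                                     cons_haps[[t]])
  }

  # --- planted variant sites (outside every tract) ----------------------
  all_tracts <- rbind(taken,
                      if (length(ind)) do.call(rbind, ind)[c("chrom", "start", "end")])
  in_tract <- rep(FALSE, n_snp)
  for (r in seq_len(nrow(all_tracts))) {
    tr <- all_tracts[r, ]
    in_tract[site_in(tr)] <- TRUE
  }
  n_special <- config$n_private_variants + config$n_decoy_variants +
    as.integer(config$causal_site)
  free <- which(!in_tract)
  assert_that(length(free) >= n_special,
              "not enough SNPs outside tracts to plant %d variants", n_special)
  special <- sample(free, n_special)
  priv_idx <- special[seq_len(config$n_private_variants)]
  decoy_idx <- special[config$n_private_variants + seq_len(config$n_decoy_variants)]
  causal_idx <- if (config$causal_site) special[n_special] else NA_integer_

  priv <- list()
  for (j in priv_idx) {
    geno[is_ctrl, j] <- 0L
    geno[is_case, j] <- 0L
    geno[is_cross, j] <- 0L
    k_case <- if (config$n_case >= 3) sample(3:config$n_case, 1) else config$n_case
    carriers <- sample(which(is_case), k_case)
    zyg <- 1L + rbinom(k_case, 1, 0.5)
    if (k_case == config$n_case && all(zyg == 2L)) zyg[1] <- 1L
    geno[cbind(carriers, j)] <- zyg
    k_cross <- if (config$n_cross >= 1) sample(seq_len(config$n_cross), 1) else 0L
    if (k_cross > 0)
      geno[cbind(sample(which(is_cross), k_cross), j)] <- 1L
    sites$impact[j] <- sample(names(config$private_impact_mix), 1,
                              prob = config$private_impact_mix)
    priv[[length(priv) + 1L]] <- data.frame(
      chrom = sites$chrom[j], pos = sites$pos[j], id = sites$id[j],
      impact = sites$impact[j], causal = FALSE,
      n_case_carriers = k_case, n_cross_carriers = k_cross,
      stringsAsFactors = FALSE)
  }
  for (j in decoy_idx) {
    sites$impact[j] <- sample(c("HIGH", "MODERATE"), 1)
    carrier <- sample(which(is_ctrl), 1)
    if (geno[carrier, j] == 0L) geno[carrier, j] <- 1L
  }
  if (config$causal_site) {
    j <- causal_idx
    geno[is_case, j] <- 2L
    geno[is_cross, j] <- 1L
    geno[is_ctrl, j] <- 0L
    sites$impact[j] <- "HIGH"
    priv[[length(priv) + 1L]] <- data.frame(
      chrom = sites$chrom[j], pos = sites$pos[j], id = sites$id[j],
      impact = "HIGH", causal = TRUE,
      n_case_carriers = config$n_case, n_cross_carriers = config$n_cross,
      stringsAsFactors = FALSE)
  }
  private_variants <- if (length(priv)) do.call(rbind, priv) else
    data.frame(chrom = character(), pos = integer(), id = character(),
               impact = character(), causal = logical(),
               n_case_carriers = integer(), n_cross_carriers = integer())

  # --- phenotype: dominant at the causal locus --------------------------
  if (config$causal_site) {
    samples$phenotype <- ifelse(geno[, causal_idx] >= 1L, "curly", "straight")
  } else {
    samples$phenotype <- ifelse(is_ctrl, "straight", "curly")
  }

  clean <- genotype_matrix(sites, samples, geno)

  observed <- clean
  if (config$genotyping_missing_rate > 0) {
    drop <- matrix(runif(length(geno)) < config$genotyping_missing_rate,
                   nrow = nrow(geno))
    g2 <- geno
    g2[drop] <- NA_integer_
    observed <- genotype_matrix(sites, samples, g2)
  }
  imputed <- inject_imputation_errors(clean, config$imputation_error_rate)

  # truth tract tables with coordinates snapped to SNP positions
  sample_tracts <- if (length(ind)) {
    it <- do.call(rbind, ind)
    do.call(rbind, lapply(seq_len(nrow(it)), function(r) snap(it[r, ])))
  } else NULL
  cons_snapped <- if (nrow(consensus_tracts)) {
    do.call(rbind, lapply(seq_len(nrow(consensus_tracts)),
                          function(r) snap(consensus_tracts[r, ])))
  } else consensus_tracts

  structure(list(
    genotypes = observed,
    genotypes_clean = clean,
    genotypes_imputed = imputed,
    truth = list(consensus_tracts = cons_snapped,
                 sample_tracts = sample_tracts,
                 private_variants = private_variants,
                 causal_id = if (config$causal_site) sites$id[causal_idx] else NA_character_,
                 phenotypes = samples[c("sample_id", "phenotype")]),
    genome = genome,
    config = config), class = "roh_simulation")
}

#' @export
print.roh_simulation <- function(x, ...) {
  cat(sprintf("roh_simulation: %d samples x %d sites, %d consensus tract(s), %d private variant(s)\n",
              n_samples(x$genotypes), n_sites(x$genotypes),
              nrow(x$truth$consensus_tracts), nrow(x$truth$private_variants)))
  invisible(x)
}

#' Inject imputation-style genotype errors
#'
#' Each called genotype is independently replaced by one of the two other
#' genotype codes with probability `rate`; missing genotypes are left
#' untouched.
#'
#' @param x a [genotype_matrix()].
#' @param rate error probability in \[0, 1\].
#' @param seed optional seed for reproducible injection outside
#'   [simulate_cohort()]'s stream.
#' @return a [genotype_matrix()] with perturbed genotypes.
#' @export
inject_imputation_errors <- function(x, rate, seed = NULL) {
  assert_that(is.numeric(rate) && rate >= 0 && rate <= 1,
              "rate must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  g <- x$geno
  err <- !is.na(g) & matrix(runif(length(g)) < rate, nrow = nrow(g))
  if (any(err)) {
    # replace with one of the two other codes, uniformly
    shift <- 1L + rbinom(sum(err), 1, 0.5)
    g[err] <- (g[err] + shift) %% 3L
  }
  genotype_matrix(x$sites, x$samples, g, x$depth)
}

#' Write simulator outputs to disk
#'
#' Emits the observed cohort as VCF and PLINK text MAP/PED, the clean
#' (pre-error) and error-perturbed matrices as VCFs, sample metadata and
#' genome spec TSVs, truth BEDs for consensus and per-sample tracts, and
#' the private-variant truth TSV.
#'
#' @param sim a `roh_simulation` ([simulate_cohort()]).
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(dir, f)
  write_vcf(sim$genotypes, fp("cohort.vcf"), sim$genome)
  write_vcf(sim$genotypes_clean, fp("cohort_clean.vcf"), sim$genome)
  write_vcf(sim$genotypes_imputed, fp("cohort_imputed.vcf"), sim$genome)
  write_plink_text(sim$genotypes, fp("cohort.map"), fp("cohort.ped"))
  utils::write.table(sim$genotypes$samples, fp("metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(chrom = names(sim$genome$chrom_lengths),
                                length = as.integer(sim$genome$chrom_lengths)),
                     fp("genome.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  ct <- sim$truth$consensus_tracts
  if (nrow(ct))
    write_intervals_bed(data.frame(chrom = ct$chrom, start = ct$start,
                                   end = ct$end, name = ct$tract_id),
                        fp("truth_consensus.bed"))
  st <- sim$truth$sample_tracts
  if (!is.null(st) && nrow(st))
    write_intervals_bed(data.frame(chrom = st$chrom, start = st$start,
                                   end = st$end, name = st$tract_id),
                        fp("truth_sample_tracts.bed"))
  utils::write.table(sim$truth$private_variants, fp("truth_private_variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
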