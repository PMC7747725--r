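test_that("identical config and seed give identical simulations", {
  a <- desk_sim(seed = 9)
  b <- desk_sim(seed = 9)
  expect_identical(a$genotypes$geno, b$genotypes$geno)
  expect_identical(a$genotypes_imputed$geno, b$genotypes_imputed$geno)
  expect_identical(a$truth, b$truth)
  c <- desk_sim(seed = 10)
  expect_false(identical(a$genotypes$geno, c$genotypes$geno))
})

test_that("simulator writes files that round-trip through the readers", {
  sim <- desk_sim(seed = 12, chrom_length_bp = 3e5, mean_spacing_bp = 500,
                  n_consensus_tracts = 1, n_planted_tracts = 0,
                  tract_length_range = c(2e4, 5e4), n_private_variants = 5,
                  n_decoy_variants = 5)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  md <- read_metadata(file.path(dir, "metadata.tsv"))
  x <- read_vcf(file.path(dir, "cohort.vcf"), md)
  expect_identical(unname(x$geno), unname(sim$genotypes$geno))
  expect_identical(x$sites$impact, sim$genotypes$sites$impact)
  gs <- read_genome_spec(file.path(dir, "genome.tsv"),
                         autosomal_captured_bp = sum(sim$genome$chrom_lengths))
  expect_equal(gs$chrom_lengths, sim$genome$chrom_lengths)
  bed <- read_bed(file.path(dir, "truth_consensus.bed"))
  expect_equal(bed$start, sim$truth$consensus_tracts$start)
  expect_equal(bed$end, sim$truth$consensus_tracts$end)
})

test_that("F1 crossbreeds are heterozygous at fixed-divergent sites", {
  sim <- desk_sim(seed = 13)
  x <- sim$genotypes_clean
  cases <- x$samples$group == "case"
  ctrls <- x$samples$group == "control"
  crosses <- x$samples$group == "crossbreed"
  # cross-shared tracts are deliberately homozygous in crossbreeds: exclude
  cs <- sim$truth$consensus_tracts
  cs <- cs[cs$cross_shared, , drop = FALSE]
  excl <- rep(FALSE, n_sites(x))
  for (r in seq_len(nrow(cs)))
    excl <- excl | (x$sites$chrom == cs$chrom[r] & x$sites$pos >= cs$start[r] &
                      x$sites$pos <= cs$end[r])
  fixed <- colSums(x$geno[cases, , drop = FALSE] == 2L) == sum(cases) &
    colSums(x$geno[ctrls, , drop = FALSE] == 0L) == sum(ctrls) & !excl
  expect_gt(sum(fixed), 0)
  expect_true(all(x$geno[crosses, fixed, drop = FALSE] == 1L))
})

test_that("planted private variants match the emitted carrier pattern exactly", {
  sim <- desk_sim(seed = 14)
  x <- sim$genotypes_clean
  cc <- carrier_counts(x)
  truth <- sim$truth$private_variants
  idx <- match(truth$id, cc$id)
  expect_false(anyNA(idx))
  expect_equal(cc$n_case_carriers[idx], truth$n_case_carriers)
  expect_equal(cc$n_cross_carriers[idx], truth$n_cross_carriers)
  expect_equal(cc$n_control_carriers[idx], rep(0L, nrow(truth)))
  expect_equal(x$sites$impact[match(truth$id, x$sites$id)], truth$impact)
})

test_that("dominant causal locus drives the phenotype with no phenocopies", {
  sim <- desk_sim(seed = 15)
  x <- sim$genotypes_clean
  expect_equal(x$samples$phenotype,
               ifelse(x$samples$group == "control", "straight", "curly"))
  disc <- dominance_consistency(x, sim$truth$causal_id)
  expect_equal(nrow(disc), 0L)
})

test_that("case F_ROH tracks the planted autozygous fraction", {
  sim <- desk_sim(seed = 16)
  segs <- call_roh(sim$genotypes_clean, roh_params_preset("wgs"), sim$genome)
  f <- froh(segs, sim$genome, sample_ids = sim$genotypes$samples$sample_id)
  ct <- sim$truth$consensus_tracts
  st <- sim$truth$sample_tracts
  for (s in sim$genotypes$samples$sample_id[sim$genotypes$samples$group == "case"]) {
    truth_bp <- sum(ct$snap_end - ct$snap_start + 1) +
      sum(st$snap_end[st$sample_id == s] - st$snap_start[st$sample_id == s] + 1)
    expect_lt(abs(f$froh[f$sample_id == s] -
                    truth_bp / sim$genome$autosomal_captured_bp), 0.01)
  }
})

test_that("with no planted tracts the background yields almost no ROH", {
  sim <- simulate_cohort(sim_config(seed = 17, chrom_length_bp = 2e6,
                                    n_consensus_tracts = 0,
                                    n_cross_shared_tracts = 0,
                                    n_planted_tracts = 0))
  segs <- call_roh(sim$genotypes_clean, roh_params_preset("wgs"), sim$genome)
  cases <- sim$genotypes$samples$sample_id[sim$genotypes$samples$group == "case"]
  case_kb <- sum(segs$length_kb[segs$sample_id %in% cases])
  genome_kb <- sum(sim$genome$chrom_lengths) / 1000 * length(cases)
  expect_lt(case_kb / genome_kb, 0.01)
})

test_that("error injection endpoints behave as documented", {
  x <- make_gm(matrix(sample(c(0L, 1L, 2L, NA), 200, TRUE), 4))
  expect_identical(inject_imputation_errors(x, 0)$geno, x$geno)
  all_flip <- inject_imputation_errors(x, 1)
  called <- !is.na(x$geno)
  expect_true(all(all_flip$geno[called] != x$geno[called]))
  expect_true(all(is.na(all_flip$geno[!called])))
  expect_error(inject_imputation_errors(x, 1.2), "rate")
})

test_that("infeasible tract placement is a hard error", {
  expect_error(sim_config(chrom_length_bp = 1e5,
                          tract_length_range = c(2e5, 2e6)),
               "tract")
  expect_error(simulate_cohort(sim_config(chrom_length_bp = 5e5,
                                          tract_length_range = c(4e5, 4.9e5),
                                          n_consensus_tracts = 4)),
               "place")
})
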