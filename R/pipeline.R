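#' Run the full selection-signature workflow
#'
#' Wires the modules into the canonical analysis order: ROH calling on the
#' case + crossbreed + control cohort, case-group consensus regions,
#' breed-specific refinement against crossbreed ROH, per-chromosome
#' coverage, F_ROH with breed means, the breed-private candidate-variant
#' funnel, and a dominant-model consistency check on the funnel survivors.
#' All stage outputs are written as TSV/BED into `out_dir` together with a
#' run manifest recording parameters and stage counts.  Deterministic
#' given its inputs.
#'
#' @param input a [genotype_matrix()] or a path to a VCF.
#' @param metadata sample metadata (data.frame or TSV path); required when
#'   `input` is a VCF path.
#' @param genome a [genome_spec()] or a path to a genome TSV.
#' @param out_dir output directory.
#' @param roh a [roh_params()]; default the WGS preset.
#' @param consensus_min_support minimum case support (`"all"` or integer).
#' @param max_support_excluded crossbreed support that removes a base.
#' @param min_fragment_bp minimum surviving breed-specific fragment.
#' @param funnel a [funnel_criteria()].
#' @param genes optional gene intervals (data.frame `chrom`, `start`,
#'   `end`, `gene_id`) for region annotation.
#' @return invisibly, a list with every stage result and the manifest.
#' @export
run_pipeline <- function(input, metadata = NULL, genome, out_dir,
                         roh = roh_params_preset("wgs"),
                         consensus_min_support = "all",
                         max_support_excluded = 1,
                         min_fragment_bp = 1000,
                         funnel = funnel_criteria(),
                         genes = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(out_dir, f)
  if (is.character(genome)) genome <- read_genome_spec(genome)
  x <- stage("load", {
    if (inherits(input, "genotype_matrix")) input
    else read_vcf(input, metadata)
  })

  segments <- stage("roh", call_roh(x, roh, genome))
  write_segments_tsv(segments, fp("segments.tsv"))
  case_ids <- x$samples$sample_id[x$samples$group == "case"]
  cross_ids <- x$samples$sample_id[x$samples$group == "crossbreed"]

  consensus <- stage("consensus", consensus_regions(
    segments[segments$sample_id %in% case_ids, , drop = FALSE],
    case_ids, consensus_min_support))
  utils::write.table(consensus, fp("consensus.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_intervals_bed(data.frame(chrom = consensus$chrom,
                                 start = consensus$start_bp,
                                 end = consensus$end_bp),
                      fp("consensus.bed"))

  specific <- stage("breed_specific", breed_specific_filter(
    consensus, segments[segments$sample_id %in% cross_ids, , drop = FALSE],
    max_support_excluded, min_fragment_bp))
  utils::write.table(specific, fp("breed_specific.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  coverage <- stage("coverage", coverage_table(specific, genome))
  utils::write.table(coverage, fp("coverage.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  froh_tab <- stage("froh", froh(segments, genome,
                                 sample_ids = x$samples$sample_id))
  froh_breeds <- froh_breed_means(froh_tab, x$samples)
  utils::write.table(froh_tab, fp("froh.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(froh_breeds, fp("froh_breeds.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  funnel_res <- stage("funnel", candidate_filter(x, funnel))
  utils::write.table(funnel_res$survivors, fp("funnel_survivors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(funnel_res$report, fp("funnel_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  gene_overlap <- NULL
  if (!is.null(genes)) {
    gene_overlap <- stage("annotation", genes_in_regions(specific, genes))
    utils::write.table(gene_overlap, fp("region_genes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  discordant <- NULL
  if (nrow(funnel_res$survivors) > 0) {
    discordant <- stage("dominance", dominance_consistency(
      x, funnel_res$survivors[c("chrom", "pos")]))
    utils::write.table(discordant, fp("dominance_discordant.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- c(
    sprintf("rohtrace %s", as.character(utils::packageVersion("rohtrace"))),
    sprintf("samples: %d  sites: %d", n_samples(x), n_sites(x)),
    sprintf("roh params: %s", paste(sprintf("%s=%s", names(roh),
            vapply(roh, function(v) paste(format(v), collapse = ","), "")),
            collapse = " ")),
    sprintf("consensus_min_support: %s  max_support_excluded: %d  min_fragment_bp: %d",
            paste(consensus_min_support), max_support_excluded, min_fragment_bp),
    sprintf("stage counts: segments=%d consensus=%d breed_specific=%d funnel_survivors=%d",
            nrow(segments), nrow(consensus), nrow(specific),
            nrow(funnel_res$survivors)))
  writeLines(manifest, fp("run_manifest.txt"))

  invisible(list(matrix = x, segments = segments, consensus = consensus,
                 breed_specific = specific, coverage = coverage,
                 froh = froh_tab, froh_breeds = froh_breeds,
                 funnel = funnel_res, genes = gene_overlap,
                 dominance_discordant = discordant, manifest = manifest))
}
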