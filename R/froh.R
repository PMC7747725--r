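#' Genomic inbreeding coefficient F_ROH
#'
#' Per sample, the summed length of autosomal ROH segments divided by the
#' autosomal genome size captured by the SNP set
#' (`genome$autosomal_captured_bp`; default 2,265,395,079 bp).  Segments on
#' excluded chromosomes are ignored.  Overlapping segments within one
#' sample violate the caller's contract and raise an error.
#'
#' @param segments a `roh_segments` data.frame.
#' @param genome a [genome_spec()].
#' @param sample_ids optional ids to report (samples without segments get
#'   F_ROH 0); defaults to the samples present in `segments`.
#' @return data.frame: `sample_id`, `sum_roh_bp`, `froh`.
#' @export
froh <- function(segments, genome, sample_ids = NULL) {
  seg <- segments[!(segments$chrom %in% genome$excluded_chroms), , drop = FALSE]
  for (key in split(seg, paste(seg$sample_id, seg$chrom))) {
    if (nrow(key) < 2) next
    o <- order(key$start_bp)
    assert_that(all(key$end_bp[o][-nrow(key)] < key$start_bp[o][-1]),
                "overlapping ROH segments for sample %s on chrom %s",
                key$sample_id[1], key$chrom[1])
  }
  if (is.null(sample_ids)) sample_ids <- unique(segments$sample_id)
  bp <- vapply(sample_ids, function(s) {
    d <- seg[seg$sample_id == s, , drop = FALSE]
    sum(as.numeric(d$end_bp - d$start_bp + 1))
  }, numeric(1))
  data.frame(sample_id = sample_ids, sum_roh_bp = unname(bp),
             froh = unname(bp / genome$autosomal_captured_bp),
             stringsAsFactors = FALSE)
}

#' Breed-level mean F_ROH
#'
#' Breed-specific inbreeding is the arithmetic mean of the individual
#' F_ROH values over the members of each breed.
#'
#' @param froh_table output of [froh()].
#' @param metadata sample metadata with `sample_id` and `breed`.
#' @return data.frame: `breed`, `n`, `mean_froh`.
#' @export
froh_breed_means <- function(froh_table, metadata) {
  breed <- metadata$breed[match(froh_table$sample_id, metadata$sample_id)]
  assert_that(!anyNA(breed), "sample(s) in froh table missing from metadata")
  agg <- split(froh_table$froh, breed)
  data.frame(breed = names(agg),
             n = vapply(agg, length, integer(1)),
             mean_froh = vapply(agg, mean, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
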