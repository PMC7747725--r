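#' Criteria for the breed-private candidate-variant funnel
#'
#' A carrier is an individual with one or two mutant (alternative) alleles,
#' i.e. genotype het or hom-alt.  The default criteria retain variants
#' carried by at least three case-breed animals and at least one
#' crossbreed but by no control ("exclusively in cases and crossbreeds"),
#' then restrict to HIGH or MODERATE predicted impact.  Missing genotypes
#' never count as carriers; by default a missing control genotype does not
#' disqualify a site (`control_missing_disqualifies = FALSE`).
#'
#' @param min_case_carriers minimum case carriers.
#' @param min_cross_carriers minimum crossbreed carriers.
#' @param max_control_carriers maximum control carriers.
#' @param impacts impact classes retained by the effect filter.
#' @param control_missing_disqualifies treat a missing control genotype as
#'   a potential carrier (drops the site).
#' @return a `funnel_criteria` list.
#' @export
funnel_criteria <- function(min_case_carriers = 3, min_cross_carriers = 1,
                            max_control_carriers = 0,
                            impacts = c("HIGH", "MODERATE"),
                            control_missing_disqualifies = FALSE) {
  assert_that(min_case_carriers >= 0 && min_cross_carriers >= 0 &&
                max_control_carriers >= 0, "carrier counts must be >= 0")
  assert_that(all(impacts %in% IMPACT_LEVELS), "invalid impact class")
  structure(list(min_case_carriers = min_case_carriers,
                 min_cross_carriers = min_cross_carriers,
                 max_control_carriers = max_control_carriers,
                 impacts = impacts,
                 control_missing_disqualifies = isTRUE(control_missing_disqualifies)),
            class = "funnel_criteria")
}

#' Per-site, per-group carrier counts
#'
#' For every site, counts carriers (genotype 1 or 2), non-carriers
#' (genotype 0) and missing genotypes within each sample group.
#'
#' @param x a [genotype_matrix()].
#' @return data.frame with one row per site: `chrom`, `pos`, `id` and, for
#'   each group g in case/crossbreed/control, `n_<g>_carriers`,
#'   `n_<g>_noncarriers`, `n_<g>_missing`.
#' @export
carrier_counts <- function(x) {
  out <- data.frame(chrom = x$sites$chrom, pos = x$sites$pos, id = x$sites$id,
                    stringsAsFactors = FALSE)
  for (g in GROUP_LEVELS) {
    rows <- group_rows(x, g)
    gm <- x$geno[rows, , drop = FALSE]
    tag <- if (g == "crossbreed") "cross" else g
    out[[sprintf("n_%s_carriers", tag)]] <- colSums(gm >= 1L, na.rm = TRUE)
    out[[sprintf("n_%s_noncarriers", tag)]] <- colSums(gm == 0L, na.rm = TRUE)
    out[[sprintf("n_%s_missing", tag)]] <- colSums(is.na(gm))
  }
  out
}

#' Breed-private candidate-variant funnel
#'
#' Applies the presence/absence filter (carriers in at least
#' `min_case_carriers` cases and `min_cross_carriers` crossbreeds, at most
#' `max_control_carriers` controls) and then the impact filter
#' (`impacts`, skipped for sites with class SV) in that order, reporting
#' the count surviving each stage.  The two filters commute; the staged
#' report mirrors the narrative order of the original screen.
#'
#' @param x a [genotype_matrix()] that already passed site QC.
#' @param criteria a [funnel_criteria()].
#' @return list with `survivors` (site table plus carrier counts),
#'   `report` (data.frame of funnel stages) and `index` (surviving site
#'   indices into `x$sites`).
#' @export
candidate_filter <- function(x, criteria = funnel_criteria()) {
  present <- GROUP_LEVELS %in% x$samples$group
  needed <- c(criteria$min_case_carriers > 0, criteria$min_cross_carriers > 0, FALSE)
  assert_that(all(present | !needed),
              "criteria require group(s) absent from metadata: %s",
              paste(GROUP_LEVELS[needed & !present], collapse = ", "))
  cc <- carrier_counts(x)
  pass_presence <- cc$n_case_carriers >= criteria$min_case_carriers &
    cc$n_cross_carriers >= criteria$min_cross_carriers &
    cc$n_control_carriers <= criteria$max_control_carriers
  if (criteria$control_missing_disqualifies)
    pass_presence <- pass_presence & cc$n_control_missing == 0
  pass_impact <- x$sites$impact %in% criteria$impacts
  keep <- pass_presence & pass_impact
  report <- data.frame(
    stage = c("input", "presence_filter", "impact_filter"),
    n_sites = c(n_sites(x), sum(pass_presence), sum(keep)),
    stringsAsFactors = FALSE)
  survivors <- cbind(x$sites[keep, , drop = FALSE],
                     cc[keep, grep("^n_", names(cc)), drop = FALSE])
  rownames(survivors) <- NULL
  list(survivors = survivors, report = report, index = which(keep))
}

#' Presence/absence screen for interval-typed variants
#'
#' The funnel's presence logic applied to records keyed by an interval
#' (structural variants): carriers in at least `min_case_carriers` cases
#' and `min_cross_carriers` crossbreeds, none in controls.  The impact
#' filter is skipped.  Optionally the screen is restricted to records whose
#' interval lies within `window_bp` of an anchor position (e.g. 40 Mb
#' around candidate SNPs).
#'
#' @param x a [genotype_matrix()] whose sites carry an `end` column (sites
#'   without `end` are treated as 1-bp intervals).
#' @param criteria a [funnel_criteria()] (impacts ignored).
#' @param anchors optional data.frame with `chrom`, `pos` anchor positions.
#' @param window_bp half-width of the window around each anchor (default
#'   4e7, i.e. 40 Mb).
#' @return as [candidate_filter()], with an extra `window_filter` stage
#'   when anchors are given.
#' @export
two_group_presence_screen <- function(x, criteria = funnel_criteria(),
                                      anchors = NULL, window_bp = 4e7) {
  cc <- carrier_counts(x)
  pass <- cc$n_case_carriers >= criteria$min_case_carriers &
    cc$n_cross_carriers >= criteria$min_cross_carriers &
    cc$n_control_carriers <= criteria$max_control_carriers
  if (criteria$control_missing_disqualifies)
    pass <- pass & cc$n_control_missing == 0
  report <- data.frame(stage = c("input", "presence_filter"),
                       n_sites = c(n_sites(x), sum(pass)),
                       stringsAsFactors = FALSE)
  if (!is.null(anchors)) {
    ends <- if (is.null(x$sites$end)) x$sites$pos else x$sites$end
    in_window <- rep(FALSE, n_sites(x))
    for (a in seq_len(nrow(anchors))) {
      in_window <- in_window |
        (x$sites$chrom == anchors$chrom[a] &
           ends >= anchors$pos[a] - window_bp &
           x$sites$pos <= anchors$pos[a] + window_bp)
    }
    pass <- pass & in_window
    report <- rbind(report, data.frame(stage = "window_filter",
                                       n_sites = sum(pass)))
  }
  survivors <- cbind(x$sites[pass, , drop = FALSE],
                     cc[pass, grep("^n_", names(cc)), drop = FALSE])
  rownames(survivors) <- NULL
  list(survivors = survivors, report = report, index = which(pass))
}
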