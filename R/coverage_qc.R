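# Per-region coverage QC. The per-region statistic is the arithmetic mean of
# per-base depth over every position in the region; positions absent from the
# depth table count as depth 0. Thresholds are strict ("greater than"):
# a mean of exactly 50 fails the 50x check.

#' Summarize sequencing depth over target regions for one sample
#'
#' @param regions region data.frame from [read_bed()].
#' @param depths depth table from [read_depth_table()].
#' @param sample sample id whose depth rows are used.
#' @param stat `"mean"` (default, the reporting statistic) or `"median"`.
#' @return data.frame with one row per region: name, chrom, start1, end1,
#'   length, mean_depth.
#' @export
summarize_depth <- function(regions, depths, sample, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  d <- depths[depths$sample == sample, , drop = FALSE]
  if (nrow(d) == 0L)
    abort_stage("coverage", "no depth records for sample '", sample,
                "' - sample-id mismatch?")
  dkey <- paste(d$chrom, d$pos)
  out <- regions[, c("name", "chrom", "start1", "end1")]
  out$length <- regions$end1 - regions$start1 + 1L
  out$mean_depth <- vapply(seq_len(nrow(regions)), function(i) {
    pos <- seq.int(regions$start1[i], regions$end1[i])
    hit <- match(paste(regions$chrom[i], pos), dkey)
    dep <- ifelse(is.na(hit), 0L, d$depth[hit])
    if (stat == "mean") mean(dep) else stats::median(dep)
  }, 0)
  out
}

#' Count and fraction of regions exceeding a depth threshold
#'
#' The comparison is strictly greater-than. Percentages are rounded half-up
#' to one decimal, matching the reporting convention of amplicon-panel QC.
#'
#' @param coverages output of [summarize_depth()].
#' @param threshold integer depth threshold.
#' @return list with `count`, `total`, `fraction`, `percent` (1-dp).
#' @export
pass_fraction <- function(coverages, threshold) {
  if (is.null(coverages) || nrow(coverages) == 0L)
    abort_stage("coverage", "empty coverage set")
  n <- sum(coverages$mean_depth > threshold)
  list(count = n, total = nrow(coverages), fraction = n / nrow(coverages),
       percent = round_half_up(100 * n / nrow(coverages), 1))
}

#' Coverage report across the standard thresholds
#'
#' @param coverages output of [summarize_depth()].
#' @param thresholds integer thresholds (default 50, 20, 10).
#' @return list with per-region flags (`regions`) and a `summary` data.frame
#'   of pass counts/percentages per threshold.
#' @export
coverage_report <- function(coverages, thresholds = c(50L, 20L, 10L)) {
  regions <- coverages
  for (t in thresholds)
    regions[[sprintf("pass_%d", t)]] <- coverages$mean_depth > t
  summary <- do.call(rbind, lapply(thresholds, function(t) {
    pf <- pass_fraction(coverages, t)
    data.frame(threshold = t, passing = pf$count, total = pf$total,
               percent = pf$percent)
  }))
  list(regions = regions, summary = summary)
}
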