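# Mendelian-consistency checks across pedigree configurations, panel pruning,
# and exclusion-power statistics. All loci are biallelic SNVs; NoCall never
# counts toward either consistency tally (it is reported separately).

#' Trio Mendelian consistency at one biallelic locus
#'
#' Consistent iff the child's two alleles can be partitioned so that one is
#' present in the sire's genotype and the other in the dam's.
#'
#' @param child,sire,dam integer allele pairs (NA = NoCall).
#' @return "consistent", "inconsistent" or "no_call".
#' @export
trio_consistent <- function(child, sire, dam) {
  if (any(is.na(c(child, sire, dam)))) return("no_call")
  ok <- (child[1L] %in% sire && child[2L] %in% dam) ||
    (child[2L] %in% sire && child[1L] %in% dam)
  if (ok) "consistent" else "inconsistent"
}

#' Single-parent (duo) Mendelian consistency at one biallelic locus
#'
#' Consistent iff the child and the alleged parent share at least one allele;
#' the only biallelic exclusion configuration is opposite homozygotes.
#'
#' @param child,parent integer allele pairs (NA = NoCall).
#' @return "consistent", "inconsistent" or "no_call".
#' @export
duo_consistent <- function(child, parent) {
  if (any(is.na(c(child, parent)))) return("no_call")
  if (any(child %in% parent)) "consistent" else "inconsistent"
}

#' Tally Mendelian consistency for one pedigree test over a panel
#'
#' Applies [trio_consistent()] when both parents are present, otherwise
#' [duo_consistent()]. consistent + inconsistent + no_call always equals the
#' panel size.
#'
#' @param gm a [genotype_matrix()] containing every tested sample.
#' @param child,sire,dam sample ids; exactly one of sire/dam may be NA.
#' @param kind label carried through to the result (e.g. "trio",
#'   "pseudo_trio", "duo"); the checker treats all kinds identically.
#' @param loci locus ids to test (default: all loci of `gm`).
#' @return an object of class `exclusion_result`.
#' @export
count_exclusions <- function(gm, child, sire = NA, dam = NA, kind = NA_character_,
                             loci = NULL) {
  for (sm in stats::na.omit(c(child, sire, dam)))
    if (!sm %in% gm$samples)
      abort_stage("parentage", "sample missing from genotype matrix: ", sm)
  loci <- loci %||% gm$loci$snv_id
  jx <- match(loci, gm$loci$snv_id)
  if (anyNA(jx)) abort_stage("parentage", "locus not in matrix: ",
                             loci[is.na(jx)][1L])
  ci <- match(child, gm$samples)
  si <- if (!is.na(sire)) match(sire, gm$samples) else NA
  di <- if (!is.na(dam)) match(dam, gm$samples) else NA
  if (is.na(si) && is.na(di))
    abort_stage("parentage", "at least one parent is required")
  verdict <- vapply(jx, function(j) {
    ch <- c(gm$a1[ci, j], gm$a2[ci, j])
    if (!is.na(si) && !is.na(di))
      trio_consistent(ch, c(gm$a1[si, j], gm$a2[si, j]),
                      c(gm$a1[di, j], gm$a2[di, j]))
    else {
      pi <- if (!is.na(si)) si else di
      duo_consistent(ch, c(gm$a1[pi, j], gm$a2[pi, j]))
    }
  }, "")
  structure(list(child = child, sire = sire, dam = dam, kind = kind,
                 consistent = sum(verdict == "consistent"),
                 inconsistent = sum(verdict == "inconsistent"),
                 no_call = sum(verdict == "no_call"),
                 inconsistent_loci = loci[verdict == "inconsistent"]),
            class = "exclusion_result")
}

#' @export
print.exclusion_result <- function(x, ...) {
  cat(sprintf("%s child=%s sire=%s dam=%s: %d consistent, %d inconsistent, %d no-call\n",
              x$kind %||% "test", x$child, x$sire, x$dam,
              x$consistent, x$inconsistent, x$no_call))
  invisible(x)
}

#' Drop panel loci that mis-inherit in any true trio
#'
#' Zero-tolerance pruning: a locus is removed when it appears among the
#' inconsistent loci of any supplied (true-trio) result. Order is preserved;
#' a locus inconsistent in several trios is removed once.
#'
#' @param panel panel data.frame.
#' @param trio_results list of `exclusion_result`s computed on true trios.
#' @return the retained panel data.frame.
#' @export
drop_misinheriting_loci <- function(panel, trio_results) {
  bad <- unique(unlist(lapply(trio_results, `[[`, "inconsistent_loci")))
  panel[!panel$snv_id %in% bad, , drop = FALSE]
}

check_freq_domain <- function(p) {
  if (any(is.na(p) | p < 0 | p > 1))
    abort_stage("parentage", "allele frequency outside [0,1]")
}

#' Expected heterozygosity of a biallelic locus
#'
#' He = 2p(1-p), maximal (0.5) at p = 0.5.
#'
#' @param p REF-allele frequency in `[0, 1]` (vectorized).
#' @return expected heterozygosity.
#' @export
heterozygosity <- function(p) {
  check_freq_domain(p)
  2 * p * (1 - p)
}

#' Trio (one-parent-known) exclusion probability of a biallelic locus
#'
#' PE1 = pq(1 - pq) with q = 1 - p: the probability that a random nonparent
#' is excluded when the other true parent's genotype is known. Maximum
#' 0.1875 at p = 0.5.
#'
#' @param p REF-allele frequency in `[0, 1]` (vectorized).
#' @return PE1.
#' @export
pe1 <- function(p) {
  check_freq_domain(p)
  pq <- p * (1 - p)
  pq * (1 - pq)
}

#' Single-parent (duo) exclusion probability of a biallelic locus
#'
#' PE2 = 2 p^2 q^2: the probability of the opposite-homozygote configuration
#' between a child and a random nonparent. Maximum 0.125 at p = 0.5.
#'
#' @param p REF-allele frequency in `[0, 1]` (vectorized).
#' @return PE2.
#' @export
pe2 <- function(p) {
  check_freq_domain(p)
  2 * (p * (1 - p))^2
}

#' Combine per-locus exclusion probabilities across a panel
#'
#' 1 - prod(1 - PE_i). Monotone nondecreasing in panel size and invariant to
#' locus order. Report-level truncation toward zero (conservative for an
#' exclusion-power claim) is applied by the caller, e.g. [panel_report()].
#'
#' @param pe numeric vector of per-locus exclusion probabilities in `[0, 1)`.
#' @return the combined exclusion probability.
#' @export
combined_pe <- function(pe) {
  if (length(pe) == 0L) return(0)
  if (any(is.na(pe) | pe < 0 | pe >= 1))
    abort_stage("parentage", "per-locus PE values must lie in [0,1)")
  1 - prod(1 - pe)
}

#' Per-locus and combined exclusion statistics for a panel
#'
#' Computes He, PE1 and PE2 per locus from the panel's REF frequencies (or
#' from frequencies re-estimated from a genotype matrix when one is given),
#' rounded half-up to 3 decimals in the table. The combined PE1 and PE2 are
#' attached truncated toward zero at 10 and 6 decimals respectively (the
#' conventional printed precisions), alongside the untruncated values.
#'
#' @param panel panel data.frame from [read_panel_table()].
#' @param gm optional [genotype_matrix()]; when supplied, frequencies are
#'   re-estimated with [estimate_allele_freq()].
#' @param digits rounding for the per-locus columns (default 3).
#' @return an object of class `panel_report`: the per-locus data.frame with
#'   attributes `combined_pe1`, `combined_pe2` (truncated) and
#'   `combined_raw`.
#' @export
panel_report <- function(panel, gm = NULL, digits = 3L) {
  p <- if (!is.null(gm))
    vapply(panel$snv_id, function(id) estimate_allele_freq(gm, id), 0)
  else panel$ref_freq
  check_freq_domain(p)
  out <- panel[, c("snv_id", "chrom", "pos", "ref", "alt")]
  out$ref_freq <- p
  out$He <- round_half_up(heterozygosity(p), digits)
  out$PE1 <- round_half_up(pe1(p), digits)
  out$PE2 <- round_half_up(pe2(p), digits)
  c1 <- combined_pe(pe1(p)); c2 <- combined_pe(pe2(p))
  structure(out,
            combined_pe1 = truncate_decimal(c1, 10L),
            combined_pe2 = truncate_decimal(c2, 6L),
            combined_raw = c(pe1 = c1, pe2 = c2),
            class = c("panel_report", "data.frame"))
}

#' @export
print.panel_report <- function(x, ...) {
  cat(sprintf("Parentage panel: %d SNVs\n", nrow(x)))
  cat(sprintf("  combined PE1 (trio, truncated 10 dp): %.10f\n",
              attr(x, "combined_pe1")))
  cat(sprintf("  combined PE2 (duo, truncated 6 dp):   %.6f\n",
              attr(x, "combined_pe2")))
  print.data.frame(utils::head(as.data.frame(x), 5L), row.names = FALSE)
  if (nrow(x) > 5L) cat(sprintf("  ... %d more loci\n", nrow(x) - 5L))
  invisible(x)
}

#' Mean inconsistent-locus count over a set of exclusion results
#'
#' @param results list of `exclusion_result`s, or a numeric vector of
#'   inconsistent counts.
#' @param digits report rounding (half-up, default 1 decimal).
#' @return the rounded mean.
#' @export
mean_exclusions <- function(results, digits = 1L) {
  counts <- if (is.numeric(results)) results else
    vapply(results, `[[`, 0L, "inconsistent")
  if (length(counts) == 0L) abort_stage("parentage", "no exclusion results")
  round_half_up(mean(counts), digits)
}

#' Write exclusion results as a TSV table
#'
#' One row per pedigree test with consistent / inconsistent / no-call tallies.
#'
#' @param results list of `exclusion_result`s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_exclusion_table <- function(results, path) {
  tb <- do.call(rbind, lapply(results, function(r)
    data.frame(kind = r$kind %||% NA_character_, child = r$child,
               sire = r$sire, dam = r$dam, consistent = r$consistent,
               inconsistent = r$inconsistent, no_call = r$no_call,
               stringsAsFactors = FALSE)))
  utils::write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
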