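# Three-step screen for artificial-edit candidates:
#   (1) keep INDEL calls whose zygosity is HomoALT or CompoundHet (ALT1/ALT2);
#       heterozygous REF/ALT INDELs and all SNVs are never candidates,
#   (2) exclude variants already present in the known population catalogue
#       (exact normalized-key match, allele identity only),
#   (3) exclude variants at low site depth (strict >, same standard as
#       genotyping).
# Statuses record the FIRST applicable exclusion; the stage-1 count always
# equals excluded_known + excluded_low_depth + final candidates.

#' Is an allele pair an INDEL?
#'
#' @param ref REF allele string.
#' @param alt ALT allele string.
#' @return TRUE iff the normalized REF and ALT lengths differ.
#' @export
is_indel <- function(ref, alt) {
  n <- normalize_allele_pair(1L, ref, alt)
  nchar(n$ref) != nchar(n$alt)
}

candidate_row <- function(sample, chrom, pos, ref, alts_used, zygosity,
                          depth, coding, note = "") {
  norm <- lapply(alts_used, function(a) normalize_allele_pair(pos, ref, a))
  keys <- vapply(norm, function(x) variant_key(chrom, x$pos, x$ref, x$alt), "")
  data.frame(sample = sample, chrom = chrom, pos = pos, ref = ref,
             alt = paste(alts_used, collapse = ","),
             key = paste(keys, collapse = ";"),
             zygosity = zygosity,
             variant_class = if (any(vapply(alts_used, function(a)
               is_indel(ref, a), TRUE))) "INDEL" else "SNV",
             depth = depth, coding = coding, note = note,
             status = "candidate", stringsAsFactors = FALSE)
}

site_depth_for <- function(depths, chrom, pos, sample, fallback = NA_integer_) {
  if (!is.null(depths)) {
    hit <- which(depths$chrom == chrom & depths$pos == pos &
                   depths$sample == sample)
    if (length(hit)) return(depths$depth[hit[1L]])
  }
  fallback
}

overlaps_region <- function(regions, chrom, start1, end1) {
  if (is.null(regions) || nrow(regions) == 0L) return(FALSE)
  any(regions$chrom == chrom & regions$start1 <= end1 & regions$end1 >= start1)
}

#' Stage 1: select HomoALT / compound-heterozygous INDEL calls
#'
#' Emits one candidate row per (sample, site) whose genotype is HomoALT or
#' CompoundHet and whose called ALT allele(s) change the allele length.
#' Additionally, pairs of overlapping heterozygous INDEL records in the same
#' sample are included conservatively with the note "possible-compound"
#' (an ALT1/ALT2 state split across records by the upstream caller).
#'
#' @param vs a [variant_set()] (records need not be pre-normalized; keys are
#'   normalized per allele here).
#' @param exons exon regions from [read_bed()] (sets the informational
#'   `coding` flag) or NULL.
#' @param depths depth table or NULL (fall back to the record's DP).
#' @return data.frame of stage-1 candidate rows.
#' @export
select_candidates <- function(vs, exons = NULL, depths = NULL) {
  rows <- list()
  for (r in vs$records) {
    span_end <- r$pos + nchar(r$ref) - 1L
    coding <- overlaps_region(exons, r$chrom, r$pos, span_end)
    for (sm in names(r$calls)) {
      cl <- r$calls[[sm]]
      zyg <- classify_zygosity(cl$gt)
      if (!zyg %in% c("HomoALT", "CompoundHet")) next
      alts_used <- r$alts[unique(cl$gt[cl$gt > 0L])]
      if (!any(vapply(alts_used, function(a) is_indel(r$ref, a), TRUE))) next
      dp <- site_depth_for(depths, r$chrom, r$pos, sm,
                           fallback = cl$dp %||% NA_integer_)
      rows[[length(rows) + 1L]] <-
        candidate_row(sm, r$chrom, r$pos, r$ref, alts_used, zyg, dp, coding)
    }
  }
  # conservative possible-compound: overlapping Het INDEL record pairs
  for (sm in vs$samples) {
    het <- Filter(function(r) {
      cl <- r$calls[[sm]]
      !is.null(cl) && classify_zygosity(cl$gt) == "Het" &&
        any(vapply(r$alts[unique(cl$gt[cl$gt > 0L])],
                   function(a) is_indel(r$ref, a), TRUE))
    }, vs$records)
    if (length(het) < 2L) next
    for (i in seq_len(length(het) - 1L)) for (k in seq(i + 1L, length(het))) {
      a <- het[[i]]; b <- het[[k]]
      if (a$chrom == b$chrom &&
          a$pos <= b$pos + nchar(b$ref) - 1L &&
          b$pos <= a$pos + nchar(a$ref) - 1L) {
        cl <- a$calls[[sm]]
        dp <- site_depth_for(depths, a$chrom, a$pos, sm,
                             fallback = cl$dp %||% NA_integer_)
        rows[[length(rows) + 1L]] <- candidate_row(
          sm, a$chrom, a$pos, a$ref, a$alts[unique(cl$gt[cl$gt > 0L])],
          "CompoundHet", dp, overlaps_region(exons, a$chrom, a$pos,
                                             a$pos + nchar(a$ref) - 1L),
          note = "possible-compound")
      }
    }
  }
  if (length(rows) == 0L)
    return(candidate_row("x", "x", 1L, "A", "AT", "HomoALT", 0L, FALSE)[0, ])
  do.call(rbind, rows)
}

#' Stage 2: exclude variants known in the population
#'
#' A candidate is excluded when every one of its called ALT allele keys is in
#' the known catalogue (allele identity only; zygosity is not compared).
#'
#' @param candidates stage-1 data.frame.
#' @param known known-variant data.frame from [read_known_variants()] (or a
#'   character vector of keys).
#' @return the candidates with `status` set to "excluded_known" where matched.
#' @export
filter_known <- function(candidates, known) {
  keys <- if (is.data.frame(known)) known$key else as.character(known)
  open <- candidates$status == "candidate"
  hit <- vapply(strsplit(candidates$key, ";", fixed = TRUE),
                function(k) all(k %in% keys), TRUE)
  candidates$status[open & hit] <- "excluded_known"
  candidates
}

#' Stage 3: exclude candidates at low site depth
#'
#' Depth must be strictly greater than the threshold to retain a candidate
#' (the same convention the genotyping stage uses). A candidate with no depth
#' information is treated as depth 0 and excluded, with a warning.
#'
#' @param candidates data.frame after [filter_known()].
#' @param threshold integer depth threshold (default 50).
#' @return the candidates with `status` set to "excluded_low_depth" where
#'   applicable.
#' @export
filter_low_depth <- function(candidates, threshold = 50L) {
  open <- candidates$status == "candidate"
  missing <- open & is.na(candidates$depth)
  if (any(missing)) {
    warning(sprintf("%d candidate(s) without depth records treated as depth 0 and excluded",
                    sum(missing)), call. = FALSE)
    candidates$depth[missing] <- 0L
  }
  candidates$status[open & candidates$depth <= threshold] <- "excluded_low_depth"
  candidates
}

annotate_blind_spots <- function(candidates, amplicons, margin = 25L,
                                 min_size = 50L) {
  if (is.null(amplicons) || nrow(candidates) == 0L) return(candidates)
  for (i in seq_len(nrow(candidates))) {
    del_len <- nchar(candidates$ref[i]) -
      min(nchar(strsplit(candidates$alt[i], ",", fixed = TRUE)[[1L]]))
    if (del_len <= min_size) next
    s <- candidates$pos[i]; e <- candidates$pos[i] + nchar(candidates$ref[i]) - 1L
    amp <- amplicons[amplicons$chrom == candidates$chrom[i] &
                       amplicons$start1 <= e & amplicons$end1 >= s, , drop = FALSE]
    near <- any(s - amp$start1 < margin | amp$end1 - e < margin)
    if (isTRUE(near))
      candidates$note[i] <- trimws(paste(candidates$note[i],
                                         "amplicon-end blind spot"))
  }
  candidates
}

#' Run the full three-step edit screen
#'
#' Applies the stages in order 1 -> 2 -> 3 over every sample of the variant
#' set and returns an auditable report. The `coding` flag is informational by
#' default; `coding_only = TRUE` restricts stage 1 to exon-overlapping calls.
#' Large deletions near an amplicon boundary are annotated as sitting in the
#' caller's soft-clip blind spot (a sensitivity caveat, not a filter).
#'
#' @param vs a [variant_set()].
#' @param exons exon regions ([read_bed()]) or NULL.
#' @param known known-variant catalogue ([read_known_variants()]) or NULL.
#' @param depths depth table ([read_depth_table()]) or NULL.
#' @param amplicons amplicon regions or NULL (enables blind-spot annotation).
#' @param min_candidate_depth stage-3 depth threshold (strict >, default 50).
#' @param coding_only restrict candidacy to coding (exon-overlapping) calls.
#' @param blind_spot_margin bp from an amplicon end within which a large
#'   deletion is annotated (default 25).
#' @return an object of class `screen_report`.
#' @export
screen_edits <- function(vs, exons = NULL, known = NULL, depths = NULL,
                         amplicons = NULL, min_candidate_depth = 50L,
                         coding_only = FALSE, blind_spot_margin = 25L) {
  totals <- do.call(rbind, lapply(vs$samples, function(sm) {
    n_var <- n_snv <- n_indel <- 0L
    for (r in vs$records) {
      cl <- r$calls[[sm]]
      if (is.null(cl) || classify_zygosity(cl$gt) %in% c("NoCall", "HomoREF")) next
      n_var <- n_var + 1L
      alts_used <- r$alts[unique(cl$gt[cl$gt > 0L])]
      if (any(vapply(alts_used, function(a) is_indel(r$ref, a), TRUE)))
        n_indel <- n_indel + 1L else n_snv <- n_snv + 1L
    }
    data.frame(sample = sm, variants = n_var, snvs = n_snv, indels = n_indel,
               stringsAsFactors = FALSE)
  }))
  cands <- select_candidates(vs, exons = exons, depths = depths)
  if (coding_only) cands <- cands[cands$coding, , drop = FALSE]
  cands <- filter_known(cands, known %||% character())
  cands <- filter_low_depth(cands, min_candidate_depth)
  cands <- annotate_blind_spots(cands, amplicons, blind_spot_margin)
  structure(list(
    totals = totals,
    stage1 = cands,
    counts = list(
      stage1 = nrow(cands),
      stage1_loci = length(unique(cands$key)),
      excluded_known = sum(cands$status == "excluded_known"),
      excluded_low_depth = sum(cands$status == "excluded_low_depth"),
      final = sum(cands$status == "candidate"),
      final_loci = length(unique(cands$key[cands$status == "candidate"]))),
    candidates = cands[cands$status == "candidate", , drop = FALSE],
    thresholds = list(min_candidate_depth = min_candidate_depth,
                      coding_only = coding_only,
                      blind_spot_margin = blind_spot_margin)),
    class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Edit screen report\n")
  cat(sprintf("  samples: %d; variant calls: %d (%d SNV, %d INDEL)\n",
              nrow(x$totals), sum(x$totals$variants), sum(x$totals$snvs),
              sum(x$totals$indels)))
  cat(sprintf("  stage 1 (HomoALT/ALT1-ALT2 INDELs): %d call(s) at %d locus/loci\n",
              x$counts$stage1, x$counts$stage1_loci))
  cat(sprintf("  stage 2 excluded (known in population): %d\n",
              x$counts$excluded_known))
  cat(sprintf("  stage 3 excluded (depth <= %d): %d\n",
              x$thresholds$min_candidate_depth, x$counts$excluded_low_depth))
  cat(sprintf("  final candidates: %d call(s) at %d locus/loci\n",
              x$counts$final, x$counts$final_loci))
  if (nrow(x$candidates) > 0L)
    print(x$candidates[, c("sample", "chrom", "pos", "ref", "alt",
                           "zygosity", "depth", "note")], row.names = FALSE)
  invisible(x)
}

#' Write a screen report as TSV + JSON audit
#'
#' @param report a `screen_report`.
#' @param tsv_path path for the per-candidate table.
#' @param json_path path for the JSON audit (counts + thresholds), or NULL.
#' @return `tsv_path`, invisibly.
#' @export
write_screen_report <- function(report, tsv_path, json_path = NULL) {
  utils::write.table(report$stage1, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(counts = report$counts,
                              thresholds = report$thresholds,
                              totals = report$totals),
                         json_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(tsv_path)
}
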