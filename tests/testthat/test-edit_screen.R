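mk_vs <- function(...) {
  recs <- list(...)
  samples <- unique(unlist(lapply(recs, function(r) names(r$calls))))
  variant_set(recs, samples)
}

hom <- function(alt_idx = 1L, dp = 200L, k = 1L)
  list(gt = c(alt_idx, alt_idx), ad = NULL, dp = dp)
het <- function(dp = 200L) list(gt = c(0L, 1L), ad = NULL, dp = dp)

test_that("INDEL detection is based on normalized length change", {
  expect_true(is_indel("C", "CT"))
  expect_false(is_indel("C", "T"))
  expect_true(is_indel(paste(rep("A", 78), collapse = ""), "A"))
  # length-preserving MNP normalizes to an SNV
  expect_false(is_indel("TGG", "TAG"))
})

test_that("stage 1 keeps exactly the HomoALT / compound-het INDEL calls", {
  vs <- mk_vs(
    variant_record("chr18", 66607750L, "C", "CT", calls = list(cell2 = hom())),
    variant_record("chr18", 66605476L, paste(rep("A", 78), collapse = ""), "A",
                   calls = list(cell1 = het())),          # Het large deletion
    variant_record("chr1", 500L, "A", "G", calls = list(h1 = hom())),  # HomoALT SNV
    variant_record("chr1", 900L, "A", c("AT", "ATT"),
                   calls = list(h2 = list(gt = c(1L, 2L), ad = NULL, dp = 150L))))
  cands <- select_candidates(vs)
  expect_equal(nrow(cands), 2L)
  expect_setequal(cands$zygosity, c("HomoALT", "CompoundHet"))
  expect_false(any(cands$pos == 66605476L))   # Het never selected
  expect_false(any(cands$variant_class == "SNV"))
})

test_that("no SNV and no heterozygous INDEL ever reaches any screen stage", {
  set.seed(53)
  for (rep in 1:4) {
    recs <- random_records(25L, c("a", "b"), seed = 530L + rep)
    vs <- variant_set(recs, c("a", "b"))
    report <- suppressWarnings(screen_edits(vs))
    if (nrow(report$stage1) == 0L) next
    expect_true(all(report$stage1$variant_class == "INDEL"))
    expect_true(all(report$stage1$zygosity %in% c("HomoALT", "CompoundHet")))
  }
})

test_that("known-population filtering excludes by exact normalized key", {
  # 11 stage-1 INDELs of which 4 HomoALT + 1 compound het are known
  recs <- lapply(1:10, function(i)
    variant_record("chr1", 1000L + 10L * i, "A", "AT",
                   calls = stats::setNames(list(hom()), sprintf("s%d", i))))
  recs[[11L]] <- variant_record("chr1", 2000L, "G", c("GA", "GAA"),
                                calls = list(s11 = list(gt = c(1L, 2L),
                                                        ad = NULL, dp = 150L)))
  vs <- variant_set(recs, sprintf("s%d", 1:11))
  known <- c(variant_key("chr1", 1000L + 10L * (1:4), "A", "AT"),
             variant_key("chr1", 2000L, "G", "GA"),
             variant_key("chr1", 2000L, "G", "GAA"))
  cands <- filter_known(select_candidates(vs), known)
  expect_equal(sum(cands$status == "excluded_known"), 5L)
  expect_equal(sum(cands$status == "candidate"), 6L)
  # empty catalogue excludes nothing
  expect_equal(sum(filter_known(select_candidates(vs),
                                character())$status == "excluded_known"), 0L)
})

test_that("a known key shared by two samples excludes both calls", {
  vs <- mk_vs(variant_record("chr1", 100L, "A", "AT",
                             calls = list(s1 = hom(), s2 = hom())))
  cands <- filter_known(select_candidates(vs), variant_key("chr1", 100L, "A", "AT"))
  expect_equal(nrow(cands), 2L)
  expect_true(all(cands$status == "excluded_known"))
})

test_that("low-depth filtering is strict and treats missing depth as zero", {
  vs <- mk_vs(
    variant_record("chr1", 100L, "A", "AT", calls = list(s1 = hom(dp = 12L))),
    variant_record("chr1", 200L, "A", "AT", calls = list(s1 = hom(dp = 51L))),
    variant_record("chr1", 300L, "A", "AT",
                   calls = list(s1 = list(gt = c(1L, 1L), ad = NULL,
                                          dp = NA_integer_))))
  cands <- select_candidates(vs)
  expect_warning(out <- filter_low_depth(cands, 50L), "depth 0")
  expect_equal(out$status[out$pos == 100L], "excluded_low_depth")
  expect_equal(out$status[out$pos == 200L], "candidate")
  expect_equal(out$status[out$pos == 300L], "excluded_low_depth")
  # boundary: exactly the threshold is excluded
  vs50 <- mk_vs(variant_record("chr1", 100L, "A", "AT",
                               calls = list(s1 = hom(dp = 50L))))
  expect_equal(filter_low_depth(select_candidates(vs50), 50L)$status,
               "excluded_low_depth")
})

test_that("the first applicable exclusion wins for known low-depth variants", {
  vs <- mk_vs(variant_record("chr1", 100L, "A", "AT",
                             calls = list(s1 = hom(dp = 10L))))
  rep <- screen_edits(vs, known = variant_key("chr1", 100L, "A", "AT"))
  expect_equal(rep$stage1$status, "excluded_known")
})

test_that("screen counts are conserved, idempotent and monotone", {
  set.seed(67)
  recs <- random_records(40L, c("a", "b", "c"), seed = 670L)
  vs <- variant_set(recs, c("a", "b", "c"))
  all_keys <- unlist(lapply(recs, function(r)
    vapply(r$alts, function(al)
      tryCatch({
        n <- normalize_allele_pair(r$pos, r$ref, al)
        variant_key(r$chrom, n$pos, n$ref, n$alt)
      }, error = function(e) NA_character_), "")))
  all_keys <- stats::na.omit(all_keys)
  known_small <- sample(all_keys, 5L)
  known_big <- unique(c(known_small, sample(all_keys, 15L)))
  r1 <- suppressWarnings(screen_edits(vs, known = known_small,
                                      min_candidate_depth = 50L))
  # conservation, in aggregate and per sample
  expect_equal(r1$counts$stage1,
               r1$counts$excluded_known + r1$counts$excluded_low_depth +
                 r1$counts$final)
  for (sm in unique(r1$stage1$sample)) {
    sub <- r1$stage1[r1$stage1$sample == sm, ]
    expect_equal(nrow(sub), sum(table(sub$status)))
  }
  # idempotence: re-screening the surviving candidate records changes nothing
  surv_pos <- unique(r1$candidates$pos)
  vs2 <- variant_set(Filter(function(r) r$pos %in% surv_pos, vs$records),
                     vs$samples)
  r2 <- suppressWarnings(screen_edits(vs2, known = known_small,
                                      min_candidate_depth = 50L))
  expect_setequal(r2$candidates$key, r1$candidates$key)
  # monotonicity: larger catalogue, higher threshold never add candidates
  r3 <- suppressWarnings(screen_edits(vs, known = known_big,
                                      min_candidate_depth = 50L))
  expect_lte(r3$counts$final, r1$counts$final)
  r4 <- suppressWarnings(screen_edits(vs, known = known_small,
                                      min_candidate_depth = 150L))
  expect_lte(r4$counts$final, r1$counts$final)
})

test_that("large deletions near amplicon ends are annotated as blind spots", {
  amp <- data.frame(chrom = "chr18", start1 = 66605340L, end1 = 66605575L,
                    name = "amp3", kind = "amplicon", stringsAsFactors = FALSE)
  del_ref <- paste(rep("A", 78), collapse = "")
  vs <- mk_vs(variant_record("chr18", 66605476L, del_ref, "A",
                             calls = list(s1 = hom(dp = 200L))))
  rep <- screen_edits(vs, amplicons = amp)
  expect_match(rep$stage1$note, "amplicon-end blind spot")
  # a mid-amplicon 1-bp insertion is not annotated
  vs2 <- mk_vs(variant_record("chr18", 66605450L, "A", "AT",
                              calls = list(s1 = hom(dp = 200L))))
  expect_equal(screen_edits(vs2, amplicons = amp)$stage1$note, "")
})

test_that("coding flags come from exon overlap and can gate candidacy", {
  ex <- data.frame(chrom = "chr1", start1 = 90L, end1 = 110L, name = "ex",
                   kind = "exon", stringsAsFactors = FALSE)
  vs <- mk_vs(
    variant_record("chr1", 100L, "A", "AT", calls = list(s1 = hom())),
    variant_record("chr1", 500L, "A", "AT", calls = list(s1 = hom())))
  rep <- screen_edits(vs, exons = ex)
  expect_equal(rep$stage1$coding[order(rep$stage1$pos)], c(TRUE, FALSE))
  expect_equal(rep$counts$final, 2L)     # informational by default
  rep2 <- screen_edits(vs, exons = ex, coding_only = TRUE)
  expect_equal(rep2$counts$final, 1L)
})

test_that("a sample with zero INDELs yields an empty report", {
  vs <- mk_vs(variant_record("chr1", 100L, "A", "G", calls = list(s1 = het())))
  rep <- screen_edits(vs)
  expect_equal(rep$counts$stage1, 0L)
  expect_equal(rep$counts$final, 0L)
  expect_equal(nrow(rep$candidates), 0L)
})

test_that("overlapping heterozygous INDELs are flagged possible-compound", {
  vs <- mk_vs(
    variant_record("chr1", 100L, "ATG", "A", calls = list(s1 = het())),
    variant_record("chr1", 101L, "T", "TC", calls = list(s1 = het())))
  cands <- select_candidates(vs)
  expect_true(any(grepl("possible-compound", cands$note)))
  expect_true(all(cands$zygosity[grepl("possible-compound", cands$note)] ==
                    "CompoundHet"))
})
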