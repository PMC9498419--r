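test_that("HWE simulation is deterministic and hits degenerate frequencies", {
  panel <- data.frame(snv_id = c("L1", "L2"), chrom = "1", pos = 1:2,
                      ref = "A", alt = "G", ref_freq = c(1, 0),
                      stringsAsFactors = FALSE)
  gm <- simulate_genotypes_hwe(panel, 50L, seed = 1L)
  expect_true(all(gm$a1[, 1L] == 0L & gm$a2[, 1L] == 0L))
  expect_true(all(gm$a1[, 2L] == 1L & gm$a2[, 2L] == 1L))
  gm2 <- simulate_genotypes_hwe(panel, 50L, seed = 1L)
  expect_identical(gm$a1, gm2$a1)
  expect_identical(gm$a2, gm2$a2)
})

test_that("offspring draw one allele from each parent per locus", {
  L <- 10000L
  loci <- data.frame(snv_id = sprintf("L%d", 1:L), chrom = "1", pos = 1:L,
                     ref = "A", alt = "G", ref_freq = 0.5,
                     stringsAsFactors = FALSE)
  # opposite homozygotes: child always Het
  gm <- gm_from(c("p1", "p2"), loci,
                rbind(rep(0L, L), rep(1L, L)), rbind(rep(0L, L), rep(1L, L)))
  gm <- simulate_offspring(gm, "p1", "p2", "kid", seed = 5L)
  ki <- match("kid", gm$samples)
  expect_true(all(sort(c(gm$a1[ki, 1L], gm$a2[ki, 1L])) == c(0L, 1L)))
  expect_true(all(gm$a1[ki, ] + gm$a2[ki, ] == 1L))

  # Het x Het segregates 1:2:1 (10,000 loci as independent draws, 3 se)
  gm2 <- gm_from(c("p1", "p2"), loci,
                 rbind(rep(0L, L), rep(0L, L)), rbind(rep(1L, L), rep(1L, L)))
  gm2 <- simulate_offspring(gm2, "p1", "p2", "kid", seed = 6L)
  ki <- match("kid", gm2$samples)
  counts <- tabulate(gm2$a1[ki, ] + gm2$a2[ki, ] + 1L, nbins = 3L)
  se <- sqrt(L * 0.25 * 0.75)
  expect_lt(abs(counts[1L] - L / 4), 3 * se)
  expect_lt(abs(counts[2L] - L / 2), 3 * sqrt(L * 0.5 * 0.5))
  expect_lt(abs(counts[3L] - L / 4), 3 * se)

  # NoCall parents propagate
  gm3 <- gm_from(c("p1", "p2"), loci[1:2, ],
                 matrix(c(NA_integer_, 0L, 0L, 0L), 2L),
                 matrix(c(NA_integer_, 0L, 0L, 0L), 2L))
  gm3 <- simulate_offspring(gm3, "p1", "p2", "kid")
  expect_true(is.na(gm3$a1[3L, 1L]))
  expect_false(is.na(gm3$a1[3L, 2L]))
})

test_that("simulated true pedigrees are Mendelian-consistent everywhere", {
  suite <- simulate_pedigree_suite(packaged_panel(), n_trios = 6L,
                                   n_pseudo_trios = 2L,
                                   n_half_pseudo_trios = 2L, n_duos = 2L,
                                   n_pseudo_duos = 2L, seed = 99L)
  true_tests <- suite$tests[suite$tests$kind %in% c("trio", "duo"), ]
  for (i in seq_len(nrow(true_tests))) {
    t <- true_tests[i, ]
    r <- count_exclusions(suite$gm, t$child,
                          sire = ifelse(is.na(t$sire), NA, t$sire),
                          dam = ifelse(is.na(t$dam), NA, t$dam), kind = t$kind)
    expect_equal(r$inconsistent, 0L)
  }
  expect_setequal(unique(suite$tests$kind),
                  c("trio", "pseudo_trio", "half_pseudo_trio", "duo",
                    "pseudo_duo"))
})

test_that("edit injection matches zygosity and is idempotent", {
  amp <- data.frame(chrom = "chr18", start1 = 66607680L, end1 = 66607830L,
                    name = "amp", kind = "amplicon", stringsAsFactors = FALSE)
  vs <- variant_set(list(), c("cell2", "other"))
  e <- table3_edits()$edit_ins2
  vs <- inject_edit(vs, e, "cell2", depth = 212L, amplicons = amp)
  expect_length(vs$records, 1L)
  r <- vs$records[[1L]]
  expect_equal(r$pos, 66607750L)
  expect_equal(r$ref, "C"); expect_equal(r$alts, "CT")
  expect_equal(r$calls$cell2$gt, c(1L, 1L))
  expect_equal(r$calls$cell2$ad, c(0L, 212L))
  # idempotent: same single record after re-application
  vs2 <- inject_edit(vs, e, "cell2", depth = 212L, amplicons = amp)
  expect_equal(length(vs2$records), 1L)
  expect_equal(record_essence(vs2$records[[1L]]), record_essence(r))
  # heterozygous edit splits allele depths
  het <- table3_edits()$edit_77del
  vs3 <- inject_edit(variant_set(list(), "cell1"), het, "cell1", depth = 200L)
  expect_equal(vs3$records[[1L]]$calls$cell1$gt, c(0L, 1L))
  expect_equal(sum(vs3$records[[1L]]$calls$cell1$ad), 200L)
  expect_equal(nchar(vs3$records[[1L]]$ref), 78L)
  # outside every amplicon: undetectable by design
  far <- edit_spec("chr2", 500L, "A", "AT", "HomoALT")
  expect_error(inject_edit(vs, far, "cell2", amplicons = amp), "outside")
})

test_that("amplicon-end dropout removes exactly the blind-spot INDELs", {
  amp <- data.frame(chrom = "chr18",
                    start1 = c(66605340L, 66607680L),
                    end1 = c(66605575L, 66607830L),
                    name = c("amp3", "amp2"), kind = "amplicon",
                    stringsAsFactors = FALSE)
  vs <- variant_set(list(), c("cell1", "cell2"))
  vs <- inject_edit(vs, table3_edits()$edit_77del, "cell1", depth = 200L)
  vs <- inject_edit(vs, table3_edits()$edit_ins2, "cell2", depth = 200L)
  # deletion end sits 22 bp from the amplicon end -> dropped at margin 25
  out <- apply_amplicon_end_dropout(vs, amp, margin = 25L, min_size = 50L)
  expect_length(out$vs$records, 1L)
  expect_equal(out$vs$records[[1L]]$pos, 66607750L)
  expect_equal(out$dropped$pos, 66605476L)
  # margin 0 removes nothing
  out0 <- apply_amplicon_end_dropout(vs, amp, margin = 0L)
  expect_length(out0$vs$records, 2L)
})

test_that("depth simulation respects strata, determinism and sd = 0", {
  amp <- data.frame(chrom = "chr1", start1 = seq(1L, 40L * 50L, by = 50L),
                    end1 = seq(1L, 40L * 50L, by = 50L) + 19L,
                    name = sprintf("amp%02d", 1:40), kind = "amplicon",
                    stringsAsFactors = FALSE)
  model <- depth_model(mean_depth = 500, sd_log = 0, low_fraction = 0.1,
                       low_mean = 5)
  d <- simulate_depths(amp, model, "s1", seed = 13L)
  expect_length(attr(d, "low_regions"), 4L)
  cov <- summarize_depth(amp, d, "s1")
  # planted fraction recovered exactly with separated strata
  expect_equal(pass_fraction(cov, 50L)$count, 36L)
  expect_equal(pass_fraction(cov, 50L)$percent, 90.0)
  # sd = 0 puts every ordinary amplicon exactly at the mean
  expect_setequal(unique(cov$mean_depth), c(500, 5))
  d2 <- simulate_depths(amp, model, "s1", seed = 13L)
  expect_identical(d, d2)
})

test_that("genotyping faults create prunable mis-inheritances (144 -> 120)", {
  panel <- packaged_panel()
  extra <- panel[1:24, ]
  extra$snv_id <- sprintf("EXTRA%02d", 1:24)
  extra$pos <- extra$pos + 7L
  panel144 <- rbind(panel, extra)
  suite <- simulate_pedigree_suite(panel144, n_trios = 29L,
                                   n_pseudo_trios = 0L,
                                   n_half_pseudo_trios = 0L, n_duos = 0L,
                                   n_pseudo_duos = 0L, seed = 17L)
  trios <- suite$tests[suite$tests$kind == "trio", ]
  faults <- data.frame(snv_id = extra$snv_id,
                       type = rep(c("allele_bias", "low_depth"), 12L),
                       stringsAsFactors = FALSE)
  gmf <- simulate_genotyping_faults(suite$gm, faults, trios = trios,
                                    seed = 18L)
  trio_res <- lapply(seq_len(nrow(trios)), function(i)
    count_exclusions(gmf, trios$child[i], trios$sire[i], trios$dam[i],
                     kind = "trio"))
  kept <- drop_misinheriting_loci(panel144, trio_res)
  expect_equal(nrow(kept), 120L)
  expect_setequal(kept$snv_id, panel$snv_id)
  # faults leave an audit trail in the flags
  expect_true(any(gmf$flags == "allele-bias-fault"))
  expect_true(any(gmf$flags == "low-depth-fault"))
  # empty fault design is the identity
  gmu <- simulate_genotyping_faults(suite$gm, faults[0, ], trios = trios)
  expect_identical(gmu$a1, suite$gm$a1)
})

test_that("an allele-bias flip turns a hand-checked trio inconsistent", {
  loci <- data.frame(snv_id = "L1", chrom = "1", pos = 1L, ref = "A",
                     alt = "G", ref_freq = 0.5, stringsAsFactors = FALSE)
  # sire A/B, dam A/B, child B/B: consistent; biasing the sire to A/A
  # removes his B and the trio becomes inconsistent
  gm <- gm_from(c("sire", "dam", "kid"), loci,
                matrix(c(0L, 0L, 1L), 3L), matrix(c(1L, 1L, 1L), 3L))
  trios <- data.frame(child = "kid", sire = "sire", dam = "dam",
                      stringsAsFactors = FALSE)
  expect_equal(trio_consistent(c(1L, 1L), c(0L, 1L), c(0L, 1L)), "consistent")
  gmf <- simulate_genotyping_faults(
    gm, data.frame(snv_id = "L1", type = "allele_bias"), trios = trios,
    seed = 3L)
  r <- count_exclusions(gmf, "kid", "sire", "dam", kind = "trio")
  expect_equal(r$inconsistent, 1L)
})

test_that("emitted datasets are byte-identical under a fixed seed", {
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  unlink(c(d1, d2), recursive = TRUE)
  emit_dataset(preset_config("casework-2022", seed = 8L), d1)
  emit_dataset(preset_config("casework-2022", seed = 8L), d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_equal(f1, f2)
  for (f in f1)
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), info = f)
})

test_that("planted truth is recovered from an emitted dataset", {
  dir <- file.path(tempdir(), "truth-val")
  if (!dir.exists(dir)) emit_dataset(preset_config("validation-2022"), dir)
  ds <- load_dataset(dir)
  rep <- screen_edits(ds$vs, exons = ds$exons, known = ds$known,
                      depths = ds$depths, amplicons = ds$amplicons)
  tr <- ds$truth
  # planted edits are recovered iff HomoALT INDELs that survived dropout
  surviving <- tr$edits[tr$edits$in_vcf & tr$edits$zygosity == "HomoALT", ]
  for (i in seq_len(nrow(surviving)))
    expect_true(any(rep$candidates$pos == surviving$pos[i] &
                      rep$candidates$sample == surviving$sample[i]))
  dropped <- tr$edits[!tr$edits$in_vcf, ]
  expect_equal(dropped$reason, "amplicon_end_dropout")
  expect_false(any(rep$stage1$pos %in% dropped$pos))
  # stage tallies match the design
  expect_equal(rep$counts$stage1, tr$expected$stage1)
  expect_equal(rep$counts$excluded_known, tr$expected$excluded_known)
  expect_equal(rep$counts$excluded_low_depth, tr$expected$excluded_low_depth)
  expect_equal(rep$counts$final, tr$expected$final)
})
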