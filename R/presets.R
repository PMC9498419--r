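# Dataset emission and the two packaged study presets.
#
# "validation-2022" mirrors the structure of the method-validation screen:
# horse samples plus four edited cell lines carrying the packaged myostatin
# edits; the known-population catalogue contains four HomoALT and one
# compound-heterozygous INDEL that are also present in the samples; three
# further HomoALT INDELs sit at low-depth sites. The heterozygous 77-bp
# deletion is removed by the amplicon-end dropout, as the upstream caller
# would. Screening therefore yields exactly three final candidates (the
# 1-bp homozygous insertions).
#
# "casework-2022" mirrors a clean casework batch: seven stage-1 loci, six
# already known in the population and one at low depth - zero candidates.

region_df <- function(chrom, start1, end1, name, kind) {
  data.frame(chrom = chrom, start1 = as.integer(start1),
             end1 = as.integer(end1), name = name, kind = kind,
             stringsAsFactors = FALSE)
}

#' Write regions to a BED file (0-based half-open)
#'
#' @param regions region data.frame with 1-based `start1`/`end1`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  utils::write.table(
    data.frame(regions$chrom, regions$start1 - 1L, regions$end1, regions$name),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge per-sample variant sets into one multi-sample set
#'
#' Records are matched on (chrom, pos, ref, alts); per-sample calls are
#' combined. Alleles must agree across files at a shared site.
#'
#' @param sets list of [variant_set()] objects.
#' @return a merged [variant_set()].
#' @export
merge_variant_sets <- function(sets) {
  samples <- unique(unlist(lapply(sets, `[[`, "samples")))
  by_key <- list()
  for (vs in sets) for (r in vs$records) {
    key <- paste(r$chrom, r$pos, r$ref, paste(r$alts, collapse = ","))
    if (is.null(by_key[[key]])) by_key[[key]] <- r
    else by_key[[key]]$calls <- c(by_key[[key]]$calls, r$calls)
  }
  recs <- unname(by_key)
  ord <- order(vapply(recs, `[[`, "", "chrom"), vapply(recs, `[[`, 1L, "pos"))
  variant_set(recs[ord], samples)
}

screen_regions <- function() {
  exons <- rbind(
    region_df("chr18", 66609900, 66610000, "MSTN_ex1", "exon"),
    region_df("chr18", 66607700, 66607800, "MSTN_ex2", "exon"),
    region_df("chr18", 66605460, 66605560, "MSTN_ex3", "exon"),
    region_df("chr1",  5001000, 5001100, "GENE_A_ex1", "exon"),
    region_df("chr5",  12000500, 12000600, "GENE_B_ex1", "exon"),
    region_df("chr11", 800200, 800300, "GENE_C_ex1", "exon"),
    region_df("chr16", 3400100, 3400200, "GENE_D_ex1", "exon"))
  amplicons <- rbind(
    region_df("chr18", 66609880, 66610020, "MSTN_amp1", "amplicon"),
    region_df("chr18", 66607680, 66607830, "MSTN_amp2", "amplicon"),
    region_df("chr18", 66605340, 66605575, "MSTN_amp3", "amplicon"),
    region_df("chr1",  5000980, 5001120, "GENE_A_amp1", "amplicon"),
    region_df("chr5",  12000480, 12000620, "GENE_B_amp1", "amplicon"),
    region_df("chr11", 800180, 800320, "GENE_C_amp1", "amplicon"),
    region_df("chr16", 3400080, 3400220, "GENE_D_amp1", "amplicon"))
  list(exons = exons, amplicons = amplicons)
}

planted_row <- function(chrom, pos, ref, alt, sample, zygosity, known,
                        depth_override = NA_integer_, alt2 = NA_character_) {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             alt2 = alt2, sample = sample, zygosity = zygosity, known = known,
             depth_override = as.integer(depth_override),
             stringsAsFactors = FALSE)
}

#' Configuration for a packaged synthetic preset
#'
#' @param name "validation-2022" or "casework-2022".
#' @param seed RNG seed controlling every random draw of the dataset.
#' @return a `sim_config` list understood by [emit_dataset()].
#' @export
preset_config <- function(name = c("validation-2022", "casework-2022"),
                          seed = 20220904L) {
  name <- match.arg(name)
  rg <- screen_regions()
  panel <- read_panel_table(packaged_panel_path())[, 1:6]
  panel$chrom <- paste0("chr", panel$chrom)
  if (name == "validation-2022") {
    horses <- sprintf("H%02d", 1:12)
    cells <- sprintf("cell%d", 1:4)
    planted <- rbind(
      planted_row("chr1", 5001010, "A", "AT", "H01", "HomoALT", TRUE),
      planted_row("chr5", 12000510, "G", "GA", "H02", "HomoALT", TRUE),
      planted_row("chr11", 800210, "C", "CT", "H03", "HomoALT", TRUE),
      planted_row("chr16", 3400110, "TG", "T", "H04", "HomoALT", TRUE),
      planted_row("chr1", 5001050, "A", "AT", "H05", "CompoundHet", TRUE,
                  alt2 = "ATT"),
      planted_row("chr5", 12000550, "C", "CA", "H06", "HomoALT", FALSE, 12L),
      planted_row("chr11", 800250, "G", "GT", "H07", "HomoALT", FALSE, 30L),
      planted_row("chr16", 3400150, "A", "AC", "H08", "HomoALT", FALSE, 45L))
    edits <- table3_edits("chr")
    edit_samples <- c(edit_77del = "cell1", edit_ins2 = "cell2",
                      edit_ins3 = "cell3", edit_ins4 = "cell4")
    pedigree <- data.frame(child = c("H03", "H06"),
                           sire = c("H01", "H04"),
                           dam = c("H02", "H05"), stringsAsFactors = FALSE)
    samples <- c(horses, cells)
    expected <- list(stage1 = 11L, excluded_known = 5L,
                     excluded_low_depth = 3L, final = 3L)
  } else {
    samples <- sprintf("C%02d", 1:12)
    planted <- rbind(
      planted_row("chr1", 5001015, "T", "TA", "C01", "HomoALT", TRUE),
      planted_row("chr5", 12000520, "A", "AG", "C02", "HomoALT", TRUE),
      planted_row("chr11", 800220, "GA", "G", "C03", "HomoALT", TRUE),
      planted_row("chr16", 3400120, "C", "CT", "C04", "HomoALT", TRUE),
      planted_row("chr18", 66607710, "A", "AC", "C05", "HomoALT", TRUE),
      planted_row("chr1", 5001060, "G", "GT", "C06", "CompoundHet", TRUE,
                  alt2 = "GTT"),
      planted_row("chr5", 12000560, "T", "TC", "C07", "HomoALT", FALSE, 25L))
    edits <- list(); edit_samples <- character()
    pedigree <- NULL
    expected <- list(stage1 = 7L, excluded_known = 6L,
                     excluded_low_depth = 1L, final = 0L)
  }
  structure(list(
    name = name, seed = as.integer(seed), samples = samples,
    exons = rg$exons, amplicons = rg$amplicons, panel = panel,
    pedigree = pedigree, planted = planted,
    edits = edits, edit_samples = edit_samples,
    noise = list(n_snv_loci = 30L, n_het_indel_loci = 6L),
    depth_model = depth_model(mean_depth = 500, sd_log = 0.3),
    dropout = list(margin = 25L, min_size = 50L),
    extra_known = 10L,
    expected = expected), class = "sim_config")
}

# random noise loci inside exons, avoiding reserved positions
make_noise_loci <- function(config, reserved) {
  ex <- config$exons
  pool <- do.call(rbind, lapply(seq_len(nrow(ex)), function(i)
    data.frame(chrom = ex$chrom[i], pos = seq.int(ex$start1[i], ex$end1[i]),
               stringsAsFactors = FALSE)))
  pool <- pool[!paste(pool$chrom, pool$pos) %in% reserved, ]
  n <- config$noise$n_snv_loci + config$noise$n_het_indel_loci
  pick <- pool[sample(nrow(pool), n), ]
  bases <- c("A", "C", "G", "T")
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ref <- substr(synthetic_sequence(pick$pos[i], 1L), 1L, 1L)
    snv <- i <= config$noise$n_snv_loci
    alt <- if (snv) sample(setdiff(bases, ref), 1L) else
      paste0(ref, sample(bases, 1L))
    out[[i]] <- data.frame(chrom = pick$chrom[i], pos = pick$pos[i],
                           ref = ref, alt = alt,
                           class = if (snv) "SNV" else "HetINDEL",
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Emit a complete synthetic dataset to a directory
#'
#' Writes one VCF per sample, a depth table, exon and amplicon BED files, a
#' panel TSV, a known-variants TSV, a pedigree TSV (when the design has one)
#' and a truth JSON recording the planted edits, catalogue and expectations.
#' Byte-identical under a fixed config seed.
#'
#' @param config a `sim_config` from [preset_config()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly; side effect: files written.
#' @export
emit_dataset <- function(config, out_dir) {
  set.seed(config$seed)
  dir.create(file.path(out_dir, "vcf"), recursive = TRUE, showWarnings = FALSE)
  samples <- config$samples

  # panel genotypes: HWE founders, Mendelian children for pedigree rows
  gm <- simulate_genotypes_hwe(config$panel, length(samples),
                               sample_ids = samples, depth = 200L)
  if (!is.null(config$pedigree)) {
    for (i in seq_len(nrow(config$pedigree))) {
      ci <- match(config$pedigree$child[i], gm$samples)
      tmp <- simulate_offspring(gm, config$pedigree$sire[i],
                                config$pedigree$dam[i], "..child..")
      k <- length(tmp$samples)
      gm$a1[ci, ] <- tmp$a1[k, ]; gm$a2[ci, ] <- tmp$a2[k, ]
    }
  }

  vs <- variant_set(list(), samples)
  # panel records: only non-HomoREF genotypes are listed (HomoREF is
  # recovered downstream from depth)
  for (j in seq_len(nrow(config$panel))) {
    calls <- list()
    for (i in seq_along(samples)) {
      g <- c(gm$a1[i, j], gm$a2[i, j])
      if (anyNA(g) || all(g == 0L)) next
      ad <- c(sum(g == 0L), sum(g > 0L)) * 100L
      calls[[samples[i]]] <- list(gt = sort(g), ad = ad, dp = 200L)
    }
    if (length(calls) == 0L) next
    vs$records[[length(vs$records) + 1L]] <-
      variant_record(config$panel$chrom[j], config$panel$pos[j],
                     config$panel$ref[j], config$panel$alt[j], calls)
  }

  # planted screen loci
  for (i in seq_len(nrow(config$planted))) {
    p <- config$planted[i, ]
    dp <- if (!is.na(p$depth_override)) p$depth_override else 500L
    spec <- edit_spec(p$chrom, p$pos, p$ref, p$alt, p$zygosity,
                      label = sprintf("planted_%d", i),
                      alt2 = if (!is.na(p$alt2)) p$alt2)
    vs <- inject_edit(vs, spec, p$sample, depth = dp,
                      amplicons = config$amplicons)
  }

  # noise loci (SNVs of any zygosity; heterozygous INDELs only)
  reserved <- c(paste(config$planted$chrom, config$planted$pos),
                unlist(lapply(config$edits, function(e)
                  paste(e$chrom, seq.int(e$pos, e$pos + nchar(e$ref) + 5L)))))
  noise <- make_noise_loci(config, reserved)
  for (i in seq_len(nrow(noise))) {
    carriers <- sample(samples, sample(1:3, 1L))
    zyg <- if (noise$class[i] == "SNV")
      sample(c("Het", "HomoALT"), 1L, prob = c(0.7, 0.3)) else "Het"
    for (sm in carriers)
      vs <- inject_edit(vs, edit_spec(noise$chrom[i], noise$pos[i],
                                      noise$ref[i], noise$alt[i], zyg),
                        sm, depth = 400L)
  }

  # the engineered edits, then the caller's amplicon-end blind spot
  for (nm in names(config$edits))
    vs <- inject_edit(vs, config$edits[[nm]], config$edit_samples[[nm]],
                      depth = 300L, amplicons = config$amplicons)
  drop <- apply_amplicon_end_dropout(vs, config$amplicons,
                                     margin = config$dropout$margin,
                                     min_size = config$dropout$min_size)
  vs <- drop$vs

  # depth table: amplicon draws + panel sites + planted overrides
  depths <- simulate_depths(config$amplicons, config$depth_model, samples)
  panel_depth <- expand.grid(sample = samples,
                             j = seq_len(nrow(config$panel)),
                             stringsAsFactors = FALSE)
  depths <- rbind(depths,
                  data.frame(chrom = config$panel$chrom[panel_depth$j],
                             pos = config$panel$pos[panel_depth$j],
                             sample = panel_depth$sample, depth = 200L,
                             stringsAsFactors = FALSE))
  for (i in seq_len(nrow(config$planted))) {
    p <- config$planted[i, ]
    if (is.na(p$depth_override)) next
    sel <- depths$chrom == p$chrom & depths$pos == p$pos
    if (any(sel)) depths$depth[sel] <- p$depth_override
    else depths <- rbind(depths, data.frame(
      chrom = p$chrom, pos = p$pos, sample = p$sample,
      depth = p$depth_override, stringsAsFactors = FALSE))
  }

  # known catalogue: planted known keys + unobserved extras
  known_rows <- list()
  for (i in which(config$planted$known)) {
    p <- config$planted[i, ]
    for (a in stats::na.omit(c(p$alt, p$alt2))) {
      n <- normalize_allele_pair(p$pos, p$ref, a)
      known_rows[[length(known_rows) + 1L]] <-
        data.frame(chrom = p$chrom, pos = n$pos, ref = n$ref, alt = n$alt,
                   stringsAsFactors = FALSE)
    }
  }
  ex <- config$exons
  for (i in seq_len(config$extra_known)) {
    r <- sample(nrow(ex), 1L)
    pos <- sample(seq.int(ex$start1[r], ex$end1[r]), 1L)
    ref <- substr(synthetic_sequence(pos, 1L), 1L, 1L)
    known_rows[[length(known_rows) + 1L]] <-
      data.frame(chrom = ex$chrom[r], pos = pos, ref = ref,
                 alt = paste0(ref, "A"), stringsAsFactors = FALSE)
  }
  known <- unique(do.call(rbind, known_rows))

  # write everything
  for (sm in samples) {
    recs <- Filter(function(r) {
      cl <- r$calls[[sm]]
      !is.null(cl) && !anyNA(cl$gt) && any(cl$gt > 0L)
    }, vs$records)
    recs <- lapply(recs, function(r) { r$calls <- r$calls[sm]; r })
    suppressMessages(write_vcf(variant_set(recs, sm),
                               file.path(out_dir, "vcf", paste0(sm, ".vcf"))))
  }
  utils::write.table(depths, file.path(out_dir, "depth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_bed(config$exons, file.path(out_dir, "exons.bed"))
  write_bed(config$amplicons, file.path(out_dir, "amplicons.bed"))
  utils::write.table(config$panel, file.path(out_dir, "panel.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(known, file.path(out_dir, "known.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(config$pedigree)) {
    ped <- config$pedigree
    ped$sire[is.na(ped$sire)] <- "."
    ped$dam[is.na(ped$dam)] <- "."
    utils::write.table(ped, file.path(out_dir, "pedigree.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  edits_truth <- lapply(names(config$edits), function(nm) {
    e <- config$edits[[nm]]
    in_vcf <- !any(drop$dropped$chrom == e$chrom & drop$dropped$pos == e$pos)
    list(label = e$label, sample = config$edit_samples[[nm]],
         chrom = e$chrom, pos = e$pos, ref = e$ref, alt = e$alt,
         zygosity = e$zygosity, in_vcf = in_vcf,
         reason = if (!in_vcf) "amplicon_end_dropout" else "")
  })
  jsonlite::write_json(list(
    name = config$name, seed = config$seed,
    edits = edits_truth,
    known_keys = variant_key(known$chrom, known$pos, known$ref, known$alt),
    low_depth = config$planted[!is.na(config$planted$depth_override),
                               c("chrom", "pos", "ref", "alt", "sample",
                                 "depth_override")],
    expected = config$expected),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(out_dir)
}

#' Load a dataset directory emitted by [emit_dataset()]
#'
#' @param dir dataset directory.
#' @return list with merged `vs`, `depths`, `exons`, `amplicons`, `panel`,
#'   `known`, `pedigree` (or NULL) and `truth`.
#' @export
load_dataset <- function(dir) {
  vcfs <- list.files(file.path(dir, "vcf"), pattern = "\\.vcf$",
                     full.names = TRUE)
  vs <- merge_variant_sets(lapply(vcfs, read_vcf))
  ped_path <- file.path(dir, "pedigree.tsv")
  list(
    vs = vs,
    depths = read_depth_table(file.path(dir, "depth.tsv")),
    exons = read_bed(file.path(dir, "exons.bed"), kind = "exon"),
    amplicons = suppressWarnings(
      read_bed(file.path(dir, "amplicons.bed"), kind = "amplicon")),
    panel = read_panel_table(file.path(dir, "panel.tsv")),
    known = read_known_variants(file.path(dir, "known.tsv")),
    pedigree = if (file.exists(ped_path)) read_pedigree(ped_path),
    truth = jsonlite::read_json(file.path(dir, "truth.json"),
                                simplifyVector = TRUE))
}
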