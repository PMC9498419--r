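# Depth-aware genotyping of the parentage SNV panel. Upstream callers emit
# only non-reference sites, so homozygous-reference genotypes are recovered
# from site depth: REF/REF is called when the site is absent from the VCF but
# covered by more than `call_depth` reads (strict >, default 50). The GT field
# of a present record is trusted as the caller's output; allele-depth
# imbalance is flagged, never re-called.

#' Genotyping thresholds
#'
#' @param call_depth minimum site depth (strict >) for any call; below or at
#'   it the genotype is NoCall. Default 50.
#' @param min_minor_allele_fraction heterozygous calls whose minor-allele
#'   depth fraction falls below this are flagged "allele-imbalance".
#' @return a list of thresholds.
#' @export
genotyping_thresholds <- function(call_depth = 50L,
                                  min_minor_allele_fraction = 0.10) {
  stopifnot(call_depth >= 0L,
            min_minor_allele_fraction >= 0, min_minor_allele_fraction <= 0.5)
  list(call_depth = as.integer(call_depth),
       min_minor_allele_fraction = min_minor_allele_fraction)
}

#' Classify a genotype into its zygosity class
#'
#' @param gt integer pair of allele indices (0 = REF, k >= 1 = ALT_k); `NA`
#'   entries yield NoCall.
#' @return one of "HomoREF", "Het", "HomoALT", "CompoundHet", "NoCall".
#' @export
classify_zygosity <- function(gt) {
  if (is.null(gt) || length(gt) < 2L || any(is.na(gt))) return("NoCall")
  a <- gt[1L]; b <- gt[2L]
  if (a == 0L && b == 0L) return("HomoREF")
  if (a == 0L || b == 0L) return("Het")
  if (a == b) return("HomoALT")
  "CompoundHet"
}

#' Call one panel locus for one sample
#'
#' Implements the depth-recovery rule: with a VCF record at the locus the GT
#' is used, subject to total depth above `call_depth`; with no record the
#' call is HomoREF when the site depth clears the same threshold, else
#' NoCall. When both a depth-table entry and a VCF DP exist, the depth table
#' (the BAM-derived stand-in) wins.
#'
#' @param locus one row of a panel data.frame (snv_id, chrom, pos, ref, alt).
#' @param record overlapping [variant_record()] or NULL.
#' @param sample sample id.
#' @param site_depth depth-table depth at the site for this sample (NA if
#'   absent).
#' @param thresholds from [genotyping_thresholds()].
#' @return list(class, gt, ad, depth, flag).
#' @export
call_panel_genotype <- function(locus, record = NULL, sample = NULL,
                                site_depth = NA_integer_,
                                thresholds = genotyping_thresholds()) {
  nocall <- list(class = "NoCall", gt = c(NA_integer_, NA_integer_),
                 ad = NULL, depth = NA_integer_, flag = "")
  if (is.null(record)) {
    if (!is.na(site_depth) && site_depth > thresholds$call_depth)
      return(list(class = "HomoREF", gt = c(0L, 0L), ad = NULL,
                  depth = as.integer(site_depth), flag = ""))
    nocall$depth <- as.integer(site_depth)
    return(nocall)
  }
  if (record$ref != toupper(locus$ref) || !(toupper(locus$alt) %in% record$alts))
    abort_stage("genotyping", sprintf(
      "locus %s alleles %s>%s do not match VCF record %s>%s at %s:%d",
      locus$snv_id, locus$ref, locus$alt, record$ref,
      paste(record$alts, collapse = ","), record$chrom, record$pos))
  cl <- record$calls[[sample]]
  if (is.null(cl) || (all(is.na(cl$gt)) && is.null(cl$ad))) {
    # the sample is not listed at this site (or carries an empty ./. call
    # with no read evidence): same situation as no record - recover HomoREF
    # from site depth
    if (!is.na(site_depth) && site_depth > thresholds$call_depth)
      return(list(class = "HomoREF", gt = c(0L, 0L), ad = NULL,
                  depth = as.integer(site_depth), flag = ""))
    nocall$depth <- as.integer(site_depth)
    return(nocall)
  }
  depth <- if (!is.na(site_depth)) as.integer(site_depth) else
    (cl$dp %||% NA_integer_)
  if (is.na(depth) || depth <= thresholds$call_depth) {
    nocall$depth <- depth
    return(nocall)
  }
  zyg <- classify_zygosity(cl$gt)
  if (zyg == "NoCall") { nocall$depth <- depth; return(nocall) }
  flag <- ""
  if (zyg == "Het" && !is.null(cl$ad) && sum(cl$ad) > 0L) {
    used <- cl$ad[cl$gt + 1L]
    if (min(used) / sum(cl$ad) < thresholds$min_minor_allele_fraction)
      flag <- "allele-imbalance"
  }
  list(class = zyg, gt = cl$gt, ad = cl$ad, depth = depth, flag = flag)
}

#' Construct a genotype matrix
#'
#' Rectangular samples x loci container of allele-index calls with depths and
#' QC flags; NoCall is represented by `NA` allele indices.
#'
#' @param samples character vector of sample ids.
#' @param loci panel data.frame (one row per locus).
#' @param a1,a2 integer matrices (samples x loci) of allele indices.
#' @param depth integer matrix of site depths.
#' @param flags character matrix of QC flags ("" = none).
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(samples, loci, a1, a2, depth = NULL, flags = NULL) {
  n <- length(samples); L <- nrow(loci)
  stopifnot(identical(dim(a1), c(n, L)), identical(dim(a2), c(n, L)))
  if (is.null(depth)) depth <- matrix(NA_integer_, n, L)
  if (is.null(flags)) flags <- matrix("", n, L)
  dimnames(a1) <- dimnames(a2) <- dimnames(depth) <- dimnames(flags) <-
    list(samples, loci$snv_id)
  structure(list(samples = samples, loci = loci, a1 = a1, a2 = a2,
                 depth = depth, flags = flags),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  called <- sum(!is.na(x$a1))
  cat(sprintf("genotype_matrix: %d samples x %d loci (%.1f%% called)\n",
              length(x$samples), nrow(x$loci),
              100 * called / length(x$a1)))
  invisible(x)
}

#' Zygosity classes of a genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @return character matrix of zygosity classes.
#' @export
zygosity_classes <- function(gm) {
  out <- matrix("NoCall", length(gm$samples), nrow(gm$loci),
                dimnames = dimnames(gm$a1))
  for (i in seq_along(gm$samples))
    for (j in seq_len(nrow(gm$loci)))
      out[i, j] <- classify_zygosity(c(gm$a1[i, j], gm$a2[i, j]))
  out
}

#' Genotype the SNV panel from a variant set and depth table
#'
#' @param vs a [variant_set()].
#' @param panel panel data.frame from [read_panel_table()].
#' @param depths depth table from [read_depth_table()] (or NULL to rely on
#'   VCF DP only; HomoREF recovery then requires depth rows).
#' @param thresholds from [genotyping_thresholds()].
#' @return a [genotype_matrix()].
#' @export
genotype_panel <- function(vs, panel, depths = NULL,
                           thresholds = genotyping_thresholds()) {
  check_chromosome_overlap(panel, vs)
  rec_key <- paste(vapply(vs$records, `[[`, "", "chrom"),
                   vapply(vs$records, `[[`, 1L, "pos"))
  dkey <- if (!is.null(depths)) paste(depths$chrom, depths$pos, depths$sample)
  n <- length(vs$samples); L <- nrow(panel)
  a1 <- a2 <- matrix(NA_integer_, n, L)
  depth <- matrix(NA_integer_, n, L)
  flags <- matrix("", n, L)
  for (j in seq_len(L)) {
    hit <- match(paste(panel$chrom[j], panel$pos[j]), rec_key)
    rec <- if (!is.na(hit)) vs$records[[hit]]
    for (i in seq_len(n)) {
      sd <- NA_integer_
      if (!is.null(dkey)) {
        dh <- match(paste(panel$chrom[j], panel$pos[j], vs$samples[i]), dkey)
        if (!is.na(dh)) sd <- depths$depth[dh]
      }
      cl <- call_panel_genotype(panel[j, ], rec, vs$samples[i], sd, thresholds)
      a1[i, j] <- cl$gt[1L]; a2[i, j] <- cl$gt[2L]
      depth[i, j] <- cl$depth %||% NA_integer_
      flags[i, j] <- cl$flag
    }
  }
  genotype_matrix(vs$samples, panel, a1, a2, depth, flags)
}

#' Estimate the REF-allele frequency at one locus
#'
#' p = (2 x HomoREF + Het) / (2 x called); NoCall genotypes are excluded from
#' the denominator.
#'
#' @param gm a [genotype_matrix()].
#' @param locus locus id or column index.
#' @return REF-allele frequency in `[0, 1]`.
#' @export
estimate_allele_freq <- function(gm, locus) {
  j <- if (is.character(locus)) match(locus, gm$loci$snv_id) else locus
  if (is.na(j)) abort_stage("genotyping", "unknown locus: ", locus)
  alleles <- c(gm$a1[, j], gm$a2[, j])
  alleles <- alleles[!is.na(alleles)]
  if (length(alleles) == 0L)
    abort_stage("genotyping", "allele frequency undefined: all calls are NoCall")
  mean(alleles == 0L)
}

#' Write a genotype matrix as a long-format TSV
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_matrix <- function(gm, path) {
  zyg <- zygosity_classes(gm)
  long <- expand.grid(sample = gm$samples, snv_id = gm$loci$snv_id,
                      stringsAsFactors = FALSE)
  long$class <- as.vector(zyg)
  long$a1 <- as.vector(gm$a1); long$a2 <- as.vector(gm$a2)
  long$depth <- as.vector(gm$depth); long$flag <- as.vector(gm$flags)
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
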