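# Seeded synthetic-data generator: Hardy-Weinberg panel genotypes, Mendelian
# pedigrees (true and pseudo), per-amplicon lognormal depth with designated
# low-coverage amplicons, CRISPR-style edit injection, the upstream caller's
# amplicon-end blind spot for large INDELs, and genotyping faults (low depth,
# allele-depth imbalance). Everything is deterministic under a fixed seed.

# deterministic placeholder sequence (no reference genome is used anywhere;
# sequences only need to be internally consistent)
synthetic_sequence <- function(pos, len) {
  bases <- c("A", "C", "G", "T")
  paste(bases[(seq.int(pos, length.out = len) %% 4L) + 1L], collapse = "")
}

#' Specification of one CRISPR-style edit
#'
#' @param chrom,pos edit site (1-based, position of the first REF base).
#' @param ref,alt REF and edited allele strings.
#' @param zygosity "HomoALT", "Het" or "CompoundHet".
#' @param label free-text label.
#' @param alt2 second ALT allele (CompoundHet only).
#' @return a list of class `edit_spec`.
#' @export
edit_spec <- function(chrom, pos, ref, alt, zygosity, label = "",
                      alt2 = NULL) {
  stopifnot(zygosity %in% c("HomoALT", "Het", "CompoundHet"))
  if (toupper(ref) == toupper(alt))
    abort_stage("edit_spec", "ref equals edited allele")
  structure(list(chrom = chrom, pos = as.integer(pos), ref = toupper(ref),
                 alt = toupper(alt), alt2 = if (!is.null(alt2)) toupper(alt2),
                 zygosity = zygosity, label = label),
            class = "edit_spec")
}

#' The four packaged myostatin edit specifications
#'
#' Three homozygous 1-bp insertions (exons 1 and 2) and one heterozygous
#' 77-bp deletion spanning the exon 3 / intron 2 boundary, at their EquCab3.0
#' coordinates. The deleted-sequence context is synthetic (deterministic
#' placeholder bases): no reference genome ships with the package.
#'
#' @param chrom_prefix chromosome naming style ("chr" or "").
#' @return list of [edit_spec()] objects.
#' @export
table3_edits <- function(chrom_prefix = "chr") {
  chrom <- paste0(chrom_prefix, "18")
  del_anchor <- 66605476L
  del_ref <- synthetic_sequence(del_anchor, 78L)   # anchor + 77 deleted bases
  list(
    edit_77del = edit_spec(chrom, del_anchor, del_ref,
                           substr(del_ref, 1L, 1L), "Het",
                           label = "edited_cell_1_77bp_del"),
    edit_ins2 = edit_spec(chrom, 66607750L, "C", "CT", "HomoALT",
                          label = "edited_cell_2_1bp_ins"),
    edit_ins3 = edit_spec(chrom, 66607753L, "T", "TA", "HomoALT",
                          label = "edited_cell_3_1bp_ins"),
    edit_ins4 = edit_spec(chrom, 66609936L, "T", "TA", "HomoALT",
                          label = "edited_cell_4_1bp_ins"))
}

#' Per-amplicon depth model
#'
#' Depth is drawn per amplicon and sample from a lognormal distribution and
#' held constant across the amplicon's bases (PCR amplification efficiency
#' varies by primer, not by base). A designated fraction of amplicons is
#' assigned a separate low-coverage stratum.
#'
#' @param mean_depth mean depth of ordinary amplicons (reads).
#' @param sd_log between-amplicon log-scale standard deviation.
#' @param low_fraction fraction of amplicons designated low-coverage.
#' @param low_mean mean depth of the low-coverage stratum.
#' @return a list of class `depth_model`.
#' @export
depth_model <- function(mean_depth = 500, sd_log = 0.3,
                        low_fraction = 0, low_mean = 10) {
  stopifnot(mean_depth >= 0, sd_log >= 0, low_fraction >= 0,
            low_fraction <= 1, low_mean >= 0)
  structure(list(mean_depth = mean_depth, sd_log = sd_log,
                 low_fraction = low_fraction, low_mean = low_mean),
            class = "depth_model")
}

#' Simulate Hardy-Weinberg genotypes at the panel frequencies
#'
#' Each locus is i.i.d. across samples with genotype probabilities
#' (p^2, 2pq, q^2); alleles are drawn independently, which is equivalent.
#'
#' @param panel panel data.frame with `ref_freq`.
#' @param n number of samples.
#' @param seed optional RNG seed.
#' @param sample_ids sample names (default S1..Sn).
#' @param depth constant site depth recorded for every call.
#' @return a [genotype_matrix()].
#' @export
simulate_genotypes_hwe <- function(panel, n, seed = NULL, sample_ids = NULL,
                                   depth = 200L) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n >= 1L)
  sample_ids <- sample_ids %||% sprintf("S%d", seq_len(n))
  L <- nrow(panel)
  p <- matrix(rep(panel$ref_freq, each = n), n, L)
  a1 <- matrix(as.integer(stats::runif(n * L) > p), n, L)
  a2 <- matrix(as.integer(stats::runif(n * L) > p), n, L)
  genotype_matrix(sample_ids, panel, a1, a2,
                  depth = matrix(as.integer(depth), n, L))
}

#' Append a Mendelian offspring of two samples to a genotype matrix
#'
#' The child receives one uniformly random allele from each parent,
#' independently per locus; a NoCall in a parent propagates to the child.
#'
#' @param gm a [genotype_matrix()].
#' @param sire,dam parent sample ids.
#' @param child_id new sample id.
#' @param seed optional RNG seed.
#' @return the matrix with the child appended.
#' @export
simulate_offspring <- function(gm, sire, dam, child_id, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  si <- match(sire, gm$samples); di <- match(dam, gm$samples)
  if (is.na(si) || is.na(di))
    abort_stage("simulate", "parent not in matrix: ",
                paste(c(sire, dam)[is.na(c(si, di))], collapse = ", "))
  L <- nrow(gm$loci)
  pick <- function(i) {
    takes <- stats::runif(L) < 0.5
    ifelse(takes, gm$a1[i, ], gm$a2[i, ])
  }
  c1 <- pick(si); c2 <- pick(di)
  nc <- is.na(gm$a1[si, ]) | is.na(gm$a1[di, ])
  c1[nc] <- NA_integer_; c2[nc] <- NA_integer_
  child_depth <- suppressWarnings(max(gm$depth, na.rm = TRUE))
  if (!is.finite(child_depth)) child_depth <- 200L
  genotype_matrix(c(gm$samples, child_id), gm$loci,
                  rbind(gm$a1, c1), rbind(gm$a2, c2),
                  rbind(gm$depth, rep(as.integer(child_depth), L)),
                  rbind(gm$flags, rep("", L)))
}

#' Simulate the full pedigree test suite
#'
#' Generates true families by Mendelian transmission from Hardy-Weinberg
#' founders, plus unrelated substitutes for the pseudo designs, and labels
#' every test with its truth status. The checker itself treats all kinds
#' identically.
#'
#' @param panel panel data.frame.
#' @param n_trios true sire-dam-foal trios.
#' @param n_pseudo_trios trios with both parents substituted.
#' @param n_half_pseudo_trios trios with one parent substituted.
#' @param n_duos true single-parent tests.
#' @param n_pseudo_duos single-parent tests with a substituted parent.
#' @param seed RNG seed.
#' @param depth constant genotyping depth.
#' @return list with elements `gm` ([genotype_matrix()]) and `tests`
#'   (data.frame: child, sire, dam, kind).
#' @export
simulate_pedigree_suite <- function(panel, n_trios = 29L, n_pseudo_trios = 5L,
                                    n_half_pseudo_trios = 5L, n_duos = 5L,
                                    n_pseudo_duos = 5L, seed = NULL,
                                    depth = 200L) {
  if (!is.null(seed)) set.seed(seed)
  n_unrel <- 2L * (n_pseudo_trios + n_pseudo_duos) + n_half_pseudo_trios
  sires <- sprintf("SIRE%02d", seq_len(n_trios))
  dams <- sprintf("DAM%02d", seq_len(n_trios))
  unrel <- if (n_unrel > 0L) sprintf("UNREL%02d", seq_len(n_unrel)) else character()
  gm <- simulate_genotypes_hwe(panel, 2L * n_trios + n_unrel,
                               sample_ids = c(sires, dams, unrel),
                               depth = depth)
  foals <- sprintf("FOAL%02d", seq_len(n_trios))
  for (i in seq_len(n_trios))
    gm <- simulate_offspring(gm, sires[i], dams[i], foals[i])
  tests <- data.frame(child = character(), sire = character(),
                      dam = character(), kind = character(),
                      stringsAsFactors = FALSE)
  add <- function(child, sire, dam, kind)
    rbind(tests, data.frame(child = child, sire = sire, dam = dam,
                            kind = kind, stringsAsFactors = FALSE))
  tests <- add(foals, sires, dams, "trio")
  u <- 0L
  for (i in seq_len(n_pseudo_trios)) {
    tests <- add(foals[i], unrel[u + 1L], unrel[u + 2L], "pseudo_trio")
    u <- u + 2L
  }
  for (i in seq_len(n_half_pseudo_trios)) {
    u <- u + 1L
    if (i %% 2L == 1L)                       # sire, pseudo-dam / pseudo-sire, dam
      tests <- add(foals[i], sires[i], unrel[u], "half_pseudo_trio")
    else
      tests <- add(foals[i], unrel[u], dams[i], "half_pseudo_trio")
  }
  for (i in seq_len(n_duos))
    tests <- add(foals[i], NA_character_, dams[i], "duo")
  for (i in seq_len(n_pseudo_duos)) {
    u <- u + 1L
    tests <- add(foals[i], NA_character_, unrel[u], "pseudo_duo")
  }
  list(gm = gm, tests = tests)
}

#' Inject an edit into a variant set
#'
#' Adds (or overwrites, idempotently) a variant record at the edit site with
#' the genotype implied by the edit's zygosity and allele depths consistent
#' with it.
#'
#' @param vs a [variant_set()].
#' @param edit an [edit_spec()].
#' @param sample carrier sample id (must be in `vs$samples`).
#' @param depth total site depth synthesized for the call.
#' @param amplicons when supplied, the edit site must fall inside an
#'   amplicon; an edit outside all amplicons is an error (undetectable by
#'   design).
#' @return the modified variant set.
#' @export
inject_edit <- function(vs, edit, sample, depth = 200L, amplicons = NULL) {
  if (!sample %in% vs$samples)
    abort_stage("inject_edit", "unknown sample: ", sample)
  if (!is.null(amplicons) &&
      !overlaps_region(amplicons, edit$chrom, edit$pos,
                       edit$pos + nchar(edit$ref) - 1L))
    abort_stage("inject_edit", sprintf(
      "edit %s at %s:%d lies outside every amplicon (undetectable by design)",
      edit$label, edit$chrom, edit$pos))
  alts <- c(edit$alt, edit$alt2)
  call <- switch(edit$zygosity,
    HomoALT = list(gt = c(1L, 1L), ad = c(0L, depth), dp = depth),
    Het = list(gt = c(0L, 1L),
               ad = c(depth %/% 2L, depth - depth %/% 2L), dp = depth),
    CompoundHet = {
      if (length(alts) < 2L)
        abort_stage("inject_edit", "CompoundHet edit needs alt2")
      list(gt = c(1L, 2L),
           ad = c(0L, depth %/% 2L, depth - depth %/% 2L), dp = depth)
    })
  idx <- which(vapply(vs$records, function(r)
    r$chrom == edit$chrom && r$pos == edit$pos, TRUE))
  calls <- if (length(idx)) vs$records[[idx[1L]]]$calls else list()
  calls[[sample]] <- call
  rec <- variant_record(edit$chrom, edit$pos, edit$ref, alts, calls)
  if (length(idx)) vs$records[[idx[1L]]] <- rec
  else vs$records[[length(vs$records) + 1L]] <- rec
  vs
}

#' Remove large INDELs near amplicon boundaries
#'
#' Emulates the upstream caller's soft-clip blind spot: INDEL records whose
#' length change exceeds `min_size` and whose normalized start or end lies
#' within `margin` bases of the boundary of the amplicon containing them are
#' dropped, reproducing the documented failure to call large deletions at
#' amplicon ends.
#'
#' @param vs a [variant_set()].
#' @param amplicons amplicon regions from [read_bed()].
#' @param margin distance (bp, strict <) from an amplicon boundary.
#' @param min_size minimum length change (bp, strict >) for dropout.
#' @return list with the filtered `vs` and `dropped` (data.frame of removed
#'   records with chrom, pos, ref, alt).
#' @export
apply_amplicon_end_dropout <- function(vs, amplicons, margin = 25L,
                                       min_size = 50L) {
  keep <- rep(TRUE, length(vs$records))
  dropped <- list()
  for (i in seq_along(vs$records)) {
    r <- vs$records[[i]]
    size <- max(abs(nchar(r$ref) - nchar(r$alts)))
    if (size <= min_size) next
    nr <- normalize_variant(r)
    s <- nr$pos; e <- nr$pos + nchar(nr$ref) - 1L
    amp <- amplicons[amplicons$chrom == r$chrom & amplicons$start1 <= e &
                       amplicons$end1 >= s, , drop = FALSE]
    if (nrow(amp) == 0L) next
    near <- any(s - amp$start1 < margin | amp$end1 - e < margin)
    if (near) {
      keep[i] <- FALSE
      dropped[[length(dropped) + 1L]] <-
        data.frame(chrom = r$chrom, pos = r$pos, ref = r$ref,
                   alt = paste(r$alts, collapse = ","),
                   stringsAsFactors = FALSE)
    }
  }
  vs$records <- vs$records[keep]
  list(vs = vs,
       dropped = if (length(dropped)) do.call(rbind, dropped) else
         data.frame(chrom = character(), pos = integer(), ref = character(),
                    alt = character(), stringsAsFactors = FALSE))
}

#' Simulate a per-position depth table over amplicons
#'
#' One lognormal draw per (amplicon, sample), constant across the amplicon's
#' bases. The designated low-coverage amplicons (chosen by seeded sampling)
#' use the model's low-coverage mean.
#'
#' @param amplicons amplicon regions from [read_bed()].
#' @param model a [depth_model()].
#' @param samples sample ids.
#' @param seed optional RNG seed.
#' @return depth data.frame (chrom, pos, sample, depth) with attribute
#'   `low_regions` naming the designated low-coverage amplicons.
#' @export
simulate_depths <- function(amplicons, model, samples, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_low <- round(model$low_fraction * nrow(amplicons))
  low <- if (n_low > 0L) sample(amplicons$name, n_low) else character()
  out <- vector("list", nrow(amplicons) * length(samples))
  k <- 0L
  for (i in seq_len(nrow(amplicons))) {
    pos <- seq.int(amplicons$start1[i], amplicons$end1[i])
    mu <- if (amplicons$name[i] %in% low) model$low_mean else model$mean_depth
    for (sm in samples) {
      d <- if (model$sd_log == 0) mu else
        stats::rlnorm(1L, log(max(mu, 1e-9)), model$sd_log)
      k <- k + 1L
      out[[k]] <- data.frame(chrom = amplicons$chrom[i], pos = pos,
                             sample = sm, depth = as.integer(round(d)),
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "low_regions") <- low
  res
}

#' Inject genotyping faults into a genotype matrix
#'
#' Two fault classes mirror the failure modes that cause mis-inheritances in
#' real panels. `allele_bias` flips a heterozygous call to the homozygote of
#' one allele in a member of a true trio, chosen so that the trio becomes
#' Mendelian-inconsistent at that locus. `low_depth` sets the site depth at
#' or below the call threshold for a random subset of samples (their calls
#' become NoCall) and additionally miscalls one marginal-depth trio member
#' through allele dropout, so the locus also exhibits a mis-inheritance (how
#' insufficient coverage manifests in real trios).
#'
#' @param gm a [genotype_matrix()].
#' @param faults data.frame with columns `snv_id` and `type`
#'   ("allele_bias" or "low_depth").
#' @param trios data.frame (child, sire, dam) of true trios; required for
#'   allele-bias faults.
#' @param seed optional RNG seed.
#' @param n_low_samples how many samples a low-depth fault hits.
#' @param call_depth the genotyping call-depth threshold the fault undercuts.
#' @return the faulted matrix.
#' @export
simulate_genotyping_faults <- function(gm, faults, trios = NULL, seed = NULL,
                                       n_low_samples = 3L, call_depth = 50L) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(faults) == 0L) return(gm)
  for (f in seq_len(nrow(faults))) {
    j <- match(faults$snv_id[f], gm$loci$snv_id)
    if (is.na(j)) abort_stage("simulate", "fault locus not in panel: ",
                              faults$snv_id[f])
    if (faults$type[f] == "low_depth") {
      hit <- sample(seq_along(gm$samples), min(n_low_samples, length(gm$samples)))
      gm$depth[hit, j] <- as.integer(sample(seq_len(call_depth), length(hit),
                                            replace = TRUE))
      gm$a1[hit, j] <- NA_integer_; gm$a2[hit, j] <- NA_integer_
      gm$flags[hit, j] <- "low-depth-fault"
      if (!is.null(trios) && nrow(trios) > 0L)
        gm <- inject_allele_bias(gm, j, trios, flag = "low-depth-fault",
                                 marginal_depth = call_depth + 5L)
    } else if (faults$type[f] == "allele_bias") {
      if (is.null(trios) || nrow(trios) == 0L)
        abort_stage("simulate", "allele-bias faults need true trios")
      gm <- inject_allele_bias(gm, j, trios)
    } else abort_stage("simulate", "unknown fault type: ", faults$type[f])
  }
  gm
}

# flip one Het call to a homozygote so that some true trio becomes
# inconsistent at locus j; falls back to flipping a Het parent when no
# suitable Het child exists
inject_allele_bias <- function(gm, j, trios, flag = "allele-bias-fault",
                               marginal_depth = NULL) {
  geno <- function(i) c(gm$a1[i, j], gm$a2[i, j])
  set <- function(i, g) {
    gm$a1[i, j] <<- g[1L]; gm$a2[i, j] <<- g[2L]
    gm$flags[i, j] <<- flag
    if (!is.null(marginal_depth)) gm$depth[i, j] <<- as.integer(marginal_depth)
  }
  for (t in seq_len(nrow(trios))) {
    ci <- match(trios$child[t], gm$samples)
    si <- match(trios$sire[t], gm$samples)
    di <- match(trios$dam[t], gm$samples)
    ch <- geno(ci); sg <- geno(si); dg <- geno(di)
    if (any(is.na(c(ch, sg, dg)))) next
    # Het child with a homozygous parent: flip child to the homozygote of
    # the allele that parent lacks
    if (classify_zygosity(ch) == "Het") {
      for (pg in list(sg, dg)) {
        if (pg[1L] == pg[2L]) {
          other <- setdiff(ch, pg[1L])
          if (length(other) == 1L) { set(ci, c(other, other)); return(gm) }
        }
      }
    }
    # homozygous child with a Het parent: flip that parent to the homozygote
    # of the allele the child lacks
    if (ch[1L] == ch[2L]) {
      for (pi in c(si, di)) {
        pg <- geno(pi)
        if (classify_zygosity(pg) == "Het") {
          other <- setdiff(pg, ch[1L])
          if (length(other) == 1L) { set(pi, c(other, other)); return(gm) }
        }
      }
    }
  }
  # degenerate panel corner (e.g. p near 0/1 everywhere): force an opposite-
  # homozygote child in the first trio
  ci <- match(trios$child[1L], gm$samples)
  si <- match(trios$sire[1L], gm$samples)
  sg <- c(gm$a1[si, j], gm$a2[si, j])
  forced <- if (!anyNA(sg) && all(sg == 1L)) 0L else 1L
  gm$a1[si, j] <- 1L - forced; gm$a2[si, j] <- 1L - forced
  gm$a1[ci, j] <- forced; gm$a2[ci, j] <- forced
  gm$flags[ci, j] <- flag
  if (!is.null(marginal_depth)) gm$depth[ci, j] <- as.integer(marginal_depth)
  gm
}
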