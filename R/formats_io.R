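# Readers/writers for every external format the pipeline touches, plus
# variant-key normalization. Coordinate conventions: VCF, depth tables and all
# internal positions are 1-based; BED is converted from 0-based half-open at
# the read boundary and nowhere else. Chromosome names are compared as exact
# strings (no "chr" harmonization).

ALLELE_CHARS <- "^[ACGTNacgtn]+$"

#' Construct a single variant record
#'
#' A variant record is one (possibly multi-allelic) site with per-sample
#' genotype calls. Genotypes are pairs of allele indices (0 = REF,
#' 1..k = ALT; `NA` = missing); allele depths (`ad`) are per-allele
#' non-negative integers in REF, ALT1, ..., ALTk order, or `NULL` when the
#' caller reported none; `dp` is the total site depth or `NA`.
#'
#' @param chrom chromosome name.
#' @param pos 1-based position of the first REF base.
#' @param ref REF allele string over A/C/G/T/N.
#' @param alts character vector of ALT allele strings (ordered).
#' @param calls named list (by sample) of lists with elements `gt`
#'   (integer pair), `ad` (integer vector or NULL) and `dp` (integer or NA).
#' @param id optional variant identifier ("." if unknown).
#' @return an object of class `variant_record`.
#' @export
variant_record <- function(chrom, pos, ref, alts, calls = list(), id = ".") {
  pos <- as.integer(pos)
  if (is.na(pos) || pos < 1L) stop("pos must be a positive integer", call. = FALSE)
  if (!grepl(ALLELE_CHARS, ref)) stop("ref must be a non-empty A/C/G/T/N string", call. = FALSE)
  alts <- as.character(alts)
  if (length(alts) == 0L || !all(grepl(ALLELE_CHARS, alts)))
    stop("every alt must be a non-empty A/C/G/T/N string", call. = FALSE)
  for (sm in names(calls)) {
    cl <- calls[[sm]]
    gt <- cl$gt
    if (!is.null(gt) && any(!is.na(gt)) &&
        any(stats::na.omit(gt) < 0L | stats::na.omit(gt) > length(alts)))
      stop(sprintf("genotype index out of range for sample %s", sm), call. = FALSE)
    if (!is.null(cl$ad) && !is.null(cl$dp) && !is.na(cl$dp) &&
        sum(cl$ad) > cl$dp)
      stop(sprintf("allele depths exceed total depth for sample %s", sm), call. = FALSE)
  }
  structure(list(chrom = unname(as.character(chrom)), pos = unname(pos),
                 id = unname(as.character(id)), ref = unname(toupper(ref)),
                 alts = unname(toupper(alts)), calls = calls),
            class = "variant_record")
}

#' Construct a set of variant records with an ordered sample list
#'
#' @param records list of [variant_record()] objects.
#' @param samples character vector of sample ids (column order).
#' @return an object of class `variant_set`.
#' @export
variant_set <- function(records, samples) {
  structure(list(records = records, samples = as.character(samples)),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d records, %d samples\n",
              length(x$records), length(x$samples)))
  invisible(x)
}

# -- VCF ---------------------------------------------------------------------

# light structural validation before handing the file to vcfR, so contract
# violations are reported with line numbers
validate_vcf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "##"))
  if (length(body) == 0L)
    abort_stage("read_vcf", "no #CHROM header line in ", path)
  hdr_i <- body[1L]
  if (!startsWith(lines[hdr_i], "#CHROM"))
    abort_stage("read_vcf", sprintf("line %d: expected #CHROM header", hdr_i))
  hdr <- strsplit(lines[hdr_i], "\t", fixed = TRUE)[[1L]]
  if (length(hdr) < 10L)
    abort_stage("read_vcf", "VCF must carry FORMAT and at least one sample column")
  ncol_expect <- length(hdr)
  for (i in body[-1L]) {
    if (!nzchar(lines[i])) next
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) != ncol_expect)
      abort_stage("read_vcf", sprintf("line %d: %d columns, expected %d",
                                      i, length(fields), ncol_expect))
    fmt <- strsplit(fields[9L], ":", fixed = TRUE)[[1L]]
    if (!"GT" %in% fmt)
      abort_stage("read_vcf", sprintf("line %d: FORMAT lacks GT", i))
    gts <- sub(":.*$", "", fields[-(1:9)])
    ok <- grepl("^(\\.|\\d+)([/|](\\.|\\d+))?$", gts)
    if (!all(ok))
      abort_stage("read_vcf", sprintf(
        "line %d: unparseable genotype '%s' (separator must be '/' or '|')",
        i, gts[!ok][1L]))
  }
  hdr[-(1:9)]
}

parse_gt_field <- function(gt) {
  a <- strsplit(gt, "[/|]")[[1L]]
  a <- suppressWarnings(as.integer(ifelse(a == ".", NA, a)))
  if (length(a) == 1L) a <- c(a, a)
  a[1:2]
}

#' Read a VCF file into a variant set
#'
#' Parses GT always and AD/DP when present in FORMAT. Missing AD/DP are kept
#' absent (`NULL`/`NA`), never coerced to zero. Multi-allelic sites are kept
#' as single records so that compound-heterozygote (ALT1/ALT2) genotypes stay
#' visible at one locus. Phased and unphased separators are treated alike.
#'
#' @param path path to an uncompressed VCF v4.x file.
#' @return a [variant_set()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) abort_stage("read_vcf", "no such file: ", path)
  samples <- validate_vcf_lines(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  gt <- v@gt
  records <- vector("list", nrow(fix))
  if (nrow(fix) > 0L) {
    for (i in seq_len(nrow(fix))) {
      fmt <- strsplit(gt[i, "FORMAT"], ":", fixed = TRUE)[[1L]]
      calls <- list()
      for (sm in samples) {
        parts <- strsplit(gt[i, sm], ":", fixed = TRUE)[[1L]]
        names(parts) <- fmt[seq_along(parts)]
        ad <- NULL
        if (!is.na(parts["AD"]) && parts["AD"] != "." && "AD" %in% names(parts))
          ad <- as.integer(strsplit(parts[["AD"]], ",", fixed = TRUE)[[1L]])
        dp <- NA_integer_
        if ("DP" %in% names(parts) && !is.na(parts["DP"]) && parts["DP"] != ".")
          dp <- as.integer(parts[["DP"]])
        calls[[sm]] <- list(gt = parse_gt_field(parts[["GT"]]), ad = ad, dp = dp)
      }
      records[[i]] <- variant_record(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"],
        alts = strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]],
        calls = calls,
        id = ifelse(is.na(fix[i, "ID"]), ".", fix[i, "ID"]))
    }
  }
  variant_set(records, samples)
}

format_call <- function(cl) {
  gt <- cl$gt
  g <- if (is.null(gt) || all(is.na(gt))) "./." else
    paste(ifelse(is.na(gt), ".", gt), collapse = "/")
  ad <- if (is.null(cl$ad)) "." else paste(cl$ad, collapse = ",")
  dp <- if (is.null(cl$dp) || is.na(cl$dp)) "." else as.character(cl$dp)
  paste(g, ad, dp, sep = ":")
}

#' Write a variant set to an uncompressed VCF file
#'
#' Records are written sorted by (chrom, pos); a message notes when the input
#' order was changed. Round-trips through [read_vcf()] reproduce positions,
#' alleles and genotypes exactly.
#'
#' @param vs a [variant_set()], or a list of records.
#' @param path output path.
#' @param samples sample ids; defaults to those of `vs`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vs, path, samples = NULL) {
  if (inherits(vs, "variant_set")) {
    records <- vs$records
    samples <- samples %||% vs$samples
  } else records <- vs
  if (length(samples) == 0L) abort_stage("write_vcf", "samples must be non-empty")
  if (length(records) > 0L) {
    ord <- order(vapply(records, `[[`, "", "chrom"),
                 vapply(records, `[[`, 1L, "pos"))
    if (!identical(ord, seq_along(records)))
      message("write_vcf: records were reordered by (chrom, pos)")
    records <- records[ord]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")), con)
  for (r in records) {
    cols <- vapply(samples, function(sm) {
      cl <- r$calls[[sm]]
      if (is.null(cl)) "./.:.:." else format_call(cl)
    }, "")
    writeLines(paste(c(r$chrom, r$pos, r$id, r$ref,
                       paste(r$alts, collapse = ","),
                       ".", "PASS", ".", "GT:AD:DP", cols), collapse = "\t"), con)
  }
  invisible(path)
}

# -- BED and plain tables ----------------------------------------------------

#' Read target regions from a BED file
#'
#' BED is 0-based half-open; returned regions carry 1-based inclusive
#' `start1`/`end1` columns (the only place the conversion happens).
#'
#' @param path BED path (3 or 4+ columns).
#' @param kind `"exon"` or `"amplicon"`; amplicon lengths outside
#'   `amplicon_range` draw a warning.
#' @param amplicon_range permitted amplicon length range in bp.
#' @return data.frame with columns chrom, start1, end1, name, kind.
#' @export
read_bed <- function(path, kind = c("exon", "amplicon"),
                     amplicon_range = c(125L, 275L)) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort_stage("read_bed", "no such file: ", path)
  if (length(readLines(path, warn = FALSE)) == 0L)
    return(data.frame(chrom = character(), start1 = integer(),
                      end1 = integer(), name = character(),
                      kind = character(), stringsAsFactors = FALSE))
  tb <- utils::read.table(path, sep = "", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tb) < 3L) abort_stage("read_bed", "BED needs at least 3 columns")
  start0 <- as.integer(tb[[2L]]); end0 <- as.integer(tb[[3L]])
  bad <- which(start0 >= end0)
  if (length(bad))
    abort_stage("read_bed", sprintf("degenerate interval at data line %d (start >= end)", bad[1L]))
  nm <- if (ncol(tb) >= 4L) as.character(tb[[4L]]) else
    sprintf("%s:%d-%d", tb[[1L]], start0, end0)
  out <- data.frame(chrom = as.character(tb[[1L]]), start1 = start0 + 1L,
                    end1 = end0, name = nm, kind = kind,
                    stringsAsFactors = FALSE)
  if (kind == "amplicon") {
    len <- out$end1 - out$start1 + 1L
    off <- len < amplicon_range[1L] | len > amplicon_range[2L]
    if (any(off))
      warning(sprintf("%d amplicon(s) outside the %d-%d bp design range",
                      sum(off), amplicon_range[1L], amplicon_range[2L]),
              call. = FALSE)
  }
  out
}

#' Read a parentage SNV panel table
#'
#' Tab-separated with a header whose first six columns are the SNV id,
#' chromosome, 1-based position, REF allele, ALT allele and REF-allele
#' frequency. Extra columns are ignored by the reader (but preserved).
#'
#' @param path panel TSV path.
#' @return data.frame with columns snv_id, chrom, pos, ref, alt, ref_freq
#'   (plus any further columns present in the file).
#' @export
read_panel_table <- function(path) {
  if (!file.exists(path)) abort_stage("read_panel_table", "no such file: ", path)
  tb <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (ncol(tb) < 6L) abort_stage("read_panel_table", "panel table needs 6 columns")
  names(tb)[1:6] <- c("snv_id", "chrom", "pos", "ref", "alt", "ref_freq")
  tb$chrom <- as.character(tb$chrom)
  tb$pos <- as.integer(tb$pos)
  tb$ref_freq <- as.numeric(tb$ref_freq)
  if (any(is.na(tb$ref_freq) | tb$ref_freq < 0 | tb$ref_freq > 1))
    abort_stage("read_panel_table", "REF frequency outside [0,1]")
  if (any(tb$ref == tb$alt))
    abort_stage("read_panel_table", "REF and ALT alleles must differ")
  tb
}

#' Path to the packaged 120-SNV parentage panel
#'
#' The panel ships with the package as a plain TSV (ids, positions on
#' EquCab3.0, alleles, REF-allele frequencies, and the published per-locus
#' statistics columns).
#'
#' @return file path.
#' @export
packaged_panel_path <- function() {
  system.file("extdata", "panel_table7.tsv", package = "gedscreen",
              mustWork = TRUE)
}

#' Read a pedigree table
#'
#' Three tab- or space-separated columns: child, sire, dam, with "." marking
#' a missing parent. A row with both parents missing is rejected.
#'
#' @param path pedigree table path.
#' @return data.frame with columns child, sire, dam, label (trio/duo).
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) abort_stage("read_pedigree", "no such file: ", path)
  tb <- utils::read.table(path, sep = "", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("child", "sire", "dam"))
  tb$sire[tb$sire == "."] <- NA_character_
  tb$dam[tb$dam == "."] <- NA_character_
  if (any(is.na(tb$sire) & is.na(tb$dam)))
    abort_stage("read_pedigree", "pedigree entry with no parent present")
  tb$label <- ifelse(!is.na(tb$sire) & !is.na(tb$dam), "trio", "duo")
  tb
}

#' Read a known-population-variant list
#'
#' Tab-separated chrom, pos, ref, alt (with header). Every row is normalized
#' on read so that membership tests against normalized candidate keys are
#' exact.
#'
#' @param path known-variants TSV path.
#' @return data.frame with columns chrom, pos, ref, alt, key.
#' @export
read_known_variants <- function(path) {
  if (!file.exists(path)) abort_stage("read_known_variants", "no such file: ", path)
  tb <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  names(tb)[1:4] <- c("chrom", "pos", "ref", "alt")
  norm <- Map(normalize_allele_pair, as.integer(tb$pos),
              as.character(tb$ref), as.character(tb$alt))
  tb$pos <- vapply(norm, `[[`, 1L, "pos")
  tb$ref <- vapply(norm, `[[`, "", "ref")
  tb$alt <- vapply(norm, `[[`, "", "alt")
  tb$key <- variant_key(tb$chrom, tb$pos, tb$ref, tb$alt)
  tb
}

#' Read a per-locus depth table
#'
#' Tab-separated chrom, pos (1-based), sample, depth — the pipeline's
#' stand-in for BAM-derived site depth.
#'
#' @param path depth TSV path.
#' @return data.frame with columns chrom, pos, sample, depth.
#' @export
read_depth_table <- function(path) {
  if (!file.exists(path)) abort_stage("read_depth_table", "no such file: ", path)
  tb <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  names(tb)[1:4] <- c("chrom", "pos", "sample", "depth")
  tb$pos <- as.integer(tb$pos)
  tb$depth <- as.integer(tb$depth)
  if (any(tb$depth < 0, na.rm = TRUE))
    abort_stage("read_depth_table", "negative depth")
  tb
}

# -- normalization -----------------------------------------------------------

#' Normalize one REF/ALT allele pair
#'
#' Context-free minimal representation: shared trailing bases are trimmed
#' first, then shared leading bases (keeping at least one base in each
#' allele), with the position advanced per trimmed leading base. Idempotent.
#'
#' @param pos 1-based position.
#' @param ref REF allele.
#' @param alt one ALT allele.
#' @return list(pos, ref, alt).
#' @export
normalize_allele_pair <- function(pos, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (ref == alt)
    abort_stage("normalize", sprintf("REF equals ALT ('%s') - not a variant", ref))
  r <- strsplit(ref, "")[[1L]]; a <- strsplit(alt, "")[[1L]]
  # trim shared suffix
  while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]; a <- a[-length(a)]
  }
  # trim shared prefix, keeping >= 1 base each
  while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
    r <- r[-1L]; a <- a[-1L]; pos <- pos + 1L
  }
  if (paste(r, collapse = "") == paste(a, collapse = ""))
    abort_stage("normalize", "REF equals ALT after trimming - not a variant")
  list(pos = as.integer(pos), ref = paste(r, collapse = ""),
       alt = paste(a, collapse = ""))
}

#' Normalize a variant record
#'
#' Applies joint suffix/prefix trimming across REF and all ALT alleles of the
#' record (so multi-allelic sites stay aligned at one position). Genotype and
#' depth fields are unchanged.
#'
#' @param record a [variant_record()].
#' @return the normalized record.
#' @export
normalize_variant <- function(record) {
  alleles <- c(record$ref, record$alts)
  if (any(record$alts == record$ref))
    abort_stage("normalize", "REF equals an ALT - not a variant")
  split <- lapply(alleles, function(x) strsplit(x, "")[[1L]])
  pos <- record$pos
  repeat {
    lens <- lengths(split)
    last <- vapply(split, function(x) x[length(x)], "")
    if (all(lens > 1L) && length(unique(last)) == 1L)
      split <- lapply(split, function(x) x[-length(x)])
    else break
  }
  repeat {
    lens <- lengths(split)
    first <- vapply(split, `[[`, "", 1L)
    if (all(lens > 1L) && length(unique(first)) == 1L) {
      split <- lapply(split, function(x) x[-1L])
      pos <- pos + 1L
    } else break
  }
  alleles <- vapply(split, paste, "", collapse = "")
  record$pos <- as.integer(pos)
  record$ref <- alleles[1L]
  record$alts <- alleles[-1L]
  record
}

#' Canonical variant key
#'
#' `chrom:pos:ref:alt` built from a normalized allele pair; population
#' catalogue membership is exact equality on this key.
#'
#' @param chrom,pos,ref,alt vectors describing normalized variants.
#' @return character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, toupper(ref), toupper(alt), sep = ":")
}

#' Warn when a panel and a variant set share no chromosome
#'
#' Chromosome names are matched as exact strings; this guard catches the
#' common "chr18" vs "18" mismatch early.
#'
#' @param panel a panel data.frame.
#' @param vs a [variant_set()].
#' @return TRUE (invisibly) when at least one chromosome is shared.
#' @export
check_chromosome_overlap <- function(panel, vs) {
  vchrom <- unique(vapply(vs$records, `[[`, "", "chrom"))
  shared <- intersect(unique(panel$chrom), vchrom)
  if (length(vchrom) > 0L && length(shared) == 0L)
    warning("panel and variant set share zero chromosome names; check 'chr' prefixes",
            call. = FALSE)
  invisible(length(shared) > 0L)
}
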