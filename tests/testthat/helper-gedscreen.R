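# Shared fixtures and independent oracles for the test suite.

# Exhaustive-gamete Mendelian oracles, independent of the package's
# partition-based checkers: enumerate every transmissible gamete pair.
oracle_trio <- function(child, sire, dam) {
  if (any(is.na(c(child, sire, dam)))) return("no_call")
  for (s in sire) for (d in dam)
    if (setequal_multiset(c(s, d), child)) return("consistent")
  "inconsistent"
}

oracle_duo <- function(child, parent) {
  if (any(is.na(c(child, parent)))) return("no_call")
  for (p in parent) for (other in 0:1)
    if (setequal_multiset(c(p, other), child)) return("consistent")
  "inconsistent"
}

setequal_multiset <- function(a, b) identical(sort(a), sort(b))

# all unordered biallelic genotypes as allele-index pairs
biallelic_genotypes <- list(c(0L, 0L), c(0L, 1L), c(1L, 1L))

# write a small VCF from raw lines (header supplied)
write_vcf_text <- function(data_lines, samples = "s1") {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    data_lines), path)
  path
}

# random variant records for round-trip and fuzz properties
random_records <- function(n, samples, seed) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  lapply(seq_len(n), function(i) {
    ref <- paste(sample(bases, sample(1:4, 1), replace = TRUE), collapse = "")
    k <- sample(1:2, 1)
    alts <- unique(vapply(seq_len(k), function(.)
      paste(sample(bases, sample(1:4, 1), replace = TRUE), collapse = ""), ""))
    alts <- setdiff(alts, ref)
    if (length(alts) == 0L) alts <- paste0(ref, "T")
    calls <- lapply(samples, function(sm) {
      if (runif(1) < 0.15)
        return(list(gt = c(NA_integer_, NA_integer_), ad = NULL,
                    dp = NA_integer_))
      gt <- sort(sample(0:length(alts), 2, replace = TRUE))
      ad <- as.integer(sample(0:200, length(alts) + 1, replace = TRUE))
      list(gt = gt, ad = ad, dp = sum(ad) + sample(0:10, 1))
    })
    names(calls) <- samples
    variant_record(sample(c("chr1", "chr2", "chrX"), 1),
                   sample(1:5e6, 1), ref, alts, calls)
  })
}

# strip incidental fields so round-trip comparison is on the contract
record_essence <- function(r) {
  list(chrom = r$chrom, pos = r$pos, ref = r$ref, alts = r$alts,
       calls = r$calls[order(names(r$calls))])
}

# packaged panel (first six columns)
packaged_panel <- function() read_panel_table(packaged_panel_path())[, 1:6]

# packaged published inheritance tallies
table6_counts <- function() {
  utils::read.table(
    system.file("extdata", "table6_inheritance.tsv", package = "gedscreen",
                mustWork = TRUE),
    sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

# small genotype matrix built directly from allele matrices
gm_from <- function(samples, p_or_loci, a1, a2, depth = NULL) {
  loci <- if (is.data.frame(p_or_loci)) p_or_loci else
    data.frame(snv_id = sprintf("L%d", seq_along(p_or_loci)),
               chrom = "1", pos = seq_along(p_or_loci), ref = "A", alt = "G",
               ref_freq = p_or_loci, stringsAsFactors = FALSE)
  genotype_matrix(samples, loci, a1, a2, depth)
}
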