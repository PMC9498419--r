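Package: gedscreen
Title: Gene-Editing Screening and SNV Parentage Verification from Targeted
    Amplicon Resequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screening pipeline for detecting CRISPR/Cas9-style genome edits in
    targeted amplicon resequencing of racehorses, together with an SNV-based
    parentage verification analysis. Implements zygosity classification of
    variant calls (homozygous-alternative and compound-heterozygous INDEL
    candidates), a three-step candidate filter against a known population
    catalogue and site depth, per-exon amplicon coverage quality control,
    depth-aware genotyping with homozygous-reference recovery, Mendelian
    consistency checks for trio and single-parent pedigree configurations,
    per-locus and combined exclusion-power statistics (expected heterozygosity,
    PE1, PE2), and a fully seeded synthetic-data generator (Hardy-Weinberg
    genotypes, pedigrees, amplicon depth models, injected edits, genotyping
    faults) so every stage is testable without sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
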