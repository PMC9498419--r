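# gedscreen

Screening for gene doping — the creation of genetically modified racehorses —
from targeted amplicon resequencing data, together with an SNV-based
parentage-verification analysis.

CRISPR/Cas9 editing by nonhomologous end joining most readily produces short
INDELs on both chromosomes, so the practical signature of an engineered
animal is a **homozygous-alternative (HomoALT) or compound-heterozygous
(ALT1/ALT2) INDEL** at a locus where the population carries no such variant.
`gedscreen` takes the outputs of an upstream amplicon-sequencing pipeline
(VCF variant calls plus a per-site depth table standing in for BAM-derived
depth) and applies a three-step candidate filter:

1. **select** INDEL calls whose zygosity is HomoALT or ALT1/ALT2 —
   heterozygous REF/ALT INDELs and all SNVs are never candidates;
2. **exclude** variants already present in a known-population catalogue
   (exact match on a normalized `chrom:pos:ref:alt` key);
3. **exclude** variants at low site depth (strictly greater than 50× is
   required, the same standard used for genotype calling).

Every call retained or excluded is reported with its reason, so the stage-1
count always equals known-exclusions + low-depth-exclusions + final
candidates. Large deletions near amplicon boundaries sit in the upstream
caller's soft-clip blind spot; the screen annotates such candidates, and the
synthetic-data generator reproduces the dropout so the limitation is
testable.

The parentage side genotypes a 120-SNV panel (homozygous-reference calls are
recovered from site depth, since variant callers emit only non-reference
sites), checks Mendelian consistency for trio and single-parent designs, and
computes per-locus and combined exclusion power. For a biallelic locus with
REF-allele frequency *p* (*q* = 1 − *p*):

- expected heterozygosity  He = 2pq
- trio (one-parent-known) exclusion power  PE1 = pq(1 − pq)
- single-parent exclusion power  PE2 = 2p²q²
- combined across loci  PE = 1 − Π(1 − PEᵢ), reported truncated toward zero
  (conservative for a power claim).

A seeded synthetic-data generator (Hardy–Weinberg genotypes at the panel
frequencies, Mendelian pedigrees with pseudo-parent substitutions,
per-amplicon lognormal depth, CRISPR-style edit injection, genotyping
faults) makes the whole pipeline testable without sequencing data.

## Worked example

Generate the packaged validation design — twelve horses plus four edited
cell lines carrying the myostatin (*MSTN*) edits: three homozygous 1-bp
insertions and one heterozygous 77-bp deletion — and screen it:

```r
library(gedscreen)

dir <- file.path(tempdir(), "demo")
emit_dataset(preset_config("validation-2022"), dir)
ds <- load_dataset(dir)

report <- screen_edits(ds$vs, exons = ds$exons, known = ds$known,
                       depths = ds$depths, amplicons = ds$amplicons)
report
#> Edit screen report
#>   samples: 16; variant calls: 1343 (1321 SNV, 22 INDEL)
#>   stage 1 (HomoALT/ALT1-ALT2 INDELs): 11 call(s) at 11 locus/loci
#>   stage 2 excluded (known in population): 5
#>   stage 3 excluded (depth <= 50): 3
#>   final candidates: 3 call(s) at 3 locus/loci
#>  sample chrom      pos ref alt zygosity depth note
#>   cell2 chr18 66607750   C  CT  HomoALT   299
#>   cell3 chr18 66607753   T  TA  HomoALT   630
#>   cell4 chr18 66609936   T  TA  HomoALT   586
```

The three final candidates are exactly the engineered homozygous 1-bp
insertions; the four known HomoALT INDELs and the known ALT1/ALT2 INDEL were
removed at stage 2, three more at stage 3 for low depth, and the
heterozygous 77-bp deletion never reaches the screen — it is lost upstream
in the amplicon-end blind spot (recorded in the dataset's `truth.json`).

Exclusion power of the packaged parentage panel:

```r
pr <- panel_report(read_panel_table(packaged_panel_path())[, 1:6])
pr
#> Parentage panel: 120 SNVs
#>   combined PE1 (trio, truncated 10 dp): 0.9999999998
#>   combined PE2 (duo, truncated 6 dp):   0.999997
#>       snv_id chrom       pos ref alt ref_freq    He   PE1   PE2
#>  BIEC2-11336     1  24061861   C   T    0.582 0.487 0.184 0.118
#>  BIEC2-23891     1  58467370   T   C    0.847 0.259 0.113 0.034
#>  ...
```

A random nonbiological single parent is excluded, on average, by about ten
of the 120 SNVs, and the panel's combined single-parent exclusion power is
0.999997 — ample to identify a surrogate dam.

`run_pipeline()` chains coverage QC, panel genotyping, the screen and
parentage into one call (config as a list or YAML path) and returns exit
status 2 when candidates are found, for scriptable lab workflows.

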