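# popdiv

Population-genetic analysis of diploid resequencing variant panels —
the kind of data produced when a few hundred crop cultivars are
whole-genome resequenced and their SNPs and small InDels (< 50 bp)
called against a reference.  The package covers the analysis chain
downstream of variant calling:

* **Filtering** into the two standard SNP subsets: the *simple* set
  (biallelic, polymorphic SNPs) and the *core* set (missing rate ≤ 10%,
  heterozygosity rate ≤ 10%, minor allele frequency ≥ 2%), plus the
  scan for sites mutated in all accessions (missing rate strictly
  < 10%, every called genotype carrying an alternate allele).
* **Annotation** by genomic region (exon, UTR, intron, 5 kb
  upstream/downstream of the start/stop codon, intergenic) and by
  coding effect in sequence-ontology terms — synonymous_variant,
  missense_variant, stop_gained, stop_lost, initiator_codon_variant,
  frameshift_variant (with recomputed-ORF secondaries),
  conservative/disruptive inframe insertion/deletion, and
  bidirectional_gene_fusion for deletions bridging two opposite-strand
  genes — with ts/tv and syn/nonsyn summaries.
* **Diversity**: windowed nucleotide diversity
  π = Σ<sub>u&lt;v</sub> c<sub>u</sub>c<sub>v</sub> / C(n,2) per site
  (the without-replacement pairwise form; the raw
  Σ x<sub>i</sub>x<sub>j</sub>π<sub>ij</sub> form is a toggle), summed
  over 100 kb windows and divided by window length, and polymorphic
  information content
  PIC = 1 − Σ p²<sub>u</sub> − ΣΣ<sub>v>u</sub> 2p²<sub>u</sub>p²<sub>v</sub>,
  both reported per sub-population (accessions binned by year of
  release, SA…SE).
* **LD decay**: genotype-dosage r² for same-chromosome pairs within
  1 Mb, binned by distance, with the half-decay distance (where the
  curve first falls to half of its short-distance maximum).
* A **seeded simulator** — Hardy–Weinberg genotype panels with
  configurable frequency laws, missingness and inbreeding; haplotypes
  with exactly exponential LD decay r²(d) ≈ e^(−d/L); sub-populations
  with ordered diversity; and an annotated toy genome (FASTA + GFF3 +
  VCF) carrying at least one implant of every effect class with a
  machine-readable truth ledger — so the whole pipeline runs and is
  testable with no external data.

Data live in Bioconductor containers: genotypes in a `GenotypeMatrix`
(a `RangedSummarizedExperiment`), files read and written through
`VariantAnnotation`, `rtracklayer` and `Biostrings`.

## Worked example

```r
library(popdiv)

## simulate a two-period cultivar panel: an early, narrow-diversity group
## and a recent, broader one (selfing lines: inbreeding f = 0.95 default)
sim <- simulateSubpops(
  subpops = list(
    list(name = "SD", n_samples = 25,
         law = list(type = "uniform", min = 0.05, max = 0.25)),
    list(name = "SE", n_samples = 25,
         law = list(type = "uniform", min = 0.25, max = 0.50))),
  n_sites = 2000, missing_rate = 0.03, seed = 42)

gm <- coreFilter(simpleFilter(sim$gm))
gm
#> GenotypeMatrix: 1986 sites x 50 samples
#>   chromosomes: Chr01
#>   classes: SNP=1986
#>   missing calls: 2955 (2.98%)

subpopDiversity(gm, sim$meta, window = 100000, step = 10000)
#>   subpop accessions           pi pi_display       pic note
#> 1     SD         25 0.0002406463  0.2406463 0.2060824
#> 2     SE         25 0.0004385791  0.4385791 0.3423687
```

`pi` is per-bp diversity averaged over all 100 kb sliding windows;
`pi_display` is the same number in the × 10⁻³ units diversity tables
print; `pic` is the mean PIC over all loci.  The recent group (`SE`),
simulated from the broader frequency law, comes out roughly twice as
diverse — the ordering the simulator implanted.

```r
## LD decay on haplotypes with a known 100 kb length scale
ld <- simulateLdPanel(n_chrom = 20, sites_per_chrom = 25, spacing = 4000,
                      L = 1e5, n_haplotypes = 200, seed = 42)
curve <- ldCurve(ld, max_dist = 1e6, bin_width = 4000)
halfDecayDistance(curve) / 1000
#> [1] 72.9664
```

For r²(d) = e^(−d/L) the true half-decay distance is
L·ln 2 = 69.3 kb; a single 500-site panel estimates it to within a few
percent.

The full pipeline (simulate/load → filter → annotate → diversity → LD →
report) runs from one YAML config, writing `filtered.vcf`,
`annotation.tsv`, `windows.tsv`, `ld_curve.tsv`, `report.tsv` and
`report.txt` into the output directory:

```r
runPipeline("config.yaml")   # or a thin CLI: inst/scripts/popdiv run -c config.yaml
```

Identical config and seed reproduce the reports byte for byte.

See `vignettes/population-diversity.Rmd` for the estimator conventions,
default parameters and their origins, generator assumptions, and known
limitations.

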