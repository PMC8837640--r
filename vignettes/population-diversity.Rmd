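---
title: "Diversity, annotation and LD decay for resequencing panels: methods"
author: "popdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversity, annotation and LD decay for resequencing panels: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popdiv)
```

popdiv implements the desk-scale analysis chain used in crop
resequencing studies of cultivar panels: genotype filtering, variant
annotation, windowed nucleotide diversity and polymorphic information
content per breeding-period sub-population, and linkage-disequilibrium
decay.  This vignette is the package's account of the statistics it
computes, the choices made where a design was genuinely open, and what
the synthetic-data generator does and does not emulate.

## The data model

Genotypes live in a `GenotypeMatrix`, a `RangedSummarizedExperiment`
with two integer assays holding the unordered pair of allele indices of
each diploid call (`NA` for missing).  Multi-allelic records are kept at
parse time — the simple filter needs to see them — and only reduced
downstream.  Phase separators in the VCF are accepted and discarded:
every statistic here (allele-count diversity, genotype-dosage
r²) is phase-free, so phasing quality never enters.  Coordinates are
1-based closed throughout, the convention of the GRanges/IRanges stack
that handles all interval arithmetic; conversion to and from the file
formats is entirely inside `VariantAnnotation` and `rtracklayer`.

## SNP subset filters

Two nested subsets mirror standard practice:

* **Simple set** — biallelic, polymorphic SNPs.  "Polymorphic" is
  judged against the reference allele: a site at which every accession
  is homozygous-alternate is a fixed difference from the reference and
  *stays* (such sites are exactly what the mutated-in-all-samples scan
  looks for); a site where no call carries any alternate allele is
  monomorphic and is removed, as are sites showing two or more distinct
  alternate alleles.
* **Core set** — sites of the simple set with missing rate ≤ 10%,
  heterozygosity rate ≤ 10% and minor allele frequency ≥ 2%.  The three
  comparisons are inclusive, exactly as the thresholds are written.
  The het-rate denominator is the *called* genotypes, and MAF is
  computed over the alleles of called genotypes only (2 × called
  diploids); both conventions are stated here because tools differ and
  boundary sites (e.g. missing exactly 10%) switch sides under the
  alternatives.

The mutated-in-all detector uses a *strict* missing-rate bound
(< 10%) — deliberately different from the core filter's inclusive one,
following the wording of the two definitions — and counts a
heterozygous call as "showing a mutation" (it carries an alternate
allele); a homozygous-only mode is available as a flag.

## Variant annotation

Region labels (`exonic`, `utr5`, `utr3`, `intronic`, `upstream`,
`downstream`, `intergenic`) are anchored at the start and stop *codons*:
upstream is the 5 kb 5' of the start codon, downstream the 5 kb 3' of
the stop codon, strand-aware.  When a site touches features of several
genes the precedence exonic > UTR > intron > flank > intergenic decides
the single reported label; this precedence is a package choice (the
reporting convention in the literature leaves it implicit).

Coding effects use the standard nuclear genetic code with the CDS taken
to include the stop codon, one transcript per gene.  SNPs become
`synonymous_variant`, `missense_variant`, `stop_gained`, `stop_lost`, or
`initiator_codon_variant` when codon 1 loses its ATG.  InDels are
normalised first (shared suffix then prefix trimmed, so equivalent VCF
spellings classify identically); a length change that is not a multiple
of 3 is a `frameshift_variant`, and the mutated CDS is rebuilt and
rescanned to attach a secondary term — `start_lost` when the first codon
is no longer ATG, `stop_gained` when an in-frame stop appears before the
final codon, `stop_lost` when none remains.  In-frame InDels aligned on
codon boundaries are `conservative_inframe_insertion`/`_deletion`,
otherwise the `disruptive_` counterparts (reported separately; the
conservative classes are the ones the source taxonomy names).  A
deletion that bridges the coding spans of two adjacent genes is called a
fusion — `bidirectional_gene_fusion` when the genes face opposite
strands.  Impact grades are HIGH for stop/start/frameshift/fusion,
MODERATE for missense and in-frame, LOW for synonymous.

Transitions are A↔G and C↔T; the ts/tv and synonymous/non-synonymous
ratios flag (rather than throw on) empty denominators, since small
panels legitimately produce them.

## Nucleotide diversity

At one site with allele counts $c_u$ summing to $n$, diversity is the
average pairwise difference between sampled alleles.  The default
estimator draws pairs without replacement,

$$\pi_{\text{site}} = \frac{\sum_{u<v} c_u c_v}{\binom{n}{2}}
  = 2\hat p \hat q\,\frac{n}{n-1}\ \ (\text{biallelic}),$$

matching the convention of the standard windowed-π tools; the plain
frequency form $\sum_{ij} x_i x_j \pi_{ij} = 1-\sum_u \hat p_u^2$ (pairs
with replacement) is available as `estimator = "raw"`.  Under binomial
allele sampling at true frequency $p$ the without-replacement estimator
has expectation exactly $2p(1-p)$ — the $n/(n-1)$ correction cancels the
$\,(n-1)/n\,$ sampling factor — and the recovery tests use that exact
enumerated expectation as their oracle.

Windowed diversity sums site values over a window and divides by the
*window length in bp*, the per-bp scale on which diversity tables print
values × 10⁻³.  The window convention in the source methods is
internally contradictory ("no overlap" yet a 10 kb step for 100 kb
windows), so both modes exist: the default is sliding 100 kb / 10 kb,
`mode = "tiling"` gives non-overlapping windows, and reports name the
mode used.  Population π is the unweighted mean over all calculation
windows; population PIC is the unweighted mean over all loci with at
least one sampled allele (after the core filter no retained locus is
monomorphic panel-wide, but a locus can be monomorphic *within* a
sub-population and then contributes 0 to that sub-population's mean —
the averaged locus set is always the full input set, stated here
because the denominator choice changes the value).

## Polymorphic information content

$$PIC_l = 1 - \sum_u p_{lu}^2 - \sum_u \sum_{v>u} 2\,p_{lu}^2 p_{lv}^2$$

evaluated on observed allele frequencies, reaching its biallelic maximum
0.375 at $p = 0.5$.  Sub-population reports compute allele frequencies
from the sub-population's own columns (not global frequencies restricted
to a sample subset) — the natural reading when diversity is compared
*between* groups — and require at least 2 samples per group.

## LD decay

LD between two sites is the squared Pearson correlation of
alternate-allele dosages (0/1/2) over pairwise-complete samples —
composite LD, the standard phase-free choice when phasing is external.
Pairs on different chromosomes are ignored; same-chromosome pairs up to
1 Mb apart are averaged in left-closed distance bins (default 1 kb,
plain binning, no smoothing, so the estimator is deterministic and
brute-force checkable).  The decay reference level is the mean of the
first non-empty bin, and the half-decay distance is the linearly
interpolated distance where the binned curve first crosses half that
level; a curve that never crosses reports "undefined" rather than
extrapolating.  Because the reference level is a short — but nonzero —
distance bin, the estimator carries a small positive bias relative to a
true $r^2(d) = e^{-d/L}$ curve (the reference sits slightly below
$r^2(0)$); at the bin widths used here this is a few percent, and the
recovery test therefore compares the *mean* over 5 seeded replicates
against $L\ln 2$ at a 15% tolerance.  Sub-population curves are only
computed for groups of at least 20 samples (configurable), echoing the
practice of refusing LD estimates for very small groups.

## The synthetic-data generator

The generator exists so every stage has inputs with known truth:

* **Allele frequencies** — fixed, uniform, or a neutral SFS with
  $P(\text{count}=i) \propto 1/i$.
* **Genotypes** — Hardy–Weinberg draws per site with MCAR missingness
  and an inbreeding-style parameter $f$ (probability a call is forced
  homozygous), giving heterozygosity $2pq(1-f)$.  The sub-population
  simulator defaults to $f = 0.95$: the emulated material is a panel of
  *selfing cultivar lines*, whose residual heterozygosity is a few
  percent — with $f = 0$ almost every site would fail a 10% het filter,
  which is the filter working as designed on the wrong organism.
* **LD haplotypes** — a copying Markov chain: each allele is copied
  from the previous site with probability $e^{-d/2L}$, else redrawn,
  so allele correlation at distance $d$ is $e^{-d/2L}$ and dosage
  $r^2(d) \approx e^{-d/L}$ — a closed-form target a coalescent
  simulator would not give.  Multi-chromosome panels run independent
  chains; recovery tests use 20 chromosomes × 25 sites (the organism
  emulated has 20 chromosomes, and independent chains are what makes
  the binned curve's variance shrink).
* **Toy genome** — seven designed genes on one chromosome: mirrored
  plus/minus gene pairs carrying every SNP effect class and every InDel
  class, an adjacent opposite-strand pair bridged by a < 50 bp deletion
  (the fusion case), a two-exon gene, and one marker site per
  non-coding region class.  All reference CDSs are clean ORFs; every
  implant is recorded exactly once in a truth ledger, and the
  frameshift implants are built so their secondary term (an immediate
  designed stop) is knowable without running the annotator.
* **Sub-populations** — per-group frequency laws over shared sites,
  release years drawn inside each group's bin.

What the generator does **not** emulate: real site-frequency spectra
shaped by selection and bottlenecks, LD heterogeneity
(hotspots/centromeres), genotyping error correlated with depth,
multi-transcript genes, and splice-region effects.  Passing tests
therefore demonstrate correctness of the estimators and the pipeline
plumbing on data satisfying the stated models — not robustness to every
pathology of real resequencing data.

## Defaults and their origins

| parameter | default | origin |
|---|---|---|
| core filter | missing ≤ 0.10, het ≤ 0.10, MAF ≥ 0.02 | the study's stated thresholds |
| mutated-in-all missing bound | < 0.10 (strict) | stated definition |
| flank | 5 000 bp from start/stop codon | stated convention |
| InDel size | < 50 bp | stated definition |
| π window / step | 100 kb / 10 kb, sliding | stated window and step |
| LD window | 1 Mb, same chromosome | stated convention |
| LD bin width | 1 kb | package choice (unstated in source) |
| min. samples for subpop LD | 20 | echoes the refusal to estimate LD for groups of ≤ 12 |
| year bins | SA 1963–80, SB 1983–88, SC 1991–2000, SD 2001–10, SE 2011–17 | the diversity table's bins; the surrounding text disagrees on the SD/SE boundary (2001–2011 / 2011- or 2012–2017), so the bins are a config item with the table as default |
| subpop simulator `f` | 0.95 | selfing-crop biology (see above) |

## Numerical and degenerate-input choices

Undefined statistics are *flagged*, not fabricated: π at sites with
fewer than 2 sampled alleles, ts/tv with zero transversions, syn/nonsyn
with no non-synonymous calls, PIC with no sampled alleles, r² with
monomorphic partners or fewer than 2 complete pairs, half-decay on
curves that never cross — all return `NA` with a warning or message.
Filter thresholds outside [0, 1] and window/step ≤ 0 are configuration
errors.  Sites are always kept sorted by (chromosome, position) with
duplicate (chrom, pos, ref, alt) records rejected at construction.
Genes whose spliced CDS is not a multiple of 3 are flagged at parse time
and skipped (with a warning) by the effect caller.

Test and acceptance problem sizes (2 000 sites × 50 diploids for π
recovery, 500 sites × 200 haplotypes for LD recovery, 10 000 × 500 for
the filter sweep, 20 seeded replicates for the ordering check) are the
package's chosen desk-scale study conditions: large enough that
3-standard-error bands are decisive, small enough to run interactively.

## Known limitations

One transcript per gene (a worst-effect-wins multi-transcript rule is
documented but not implemented); effect calling annotates the first
alternate allele of multi-allelic records; no splice-site or regulatory
classes; no Watterson's θ, Tajima's D or F~ST~ (not part of the
emulated analysis); the pipeline holds the genotype matrix in memory,
which is ample at desk scale but would need chunking at
whole-genome-resequencing scale.
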