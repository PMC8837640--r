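#' @include GenotypeMatrix-class.R
NULL

#' Per-site quality statistics
#'
#' Computes, for one or all sites of a [GenotypeMatrix]:
#' \describe{
#'   \item{n_called}{non-missing diploid calls}
#'   \item{missing_rate}{`1 - n_called / n_samples`}
#'   \item{het_rate}{fraction of the *non-missing* calls that are
#'     heterozygous}
#'   \item{maf}{minor allele frequency: the second-largest allele
#'     frequency over the `2 * n_called` observed alleles (for a biallelic
#'     site, the frequency of the rarer allele)}
#'   \item{n_alleles}{number of distinct alleles observed in non-missing
#'     calls}
#' }
#' `het_rate` and `maf` are `NA` when no call is non-missing.
#'
#' @param x a [GenotypeMatrix].
#' @param sites integer indices of sites (default: all).
#' @return data.frame with one row per site, columns as above plus
#'   `chrom` and `pos`.
#' @export
siteStats <- function(x, sites = seq_len(nSites(x))) {
  a1 <- assay(x, "allele1")[sites, , drop = FALSE]
  a2 <- assay(x, "allele2")[sites, , drop = FALSE]
  n_samples <- ncol(x)
  n_called <- rowSums(!is.na(a1))
  het <- rowSums(a1 != a2, na.rm = TRUE)
  n_alt <- lengths(altAlleles(x))[sites]
  maf <- numeric(length(sites))
  n_alleles <- integer(length(sites))
  for (i in seq_along(sites)) {
    cnt <- tabulate(c(a1[i, ], a2[i, ]) + 1L, nbins = n_alt[i] + 1L)
    n <- sum(cnt)
    n_alleles[i] <- sum(cnt > 0L)
    maf[i] <- if (n == 0L) NA_real_ else {
      freqs <- sort(cnt / n, decreasing = TRUE)
      if (length(freqs) >= 2L) freqs[2L] else 0
    }
  }
  data.frame(
    chrom = siteChrom(x)[sites],
    pos = sitePos(x)[sites],
    n_called = n_called,
    missing_rate = (n_samples - n_called) / n_samples,
    het_rate = ifelse(n_called > 0L, het / n_called, NA_real_),
    maf = maf,
    n_alleles = n_alleles)
}

#' Observed allele counts at one site
#'
#' Tallies the alleles of all non-missing diploid calls at a site; each
#' heterozygote contributes one copy of each of its alleles.  These counts
#' carry the allele frequencies used by [sitePi()] and [locusPic()].
#'
#' @param x a [GenotypeMatrix].
#' @param site site index.
#' @return integer vector of counts for allele indices `0..n_alt`.
#' @export
alleleCounts <- function(x, site) {
  a1 <- assay(x, "allele1")[site, ]
  a2 <- assay(x, "allele2")[site, ]
  tabulate(c(a1, a2) + 1L, nbins = lengths(altAlleles(x))[site] + 1L)
}

#' Simple SNP subset: biallelic, polymorphic SNPs
#'
#' Keeps exactly the SNP sites that are polymorphic relative to the
#' reference and biallelic: at least one call carries an alternate
#' allele (a site where every call is homozygous reference is
#' monomorphic) and exactly one distinct alternate allele is observed
#' (the reference allele always counts as present, so a site fixed for
#' one alternate allele — mutated in every sample — is biallelic and is
#' retained; a site showing two different alternate alleles has more
#' than two alleles and is removed).  InDel sites are not part of this
#' subset; obtain them separately with `variantClassSubset(x, "InDel")`.
#'
#' @param x a [GenotypeMatrix].
#' @return the filtered [GenotypeMatrix] (SNPs only).
#' @seealso [coreFilter()] for the high-quality subset.
#' @export
simpleFilter <- function(x) {
  x[.simpleKeep(x), ]
}

.simpleKeep <- function(x) {
  a1 <- assay(x, "allele1")
  a2 <- assay(x, "allele2")
  n_obs_alt <- vapply(seq_len(nrow(a1)), function(i) {
    alleles <- c(a1[i, ], a2[i, ])
    length(unique(alleles[!is.na(alleles) & alleles > 0L]))
  }, integer(1))
  variantClass(x) == "SNP" & n_obs_alt == 1L
}

#' Core SNP subset: missingness, heterozygosity and MAF thresholds
#'
#' Applied after [simpleFilter()].  A site is retained iff
#' `missing_rate <= max_missing` and `het_rate <= max_het` and
#' `maf >= min_maf` (all comparisons inclusive, as the thresholds are
#' stated: missing and heterozygosity rate \eqn{\le} 10%, MAF \eqn{\ge}
#' 2%).
#'
#' @param x a [GenotypeMatrix], normally the simple-filtered SNP set.
#' @param max_missing,max_het,min_maf thresholds in `[0, 1]`.
#' @return the filtered [GenotypeMatrix].
#' @export
coreFilter <- function(x, max_missing = 0.10, max_het = 0.10,
                       min_maf = 0.02) {
  thr <- c(max_missing, max_het, min_maf)
  if (any(thr < 0) || any(thr > 1)) {
    stop("filter thresholds must lie in [0, 1]")
  }
  stats <- siteStats(x)
  keep <- stats$missing_rate <= max_missing &
    !is.na(stats$het_rate) & stats$het_rate <= max_het &
    !is.na(stats$maf) & stats$maf >= min_maf
  x[keep, ]
}

#' Per-chromosome site counts
#'
#' @param x a [GenotypeMatrix].
#' @return data.frame with columns `chrom` and `n_sites`; the counts sum
#'   to `nSites(x)`.
#' @export
chromCounts <- function(x) {
  if (nSites(x) == 0L) {
    return(data.frame(chrom = character(), n_sites = integer()))
  }
  tab <- table(siteChrom(x))
  data.frame(chrom = names(tab), n_sites = as.integer(tab),
             row.names = NULL)
}

#' Sites mutated in all samples
#'
#' Finds the sites at which the missing rate is *strictly* below
#' `max_missing_exclusive` and every non-missing call shows a mutation.
#' By default a heterozygous call counts as showing a mutation (the call
#' carries at least one alternate allele); `hom_alt_only = TRUE` requires
#' both alleles to be alternate.
#'
#' @param x a [GenotypeMatrix], normally the simple-filtered set.
#' @param max_missing_exclusive strict missing-rate bound (default 0.10).
#' @param hom_alt_only require homozygous-alternate calls.
#' @return integer vector of site indices.
#' @export
mutatedInAll <- function(x, max_missing_exclusive = 0.10,
                         hom_alt_only = FALSE) {
  a1 <- assay(x, "allele1")
  a2 <- assay(x, "allele2")
  missing_rate <- rowMeans(is.na(a1))
  mutated <- if (hom_alt_only) a1 > 0L & a2 > 0L else a2 > 0L
  all_mut <- rowSums(!mutated, na.rm = TRUE) == 0L &
    rowSums(!is.na(a1)) > 0L
  which(missing_rate < max_missing_exclusive & all_mut)
}

#' Filter report for a genotype matrix
#'
#' Evaluates the core-filter predicates per site and reports the verdict,
#' for writing as a TSV audit trail.
#'
#' @inheritParams coreFilter
#' @return data.frame with per-site statistics and a logical `retained`
#'   column.
#' @export
filterReport <- function(x, max_missing = 0.10, max_het = 0.10,
                         min_maf = 0.02) {
  stats <- siteStats(x)
  stats$retained <- stats$missing_rate <= max_missing &
    !is.na(stats$het_rate) & stats$het_rate <= max_het &
    !is.na(stats$maf) & stats$maf >= min_maf
  stats
}
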