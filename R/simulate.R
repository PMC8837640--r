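#' @include GenotypeMatrix-class.R
NULL

#' Draw per-site allele frequencies from a configured law
#'
#' Supported laws:
#' \describe{
#'   \item{fixed}{all sites at frequency `p`}
#'   \item{uniform}{i.i.d. uniform on `[min, max]`}
#'   \item{sfs}{neutral site-frequency spectrum: the alternate-allele
#'     *count* `i` over `n_alleles` sampled alleles is drawn with
#'     probability proportional to `1/i` for `i = 1 .. n_alleles - 1`,
#'     and the frequency is `i / n_alleles`}
#' }
#'
#' @param n_sites number of sites.
#' @param law list with element `type` (`"fixed"`, `"uniform"` or
#'   `"sfs"`) and its parameters: `p`; `min`, `max`; `n_alleles`.
#' @param seed optional integer seed.
#' @return numeric vector of alternate-allele frequencies.
#' @export
simulateFrequencies <- function(n_sites, law = list(type = "fixed", p = 0.3),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  switch(law$type,
    fixed = rep(law$p, n_sites),
    uniform = runif(n_sites, law$min, law$max),
    sfs = {
      n_all <- law$n_alleles
      i <- seq_len(n_all - 1L)
      counts <- sample(i, n_sites, replace = TRUE, prob = 1 / i)
      counts / n_all
    },
    stop("unknown frequency law: ", law$type))
}

#' Simulate Hardy-Weinberg diploid genotypes (linkage-free)
#'
#' Each site is an independent biallelic SNP: the two alleles of every
#' call are Bernoulli draws at the site's alternate-allele frequency
#' (Hardy-Weinberg genotype frequencies \eqn{p^2, 2pq, q^2}), optionally
#' distorted by an inbreeding-style coefficient `f` (probability that a
#' call is forced homozygous by drawing one allele and duplicating it,
#' giving heterozygosity \eqn{2pq(1-f)}).  Calls are then masked missing
#' completely at random at `missing_rate`.  REF/ALT bases are drawn
#' uniformly over distinct nucleotide pairs.
#'
#' The generator parameters are recorded in `metadata(x)$truth`.
#'
#' @param freqs per-site alternate-allele frequencies.
#' @param n_samples number of diploid samples.
#' @param missing_rate probability a call is missing.
#' @param f heterozygosity-deficit parameter in `[0, 1]` (default 0:
#'   Hardy-Weinberg).
#' @param chrom chromosome id.
#' @param positions site positions (default 1 kb spacing).
#' @param sample_prefix prefix for sample ids.
#' @param seed optional integer seed.
#' @return a [GenotypeMatrix].
#' @export
simulateGenotypes <- function(freqs, n_samples, missing_rate = 0, f = 0,
                              chrom = "Chr01", positions = NULL,
                              sample_prefix = "s", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(missing_rate >= 0, missing_rate <= 1, f >= 0, f <= 1)
  n_sites <- length(freqs)
  if (is.null(positions)) positions <- seq_len(n_sites) * 1000L
  ncall <- n_sites * n_samples
  pmat <- rep(freqs, times = n_samples)
  a1 <- matrix(rbinom(ncall, 1L, pmat), nrow = n_sites)
  a2 <- matrix(rbinom(ncall, 1L, pmat), nrow = n_sites)
  if (f > 0) {
    forced <- matrix(runif(ncall) < f, nrow = n_sites)
    a2[forced] <- a1[forced]
  }
  if (missing_rate > 0) {
    miss <- matrix(runif(ncall) < missing_rate, nrow = n_sites)
    a1[miss] <- NA_integer_
    a2[miss] <- NA_integer_
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  gm <- GenotypeMatrix(
    chrom = rep(chrom, n_sites), pos = positions,
    ref = ref, alt = as.list(unname(alt)),
    allele1 = a1, allele2 = a2,
    samples = paste0(sample_prefix, seq_len(n_samples)))
  metadata(gm)$truth <- list(freqs = freqs[order(positions)],
                             missing_rate = missing_rate, f = f)
  gm
}

#' Simulate haplotypes with exponentially decaying LD
#'
#' A copying Markov chain along each haplotype: the allele at the first
#' site is Bernoulli(`p`); at each subsequent site, at distance `d` from
#' the previous one, the previous allele is copied with probability
#' `exp(-d / (2 * L))` and otherwise redrawn Bernoulli(`p`).  The allele
#' correlation between sites at distance `d` is then `exp(-d / (2L))`, so
#' the r-squared between dosages decays as approximately `exp(-d / L)` —
#' an analytically known target for the LD estimators.
#'
#' @param positions sorted site positions (bp).
#' @param L LD length scale in bp.
#' @param n_haplotypes number of haplotypes.
#' @param p allele frequency (constant across sites).
#' @param seed optional integer seed.
#' @return 0/1 integer matrix, `n_haplotypes` x `length(positions)`.
#' @export
simulateLdHaplotypes <- function(positions, L, n_haplotypes, p = 0.5,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(L > 0, !is.unsorted(positions))
  S <- length(positions)
  hap <- matrix(0L, nrow = n_haplotypes, ncol = S)
  hap[, 1] <- rbinom(n_haplotypes, 1L, p)
  if (S > 1L) {
    copy_p <- exp(-diff(positions) / (2 * L))
    for (k in 2:S) {
      fresh <- rbinom(n_haplotypes, 1L, p)
      keep <- runif(n_haplotypes) < copy_p[k - 1L]
      hap[, k] <- ifelse(keep, hap[, k - 1L], fresh)
    }
  }
  hap
}

#' Pair haplotypes into a diploid GenotypeMatrix
#'
#' Random-mating diploids: haplotype rows (1,2), (3,4), ... become
#' samples.
#'
#' @param hap 0/1 haplotype matrix (rows = haplotypes, columns = sites).
#' @param positions site positions.
#' @param chrom chromosome id.
#' @return a [GenotypeMatrix] of biallelic A/G SNPs.
#' @export
haplotypesToGenotypes <- function(hap, positions, chrom = "Chr01") {
  stopifnot(nrow(hap) %% 2L == 0L)
  n_samples <- nrow(hap) %/% 2L
  a1 <- t(hap[seq(1L, nrow(hap), by = 2L), , drop = FALSE])
  a2 <- t(hap[seq(2L, nrow(hap), by = 2L), , drop = FALSE])
  n_sites <- ncol(hap)
  GenotypeMatrix(
    chrom = rep(chrom, n_sites), pos = positions,
    ref = rep("A", n_sites), alt = as.list(rep("G", n_sites)),
    allele1 = a1, allele2 = a2,
    samples = paste0("s", seq_len(n_samples)))
}

#' Simulate sub-populations with distinct frequency laws
#'
#' Draws, for each sub-population, its own per-site allele frequencies
#' from its configured law and Hardy-Weinberg genotypes for its samples,
#' merging everything into one matrix over shared site positions.
#' Release years are drawn uniformly inside each sub-population's year
#' bin.  The per-subpopulation frequency truth and the expected diversity
#' ordering are returned alongside.
#'
#' @param subpops list of lists with elements `name`, `n_samples`, `law`
#'   (see [simulateFrequencies()]) and optionally `years` (length-2
#'   `c(from, to)`); defaults to the bin of that name in `bins`.
#' @param n_sites number of shared sites.
#' @param missing_rate missing-call rate.
#' @param f heterozygosity-deficit (inbreeding) parameter in `[0, 1]`;
#'   the default 0.95 emulates a panel of selfing cultivar lines, whose
#'   residual heterozygosity is a few percent (`f = 0` gives
#'   Hardy-Weinberg proportions).
#' @param chrom chromosome id.
#' @param positions site positions (default 1 kb spacing).
#' @param bins year bins (see [defaultYearBins()]).
#' @param seed optional integer seed.
#' @return list with `gm` ([GenotypeMatrix]), `meta` (data.frame
#'   `sample`, `year`, `subpop`) and `truth` (per-subpop frequencies and
#'   expected heterozygosity).
#' @export
simulateSubpops <- function(subpops, n_sites, missing_rate = 0, f = 0.95,
                            chrom = "Chr01", positions = NULL,
                            bins = defaultYearBins(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(subpops) >= 2L)
  if (is.null(positions)) positions <- seq_len(n_sites) * 1000L
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  a1 <- NULL; a2 <- NULL
  samples <- character(); years <- integer(); labels <- character()
  truth <- list()
  for (sp in subpops) {
    freqs <- simulateFrequencies(n_sites, sp$law)
    ncall <- n_sites * sp$n_samples
    pm <- rep(freqs, times = sp$n_samples)
    m1 <- matrix(rbinom(ncall, 1L, pm), nrow = n_sites)
    m2 <- matrix(rbinom(ncall, 1L, pm), nrow = n_sites)
    if (f > 0) {
      forced <- matrix(runif(ncall) < f, nrow = n_sites)
      m2[forced] <- m1[forced]
    }
    if (missing_rate > 0) {
      miss <- matrix(runif(ncall) < missing_rate, nrow = n_sites)
      m1[miss] <- NA_integer_
      m2[miss] <- NA_integer_
    }
    a1 <- cbind(a1, m1); a2 <- cbind(a2, m2)
    ids <- paste0(sp$name, "_", seq_len(sp$n_samples))
    samples <- c(samples, ids)
    yr_range <- sp$years
    if (is.null(yr_range)) {
      row <- bins[bins$subpop == sp$name, ]
      if (nrow(row) == 0L) stop("no year bin known for subpop ", sp$name)
      yr_range <- c(row$from, row$to)
    }
    years <- c(years, sample(seq(yr_range[1], yr_range[2]), sp$n_samples,
                             replace = TRUE))
    labels <- c(labels, rep(sp$name, sp$n_samples))
    truth[[sp$name]] <- list(freqs = freqs,
                             expected_het = mean(2 * freqs * (1 - freqs)))
  }
  gm <- GenotypeMatrix(chrom = rep(chrom, n_sites), pos = positions,
                       ref = ref, alt = as.list(unname(alt)),
                       allele1 = a1, allele2 = a2, samples = samples)
  meta <- data.frame(sample = samples, year = years, subpop = labels,
                     stringsAsFactors = FALSE)
  metadata(gm)$truth <- truth
  list(gm = gm, meta = meta, truth = truth)
}

#' Simulate a multi-chromosome LD panel
#'
#' Runs [simulateLdHaplotypes()] independently on several chromosomes
#' (independent copying chains, mirroring the within-chromosome scope of
#' LD estimation) and pairs the haplotypes into one diploid
#' [GenotypeMatrix].  Independent chromosomes act as replicate
#' realisations of the decay curve, which stabilises the binned means.
#'
#' @param n_chrom number of chromosomes.
#' @param sites_per_chrom sites per chromosome.
#' @param spacing inter-site spacing in bp.
#' @param L LD length scale in bp.
#' @param n_haplotypes haplotypes per chromosome (2 x samples).
#' @param p allele frequency.
#' @param seed optional integer seed.
#' @return a [GenotypeMatrix] with `n_haplotypes / 2` samples.
#' @export
simulateLdPanel <- function(n_chrom, sites_per_chrom, spacing = 1000L,
                            L = 100000, n_haplotypes = 200L, p = 0.5,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pos <- seq(1L, by = as.integer(spacing), length.out = sites_per_chrom)
  a1 <- NULL; a2 <- NULL
  odd <- seq(1L, n_haplotypes, by = 2L)
  for (ch in seq_len(n_chrom)) {
    hap <- simulateLdHaplotypes(pos, L, n_haplotypes, p)
    a1 <- rbind(a1, t(hap[odd, , drop = FALSE]))
    a2 <- rbind(a2, t(hap[odd + 1L, , drop = FALSE]))
  }
  n_sites <- n_chrom * sites_per_chrom
  GenotypeMatrix(
    chrom = rep(sprintf("Chr%02d", seq_len(n_chrom)),
                each = sites_per_chrom),
    pos = rep(pos, n_chrom),
    ref = rep("A", n_sites), alt = as.list(rep("G", n_sites)),
    allele1 = a1, allele2 = a2,
    samples = paste0("s", seq_len(n_haplotypes %/% 2L)))
}
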