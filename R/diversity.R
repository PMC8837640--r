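#' @include site-filters.R
NULL

#' Per-site nucleotide diversity from allele counts
#'
#' Average pairwise difference between the sampled allele sequences at
#' one site.  With allele counts \eqn{c_u} summing to \eqn{n}, the
#' default (`estimator = "unbiased"`) is the mean 0/1 difference over all
#' \eqn{C(n,2)} unordered allele pairs drawn without replacement,
#' \deqn{\pi = \sum_{u<v} c_u c_v / \binom{n}{2},}
#' which equals \eqn{2pq\,n/(n-1)} at a biallelic site.  The
#' with-replacement form \eqn{\sum_{i j} x_i x_j \pi_{ij} = 1 - \sum_u
#' p_u^2} is available as `estimator = "raw"`.
#'
#' @param counts integer vector of per-allele counts at the site (as from
#'   [alleleCounts()]).
#' @param estimator `"unbiased"` (without replacement; default) or
#'   `"raw"` (with replacement).
#' @return the site diversity in `[0, 1]`; `NA` with a warning when fewer
#'   than 2 alleles were sampled.
#' @export
sitePi <- function(counts, estimator = c("unbiased", "raw")) {
  estimator <- match.arg(estimator)
  n <- sum(counts)
  if (n < 2L) {
    warning("site has fewer than 2 sampled alleles; pi undefined")
    return(NA_real_)
  }
  same <- sum(counts * (counts - 1))  # ordered identical pairs
  if (estimator == "unbiased") {
    (n * n - sum(counts^2)) / (n * (n - 1))
  } else {
    1 - sum((counts / n)^2)
  }
}

#' Polymorphic information content of one locus
#'
#' Evaluates
#' \deqn{PIC_l = 1 - \sum_u p_{lu}^2 - \sum_u \sum_{v>u} 2 p_{lu}^2
#'   p_{lv}^2}
#' on the observed allele frequencies \eqn{p_{lu}} of the locus.
#'
#' @param counts integer vector of per-allele counts (or, with
#'   `freq = TRUE`, allele frequencies summing to 1).
#' @param freq interpret `counts` as frequencies.
#' @return PIC value; 0 for a monomorphic locus; `NA` with a warning when
#'   no allele was sampled.
#' @export
locusPic <- function(counts, freq = FALSE) {
  if (freq) {
    p <- counts
  } else {
    n <- sum(counts)
    if (n == 0L) {
      warning("locus has no sampled alleles; PIC undefined")
      return(NA_real_)
    }
    p <- counts / n
  }
  s2 <- sum(p^2)
  s4 <- sum(p^4)
  1 - s2 - (s2^2 - s4)
}

## per-site pi for every site of a matrix (vectorised allele tallies)
.sitePiAll <- function(x, estimator = "unbiased") {
  a1 <- assay(x, "allele1")
  a2 <- assay(x, "allele2")
  n_alt <- lengths(altAlleles(x))
  vapply(seq_len(nrow(a1)), function(i) {
    cnt <- tabulate(c(a1[i, ], a2[i, ]) + 1L, nbins = n_alt[i] + 1L)
    if (sum(cnt) < 2L) return(NA_real_)
    sitePi(cnt, estimator)
  }, numeric(1))
}

#' Windowed nucleotide diversity along the genome
#'
#' Sums per-site diversity over windows and divides by the *window length
#' in bp*, giving per-bp diversity on the scale conventionally reported
#' as \eqn{\times 10^{-3}}.  Windows of `window` bp advance by `step` bp
#' (sliding mode; the default 100 kb / 10 kb); `mode = "tiling"` forces
#' `step = window` (non-overlapping).  Sites with fewer than 2 sampled
#' alleles are skipped.
#'
#' @param x a [GenotypeMatrix].
#' @param window window length in bp.
#' @param step step length in bp (ignored in tiling mode).
#' @param mode `"sliding"` or `"tiling"`.
#' @param chromLengths named integer vector of chromosome lengths;
#'   defaults to the last site position per chromosome.
#' @param estimator passed to [sitePi()].
#' @return data.frame with columns `chrom`, `start`, `end`, `n_sites`,
#'   `pi` (per bp); empty windows have `pi = 0`.
#' @export
windowedPi <- function(x, window = 100000L, step = 10000L,
                       mode = c("sliding", "tiling"),
                       chromLengths = NULL,
                       estimator = c("unbiased", "raw")) {
  mode <- match.arg(mode)
  estimator <- match.arg(estimator)
  if (window <= 0L || step <= 0L) stop("window and step must be positive")
  if (mode == "tiling") step <- window
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_sites = integer(), pi = numeric())
  if (nSites(x) == 0L) return(empty)
  chrom <- siteChrom(x)
  pos <- sitePos(x)
  pis <- .sitePiAll(x, estimator)
  if (is.null(chromLengths)) {
    chromLengths <- vapply(split(pos, chrom), max, integer(1))
  }
  out <- list()
  for (ch in names(chromLengths)) {
    len <- chromLengths[[ch]]
    starts <- seq.int(1L, max(1L, len), by = step)
    ends <- starts + window - 1L
    idx <- which(chrom == ch & !is.na(pis))
    p <- pos[idx]; v <- pis[idx]
    n_sites <- integer(length(starts))
    pi_sum <- numeric(length(starts))
    for (w in seq_along(starts)) {
      inw <- p >= starts[w] & p <= ends[w]
      n_sites[w] <- sum(inw)
      pi_sum[w] <- sum(v[inw])
    }
    out[[ch]] <- data.frame(chrom = ch, start = starts, end = ends,
                            n_sites = n_sites, pi = pi_sum / window)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Population-level diversity summaries
#'
#' `populationPi` averages window diversity values (unweighted) over all
#' calculation windows on the genome; `populationPic` averages
#' [locusPic()] over all loci with at least one sampled allele.
#'
#' @param windows data.frame from [windowedPi()].
#' @return a single number.
#' @export
populationPi <- function(windows) {
  if (nrow(windows) == 0L) stop("no calculation windows")
  mean(windows$pi)
}

#' @rdname populationPi
#' @param x a [GenotypeMatrix].
#' @export
populationPic <- function(x) {
  a1 <- assay(x, "allele1")
  a2 <- assay(x, "allele2")
  n_alt <- lengths(altAlleles(x))
  pics <- vapply(seq_len(nrow(a1)), function(i) {
    cnt <- tabulate(c(a1[i, ], a2[i, ]) + 1L, nbins = n_alt[i] + 1L)
    if (sum(cnt) == 0L) return(NA_real_)
    locusPic(cnt)
  }, numeric(1))
  usable <- !is.na(pics)
  if (!any(usable)) stop("no usable loci for PIC")
  mean(pics[usable])
}

#' Sub-population diversity report
#'
#' Computes, for every sub-population with at least `min_samples`
#' samples, the number of accessions, the genome-wide average windowed
#' nucleotide diversity and the average PIC, using the sub-population's
#' own columns and allele counts only.  Sub-populations below the minimum
#' are excluded with a warning and listed with a reason.
#'
#' @param x a [GenotypeMatrix] (normally the core SNP set).
#' @param meta data.frame with columns `sample` and `subpop` (see
#'   [readSampleMeta()]).
#' @param min_samples minimum samples per sub-population (default 2).
#' @param ... passed to [windowedPi()] (window, step, mode,
#'   chromLengths).
#' @return data.frame with columns `subpop`, `accessions`, `pi`,
#'   `pi_display` (pi in units of 1e-3), `pic`, `note`.
#' @export
subpopDiversity <- function(x, meta, min_samples = 2L, ...) {
  meta <- meta[!is.na(meta$subpop), , drop = FALSE]
  subpops <- unique(meta$subpop)
  rows <- list()
  for (sp in subpops) {
    ids <- meta$sample[meta$subpop == sp]
    ids <- intersect(ids, sampleNames(x))
    if (length(ids) < min_samples) {
      warning("sub-population ", sp, " has fewer than ", min_samples,
              " samples; excluded")
      rows[[sp]] <- data.frame(subpop = sp, accessions = length(ids),
                               pi = NA_real_, pi_display = NA_real_,
                               pic = NA_real_,
                               note = "excluded: too few samples")
      next
    }
    sub <- x[, ids]
    win <- windowedPi(sub, ...)
    pi <- populationPi(win)
    pic <- populationPic(sub)
    rows[[sp]] <- data.frame(subpop = sp, accessions = length(ids),
                             pi = pi, pi_display = pi * 1e3, pic = pic,
                             note = "")
  }
  res <- do.call(rbind, rows[order(names(rows))])
  rownames(res) <- NULL
  res
}
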