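#' @include GenotypeMatrix-class.R
NULL

#' LDCurve: distance-binned linkage-disequilibrium decay curve
#'
#' Holds the mean genotype-dosage r-squared of same-chromosome site pairs
#' in left-closed distance bins, the reference "maximum" level (the mean
#' of the first non-empty bin) and the pair count per bin.
#'
#' @slot bins data.frame with columns `bin_start`, `bin_end` (bp,
#'   left-closed `[bin_start, bin_end)`), `distance` (bin midpoint, bp),
#'   `n_pairs`, `mean_r2`.
#' @slot maxDist maximum pair distance considered (bp).
#'
#' @seealso [ldCurve()], [halfDecayDistance()]
#' @export
setClass("LDCurve",
         representation(bins = "data.frame", maxDist = "numeric"))

setValidity("LDCurve", function(object) {
  b <- object@bins
  need <- c("bin_start", "bin_end", "distance", "n_pairs", "mean_r2")
  if (!all(need %in% names(b))) {
    return(paste("bins needs columns:", paste(need, collapse = ", ")))
  }
  if (nrow(b) && is.unsorted(b$distance)) return("bins must be ordered")
  ok <- is.na(b$mean_r2) | (b$mean_r2 >= 0 & b$mean_r2 <= 1 + 1e-12)
  if (!all(ok)) return("mean r2 must lie in [0, 1]")
  if (any(b$n_pairs < 0)) return("pair counts must be >= 0")
  TRUE
})

#' Construct an LDCurve from binned values
#'
#' @param distance bin representative distances (bp), increasing.
#' @param mean_r2 mean r-squared per bin.
#' @param n_pairs pair count per bin.
#' @param bin_start,bin_end optional bin edges; default a zero-width bin
#'   at `distance`.
#' @param maxDist maximum pair distance (default the last bin end).
#' @return an [LDCurve].
#' @export
LDCurve <- function(distance, mean_r2, n_pairs = rep(1L, length(distance)),
                    bin_start = distance, bin_end = distance,
                    maxDist = max(bin_end)) {
  new("LDCurve",
      bins = data.frame(bin_start = bin_start, bin_end = bin_end,
                        distance = distance, n_pairs = n_pairs,
                        mean_r2 = mean_r2),
      maxDist = as.numeric(maxDist))
}

#' @describeIn LDCurve bins with at least one defined pair.
#' @param x an `LDCurve`.
#' @export
ldBins <- function(x) x@bins[x@bins$n_pairs > 0L, , drop = FALSE]

#' @describeIn LDCurve reference maximum: mean r-squared of the first
#'   non-empty bin.
#' @export
maxR2 <- function(x) {
  b <- ldBins(x)
  if (nrow(b) == 0L) NA_real_ else b$mean_r2[1]
}

setMethod("show", "LDCurve", function(object) {
  b <- ldBins(object)
  cat("LDCurve:", nrow(b), "non-empty bins,",
      sum(b$n_pairs), "pairs, max r2 =",
      format(maxR2(object), digits = 3), "\n")
})

#' Squared dosage correlation between two sites
#'
#' The squared Pearson correlation of alternate-allele dosage vectors
#' over samples where both calls are non-missing (composite,
#' phase-free LD).
#'
#' @param a,b numeric vectors of per-sample dosages (0/1/2, `NA`
#'   missing).
#' @return r-squared in `[0, 1]`, or `NA` when fewer than 2 complete
#'   pairs remain or either site is monomorphic among them.
#' @export
pairwiseR2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2L) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  cor(a, b)^2
}

#' Linkage-disequilibrium decay curve
#'
#' Computes dosage r-squared for every same-chromosome site pair at
#' distance `1..max_dist` bp (pairs on different chromosomes are
#' ignored), and averages the defined values in left-closed distance bins
#' of `bin_width` bp.
#'
#' @param x a [GenotypeMatrix] (biallelic SNPs recommended).
#' @param max_dist maximum pair distance in bp (default 1 Mb).
#' @param bin_width distance bin width in bp (default 1 kb).
#' @return an [LDCurve]; empty (no bins with pairs) when no valid pair
#'   exists.
#' @export
ldCurve <- function(x, max_dist = 1000000L, bin_width = 1000L) {
  if (max_dist <= 0L || bin_width <= 0L) {
    stop("max_dist and bin_width must be positive")
  }
  n_bins <- as.integer(ceiling(max_dist / bin_width))
  sums <- numeric(n_bins)
  counts <- integer(n_bins)
  dos <- altDosage(x)
  chrom <- siteChrom(x)
  pos <- sitePos(x)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    if (length(idx) < 2L) next
    m <- t(dos[idx, , drop = FALSE])  # samples x sites
    r2 <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))^2
    p <- pos[idx]
    d <- abs(outer(p, p, "-"))
    ut <- upper.tri(d)
    sel <- ut & d >= 1L & d <= max_dist & !is.na(r2)
    if (!any(sel)) next
    bin <- as.integer((d[sel] - 1L) %/% bin_width + 1L)
    sums <- sums + vapply(seq_len(n_bins), function(k) sum(r2[sel][bin == k]),
                          numeric(1))
    counts <- counts + tabulate(bin, nbins = n_bins)
  }
  bin_start <- (seq_len(n_bins) - 1L) * bin_width
  bin_end <- bin_start + bin_width
  mean_r2 <- ifelse(counts > 0L, sums / pmax(counts, 1L), NA_real_)
  new("LDCurve",
      bins = data.frame(bin_start = bin_start, bin_end = bin_end,
                        distance = (bin_start + bin_end) / 2,
                        n_pairs = counts, mean_r2 = mean_r2),
      maxDist = as.numeric(max_dist))
}

#' Half-decay distance of an LD curve
#'
#' The physical distance at which the binned mean r-squared first falls
#' to half of its maximum, the maximum being the mean of the shortest
#' distance bin.  The crossing is located by linear interpolation between
#' the two bracketing bins (at their representative distances); `NA`
#' with a message when the curve never drops below half its maximum
#' within the curve's range.
#'
#' @param x an [LDCurve].
#' @param ... unused.
#' @return distance in bp, or `NA` when undefined.
#' @export
setMethod("halfDecayDistance", "LDCurve", function(x, ...) {
  b <- ldBins(x)
  if (nrow(b) == 0L) return(NA_real_)
  y <- b$mean_r2
  d <- b$distance
  half <- y[1] / 2
  below <- which(y <= half)
  if (length(below) == 0L) {
    message("LD curve never decays to half of its maximum; ",
            "half-decay distance undefined")
    return(NA_real_)
  }
  k <- below[1]
  if (k == 1L) return(d[1])
  d[k - 1L] + (d[k] - d[k - 1L]) * (y[k - 1L] - half) / (y[k - 1L] - y[k])
})
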