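# Independent brute-force oracles and small fixture builders.
# These deliberately avoid the package's own code paths wherever the test
# compares against them.

suppressPackageStartupMessages({
  library(SummarizedExperiment)
})

# Build a GenotypeMatrix from genotype strings ("0/0", "0/1", "./.", ...)
# given as a sites x samples character matrix.
gmFromStrings <- function(gt, chrom = rep("Chr01", nrow(gt)),
                          pos = seq_len(nrow(gt)) * 100L,
                          ref = rep("A", nrow(gt)),
                          alt = as.list(rep("G", nrow(gt))),
                          samples = paste0("s", seq_len(ncol(gt)))) {
  split1 <- function(g, k) {
    p <- strsplit(g, "/", fixed = TRUE)[[1]]
    if (any(p == ".")) NA_integer_ else as.integer(p[k])
  }
  a1 <- apply(gt, c(1, 2), split1, k = 1L)
  a2 <- apply(gt, c(1, 2), split1, k = 2L)
  GenotypeMatrix(chrom = chrom, pos = pos, ref = ref, alt = alt,
                 allele1 = a1, allele2 = a2, samples = samples)
}

# Exhaustive pairwise-difference pi over individual alleles at one site.
brutePi <- function(alleles) {
  alleles <- alleles[!is.na(alleles)]
  n <- length(alleles)
  if (n < 2) return(NA_real_)
  pairs <- utils::combn(n, 2)
  mean(alleles[pairs[1, ]] != alleles[pairs[2, ]])
}

# Direct textbook evaluation of the PIC formula with explicit double sum.
brutePic <- function(p) {
  s <- 1 - sum(p^2)
  for (u in seq_along(p)) {
    for (v in seq_along(p)) {
      if (v > u) s <- s - 2 * p[u]^2 * p[v]^2
    }
  }
  s
}

# O(S^2) double-loop LD curve oracle on raw dosage vectors.
bruteLdBins <- function(dos, chrom, pos, max_dist, bin_width) {
  n_bins <- ceiling(max_dist / bin_width)
  sums <- numeric(n_bins)
  counts <- integer(n_bins)
  S <- nrow(dos)
  for (i in seq_len(S - 1)) {
    for (j in (i + 1):S) {
      if (chrom[i] != chrom[j]) next
      d <- abs(pos[j] - pos[i])
      if (d < 1 || d > max_dist) next
      ok <- !is.na(dos[i, ]) & !is.na(dos[j, ])
      if (sum(ok) < 2) next
      x <- dos[i, ok]; y <- dos[j, ok]
      if (var(x) == 0 || var(y) == 0) next
      b <- (d - 1) %/% bin_width + 1
      sums[b] <- sums[b] + cor(x, y)^2
      counts[b] <- counts[b] + 1L
    }
  }
  list(mean_r2 = ifelse(counts > 0, sums / pmax(counts, 1), NA_real_),
       n_pairs = counts)
}

# Per-site filter statistics recomputed from scratch on the assay
# matrices (the oracle for the filter-equivalence tests).
bruteSiteVerdicts <- function(a1, a2, max_missing = 0.10, max_het = 0.10,
                              min_maf = 0.02) {
  S <- nrow(a1)
  n <- ncol(a1)
  out <- data.frame(simple = logical(S), core = logical(S),
                    mut_all = logical(S))
  for (i in seq_len(S)) {
    x1 <- a1[i, ]; x2 <- a2[i, ]
    called <- !is.na(x1)
    miss_rate <- sum(!called) / n
    alleles <- c(x1[called], x2[called])
    obs_alt <- unique(alleles[alleles > 0])
    out$simple[i] <- length(obs_alt) == 1
    het_rate <- if (sum(called) > 0) {
      sum(x1[called] != x2[called]) / sum(called)
    } else NA_real_
    maf <- if (length(alleles) > 0) {
      f <- sort(table(factor(alleles, levels = 0:max(1, alleles))) /
                  length(alleles), decreasing = TRUE)
      if (length(f) >= 2) as.numeric(f[2]) else 0
    } else NA_real_
    out$core[i] <- out$simple[i] && !is.na(het_rate) && !is.na(maf) &&
      miss_rate <= max_missing && het_rate <= max_het && maf >= min_maf
    out$mut_all[i] <- out$simple[i] && miss_rate < 0.10 &&
      sum(called) > 0 && all(x2[called] > 0)
  }
  out
}
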