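test_that("frequency laws are honoured and seeded draws reproduce", {
  expect_equal(simulateFrequencies(5, list(type = "fixed", p = 0.3)),
               rep(0.3, 5))
  f1 <- simulateFrequencies(100, list(type = "uniform", min = 0.1, max = 0.4),
                            seed = 5)
  f2 <- simulateFrequencies(100, list(type = "uniform", min = 0.1, max = 0.4),
                            seed = 5)
  expect_identical(f1, f2)
  expect_true(all(f1 >= 0.1 & f1 <= 0.4))
  expect_error(simulateFrequencies(5, list(type = "zipf")), "unknown")
})

test_that("the neutral SFS law draws counts proportional to 1/i", {
  n_all <- 20L
  f <- simulateFrequencies(40000, list(type = "sfs", n_alleles = n_all),
                           seed = 8)
  counts <- round(f * n_all)
  obs <- tabulate(counts, nbins = n_all - 1L)
  i <- seq_len(n_all - 1L)
  expected <- (1 / i) / sum(1 / i) * length(f)
  chi2 <- sum((obs - expected)^2 / expected)
  ## 18 df; 99.9th percentile ~ 42.3
  expect_lt(chi2, stats::qchisq(0.999, df = n_all - 2L))
})

test_that("genotype marginals match Hardy-Weinberg and the missing rate", {
  p <- 0.5; n <- 400L; S <- 500L
  gm <- simulateGenotypes(rep(p, S), n_samples = n, missing_rate = 0.07,
                          seed = 2)
  a1 <- assay(gm, "allele1"); a2 <- assay(gm, "allele2")
  miss <- mean(is.na(a1))
  se_miss <- sqrt(0.07 * 0.93 / length(a1))
  expect_lt(abs(miss - 0.07), 3 * se_miss)
  het <- mean(a1 != a2, na.rm = TRUE)
  n_called <- sum(!is.na(a1))
  expect_lt(abs(het - 2 * p * (1 - p)), 3 * sqrt(0.25 / n_called))
  ## missing rate 0 gives no missing calls
  gm0 <- simulateGenotypes(rep(p, 10), n_samples = 5, seed = 3)
  expect_false(anyNA(assay(gm0, "allele1")))
})

test_that("the inbreeding parameter suppresses heterozygosity", {
  gm <- simulateGenotypes(rep(0.5, 300), n_samples = 100, f = 0.9, seed = 6)
  a1 <- assay(gm, "allele1"); a2 <- assay(gm, "allele2")
  het <- mean(a1 != a2)
  ## expected 2pq(1-f) = 0.05
  expect_lt(abs(het - 0.05), 3 * sqrt(0.05 * 0.95 / length(a1)))
})

test_that("LD chain approaches independence and perfect linkage limits", {
  pos <- c(1, 1001)
  hap_lo <- simulateLdHaplotypes(pos, L = 1, n_haplotypes = 4000, seed = 4)
  r_lo <- cor(hap_lo[, 1], hap_lo[, 2])^2
  expect_lt(r_lo, 0.01)   # 1/n-level noise
  hap_hi <- simulateLdHaplotypes(pos, L = 1e9, n_haplotypes = 400, seed = 4)
  expect_gt(cor(hap_hi[, 1], hap_hi[, 2])^2, 0.99)
})

test_that("toy genome generation is byte-identical under a fixed seed", {
  d1 <- file.path(tempdir(), "toyA")
  d2 <- file.path(tempdir(), "toyB")
  makeToyGenome(seed = 12, out_dir = d1)
  makeToyGenome(seed = 12, out_dir = d2)
  for (f in c("genome.fasta", "genes.gff3", "variants.vcf", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  ## a different seed changes the sequence
  d3 <- file.path(tempdir(), "toyC")
  makeToyGenome(seed = 13, out_dir = d3)
  expect_false(identical(readLines(file.path(d1, "genome.fasta")),
                         readLines(file.path(d3, "genome.fasta"))))
})

test_that("every implanted variant appears once in VCF and truth", {
  toy <- makeToyGenome(seed = 19)
  expect_identical(anyDuplicated(toy$truth$pos), 0L)
  expect_identical(nSites(toy$gm), nrow(toy$truth))
  expect_identical(sitePos(toy$gm), toy$truth$pos)
  ## every coding effect class in scope is exercised
  expect_true(all(c("synonymous_variant", "missense_variant", "stop_gained",
                    "stop_lost", "initiator_codon_variant",
                    "frameshift_variant", "conservative_inframe_insertion",
                    "conservative_inframe_deletion",
                    "bidirectional_gene_fusion") %in% toy$truth$so_term))
  ## reference CDSs are clean ORFs
  for (g in toy$genes) {
    aa <- as.character(Biostrings::translate(cdsSequence(g, toy$genome)))
    expect_identical(substr(aa, 1, 1), "M")
    expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE))
  }
})

test_that("sub-population simulation respects laws, years and diversity order", {
  subpops <- list(
    list(name = "SB", n_samples = 15,
         law = list(type = "uniform", min = 0.02, max = 0.15)),
    list(name = "SD", n_samples = 15,
         law = list(type = "uniform", min = 0.3, max = 0.5)))
  sim <- simulateSubpops(subpops, n_sites = 400, missing_rate = 0.02,
                         seed = 14)
  expect_identical(ncol(sim$gm), 30L)
  bins <- defaultYearBins()
  for (sp in c("SB", "SD")) {
    yrs <- sim$meta$year[sim$meta$subpop == sp]
    row <- bins[bins$subpop == sp, ]
    expect_true(all(yrs >= row$from & yrs <= row$to))
  }
  ## the high-diversity law must come out more diverse
  rep2 <- subpopDiversity(sim$gm, sim$meta, window = 100000L,
                          mode = "tiling")
  expect_gt(rep2$pi[rep2$subpop == "SD"], rep2$pi[rep2$subpop == "SB"])
  expect_gt(rep2$pic[rep2$subpop == "SD"], rep2$pic[rep2$subpop == "SB"])
})

test_that("identical subpopulation laws are statistically indistinguishable", {
  law <- list(type = "uniform", min = 0.1, max = 0.4)
  subpops <- list(list(name = "SD", n_samples = 20, law = law),
                  list(name = "SE", n_samples = 20, law = law))
  sim <- simulateSubpops(subpops, n_sites = 600, seed = 15)
  ## per-site pi difference between the groups, against its own SE
  ids_d <- sim$meta$sample[sim$meta$subpop == "SD"]
  ids_e <- sim$meta$sample[sim$meta$subpop == "SE"]
  pi_of <- function(ids) {
    sub <- sim$gm[, ids]
    vapply(seq_len(nSites(sub)),
           function(i) sitePi(alleleCounts(sub, i)), numeric(1))
  }
  dd <- pi_of(ids_d) - pi_of(ids_e)
  expect_lt(abs(mean(dd)), 3 * stats::sd(dd) / sqrt(length(dd)))
})
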