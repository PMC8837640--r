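test_that("sitePi matches hand-enumerated pair counts", {
  expect_equal(sitePi(c(8, 0)), 0)            # monomorphic
  expect_equal(sitePi(c(4, 4)), 16 / 28)      # 16 of 28 pairs differ
  expect_equal(sitePi(c(2, 2, 2)), 0.8)       # 12 of 15 pairs differ
  expect_equal(sitePi(c(4, 4), estimator = "raw"), 0.5)
  expect_warning(p <- sitePi(c(1, 0)), "fewer than 2")
  expect_true(is.na(p))
})

test_that("sitePi equals the exhaustive pairwise oracle", {
  set.seed(3)
  for (rep in 1:60) {
    n <- sample(2:20, 1)
    k <- sample(2:4, 1)
    alleles <- sample(0:(k - 1), n, replace = TRUE)
    counts <- tabulate(alleles + 1L, nbins = k)
    expect_equal(sitePi(counts), brutePi(alleles), tolerance = 1e-14)
  }
})

test_that("locusPic evaluates the printed formula", {
  expect_equal(locusPic(c(6, 0)), 0)
  expect_equal(locusPic(c(4, 4)), 0.375, tolerance = 1e-12)
  expect_equal(locusPic(c(0.9, 0.1), freq = TRUE), 0.1638, tolerance = 1e-12)
  expect_equal(locusPic(c(2, 2, 2)), 16 / 27, tolerance = 1e-12)
  ## against the explicit double-sum oracle at random frequency vectors
  set.seed(4)
  for (rep in 1:40) {
    k <- sample(2:5, 1)
    p <- as.vector(stats::rgamma(k, 1)); p <- p / sum(p)
    expect_equal(locusPic(p, freq = TRUE), brutePic(p), tolerance = 1e-12)
  }
})

test_that("PIC is bounded by expected heterozygosity and 0.375 (biallelic)", {
  for (p in seq(0, 1, by = 0.05)) {
    pic <- locusPic(c(p, 1 - p), freq = TRUE)
    he <- 1 - p^2 - (1 - p)^2
    expect_lte(pic, he + 1e-12)
    expect_lte(pic, 0.375 + 1e-12)
    if (p %in% c(0, 1)) expect_equal(pic, he)
  }
})

test_that("pi and PIC are invariant to sample order and allele relabelling", {
  set.seed(9)
  gm <- simulateGenotypes(runif(50, 0.1, 0.9), n_samples = 12,
                          missing_rate = 0.1)
  i <- 7L
  cnt <- alleleCounts(gm, i)
  expect_equal(sitePi(rev(cnt)), sitePi(cnt))     # ref/alt swap
  expect_equal(locusPic(rev(cnt)), locusPic(cnt))
  perm <- sample(ncol(gm))
  expect_equal(alleleCounts(gm[, perm], i), cnt)  # sample permutation
})

test_that("windowedPi divides by window length and honours both modes", {
  gt <- matrix(rep(c("0/1", "0/0", "0/0", "0/1"), 1), 1, 4)
  gm <- gmFromStrings(gt, pos = 155000L)
  cnt <- alleleCounts(gm, 1)
  site_pi <- sitePi(cnt)
  ## tiling: the site falls in the second of two non-overlapping windows
  wt <- windowedPi(gm, window = 100000L, mode = "tiling",
                   chromLengths = c(Chr01 = 200000L))
  expect_identical(nrow(wt), 2L)
  expect_equal(wt$pi, c(0, site_pi / 1e5))
  ## sliding 100 kb / 10 kb: an interior site sits in exactly 10 windows
  ws <- windowedPi(gm, window = 100000L, step = 10000L,
                   chromLengths = c(Chr01 = 300000L))
  expect_identical(sum(ws$n_sites), 10L)
  expect_equal(sum(ws$pi > 0), 10L)
  ## empty windows report zero diversity
  expect_true(all(ws$pi[ws$n_sites == 0] == 0))
  expect_error(windowedPi(gm, window = 0L), "positive")
})

test_that("population summaries average windows and loci", {
  expect_equal(populationPi(data.frame(pi = c(1e-3, 3e-3))), 2e-3)
  expect_equal(populationPi(data.frame(pi = rep(5e-4, 4))), 5e-4)
  expect_error(populationPi(data.frame(pi = numeric())), "windows")
  gt <- rbind(rep(c("0/1"), 4), rep("0/0", 4))
  gm <- gmFromStrings(gt, pos = c(100L, 200L))
  ## mean of PIC over both loci, the monomorphic one contributing 0
  expect_equal(populationPic(gm), locusPic(c(4, 4)) / 2)
})

test_that("subpopDiversity reports per-subpopulation statistics", {
  ## two identical sub-populations: identical rows
  gt <- rbind(c("0/1", "0/0", "0/1", "0/0"),
              c("1/1", "0/1", "1/1", "0/1"))
  gm <- gmFromStrings(gt, pos = c(1000L, 2000L))
  meta <- data.frame(sample = paste0("s", 1:4),
                     year = c(1970L, 1975L, 2005L, 2008L),
                     subpop = c("SA", "SA", "SD", "SD"))
  rep2 <- subpopDiversity(gm, meta, window = 10000L, mode = "tiling")
  expect_equal(rep2$pi[1], rep2$pi[2])
  expect_equal(rep2$pic[1], rep2$pic[2])
  expect_equal(rep2$pi_display, rep2$pi * 1e3)
  ## clones (identical homozygous lines): zero diversity and zero PIC
  gtc <- matrix("1/1", 2, 4)
  gmc <- gmFromStrings(gtc, pos = c(1000L, 2000L))
  repc <- subpopDiversity(gmc, meta, window = 10000L, mode = "tiling")
  expect_true(all(repc$pi == 0))
  expect_true(all(repc$pic == 0))
  ## an undersized subpopulation is excluded with a warning
  meta1 <- rbind(meta, data.frame(sample = "s9", year = 2012L,
                                  subpop = "SE"))
  expect_warning(rep1 <- subpopDiversity(gm, meta1, window = 10000L,
                                         mode = "tiling"),
                 "excluded")
  expect_true(is.na(rep1$pi[rep1$subpop == "SE"]))
})

test_that("mean site pi recovers the exact binomial-sampling expectation", {
  ## oracle: E[pi] enumerated over the allele-count distribution
  p <- 0.3; n_dip <- 25; n_all <- 2 * n_dip
  exp_pi <- sum(vapply(0:n_all, function(c) {
    stats::dbinom(c, n_all, p) *
      (if (c %in% c(0, n_all)) 0 else sitePi(c(n_all - c, c)))
  }, numeric(1)))
  set.seed(21)
  gm <- simulateGenotypes(rep(p, 1500), n_samples = n_dip)
  pis <- vapply(seq_len(nSites(gm)),
                function(i) sitePi(alleleCounts(gm, i)), numeric(1))
  se <- stats::sd(pis) / sqrt(length(pis))
  expect_lt(abs(mean(pis) - exp_pi), 3 * se)
})
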