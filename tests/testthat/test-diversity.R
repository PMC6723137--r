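test_that("allele frequencies match direct tallies, with and without missing", {
  pg0 <- pgFromCalls(matrix(c("0|0", "0|0"), 1, 2))
  expect_equal(unname(alleleFrequencies(pg0)), 0)

  pg5 <- pgFromCalls(matrix(c("0|1", "0|1"), 1, 2))
  expect_equal(unname(alleleFrequencies(pg5)), 0.5)

  pg <- randomPG(16, 50, miss = 0.1, seed = 7)
  expect_equal(unname(alleleFrequencies(pg)),
               bruteAlleleFreq(list(a1 = hapAlleles(pg, 1),
                                    a2 = hapAlleles(pg, 2))))
})

test_that("He follows 2pq and respects the 0.5 ceiling", {
  expect_equal(expectedHet(pgFromFreqs(0.5)), 0.5)
  expect_equal(expectedHet(pgFromFreqs(1)), 0)
  expect_equal(expectedHet(pgFromFreqs(0.9)), 0.18)
  pg <- randomPG(20, 60, seed = 3)
  he <- expectedHet(pg, per_marker = TRUE)
  expect_true(all(he >= 0 & he <= 0.5))
})

test_that("Ho counts heterozygotes among complete calls", {
  allhet <- pgFromCalls(matrix("0|1", 3, 4))
  expect_equal(observedHet(allhet), 1)
  allhom <- pgFromCalls(matrix(c("0|0", "1|1"), 2, 2))
  expect_equal(observedHet(allhom), 0)
  mixed <- pgFromCalls(matrix(c("0|0", "0|1", "1|1", "0|1"), 1, 4))
  expect_equal(observedHet(mixed), 0.5)
})

test_that("Fis is the ratio-of-means form and behaves at its anchors", {
  # all homozygous, intermediate frequencies: Fis = 1
  hom <- pgFromCalls(matrix(rep(c("0|0", "1|1"), 5), 4, 10, byrow = TRUE))
  expect_equal(inbreedingCoefficient(hom), 1)

  # Ho = He at every locus: Fis = 0
  hw_exact <- pgFromCalls(matrix(c("0|0", "0|1", "1|0", "1|1"), 3, 4,
                                 byrow = TRUE))
  expect_equal(inbreedingCoefficient(hw_exact), 0, tolerance = 1e-12)

  # random mating at large n: Fis ~ 0
  pg <- hwPG(1e4, runif(100, 0.1, 0.9), seed = 11)
  expect_lt(abs(inbreedingCoefficient(pg)), 0.02)

  # matches the brute-force ratio and ignores marker/individual order
  pg2 <- randomPG(18, 40, miss = 0.05, seed = 5)
  expect_equal(inbreedingCoefficient(pg2),
               bruteFis(hapAlleles(pg2, 1), hapAlleles(pg2, 2)),
               tolerance = 1e-12)
  # order invariance: same calls, markers and individuals permuted (map
  # positions collapsed so any marker order is a valid map)
  map0 <- geneticMap(pg2)
  map0$position_cM <- 0
  mi <- sample(40)
  ii <- sample(18)
  orig <- PhasedGenotypes(hapAlleles(pg2, 1), hapAlleles(pg2, 2), map0)
  perm <- PhasedGenotypes(hapAlleles(pg2, 1)[mi, ii],
                          hapAlleles(pg2, 2)[mi, ii], map0[mi, ])
  expect_equal(inbreedingCoefficient(perm), inbreedingCoefficient(orig),
               tolerance = 1e-12)

  # zero passing markers is an explicit error
  mono <- pgFromCalls(matrix("0|0", 5, 4))
  expect_error(inbreedingCoefficient(mono), "undefined")
})

test_that("g2 equals the brute-force pairwise definition", {
  # complete data
  pg <- randomPG(20, 30, seed = 21)
  g2 <- identityDisequilibrium(pg, n_boot = 0)
  expect_equal(g2$g2, bruteG2(genotypeCodes(pg)), tolerance = 1e-10)

  # pairwise-complete handling of missing data
  pgm <- randomPG(20, 25, miss = 0.1, seed = 22)
  g2m <- identityDisequilibrium(pgm, n_boot = 0)
  expect_equal(g2m$g2, bruteG2(genotypeCodes(pgm)), tolerance = 1e-10)
})

test_that("g2 anchors: uniform heterozygosity gives 0, none is undefined", {
  allhet <- pgFromCalls(matrix("0|1", 6, 8))
  expect_equal(identityDisequilibrium(allhet, n_boot = 0)$g2, 0,
               tolerance = 1e-12)
  allhom <- pgFromCalls(matrix(c("0|0", "1|1"), 4, 6))
  expect_error(identityDisequilibrium(allhom, n_boot = 0), "undefined")
})

test_that("g2 is ~0 under random mating and > 0 under partial selfing", {
  pg <- hwPG(1000, runif(40, 0.2, 0.8), seed = 31)
  res <- identityDisequilibrium(pg, n_boot = 50, seed = 1)
  expect_lt(abs(res$g2), 3 * res$se + 0.01)

  map <- generateMap(6, 8, 50)
  pop <- evolvePopulation(s = 0.5, N = 300, generations = 25, map,
                          sample_size = 200, seed = 32)
  res2 <- identityDisequilibrium(pop$sample, n_boot = 50, seed = 2)
  expect_gt(res2$g2, 2 * res2$se)
  # and the estimator still matches brute force on this matrix (<= 50 markers)
  expect_equal(res2$g2, bruteG2(genotypeCodes(pop$sample)), tolerance = 1e-10)
})

test_that("windowed he matches hand counts and the brute-force tabulation", {
  # one 10-SNP window, 2 individuals, 4 distinct haplotypes at 0.25 each
  map <- generateMap(1, 10, 50)
  a1 <- cbind(rep(0L, 10), rep(1L, 10))
  a2 <- cbind(c(rep(0L, 5), rep(1L, 5)), c(rep(1L, 5), rep(0L, 5)))
  pg <- PhasedGenotypes(a1, a2, map)
  expect_equal(effectiveHaplotypeNumber(pg)$mean_he, 4)

  # monomorphic window
  mono <- PhasedGenotypes(matrix(0L, 10, 4), matrix(0L, 10, 4), map)
  expect_equal(effectiveHaplotypeNumber(mono)$mean_he, 1)

  # frequencies (0.5, 0.25, 0.25) -> 1/0.375
  b1 <- cbind(rep(0L, 10), rep(0L, 10))
  b2 <- cbind(rep(1L, 10), c(rep(1L, 9), 0L))
  pg3 <- PhasedGenotypes(b1, b2, map)
  expect_equal(effectiveHaplotypeNumber(pg3)$mean_he, 1 / 0.375)

  # random matrix vs direct tabulation; trailing remainder dropped
  pgr <- randomPG(12, 25, seed = 41)
  res <- effectiveHaplotypeNumber(pgr)
  expect_equal(nrow(res$windows), 2)  # 25 %/% 10
  expect_equal(res$windows$he[1],
               bruteWindowHe(hapAlleles(pgr, 1), hapAlleles(pgr, 2), 1:10))
  expect_equal(res$windows$he[2],
               bruteWindowHe(hapAlleles(pgr, 1), hapAlleles(pgr, 2), 11:20))
})

test_that("he is invariant to REF/ALT relabeling and refuses unphased data", {
  pg <- randomPG(10, 20, seed = 51)
  flipped <- PhasedGenotypes(1L - hapAlleles(pg, 1), 1L - hapAlleles(pg, 2),
                             geneticMap(pg))
  expect_equal(effectiveHaplotypeNumber(pg)$mean_he,
               effectiveHaplotypeNumber(flipped)$mean_he)

  unph <- PhasedGenotypes(hapAlleles(pg, 1), hapAlleles(pg, 2),
                          geneticMap(pg), phased = FALSE)
  expect_error(effectiveHaplotypeNumber(unph), "unphased")
})

test_that("diploid haplotype unit counts one genotype per individual", {
  map <- generateMap(1, 10, 50)
  # two individuals, same unordered pair of haplotypes in opposite order
  h <- c(rep(0L, 5), rep(1L, 5))
  pg <- PhasedGenotypes(cbind(h, 1L - h), cbind(1L - h, h), map)
  expect_equal(effectiveHaplotypeNumber(pg, unit = "diploid")$mean_he, 1)
  expect_equal(effectiveHaplotypeNumber(pg, unit = "haploid")$mean_he, 2)
})

test_that("jackknife matching averages the metric over size-16 subsets", {
  pg <- randomPG(16, 30, seed = 61)
  jk <- jackknifeMatch(expectedHet, pg)
  expect_equal(jk$mean, expectedHet(pg))
  expect_equal(jk$n_subsets, 1L)

  pg18 <- randomPG(18, 30, seed = 62)
  expect_equal(jackknifeMatch(nIndividuals, pg18, n_subsets = 200)$values,
               rep(16, choose(18, 16)))

  # exhaustive enumeration oracle on 18 choose 16 subsets
  jk18 <- jackknifeMatch(expectedHet, pg18, n_subsets = 200)
  combos <- combn(18, 16, simplify = FALSE)
  oracle <- mean(vapply(combos, function(s) expectedHet(pg18[, s]),
                        numeric(1)))
  expect_equal(jk18$mean, oracle, tolerance = 1e-12)

  expect_warning(jackknifeMatch(expectedHet, randomPG(10, 30, seed = 63)),
                 "full sample")
})

test_that("frequency-change correlation hits its exact anchors", {
  p0 <- seq(0.2, 0.65, by = 0.05)  # multiples of 1/20
  d <- rep(c(0.1, -0.1, 0.15, -0.05, 0.05), 2)
  gA <- pgFromFreqs(p0)
  gB <- pgFromFreqs(p0 + d)
  gC_rev <- pgFromFreqs(p0)          # d2 = -d1 exactly
  gC_fwd <- pgFromFreqs(p0 + 2 * d)  # d2 = +d1 exactly
  expect_equal(frequencyChangeCorrelation(gA, gB, gC_rev), -1)
  expect_equal(frequencyChangeCorrelation(gA, gB, gC_fwd), 1)
})

test_that("independent frequency changes give near-zero correlation", {
  set.seed(71)
  L <- 400
  p0 <- round(runif(L, 0.3, 0.7) * 32) / 32
  d1 <- sample(c(-2, -1, 1, 2), L, replace = TRUE) / 32
  d2 <- sample(c(-2, -1, 1, 2), L, replace = TRUE) / 32
  gA <- pgFromFreqs(p0, n_ind = 16)
  gB <- pgFromFreqs(p0 + d1, n_ind = 16)
  gC <- pgFromFreqs(p0 + d1 + d2, n_ind = 16)
  r <- frequencyChangeCorrelation(gA, gB, gC)
  # permutation null on the same marker set
  pA <- alleleFrequencies(gA); pB <- alleleFrequencies(gB)
  pC <- alleleFrequencies(gC)
  null <- replicate(200, cor(pB - pA, sample(pC - pB)))
  expect_lt(abs(r), quantile(abs(null), 0.999) + 0.05)
})

test_that("diversityReport assembles all statistics for one population", {
  pg <- randomPG(16, 60, chromosomes = 2, seed = 81)
  rep1 <- diversityReport(pg, "toy", n_boot = 20, seed = 1)
  expect_equal(rep1$mean_He, expectedHet(pg))
  expect_equal(rep1$Fis, inbreedingCoefficient(pg))
  expect_equal(rep1$mean_he, effectiveHaplotypeNumber(pg)$mean_he)
  expect_true(rep1$n_markers_used <= 60)

  # fully homozygous population: g2 undefined -> NA, Fis = 1
  hom <- pgFromCalls(matrix(rep(c("0|0", "1|1"), 8), 4, 16, byrow = TRUE))
  rep2 <- diversityReport(hom, "mono", n_boot = 0)
  expect_true(is.na(rep2$g2))
  expect_equal(rep2$Fis, 1)
})
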