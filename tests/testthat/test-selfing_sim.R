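test_that("meiosis honors its degenerate cases", {
  pos <- seq(0, 50, length.out = 10)
  hom <- rep(1L, 10)
  set.seed(1)
  expect_identical(meiosis(hom, hom, pos), hom)

  # zero-length map: gamete is an unrecombined parental haplotype
  h1 <- rep(0L, 10); h2 <- rep(1L, 10)
  set.seed(2)
  for (i in 1:20) {
    g <- meiosis(h1, h2, rep(0, 10))
    expect_true(identical(g, h1) || identical(g, h2))
  }

  # single-marker chromosome can never recombine
  set.seed(3)
  expect_true(meiosis(0L, 1L, 0) %in% c(0L, 1L))
})

test_that("crossover frequency is the map length in Morgans, capped at 1", {
  # 0/1 parental haplotypes make crossovers visible as mixed gametes
  n <- 1e5
  pos <- c(0, 10, 15, 40, 50)  # uneven intervals on a 50 cM chromosome
  h1 <- matrix(0L, 5, n)
  h2 <- matrix(1L, 5, n)
  set.seed(11)
  g <- selfdiv:::.meiosisStack(h1, h2, pos)
  mixed <- colSums(g) %in% 1:4
  # P(crossover) = 0.5; 3 MC SEs
  se <- sqrt(0.25 / n)
  expect_lt(abs(mean(mixed) - 0.5), 3 * se)

  # crossover position ~ interval length: chi-square goodness of fit
  cuts <- apply(g[, mixed, drop = FALSE], 2, function(v) {
    which(v != v[1])[1] - 1L   # interval index of the single switch
  })
  obs <- tabulate(cuts, nbins = 4)
  expect_gt(stats::chisq.test(obs, p = diff(pos) / 50)$p.value, 1e-3)

  # each gamete has at most one switch (complete interference)
  nswitch <- apply(g[, mixed, drop = FALSE], 2,
                   function(v) sum(diff(v) != 0))
  expect_true(all(nswitch == 1))
})

test_that("selfing a lineage halves heterozygosity per generation", {
  founder <- fullyHetPG(1, chromosomes = 6, markers_per_chromosome = 20)

  # homozygous founder is a fixed point
  hom <- PhasedGenotypes(matrix(1L, 120, 1), matrix(1L, 120, 1),
                         geneticMap(founder))
  set.seed(21)
  out <- selfLineage(hom, 7)
  expect_identical(hapAlleles(out, 1), hapAlleles(hom, 1))
  expect_identical(hapAlleles(out, 2), hapAlleles(hom, 2))

  # generations = 0 returns the founder
  expect_identical(hapAlleles(selfLineage(founder, 0), 1),
                   hapAlleles(founder, 1))

  # halving law at t = 4 over replicate lineages from one het founder
  set.seed(22)
  lines <- deriveInbredLines(founder, generations = 4, n_lines = 3000)
  ho_line <- colMeans(hapAlleles(lines, 1) != hapAlleles(lines, 2))
  exp_ho <- 2^-4
  se <- sd(ho_line) / sqrt(length(ho_line))
  expect_lt(abs(mean(ho_line) - exp_ho), 3 * se)
})

test_that("fixing the seed reproduces the neutral simulation bit-identically", {
  pg <- evolvePopulation(0.5, 100, 10, generateMap(3, 10, 50), seed = 31)$sample
  s1 <- neutralInbreedingSim(pg, 5, n_sims = 30, n_lines = 20, seed = 99)
  s2 <- neutralInbreedingSim(pg, 5, n_sims = 30, n_lines = 20, seed = 99)
  expect_identical(s1$He@values, s2$He@values)
  expect_identical(s1$he@values, s2$he@values)
  expect_identical(s1$Ho@values, s2$Ho@values)
})

test_that("the simulator conserves expected allele frequencies (neutrality)", {
  pg <- evolvePopulation(0, 200, 10, generateMap(2, 15, 50), seed = 41)$sample
  p0 <- alleleFrequencies(pg)
  set.seed(42)
  lines <- deriveInbredLines(pg, generations = 8, n_lines = 4000)
  p1 <- alleleFrequencies(lines)
  # founder resampling + drift is unbiased: genome-wide mean drift ~ 0
  se <- sd(p1 - p0) / sqrt(length(p0))
  expect_lt(abs(mean(p1 - p0)), 4 * se + 0.01)
})

test_that("drift during inbreeding can only lose haplotype diversity on average", {
  pg <- evolvePopulation(0.5, 150, 20, generateMap(6, 10, 50), seed = 51)$sample
  founder_he <- lineDiversityMetrics(pg, n_subsets = 1, seed = 1)[["he"]]
  sim <- neutralInbreedingSim(pg, 13, n_sims = 150, n_lines = 50,
                              n_subsets = 5, seed = 52)
  expect_lt(sim$he@expectation, founder_he)
  expect_true(sim$he@ci[1] <= sim$he@expectation &&
                sim$he@expectation <= sim$he@ci[2])
})

test_that("without recombination each line doubles one founder haplotype", {
  map <- generateMap(1, 12, 50)
  map$position_cM <- rep(0, 12)   # zero-length chromosome
  h1 <- rbinom(12, 1, 0.5)
  h2 <- 1L - h1
  founder <- PhasedGenotypes(matrix(as.integer(h1), 12, 1),
                             matrix(as.integer(h2), 12, 1), map)
  set.seed(61)
  lines <- deriveInbredLines(founder, generations = 25, n_lines = 400)
  a1 <- hapAlleles(lines, 1); a2 <- hapAlleles(lines, 2)
  expect_true(all(a1 == a2))    # fully homozygous
  is_h1 <- colSums(a1 == h1) == 12
  is_h2 <- colSums(a1 == h2) == 12
  expect_true(all(is_h1 | is_h2))
  expect_lt(abs(mean(is_h1) - 0.5), 3 * sqrt(0.25 / 400))
})

test_that("an all-homozygous population cannot gain heterozygosity", {
  calls <- ifelse(outer(1:20, 1:16, "+") %% 2 == 0, "0|0", "1|1")
  pg <- pgFromCalls(calls, map = generateMap(1, 20, 50))
  sim <- neutralInbreedingSim(pg, 13, n_sims = 50, n_lines = 30, seed = 71)
  expect_equal(sim$Ho@expectation, 0)
  expect_lte(sim$He@expectation, expectedHet(pg) + 1e-9)
})

test_that("unphased input is refused by phase-dependent operations", {
  pg <- randomPG(16, 20, seed = 81)
  unph <- PhasedGenotypes(hapAlleles(pg, 1), hapAlleles(pg, 2),
                          geneticMap(pg), phased = FALSE)
  expect_error(neutralInbreedingSim(unph, 5), "unphased")
  expect_error(selfLineage(unph, 5), "unphased")
  expect_error(deriveInbredLines(unph, 5, 10), "unphased")
})
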