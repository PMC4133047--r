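test_that("Balding-Nichols drift has the model's mean and variance", {
  set.seed(1)
  nSnps <- 10000
  F <- 0.1
  f <- simulateSourceFrequencies(nSnps, route = "P1", driftF = F, seed = 42)
  root <- attr(f, "root")
  child <- f["P1", ]
  # standardised residuals: mean 0, variance F p(1-p)
  z <- (child - root) / sqrt(F * root * (1 - root))
  expect_lt(abs(mean(z)), 3 / sqrt(nSnps))
  expect_lt(abs(mean(z^2) - 1), 3 * sqrt(2 / nSnps) * 1.5)
  # F -> 0 limit returns the parent frequencies exactly
  f0 <- simulateSourceFrequencies(100, "P1", driftF = 1e-13, seed = 7)
  expect_equal(unname(f0["P1", ]), attr(f0, "root"))
  expect_error(simulateSourceFrequencies(10, "P1", driftF = 1.5), "driftF")
})

test_that("heterozygosity declines in expectation along the simulated route", {
  f <- simulateSourceFrequencies(5000, sprintf("P%d", 1:8), driftF = 0.03,
                                 seed = 5)
  het <- rowMeans(2 * f * (1 - f))
  expect_lt(het[8], het[1])
  expect_lt(mean(diff(het) > 0), 0.5)  # mostly decreasing steps
})

test_that("pulse-model ancestry fractions have the variance-halving law", {
  # g = 1, s = (1/2, 1/2): Var(H) = s(1-s)/2 = 0.125
  H1 <- simulateAdmixtureFractions(20000, c(a = .5, b = .5), g = 1, seed = 1,
                                   pedigreeSize = 20000)
  expect_equal(var(H1[, 1]), 0.125, tolerance = 0.02)
  expect_equal(rowSums(H1), rep(1, nrow(H1)), tolerance = 1e-12)
  # log2 Var(H_g) declines with slope ~ -1 in g
  vs <- sapply(1:5, function(g)
    var(simulateAdmixtureFractions(8000, c(a = .5, b = .5), g, seed = g + 10,
                                   pedigreeSize = 8000)[, 1]))
  slope <- coef(lm(log2(vs) ~ seq_along(vs)))[2]
  expect_equal(unname(slope), -1, tolerance = 0.1)
  # degenerate mix: all ancestry from one source
  Hd <- simulateAdmixtureFractions(50, c(a = 1, b = 0), g = 3, seed = 2)
  expect_true(all(Hd[, "a"] == 1))
  expect_error(simulateAdmixtureFractions(1, c(a = 1), g = 1), "at least 2")
})

test_that("mean ancestry is drift-free across generations", {
  for (g in c(2, 6)) {
    H <- simulateAdmixtureFractions(5000, c(a = .3, b = .7), g, seed = g,
                                    pedigreeSize = 5000)
    expect_equal(mean(H[, "a"]), 0.3, tolerance = 0.03)
  }
})

test_that("simulated genotypes match binomial expectations", {
  freqs <- rbind(S1 = rep(1, 50), S2 = rep(1, 50))
  truth <- matrix(c(.5, .5), 20, 2, byrow = TRUE, dimnames = list(NULL, c("S1", "S2")))
  g <- simulateGenotypes(freqs, truth, populations = rep("p", 20), seed = 1)
  expect_true(all(dosage(g) == 2L))  # all sources fixed for allele 2

  set.seed(2)
  freqs2 <- rbind(S1 = runif(2000, .1, .9), S2 = runif(2000, .1, .9))
  truth2 <- matrix(c(.7, .3), 100, 2, byrow = TRUE,
                   dimnames = list(NULL, c("S1", "S2")))
  g2 <- simulateGenotypes(freqs2, truth2, populations = rep("p", 100),
                          missingRate = 0.05, seed = 3)
  exp_p <- .7 * freqs2["S1", ] + .3 * freqs2["S2", ]
  obs_p <- rowMeans(dosage(g2), na.rm = TRUE) / 2
  z <- (obs_p - exp_p) / sqrt(exp_p * (1 - exp_p) / (2 * 100))
  expect_lt(abs(mean(z)), 0.1)
  expect_lt(max(abs(z)), 5)
  miss <- mean(is.na(dosage(g2)))
  expect_lt(abs(miss - 0.05), 3 * sqrt(0.05 * 0.95 / (2000 * 100)))
  expect_error(simulateGenotypes(freqs2 * 2, truth2, rep("p", 100)), "frequencies")
})

test_that("planted recombination map runs are exactly recovered by the block builder", {
  snps <- data.frame(id = sprintf("s%03d", 1:60), chromosome = 1,
                     position_bp = (1:60) * 1000, allele1 = "A", allele2 = "G")
  runs <- data.frame(chromosome = 1, first = c(5L, 30L), last = c(14L, 36L))
  map <- simulateRecombinationMap(snps, runs)
  rates <- intervalRates(map, snps)
  bs <- buildBlocks(rates, minSize = 5, maxSize = 15, threshold = 0.5)
  got <- blockTable(bs)
  expect_identical(got$first, runs$first)
  expect_identical(got$last, runs$last)
  # uniform high-rate map yields no blocks under the below-threshold rule
  mapHigh <- simulateRecombinationMap(snps, runs = NULL, highRate = 1.0)
  expect_identical(nrow(blockTable(buildBlocks(intervalRates(mapHigh, snps)))), 0L)
})

test_that("uniformly low-rate chromosome tiles into greedy 5-15 blocks", {
  snps <- data.frame(id = sprintf("s%03d", 1:30), chromosome = 1,
                     position_bp = (1:30) * 1000, allele1 = "A", allele2 = "G")
  map <- data.frame(chromosome = 1, position_bp = (1:29) * 1000 + 500,
                    rate_cM_per_Mb = 0.1)
  bs <- buildBlocks(intervalRates(map, snps))
  expect_identical(blockTable(bs)$n_snps, greedyTilingOracle(30))
})

test_that("study fixture is seed-deterministic down to the PED bytes", {
  cfg <- list(nSnps = 150, blockLengths = rep(5L, 6), nPerRoutePop = 4,
              nPerColonist = 4,
              admixed = data.frame(label = c("Coast1", "Coast2", "Int1", "Int2"),
                                   sA = c(.3, .3, .15, .15), sB = c(.05, .05, .1, .1),
                                   g = c(3L, 3L, 2L, 2L), n = 4L,
                                   group = c("coastal", "coastal", "interior", "interior")))
  fx1 <- do.call(makeStudyFixture, c(cfg, seed = 99))
  fx2 <- do.call(makeStudyFixture, c(cfg, seed = 99))
  dir <- withr::local_tempdir()
  writePedMap(fx1$genotypes, file.path(dir, "a"))
  writePedMap(fx2$genotypes, file.path(dir, "b"))
  expect_identical(readLines(file.path(dir, "a.ped")),
                   readLines(file.path(dir, "b.ped")))
  expect_identical(fx1$truth, fx2$truth)
  # truth rows are proper ancestry vectors
  expect_true(all(fx1$truth >= 0 & fx1$truth <= 1))
  expect_equal(unname(rowSums(fx1$truth)), rep(1, nrow(fx1$truth)),
               tolerance = 1e-12)
})

test_that("admixed fixture populations inflate haplotype heterozygosity", {
  fx <- makeStudyFixture(nSnps = 200, blockLengths = rep(6L, 9),
                         nPerRoutePop = 15, nPerColonist = 20,
                         admixed = data.frame(label = "Mix1", sA = .4, sB = .3,
                                              g = 2L, n = 20L, group = "coastal"),
                         seed = 21)
  rates <- intervalRates(fx$map, snpInfo(fx$genotypes))
  bs <- buildBlocks(rates)
  het <- genomewideHeterozygosity(fx$genotypes, bs,
                                  populationNames = c("Mix1", "ColonistA",
                                                      "ColonistB", "Route09"))
  h <- setNames(het$table$mean_het, het$table$population)
  # admixture between differentiated sources inflates diversity
  expect_gt(h["Mix1"], max(h["ColonistA"], h["Route09"]))
})
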