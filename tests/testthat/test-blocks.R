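snpsGrid <- function(n, chrom = 1, spacing = 1000) {
  data.frame(id = sprintf("c%ds%03d", chrom, seq_len(n)), chromosome = chrom,
             position_bp = seq_len(n) * spacing, allele1 = "A", allele2 = "G")
}

test_that("interval rates average inside points and interpolate empty intervals", {
  snps <- snpsGrid(3)  # SNPs at 1000, 2000, 3000
  map <- data.frame(chromosome = 1,
                    position_bp = c(1200, 1800, 2500),
                    rate_cM_per_Mb = c(0.2, 0.4, 0.7))
  r <- intervalRates(map, snps)
  expect_equal(r$rate[1], 0.3)  # mean of the two inside points
  expect_equal(r$rate[2], 0.7)  # single inside point
  # empty interval: linear interpolation between flanking map points,
  # evaluated at the interval midpoint
  map2 <- data.frame(chromosome = 1, position_bp = c(500, 3500),
                     rate_cM_per_Mb = c(1.0, 2.0))
  r2 <- intervalRates(map2, snps)
  w <- (2500 - 500) / (3500 - 500)
  expect_equal(r2$rate[2], (1 - w) * 1.0 + w * 2.0)
})

test_that("block construction follows the greedy below-threshold rule", {
  snps <- snpsGrid(20)
  map <- data.frame(chromosome = 1, position_bp = (1:19) * 1000 + 500,
                    rate_cM_per_Mb = 0.1)
  bs <- buildBlocks(intervalRates(map, snps))
  expect_identical(blockTable(bs)$first, c(1L, 16L))
  expect_identical(blockTable(bs)$n_snps, c(15L, 5L))
  # a 4-SNP low-rate run falls below the minimum size: no block
  map$rate_cM_per_Mb <- 2
  map$rate_cM_per_Mb[3:5] <- 0.1  # SNPs 3..6 linked (4 SNPs)
  bs2 <- buildBlocks(intervalRates(map, snps))
  expect_identical(nrow(blockTable(bs2)), 0L)
  # above mode mirrors the rule with the comparison reversed: SNPs 6..20
  # are chained by above-threshold intervals 6..19 (capped at 15 SNPs)
  bs3 <- buildBlocks(intervalRates(map, snps), mode = "above")
  expect_identical(blockTable(bs3)$n_snps, c(15L))
  expect_identical(blockTable(bs3)$first, 6L)
})

test_that("every emitted block satisfies size and rate constraints", {
  set.seed(4)
  snps <- rbind(snpsGrid(120, 1), snpsGrid(80, 2))
  map <- do.call(rbind, lapply(c(1, 2), function(ch) {
    n <- sum(snps$chromosome == ch)
    data.frame(chromosome = ch, position_bp = (1:(n - 1)) * 1000 + 500,
               rate_cM_per_Mb = sample(c(0.1, 0.9), n - 1, TRUE))
  }))
  rates <- intervalRates(map, snps)
  bs <- buildBlocks(rates)
  b <- blockTable(bs)
  expect_gt(nrow(b), 0)
  for (k in seq_len(nrow(b))) {
    expect_gte(b$n_snps[k], 5L); expect_lte(b$n_snps[k], 15L)
    within <- rates$left >= b$first[k] & rates$right <= b$last[k]
    expect_true(all(rates$rate[within] < 0.5))
  }
  # disjointness
  o <- order(b$first)
  expect_true(all(b$first[o][-1] > b$last[o][-nrow(b)]))
})

test_that("random mode reproduces the reference length multiset disjointly", {
  snps <- snpsGrid(200)
  map <- simulateRecombinationMap(
    snps, runs = data.frame(chromosome = 1, first = c(10L, 40L), last = c(14L, 46L)))
  rates <- intervalRates(map, snps)
  ref <- buildBlocks(rates, minSize = 5, maxSize = 7)
  expect_identical(sort(blockTable(ref)$n_snps), c(5L, 7L))
  rb <- buildBlocks(rates, mode = "random", reference = ref, seed = 5)
  expect_identical(sort(blockTable(rb)$n_snps), sort(blockTable(ref)$n_snps))
  b <- blockTable(rb)
  o <- order(b$first)
  expect_true(all(b$first[o][-1] > b$last[o][-nrow(b)]))
  expect_error(buildBlocks(rates, mode = "random"), "reference")
})

test_that("EM equals direct counting when phase is unambiguous", {
  # all homozygous: haplotypes readable directly
  dos <- rbind(c(0, 2, 0, 2), c(0, 2, 2, 0), c(2, 0, 0, 2))
  g <- makeGeno(dos, pops = rep("p", 4))
  spec <- emHaplotypeFrequencies(g, 1:3)
  expect_identical(spec$n, 8L)
  expect_equal(sort(unname(spec$freq[spec$freq > 0]), decreasing = TRUE),
               c(.25, .25, .25, .25))
  expect_equal(unname(spec$freq[["010"]]), 0.25)
  # at most one heterozygous site per individual: still unambiguous.
  # columns: ind1 = (0,0,2) -> 001 x2; ind2 = (1,0,2) -> 001 + 101;
  # ind3 = (2,2,0) -> 110 x2
  dos2 <- rbind(c(0, 1, 2), c(0, 0, 2), c(2, 2, 0))
  g2 <- makeGeno(dos2, pops = rep("p", 3))
  spec2 <- emHaplotypeFrequencies(g2, 1:3)
  counts <- c("001" = 3, "101" = 1, "110" = 2)
  for (h in names(counts))
    expect_equal(unname(spec2$freq[h] %||% 0), unname(counts[h] / 6),
                 tolerance = 1e-12)
})

test_that("EM matches a 1-D likelihood grid search on the classic 2-SNP case", {
  # AABB x4, aabb x4, AaBb x2 (dosage = count of the second allele)
  dos <- cbind(matrix(0, 2, 4), matrix(2, 2, 4), matrix(1, 2, 2))
  g <- makeGeno(dos, pops = rep("p", 10))
  spec <- emHaplotypeFrequencies(g, 1:2, tol = 1e-12)
  # grid over x = expected double-hets phased in coupling (00/11)
  lik <- function(x) {
    f <- c("00" = (8 + x) / 20, "11" = (8 + x) / 20,
           "01" = (2 - x) / 20, "10" = (2 - x) / 20)
    8 * log(f["00"]) + 8 * log(f["11"]) +
      2 * log(2 * f["00"] * f["11"] + 2 * f["01"] * f["10"])
  }
  xs <- seq(0, 2, by = 1e-4)
  xhat <- xs[which.max(sapply(xs, lik))]
  expect_equal(unname(spec$freq[["00"]]), (8 + xhat) / 20, tolerance = 1e-3)
  expect_equal(unname(spec$freq[["01"]] %||% 0), (2 - xhat) / 20, tolerance = 1e-3)
})

test_that("EM log-likelihood is non-decreasing and respects preconditions", {
  set.seed(8)
  dos <- matrix(sample(0:2, 6 * 40, TRUE), 6, 40)
  g <- makeGeno(dos, pops = rep("p", 40))
  spec <- emHaplotypeFrequencies(g, 1:6, tol = 1e-10)
  expect_true(all(diff(spec$logLik) > -1e-8))
  expect_equal(sum(spec$freq), 1, tolerance = 1e-9)
  dosNA <- matrix(NA_integer_, 3, 2)
  expect_error(emHaplotypeFrequencies(makeGeno(dosNA, pops = c("p", "p")), 1:3),
               "no individuals")
  expect_error(emHaplotypeFrequencies(g, 1:16), "at most 15")
})

test_that("Nei block heterozygosity follows the unbiased formula", {
  expect_equal(blockHeterozygosity(list(freq = c(a = 1), n = 10)), 0)
  expect_equal(blockHeterozygosity(list(freq = c(a = .5, b = .5), n = 4)),
               (4 / 3) * 0.5)
  expect_equal(blockHeterozygosity(list(freq = c(a = .5, b = .5), n = 4),
                                   unbiased = FALSE), 0.5)
  # uniform over m haplotypes at large n approaches 1 - 1/m
  m <- 8
  expect_equal(blockHeterozygosity(list(freq = rep(1 / m, m), n = 1e9)),
               1 - 1 / m, tolerance = 1e-6)
  expect_error(blockHeterozygosity(list(freq = 1, n = 1)), "at least 2")
})

test_that("Nei estimator is nearly unbiased under multinomial resampling", {
  set.seed(9)
  p <- c(.4, .3, .2, .1)
  trueH <- 1 - sum(p^2)
  n <- 40
  est <- replicate(4000, {
    cnt <- as.numeric(rmultinom(1, n, p))
    f <- cnt / n
    (n / (n - 1)) * (1 - sum(f^2))
  })
  expect_lt(abs(mean(est) - trueH), trueH / n)
})

test_that("genome-wide summary averages within chromosomes then across", {
  # two chromosomes of homozygous individuals with known haplotype makeup
  dos <- rbind(matrix(rep(c(0, 2), each = 5), 5, 2),   # chrom 1: two haplotypes
               matrix(0, 5, 2))                        # chrom 2: one haplotype
  g <- makeGeno(dos, pops = c("p", "p"), chrom = rep(1:2, each = 5),
                pos = rep(1:5 * 1000, 2))
  bs <- new("BlockSet",
            blocks = data.frame(chromosome = 1:2, first = c(1L, 6L),
                                last = c(5L, 10L), n_snps = 5L),
            mode = "below", minSize = 5L, maxSize = 15L, threshold = 0.5)
  het <- genomewideHeterozygosity(g, bs)
  # chrom 1: two haplotypes at 1/2 with n = 4 -> H = 2/3; chrom 2: H = 0
  expect_equal(unname(het$perChromosome["p", ]), c(2 / 3, 0))
  expect_equal(het$table$mean_het, 1 / 3)
  expect_equal(het$table$sd_het, sd(c(2 / 3, 0)))
})

test_that("low-recombination blocks carry more haplotype structure than high", {
  fx <- makeStudyFixture(nSnps = 300, blockLengths = rep(6L, 9),
                         nPerRoutePop = 15, nPerColonist = 15, seed = 31)
  rates <- intervalRates(fx$map, snpInfo(fx$genotypes))
  below <- buildBlocks(rates, mode = "below")
  above <- buildBlocks(rates, minSize = 5, maxSize = 6, mode = "above")
  pops <- c("Route01", "Route05")
  hBelow <- genomewideHeterozygosity(fx$genotypes, below, pops)$table$mean_het
  hAbove <- genomewideHeterozygosity(fx$genotypes, above, pops)$table$mean_het
  # pool-structured (low-recombination) blocks have *lower* heterozygosity
  # than length-matched blocks of unlinked SNPs, which approach the
  # independent-sites maximum
  expect_true(all(hBelow < hAbove))
})
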