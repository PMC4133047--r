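test_that("allele-sharing dissimilarity follows the shared-allele count", {
  # identical, opposite, and a hand-counted mixed pair
  dos <- cbind(c(0, 1, 2), c(1, 1, 0))
  g <- makeGeno(dos, pops = c("p", "p"), ids = c("u", "v"))
  m <- distanceMatrix(asdMatrix(g))
  expect_equal(m["u", "v"], 1 - (1 / 2 + 1 + 0) / 3)  # = 0.5
  gSame <- makeGeno(cbind(c(0, 1, 2), c(0, 1, 2)), pops = c("p", "p"))
  expect_equal(max(distanceMatrix(asdMatrix(gSame))), 0)
  gOpp <- makeGeno(cbind(c(0, 0, 0), c(2, 2, 2)), pops = c("p", "p"))
  expect_equal(distanceMatrix(asdMatrix(gOpp))[1, 2], 1)
})

test_that("ASD uses pairwise-complete SNPs and errors on empty overlap", {
  dos <- cbind(c(0, NA, 2, 1), c(0, 1, NA, 1))
  g <- makeGeno(dos, pops = c("p", "p"), ids = c("u", "v"))
  m <- distanceMatrix(asdMatrix(g))
  expect_equal(m["u", "v"], 1 - (1 + 1) / 2)  # SNPs 1 and 4 only
  gBad <- makeGeno(cbind(c(0L, NA), c(NA, 2L)), pops = c("p", "p"))
  expect_error(asdMatrix(gBad), "no overlapping")
})

test_that("ASD is a metric on complete-data inputs", {
  set.seed(31)
  dos <- matrix(sample(0:2, 50 * 12, TRUE), 50, 12)
  m <- distanceMatrix(asdMatrix(makeGeno(dos, pops = rep("p", 12))))
  expect_equal(m, t(m))
  expect_true(all(diag(m) == 0))
  for (i in 1:12) for (j in 1:12) for (k in 1:12)
    expect_lte(m[i, k], m[i, j] + m[j, k] + 1e-12)
})

test_that("distance-gap grouping applies the chaining rule", {
  pops <- data.frame(population = c("a", "b", "c"),
                     distance_km = c(100, 150, 900))
  gr <- buildGroups(pops, d = 350)
  expect_identical(unname(gr$assignment[c("a", "b")]), c(1L, 1L))
  expect_false(gr$assignment["c"] == gr$assignment["a"])
  # d larger than every gap: one group; smaller than every gap: singletons
  expect_identical(length(unique(buildGroups(pops, d = 1000)$assignment)), 1L)
  expect_identical(length(unique(buildGroups(pops, d = 10)$assignment)), 3L)
  expect_error(buildGroups(pops, d = 0), "positive")
})

test_that("special groups are set aside first and exclusions dropped", {
  pops <- data.frame(
    population = c("nw1", "nw2", "asw", "ceu", "x", "y"),
    distance_km = c(15000, 15200, 11000, 8000, 1000, 1200),
    special_group = c("indigenous_NW", "indigenous_NW", "ASW", "none", "none", "none"),
    exclude_from_grouping = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
  gr <- buildGroups(pops, d = 500)
  expect_identical(unname(gr$assignment["nw1"]), unname(gr$assignment["nw2"]))
  expect_false("ceu" %in% names(gr$assignment))
  expect_identical(unname(gr$assignment["x"]), unname(gr$assignment["y"]))
  expect_true(gr$assignment["asw"] != gr$assignment["x"])
})

test_that("resampled MDS selects the max-fidelity replicate and respects caps", {
  set.seed(32)
  pts <- matrix(rnorm(60), 30, 2)
  rownames(pts) <- sprintf("i%02d", 1:30)
  D <- as.matrix(dist(pts))
  asd <- new("PopDistance", distance = D, flavor = "Euclidean")
  indivPops <- setNames(rep(c("p1", "p2", "p3"), each = 10), rownames(pts))
  scheme <- buildGroups(data.frame(population = c("p1", "p2", "p3"),
                                   distance_km = c(0, 5000, 10000)), d = 1000)
  res <- resampledMDS(asd, scheme, indivPops, nPerGroup = 5, replicates = 20,
                      seed = 1)
  expect_equal(res$rho, max(res$log$rho))
  grpSizes <- table(indivPops[res$ids])
  expect_true(all(grpSizes == 5))
  # groups smaller than the cap: all individuals sampled, replicates identical
  resAll <- resampledMDS(asd, scheme, indivPops, nPerGroup = 82,
                         replicates = 3, seed = 2)
  expect_identical(sort(resAll$ids), sort(rownames(pts)))
  expect_equal(var(resAll$log$rho), 0)
  # a single replicate equals a direct MDS of the sampled set
  res1 <- resampledMDS(asd, scheme, indivPops, nPerGroup = 82, replicates = 1,
                       seed = 3)
  direct <- classicalMDS(D[sort(res1$ids), sort(res1$ids)])
  expect_equal(abs(mdsPoints(res1$mds)[sort(res1$ids), ]),
               abs(mdsPoints(direct)), tolerance = 1e-9)
})

test_that("Procrustes similarity is exact for similarity transforms", {
  set.seed(33)
  X <- matrix(rnorm(40), 20, 2); rownames(X) <- sprintf("i%02d", 1:20)
  th <- 1.1; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  Y <- 2.5 * X %*% R + matrix(c(3, -7), 20, 2, byrow = TRUE)
  rownames(Y) <- rownames(X)
  pr <- procrustesAlign(X, Y)
  expect_equal(pr$t0, 1, tolerance = 1e-9)
  # reflection is an allowed transform
  Yr <- Y %*% diag(c(-1, 1)); rownames(Yr) <- rownames(X)
  expect_equal(procrustesAlign(X, Yr)$t0, 1, tolerance = 1e-9)
  # invariance to row order of the moving configuration
  perm <- sample(rownames(Y))
  expect_equal(procrustesAlign(X, Y[perm, ])$t0, 1, tolerance = 1e-9)
  expect_error(procrustesAlign(X[1:2, ], Y[1:2, ]), "at least 3")
  Z <- matrix(1, 5, 2); rownames(Z) <- sprintf("i%02d", 1:5)
  expect_error(procrustesAlign(Z, Y[1:5, ]), "degenerate")
})

test_that("Procrustes t0 matches a brute-force rotation-grid optimum", {
  set.seed(34)
  for (rep in 1:3) {
    X <- matrix(rnorm(60), 30, 2); rownames(X) <- sprintf("i%02d", 1:30)
    Y <- matrix(rnorm(60), 30, 2); rownames(Y) <- rownames(X)
    pr <- procrustesAlign(X, Y)
    expect_equal(pr$t0, procrustesGridOracle(X, Y, nGrid = 20000),
                 tolerance = 1e-3)
    expect_equal(pr$t0, sqrt(1 - pr$D), tolerance = 1e-12)
  }
})

test_that("t0 is invariant to similarity transforms of either input", {
  set.seed(35)
  X <- matrix(rnorm(30), 15, 2); rownames(X) <- sprintf("i%02d", 1:15)
  Y <- matrix(rnorm(30), 15, 2); rownames(Y) <- rownames(X)
  base <- procrustesAlign(X, Y)$t0
  th <- 0.4; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  X2 <- 3 * X %*% R + 5; rownames(X2) <- rownames(X)
  expect_equal(procrustesAlign(X2, Y)$t0, base, tolerance = 1e-9)
  Y2 <- 0.1 * Y %*% R - 2; rownames(Y2) <- rownames(Y)
  expect_equal(procrustesAlign(X, Y2)$t0, base, tolerance = 1e-9)
})

test_that("L0 statistic is label-symmetric and detects extreme separation", {
  set.seed(36)
  pts <- rbind(matrix(rnorm(40), 20, 2),
               matrix(rnorm(40, mean = 100), 20, 2))
  rownames(pts) <- sprintf("i%02d", 1:40)
  A <- rownames(pts)[1:20]; B <- rownames(pts)[21:40]
  r1 <- l0Test(pts, A, B, nPerm = 500, seed = 1)
  r2 <- l0Test(pts, B, A, nPerm = 500, seed = 1)
  expect_equal(r1$l0, r2$l0)
  expect_lt(r1$p, 0.001)
  expect_match(r1$pDisplay, "<")
  expect_error(l0Test(pts, character(0), B), "empty")
  expect_error(l0Test(pts, A, c(B, A[1])), "disjoint")
})

test_that("L0 permutation p-values are calibrated under the exchangeable null", {
  set.seed(37)
  hits <- 0L
  nSim <- 200
  for (s in seq_len(nSim)) {
    pts <- matrix(rnorm(60), 30, 2)
    rownames(pts) <- sprintf("i%02d", 1:30)
    r <- l0Test(pts, rownames(pts)[1:15], rownames(pts)[16:30],
                nPerm = 99, seed = s)
    if (r$p <= 0.05) hits <- hits + 1L
  }
  # binomial(200, ~0.05): mean 10, 3 sd ~ 9.3
  expect_gte(hits, 1); expect_lte(hits, 21)
})

test_that("distinct source mixes separate interior from coastal on the fixture", {
  fx <- makeStudyFixture(nSnps = 800, blockLengths = rep(5L, 6),
                         nPerRoutePop = 8, nPerColonist = 12, seed = 41)
  pops <- populations(fx$genotypes)
  nw <- names(pops)[pops %in% c("Coast1", "Coast2", "Int1", "Int2")]
  asd <- asdMatrix(fx$genotypes[, nw])
  cfg <- classicalMDS(distanceMatrix(asd))
  A <- names(pops)[pops %in% c("Coast1", "Coast2")]
  B <- names(pops)[pops %in% c("Int1", "Int2")]
  r <- l0Test(cfg, A, B, nPerm = 500, seed = 5)
  expect_lt(r$p, 0.05)
})
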