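test_that("standardised heterozygosity is a normalised proportion", {
  # two individuals with het proportions 0.1 and 0.3 -> Hs 0.5 and 1.5
  g <- rbind(a = c(rep(1, 1), rep(0, 9)),
             b = c(rep(1, 3), rep(0, 7)))
  hs <- standardizedHeterozygosity(GenotypeMatrix(g))
  expect_equal(hs$Hs, c(0.5, 1.5))
  expect_equal(mean(hs$Hs), 1)

  same <- GenotypeMatrix(matrix(rep(c(1, 0, 1, 2), 3), 3, 4, byrow = TRUE))
  expect_equal(standardizedHeterozygosity(same)$Hs, rep(1, 3))

  g2 <- rbind(a = c(1, 0), b = c(NA, NA), c = c(0, 1))
  expect_warning(hs2 <- standardizedHeterozygosity(GenotypeMatrix(g2)),
                 "excluded")
  expect_equal(nrow(hs2), 2)
})

test_that("Ho/He use the unbiased small-sample correction", {
  # every individual heterozygous: Ho = 1
  gAllHet <- GenotypeMatrix(matrix(1, 4, 5))
  res <- hoHe(gAllHet, rep("P", 4))
  expect_equal(res$Ho, 1)

  # p = 0.5, n = 2: He = 2 * 0.25 * (4/3) = 2/3
  g <- GenotypeMatrix(rbind(c(0), c(2)))
  res2 <- hoHe(g, c("P", "P"))
  expect_equal(res2$He, 2 / 3, tolerance = 1e-12)

  # Hardy-Weinberg limit: panmictic simulation has Ho ~ He
  gm <- simulateIslandGenotypes(1, 100, 1000, 0, seed = 8)
  res3 <- hoHe(gm, rep("P", 100))
  expect_lt(abs(res3$Ho - res3$He), 0.02)

  expect_error(hoHe(gAllHet, rep(c("P", "Q"), c(3, 1))), "n >= 2")
})

test_that("rarefied allelic richness matches the hypergeometric closed form", {
  # monomorphic locus: Ar = 1
  mono <- GenotypeMatrix(matrix(0, 5, 3))
  expect_equal(unname(rarefiedAllelicRichness(mono, rep("P", 5), g = 4)), 1)

  # allele counts (50, 50), rarefied to 6 genes
  g5050 <- GenotypeMatrix(matrix(rep(c(0, 2), each = 25), 50, 1))
  ar <- rarefiedAllelicRichness(g5050, rep("P", 50), g = 6)
  expect_equal(unname(ar), 2 * (1 - choose(50, 6) / choose(100, 6)),
               tolerance = 1e-10)
  expect_equal(unname(ar), 1.9733, tolerance = 1e-4)

  # g = N: Ar equals the observed allele count
  gSmall <- GenotypeMatrix(rbind(c(0, 1), c(2, 1)))
  expect_equal(unname(rarefiedAllelicRichness(gSmall, rep("P", 2), g = 4)), 2)

  # monotone non-decreasing in g
  gm <- simulateIslandGenotypes(1, 12, 300, 0, seed = 4)
  ars <- vapply(c(2, 6, 12, 18, 24), function(gg)
    unname(rarefiedAllelicRichness(gm, rep("P", 12), g = gg)), numeric(1))
  expect_true(all(diff(ars) >= -1e-12))

  expect_error(rarefiedAllelicRichness(mono, rep("P", 5), g = 1), ">= 2")
})

test_that("private alleles are counted only where exclusive", {
  # locus 1: alt allele only in A; locus 2: alt in both; locus 3: ref only
  # in B (A is fixed for alt there)
  g <- rbind(a1 = c(1, 1, 2), a2 = c(0, 1, 2),
             b1 = c(0, 1, 1), b2 = c(0, 1, 2))
  pa <- privateAlleles(GenotypeMatrix(g), c("A", "A", "B", "B"))
  expect_equal(unname(pa["A"]), 1L)  # alt at locus 1
  expect_equal(unname(pa["B"]), 1L)  # ref at locus 3
  # sum over populations never exceeds alleles observed exactly once
  gm <- simulateIslandGenotypes(4, 8, 500, 0.2, seed = 6)
  paSim <- privateAlleles(gm)
  expect_lte(sum(paSim), 2 * 500)
})

test_that("Weir-Cockerham theta matches limits and the independent oracle", {
  # fixation: two populations fixed for alternate alleles
  gFix <- GenotypeMatrix(rbind(matrix(0, 5, 20), matrix(2, 5, 20)))
  pops <- rep(c("A", "B"), each = 5)
  expect_equal(wcFst(gFix, pops, nBoot = 0)$overall$theta, 1)

  # identical genotype tables: theta <= 0
  half <- matrix(rbinom(5 * 50, 2, 0.4), 5, 50)
  gSame <- GenotypeMatrix(rbind(half, half))
  expect_lte(wcFst(gSame, pops, nBoot = 0)$overall$theta, 0)

  # single-locus two-population fixture vs the scalar oracle
  g1 <- GenotypeMatrix(cbind(c(rep(2, 8), 1, 1, rep(0, 8), 1, 1)))
  p1 <- rep(c("A", "B"), each = 10)
  expect_equal(wcFst(g1, p1, nBoot = 0)$overall$theta,
               oracleWcTheta(genotypes(g1), p1), tolerance = 1e-12)

  # multi-locus simulated data vs oracle, including missing genotypes
  gm <- simulateIslandGenotypes(3, 6, 80, 0.15, seed = 12)
  g <- genotypes(gm)
  set.seed(1); g[sample(length(g), 40)] <- NA
  gmNA <- GenotypeMatrix(g, sampleInfo = sampleInfo(gm))
  expect_equal(wcFst(gmNA, nBoot = 0)$overall$theta,
               oracleWcTheta(g, popLabels(gm)), tolerance = 1e-12)

  # bootstrap CI brackets the estimate and is seed-stable
  f1 <- wcFst(gm, nBoot = 200, seed = 9)
  f2 <- wcFst(gm, nBoot = 200, seed = 9)
  expect_identical(f1$overall, f2$overall)
  expect_lte(f1$overall$ciLower, f1$overall$theta + 0.02)
  expect_gte(f1$overall$ciUpper, f1$overall$theta - 0.02)

  # pairwise matrix is symmetric with zero diagonal
  pw <- wcFst(gm, pairwise = TRUE, nBoot = 0)$pairwise
  expect_equal(pw, t(pw))
  expect_equal(unname(diag(pw)), rep(0, 3))
})

test_that("QG relatedness is invariant to locus order and allele relabeling", {
  ped <- referencePedigree(20)
  sim <- simulatePedigreeGenotypes(ped, 300, seed = 3)
  g <- genotypes(sim$genotypes)
  r1 <- qgRelatedness(GenotypeMatrix(g))
  # permute loci
  set.seed(2); perm <- sample(ncol(g))
  r2 <- qgRelatedness(GenotypeMatrix(g[, perm]))
  expect_equal(r1, r2, tolerance = 1e-12)
  # flip ref/alt at a subset of loci (code -> 2 - code)
  gFlip <- g
  gFlip[, 1:100] <- 2 - gFlip[, 1:100]
  r3 <- qgRelatedness(GenotypeMatrix(gFlip))
  expect_equal(r1, r3, tolerance = 1e-12)

  expect_error(qgRelatedness(GenotypeMatrix(g[1:2, ])), "at least 3")
})

test_that("genetic distance handles missingness by rescaling", {
  g <- rbind(a = c(0, 1, 2), b = c(2, 1, 2))
  d <- distanceValues(geneticDistance(GenotypeMatrix(g)))
  expect_equal(d["a", "b"], 2)
  expect_equal(unname(diag(d)), c(0, 0))

  # identical rows -> 0
  gSame <- rbind(a = c(1, 2, 0), b = c(1, 2, 0))
  expect_equal(distanceValues(geneticDistance(GenotypeMatrix(gSame)))[1, 2], 0)

  # locus permutation leaves distances unchanged
  gm <- simulateIslandGenotypes(2, 5, 100, 0.1, seed = 5)
  d1 <- distanceValues(geneticDistance(gm))
  set.seed(3); perm <- sample(100)
  d2 <- distanceValues(geneticDistance(GenotypeMatrix(genotypes(gm)[, perm])))
  expect_equal(d1, d2, tolerance = 1e-12)

  # missing-data rescaling: one shared locus out of two, difference 2
  gMiss <- rbind(a = c(2, NA), b = c(0, 1))
  dM <- distanceValues(geneticDistance(GenotypeMatrix(gMiss)))
  expect_equal(dM["a", "b"], sqrt(4 * 2 / 1))

  gNone <- rbind(a = c(2, NA), b = c(NA, 1))
  expect_warning(dN <- geneticDistance(GenotypeMatrix(gNone)), "shared")
  expect_true(is.na(distanceValues(dN)[1, 2]))
})

test_that("PCA separates clusters and reports variance shares", {
  g <- rbind(matrix(0, 5, 30), matrix(2, 5, 30))
  rownames(g) <- paste0("i", 1:10)
  res <- pcaGenotypes(GenotypeMatrix(g))
  # PC1 separates the clusters (sign is arbitrary); within-cluster spread 0
  expect_equal(sd(res$coords[1:5, 1]), 0, tolerance = 1e-9)
  expect_equal(sd(res$coords[6:10, 1]), 0, tolerance = 1e-9)
  expect_gt(abs(mean(res$coords[1:5, 1]) - mean(res$coords[6:10, 1])), 1)
  expect_lt(sum(res$explained), 1 + 1e-9)
  expect_equal(res$explained[1], 1, tolerance = 1e-9)

  expect_error(pcaGenotypes(GenotypeMatrix(matrix(1, 1, 5))), "2 individuals")
})

test_that("Evanno delta-K picks the knee of the likelihood curve", {
  lnp <- data.frame(K = rep(1:4, each = 2), replicate = rep(1:2, 4),
                    lnP = c(-100.5, -99.5, -50.5, -49.5, -48.5, -47.5,
                            -47.5, -46.5))
  ev <- evannoDeltaK(lnp)
  # means -100, -50, -48, -47 with sd sqrt(0.5): deltaK = |L''|/sd
  expect_equal(ev$deltaK[2], 48 / sd(c(-50.5, -49.5)))
  expect_equal(ev$deltaK[3], 1 / sd(c(-48.5, -47.5)))
  expect_equal(which.max(ev$deltaK), 2)
  expect_true(is.na(ev$deltaK[1]) && is.na(ev$deltaK[4]))

  # linear L(K): deltaK = 0 in the interior
  lin <- data.frame(K = rep(1:4, each = 2), replicate = rep(1:2, 4),
                    lnP = rep(c(-40, -30, -20, -10), each = 2) +
                      rep(c(-0.5, 0.5), 4))
  evLin <- evannoDeltaK(lin)
  expect_equal(evLin$deltaK[2:3], c(0, 0))

  expect_error(evannoDeltaK(data.frame(K = rep(1:2, each = 2),
                                       lnP = rnorm(4))), "3 consecutive")
})

test_that("pairwise population comparisons adjust by Benjamini-Hochberg", {
  same <- list(A = rnorm(50), B = NULL)
  same$B <- same$A
  res <- comparePopulations(same)
  expect_gte(res$pvalues["A", "B"], 0.9)

  set.seed(4)
  vals <- list(A = rnorm(200), B = rnorm(200, 2), C = rnorm(200, 0.1))
  res2 <- comparePopulations(vals)
  expect_lt(res2$pvalues["A", "B"], 0.001)
  # BH preserves ordering of raw p-values
  rawOrd <- order(res2$raw[upper.tri(res2$raw)])
  adjOrd <- order(res2$pvalues[upper.tri(res2$pvalues)])
  expect_identical(rawOrd, adjOrd)
  expect_true(all(res2$pvalues >= res2$raw, na.rm = TRUE))
})

test_that("Moran's I matches closed forms and the null expectation", {
  # checkerboard on a 4x4 rook grid: I = -1 exactly
  xy <- expand.grid(x = 1:4, y = 1:4)
  v <- (-1)^(xy$x + xy$y)
  m <- moransI(v, xy, scheme = "band", band = 1.01)
  expect_equal(m$I, -1, tolerance = 1e-12)
  expect_equal(m$expectation, -1 / 15)
  # local I: every observation equally negative on the checkerboard interior
  expect_true(all(m$localI < 0))

  # values independent of coordinates: I ~ -1/(n-1)
  set.seed(7)
  n <- 400
  xy2 <- data.frame(x = runif(n, 0, 100), y = runif(n, 0, 100))
  m2 <- moransI(rnorm(n), xy2, k = 8)
  expect_lt(abs(m2$I - (-1 / (n - 1))), 0.05)
  expect_gt(m2$p.value, 1e-4)

  # smooth gradient: strongly positive I
  xy3 <- expand.grid(x = 1:10, y = 1:10)
  m3 <- moransI(xy3$x + xy3$y, xy3, k = 8)
  expect_gt(m3$I, 0.5)
  expect_lt(m3$p.value, 1e-6)

  expect_error(moransI(rep(1, 10), xy3[1:10, ]), "constant")
  expect_error(moransI(1:3, xy3[1:3, ]), "at least 4")
})

test_that("Hs ~ urban regression recovers a planted slope", {
  set.seed(5)
  n <- 80
  urban <- runif(n)
  hs <- data.frame(id = paste0("i", 1:n),
                   Hs = 1 - 0.5 * urban + rnorm(n, 0, 0.01))
  fit <- fitHsUrban(hs, urban)
  expect_lt(abs(fit$slope - (-0.5)), 0.05)
  expect_lt(fit$slopeP, 1e-6)

  expect_error(fitHsUrban(hs, rep(0.3, n)), "constant")

  # a spatially clustered residual block shows up in residual Moran's I
  xy <- data.frame(x = runif(n, 0, 100), y = runif(n, 0, 100))
  block <- xy$x < 30 & xy$y < 30
  hs2 <- hs
  hs2$Hs <- hs2$Hs + ifelse(block, 0.3, 0)
  fit2 <- fitHsUrban(hs2, urban, coords = xy, k = 8)
  expect_lt(fit2$residualMoran$p.value, 0.01)
  expect_gt(fit2$residualMoran$I, 0)
})
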