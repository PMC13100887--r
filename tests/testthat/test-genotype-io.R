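test_that("VCF round trip is lossless for filter-relevant fields", {
  gm <- simulateIslandGenotypes(1, 3, 20, 0.1, seed = 2)
  vt <- degradeToVcfRecords(gm, missingRate = 0.2, seed = 4)
  path <- tempfile(fileext = ".vcf.gz")
  writeGenotypeVcf(vt, path)
  back <- readGenotypeVcf(path)
  expect_equal(back@gt, vt@gt, ignore_attr = TRUE)
  expect_equal(back@dp, round(vt@dp), ignore_attr = TRUE)
  expect_equal(back@qual, vt@qual, tolerance = 1e-2)
  expect_equal(back@mq, vt@mq, tolerance = 1e-2)
  expect_identical(back@locus, vt@locus)
  expect_identical(back@pos, vt@pos)

  # missing GT "./." comes back as missing
  expect_true(anyNA(back@gt))

  # non-diploid GT is rejected with a clear error
  lines <- c("##fileformat=VCFv4.2",
             paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "s1", sep = "\t"),
             paste("chr1", "100", "v1", "A", "T", "50", "PASS", "DP=10",
                   "GT", "0/1/1", sep = "\t"))
  bad <- tempfile(fileext = ".vcf")
  writeLines(lines, bad)
  expect_error(readGenotypeVcf(bad), "non-diploid")
})

test_that("genotype CSV and metadata round trip", {
  gm <- simulateIslandGenotypes(2, 4, 10, 0.1, seed = 3)
  g <- genotypes(gm)
  g[2, 3] <- NA
  gm2 <- GenotypeMatrix(g)
  path <- tempfile(fileext = ".csv")
  writeGenotypeCsv(gm2, path)
  back <- readGenotypeCsv(path)
  expect_equal(genotypes(back), genotypes(gm2))

  meta <- data.frame(id = c("a", "b"), x = c(0, 10), y = c(0, 0),
                     location = "L", date = c("2020-01-02", "2021-03-04"))
  mPath <- tempfile(fileext = ".csv")
  write.csv(meta, mPath, row.names = FALSE)
  m <- readSampleMetadata(mPath)
  expect_s3_class(m$date, "Date")
  expect_identical(rownames(m), c("a", "b"))
})

test_that("filter chain applies rules in order with exact per-step counts", {
  # constructed fixture: 10 sites, 8 individuals; one site fails each of
  # QUAL, mean depth, MAC; one is triallelic; hand-counted survivors: 6
  n <- 8
  gt <- matrix(rep(c(0, 0, 1, 1, 2, 2, 0, 1), 10), n, 10)  # MAC 4 per site
  gt[, 5] <- c(0, 0, 0, 0, 0, 0, 0, 1)                     # MAC 1 -> fails
  dp <- matrix(30, n, 10)
  dp[, 4] <- 8                                             # mean depth 8
  qual <- rep(60, 10); qual[2] <- 10                       # fails QUAL
  alt <- rep("T", 10); alt[9] <- "T,G"                     # triallelic
  dimnames(gt) <- list(paste0("s", 1:n), paste0("v", 1:10))
  dimnames(dp) <- dimnames(gt)
  vt <- new("VariantTable", chrom = rep("chr1", 10), pos = 1:10 * 50L,
            ref = rep("A", 10), alt = alt, qual = qual, mq = rep(60, 10),
            locus = paste0("uce-", 1:10), gt = gt, dp = dp)
  res <- applyFilterChain(vt, filterConfig())
  expect_equal(res$report$sitesOut,
               c(10, 9, 8, 8, 7, 7, 6, 6))
  expect_equal(nLoci(res$genotypes), 6)
  expect_false(any(c("v2", "v4", "v5", "v9") %in% lociIds(res$genotypes)))

  # report conservation: each step's out is the next step's in
  expect_equal(res$report$sitesIn[-1],
               res$report$sitesOut[-nrow(res$report)])

  # all-pass fixture: identity, constant counts
  vtOk <- vt[, c(1, 3, 6, 7, 8, 10)]
  resOk <- applyFilterChain(vtOk, filterConfig())
  expect_equal(unique(resOk$report$sitesOut), 6)

  # idempotence: refiltering the surviving genotypes changes nothing
  surv <- vt[, match(lociIds(res$genotypes), colnames(vt@gt))]
  res2 <- applyFilterChain(surv, filterConfig())
  expect_identical(genotypes(res2$genotypes), genotypes(res$genotypes))

  # missing annotation for an enabled rule is a configuration error
  vtNoMq <- vt
  vtNoMq@mq <- rep(NA_real_, 10)
  expect_error(applyFilterChain(vtNoMq, filterConfig()), "annotation")
})

test_that("MAC is computed on depth-masked genotypes", {
  # site where low-depth calls carry all the minor alleles: masking them
  # must drop the MAC below threshold
  gt <- matrix(0, 8, 1, dimnames = list(paste0("s", 1:8), "v1"))
  gt[1:3, 1] <- 1
  dp <- matrix(30, 8, 1, dimnames = dimnames(gt))
  dp[1:3, 1] <- 2   # the three het calls are low-depth
  vt <- new("VariantTable", chrom = "chr1", pos = 1L, ref = "A", alt = "T",
            qual = 60, mq = 60, locus = "uce-1", gt = gt, dp = dp)
  res <- applyFilterChain(vt, filterConfig(maxSiteMissing = 1,
                                           oneSnpPerLocus = FALSE))
  expect_equal(nLoci(res$genotypes), 0)
  withDepth <- applyFilterChain(vt, filterConfig(minGenotypeDepth = 0,
                                                 maxSiteMissing = 1,
                                                 oneSnpPerLocus = FALSE))
  expect_equal(nLoci(withDepth$genotypes), 1)
})

test_that("individual missingness uses a strict threshold", {
  g <- matrix(0, 3, 100, dimnames = list(c("keep20", "drop21", "clean"),
                                         paste0("v", 1:100)))
  g["keep20", 1:20] <- NA   # exactly 20%
  g["drop21", 1:21] <- NA   # strictly more
  gm <- GenotypeMatrix(g)
  out <- removeHighMissingIndividuals(gm, 0.20)
  expect_identical(out$removed$id, "drop21")
  expect_setequal(sampleIds(out$genotypes), c("keep20", "clean"))

  clean <- removeHighMissingIndividuals(GenotypeMatrix(matrix(1, 4, 5)), 0.2)
  expect_equal(nSamples(clean$genotypes), 4)
  allNA <- GenotypeMatrix(matrix(NA_real_, 2, 5))
  expect_error(removeHighMissingIndividuals(allNA, 0.2), "all individuals")
})

test_that("one-SNP-per-locus thinning keeps the best-called SNP", {
  g <- matrix(1, 4, 4, dimnames = list(paste0("s", 1:4), paste0("v", 1:4)))
  g[1:2, 1] <- NA  # v1 has worse call rate than v2
  gm <- GenotypeMatrix(g, lociInfo = data.frame(
    locus = c("A", "A", "A", "B"), pos = c(10L, 30L, 20L, 5L),
    row.names = paste0("v", 1:4)))
  thin <- thinOneSnpPerLocus(gm)
  # locus A: v2 and v3 tie on call rate; v3 wins on lower pos
  expect_setequal(lociIds(thin), c("v3", "v4"))

  distinct <- GenotypeMatrix(matrix(1, 3, 3), lociInfo = data.frame(
    locus = c("A", "B", "C"), row.names = paste0("snp", 1:3)))
  expect_equal(nLoci(thinOneSnpPerLocus(distinct)), 3)
  expect_error(thinOneSnpPerLocus(GenotypeMatrix(matrix(1, 2, 2))), "locus")
})

test_that("spatial grouping uses single linkage with a 1 km chain rule", {
  meta <- data.frame(id = c("a", "b", "c"), x = c(0, 900, 1800), y = 0)
  labs <- groupByLocation(meta, radius = 1000)
  expect_equal(length(unique(labs)), 1)

  meta2 <- data.frame(id = c("a", "b"), x = c(0, 1200), y = 0)
  expect_equal(length(unique(groupByLocation(meta2, radius = 1000))), 2)

  dup <- data.frame(id = c("a", "b"), x = c(5, 5), y = c(5, 5))
  expect_equal(length(unique(groupByLocation(dup))), 1)

  withNA <- data.frame(id = c("a", "b"), x = c(0, NA), y = c(0, NA))
  expect_warning(labs3 <- groupByLocation(withNA), "unlabelled")
  expect_true(is.na(labs3["b"]))
})

test_that("over-sampled site curation keeps recent, unrelated samples", {
  ids <- paste0("s", 1:10)
  g <- matrix(rbinom(10 * 50, 2, 0.5), 10, 50, dimnames = list(ids, NULL))
  gm <- GenotypeMatrix(g)
  meta <- data.frame(id = ids,
                     location = c(rep("RP", 8), "other", "other"),
                     date = as.Date("2021-01-01") - c(0:7, 0, 0) * 100,
                     row.names = ids)
  rel <- matrix(0, 10, 10, dimnames = list(ids, ids))
  # s1 (newest) and s2 (next) are a first-degree pair
  rel["s1", "s2"] <- rel["s2", "s1"] <- 0.5
  out <- subsetOversampledSite(gm, meta, rel, "RP", nKeep = 5)
  expect_equal(length(out$kept), 5)
  expect_true("s1" %in% out$kept)   # newer member of the pair
  expect_false("s2" %in% out$kept)  # older member skipped
  expect_identical(out$kept, c("s1", "s3", "s4", "s5", "s6"))
  expect_true(all(c("s9", "s10") %in% sampleIds(out$genotypes)))

  # nKeep >= site size with no relatives: identity
  rel0 <- matrix(0, 10, 10, dimnames = list(ids, ids))
  outAll <- subsetOversampledSite(gm, meta, rel0, "RP", nKeep = 8)
  expect_equal(length(outAll$kept), 8)

  # all pairs first-degree: only the newest survives
  relAll <- matrix(0.6, 10, 10, dimnames = list(ids, ids))
  diag(relAll) <- NA
  out1 <- subsetOversampledSite(gm, meta, relAll, "RP", nKeep = 5)
  expect_identical(out1$kept, "s1")

  expect_error(subsetOversampledSite(gm, meta, rel, "nowhere"), "site")
})
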