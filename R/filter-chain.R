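#' Filter configuration for the post-variant-calling chain
#'
#' Defaults follow standard practice for reduced-representation SNP data:
#' genotype calls supported by fewer than 5 reads are masked, then sites are
#' dropped for QUAL < 20, mean depth across individuals < 10, mapping
#' quality < 30, minor allele count < 3, call rate < 95%, or more than two
#' alleles, and finally thinned to one SNP per UCE locus.
#'
#' @param minGenotypeDepth mask genotypes with read depth below this (5).
#' @param minSiteQuality drop sites with QUAL below this (20).
#' @param minMeanDepth drop sites whose mean depth across individuals is
#'   below this (10).
#' @param minMappingQuality drop sites with MQ below this (30).
#' @param minMac drop sites with minor allele count below this (3).
#' @param maxSiteMissing drop sites with missing-call fraction strictly
#'   greater than this (0.05, i.e. call rate >= 95% retained).
#' @param maxIndividualMissing threshold for
#'   [removeHighMissingIndividuals()] (0.20).
#' @param biallelicOnly keep only biallelic sites (TRUE).
#' @param oneSnpPerLocus thin to one SNP per locus (TRUE).
#' @return list of class `FilterConfig`.
#' @export
filterConfig <- function(minGenotypeDepth = 5, minSiteQuality = 20,
                         minMeanDepth = 10, minMappingQuality = 30,
                         minMac = 3, maxSiteMissing = 0.05,
                         maxIndividualMissing = 0.20,
                         biallelicOnly = TRUE, oneSnpPerLocus = TRUE) {
  cfg <- list(minGenotypeDepth = minGenotypeDepth,
              minSiteQuality = minSiteQuality, minMeanDepth = minMeanDepth,
              minMappingQuality = minMappingQuality, minMac = minMac,
              maxSiteMissing = maxSiteMissing,
              maxIndividualMissing = maxIndividualMissing,
              biallelicOnly = biallelicOnly, oneSnpPerLocus = oneSnpPerLocus)
  num <- unlist(cfg[1:7])
  if (any(num < 0)) stop("thresholds must be nonnegative")
  if (cfg$maxSiteMissing > 1 || cfg$maxIndividualMissing > 1)
    stop("missingness fractions must lie in [0, 1]")
  structure(cfg, class = "FilterConfig")
}

#' Apply the site filter chain to variant records
#'
#' Rules run in a fixed order: genotype-level depth mask (failing calls
#' become missing, the site is kept), then site-level removals — quality,
#' mean depth across individuals, mapping quality, minor allele count
#' (computed on the *masked* genotypes, so depth-masked calls count as
#' missing), call rate, biallelic-only — and finally one SNP per UCE locus
#' (tie-break: highest call rate, then lowest position). A step whose
#' annotation is entirely absent from the records raises a configuration
#' error. Set a threshold argument of [filterConfig()] to 0 (or the flag to
#' FALSE) to disable its rule.
#'
#' @param vt a [VariantTable-class].
#' @param cfg a [filterConfig()].
#' @return list with `genotypes` (a [GenotypeMatrix-class] of surviving
#'   sites), and `report` (data.frame with columns step, sitesIn, sitesOut).
#' @export
applyFilterChain <- function(vt, cfg = filterConfig()) {
  report <- data.frame(step = character(), sitesIn = integer(),
                       sitesOut = integer(), stringsAsFactors = FALSE)
  note <- function(step, before, after) {
    report <<- rbind(report, data.frame(step = step, sitesIn = before,
                                        sitesOut = after))
  }
  needAnnotation <- function(values, rule) {
    if (all(is.na(values)))
      stop("rule '", rule, "' is enabled but its annotation is missing ",
           "from the records")
  }

  # 1. genotype-level depth mask: failing calls -> missing, sites retained
  if (cfg$minGenotypeDepth > 0) {
    needAnnotation(vt@dp, "minGenotypeDepth")
    masked <- !is.na(vt@dp) & vt@dp < cfg$minGenotypeDepth
    vt@gt[masked] <- NA
    note("genotype depth mask", nSites(vt), nSites(vt))
  }
  keepSites <- function(keep, label) {
    note(label, nSites(vt), sum(keep))
    vt <<- vt[, keep]
  }
  if (cfg$minSiteQuality > 0) {
    needAnnotation(vt@qual, "minSiteQuality")
    keepSites(!is.na(vt@qual) & vt@qual >= cfg$minSiteQuality, "site quality")
  }
  if (cfg$minMeanDepth > 0) {
    needAnnotation(vt@dp, "minMeanDepth")
    meanDp <- colMeans(vt@dp, na.rm = TRUE)
    keepSites(meanDp >= cfg$minMeanDepth, "mean depth")
  }
  if (cfg$minMappingQuality > 0) {
    needAnnotation(vt@mq, "minMappingQuality")
    keepSites(!is.na(vt@mq) & vt@mq >= cfg$minMappingQuality,
              "mapping quality")
  }
  if (cfg$minMac > 0) {
    mac <- siteMac(vt@gt)
    keepSites(mac >= cfg$minMac, "minor allele count")
  }
  if (cfg$maxSiteMissing < 1) {
    missFrac <- colMeans(is.na(vt@gt))
    keepSites(missFrac <= cfg$maxSiteMissing, "call rate")
  }
  if (isTRUE(cfg$biallelicOnly)) {
    keepSites(!grepl(",", vt@alt), "biallelic only")
  }
  if (isTRUE(cfg$oneSnpPerLocus) && !all(is.na(vt@locus))) {
    keep <- thinIndices(vt)
    keepSites(seq_len(nSites(vt)) %in% keep, "one SNP per locus")
  }
  list(genotypes = asGenotypeMatrix(vt), report = report)
}

# minor allele count per site on coded genotypes (masked calls = missing)
siteMac <- function(gt) {
  altCount <- colSums(gt, na.rm = TRUE)
  genes <- 2 * colSums(!is.na(gt))
  pmin(altCount, genes - altCount)
}

# one SNP per locus: highest call rate wins, then lowest position
thinIndices <- function(vt) {
  callRate <- colMeans(!is.na(vt@gt))
  ord <- order(vt@locus, -callRate, vt@pos)
  ord[!duplicated(vt@locus[ord])]
}

#' Remove individuals with excessive missing data
#'
#' Individuals whose missing-call fraction is *strictly greater* than the
#' threshold are removed (an individual at exactly the threshold is kept).
#'
#' @param gm a [GenotypeMatrix-class].
#' @param maxIndividualMissing threshold in [0, 1]; default 0.20.
#' @return list with `genotypes` (filtered matrix) and `removed` (ids with
#'   their missing fractions).
#' @export
removeHighMissingIndividuals <- function(gm, maxIndividualMissing = 0.20) {
  if (maxIndividualMissing < 0 || maxIndividualMissing > 1)
    stop("threshold must lie in [0, 1]")
  frac <- missingRateByIndividual(gm)
  drop <- frac > maxIndividualMissing
  if (all(drop)) stop("all individuals exceed the missingness threshold")
  list(genotypes = gm[!drop, ],
       removed = data.frame(id = sampleIds(gm)[drop],
                            missingFraction = unname(frac[drop])))
}

#' Thin a genotype matrix to one SNP per locus
#'
#' @param gm a [GenotypeMatrix-class]; every SNP must carry a `locus`
#'   assignment in `lociInfo` (or supply `locus`).
#' @param locus optional character vector of locus ids per SNP.
#' @return A thinned [GenotypeMatrix-class]; the retained SNP per locus is
#'   the one with the highest call rate, ties broken by lowest position
#'   (column order when positions are absent).
#' @export
thinOneSnpPerLocus <- function(gm, locus = NULL) {
  if (is.null(locus)) locus <- lociInfo(gm)$locus
  if (is.null(locus) || anyNA(locus))
    stop("every SNP must be mapped to a locus id")
  g <- genotypes(gm)
  callRate <- colMeans(!is.na(g))
  pos <- lociInfo(gm)$pos
  if (is.null(pos)) pos <- seq_len(ncol(g))
  ord <- order(locus, -callRate, pos)
  keep <- sort(ord[!duplicated(locus[ord])])
  gm[, keep]
}

#' Write a filter report as TSV and JSON
#' @param report data.frame from [applyFilterChain()].
#' @param prefix output path prefix (writes `<prefix>.tsv`,
#'   `<prefix>.json`).
#' @export
writeFilterReport <- function(report, prefix) {
  write.table(report, paste0(prefix, ".tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  jsonlite::write_json(report, paste0(prefix, ".json"), dataframe = "rows")
  invisible(prefix)
}
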