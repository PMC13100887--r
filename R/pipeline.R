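#' Run the population-genetics pipeline
#'
#' End-to-end orchestration on either user data or a synthetic scenario:
#' obtain a genotype matrix and population labels, compute the per-population
#' diversity table, overall and pairwise Weir-Cockerham Fst, the Hs table,
#' and (when urban proportions are available) the Hs ~ urban regression.
#' All artifacts are written under `outDir` together with a run manifest;
#' identical configuration and seeds reproduce identical outputs.
#'
#' @param config list with either
#'   \describe{
#'     \item{scenario}{a [SyntheticScenario-class]: genotypes are simulated
#'       under the island model at the scenario's `fstTarget`}
#'     \item{vcf / genotypeCsv + metadata}{paths to user data; populations
#'       are taken from the metadata `location` column or derived with
#'       [groupByLocation()]}
#'   }
#'   plus optional `filter` (a [filterConfig()]), `fstBoot` (default 200),
#'   `seed` (default 1).
#' @param outDir output directory (created).
#' @return list with `genotypes`, `summary`, `fst`, `hs`, `manifest`
#'   (invisible file paths in `manifest$files`).
#' @export
runPopgenPipeline <- function(config, outDir) {
  t0 <- Sys.time()
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  warnings <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }

  if (!is.null(config$scenario)) {
    sc <- config$scenario
    gm <- stage("simulate", simulateIslandGenotypes(
      sc@nPops, sc@nPerPop, sc@nLoci, sc@fstTarget, seed = sc@seed))
    pops <- popLabels(gm)
  } else {
    gm <- stage("read", {
      if (!is.null(config$vcf)) {
        vt <- readGenotypeVcf(config$vcf)
        res <- applyFilterChain(vt, if (is.null(config$filter))
          filterConfig() else config$filter)
        res$genotypes
      } else readGenotypeCsv(config$genotypeCsv)
    })
    meta <- stage("metadata", readSampleMetadata(config$metadata))
    pops <- if ("location" %in% names(meta)) {
      as.character(meta[sampleIds(gm), "location"])
    } else unname(groupByLocation(meta)[sampleIds(gm)])
  }
  tab <- table(pops)
  if (any(tab == 0) || any(is.na(pops)))
    stop("stage 'populations': empty or missing population label")

  summary <- stage("diversity", diversitySummary(
    GenotypeMatrix(genotypes(gm),
                   sampleInfo = data.frame(pop = pops,
                                           row.names = sampleIds(gm)),
                   lociInfo = lociInfo(gm)), pops))
  nBoot <- if (is.null(config$fstBoot)) 200 else config$fstBoot
  fst <- stage("fst", wcFst(gm, pops, pairwise = TRUE, nBoot = nBoot,
                            seed = seed))
  hs <- stage("hs", standardizedHeterozygosity(gm))

  hsUrban <- NULL
  if (!is.null(config$urban)) {
    hsUrban <- stage("hs-urban", fitHsUrban(hs, config$urban))
  }

  files <- c(summary = file.path(outDir, "diversity_summary.tsv"),
             fst = file.path(outDir, "fst_pairwise.tsv"),
             hs = file.path(outDir, "hs_table.csv"),
             manifest = file.path(outDir, "manifest.json"))
  write.table(summary, files["summary"], sep = "\t", row.names = FALSE,
              quote = FALSE)
  write.table(data.frame(pop = rownames(fst$pairwise), fst$pairwise,
                         check.names = FALSE),
              files["fst"], sep = "\t", row.names = FALSE, quote = FALSE)
  write.csv(hs, files["hs"], row.names = FALSE)
  manifest <- list(
    pipeline = "popgen", seed = seed,
    nIndividuals = nSamples(gm), nLoci = nLoci(gm),
    populations = as.list(tab),
    overallTheta = fst$overall$theta,
    wallClockSec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    warnings = warnings, files = as.list(files))
  jsonlite::write_json(manifest, files["manifest"], auto_unbox = TRUE,
                       digits = NA)
  invisible(list(genotypes = gm, summary = summary, fst = fst, hs = hs,
                 hsUrban = hsUrban, manifest = manifest))
}

#' Run the landscape-connectivity pipeline
#'
#' Builds (or loads) the landscape, obtains individual locations and a
#' genetic distance matrix — simulated under isolation by resistance for a
#' synthetic scenario — then runs the full MLPE model suite, writes the
#' comparison table, the averaged passage map (under the first hypothesis)
#' and the least-cost routes, plus a manifest recording snapping and seeds.
#'
#' @param config list with `scenario` (a [SyntheticScenario-class]) or
#'   `landcover`+`points`+`gdist` paths; optional `hypotheses` (default
#'   c("NULL", "EMP")-style names valid for the landscape), `algorithms`,
#'   `includeDistance`, `epsilon`, `seed`.
#' @param outDir output directory.
#' @return list with `comparison`, `fits`, `passage`, `paths`, `manifest`.
#' @export
runConnectivityPipeline <- function(config, outDir) {
  t0 <- Sys.time()
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }

  if (!is.null(config$scenario)) {
    sc <- config$scenario
    lc <- stage("landscape", pruneIsolatedHabitat(
      generateLandscape(sc@landscape, seed = sc@seed)))
    hyps <- if (is.null(config$hypotheses)) c("NULL", "EMP")
            else config$hypotheses
    genSurface <- stage("surface", buildResistanceSurface(
      lc, if (is.null(config$generatingHypothesis)) hyps[length(hyps)]
          else config$generatingHypothesis))
    pts <- stage("locations", sampleClusteredLocations(
      genSurface, sc@nPops, sc@nPerPop, seed = sc@seed))
    phi <- sc@ibrPhi
    if (is.na(phi)) {
      gTmp <- buildTransitionGraph(genSurface, epsilon = 1e-4)
      sites <- pts[!duplicated(pts$location), ]
      dTmp <- distanceValues(commuteDistance(gTmp, sites))
      phi <- median(dTmp[upper.tri(dTmp)])
    }
    gm <- stage("simulate", simulateIbrGenotypes(
      pts, genSurface, sc@nLoci, phi = phi, sigma2 = sc@ibrSigma2,
      seed = sc@seed))
    gdist <- stage("gdist", geneticDistance(gm))
  } else {
    lc <- stage("landscape", readLandcover(config$landcover))
    pts <- stage("points", read.csv(config$points))
    gdist <- stage("gdist", {
      m <- as.matrix(read.csv(config$gdist, row.names = 1,
                              check.names = FALSE))
      new("PairwiseDistanceMatrix", values = m, kind = "genetic",
          units = "dimensionless")
    })
    hyps <- config$hypotheses
  }

  suite <- stage("mlpe-suite", runModelSuite(
    gdist, lc, hyps, pts,
    algorithms = if (is.null(config$algorithms)) c("lcp", "commute")
                 else config$algorithms,
    includeDistance = !isFALSE(config$includeDistance),
    epsilon = if (is.null(config$epsilon)) 1e-4 else config$epsilon))

  firstHyp <- if (is.character(hyps[[1]]))
    resistanceHypothesis(hyps[[1]], classes = unname(lc@legend))
  else hyps[[1]]
  rsFirst <- buildResistanceSurface(lc, firstHyp)
  gPass <- buildTransitionGraph(rsFirst, epsilon = 1e-4)
  pass <- stage("passage", passageMap(gPass, pts))
  gLcp <- buildTransitionGraph(rsFirst, epsilon = 0)
  routes <- stage("routes", lcpDistance(gLcp, pts, paths = TRUE)$paths)

  files <- c(comparison = file.path(outDir, "model_comparison.tsv"),
             passage = file.path(outDir, "passage_map.asc"),
             routes = file.path(outDir, "lcp_routes.csv"),
             manifest = file.path(outDir, "manifest.json"))
  writeComparisonTable(suite$comparison, files["comparison"])
  writeAsciiGrid(pass, files["passage"], lc@resolution, lc@origin)
  write.csv(routes, files["routes"], row.names = FALSE)
  manifest <- list(
    pipeline = "connectivity", seed = seed,
    nPoints = nrow(pts), nPairs = nrow(suite$table),
    hypotheses = as.character(vapply(hyps, function(h)
      if (is.character(h)) h else h@name, character(1))),
    best = suite$comparison$model[suite$comparison$best],
    wallClockSec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    files = as.list(files))
  jsonlite::write_json(manifest, files["manifest"], auto_unbox = TRUE,
                       digits = NA)
  invisible(list(comparison = suite$comparison, fits = suite$fits,
                 passage = pass, paths = routes, manifest = manifest))
}
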