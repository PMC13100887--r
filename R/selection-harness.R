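#' Reference landscape specification for model-selection experiments
#'
#' A compact urban-mosaic template: garden and woodland patches (the
#' woodland contrast matters — it is traversable under every hypothesis but
#' carries high empirical resistance, so the candidate surfaces are
#' genuinely distinguishable), building and impervious patches, and
#' crossing street/railway strips.
#'
#' @param nrow,ncol grid dimensions; default 24 x 24.
#' @param resolution cell size in metres; default 5.
#' @return a landscape spec list for [generateLandscape()].
#' @export
ibrStudyLandscapeSpec <- function(nrow = 24, ncol = 24, resolution = 5) {
  list(nrow = nrow, ncol = ncol, resolution = resolution, classes = list(
    list(name = "Private Garden", weight = 2),
    list(name = "Woodland", weight = 2),
    list(name = "Buildings", weight = 1),
    list(name = "Impervious", weight = 1),
    list(name = "Large street", type = "vstrip", width = 2),
    list(name = "Railways", type = "hstrip", width = 2)))
}

#' Remove habitat pockets isolated by absolute barriers
#'
#' Random patch landscapes can enclose small traversable pockets entirely
#' ringed by barrier classes; random-walk commute distances are undefined
#' across such physical breaks (conductance repair only reconnects cells
#' isolated by high *resistance*, not by barriers). This utility keeps the
#' largest 8-connected non-barrier component and converts every other
#' non-barrier cell to the first barrier class, so all movement hypotheses
#' share one connected habitat.
#'
#' @param lc a [LandcoverRaster-class].
#' @param barrierClasses classes treated as absolute barriers; default
#'   buildings and waterbodies.
#' @return A [LandcoverRaster-class] with isolated pockets reclassified.
#' @export
pruneIsolatedHabitat <- function(lc, barrierClasses = c("Buildings",
                                                        "Waterbodies")) {
  codes <- lc@codes
  legend <- lc@legend
  barrierCodes <- as.integer(names(legend)[legend %in% barrierClasses])
  if (!length(barrierCodes))
    stop("no barrier class present in the legend")
  open <- !(codes %in% barrierCodes)
  dim(open) <- dim(codes)
  lab <- matrix(0L, nrow(codes), ncol(codes))
  cur <- 0L
  for (start in which(open)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    nr <- nrow(codes)
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      r0 <- ((v - 1L) %% nr) + 1L; c0 <- ((v - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- r0 + dr; c2 <- c0 + dc
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > ncol(codes)) next
        w <- (c2 - 1L) * nr + r2
        if (open[w] && lab[w] == 0L) { lab[w] <- cur; stack <- c(stack, w) }
      }
    }
  }
  if (cur > 1L) {
    sizes <- tabulate(lab[lab > 0L], cur)
    keep <- which.max(sizes)
    codes[open & lab != keep] <- barrierCodes[1]
  }
  new("LandcoverRaster", codes = codes, resolution = lc@resolution,
      origin = lc@origin, legend = legend)
}

#' One isolation-by-distance / isolation-by-resistance selection experiment
#'
#' Generates a landscape, samples clustered individual locations on the
#' truth surface, simulates genotypes under the spatial logit-normal model
#' with covariance decaying in commute distance on that surface, and runs
#' the MLPE suite over the candidate hypotheses. The spatial range defaults
#' to `phiFraction` times the median pairwise commute distance among sites,
#' so differentiation decays appreciably across the study extent.
#'
#' @param seed integer seed (drives landscape, locations and genotypes).
#' @param truth generating hypothesis name ("EMP" for isolation by
#'   resistance, "NULL" for isolation by distance).
#' @param candidates hypothesis names to compare; default c("NULL", "EMP").
#' @param nClusters,nPerCluster sampling design; default 5 x 4.
#' @param nLociSim loci; default 1500.
#' @param sigma2 logit-frequency variance; default 1.
#' @param phiFraction fraction of the median site commute distance used as
#'   the covariance range; default 0.5.
#' @param algorithms connectivity algorithms for the suite; default "lcp".
#' @param includeDistance fit models with a Euclidean term too; default
#'   FALSE.
#' @param landscapeSpec landscape template; default
#'   [ibrStudyLandscapeSpec()].
#' @return list with `aicc` (named per candidate x algorithm), `comparison`
#'   and `points`.
#' @export
runSelectionExperiment <- function(seed, truth = "EMP",
                                   candidates = c("NULL", "EMP"),
                                   nClusters = 5, nPerCluster = 4,
                                   nLociSim = 1500, sigma2 = 1,
                                   phiFraction = 0.5, algorithms = "lcp",
                                   includeDistance = FALSE,
                                   landscapeSpec = ibrStudyLandscapeSpec()) {
  lc <- pruneIsolatedHabitat(generateLandscape(landscapeSpec, seed = seed))
  rsTruth <- buildResistanceSurface(lc, truth)
  pts <- sampleClusteredLocations(rsTruth, nClusters, nPerCluster,
                                  seed = seed)
  gT <- buildTransitionGraph(rsTruth, epsilon = 1e-4)
  sites <- pts[!duplicated(pts$location), ]
  dS <- distanceValues(commuteDistance(gT, sites))
  phi <- phiFraction * median(dS[upper.tri(dS)])
  gm <- simulateIbrGenotypes(pts, rsTruth, nLociSim, phi = phi,
                             sigma2 = sigma2, seed = seed)
  gdist <- geneticDistance(gm)
  suite <- runModelSuite(gdist, lc, candidates, pts,
                         algorithms = algorithms,
                         includeDistance = includeDistance)
  cmp <- suite$comparison
  key <- paste0(cmp$hypothesis, ".", cmp$algorithm,
                ifelse(cmp$distTerm, ".dist", ""))
  list(aicc = setNames(cmp$AICc, key), comparison = cmp, points = pts)
}
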