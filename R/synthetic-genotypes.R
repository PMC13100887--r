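#' Simulate genotypes under a Balding-Nichols island model
#'
#' Ancestral allele frequencies are drawn Uniform(0.1, 0.9); each
#' population's frequency is Beta-distributed with mean `p` and variance
#' `fstTarget * p * (1 - p)`; genotypes are Binomial(2, p_pop). With
#' `fstTarget = 0` every population uses the ancestral frequency exactly.
#' The expected Weir-Cockerham theta over many loci equals `fstTarget`.
#'
#' @param nPops number of demes.
#' @param nPerPop individuals per deme.
#' @param nLoci number of biallelic loci.
#' @param fstTarget target differentiation in [0, 1).
#' @param seed integer seed; identical seed gives identical output.
#' @return A [GenotypeMatrix-class] with a `pop` column in `sampleInfo`.
#' @export
simulateIslandGenotypes <- function(nPops, nPerPop, nLoci, fstTarget, seed) {
  if (fstTarget < 0 || fstTarget >= 1) stop("fstTarget must lie in [0, 1)")
  stopifnot(nPops >= 1, nPerPop >= 1, nLoci >= 1)
  set.seed(seed)
  pAnc <- runif(nLoci, 0.1, 0.9)
  if (fstTarget == 0) {
    pPop <- matrix(pAnc, nrow = nPops, ncol = nLoci, byrow = TRUE)
  } else {
    scale <- (1 - fstTarget) / fstTarget
    pPop <- matrix(rbeta(nPops * nLoci,
                         shape1 = rep(pAnc * scale, each = nPops),
                         shape2 = rep((1 - pAnc) * scale, each = nPops)),
                   nrow = nPops, ncol = nLoci)
  }
  n <- nPops * nPerPop
  popIdx <- rep(seq_len(nPops), each = nPerPop)
  g <- matrix(rbinom(n * nLoci, 2L, pPop[popIdx, ]), nrow = n, ncol = nLoci)
  rownames(g) <- sprintf("p%02d_i%03d", popIdx, seq_len(n))
  colnames(g) <- sprintf("snp%05d", seq_len(nLoci))
  GenotypeMatrix(g, sampleInfo = data.frame(
    pop = sprintf("pop%02d", popIdx), row.names = rownames(g)))
}

#' Simulate genotypes under isolation by resistance
#'
#' A logit-normal spatial model: pairwise commute distances `d_ij` between
#' sampling locations are computed on the supplied resistance surface; per
#' locus, location-level deviations on the logit-frequency scale are drawn
#' from a zero-mean Gaussian with covariance `sigma2 * exp(-d_ij / phi)`,
#' added to a Uniform(0.1, 0.9) ancestral logit frequency, back-transformed
#' and clipped to [0.01, 0.99]; genotypes are Binomial(2, freq). With
#' `sigma2 = 0` the result is panmictic; with `sigma2 > 0` pairwise genetic
#' distance increases with commute distance in expectation.
#'
#' @param locations data.frame with columns `id`, `x`, `y` (projected m) and
#'   optionally `location` (cluster label); one row per individual.
#' @param surface a [ResistanceSurface-class]; all locations must fall on
#'   traversable cells.
#' @param nLoci number of loci.
#' @param phi spatial range parameter (> 0), commute-distance units.
#' @param sigma2 logit-frequency variance (>= 0).
#' @param seed integer seed.
#' @param epsilon conductance repair passed to [buildTransitionGraph()];
#'   default 1e-4.
#' @return A [GenotypeMatrix-class] whose `sampleInfo` carries x, y and (if
#'   given) location labels.
#' @export
simulateIbrGenotypes <- function(locations, surface, nLoci, phi, sigma2, seed,
                                 epsilon = 1e-4) {
  if (phi <= 0) stop("phi must be positive")
  if (sigma2 < 0) stop("sigma2 must be nonnegative")
  stopifnot(all(c("id", "x", "y") %in% names(locations)))
  cells <- cellAt(surface, as.matrix(locations[, c("x", "y")]))
  if (anyNA(cells)) stop("location outside the surface extent")
  onBarrier <- is.na(surface@resistance[cells])
  if (any(onBarrier))
    stop("location on a barrier cell: ",
         paste(locations$id[onBarrier], collapse = ", "))

  # distinct sites (several individuals may share a cell)
  siteKey <- paste(cells[, 1], cells[, 2], sep = "_")
  sites <- !duplicated(siteKey)
  siteOf <- match(siteKey, siteKey[sites])
  g <- buildTransitionGraph(surface, epsilon = epsilon)
  pts <- data.frame(id = siteKey[sites],
                    x = locations$x[sites], y = locations$y[sites])
  D <- distanceValues(commuteDistance(g, pts))

  set.seed(seed)
  nSites <- nrow(D)
  mu <- qlogis(runif(nLoci, 0.1, 0.9))
  if (sigma2 > 0) {
    C <- sigma2 * exp(-D / phi)
    L <- chol(C + diag(1e-10, nSites))
    z <- crossprod(L, matrix(rnorm(nSites * nLoci), nSites, nLoci))
  } else {
    z <- matrix(0, nSites, nLoci)
  }
  freq <- plogis(sweep(z, 2L, mu, "+"))
  freq <- pmin(pmax(freq, 0.01), 0.99)
  n <- nrow(locations)
  gm <- matrix(rbinom(n * nLoci, 2L, freq[siteOf, , drop = FALSE]), n, nLoci)
  rownames(gm) <- locations$id
  colnames(gm) <- sprintf("snp%05d", seq_len(nLoci))
  info <- data.frame(x = locations$x, y = locations$y,
                     row.names = locations$id)
  if ("location" %in% names(locations)) info$location <- locations$location
  GenotypeMatrix(gm, sampleInfo = info)
}

#' Pedigree specification
#'
#' @param id individual identifiers.
#' @param dam,sire parent ids or NA (founders); parents must precede their
#'   offspring in the listing.
#' @param cloneOf optional: id of an individual this one duplicates exactly
#'   (for clone / identity checks).
#' @return data.frame of class checked by [simulatePedigreeGenotypes()].
#' @export
pedigreeSpec <- function(id, dam = NA, sire = NA, cloneOf = NA) {
  ped <- data.frame(id = as.character(id),
                    dam = as.character(dam), sire = as.character(sire),
                    cloneOf = as.character(cloneOf),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(ped))) {
    for (p in c(ped$dam[i], ped$sire[i], ped$cloneOf[i])) {
      if (!is.na(p) && !p %in% ped$id[seq_len(i - 1L)])
        stop("parent/clone source '", p, "' must precede '", ped$id[i],
             "' (pedigree must be acyclic with parents first)")
    }
  }
  ped
}

#' Simulate genotypes down a pedigree by Mendelian sampling
#'
#' Founders are drawn Binomial(2, p) from the founder allele frequencies;
#' each offspring receives one allele from each parent, transmitted with
#' probability `genotype / 2`. Clones copy their source exactly.
#'
#' @param ped a [pedigreeSpec()] data.frame.
#' @param nLociSim number of loci.
#' @param seed integer seed.
#' @param founderFreq allele frequencies, length `nLociSim` or recycled;
#'   default Uniform(0.1, 0.9) draws. Must lie in (0, 1).
#' @return list with `genotypes` (a [GenotypeMatrix-class]) and
#'   `relationships` (data.frame of all pairs with a `relation` column:
#'   clone, parent-offspring, full-sib, half-sib, unrelated, other).
#' @export
simulatePedigreeGenotypes <- function(ped, nLociSim, seed, founderFreq = NULL) {
  set.seed(seed)
  if (is.null(founderFreq)) founderFreq <- runif(nLociSim, 0.1, 0.9)
  founderFreq <- rep_len(founderFreq, nLociSim)
  if (any(founderFreq <= 0) || any(founderFreq >= 1))
    stop("founder frequencies must lie in (0, 1)")
  n <- nrow(ped)
  g <- matrix(NA_integer_, n, nLociSim, dimnames = list(ped$id, NULL))
  transmit <- function(geno) rbinom(nLociSim, 1L, geno / 2)
  for (i in seq_len(n)) {
    if (!is.na(ped$cloneOf[i])) {
      g[i, ] <- g[ped$cloneOf[i], ]
    } else if (is.na(ped$dam[i]) && is.na(ped$sire[i])) {
      g[i, ] <- rbinom(nLociSim, 2L, founderFreq)
    } else {
      fromDam <- if (is.na(ped$dam[i])) rbinom(nLociSim, 1L, founderFreq)
                 else transmit(g[ped$dam[i], ])
      fromSire <- if (is.na(ped$sire[i])) rbinom(nLociSim, 1L, founderFreq)
                  else transmit(g[ped$sire[i], ])
      g[i, ] <- fromDam + fromSire
    }
  }
  colnames(g) <- sprintf("snp%05d", seq_len(nLociSim))
  list(genotypes = GenotypeMatrix(g),
       relationships = classifyPedigreePairs(ped))
}

# label every unordered pair by its pedigree relationship
classifyPedigreePairs <- function(ped) {
  n <- nrow(ped)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  rel <- character(nrow(pairs))
  parents <- function(i) stats::na.omit(c(ped$dam[i], ped$sire[i]))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    pi <- parents(i); pj <- parents(j)
    if ((!is.na(ped$cloneOf[j]) && ped$cloneOf[j] == ped$id[i]) ||
        (!is.na(ped$cloneOf[i]) && ped$cloneOf[i] == ped$id[j])) {
      rel[k] <- "clone"
    } else if (ped$id[i] %in% pj || ped$id[j] %in% pi) {
      rel[k] <- "parent-offspring"
    } else if (length(pi) == 2 && length(pj) == 2 && setequal(pi, pj)) {
      rel[k] <- "full-sib"
    } else if (length(intersect(pi, pj)) == 1) {
      rel[k] <- "half-sib"
    } else if (!length(pi) && !length(pj)) {
      rel[k] <- "unrelated"
    } else rel[k] <- "other"
  }
  data.frame(idA = ped$id[pairs[, 1]], idB = ped$id[pairs[, 2]],
             relation = rel, stringsAsFactors = FALSE)
}

#' Default synthetic study scenario
#'
#' Bundles the package's reference simulation conditions: about 70 diploid
#' individuals in 4-8 spatial clusters, about 1400 biallelic SNPs, 5%
#' missing calls, moderate differentiation, and a categorical landscape with
#' gardens/buildings patches crossed by linear road, railway and river
#' features.
#'
#' @param seed master seed.
#' @param nPops,nPerPop,nLoci,fstTarget,ibrPhi,ibrSigma2,missingRate,landscape
#'   overrides of the defaults.
#' @return A [SyntheticScenario-class].
#' @export
syntheticScenario <- function(seed = 1L, nPops = 6L, nPerPop = 12L,
                              nLoci = 1400L, fstTarget = 0.10,
                              ibrPhi = NA_real_, ibrSigma2 = 1,
                              missingRate = 0.05, landscape = NULL) {
  if (is.null(landscape)) {
    landscape <- list(
      nrow = 48L, ncol = 48L, resolution = 5,
      classes = list(
        list(name = "Private Garden", weight = 3),
        list(name = "Parks and Playspace", weight = 2),
        list(name = "Buildings", weight = 2),
        list(name = "Impervious", weight = 1),
        list(name = "Large street", type = "vstrip", width = 1),
        list(name = "Railways", type = "hstrip", width = 1),
        list(name = "Linear Water", type = "wander", width = 1)))
  }
  new("SyntheticScenario", seed = as.integer(seed), nPops = as.integer(nPops),
      nPerPop = as.integer(nPerPop), nLoci = as.integer(nLoci),
      fstTarget = fstTarget, ibrPhi = ibrPhi, ibrSigma2 = ibrSigma2,
      missingRate = missingRate, landscape = landscape)
}

setMethod("show", "SyntheticScenario", function(object) {
  cat("SyntheticScenario: seed", object@seed, "\n")
  cat(sprintf("  %d pops x %d inds, %d loci, Fst target %.3f, missing %.2f\n",
              object@nPops, object@nPerPop, object@nLoci, object@fstTarget,
              object@missingRate))
  cat(sprintf("  landscape %dx%d @ %gm, sigma2 %.2f, phi %s\n",
              object@landscape$nrow, object@landscape$ncol,
              object@landscape$resolution, object@ibrSigma2,
              ifelse(is.na(object@ibrPhi), "auto (median commute distance)",
                     format(object@ibrPhi))))
  invisible(object)
})

#' Sample individual locations in spatial clusters on a surface
#'
#' Draws `nClusters` cluster centres on traversable cells (well separated by
#' rejection sampling), then scatters individuals around each centre on
#' traversable cells.
#'
#' @param surface a [ResistanceSurface-class].
#' @param nClusters number of clusters.
#' @param nPerCluster individuals per cluster.
#' @param seed integer seed.
#' @param spreadCells cluster radius in cells (default 2).
#' @return data.frame with id, x, y, location.
#' @export
sampleClusteredLocations <- function(surface, nClusters, nPerCluster, seed,
                                     spreadCells = 2) {
  set.seed(seed)
  r <- surface@resistance
  trav <- which(!is.na(r), arr.ind = TRUE)
  if (nrow(trav) < nClusters) stop("not enough traversable cells")
  minSep <- max(dim(r)) / (nClusters + 1)
  centres <- trav[sample.int(nrow(trav), 1L), , drop = FALSE]
  tries <- 0L
  while (nrow(centres) < nClusters && tries < 5000L) {
    cand <- trav[sample.int(nrow(trav), 1L), , drop = FALSE]
    d <- sqrt(rowSums((sweep(centres, 2L, cand))^2))
    if (all(d >= minSep)) centres <- rbind(centres, cand)
    tries <- tries + 1L
  }
  while (nrow(centres) < nClusters)  # fall back if rejection stalls
    centres <- rbind(centres, trav[sample.int(nrow(trav), 1L), , drop = FALSE])
  out <- NULL
  used <- character()  # one individual per cell, so no zero pairwise distances
  for (k in seq_len(nClusters)) {
    picked <- 0L
    tries <- 0L
    spread <- spreadCells
    while (picked < nPerCluster) {
      dr <- round(rnorm(1, 0, spread)); dc <- round(rnorm(1, 0, spread))
      rr <- centres[k, 1] + dr; cc <- centres[k, 2] + dc
      tries <- tries + 1L
      if (tries %% 200L == 0L) spread <- spread + 1  # widen if cluster is full
      key <- paste(rr, cc)
      if (rr >= 1 && rr <= nrow(r) && cc >= 1 && cc <= ncol(r) &&
          !is.na(r[rr, cc]) && !key %in% used) {
        picked <- picked + 1L
        used <- c(used, key)
        out <- rbind(out, c(k, rr, cc))
      }
    }
  }
  xy <- cellCentres(surface, out[, 2], out[, 3])
  data.frame(id = sprintf("c%02d_i%03d", out[, 1], seq_len(nrow(out))),
             x = xy[, 1], y = xy[, 2],
             location = sprintf("cluster%02d", out[, 1]),
             stringsAsFactors = FALSE)
}
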