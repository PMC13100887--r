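#' Evanno delta-K from clustering replicate log-likelihoods
#'
#' Post-processes a table of replicate log-likelihoods from an external
#' Bayesian clustering run (one row per K x replicate): for each interior K,
#' `deltaK = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd(L(K))`. deltaK
#' is undefined (NA, flagged) at the smallest and largest K and wherever the
#' replicate standard deviation is zero.
#'
#' @param lnp data.frame with columns `K`, `replicate`, `lnP`.
#' @return data.frame per K: nReplicates, meanL, sdL, Lprime (first
#'   difference of means), Ldoubleprime (|second difference|), deltaK.
#' @export
evannoDeltaK <- function(lnp) {
  stopifnot(all(c("K", "lnP") %in% names(lnp)))
  ks <- sort(unique(lnp$K))
  if (length(ks) < 3) stop("need at least 3 consecutive K values")
  if (!all(diff(ks) == 1)) stop("K values must be consecutive")
  byK <- split(lnp$lnP, lnp$K)
  if (any(lengths(byK) < 2)) stop("need >= 2 replicates per K")
  meanL <- vapply(byK, mean, numeric(1))
  sdL <- vapply(byK, sd, numeric(1))
  nRep <- lengths(byK)
  m <- length(ks)
  Lprime <- c(NA, diff(meanL))
  Ldd <- rep(NA_real_, m)
  deltaK <- rep(NA_real_, m)
  for (i in 2:(m - 1)) {
    Ldd[i] <- abs(meanL[i + 1] - 2 * meanL[i] + meanL[i - 1])
    deltaK[i] <- if (sdL[i] > 0) Ldd[i] / sdL[i] else NA_real_
  }
  if (any(sdL[2:(m - 1)] == 0))
    warning("zero replicate sd at some K; deltaK undefined there")
  data.frame(K = ks, nReplicates = as.integer(nRep), meanL = meanL,
             sdL = sdL, Lprime = Lprime, Ldoubleprime = Ldd,
             deltaK = deltaK, row.names = NULL)
}

#' Pairwise population comparisons of per-locus statistics
#'
#' Two-sided Wilcoxon rank-sum tests between every pair of populations on
#' vectors of per-locus values (e.g. per-locus allelic richness or
#' heterozygosity), with Benjamini-Hochberg adjustment across all pairs.
#'
#' @param values named list: one numeric vector of per-locus values per
#'   population (each length >= 2).
#' @return list with `pvalues` (symmetric matrix of adjusted p-values) and
#'   `raw` (unadjusted).
#' @export
comparePopulations <- function(values) {
  stopifnot(is.list(values), length(values) >= 2)
  if (any(lengths(values) < 2)) stop("need >= 2 values per population")
  u <- names(values)
  nPair <- choose(length(u), 2)
  pairs <- utils::combn(length(u), 2)
  raw <- apply(pairs, 2, function(ij) {
    a <- values[[ij[1]]]; b <- values[[ij[2]]]
    if (length(unique(c(a, b))) == 1) return(1)
    suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
  })
  adj <- p.adjust(raw, method = "BH")
  mk <- function(v) {
    m <- matrix(NA_real_, length(u), length(u), dimnames = list(u, u))
    for (k in seq_len(ncol(pairs)))
      m[pairs[1, k], pairs[2, k]] <- m[pairs[2, k], pairs[1, k]] <- v[k]
    m
  }
  list(pvalues = mk(adj), raw = mk(raw))
}

#' Per-locus diversity vectors for population comparisons
#'
#' Convenience builder: per-locus expected heterozygosity (or observed, or
#' rarefied allelic richness) per population, for use with
#' [comparePopulations()].
#'
#' @param gm a [GenotypeMatrix-class].
#' @param pops population labels.
#' @param stat one of "He", "Ho", "Ar".
#' @param g rarefaction gene count when `stat = "Ar"`.
#' @return named list of per-locus vectors, one per population.
#' @export
perLocusStatistics <- function(gm, pops = popLabels(gm),
                               stat = c("He", "Ho", "Ar"), g = NULL) {
  stat <- match.arg(stat)
  if (is.null(pops)) stop("population labels required")
  if (is.null(g)) g <- 2L * min(table(pops))
  gmat <- genotypes(gm)
  lapply(split(seq_len(nrow(gmat)), pops), function(idx) {
    sub <- gmat[idx, , drop = FALSE]
    nGeno <- colSums(!is.na(sub))
    use <- nGeno > 0
    if (stat == "Ho") {
      colSums(sub[, use, drop = FALSE] == 1, na.rm = TRUE) / nGeno[use]
    } else if (stat == "He") {
      p <- colSums(sub[, use, drop = FALSE], na.rm = TRUE) / (2 * nGeno[use])
      2 * p * (1 - p) * (2 * nGeno[use]) / (2 * nGeno[use] - 1)
    } else {
      nGenes <- 2 * nGeno
      nAlt <- colSums(sub, na.rm = TRUE)
      ok <- nGenes >= g
      rarefactionTerm(nAlt[ok], nGenes[ok], g) +
        rarefactionTerm(nGenes[ok] - nAlt[ok], nGenes[ok], g)
    }
  })
}
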