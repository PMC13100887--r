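#' Individual standardised heterozygosity (Hs)
#'
#' Per individual, the proportion of heterozygous calls among non-missing
#' sites, divided by the mean proportion across all included individuals —
#' so mean(Hs) = 1 exactly. Individuals with zero non-missing sites are
#' excluded with a warning.
#'
#' @param gm a [GenotypeMatrix-class].
#' @return data.frame with columns id, hetSites, nonMissing, propHet, Hs.
#' @export
standardizedHeterozygosity <- function(gm) {
  g <- genotypes(gm)
  het <- rowSums(g == 1, na.rm = TRUE)
  nonMiss <- rowSums(!is.na(g))
  if (any(nonMiss == 0)) {
    warning("individuals with no non-missing sites excluded: ",
            paste(sampleIds(gm)[nonMiss == 0], collapse = ", "))
  }
  keep <- nonMiss > 0
  if (sum(keep) < 2) stop("need at least 2 individuals with data")
  prop <- het[keep] / nonMiss[keep]
  data.frame(id = sampleIds(gm)[keep], hetSites = het[keep],
             nonMissing = nonMiss[keep], propHet = prop,
             Hs = prop / mean(prop), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Observed and expected heterozygosity per population
#'
#' Ho is the mean over loci of the observed heterozygote fraction among
#' non-missing genotypes. He is the mean over loci of the unbiased gene
#' diversity `2p(1-p) * 2n/(2n-1)` where `n` is the number of genotyped
#' individuals at the locus; loci monomorphic within a population
#' contribute 0. Fis = 1 - Ho/He.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param pops population labels per individual (defaults to the `pop`
#'   metadata column).
#' @return data.frame with columns pop, n, Ho, He, Fis.
#' @export
hoHe <- function(gm, pops = popLabels(gm)) {
  if (is.null(pops)) stop("population labels required")
  g <- genotypes(gm)
  out <- lapply(split(seq_len(nrow(g)), pops), function(idx) {
    if (length(idx) < 2) stop("populations must have n >= 2")
    sub <- g[idx, , drop = FALSE]
    nGeno <- colSums(!is.na(sub))
    use <- nGeno > 0
    ho <- colSums(sub[, use, drop = FALSE] == 1, na.rm = TRUE) / nGeno[use]
    p <- colSums(sub[, use, drop = FALSE], na.rm = TRUE) / (2 * nGeno[use])
    he <- 2 * p * (1 - p) * (2 * nGeno[use]) / (2 * nGeno[use] - 1)
    Ho <- mean(ho); He <- mean(he)
    data.frame(n = length(idx), Ho = Ho, He = He,
               Fis = if (He > 0) 1 - Ho / He else NA_real_)
  })
  res <- do.call(rbind, out)
  data.frame(pop = names(out), res, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a random draw of `g` genes
#' (2 per diploid individual) from each population at each locus:
#' `Ar = sum_a [1 - C(N - N_a, g) / C(N, g)]` with `N` total non-missing
#' genes and `N_a` copies of allele `a`. Loci with fewer than `g` genes in a
#' population are skipped for that population; the population value is the
#' mean over usable loci. For biallelic loci, 1 <= Ar <= 2.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param pops population labels.
#' @param g rarefaction gene count (>= 2); default `2 * min(table(pops))`,
#'   i.e. rarefied to the smallest population's gene count.
#' @return named numeric vector of Ar per population.
#' @export
rarefiedAllelicRichness <- function(gm, pops = popLabels(gm), g = NULL) {
  if (is.null(pops)) stop("population labels required")
  if (is.null(g)) g <- 2L * min(table(pops))
  if (g < 2) stop("rarefaction gene count g must be >= 2")
  gm_ <- genotypes(gm)
  vapply(split(seq_len(nrow(gm_)), pops), function(idx) {
    sub <- gm_[idx, , drop = FALSE]
    nGenes <- 2 * colSums(!is.na(sub))
    nAlt <- colSums(sub, na.rm = TRUE)
    use <- nGenes >= g
    if (!any(use)) return(NA_real_)
    mean(rarefactionTerm(nAlt[use], nGenes[use], g) +
         rarefactionTerm(nGenes[use] - nAlt[use], nGenes[use], g))
  }, numeric(1))
}

# P(allele with count na among N genes appears in a sample of g genes)
rarefactionTerm <- function(na, N, g) {
  # 1 - C(N - na, g) / C(N, g), with the convention C(m, g) = 0 for m < g
  out <- 1 - exp(lchoose(N - na, g) - lchoose(N, g))
  out[N - na < g] <- 1
  out[na == 0] <- 0
  out
}

#' Private allele counts per population
#'
#' An allele is private to population P iff it is observed (count > 0 among
#' non-missing genes) in P and in no other population. Counts are summed
#' over loci and both alleles.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param pops population labels.
#' @return named integer vector of private-allele counts.
#' @export
privateAlleles <- function(gm, pops = popLabels(gm)) {
  if (is.null(pops)) stop("population labels required")
  u <- unique(pops)
  if (length(u) < 2) stop("need at least 2 populations")
  g <- genotypes(gm)
  # presence matrices: populations x loci, for alt and ref alleles
  altPresent <- do.call(rbind, lapply(u, function(p)
    colSums(g[pops == p, , drop = FALSE], na.rm = TRUE) > 0))
  refPresent <- do.call(rbind, lapply(u, function(p)
    colSums(2 - g[pops == p, , drop = FALSE], na.rm = TRUE) > 0))
  soleAlt <- matrix(colSums(altPresent) == 1, nrow(altPresent),
                    ncol(altPresent), byrow = TRUE)
  soleRef <- matrix(colSums(refPresent) == 1, nrow(refPresent),
                    ncol(refPresent), byrow = TRUE)
  counts <- rowSums(altPresent & soleAlt) + rowSums(refPresent & soleRef)
  setNames(as.integer(counts), u)
}

#' Population diversity summary table
#'
#' Combines sample size, private alleles, rarefied allelic richness,
#' observed/expected heterozygosity and Fis into one table per population.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param pops population labels.
#' @param g rarefaction gene count (see [rarefiedAllelicRichness()]).
#' @return data.frame with columns pop, n, privateAlleles, Ar, Ho, He, Fis.
#' @export
diversitySummary <- function(gm, pops = popLabels(gm), g = NULL) {
  hh <- hoHe(gm, pops)
  ar <- rarefiedAllelicRichness(gm, pops, g)
  pa <- privateAlleles(gm, pops)
  hh$privateAlleles <- as.integer(pa[hh$pop])
  hh$Ar <- as.numeric(ar[hh$pop])
  hh[, c("pop", "n", "privateAlleles", "Ar", "Ho", "He", "Fis")]
}
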