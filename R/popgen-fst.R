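#' Weir-Cockerham Fst (theta)
#'
#' The 1984 variance-component estimator for biallelic loci: per-locus
#' components `a` (among populations), `b` (among individuals within
#' populations) and `c` (within individuals) are summed over loci and
#' theta = sum(a) / sum(a + b + c) (ratio of sums). Missing genotypes are
#' dropped per locus; loci informative in fewer than two populations are
#' skipped. Confidence intervals come from a seeded percentile bootstrap
#' over loci.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param pops population labels (default: `pop` metadata column). Every
#'   population must contain at least 2 individuals.
#' @param pairwise if TRUE, additionally return theta for every population
#'   pair.
#' @param nBoot bootstrap resamples over loci for the CI (0 disables);
#'   default 1000.
#' @param seed seed for the bootstrap.
#' @return list with `overall` (data.frame: theta, ciLower, ciUpper) and,
#'   when `pairwise`, `pairwise` (symmetric matrix of pairwise theta).
#' @export
wcFst <- function(gm, pops = popLabels(gm), pairwise = FALSE,
                  nBoot = 1000, seed = 1L) {
  if (is.null(pops)) stop("population labels required")
  pops <- as.character(pops)
  tab <- table(pops)
  if (length(tab) < 2) stop("need at least 2 populations")
  if (any(tab < 2)) stop("every population needs n >= 2")
  g <- genotypes(gm)

  comp <- wcComponents(g, pops)
  theta <- thetaFromComponents(comp)
  ci <- c(NA_real_, NA_real_)
  if (nBoot > 0) {
    set.seed(seed)
    usable <- which(is.finite(comp$a))
    boot <- vapply(seq_len(nBoot), function(b) {
      idx <- sample(usable, length(usable), replace = TRUE)
      sum(comp$a[idx]) / sum(comp$a[idx] + comp$b[idx] + comp$c[idx])
    }, numeric(1))
    ci <- unname(quantile(boot, c(0.025, 0.975), na.rm = TRUE))
  }
  out <- list(overall = data.frame(theta = theta,
                                   ciLower = ci[1], ciUpper = ci[2]))
  if (pairwise) {
    u <- sort(unique(pops))
    m <- matrix(NA_real_, length(u), length(u), dimnames = list(u, u))
    diag(m) <- 0
    for (i in seq_along(u)[-length(u)]) {
      for (j in (i + 1):length(u)) {
        sel <- pops %in% c(u[i], u[j])
        cij <- wcComponents(g[sel, , drop = FALSE], pops[sel])
        m[i, j] <- m[j, i] <- thetaFromComponents(cij)
      }
    }
    out$pairwise <- m
  }
  out
}

thetaFromComponents <- function(comp) {
  tot <- sum(comp$a + comp$b + comp$c, na.rm = TRUE)
  if (!is.finite(tot) || tot == 0) {
    warning("a + b + c is zero over all loci; theta undefined")
    return(NA_real_)
  }
  sum(comp$a, na.rm = TRUE) / tot
}

# per-locus Weir & Cockerham (1984) variance components for biallelic loci
wcComponents <- function(g, pops) {
  u <- unique(pops)
  L <- ncol(g)
  # per population per locus: sample size, alt frequency, het frequency
  nMat <- do.call(rbind, lapply(u, function(p)
    colSums(!is.na(g[pops == p, , drop = FALSE]))))
  pMat <- do.call(rbind, lapply(u, function(p)
    colSums(g[pops == p, , drop = FALSE], na.rm = TRUE))) / (2 * nMat)
  hMat <- do.call(rbind, lapply(u, function(p)
    colSums(g[pops == p, , drop = FALSE] == 1, na.rm = TRUE))) / nMat

  a <- b <- cc <- rep(NA_real_, L)
  for (l in seq_len(L)) {
    use <- nMat[, l] >= 1 & is.finite(pMat[, l])
    r <- sum(use)
    if (r < 2) next
    n <- nMat[use, l]; p <- pMat[use, l]; h <- hMat[use, l]
    nbar <- mean(n)
    if (nbar <= 1) next
    nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
    pbar <- sum(n * p) / (r * nbar)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / (r * nbar)
    a[l] <- (nbar / nc) *
      (s2 - (1 / (nbar - 1)) *
         (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
    b[l] <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (r - 1) / r -
         hbar * (2 * nbar - 1) / (4 * nbar))
    cc[l] <- hbar / 2
  }
  list(a = a, b = b, c = cc)
}

#' Queller-Goodnight pairwise relatedness
#'
#' The QG estimator summed over biallelic loci, with reference allele
#' frequencies computed from the sample *excluding the focal pair*, and
#' reciprocal estimates averaged to symmetrise. Loci missing in either
#' member of a pair are skipped; a pair with no usable loci is NA.
#'
#' @param gm a [GenotypeMatrix-class] with at least 3 individuals.
#' @return symmetric matrix of pairwise relatedness (diagonal NA).
#' @export
qgRelatedness <- function(gm) {
  g <- genotypes(gm)
  n <- nrow(g)
  if (n < 3) stop("need at least 3 individuals (frequencies exclude the pair)")
  altTot <- colSums(g, na.rm = TRUE)
  genesTot <- 2 * colSums(!is.na(g))
  out <- matrix(NA_real_, n, n, dimnames = list(rownames(g), rownames(g)))
  for (i in seq_len(n - 1)) {
    gi <- g[i, ]
    for (j in (i + 1):n) {
      gj <- g[j, ]
      use <- !is.na(gi) & !is.na(gj)
      if (!any(use)) next
      # frequencies excluding the focal pair
      genes <- genesTot[use] - 4
      ok <- use
      ok[use] <- genes > 0
      if (!any(ok)) next
      x <- gi[ok]; y <- gj[ok]
      p <- (altTot[ok] - x - y) / (genesTot[ok] - 4)
      # shared-allele similarity: 0.5 * number of matching ordered allele
      # pairs between the two genotypes
      sim <- 0.5 * (x * y + (2 - x) * (2 - y))
      pxSum <- x * p + (2 - x) * (1 - p)   # sum of freq of x's two alleles
      pySum <- y * p + (2 - y) * (1 - p)
      numXY <- sim - pxSum
      denX <- 1 + as.numeric(x != 1) - pxSum
      numYX <- sim - pySum
      denY <- 1 + as.numeric(y != 1) - pySum
      rXY <- sum(numXY) / sum(denX)
      rYX <- sum(numYX) / sum(denY)
      out[i, j] <- out[j, i] <- (rXY + rYX) / 2
    }
  }
  out
}
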