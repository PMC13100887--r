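#' Euclidean genetic distance between individuals
#'
#' Euclidean distance on genotype codes over the loci non-missing in both
#' individuals, rescaled by `sqrt(L / L_shared)` so pairs with different
#' amounts of missing data are comparable. Pairs with zero shared loci are
#' NA with a warning.
#'
#' @param gm a [GenotypeMatrix-class].
#' @return A [PairwiseDistanceMatrix-class] of kind `"genetic"`.
#' @export
geneticDistance <- function(gm) {
  g <- genotypes(gm)
  n <- nrow(g); L <- ncol(g)
  if (n < 2) stop("need at least 2 individuals")
  out <- matrix(0, n, n, dimnames = list(rownames(g), rownames(g)))
  anyUndefined <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- !is.na(g[i, ]) & !is.na(g[j, ])
      Ls <- sum(shared)
      if (Ls == 0) {
        out[i, j] <- out[j, i] <- NA_real_
        anyUndefined <- TRUE
      } else {
        d <- sqrt(sum((g[i, shared] - g[j, shared])^2) * L / Ls)
        out[i, j] <- out[j, i] <- d
      }
    }
  }
  if (anyUndefined) warning("pairs with zero shared loci set to NA")
  new("PairwiseDistanceMatrix", values = out, kind = "genetic",
      units = "dimensionless")
}

#' @describeIn geneticDistance value matrix of a PairwiseDistanceMatrix
#' @param x a PairwiseDistanceMatrix
#' @export
distanceValues <- function(x) x@values

#' @describeIn geneticDistance kind of a PairwiseDistanceMatrix
#' @export
distanceKind <- function(x) x@kind

setMethod("show", "PairwiseDistanceMatrix", function(object) {
  v <- object@values
  cat("PairwiseDistanceMatrix (", object@kind, ", ", object@units, "): ",
      nrow(v), " individuals\n", sep = "")
  off <- v[upper.tri(v)]
  if (length(off))
    cat(sprintf("  range %.4g - %.4g (%d undefined, %d infinite)\n",
                min(off[is.finite(off)]), max(off[is.finite(off)]),
                sum(is.na(off)), sum(is.infinite(off))))
  invisible(object)
})

#' Principal components analysis of a genotype matrix
#'
#' Missing genotypes are mean-imputed per locus, the matrix is centred
#' (optionally scaled), and decomposed with `prcomp`. Axes are ordered by
#' explained variance; signs are arbitrary.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param scale scale loci to unit variance; default FALSE.
#' @param nAxes number of axes to return (default all).
#' @return list with `coords` (individuals x axes) and `explained`
#'   (variance shares per axis, summing to <= 1).
#' @export
pcaGenotypes <- function(gm, scale = FALSE, nAxes = NULL) {
  g <- genotypes(gm)
  if (nrow(g) < 2) stop("need at least 2 individuals")
  mu <- colMeans(g, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  for (j in seq_len(ncol(g))) g[is.na(g[, j]), j] <- mu[j]
  keep <- apply(g, 2, function(col) var(col) > 0)
  fit <- prcomp(g[, keep, drop = FALSE], center = TRUE,
                scale. = scale && any(keep))
  expl <- fit$sdev^2 / max(sum(fit$sdev^2), .Machine$double.eps)
  if (is.null(nAxes)) nAxes <- ncol(fit$x)
  nAxes <- min(nAxes, ncol(fit$x))
  list(coords = fit$x[, seq_len(nAxes), drop = FALSE],
       explained = expl[seq_len(nAxes)])
}
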