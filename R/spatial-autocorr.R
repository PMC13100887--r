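#' Global and local Moran's I
#'
#' Spatial autocorrelation of a variable observed at projected point
#' locations. Weights are row-standardised and built either from the k
#' nearest neighbours (default k = 8) or from a distance band (all
#' neighbours within `band` metres; on a regular grid with `band` equal to
#' the cell spacing this gives rook contiguity). Global I is reported with
#' its expectation -1/(n-1), normal-approximation variance and two-sided
#' p-value; local I_i is returned per observation.
#'
#' @param values numeric vector (non-constant).
#' @param coords 2-column matrix / data.frame of projected x, y.
#' @param scheme `"knn"` or `"band"`.
#' @param k neighbours for `"knn"`; default 8 (capped at n - 1).
#' @param band distance threshold in metres for `"band"`.
#' @return list with `I`, `expectation`, `variance`, `p.value`, `localI`,
#'   and the weight matrix `W`.
#' @export
moransI <- function(values, coords, scheme = c("knn", "band"), k = 8,
                    band = NULL) {
  scheme <- match.arg(scheme)
  n <- length(values)
  if (n < 4) stop("need at least 4 observations")
  if (sd(values) == 0) stop("values are constant; Moran's I undefined")
  coords <- as.matrix(coords)
  D <- as.matrix(dist(coords))
  W <- matrix(0, n, n)
  if (scheme == "knn") {
    k <- min(k, n - 1)
    for (i in seq_len(n)) {
      nb <- setdiff(order(D[i, ]), i)[seq_len(k)]
      W[i, nb] <- 1
    }
  } else {
    if (is.null(band)) stop("scheme 'band' requires a distance band")
    W <- (D > 0 & D <= band) * 1
  }
  rs <- rowSums(W)
  if (any(rs == 0)) stop("isolated observations (no neighbours); ",
                         "increase k or the band")
  W <- W / rs
  z <- values - mean(values)
  m2 <- sum(z^2) / n
  I <- sum(z * (W %*% z)) / sum(z^2)
  EI <- -1 / (n - 1)
  S0 <- sum(W)
  S1 <- 0.5 * sum((W + t(W))^2)
  S2 <- sum((rowSums(W) + colSums(W))^2)
  b2 <- (sum(z^4) / n) / m2^2
  # variance of I under normality
  VI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
           b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
  zScore <- (I - EI) / sqrt(VI)
  p <- 2 * pnorm(-abs(zScore))
  localI <- as.numeric((z / m2) * (W %*% z))
  list(I = I, expectation = EI, variance = VI, p.value = p,
       localI = localI, W = W)
}

#' Linear model of individual heterozygosity against urban cover
#'
#' Ordinary least squares of Hs on the proportion of urban landcover in a
#' buffer around each individual, with Moran's I on the residuals to flag
#' spatial autocorrelation (the standard caveat for individual-level
#' diversity regressions).
#'
#' @param hs data.frame from [standardizedHeterozygosity()] (or any frame
#'   with `id` and `Hs`).
#' @param urban named numeric vector of urban proportions (names = ids), or
#'   unnamed in `hs` order.
#' @param coords 2-column matrix of projected x, y per individual (same
#'   order as `hs`).
#' @param ... weight options passed to [moransI()].
#' @return list with `fit` (the lm), `slope`, `slopeP`, and
#'   `residualMoran` (the [moransI()] result, or NULL if no coords given).
#' @export
fitHsUrban <- function(hs, urban, coords = NULL, ...) {
  if (!is.null(names(urban))) urban <- urban[hs$id]
  if (length(urban) != nrow(hs)) stop("urban proportions must match individuals")
  if (nrow(hs) < 3) stop("need at least 3 observations")
  if (sd(urban, na.rm = TRUE) == 0)
    stop("urban proportion is constant; slope undefined")
  df <- data.frame(Hs = hs$Hs, urban = as.numeric(urban))
  fit <- lm(Hs ~ urban, data = df)
  sm <- summary(fit)
  res <- list(fit = fit,
              slope = unname(coef(fit)["urban"]),
              slopeP = sm$coefficients["urban", "Pr(>|t|)"],
              residualMoran = NULL)
  if (!is.null(coords))
    res$residualMoran <- moransI(resid(fit), coords, ...)
  res
}
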