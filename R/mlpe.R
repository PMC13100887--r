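#' Build the pairwise table for MLPE regression
#'
#' One row per unordered individual pair: the genetic-distance response and
#' one column per candidate predictor. Resistance-distance predictors are
#' natural-log transformed by default (they must be strictly positive);
#' Euclidean distance is conventionally left untransformed. Pairs with an
#' infinite predictor (disconnected least-cost pairs) are dropped from the
#' table with a warning, so every model fitted on it shares the same
#' response.
#'
#' @param gdist a [PairwiseDistanceMatrix-class] of kind `"genetic"` (the
#'   response).
#' @param predictors named list of [PairwiseDistanceMatrix-class] objects
#'   (or plain symmetric matrices) sharing the same individuals.
#' @param logTransform logical, recycled over predictors: take the natural
#'   log of the predictor. Default: TRUE for resistance kinds
#'   (lcp/commute), FALSE for euclidean.
#' @return data.frame with columns idA, idB, gd, then one per predictor.
#' @export
buildPairwiseTable <- function(gdist, predictors, logTransform = NULL) {
  gv <- if (is(gdist, "PairwiseDistanceMatrix")) distanceValues(gdist)
        else as.matrix(gdist)
  ids <- rownames(gv)
  if (is.null(logTransform)) {
    logTransform <- vapply(predictors, function(p)
      is(p, "PairwiseDistanceMatrix") && distanceKind(p) %in% c("lcp", "commute"),
      logical(1))
  }
  logTransform <- rep_len(logTransform, length(predictors))
  pm <- lapply(predictors, function(p) {
    v <- if (is(p, "PairwiseDistanceMatrix")) distanceValues(p) else as.matrix(p)
    if (!identical(sort(rownames(v)), sort(ids)))
      stop("predictor matrices must share the response's individual ids")
    v[ids, ids]
  })
  ut <- which(upper.tri(gv), arr.ind = TRUE)
  tab <- data.frame(idA = ids[ut[, 1]], idB = ids[ut[, 2]],
                    gd = gv[ut], stringsAsFactors = FALSE)
  for (k in seq_along(pm)) {
    v <- pm[[k]][ut]
    if (logTransform[k]) {
      if (any(is.finite(v) & v <= 0)) {
        bad <- which(is.finite(v) & v <= 0)
        stop("nonpositive resistance distance under log for pair(s): ",
             paste(paste(tab$idA[bad], tab$idB[bad], sep = "-"),
                   collapse = ", "))
      }
      v <- log(v)
    }
    tab[[names(pm)[k]]] <- v
  }
  predCols <- names(pm)
  finite <- rowSums(!is.finite(as.matrix(tab[, c("gd", predCols)]))) == 0
  if (any(!finite)) {
    warning(sum(!finite), " pair(s) with non-finite values dropped ",
            "(disconnected least-cost pairs)")
    tab <- tab[finite, , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab
}

#' Fit a maximum-likelihood-population-effects model
#'
#' Linear mixed model for pairwise distance data:
#' `y_ab = X beta + u_a + u_b + e_ab`, `u ~ N(0, tau2)` per individual,
#' `e ~ N(0, sigma2)`, fitted by full maximum likelihood. The likelihood is
#' profiled over the variance ratio `lambda = tau2/sigma2` (beta and sigma2
#' have closed-form GLS/ML solutions given lambda) and the ratio optimised
#' numerically, including the `lambda = 0` boundary. The parameter count
#' `k` includes the intercept, each slope, tau2 and sigma2; `n` is the
#' number of pairs.
#'
#' @param table a [buildPairwiseTable()] data.frame.
#' @param predictorCols character vector of predictor column names (fit an
#'   intercept-only model with `character(0)`).
#' @return An [MLPEFit-class].
#' @export
fitMLPE <- function(table, predictorCols) {
  y <- table$gd
  n <- length(y)
  if (n < 3) stop("need at least 3 pairs")
  if (sd(y) == 0) stop("constant response; MLPE undefined")
  X <- cbind(`(Intercept)` = rep(1, n))
  for (pc in predictorCols) X <- cbind(X, table[[pc]])
  colnames(X) <- c("(Intercept)", predictorCols)
  if (qr(X)$rank < ncol(X)) stop("singular fixed-effect design")

  inds <- sort(unique(c(table$idA, table$idB)))
  Z <- Matrix::sparseMatrix(
    i = rep(seq_len(n), 2),
    j = c(match(table$idA, inds), match(table$idB, inds)),
    x = 1, dims = c(n, length(inds)))
  ZZt <- Matrix::tcrossprod(Z)

  profile <- function(lambda) {
    V <- Matrix::Diagonal(n) + lambda * ZZt
    ch <- Matrix::Cholesky(V, LDL = FALSE)
    logDetV <- 2 * Matrix::determinant(ch, logarithm = TRUE,
                                       sqrt = TRUE)$modulus
    Vi_X <- as.matrix(Matrix::solve(V, X))
    Vi_y <- as.numeric(Matrix::solve(V, y))
    XtViX <- crossprod(X, Vi_X)
    beta <- solve(XtViX, crossprod(X, Vi_y))
    r <- y - X %*% beta
    q <- sum(r * as.numeric(Matrix::solve(V, r)))
    sigma2 <- q / n
    ll <- -0.5 * (n * log(2 * pi * sigma2) + as.numeric(logDetV) + n)
    list(ll = ll, beta = as.numeric(beta), sigma2 = sigma2)
  }
  obj <- function(u) -profile(exp(u))$ll
  opt <- optimize(obj, interval = c(-15, 8))
  lambda <- exp(opt$minimum)
  best <- profile(lambda)
  at0 <- profile(0)
  if (at0$ll >= best$ll) { lambda <- 0; best <- at0 }
  if (!is.finite(best$ll)) stop("MLPE likelihood did not converge")

  sigma2 <- best$sigma2
  tau2 <- lambda * sigma2
  beta <- setNames(best$beta, colnames(X))
  fitted <- as.numeric(X %*% beta)
  k <- ncol(X) + 2
  ll <- best$ll
  new("MLPEFit", beta = beta, tau2 = tau2, sigma2 = sigma2,
      rho = tau2 / (2 * tau2 + sigma2), logLik = ll, k = k, n = n,
      AICc = aicc(ll, k, n), BIC = bic(ll, k, n),
      R2 = if (ncol(X) > 1) cor(fitted, y)^2 else 0,
      fitted = fitted, predictors = predictorCols)
}

setMethod("show", "MLPEFit", function(object) {
  cat("MLPEFit:", object@n, "pairs;",
      if (length(object@predictors)) paste(object@predictors, collapse = " + ")
      else "(intercept only)", "\n")
  print(round(object@beta, 4))
  cat(sprintf("  tau2 %.4g  sigma2 %.4g  rho %.3f\n",
              object@tau2, object@sigma2, object@rho))
  cat(sprintf("  logLik %.3f  AICc %.3f  BIC %.3f  R2 %.3f\n",
              object@logLik, object@AICc, object@BIC, object@R2))
  invisible(object)
})

#' Small-sample-corrected Akaike and Bayesian information criteria
#'
#' `AIC = -2 logLik + 2k`; `AICc = AIC + 2k(k+1)/(n-k-1)` (undefined,
#' flagged NA, when `n <= k + 1`); `BIC = -2 logLik + k log(n)`.
#'
#' @param logLik maximised log-likelihood.
#' @param k number of estimated parameters.
#' @param n sample size (number of pairs).
#' @export
aicc <- function(logLik, k, n) {
  if (n <= k + 1) {
    warning("AICc undefined for n <= k + 1")
    return(NA_real_)
  }
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' @rdname aicc
#' @export
bic <- function(logLik, k, n) -2 * logLik + k * log(n)

#' Compare fitted MLPE models by AICc
#'
#' Ranks fits within blocks (same algorithm and distance-term status),
#' computing delta-AICc relative to the block minimum and flagging the best
#' model per block (tie on AICc broken by lower BIC). All fits must share
#' the identical response vector.
#'
#' @param fits named list of [MLPEFit-class] objects.
#' @param keys optional data.frame with one row per fit giving blocking
#'   columns (e.g. hypothesis, algorithm, distTerm); defaults to a single
#'   block.
#' @return data.frame sorted by block and AICc, with columns of `keys` plus
#'   model, AICc, deltaAICc, BIC, R2, logLik, best.
#' @export
compareModels <- function(fits, keys = NULL) {
  stopifnot(length(fits) >= 1)
  ns <- vapply(fits, function(f) f@n, numeric(1))
  if (length(unique(ns)) != 1)
    stop("all fits must be on the identical pair set")
  if (is.null(keys))
    keys <- data.frame(block = rep("all", length(fits)))
  tab <- cbind(keys,
               data.frame(model = names(fits),
                          AICc = vapply(fits, function(f) f@AICc, numeric(1)),
                          BIC = vapply(fits, function(f) f@BIC, numeric(1)),
                          R2 = vapply(fits, function(f) f@R2, numeric(1)),
                          logLik = vapply(fits, function(f) f@logLik,
                                          numeric(1)),
                          stringsAsFactors = FALSE))
  blockId <- do.call(paste, c(keys, sep = "\r"))
  tab$deltaAICc <- NA_real_
  tab$best <- FALSE
  for (b in unique(blockId)) {
    sel <- which(blockId == b)
    tab$deltaAICc[sel] <- tab$AICc[sel] - min(tab$AICc[sel])
    cand <- sel[tab$AICc[sel] == min(tab$AICc[sel])]
    tab$best[cand[which.min(tab$BIC[cand])]] <- TRUE
  }
  tab <- tab[order(blockId, tab$AICc, tab$BIC), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
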