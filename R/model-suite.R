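#' Run the full isolation-by-distance vs isolation-by-resistance suite
#'
#' For each movement hypothesis and each connectivity algorithm (least-cost
#' path, random-walk commute distance), computes pairwise resistance
#' distances between the sampled individuals, regresses genetic distance on
#' the log resistance distance with an MLPE model, optionally refits with a
#' Euclidean-distance covariate, and ranks all models by AICc within each
#' (algorithm, distance-term) block. Pairs disconnected under any least-cost
#' model are dropped from every model so all fits share one response.
#'
#' @param gdist a genetic [PairwiseDistanceMatrix-class] over the points.
#' @param landscape a [LandcoverRaster-class].
#' @param hypotheses character vector of hypothesis names, or a list of
#'   [ResistanceHypothesis-class] objects.
#' @param points data.frame with `id`, `x`, `y` matching `gdist` ids.
#' @param algorithms subset of `c("lcp", "commute")`.
#' @param includeDistance also fit every model with a Euclidean-distance
#'   term (default TRUE).
#' @param epsilon conductance repair used for commute-distance graphs;
#'   default 1e-4 (never applied to least-cost paths).
#' @param neighbours graph connectivity, 8 (default) or 4.
#' @return list with `comparison` (the ranked table), `fits` (named list of
#'   [MLPEFit-class]), and `table` (the shared pairwise table).
#' @export
runModelSuite <- function(gdist, landscape, hypotheses, points,
                          algorithms = c("lcp", "commute"),
                          includeDistance = TRUE, epsilon = 1e-4,
                          neighbours = 8) {
  if (is.character(hypotheses))
    hypotheses <- lapply(hypotheses, resistanceHypothesis,
                         classes = unname(landscape@legend))
  names(hypotheses) <- vapply(hypotheses, function(h) h@name, character(1))
  algorithms <- match.arg(algorithms, c("lcp", "commute"), several.ok = TRUE)

  predictors <- list()
  for (h in hypotheses) {
    rs <- buildResistanceSurface(landscape, h)
    if ("lcp" %in% algorithms) {
      gL <- buildTransitionGraph(rs, epsilon = 0, neighbours = neighbours)
      predictors[[paste0(h@name, ".lcp")]] <- lcpDistance(gL, points)
    }
    if ("commute" %in% algorithms) {
      gC <- buildTransitionGraph(rs, epsilon = epsilon,
                                 neighbours = neighbours)
      predictors[[paste0(h@name, ".commute")]] <- commuteDistance(gC, points)
    }
  }
  eu <- euclideanDistance(points)
  predictors[["euclid"]] <- eu

  logT <- c(rep(TRUE, length(predictors) - 1L), FALSE)
  tab <- buildPairwiseTable(gdist, predictors, logTransform = logT)

  fits <- list()
  keys <- NULL
  for (h in names(hypotheses)) {
    for (alg in algorithms) {
      col <- paste0(h, ".", alg)
      key <- paste(h, alg, sep = ".")
      fits[[key]] <- fitMLPE(tab, col)
      keys <- rbind(keys, data.frame(hypothesis = h, algorithm = alg,
                                     distTerm = FALSE))
      if (includeDistance) {
        fits[[paste0(key, ".dist")]] <- fitMLPE(tab, c(col, "euclid"))
        keys <- rbind(keys, data.frame(hypothesis = h, algorithm = alg,
                                       distTerm = TRUE))
      }
    }
  }
  comparison <- compareModels(fits, keys[, c("algorithm", "distTerm"),
                                         drop = FALSE])
  comparison$hypothesis <- keys$hypothesis[match(comparison$model,
                                                 names(fits))]
  comparison <- comparison[, c("algorithm", "distTerm", "hypothesis",
                               "model", "AICc", "deltaAICc", "BIC", "R2",
                               "logLik", "best")]
  list(comparison = comparison, fits = fits, table = tab)
}

#' Write a model-comparison table as TSV
#' @param comparison data.frame from [runModelSuite()] / [compareModels()].
#' @param path output path.
#' @export
writeComparisonTable <- function(comparison, path) {
  write.table(comparison, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
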