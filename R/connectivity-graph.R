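#' Build a movement graph from a resistance surface
#'
#' One node per traversable cell; undirected edges join 8-neighbouring (or,
#' by option, 4-neighbouring) traversable cells with conductance
#' `((1/r_i + 1/r_j)/2) / d`, where `d` is the centre-to-centre distance
#' (`resolution` for orthogonal steps, `sqrt(2) * resolution` for
#' diagonals). No edges touch barrier cells. With `epsilon > 0`, that value
#' is added to the conductance of every adjacent traversable cell pair — a
#' connectivity repair used before commute-distance computations so that
#' clusters of cells isolated by high resistance do not disconnect the
#' graph.
#'
#' @param rs a [ResistanceSurface-class].
#' @param epsilon conductance added between all adjacent traversable cells;
#'   default 0 (use 1e-4 for commute/passage computations).
#' @param neighbours 8 (default) or 4.
#' @return A [TransitionGraph-class].
#' @export
buildTransitionGraph <- function(rs, epsilon = 0, neighbours = 8) {
  stopifnot(neighbours %in% c(4, 8))
  r <- rs@resistance
  nr <- nrow(r); nc <- ncol(r)
  trav <- !is.na(r)
  cellIndex <- which(trav)           # linear, column-major
  nodeOf <- integer(nr * nc)
  nodeOf[cellIndex] <- seq_along(cellIndex)

  steps <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  if (neighbours == 4) steps <- steps[1:2]
  ii <- jj <- integer(0); ww <- numeric(0)
  row0 <- ((cellIndex - 1L) %% nr) + 1L
  col0 <- ((cellIndex - 1L) %/% nr) + 1L
  invR <- 1 / r
  for (s in steps) {
    r2 <- row0 + s[1]; c2 <- col0 + s[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    lin2 <- (c2[ok] - 1L) * nr + r2[ok]
    ok2 <- trav[lin2]
    from <- cellIndex[ok][ok2]
    to <- lin2[ok2]
    d <- rs@resolution * if (all(s != 0)) sqrt(2) else 1
    cond <- ((invR[from] + invR[to]) / 2) / d + epsilon
    ii <- c(ii, nodeOf[from]); jj <- c(jj, nodeOf[to]); ww <- c(ww, cond)
  }
  n <- length(cellIndex)
  A <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(ww, ww),
                            dims = c(n, n))
  new("TransitionGraph", conductance = A, cellIndex = cellIndex,
      dims = c(nr, nc), resolution = rs@resolution, origin = rs@origin,
      epsilon = epsilon)
}

setMethod("show", "TransitionGraph", function(object) {
  cat("TransitionGraph:", length(object@cellIndex), "nodes,",
      length(object@conductance@x) / 2, "edges",
      if (object@epsilon > 0) sprintf("(epsilon %.2g)", object@epsilon),
      "\n")
  invisible(object)
})

#' @describeIn buildTransitionGraph number of graph nodes
#' @param x a TransitionGraph
#' @export
nNodes <- function(x) length(x@cellIndex)

#' @describeIn buildTransitionGraph symmetric sparse conductance matrix
#' @export
conductanceMatrix <- function(x) x@conductance

# projected centre coordinates of every node
nodeCoordinates <- function(g) {
  nr <- g@dims[1]
  rows <- ((g@cellIndex - 1L) %% nr) + 1L
  cols <- ((g@cellIndex - 1L) %/% nr) + 1L
  cbind(x = g@origin[1] + (cols - 0.5) * g@resolution,
        y = g@origin[2] - (rows - 0.5) * g@resolution)
}

#' Snap projected points to graph nodes
#'
#' Each point snaps to the nearest traversable cell centre; points farther
#' than `toleranceCells` cell widths from any node raise an error naming
#' the point.
#'
#' @param g a [TransitionGraph-class].
#' @param points data.frame with `id`, `x`, `y`.
#' @param toleranceCells snap tolerance in cells; default 3.
#' @return integer node indices named by point id.
#' @export
snapPoints <- function(g, points, toleranceCells = 3) {
  nodeXY <- nodeCoordinates(g)
  idx <- integer(nrow(points))
  for (k in seq_len(nrow(points))) {
    d2 <- (nodeXY[, 1] - points$x[k])^2 + (nodeXY[, 2] - points$y[k])^2
    best <- which.min(d2)
    if (sqrt(d2[best]) > toleranceCells * g@resolution)
      stop("point '", points$id[k], "' is more than ", toleranceCells,
           " cells from any traversable cell (it may lie on a barrier)")
    idx[k] <- best
  }
  setNames(idx, points$id)
}
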