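#' Least-cost-path distances (and routes) between points
#'
#' Shortest-path distance on the transition graph with step cost
#' `1 / conductance`, computed by Dijkstra's algorithm per source. For a
#' uniform surface of resistance r at resolution h, the cost of a straight
#' orthogonal route of length d metres is `r * d`. Disconnected pairs get
#' `Inf` with a warning. Optionally returns one least-cost route per pair
#' (an ordered cell sequence whose summed step cost equals the pair's
#' distance).
#'
#' @param g a [TransitionGraph-class] (build without epsilon repair:
#'   least-cost paths use the raw conductances).
#' @param points data.frame with `id`, `x`, `y` (projected metres).
#' @param paths if TRUE also return explicit routes.
#' @param toleranceCells snap tolerance passed to [snapPoints()].
#' @return A [PairwiseDistanceMatrix-class] of kind `"lcp"`; with
#'   `paths = TRUE`, a list with elements `distances` and `paths` (a
#'   data.frame with idA, idB, step, row, col, x, y and per-pair cost).
#' @export
lcpDistance <- function(g, points, paths = FALSE, toleranceCells = 3) {
  nodes <- snapPoints(g, points, toleranceCells)
  ig <- igraph::graph_from_adjacency_matrix(g@conductance, mode = "undirected",
                                            weighted = TRUE)
  igraph::E(ig)$weight <- 1 / igraph::E(ig)$weight
  un <- unique(nodes)  # several points may share a snapped cell
  D0 <- igraph::distances(ig, v = un, to = un, algorithm = "dijkstra")
  D <- D0[match(nodes, un), match(nodes, un)]
  dimnames(D) <- list(points$id, points$id)
  diag(D) <- 0
  if (any(is.infinite(D)))
    warning("disconnected point pairs present (infinite LCP distance)")
  pdm <- new("PairwiseDistanceMatrix", values = D, kind = "lcp",
             units = "cost.m")
  if (!paths) return(pdm)
  nr <- g@dims[1]
  pathRows <- list()
  for (i in seq_len(nrow(points) - 1)) {
    tgt <- unique(nodes[(i + 1):nrow(points)])
    sp <- igraph::shortest_paths(ig, from = nodes[i], to = tgt,
                                 output = "vpath")
    for (j in (i + 1):nrow(points)) {
      v <- as.integer(sp$vpath[[match(nodes[j], tgt)]])
      if (!length(v)) next
      cells <- g@cellIndex[v]
      rows <- ((cells - 1L) %% nr) + 1L
      cols <- ((cells - 1L) %/% nr) + 1L
      pathRows[[length(pathRows) + 1L]] <- data.frame(
        idA = points$id[i], idB = points$id[j], step = seq_along(v),
        row = rows, col = cols,
        x = g@origin[1] + (cols - 0.5) * g@resolution,
        y = g@origin[2] - (rows - 0.5) * g@resolution,
        cost = D[i, j])
    }
  }
  list(distances = pdm, paths = do.call(rbind, pathRows))
}

#' Random-walk commute distances between points
#'
#' Expected round-trip steps of the random walk on the conductance graph:
#' `C_ij = 2 * S * R_eff(i, j)` where `S` is the total edge conductance and
#' `R_eff` the effective resistance between the snapped nodes, obtained
#' from sparse linear solves on the graph Laplacian (one solve per source
#' point, against a grounded reference node).
#'
#' @param g a [TransitionGraph-class]; the traversable cells must form a
#'   single connected component (build the graph with `epsilon = 1e-4` to
#'   repair resistance-isolated clusters).
#' @param points data.frame with `id`, `x`, `y`.
#' @param toleranceCells snap tolerance.
#' @return A [PairwiseDistanceMatrix-class] of kind `"commute"` (units:
#'   expected steps).
#' @export
commuteDistance <- function(g, points, toleranceCells = 3) {
  nodes <- snapPoints(g, points, toleranceCells)
  R <- effectiveResistance(g, nodes)
  S <- sum(g@conductance@x) / 2
  C <- 2 * S * R
  dimnames(C) <- list(points$id, points$id)
  diag(C) <- 0
  new("PairwiseDistanceMatrix", values = C, kind = "commute",
      units = "expected.steps")
}

# effective resistance among a set of nodes via grounded Laplacian solves
effectiveResistance <- function(g, nodes) {
  A <- g@conductance
  n <- nrow(A)
  if (!graphIsConnected(A))
    stop("transition graph is disconnected; rebuild with epsilon > 0 ",
         "(e.g. 1e-4) to repair isolated cell clusters")
  L <- Matrix::Diagonal(x = Matrix::rowSums(A)) - A
  ground <- n  # arbitrary reference
  keep <- seq_len(n - 1L)
  Lg <- L[keep, keep]
  k <- length(nodes)
  rhs <- matrix(0, n - 1L, k)
  for (s in seq_len(k)) {
    if (nodes[s] != ground) rhs[nodes[s], s] <- 1
  }
  V <- as.matrix(Matrix::solve(Lg, rhs))
  pot <- rbind(V, 0)  # potential of ground = 0; column s: unit injection at
                      # node s, extraction at ground
  R <- matrix(0, k, k)
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      # R_eff(a,b) = (e_a - e_b)' L^+ (e_a - e_b), identical under grounding
      R[a, b] <- R[b, a] <-
        pot[nodes[a], a] - pot[nodes[b], a] -
        (pot[nodes[a], b] - pot[nodes[b], b])
    }
  }
  R
}

graphIsConnected <- function(A) {
  n <- nrow(A)
  seen <- logical(n)
  frontier <- 1L
  seen[1L] <- TRUE
  Ap <- as(A, "CsparseMatrix")
  while (length(frontier)) {
    nb <- unique(unlist(lapply(frontier, function(v) {
      if (Ap@p[v + 1L] == Ap@p[v]) return(integer(0))
      Ap@i[(Ap@p[v] + 1L):Ap@p[v + 1L]] + 1L
    })))
    nb <- nb[!seen[nb]]
    seen[nb] <- TRUE
    frontier <- nb
  }
  all(seen)
}

#' Straight-line distances between points
#'
#' @param points data.frame with `id`, `x`, `y` in projected metres.
#' @return A [PairwiseDistanceMatrix-class] of kind `"euclidean"`.
#' @export
euclideanDistance <- function(points) {
  D <- as.matrix(dist(points[, c("x", "y")]))
  dimnames(D) <- list(points$id, points$id)
  new("PairwiseDistanceMatrix", values = D, kind = "euclidean", units = "m")
}

#' Random-walk passage map
#'
#' For each origin-destination pair, a unit current is injected at the
#' origin and extracted at the destination; the harmonic potential gives the
#' net flow on every edge, and each cell's expected net passage is half the
#' sum of the absolute net flows on its incident edges (1 for every interior
#' cell of a single corridor, 0.5 per branch for two equal parallel routes).
#' Maps are averaged over the supplied pairs. Scale-invariant: doubling all
#' conductances leaves the map unchanged.
#'
#' @param g a connected [TransitionGraph-class] (use epsilon repair).
#' @param points data.frame with `id`, `x`, `y`.
#' @param pairs 2-column matrix of point-index pairs; default all unordered
#'   pairs.
#' @return matrix of per-cell mean net passage (grid dims; NA on barrier
#'   cells).
#' @export
passageMap <- function(g, points, pairs = NULL) {
  nodes <- snapPoints(g, points)
  if (is.null(pairs)) pairs <- t(utils::combn(length(nodes), 2))
  A <- g@conductance
  n <- nrow(A)
  if (!graphIsConnected(A))
    stop("transition graph is disconnected; rebuild with epsilon > 0")
  L <- Matrix::Diagonal(x = Matrix::rowSums(A)) - A
  keep <- seq_len(n - 1L)
  Lg <- L[keep, keep]
  Ap <- as(A, "CsparseMatrix")
  acc <- numeric(n)
  for (k in seq_len(nrow(pairs))) {
    s <- nodes[pairs[k, 1]]; t <- nodes[pairs[k, 2]]
    rhs <- numeric(n); rhs[s] <- 1; rhs[t] <- -1
    phi <- c(as.numeric(Matrix::solve(Lg, rhs[keep])), 0)
    # net |flow| summed over incident edges, halved
    flowSum <- numeric(n)
    for (v in seq_len(n)) {
      if (Ap@p[v + 1L] == Ap@p[v]) next
      idx <- (Ap@p[v] + 1L):Ap@p[v + 1L]
      nb <- Ap@i[idx] + 1L
      flowSum[v] <- sum(abs(Ap@x[idx] * (phi[v] - phi[nb])))
    }
    acc <- acc + flowSum / 2
  }
  acc <- acc / nrow(pairs)
  out <- matrix(NA_real_, g@dims[1], g@dims[2])
  out[g@cellIndex] <- acc
  out
}

#' Write a pairwise distance matrix as square CSV
#' @param x a [PairwiseDistanceMatrix-class].
#' @param path output path.
#' @export
writeDistanceMatrix <- function(x, path) {
  write.csv(data.frame(id = rownames(x@values), x@values,
                       check.names = FALSE), path, row.names = FALSE)
  invisible(path)
}
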