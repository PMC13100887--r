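# Independent oracles and fixture builders shared across test files.
# Each oracle is deliberately naive (dense algebra, scalar loops, exhaustive
# relaxation) and shares no code with the package implementations it checks.

# commute distance via the dense Laplacian pseudoinverse:
# C_ij = 2 * sum(conductances) * (Lp_ii + Lp_jj - 2 Lp_ij)
oracleCommute <- function(A) {
  A <- as.matrix(A)
  n <- nrow(A)
  L <- diag(rowSums(A)) - A
  e <- eigen(L, symmetric = TRUE)
  keep <- e$values > 1e-9 * max(e$values)
  Lp <- e$vectors[, keep, drop = FALSE] %*%
    diag(1 / e$values[keep], sum(keep)) %*%
    t(e$vectors[, keep, drop = FALSE])
  S <- sum(A) / 2
  C <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    C[i, j] <- 2 * S * (Lp[i, i] + Lp[j, j] - 2 * Lp[i, j])
  C
}

# all-pairs shortest paths by exhaustive Bellman-Ford-style relaxation on a
# dense cost matrix (Inf = no edge)
oracleShortestPaths <- function(W) {
  n <- nrow(W)
  D <- W
  diag(D) <- 0
  for (rep in seq_len(n)) {
    for (i in 1:n) for (j in 1:n) {
      via <- D[i, ] + D[, j]
      D[i, j] <- min(D[i, j], min(via))
    }
  }
  D
}

# dense 8-neighbour cost matrix for a small resistance grid (NA = barrier),
# built independently of buildTransitionGraph
denseGridCosts <- function(r, resolution = 1) {
  nr <- nrow(r); nc <- ncol(r)
  idx <- function(row, col) (col - 1) * nr + row
  n <- nr * nc
  W <- matrix(Inf, n, n)
  for (row in 1:nr) for (col in 1:nc) {
    if (is.na(r[row, col])) next
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- row + dr; c2 <- col + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (is.na(r[r2, c2])) next
      d <- resolution * sqrt(dr^2 + dc^2)
      cond <- ((1 / r[row, col] + 1 / r[r2, c2]) / 2) / d
      W[idx(row, col), idx(r2, c2)] <- 1 / cond
    }
  }
  W
}

# Weir & Cockerham (1984) theta by direct scalar translation of the
# published component formulas, one locus at a time
oracleWcTheta <- function(g, pops) {
  u <- unique(pops)
  aSum <- bSum <- cSum <- 0
  for (l in seq_len(ncol(g))) {
    n <- p <- h <- numeric(0)
    for (pp in u) {
      gl <- g[pops == pp, l]
      gl <- gl[!is.na(gl)]
      if (length(gl) >= 1) {
        n <- c(n, length(gl))
        p <- c(p, sum(gl) / (2 * length(gl)))
        h <- c(h, mean(gl == 1))
      }
    }
    r <- length(n)
    if (r < 2) next
    nbar <- mean(n)
    if (nbar <= 1) next
    nc_ <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
    pbar <- sum(n * p) / (r * nbar)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / (r * nbar)
    a <- (nbar / nc_) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    aSum <- aSum + a; bSum <- bSum + b; cSum <- cSum + cc
  }
  aSum / (aSum + bSum + cSum)
}

# build a ResistanceSurface directly from a matrix (test-only shortcut)
surfaceFromMatrix <- function(r, resolution = 1, origin = NULL,
                              hypothesis = "test") {
  if (is.null(origin)) origin <- c(0, nrow(r) * resolution)
  new("ResistanceSurface", resistance = r, hypothesis = hypothesis,
      resolution = resolution, origin = origin)
}

# points at the centres of given (row, col) cells of a surface
pointsAtCells <- function(rs, rows, cols, ids = NULL) {
  xy <- cellCentres(rs, rows, cols)
  if (is.null(ids)) ids <- paste0("p", seq_along(rows))
  data.frame(id = ids, x = xy[, 1], y = xy[, 2], stringsAsFactors = FALSE)
}

# random connected resistance grid (values 1..100, no barriers)
randomResistanceGrid <- function(nr, nc, seed) {
  set.seed(seed)
  matrix(sample(c(1, 2, 5, 10, 50, 100), nr * nc, replace = TRUE), nr, nc)
}

# symmetric PairwiseDistanceMatrix from an upper-triangle filler
symmetricDistance <- function(n, filler, ids = paste0("i", seq_len(n)),
                              kind = "genetic", units = "d") {
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  m[upper.tri(m)] <- filler
  m <- m + t(m)
  new("PairwiseDistanceMatrix", values = m, kind = kind, units = units)
}

# flood fill over a logical mask (8-neighbour), used to test that linear
# features sever the grid
floodReaches <- function(open, from, to) {
  nr <- nrow(open); nc <- ncol(open)
  seen <- matrix(FALSE, nr, nc)
  stack <- list(from)
  seen[from[1], from[2]] <- TRUE
  while (length(stack)) {
    cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    for (dr in -1:1) for (dc in -1:1) {
      r2 <- cur[1] + dr; c2 <- cur[2] + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (seen[r2, c2] || !open[r2, c2]) next
      seen[r2, c2] <- TRUE
      stack[[length(stack) + 1L]] <- c(r2, c2)
    }
  }
  seen[to[1], to[2]]
}

# reference pedigree used by relatedness checks: broad founder base plus
# parent-offspring, full-sib, half-sib pairs and one clone
referencePedigree <- function(nFounders = 30) {
  stopifnot(nFounders >= 20)  # family structure references founders up to f20
  ids <- paste0("f", seq_len(nFounders))
  dam <- rep(NA_character_, nFounders)
  sire <- rep(NA_character_, nFounders)
  clone <- rep(NA_character_, nFounders)
  ids <- c(ids, paste0("o", 1:10), paste0("h", 1:5), "cl1")
  dam <- c(dam, rep(paste0("f", 1:5), each = 2),
           rep("f11", 3), rep("f14", 2), NA)
  sire <- c(sire, rep(paste0("f", 6:10), each = 2),
            "f12", "f13", "f17", "f15", "f16", NA)
  clone <- c(clone, rep(NA, 15), "f20")
  pedigreeSpec(ids, dam, sire, clone)
}

meanRelatednessByClass <- function(r, rel) {
  vapply(split(seq_len(nrow(rel)), rel$relation), function(rows)
    mean(mapply(function(a, b) r[a, b], rel$idA[rows], rel$idB[rows])),
    numeric(1))
}
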