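test_that("transition graph edges follow the mean-conductance formula", {
  rs <- surfaceFromMatrix(rbind(c(1, 1), c(4, NA)), resolution = 1)
  g <- buildTransitionGraph(rs)
  A <- as.matrix(conductanceMatrix(g))
  # node order is column-major over traversable cells:
  # 1=(1,1), 2=(2,1) r=4, 3=(1,2)
  expect_equal(A[1, 3], 1)                        # orthogonal r=1,r=1
  expect_equal(A[1, 2], (1 + 1 / 4) / 2)          # vertical r=1,r=4
  expect_equal(A[2, 3], ((1 / 4 + 1) / 2) / sqrt(2))  # diagonal
  expect_equal(nNodes(g), 3)                      # barrier cell has no node

  # diagonal distance scales with resolution
  rs5 <- surfaceFromMatrix(matrix(1, 2, 2), resolution = 5)
  A5 <- as.matrix(conductanceMatrix(buildTransitionGraph(rs5)))
  expect_equal(A5[1, 2], 1 / 5)
  expect_equal(A5[1, 4], 1 / (5 * sqrt(2)))

  # 4-neighbour option drops diagonals
  A4 <- as.matrix(conductanceMatrix(buildTransitionGraph(rs5,
                                                         neighbours = 4)))
  expect_equal(A4[1, 4], 0)
  expect_equal(A4[1, 2], 1 / 5)

  # epsilon repair connects resistance-isolated but contiguous cells
  rsHard <- surfaceFromMatrix(matrix(c(1, 1e9, 1), 1, 3), resolution = 1)
  rsHard@resistance[1, 2] <- 1e9  # effectively isolating middle strip
  gRep <- buildTransitionGraph(rsHard, epsilon = 1e-4)
  expect_true(hedgescape:::graphIsConnected(conductanceMatrix(gRep)))
})

test_that("least-cost paths match closed forms and exhaustive search", {
  # uniform surface: 10 m straight line costs 10
  rs <- surfaceFromMatrix(matrix(1, 3, 12), resolution = 1)
  pts <- pointsAtCells(rs, c(2, 2), c(1, 11), ids = c("a", "b"))
  g <- buildTransitionGraph(rs)
  D <- distanceValues(lcpDistance(g, pts))
  expect_equal(D["a", "b"], 10)
  expect_equal(D["b", "a"], 10)
  expect_equal(unname(diag(D)), c(0, 0))

  # wall with a gap: route must use the gap; cost equals brute force
  r <- matrix(1, 5, 5)
  r[, 3] <- 100
  r[4, 3] <- 1   # the gap
  rsW <- surfaceFromMatrix(r, resolution = 1)
  gW <- buildTransitionGraph(rsW)
  ptsW <- pointsAtCells(rsW, c(2, 2), c(1, 5), ids = c("l", "r"))
  res <- lcpDistance(gW, ptsW, paths = TRUE)
  W <- denseGridCosts(r, 1)
  DO <- oracleShortestPaths(W)
  idx <- function(row, col) (col - 1) * 5 + row
  expect_equal(distanceValues(res$distances)["l", "r"],
               DO[idx(2, 1), idx(2, 5)], tolerance = 1e-12)
  route <- res$paths
  expect_true(any(route$row == 4 & route$col == 3))   # passes the gap
  # consecutive route cells are 8-neighbours; step costs sum to the distance
  expect_true(all(abs(diff(route$row)) <= 1 & abs(diff(route$col)) <= 1))
  expect_equal(route$cost[1], distanceValues(res$distances)["l", "r"])

  # oracle equivalence on random grids
  for (s in 1:3) {
    rr <- randomResistanceGrid(5, 5, seed = s)
    rsR <- surfaceFromMatrix(rr, resolution = 1)
    gR <- buildTransitionGraph(rsR)
    ptsR <- pointsAtCells(rsR, c(1, 5, 3), c(1, 5, 2),
                          ids = c("p1", "p2", "p3"))
    DR <- distanceValues(lcpDistance(gR, ptsR))
    DOR <- oracleShortestPaths(denseGridCosts(rr, 1))
    expect_equal(DR["p1", "p2"], DOR[idx(1, 1), idx(5, 5)], tolerance = 1e-10)
    expect_equal(DR["p1", "p3"], DOR[idx(1, 1), idx(3, 2)], tolerance = 1e-10)
  }

  # raising a cell's resistance never shortens any path
  rUp <- r
  rUp[4, 3] <- 50
  DUp <- distanceValues(lcpDistance(buildTransitionGraph(
    surfaceFromMatrix(rUp, resolution = 1)), ptsW))
  expect_gte(DUp["l", "r"], distanceValues(res$distances)["l", "r"])

  # disconnected pair: infinite distance, flagged
  rSplit <- matrix(1, 3, 3); rSplit[, 2] <- NA
  rsS <- surfaceFromMatrix(rSplit, resolution = 1)
  ptsS <- pointsAtCells(rsS, c(2, 2), c(1, 3), ids = c("a", "b"))
  expect_warning(DS <- lcpDistance(buildTransitionGraph(rsS), ptsS,
                                   toleranceCells = 0.8), "disconnected")
  expect_true(is.infinite(distanceValues(DS)["a", "b"]))

  # snapping tolerance: a point on a barrier-only area errors by name
  expect_error(snapPoints(buildTransitionGraph(rsS),
                          data.frame(id = "far", x = 50, y = 50)), "far")
})

test_that("commute distances equal 2 * total conductance * R_eff", {
  # path graph A-B-C with unit conductances: C(A,C) = 2*2*2 = 8
  rs <- surfaceFromMatrix(matrix(1, 1, 3), resolution = 1)
  g <- buildTransitionGraph(rs)
  pts <- pointsAtCells(rs, c(1, 1), c(1, 3), ids = c("A", "C"))
  C <- distanceValues(commuteDistance(g, pts))
  expect_equal(C["A", "C"], 8)
  expect_equal(C["C", "A"], 8)
  expect_equal(unname(diag(C)), c(0, 0))

  # dense pseudoinverse oracle on random grids (5 seeds)
  for (s in 1:5) {
    nr <- sample(3:10, 1); nc <- sample(3:10, 1)
    rr <- randomResistanceGrid(nr, nc, seed = 100 + s)
    rsR <- surfaceFromMatrix(rr, resolution = 1)
    gR <- buildTransitionGraph(rsR)
    ptsR <- pointsAtCells(rsR, c(1, nr, max(1, nr %/% 2)),
                          c(1, nc, max(1, nc %/% 2)),
                          ids = c("p1", "p2", "p3"))
    CR <- distanceValues(commuteDistance(gR, ptsR))
    CO <- oracleCommute(conductanceMatrix(gR))
    nodes <- snapPoints(gR, ptsR)
    for (i in 1:2) for (j in (i + 1):3)
      expect_equal(CR[i, j], CO[nodes[i], nodes[j]], tolerance = 1e-8)
  }

  # disconnected graph errors with epsilon advice
  rSplit <- matrix(1, 3, 3); rSplit[, 2] <- NA
  rsS <- surfaceFromMatrix(rSplit, resolution = 1)
  ptsS <- pointsAtCells(rsS, c(2, 2), c(1, 3), ids = c("a", "b"))
  expect_error(commuteDistance(buildTransitionGraph(rsS), ptsS,
                               toleranceCells = 0.8), "epsilon")
})

test_that("both resistance distances behave as metrics on connected graphs", {
  for (s in 1:3) {
    rr <- randomResistanceGrid(6, 6, seed = 200 + s)
    rsR <- surfaceFromMatrix(rr, resolution = 1)
    gR <- buildTransitionGraph(rsR)
    ptsR <- pointsAtCells(rsR, c(1, 6, 3, 2), c(1, 6, 4, 5),
                          ids = paste0("p", 1:4))
    for (D in list(distanceValues(lcpDistance(gR, ptsR)),
                   distanceValues(commuteDistance(gR, ptsR)))) {
      expect_true(all(D >= -1e-9))
      expect_equal(D, t(D), tolerance = 1e-9)
      for (i in 1:4) for (j in 1:4) for (k in 1:4)
        expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-8)
    }
  }
})

test_that("euclidean distance is exact and bounds the LCP discretisation", {
  pts <- data.frame(id = c("a", "b"), x = c(0, 3), y = c(0, 4))
  E <- distanceValues(euclideanDistance(pts))
  expect_equal(E["a", "b"], 5)
  expect_equal(unname(diag(E)), c(0, 0))

  # on an all-ones surface the LCP exceeds Euclidean by at most the octile
  # worst case (ratio <= 1.083 for 8-neighbour grids)
  rs <- surfaceFromMatrix(matrix(1, 20, 20), resolution = 1)
  g <- buildTransitionGraph(rs)
  set.seed(9)
  cells <- cbind(sample(20, 6), sample(20, 6))
  pts2 <- pointsAtCells(rs, cells[, 1], cells[, 2], ids = paste0("p", 1:6))
  L <- distanceValues(lcpDistance(g, pts2))
  E2 <- distanceValues(euclideanDistance(pts2))
  off <- upper.tri(L)
  ratio <- L[off] / E2[off]
  expect_true(all(ratio <= 1.0824 + 1e-9))
  expect_true(all(ratio >= 1 - 1e-9))
})

test_that("passage maps carry unit net flow along forced corridors", {
  # single-corridor graph: every interior cell sees net passage 1
  rs <- surfaceFromMatrix(matrix(1, 1, 6), resolution = 1)
  g <- buildTransitionGraph(rs)
  pts <- pointsAtCells(rs, c(1, 1), c(1, 6), ids = c("s", "t"))
  pm <- passageMap(g, pts)
  expect_equal(unname(pm[1, 2:5]), rep(1, 4), tolerance = 1e-10)
  expect_equal(unname(pm[1, c(1, 6)]), c(0.5, 0.5), tolerance = 1e-10)

  # two equal parallel branches: half the flow per branch cell
  rr <- matrix(NA_real_, 3, 4)
  rr[2, 1] <- rr[2, 4] <- 1   # endpoints
  rr[1, 2:3] <- 1             # top branch
  rr[3, 2:3] <- 1             # bottom branch
  rsP <- surfaceFromMatrix(rr, resolution = 1)
  gP <- buildTransitionGraph(rsP, neighbours = 8)
  ptsP <- pointsAtCells(rsP, c(2, 2), c(1, 4), ids = c("s", "t"))
  pmP <- passageMap(gP, ptsP)
  expect_equal(unname(pmP[1, 2]), 0.5, tolerance = 1e-10)
  expect_equal(unname(pmP[3, 2]), 0.5, tolerance = 1e-10)

  # doubling all conductances leaves the map unchanged
  gP2 <- gP
  gP2@conductance <- gP@conductance * 2
  expect_equal(passageMap(gP2, ptsP), pmP, tolerance = 1e-10)

  # barrier cells stay NA
  expect_true(is.na(pmP[1, 1]))
})
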