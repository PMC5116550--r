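test_that("end and branch voxels are detected on a hand-built Y skeleton", {
  m <- array(FALSE, c(11, 11, 5))
  m[6, 2:6, 3] <- TRUE                 # stem
  m[cbind(5:3, 7:9, 3)] <- TRUE        # limb 1 (diagonal)
  m[cbind(7:9, 7:9, 3)] <- TRUE        # limb 2 (diagonal)
  ends <- findEndVoxels(m)
  expect_equal(nrow(ends), 3)
  cand <- branchCandidates(m)
  expect_true(nrow(cand) >= 1)
  expect_true(any(cand[, 1] == 6 & cand[, 2] == 6))
  res <- resolveBranchVoxels(cand, m)
  expect_equal(nrow(res), 1)
})

test_that("branchCost weights neighbour classes 4/3/2/1", {
  m <- array(FALSE, c(7, 7, 7))
  m[4, 4, 4] <- TRUE
  m[3, 4, 4] <- TRUE; m[5, 4, 4] <- TRUE; m[4, 3, 4] <- TRUE
  cand <- matrix(c(4, 4, 4,
                   3, 4, 4,
                   4, 3, 4), byrow = TRUE, ncol = 3)
  # centre: 3 skeleton nbrs, 2 face-connected candidates
  expect_equal(branchCost(c(4, 4, 4), cand, m), 4 * 3 + 3 * 2)
  # (3,4,4): 2 skeleton nbrs (centre, (4,3,4) diagonally); candidate nbrs:
  # centre (face-connected), (4,3,4) (edge-connected)
  expect_equal(branchCost(c(3, 4, 4), cand, m), 4 * 2 + 3 * 1 + 2 * 1)
})

test_that("buildGraph recovers the Y phantom exactly", {
  spec <- ySpec()
  m <- voxelData(rasterizeTree(spec)) > 0
  sk <- thin(m)
  g <- buildGraph(sk, m, spacing = c(1, 1, 1))
  v <- vertexTable(g)
  expect_equal(sum(v$kind == "end"), 3)
  expect_equal(sum(v$kind == "branch"), 1)
  expect_equal(nEdges(g), 3)
  e <- edgeTable(g)
  expect_true(all(e$distance <= e$length + 1e-9))
  # measured radii within half a voxel of the tube radii
  expect_true(all(e$meanRadius > 1.4 & e$meanRadius < 3.1))
})

test_that("edge volumes account for every vessel voxel", {
  spec <- ySpec()
  m <- voxelData(rasterizeTree(spec)) > 0
  sk <- thin(m)
  g <- buildGraph(sk, m, spacing = c(1, 1, 1))
  expect_equal(sum(edgeTable(g)$volume), sum(m))
})

test_that("graph of a pure cycle keeps the cycle", {
  ring <- array(FALSE, c(10, 10, 4))
  ring[3:8, 3:8, 2:3] <- TRUE; ring[5:6, 5:6, 2:3] <- FALSE
  sk <- thin(ring)
  g <- buildGraph(sk, ring, spacing = c(1, 1, 1))
  # chi = 0: one independent cycle, so #edges = #vertices
  expect_equal(nEdges(g), nVertices(g))
})

test_that("buildGraph rejects a skeleton escaping its vessel mask", {
  m <- array(FALSE, c(6, 6, 6)); m[2:5, 3, 3] <- TRUE
  vm <- m; vm[5, 3, 3] <- FALSE
  expect_error(buildGraph(m, vm), "outside")
})

test_that("paths connect their edge's endpoint regions", {
  spec <- ySpec()
  m <- voxelData(rasterizeTree(spec)) > 0
  sk <- thin(m)
  g <- buildGraph(sk, m, spacing = c(1, 1, 1))
  v <- vertexTable(g); e <- edgeTable(g); p <- edgePaths(g)
  for (k in seq_len(nrow(e))) {
    a <- v[match(e$from[k], v$id), c("vx", "vy", "vz")]
    b <- v[match(e$to[k], v$id), c("vx", "vy", "vz")]
    first <- p[[k]][1, ]; last <- p[[k]][nrow(p[[k]]), ]
    expect_lt(max(abs(first - as.numeric(a))), 3)  # contact voxel of tangle
    expect_lt(max(abs(last - as.numeric(b))), 3)
    steps <- diff(p[[k]])
    expect_true(all(abs(steps) <= 1))              # voxel-to-voxel path
  }
})
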