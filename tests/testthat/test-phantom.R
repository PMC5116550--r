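test_that("TreeSpec validity catches malformed trees", {
  nodes <- data.frame(id = 1:3, x = c(10, 10, 20), y = 10, z = c(5, 15, 25))
  edges <- data.frame(parent = c(1, 2), child = c(2, 3), radius = 2)
  expect_s4_class(TreeSpec(nodes, edges, c(1, 1, 1), c(32, 32, 32), 0L),
                  "TreeSpec")
  # two roots / not spanning
  badE <- data.frame(parent = 1, child = 2, radius = 2)
  expect_error(TreeSpec(nodes, badE, c(1, 1, 1), c(32, 32, 32), 0L))
  # radius below the voxel spacing
  thin <- edges; thin$radius <- 0.3
  expect_error(TreeSpec(nodes, thin, c(1, 1, 1), c(32, 32, 32), 0L))
  # node outside the grid extent
  far <- nodes; far$x[3] <- 80
  expect_error(TreeSpec(far, edges, c(1, 1, 1), c(32, 32, 32), 0L))
})

test_that("rasterized 8-leaf binary tree volume is within 15% of analytic", {
  nodes <- data.frame(
    id = 1:15,
    x = c(40, 40, 22, 58, 12, 32, 48, 68, 6, 18, 26, 38, 42, 54, 62),
    y = c(40, 40, 40, 40, 26, 54, 26, 54, 14, 38, 62, 42, 14, 38, 62),
    z = c(5, 20, 32, 32, 46, 46, 46, 46, 60, 60, 60, 60, 60, 60, 60))
  edges <- data.frame(
    parent = c(1, 2, 2, 3, 3, 4, 4, 5, 5, 6, 6, 7, 7, 8),
    child = c(2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15),
    radius = c(3, 2.5, 2.5, 2, 2, 2, 2, 1.5, 1.5, 1.5, 1.5, 1.5, 1.5, 1.5))
  spec <- TreeSpec(nodes, edges, c(1, 1, 1), c(80, 80, 72), 0L)
  vol <- rasterizeTree(spec)
  m <- voxelData(vol) > 0
  p <- as.matrix(nodes[, c("x", "y", "z")])
  L <- sqrt(rowSums((p[edges$parent, ] - p[edges$child, ])^2))
  analytic <- sum(pi * edges$radius^2 * L)
  expect_lt(abs(sum(m) - analytic) / analytic, 0.15)
  expect_equal(oracleComponents(m), 1L)
})

test_that("rasterizeTree names the offending edge when out of bounds", {
  nodes <- data.frame(id = 1:2, x = c(1, 1), y = c(16, 16), z = c(5, 25))
  edges <- data.frame(parent = 1, child = 2, radius = 2.5)
  spec <- TreeSpec(nodes, edges, c(1, 1, 1), c(32, 32, 32), 0L)
  expect_error(rasterizeTree(spec), "edge")
})

test_that("makeLiverPhantom nests vessels and clips tumours", {
  ph <- makeLiverPhantom(ySpec(), tumorCenters = c(24, 24, 30), tumorRadii = 6)
  liver <- voxelData(ph$liver); vessels <- voxelData(ph$vessels) > 0
  tumors <- voxelData(ph$tumors)
  expect_true(all(liver[vessels]))
  expect_true(all(liver[tumors]))
  expect_gt(sum(tumors), 0)
})

test_that("corruptMask is seed-deterministic and keeps one component", {
  m <- voxelData(rasterizeTree(ySpec())) > 0
  c1 <- corruptMask(m, cavityRate = 0.2, bridgeCount = 2, seed = 7)
  c2 <- corruptMask(m, cavityRate = 0.2, bridgeCount = 2, seed = 7)
  c3 <- corruptMask(m, cavityRate = 0.2, bridgeCount = 2, seed = 8)
  expect_identical(c1, c2)
  expect_false(identical(c1, c3))
  expect_false(identical(c1, m))
  expect_equal(oracleComponents(c1), 1L)
})

test_that("TreeSpec JSON round trip", {
  spec <- ySpec()
  f <- tempfile(fileext = ".json")
  writeTreeSpec(spec, f)
  back <- readTreeSpec(f)
  expect_equal(back@nodes$x, spec@nodes$x)
  expect_equal(back@edges$radius, spec@edges$radius)
  expect_equal(back@shape, spec@shape)
  unlink(f)
})
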