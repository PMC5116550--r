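# hand-built rooted tree used by the subtree tests: a fat trunk 1-2-3 and
# two thin limbs hanging off vertices 3 and 2
.handTree <- function(meanRadius = c(3, 3, 1, 1, 1, 1, 1)) {
  v <- data.frame(id = 1:8,
                  vx = c(2, 8, 14, 20, 24, 20, 8, 8),
                  vy = c(2, 2, 2, 2, 6, 8, 8, 14),
                  vz = 2,
                  radius = 1,
                  kind = c("end", "branch", "branch", "branch",
                           "end", "end", "branch", "end"))
  v$x <- v$vx - 1; v$y <- v$vy - 1; v$z <- v$vz - 1
  e <- data.frame(id = 1:7,
                  from = c(1, 2, 3, 4, 4, 2, 7),
                  to = c(2, 3, 4, 5, 6, 7, 8),
                  length = 1, distance = 1, volume = 1,
                  meanRadius = meanRadius)
  e$meanRadiusRaw <- e$meanRadius^2
  e$angle <- NA_real_; e$cyclic <- FALSE; e$label <- "portal"
  paths <- lapply(seq_len(nrow(e)), function(k) {
    a <- match(e$from[k], v$id); b <- match(e$to[k], v$id)
    rbind(as.integer(unlist(v[a, c("vx", "vy", "vz")])),
          as.integer(unlist(v[b, c("vx", "vy", "vz")])))
  })
  new("VesselTree", vertices = v, edges = e, paths = paths,
      spacing = c(1, 1, 1), dim = c(32L, 32L, 32L), root = 1L)
}

test_that("fitRadiusThreshold recovers a well-separated two-Gaussian mixture", {
  set.seed(42)
  radii <- pmax(c(rnorm(700, 1.5, 0.2), rnorm(300, 4, 0.4)), 0.2)
  model <- fitRadiusThreshold(radii, seed = 0L)
  expect_s4_class(model, "RadiusModel")
  expect_false(model@fallback)
  expect_lt(abs(model@mu2 - 1.5), 0.1)
  expect_lt(abs(model@mu1 - 4), 0.15)
  expect_lt(model@sigma2, model@sigma1)
  # theta = 2 * mu - Min with mu the small-radius component mean
  expect_equal(model@theta, 2 * model@mu2 - min(radii))
  expect_equal(radiusThreshold(model), model@theta)
  # the threshold actually separates the two populations
  expect_gt(model@theta, 1.5)
  expect_lt(model@theta, 4 - 2 * 0.4)
  # deterministic for a fixed seed
  model2 <- fitRadiusThreshold(radii, seed = 0L)
  expect_equal(model2@theta, model@theta)
})

test_that("fitRadiusThreshold falls back to 0.5 * Max when degenerate", {
  expect_warning(m1 <- fitRadiusThreshold(c(1, 2, 3)), "fewer than 4")
  expect_true(m1@fallback)
  expect_equal(m1@theta, 1.5)
  # a single point mass cannot support two components
  m2 <- fitRadiusThreshold(rep(2, 50))
  expect_true(m2@fallback)
  expect_equal(m2@theta, 2)          # 0.5 * Max clamped up to Min
  expect_error(fitRadiusThreshold(c(1, -1, 2, 3)))
})

test_that("splitSubtrees partitions edges at theta and roots each subtree", {
  t <- .handTree()
  s <- splitSubtrees(t, theta = 2)
  expect_setequal(s$first, c(1, 2))                  # the two fat trunk edges
  expect_equal(length(s$second), 2)
  vsets <- lapply(s$second, `[[`, "vertices")
  i <- which(vapply(vsets, function(x) 4 %in% x, TRUE))
  expect_setequal(vsets[[i]], c(3, 4, 5, 6))
  expect_equal(s$second[[i]]$root, 3)                # closest to the main root
  expect_setequal(vsets[[3 - i]], c(2, 7, 8))
  expect_equal(s$second[[3 - i]]$root, 2)
  expect_setequal(unlist(lapply(s$second, `[[`, "edges")), 3:7)
  # everything below theta: one subtree spanning the whole tree
  sAll <- splitSubtrees(t, theta = 5)
  expect_equal(length(sAll$first), 0)
  expect_equal(length(sAll$second), 1)
  expect_equal(sAll$second[[1]]$root, 1)
})

test_that("pruneMicro removes subtrees with five or fewer vertices", {
  big <- list(root = 1L, vertices = 1:6, edges = 1:5)
  small <- list(root = 7L, vertices = 7:10, edges = 6:8)
  kept <- pruneMicro(list(big, small))
  expect_equal(length(kept), 1)
  expect_equal(kept[[1]]$root, 1L)
  expect_error(pruneMicro(list(small)), "Micro")
  expect_equal(pruneMicro(list()), list())
})

test_that("clusterBranches groups subtree roots by spatial proximity", {
  # 9 one-vertex subtrees whose roots form 3 tight spatial clusters
  v <- data.frame(id = 1:9,
                  vx = c(2, 3, 2, 20, 21, 20, 2, 3, 2),
                  vy = c(2, 2, 3, 2, 2, 3, 20, 20, 21),
                  vz = 2, radius = 1,
                  kind = c("end", rep("branch", 7), "end"))
  v$x <- v$vx - 1; v$y <- v$vy - 1; v$z <- v$vz - 1
  e <- data.frame(id = 1:8, from = 1, to = 2:9,
                  length = 1, distance = 1, volume = 1, meanRadius = 1,
                  meanRadiusRaw = 1, angle = NA_real_, cyclic = FALSE,
                  label = "portal")
  paths <- lapply(seq_len(nrow(e)), function(k) {
    a <- match(e$from[k], v$id); b <- match(e$to[k], v$id)
    rbind(as.integer(unlist(v[a, c("vx", "vy", "vz")])),
          as.integer(unlist(v[b, c("vx", "vy", "vz")])))
  })
  t <- new("VesselTree", vertices = v, edges = e, paths = paths,
           spacing = c(1, 1, 1), dim = c(32L, 32L, 32L), root = 1L)
  subtrees <- lapply(1:9, function(i)
    list(root = i, vertices = i, edges = integer(0)))
  d <- clusterBranches(t, subtrees, K = 3L, seed = 0L)
  expect_s4_class(d, "BranchDivision")
  lab <- branchLabels(d)
  expect_equal(length(lab), 9)
  expect_equal(lab[1], 1L)                           # first-occurrence labels
  expect_equal(lab[1:3], rep(lab[1], 3))             # tight triples co-cluster
  expect_equal(lab[4:6], rep(lab[4], 3))
  expect_equal(lab[7:9], rep(lab[7], 3))
  expect_equal(length(unique(lab)), 3)
  # determinism for a fixed seed
  d2 <- clusterBranches(t, subtrees, K = 3L, seed = 0L)
  expect_identical(branchLabels(d2), lab)
  # too few subtrees for K: lowered with a warning
  expect_warning(d3 <- clusterBranches(t, subtrees[1:2], K = 3L), "lowering K")
  expect_equal(d3@K, 2L)
})

test_that("k-means++ initial centres are distinct input rows", {
  X <- matrix(c(0, 0, 0, 10, 0, 0, 0, 10, 0, 10, 10, 0, 5, 5, 9),
              ncol = 3, byrow = TRUE)
  centers <- withr::with_seed(1, livertree:::.kmeansppInit(X, 3))
  expect_equal(dim(centers), c(3, 3))
  expect_equal(nrow(unique(centers)), 3)
  hits <- apply(centers, 1, function(r)
    any(apply(X, 1, function(x) all(x == r))))
  expect_true(all(hits))
})
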