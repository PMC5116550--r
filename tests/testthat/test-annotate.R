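# minimal rooted tree whose 1-vertex subtrees sit at chosen voxels; used to
# drive the minimum-distance classifier with known group members
.seedDivision <- function(seedVox, labels = seq_len(nrow(seedVox)),
                          K = max(labels), dims = c(16L, 16L, 16L),
                          spacing = c(1, 1, 1)) {
  n <- nrow(seedVox) + 1
  v <- data.frame(id = seq_len(n),
                  vx = c(1L, seedVox[, 1]), vy = c(1L, seedVox[, 2]),
                  vz = c(1L, seedVox[, 3]),
                  radius = 1, kind = c("end", rep("end", n - 1)))
  v$kind[1] <- "branch"
  v$x <- (v$vx - 1) * spacing[1]
  v$y <- (v$vy - 1) * spacing[2]
  v$z <- (v$vz - 1) * spacing[3]
  e <- data.frame(id = seq_len(n - 1), from = 1L, to = 2:n,
                  length = 1, distance = 1, volume = 1, meanRadius = 1,
                  meanRadiusRaw = 1, angle = NA_real_, cyclic = FALSE,
                  label = "portal")
  paths <- lapply(seq_len(nrow(e)), function(k) {
    a <- match(e$from[k], v$id); b <- match(e$to[k], v$id)
    rbind(as.integer(unlist(v[a, c("vx", "vy", "vz")])),
          as.integer(unlist(v[b, c("vx", "vy", "vz")])))
  })
  t <- new("VesselTree", vertices = v, edges = e, paths = paths,
           spacing = spacing, dim = dims, root = 1L)
  subtrees <- lapply(2:n, function(i)
    list(root = i, vertices = i, edges = integer(0)))
  new("BranchDivision", tree = t, subtrees = subtrees,
      labels = as.integer(labels), K = as.integer(K),
      centers = matrix(0, K, 3))
}

test_that("classifyVoxels matches the brute-force nearest-group oracle", {
  dims <- c(14L, 12L, 10L)
  spacing <- c(1, 1.5, 2)
  seeds <- rbind(c(3, 3, 3), c(11, 4, 3), c(6, 10, 8), c(12, 11, 8))
  div <- .seedDivision(seeds, dims = dims, spacing = spacing)
  liver <- array(FALSE, dims); liver[2:13, 2:11, 2:9] <- TRUE
  seg <- classifyVoxels(liver, div, spacing = spacing, verticesOnly = TRUE)
  expect_s4_class(seg, "SegmentMap")
  lab <- voxelData(seg)
  expect_true(all(lab[!liver] == 0))
  expect_true(all(lab[liver] > 0))
  groupsVox <- lapply(seq_len(4), function(k) seeds[k, , drop = FALSE])
  idx <- which(liver, arr.ind = TRUE)
  pick <- seq(1, nrow(idx), by = 17)           # sampled voxels, all regions
  for (r in pick) {
    expect_equal(lab[idx[r, 1], idx[r, 2], idx[r, 3]],
                 oracleNearestLabel(idx[r, ], groupsVox, spacing))
  }
})

test_that("classifyVoxels resolves distance ties to the lower label", {
  dims <- c(11L, 5L, 5L)
  seeds <- rbind(c(3, 3, 3), c(9, 3, 3))
  div <- .seedDivision(seeds, dims = dims)
  liver <- array(TRUE, dims)
  lab <- voxelData(classifyVoxels(liver, div, spacing = c(1, 1, 1),
                                  verticesOnly = TRUE))
  expect_equal(lab[6, 3, 3], 1L)               # equidistant: lower label
  expect_equal(lab[2, 3, 3], 1L)
  expect_equal(lab[10, 3, 3], 2L)
})

test_that("classifyVoxels rejects empty masks and empty groups", {
  div <- .seedDivision(rbind(c(3, 3, 3)), labels = 1L, K = 2L)
  liver <- array(TRUE, c(16, 16, 16))
  expect_error(classifyVoxels(liver, div, spacing = c(1, 1, 1),
                              verticesOnly = TRUE), "empty")
  expect_error(classifyVoxels(array(FALSE, c(4, 4, 4)),
                              .seedDivision(rbind(c(2, 2, 2))),
                              spacing = c(1, 1, 1), verticesOnly = TRUE),
               "empty liver")
})

test_that("branchGroupVoxels pools and deduplicates member voxels", {
  seeds <- rbind(c(3, 3, 3), c(9, 9, 9))
  div <- .seedDivision(seeds, labels = c(1L, 1L), K = 1L)
  g <- branchGroupVoxels(div, verticesOnly = TRUE)
  expect_equal(length(g), 1)
  expect_equal(nrow(g[[1]]), 2)
  expect_setequal(g[[1]][, 1], c(3, 9))
})

test_that("segmentAttributes arithmetic on raw counts", {
  a <- segmentAttributes(c(100, 100, 200))
  expect_equal(a$rSeg, c(25, 25, 50))
  expect_equal(a$vSeg, c(0.1, 0.1, 0.2))       # mL at 1 mm isotropic
  expect_equal(a$rTumor, c(0, 0, 0))
  a2 <- segmentAttributes(c(100, 100, 200), tumors = c(10, 0, 50),
                          spacing = c(2, 2, 2))
  expect_equal(a2$vSeg, c(0.8, 0.8, 1.6))
  expect_equal(a2$rTumor, c(10, 0, 25))
  expect_equal(sum(a2$rSeg), 100)
})

test_that("segmentAttributes on a SegmentMap counts labels and tumours", {
  lab <- array(0L, c(6, 6, 6))
  lab[2:3, 2:3, 2:3] <- 1L                     # 8 voxels
  lab[5, 2:5, 2] <- 2L                         # 4 voxels
  seg <- new("SegmentMap", data = lab, spacing = c(1, 2, 1), K = 2L)
  tm <- array(FALSE, c(6, 6, 6)); tm[2, 2, 2] <- TRUE
  a <- segmentAttributes(seg, tumors = tm)
  expect_equal(a$nSeg, c(8, 4))
  expect_equal(a$rSeg, c(66.67, 33.33))
  expect_equal(a$vSeg, round(c(8, 4) * 2 / 1000, 2))
  expect_equal(a$rTumor, c(12.5, 0))
  bad <- tm; bad[6, 6, 6] <- TRUE              # outside every segment
  expect_error(segmentAttributes(seg, tumors = bad), "outside")
})

test_that("lobeReport groups Couinaud segments into anatomical lobes", {
  a <- segmentAttributes(rep(100, 8))
  lr <- lobeReport(a)
  expect_equal(nrow(lr), 7)
  expect_equal(lr$ratio[lr$lobe == "caudate"], 12.5)
  expect_equal(lr$ratio[lr$lobe == "left lateral"], 25)
  expect_equal(lr$ratio[lr$lobe == "right lobe"], 50)
  # a permuted relabelling moves the counts with the anatomy
  counts <- c(10, 20, 30, 40, 50, 60, 70, 120)   # total 400
  a2 <- segmentAttributes(counts)
  relabel <- setNames(paste0("Seg", c("VIII", "VII", "VI", "V",
                                      "IV", "III", "II", "I")), 1:8)
  lr2 <- lobeReport(a2, relabel)
  expect_equal(lr2$ratio[lr2$lobe == "caudate"], 30)       # SegI = 120/400
  expect_equal(lr2$ratio[lr2$lobe == "left lateral"], 32.5)  # 70 + 60
  expect_error(lobeReport(segmentAttributes(rep(1, 5))), "8 segments")
  badMap <- setNames(rep("SegI", 8), 1:8)
  expect_error(lobeReport(a, badMap), "distinct")
})

test_that("writeReport writes a deterministic report bundle", {
  seeds <- rbind(c(3, 3, 3), c(9, 3, 3))
  div <- .seedDivision(seeds, dims = c(11L, 5L, 5L))
  liver <- array(TRUE, c(11, 5, 5))
  seg <- classifyVoxels(liver, div, spacing = c(1, 1, 1), verticesOnly = TRUE)
  tm <- array(FALSE, c(11, 5, 5)); tm[3, 3, 3] <- TRUE
  attrs <- segmentAttributes(seg, tumors = tm)
  d1 <- tempfile(); d2 <- tempfile()
  f1 <- writeReport(seg, attrs, NULL, div@tree, d1, tumors = tm,
                    params = list(seed = 0))
  f2 <- writeReport(seg, attrs, NULL, div@tree, d2, tumors = tm,
                    params = list(seed = 0))
  expect_true(all(file.exists(f1)))
  expect_true(any(grepl("segment_attributes[.]csv$", f1)))
  for (nm in c("segment_attributes.csv", "vessel_tree.json", "manifest.json")) {
    expect_identical(readLines(file.path(d1, nm)),
                     readLines(file.path(d2, nm)))
  }
  back <- readVolume(file.path(d1, "segments.nii.gz"))
  expect_equal(voxelData(back), voxelData(seg) * 1, tolerance = 1e-6)
  tj <- jsonlite::read_json(file.path(d1, "vessel_tree.json"))
  expect_equal(tj$tree$root, 1)
  expect_equal(length(tj$lesions), 1)
  expect_equal(tj$lesions[[1]]$segment, 1)
  unlink(c(d1, d2), recursive = TRUE)
})
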