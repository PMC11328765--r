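# Centerline extraction, junction detection and confluence demarcation.

test_that("arc length matches closed forms", {
  expect_equal(arcLength(rbind(c(0, 0, 0), c(3, 4, 0))), 5)
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0), c(0, 0, 0))
  expect_equal(arcLength(sq), 4)
  th <- seq(0, pi, length.out = 1000)
  semi <- cbind(cos(th), sin(th), 0)
  expect_lt(abs(arcLength(semi) - pi), 1e-4)
  expect_error(arcLength(matrix(c(1, 2, 3), 1)), "2 points")
  # arc length >= straight end-to-end distance
  set.seed(5)
  for (i in 1:10) {
    P <- matrix(rnorm(30), ncol = 3)
    expect_gte(arcLength(P) + 1e-12,
               sqrt(sum((P[10, ] - P[1, ])^2)))
  }
})

test_that("a straight cylinder yields an axial centerline of the right length", {
  vol <- makeCylinderVolume(radius = 4, length = 40, spacing = 0.5)
  tree <- extractCenterlineTree(vol, roles = "PVC")
  P <- branchPolylines(tree)$PVC
  # true axis: x = z = 0, y in [0, 40]
  axisDev <- sqrt(P[, 1]^2 + P[, 3]^2)
  expect_lt(max(axisDev), 0.5)          # within one voxel of the axis
  expect_lt(abs(arcLength(P) - 40) / 40, 0.05)
})

test_that("halving the spacing reduces the axis deviation", {
  dev <- vapply(c(1.0, 0.5), function(h) {
    vol <- makeCylinderVolume(radius = 4, length = 30, spacing = h)
    P <- branchPolylines(extractCenterlineTree(vol, roles = "PVC"))$PVC
    max(sqrt(P[, 1]^2 + P[, 3]^2))
  }, numeric(1))
  expect_lt(dev[2], dev[1])
})

test_that("the skeleton of a one-voxel line is the line itself", {
  vox <- array(0L, c(20, 3, 3))
  vox[3:18, 2, 2] <- 2L
  vol <- LabelVolume(vox, spacing = c(1, 1, 1))
  P <- branchPolylines(extractCenterlineTree(vol, roles = "PVC"))$PVC
  centers <- voxelToWorld(vol, cbind(2:17, 1, 1))
  expect_true(isTRUE(all.equal(P, centers, check.attributes = FALSE)) ||
              isTRUE(all.equal(P, centers[16:1, ],
                               check.attributes = FALSE)))
})

test_that("an L-shaped tube keeps most of its length through the corner", {
  vol <- makeLTubeVolume(radius = 2, limb = 20, spacing = 0.5)
  P <- branchPolylines(extractCenterlineTree(vol, roles = "PVC"))$PVC
  expect_lt(abs(arcLength(P) - 40) / 40, 0.075)
})

test_that("whole-voxel translation translates the centerline exactly", {
  vol <- makeCylinderVolume(radius = 3, length = 20, spacing = 0.5)
  P1 <- branchPolylines(extractCenterlineTree(vol, roles = "PVC"))$PVC
  shifted <- LabelVolume(voxelData(vol), spacing = voxelSpacing(vol),
                         origin = volumeOrigin(vol) + c(2, -1.5, 0.5))
  P2 <- branchPolylines(extractCenterlineTree(shifted, roles = "PVC"))$PVC
  expect_equal(sweep(P2, 2, c(2, -1.5, 0.5)), P1, tolerance = 1e-12)
})

test_that("degenerate labels produce informative errors", {
  vox <- array(0L, c(10, 10, 10))
  vol <- LabelVolume(vox, spacing = c(1, 1, 1))
  expect_error(extractCenterlineTree(vol, roles = "PVC"), "PVC")
  vox[2:4, 2, 2] <- 2L
  vox[8:9, 8, 8] <- 2L   # second 6-connected component
  vol <- LabelVolume(vox, spacing = c(1, 1, 1))
  expect_error(extractCenterlineTree(vol, roles = "PVC"), "disconnected")
  # an empty requested role is named in the error
  sound <- makeCylinderVolume(radius = 3, length = 15, spacing = 0.5)
  expect_error(extractCenterlineTree(sound, roles = c("PVC", "VV")), "VV")
})

test_that("junction nodes land on the phantom junction planes", {
  ph <- cachedPhantom("slab")
  tree <- extractCenterlineTree(ph$volume)
  jx <- findJunctions(tree, ph$volume)
  expect_length(jx, 2L)
  h <- max(voxelSpacing(ph$volume))
  for (j in jx) {
    truthJ <- if ("VV" %in% j$roles) ph$truth$junctions[[2]]
              else ph$truth$junctions[[1]]
    expect_lt(sqrt(sum((j$point - truthJ$point)^2)), h)
    expect_true(all(truthJ$roles %in% j$roles))
  }
})

test_that("three tubes meeting at a point give one junction of three roles", {
  h <- 0.5
  xs <- seq(-12, 12, by = h) + h / 4
  g <- expand.grid(x = xs, y = xs, z = xs, KEEP.OUT.ATTRS = FALSE)
  segDist <- function(S, E) {
    D <- E - S; l2 <- sum(D^2)
    t <- pmin(1, pmax(0, ((g$x - S[1]) * D[1] + (g$y - S[2]) * D[2] +
                            (g$z - S[3]) * D[3]) / l2))
    sqrt((g$x - S[1] - t * D[1])^2 + (g$y - S[2] - t * D[2])^2 +
           (g$z - S[3] - t * D[3])^2)
  }
  vox <- array(0L, rep(length(xs), 3))
  vox[segDist(c(0, -10, 0), c(0, 0, 0)) <= 2] <- 2L                 # PVC
  vox[vox == 0L & segDist(c(0, 0, 0), c(8, 4, 0)) <= 1.5] <- 4L     # RUPV
  vox[vox == 0L & segDist(c(0, 0, 0), c(-8, 4, 0)) <= 1.5] <- 6L    # RIPV
  vol <- LabelVolume(vox, spacing = rep(h, 3),
                     origin = c(xs[1], xs[1], xs[1]))
  tree <- extractCenterlineTree(vol, roles = c("PVC", "RUPV", "RIPV"))
  jx <- findJunctions(tree, vol)
  expect_length(jx, 1L)
  expect_setequal(jx[[1]]$roles, c("PVC", "RUPV", "RIPV"))

  # an unbranched single tube has no junctions
  solo <- makeCylinderVolume(radius = 3, length = 20, spacing = 0.5)
  treeSolo <- extractCenterlineTree(solo, roles = "PVC")
  expect_length(findJunctions(treeSolo, solo), 0L)
})

test_that("a vein that never touches the main channel is a topology error", {
  vol <- makeCylinderVolume(radius = 3, length = 20, spacing = 0.5)
  vox <- voxelData(vol)
  vox[2:5, 2, 2] <- 4L    # floating RUPV far from the tube
  vol2 <- LabelVolume(vox, spacing = voxelSpacing(vol),
                      origin = volumeOrigin(vol))
  tree <- extractCenterlineTree(vol2, roles = c("PVC", "RUPV"))
  expect_error(findJunctions(tree, vol2), "RUPV")
})

test_that("the demarcated confluence matches the junction-plane clip", {
  ph <- cachedPhantom("slab")
  tree <- extractCenterlineTree(ph$volume)
  jx <- findJunctions(tree, ph$volume)
  seg <- demarcateConfluence(tree, jx)
  expect_lt(abs(seg@arcLen - 30) / 30, 0.05)
  h <- max(voxelSpacing(ph$volume))
  # endpoints sit on the junction planes (within a voxel along the axis)
  u <- c(0, 1, 0.15) / sqrt(1 + 0.15^2)
  P <- segmentPoints(seg)
  sFirst <- sum((P[1, ] - c(3, 0, 0)) * u)
  sLast <- sum((P[nrow(P), ] - c(3, 0, 0)) * u)
  expect_lt(min(abs(c(sFirst, sLast))), h)
  expect_lt(min(abs(c(sFirst, sLast) - 30)), h)
  # the segment stays inside the confluence label support
  idx <- worldToVoxel(ph$volume, P)
  labs <- voxelData(ph$volume)[idx + 1]
  expect_true(all(labs == labelSchema(ph$volume)[["PVC"]]))

  sph <- cachedPhantom("sphere")
  treeS <- extractCenterlineTree(sph$volume)
  segS <- demarcateConfluence(treeS, findJunctions(treeS, sph$volume))
  expect_lt(abs(segS@arcLen - 22) / 22, 0.05)   # centerline arc (R+g)*theta
})

test_that("coincident junctions are a degenerate-confluence error", {
  ph <- cachedPhantom("slab")
  tree <- extractCenterlineTree(ph$volume)
  jx <- findJunctions(tree, ph$volume)
  jx2 <- jx
  jx2[[2]]$station <- jx[[1]]$station
  expect_error(demarcateConfluence(tree, jx2), "degenerate")
})
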