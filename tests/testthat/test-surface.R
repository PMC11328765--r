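# LA isosurface extraction and closest-point projection.

test_that("sphere surface vertices sit on the label isosurface", {
  ph <- cachedPhantom("sphere")
  mesh <- cachedQuantification("sphere")$mesh
  r <- sqrt(rowSums(meshVertices(mesh)^2))
  expect_lt(max(abs(r - 20)), 0.5)   # within one voxel of the true radius
})

test_that("the marching-tetrahedra mesh is watertight", {
  vox <- array(0L, c(12, 12, 12))
  g <- expand.grid(i = 1:12, j = 1:12, k = 1:12)
  inside <- (g$i - 6.5)^2 + (g$j - 6.5)^2 + (g$k - 6.5)^2 <= 16
  vox[as.matrix(g)[inside, ]] <- 1L
  vol <- LabelVolume(vox, spacing = c(1, 1, 1))
  mesh <- extractLASurface(vol)
  f <- meshFaces(mesh)
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  keys <- paste(pmin(edges[, 1], edges[, 2]),
                pmax(edges[, 1], edges[, 2]))
  expect_true(all(table(keys) == 2L))   # every edge borders two triangles
})

test_that("a single-voxel LA yields a small closed surface around it", {
  vox <- array(0L, c(5, 5, 5)); vox[3, 3, 3] <- 1L
  vol <- LabelVolume(vox, spacing = c(1, 1, 1), origin = c(0, 0, 0))
  mesh <- extractLASurface(vol)
  V <- meshVertices(mesh)
  expect_gt(nrow(meshFaces(mesh)), 0)
  centre <- c(2, 2, 2)   # world mm of voxel (2,2,2) with origin 0
  expect_lt(max(abs(sweep(V, 2, centre))), 1)   # encloses the voxel
  # positive total area
  f <- meshFaces(mesh)
  a <- V[f[, 2], ] - V[f[, 1], ]; b <- V[f[, 3], ] - V[f[, 1], ]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  expect_gt(sum(sqrt(rowSums(cr^2))) / 2, 0)
})

test_that("the slab face appears as a planar patch at the box boundary", {
  ph <- cachedPhantom("slab")
  mesh <- cachedQuantification("slab")$mesh
  V <- meshVertices(mesh)
  onFace <- abs(V[, 1]) < 1e-9
  expect_gt(sum(onFace), 100)   # a real patch, exactly on x = 0
})

test_that("projection onto the slab face is the perpendicular foot", {
  q <- cachedQuantification("slab")
  curve <- q$correspondence@curve
  expect_lt(max(abs(curve[, 1])), 0.3)            # curve lies on the face
  expect_lt(abs(q$correspondence@ccl - 30) / 30, 0.05)
})

test_that("a segment lying on the surface is a fixed point of projection", {
  ph <- cachedPhantom("slab")
  mesh <- cachedQuantification("slab")$mesh
  # a straight segment on the x = 0 face, well inside the face patch
  seg <- new("ConfluenceSegment",
             points = cbind(0, seq(5, 25, by = 0.5), 0),
             arcLen = 20,
             endRoles = list(first = "RUPV", last = "VV"))
  cs <- projectConfluence(seg, mesh)
  expect_lt(max(confluencemorph:::.closestOnPolyline(
    seg@points, cs@curve)$dist), 1e-6)
  expect_equal(cs@ccl, 20, tolerance = 1e-6)
})

test_that("projection onto a convex surface contracts the curve", {
  q <- cachedQuantification("sphere")
  expect_lte(q$correspondence@ccl, q$segment@arcLen)
})

test_that("projection guards: empty mesh errors, distant segments warn", {
  emptyMesh <- new("SurfaceMesh", vertices = matrix(0, 0, 3),
                   faces = matrix(0L, 0, 3))
  seg <- new("ConfluenceSegment",
             points = cbind(0, seq(0, 10, by = 1), 3), arcLen = 10,
             endRoles = list(first = "RUPV", last = "VV"))
  expect_error(projectConfluence(seg, emptyMesh), "empty")
  mesh <- cachedQuantification("slab")$mesh
  far <- new("ConfluenceSegment",
             points = cbind(60, seq(5, 15, by = 1), 0), arcLen = 10,
             endRoles = list(first = "RUPV", last = "VV"))
  expect_warning(projectConfluence(far, mesh), "sanity bound")
  expect_error(extractLASurface(
    LabelVolume(array(0L, c(3, 3, 3)), spacing = c(1, 1, 1))), "LA")
})
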