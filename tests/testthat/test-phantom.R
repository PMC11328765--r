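# Phantom generation: closed-form truth, rasterization accuracy, layout
# topology and the synthetic cohort generator.

test_that("phantom truth values come from the closed forms", {
  slab <- cachedPhantom("slab")
  expect_equal(slab$truth$ccl, 30)
  expect_equal(slab$truth$dblc, 3)
  expect_equal(slab$truth$ratio, 10)
  expect_equal(slab$truth$pvcVolume, pi * 2.5^2 * 30 / 1000)

  sph <- cachedPhantom("sphere")
  expect_equal(sph$truth$ccl, 20)       # R * theta
  expect_equal(sph$truth$dblc, 2)
  expect_equal(sph$truth$laVolume, 4 / 3 * pi * 20^3 / 1000)
  expect_equal(sph$truth$pvcVolume, pi * 1.8^2 * 22 / 1000)
})

test_that("rasterized volumes track the analytic values", {
  # ellipsoid with equal semi-axes: the analytic sphere volume (33.510
  # cm^3 for r = 20 mm) is the oracle
  ph <- makePhantom(phantomConfig("ellipsoid_tree", semiAxes = c(20, 20, 20)))
  vLA <- voxelVolume(ph$volume, "LA")
  expect_lt(abs(vLA - 33.5103) / 33.5103, 0.02)

  # refinement: the voxel-count error shrinks as spacing decreases
  coarse <- suppressWarnings(
    makePhantom(phantomConfig("ellipsoid_tree", spacing = 2,
                              semiAxes = c(20, 20, 20))))
  errCoarse <- abs(voxelVolume(coarse$volume, "LA") - 33.5103)
  errFine <- abs(vLA - 33.5103)
  expect_lt(errFine, errCoarse)
})

test_that("phantom labels are disjoint and wired per the supracardiac layout", {
  ph <- cachedPhantom("slab")
  vol <- ph$volume
  counts <- labelCounts(vol)
  expect_true(all(counts > 0))   # all seven structures present
  # the confluence touches the four PV stubs and the VV, and nothing is
  # mislabelled: every venous structure attaches to the main channel
  tree <- extractCenterlineTree(vol)
  jx <- findJunctions(tree, vol)
  touching <- sort(unique(unlist(lapply(jx, `[[`, "roles"))))
  expect_setequal(touching, c("PVC", "LUPV", "RUPV", "LIPV", "RIPV", "VV"))
})

test_that("configuration errors are rejected before rasterization", {
  expect_error(phantomConfig("slab", gap = 2, tubeRadius = 2.5),
               "intersect")
  expect_error(phantomConfig("sphere_arc", gap = 1.5, tubeRadius = 1.8),
               "intersect")
  expect_error(phantomConfig("slab", spacing = -1), "spacing")
  expect_error(phantomConfig("slab", tubeRadius = 0.6, stubRadius = 0.5,
                             strict = TRUE),
               "under-resolved")
  expect_warning(phantomConfig("slab", tubeRadius = 0.6, stubRadius = 0.5),
                 "under-resolved")
})

test_that("the type Ib layout mirrors the junction roles left-right", {
  ph <- makePhantom(phantomConfig("slab", vvSide = "right"))
  tree <- extractCenterlineTree(ph$volume)
  jx <- findJunctions(tree, ph$volume)
  seg <- demarcateConfluence(tree, jx)
  expect_setequal(seg@endRoles$first, c("LUPV", "LIPV"))
  expect_true("VV" %in% seg@endRoles$last)
  expect_true("RUPV" %in% seg@endRoles$last)
})

test_that("synthetic cohorts are reproducible and respect the censoring knob", {
  a <- makeSyntheticCohort(50, seed = 7)
  b <- makeSyntheticCohort(50, seed = 7)
  expect_identical(a$cohort, b$cohort)
  c2 <- makeSyntheticCohort(50, seed = 8)
  expect_false(identical(a$cohort$time_months, c2$cohort$time_months))

  noCens <- makeSyntheticCohort(40, censorRate = 0, seed = 1)
  expect_true(all(noCens$cohort$event))

  heavy <- makeSyntheticCohort(2000, censorRate = 0.6, seed = 2)
  expect_lt(abs(mean(!heavy$cohort$event) - 0.6), 0.05)

  expect_error(makeSyntheticCohort(100, censorRate = 1.2), "censorRate")
  expect_error(makeSyntheticCohort(1), "n must be")
})

test_that("cohort truth metrics match their geometric closed forms", {
  sc <- makeSyntheticCohort(30, seed = 3)
  cfg <- sc$configs[[5]]
  row <- sc$cohort[5, ]
  expect_equal(row$ila_volume,
               (4 / 3 * pi * cfg$laRadius^3 / 1000) / row$bsa_m2)
  expect_equal(row$ratio, cfg$laRadius * cfg$arcAngle / cfg$gap)
  expect_equal(row$itvlc, row$ila_volume + row$ipvc_volume)
})
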