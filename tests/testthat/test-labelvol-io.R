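# Volume and cohort I/O: round trips, schema validation, unit metadata.

test_that("NIfTI round trip preserves voxels, spacing and origin exactly", {
  v <- array(0L, c(8, 6, 5))
  v[2, 3, 4] <- 1L; v[5, 5, 2] <- 2L; v[1, 1, 1] <- 7L
  vol <- LabelVolume(v, spacing = c(0.25, 0.25, 0.5),
                     origin = c(-2, 1.5, 0))
  f <- tempfile(fileext = ".nii.gz")
  writeLabelVolume(vol, f)
  back <- readLabelVolume(f)
  expect_identical(voxelData(back), voxelData(vol))
  expect_identical(voxelSpacing(back), c(0.25, 0.25, 0.5))
  expect_equal(volumeOrigin(back), c(-2, 1.5, 0))
  unlink(f)
})

test_that("MetaImage round trip matches NIfTI semantics", {
  v <- array(0L, c(4, 4, 4)); v[2, 2, 2] <- 1L
  vol <- LabelVolume(v, spacing = c(0.5, 0.5, 1), origin = c(1, 2, 3))
  f <- tempfile(fileext = ".mha")
  writeLabelVolume(vol, f)
  back <- readLabelVolume(f)
  expect_identical(voxelData(back), voxelData(vol))
  expect_identical(voxelSpacing(back), c(0.5, 0.5, 1))
  expect_identical(volumeOrigin(back), c(1, 2, 3))
  unlink(f)
})

test_that("an all-background volume round-trips with zero foreground", {
  vol <- LabelVolume(array(0L, c(3, 3, 3)), spacing = c(1, 1, 1))
  f <- tempfile(fileext = ".nii.gz")
  writeLabelVolume(vol, f)
  expect_identical(sum(voxelData(readLabelVolume(f)) != 0L), 0L)
  unlink(f)
})

test_that("minimal volumes and metadata validation behave as specified", {
  # one LA voxel
  v <- array(0L, c(3, 3, 3)); v[2, 2, 2] <- 1L
  vol <- LabelVolume(v, spacing = c(1, 1, 1))
  expect_identical(unname(labelCounts(vol)["LA"]), 1L)
  # anisotropic spacing passes through construction untouched
  va <- LabelVolume(v, spacing = c(0.5, 0.5, 1.0))
  expect_identical(voxelSpacing(va), c(0.5, 0.5, 1.0))
  # unknown label under the default schema names the offender
  vbad <- array(0L, c(3, 3, 3)); vbad[1, 1, 1] <- 9L
  expect_error(LabelVolume(vbad, spacing = c(1, 1, 1)), "9")
  # spacing must be positive and finite
  expect_error(LabelVolume(v, spacing = c(1, 0, 1)), "spacing")
})

test_that("voxel/world coordinate mapping is the identity on indices", {
  vol <- LabelVolume(array(0L, c(10, 12, 9)),
                     spacing = c(0.5, 0.7, 1.1), origin = c(-3, 2, 5))
  set.seed(42)
  idx <- cbind(sample(0:9, 25, TRUE), sample(0:11, 25, TRUE),
               sample(0:8, 25, TRUE))
  expect_identical(worldToVoxel(vol, voxelToWorld(vol, idx)), idx * 1.0)
  expect_equal(voxelToWorld(vol, matrix(c(0, 0, 0), 1)),
               matrix(c(-3, 2, 5), 1))
})

test_that("cohort tables are parsed, typed and validated", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("id,age_days,bsa_m2,prepvo,time_months,event,clamp_min",
               "P1,61,0.26,1,12.5,0,45",
               "P2,30,0.22,0,1.5,1,60",
               "P3,150,0.31,0,24,0,38"), f)
  tab <- readCohortTable(f)
  expect_identical(nrow(tab), 3L)
  expect_type(tab$prepvo, "logical")
  expect_type(tab$event, "logical")
  expect_true("clamp_min" %in% names(tab))   # extras retained
  unlink(f)

  fbad <- tempfile(fileext = ".csv")
  writeLines(c("id,age_days,bsa_m2,prepvo,time_months,event",
               "P1,61,0.26,1,12.5,0",
               "P2,30,0,0,1.5,1"), fbad)
  expect_error(readCohortTable(fbad), "row 2")
  writeLines(c("id,age_days,bsa_m2,prepvo,time_months,event",
               "P1,61,0.26,1,12.5,0",
               "P1,30,0.22,0,1.5,1"), fbad)
  expect_error(readCohortTable(fbad), "duplicate")
  writeLines(c("id,age_days,bsa_m2,prepvo,time_months,event",
               "P1,61,0.26,1,-3,0"), fbad)
  expect_error(readCohortTable(fbad), "time_months")
  unlink(fbad)
})
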