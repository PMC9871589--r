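test_that("probability maps round-trip through NIfTI unchanged", {
  dims <- c(16L, 16L, 16L)
  pm <- probability_map(array(0.5, dims), "GM")
  path <- tempfile(fileext = ".nii.gz")
  write_probability_map(pm, path)
  back <- load_probability_map(path, "GM")
  expect_identical(dim(back), dims)
  expect_equal(as.numeric(back), as.numeric(pm), tolerance = 1e-7)

  set.seed(11)
  pm2 <- probability_map(array(runif(prod(dims)), dims), "WM",
                         affine = diag(c(2, 2, 2, 1)))
  path2 <- tempfile(fileext = ".nii.gz")
  write_probability_map(pm2, path2)
  back2 <- load_probability_map(path2, "WM")
  expect_equal(as.numeric(back2), as.numeric(pm2), tolerance = 1e-7)
  expect_equal(attr(back2, "affine")[1:3, 1:3], diag(c(2, 2, 2)),
               tolerance = 1e-6)
})

test_that("loading clamps float excursions outside [0, 1]", {
  arr <- array(0.5, c(4, 4, 4))
  arr[1, 1, 1] <- 1.0000001
  arr[2, 1, 1] <- -0.0000001
  path <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  pm <- load_probability_map(path, "GM")
  expect_equal(max(pm), 1)
  expect_equal(min(pm), 0)
})

test_that("non-3D images are rejected with a format error", {
  path <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(matrix(0.5, 4, 4)), path)
  expect_error(load_probability_map(path, "GM"), class = "epcog_format_error")
  expect_error(load_probability_map(tempfile(fileext = ".nii"), "GM"),
               class = "epcog_io_error")
})

test_that("resampling: identity, constants, and the trilinear oracle", {
  pm <- probability_map(array(0.3, c(6, 6, 6)), "GM")
  expect_identical(resample_volume(pm, c(6, 6, 6)), pm)
  up <- resample_volume(pm, c(9, 7, 5))
  expect_identical(dim(up), c(9L, 7L, 5L))
  expect_true(all(abs(up - 0.3) < 1e-12))

  checker <- array((outer(outer(1:4, 1:4, "+"), 1:4, "+") %% 2), c(4, 4, 4))
  pm2 <- probability_map(checker, "GM")
  got <- resample_volume(pm2, c(2, 2, 2))
  expect_equal(array(got, c(2, 2, 2)), oracle_trilinear(checker, c(2, 2, 2)),
               tolerance = 1e-9)

  set.seed(21)
  for (rep in 1:10) {
    sd <- sample(2:8, 3, replace = TRUE)
    td <- sample(2:8, 3, replace = TRUE)
    src <- array(runif(prod(sd)), sd)
    got <- resample_volume(probability_map(src, "GM"), td)
    expect_equal(array(got, td), oracle_trilinear(src, td), tolerance = 1e-6)
  }
})

test_that("channel stacking fixes GM/WM order and replicates lone maps", {
  gm <- probability_map(array(0.2, c(4, 4, 4)), "GM")
  wm <- probability_map(array(0.7, c(4, 4, 4)), "WM")
  both <- stack_channels(gm, wm)
  expect_identical(dim(both), c(4L, 4L, 4L, 2L))
  expect_equal(attr(both, "channel_names"), c("GM", "WM"))
  expect_equal(both[, , , 1], array(0.2, c(4, 4, 4)))
  expect_equal(both[, , , 2], array(0.7, c(4, 4, 4)))

  solo <- stack_channels(gm = gm)
  expect_identical(dim(solo)[4], 2L)
  expect_equal(solo[, , , 1], solo[, , , 2])
  solo_wm <- stack_channels(wm = wm)
  expect_identical(dim(solo_wm)[4], 2L)

  expect_error(stack_channels(), class = "epcog_argument_error")
  wm_small <- probability_map(array(0.5, c(2, 2, 2)), "WM")
  expect_error(stack_channels(gm, wm_small), class = "epcog_shape_error")
})

test_that("cohorts load from CSV plus volume files, flagging gaps", {
  dir <- tempfile()
  dir.create(dir)
  meta <- data.frame(subject_id = c("s1", "s2", "s3"),
                     diagnosis = c("EP", "HC", "EP"),
                     gender = c("M", "F", "M"),
                     ethnicity = "caucasian", age = c(24, 25, 26),
                     psp = c(50, NA, 41), vig = 50, wme = 50, vel = 50,
                     vil = 50, pso = 50)
  csv <- file.path(dir, "metadata.csv")
  write.csv(meta, csv, row.names = FALSE, na = "")
  for (id in meta$subject_id) {
    write_probability_map(probability_map(array(0.4, c(4, 4, 4)), "GM"),
                          file.path(dir, paste0(id, "_gm.nii.gz")))
  }
  coh <- load_cohort(csv, dir)
  expect_s3_class(coh, "epcog_cohort")
  expect_equal(nrow(coh), 3)
  # WM channel replicated from the GM map
  expect_equal(coh$volume[[1]][, , , 1], coh$volume[[1]][, , , 2])
  expect_true(is.na(coh$psp[2]))
  expect_false(is.na(coh$psp[1]))

  bad <- meta[, setdiff(names(meta), "diagnosis")]
  csv_bad <- file.path(dir, "bad.csv")
  write.csv(bad, csv_bad, row.names = FALSE)
  expect_error(load_cohort(csv_bad, dir), class = "epcog_schema_error")

  meta4 <- rbind(meta, data.frame(subject_id = "s4", diagnosis = "HC",
                                  gender = "M", ethnicity = "other", age = 30,
                                  psp = 50, vig = 50, wme = 50, vel = 50,
                                  vil = 50, pso = 50))
  csv4 <- file.path(dir, "four.csv")
  write.csv(meta4, csv4, row.names = FALSE, na = "")
  expect_error(load_cohort(csv4, dir), regexp = "s4",
               class = "epcog_io_error")
})

test_that("cohorts round-trip through the on-disk layout", {
  coh <- tiny_cohort(n_hc = 2, n_ep = 2, dims = c(6, 6, 6), seed = 5)
  dir <- tempfile()
  write_cohort(coh, dir)
  back <- load_cohort(file.path(dir, "metadata.csv"), dir)
  expect_equal(back$subject_id, coh$subject_id)
  expect_equal(as.character(back$diagnosis), as.character(coh$diagnosis))
  expect_equal(back$psp, coh$psp, tolerance = 1e-6)
  expect_equal(as.numeric(back$volume[[1]]), as.numeric(coh$volume[[1]]),
               tolerance = 1e-6)
})
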