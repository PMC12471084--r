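# NIfTI round trips, resampling, depth cropping, ROI masking

test_that("NIfTI volumes round-trip through .nii and .nii.gz", {
  set.seed(1)
  vol <- volume(array(stats::rnorm(16^3), c(16, 16, 16)), c(1, 2, 3), "MRI_like")
  for (ext in c("nii", "nii.gz")) {
    path <- file.path(tempdir(), paste0("rt.", ext))
    write_volume(vol, path)
    back <- read_volume(path)
    expect_lt(max(abs(back$data - vol$data)), 1e-6)
    expect_lt(max(abs(back$spacing_mm - c(1, 2, 3))), 1e-6)
  }
  expect_error(read_volume(file.path(tempdir(), "nope.nii.gz")), "not found")
  # malformed file
  bad <- file.path(tempdir(), "bad.nii")
  writeBin(raw(100), bad)
  expect_error(read_volume(bad), "malformed")
})

test_that("external NIfTI reader (nibabel) agrees on a written volume", {
  vol <- volume(array(seq_len(4 * 5 * 6) / 10, c(4, 5, 6)), c(0.5, 1, 1.5))
  path <- file.path(tempdir(), "nib.nii.gz")
  write_volume(vol, path)
  out <- system2("python", c("-c", shQuote(paste0(
    "import nibabel, numpy; img = nibabel.load('", path, "'); ",
    "d = numpy.asarray(img.dataobj); ",
    "print(d.shape, round(float(d[1,2,3]), 5), ",
    "[round(float(z),4) for z in img.header.get_zooms()])"))),
    stdout = TRUE)
  expect_match(out, "(4, 5, 6)", fixed = TRUE)
  expect_match(out, as.character(round(vol$data[2, 3, 4], 5)), fixed = TRUE)
  expect_match(out, "0.5, 1.0, 1.5", fixed = TRUE)
})

test_that("deformation fields and landmarks round-trip", {
  v <- make_velocity_field(c(8, 8, 8), 1, 4, 1)
  path <- file.path(tempdir(), "field.nii.gz")
  write_field(v, path)
  back <- read_field(path)
  expect_lt(max(abs(back - v)), 1e-6)
  lms <- landmark_set(matrix(c(1.5, 2, 3, 4, 5.25, 6), 2, byrow = TRUE), c("a", "b"))
  lp <- file.path(tempdir(), "lms.csv")
  write_landmarks(lms, lp)
  back <- read_landmarks(lp)
  expect_equal(back$points, lms$points)
  expect_identical(back$ids, lms$ids)
})

test_that("resample_to_grid interpolates correctly", {
  vol <- volume(array(stats::rnorm(8^3), c(8, 8, 8)))
  expect_equal(resample_to_grid(vol, c(8, 8, 8))$data, vol$data, tolerance = 1e-12)
  cst <- volume(array(2.5, c(8, 8, 8)))
  expect_true(all(abs(resample_to_grid(cst, c(16, 16, 16))$data - 2.5) < 1e-12))
  # linear ramp stays a monotone ramp along the same axis
  ramp <- volume(array(rep(seq_len(8), times = 64), c(8, 8, 8)))
  up <- resample_to_grid(ramp, c(16, 16, 16))
  expect_true(all(apply(up$data, c(2, 3), function(r) all(diff(r) >= 0))))
  # spacing preserves physical extent
  expect_equal(up$spacing_mm, c(0.5, 0.5, 0.5))
  # nearest-neighbor keeps masks binary
  msk <- label_mask((array(stats::runif(8^3), c(8, 8, 8)) > 0.5) + 0)
  rs <- resample_to_grid(msk, c(12, 12, 12))
  expect_true(all(rs$data %in% c(0, 1)))
  expect_error(resample_to_grid(vol, c(1, 8, 8)), "target_shape")
})

test_that("crop_depth and pad_depth behave as specified", {
  vol <- volume(array(stats::rnorm(128 * 6 * 6), c(128, 6, 6)))
  cropped <- crop_depth(vol, 4)
  expect_equal(dim(cropped$data), c(120, 6, 6))
  expect_identical(crop_depth(vol, 0), vol)
  v16 <- volume(array(seq_len(16 * 4 * 4), c(16, 4, 4)))
  c16 <- crop_depth(v16, 4)
  expect_equal(dim(c16$data), c(8, 4, 4))
  expect_equal(c16$data, v16$data[5:12, , ])
  expect_error(crop_depth(v16, 8), "too small")
  # pad-back restores the shape
  expect_equal(dim(pad_depth(c16, 16)$data), dim(v16$data))
})

test_that("apply_roi masks element-wise and is idempotent", {
  vol <- volume(array(3, c(4, 4, 4)))
  ones <- label_mask(array(1, c(4, 4, 4)))
  zeros <- label_mask(array(0, c(4, 4, 4)))
  expect_equal(apply_roi(vol, ones)$data, vol$data)
  expect_true(all(apply_roi(vol, zeros)$data == 0))
  half <- array(0, c(4, 4, 4)); half[1:2, , ] <- 1
  hm <- label_mask(half)
  out <- apply_roi(vol, hm)
  expect_equal(sum(out$data != 0), sum(half))
  expect_equal(apply_roi(apply_roi(vol, hm), hm)$data, out$data)
  expect_error(apply_roi(vol, label_mask(array(1, c(3, 4, 4)))), "shapes")
})

test_that("container invariants are enforced", {
  expect_error(volume(array(c(1, NA), c(2, 1, 1))), "finite")
  expect_error(volume(array(1, c(2, 2, 2)), spacing_mm = c(1, -1, 1)), "positive")
  expect_error(label_mask(array(0.5, c(2, 2, 2))), "exactly")
  expect_error(landmark_set(matrix(0, 2, 3), ids = "a"), "lengths")
})
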