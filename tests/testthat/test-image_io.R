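## frames with controllable metadata for error-path tests
write_frame <- function(dir, name, ..., orientation = c(1, 0, 0, 0, 1, 0),
                        spacing = c(1, 1), position = c(0, 0, 0),
                        instance = 1L, trigger = NULL) {
  f <- file.path(dir, name)
  write_dicom_frame(f, matrix(100, 8, 8), pixel_spacing = spacing,
                    image_position = position, image_orientation = orientation,
                    instance_number = instance, trigger_time = trigger,
                    sop_uid = paste0("2.25.77.", instance))
  f
}

test_that("a phantom stack loads as 2 slices x 20 phases with 0.7 mm pixels", {
  spec <- phantom_spec("image_stack", seed = 5, n_slices = 2, n_phases = 20,
                       rows = 64, cols = 64, r_base = 10, wall_thickness = 5)
  dir <- tempfile("stack")
  ph <- make_image_stack(spec, dir = dir)
  stacks <- load_cine_stack(ph$files)
  expect_length(stacks, 1)
  st <- stacks[[1]]
  expect_identical(st$n_phases, 20L)
  expect_identical(st$n_slices, 2L)
  expect_equal(st$pixel_spacing, c(0.7, 0.7))
  expect_identical(st$view, "short_axis")
  ## reading back reproduces the written pixel data bit-exactly
  expect_identical(st$frames[[2]][[3]],
                   matrix(as.integer(round(ph$images[[1]][[3]])), 64, 64))
})

test_that("missing or inconsistent metadata raises errors", {
  dir <- tempfile("bad"); dir.create(dir)
  ## strip ImageOrientationPatient by writing a truncated element set
  f <- write_frame(dir, "a.dcm")
  raw <- readBin(f, raw(), file.info(f)$size)
  ## locate tag (0020,0037) and excise the element (6 values, DS)
  tag <- c(0x20, 0x00, 0x37, 0x00)
  pos <- which(vapply(seq_len(length(raw) - 3), function(i)
    all(as.integer(raw[i:(i + 3)]) == tag), TRUE))[1]
  vr_len <- as.integer(raw[pos + 6]) + 256L * as.integer(raw[pos + 7])
  raw2 <- raw[-(pos:(pos + 7 + vr_len))]
  f2 <- file.path(dir, "noorient.dcm")
  writeBin(raw2, f2)
  expect_error(load_cine_stack(f2), "image_orientation")

  ## non-orthogonal cosines
  f3 <- write_frame(dir, "skew.dcm",
                    orientation = c(1, 0, 0, 0.1, 0.9949874371, 0))
  expect_error(load_cine_stack(f3), "orthonormal")

  ## mixed pixel spacings within one slice position
  d2 <- tempfile("mix"); dir.create(d2)
  write_frame(d2, "p1.dcm", spacing = c(1, 1), instance = 1L, trigger = 0)
  write_frame(d2, "p2.dcm", spacing = c(2, 2), instance = 2L, trigger = 50)
  expect_error(load_cine_stack(list.files(d2, full.names = TRUE)),
               "mixed pixel spacings")
})

test_that("views are split by orientation and classified against the short-axis normal", {
  dir <- tempfile("views"); dir.create(dir)
  fs <- character(0)
  ## short-axis stack: 3 slices x 2 phases, axial orientation
  k <- 0
  for (s in 1:3) for (p in 1:2) {
    k <- k + 1
    fs <- c(fs, write_frame(dir, sprintf("sa%d.dcm", k),
                            position = c(0, 0, -8 * (s - 1)),
                            instance = k, trigger = 100 * (p - 1)))
  }
  ## long-axis plane: normal perpendicular to the short-axis normal
  for (p in 1:2) {
    k <- k + 1
    fs <- c(fs, write_frame(dir, sprintf("la%d.dcm", k),
                            orientation = c(1, 0, 0, 0, 0, 1),
                            instance = k, trigger = 100 * (p - 1)))
  }
  stacks <- load_cine_stack(fs)
  expect_length(stacks, 2)
  expect_identical(stacks[[1]]$view, "short_axis")
  expect_identical(stacks[[1]]$n_slices, 3L)
  expect_identical(stacks[[2]]$view, "long_axis")
})

test_that("pixel_to_patient follows the DICOM affine convention", {
  spec <- phantom_spec("image_stack", seed = 2, n_slices = 3, n_phases = 2,
                       rows = 32, cols = 32, r_base = 6, wall_thickness = 3)
  dir <- tempfile("geom")
  ph <- make_image_stack(spec, dir = dir)
  st <- load_cine_stack(ph$files)[[1]]
  ## origin pixel maps to ImagePositionPatient exactly
  expect_equal(pixel_to_patient(st, 1, c(0, 0)), st$slice_positions[[1]])
  ## identity orientation, 0.7 mm spacing: pixel (0, 10) is +7 mm along x
  expect_equal(pixel_to_patient(st, 1, c(0, 10)) - pixel_to_patient(st, 1, c(0, 0)),
               c(7, 0, 0))
  ## parallel slices 8 mm apart along the slice normal
  d <- pixel_to_patient(st, 2, c(5, 5)) - pixel_to_patient(st, 1, c(5, 5))
  expect_equal(sqrt(sum(d^2)), 8)
  expect_equal(abs(sum(d * st$normal)), 8)
  ## out-of-range slice
  expect_error(pixel_to_patient(st, 9, c(0, 0)), "out of range")
})

test_that("pixel <-> patient round-trip is exact to 1e-9 mm", {
  spec <- phantom_spec("image_stack", seed = 2, n_slices = 3, n_phases = 2,
                       rows = 32, cols = 32, r_base = 6, wall_thickness = 3)
  dir <- tempfile("rt")
  ph <- make_image_stack(spec, dir = dir)
  st <- load_cine_stack(ph$files)[[1]]
  pts <- cbind(runif(20, 0, 31), runif(20, 0, 31))
  back <- patient_to_pixel(st, 2, pixel_to_patient(st, 2, pts))
  expect_lt(max(abs(back - pts)), 1e-9)
})
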