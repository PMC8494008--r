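test_that("scan_images orders by byte-wise codepoint, independent of listing order", {
  root <- withr::local_tempdir()
  png::writePNG(matrix(0.5, 4, 4), file.path(root, "b.png"))
  jpeg::writeJPEG(matrix(0.5, 4, 4), file.path(root, "A.jpg"))
  tiff::writeTIFF(matrix(0.5, 4, 4), file.path(root, "10.tif"))
  ds <- scan_images(root)
  # digits < uppercase < lowercase in codepoint order
  expect_equal(ds$records$path, c("10.tif", "A.jpg", "b.png"))
  expect_equal(ds$records$position, 0:2)
  expect_equal(ds$records$class_index, rep(0L, 3))
})

test_that("class sub-folders give alphabetically indexed labels", {
  root <- withr::local_tempdir()
  for (cls in c("cat", "ant")) {
    dir.create(file.path(root, cls))
    for (i in 1:2) {
      png::writePNG(matrix(0.2, 4, 4), file.path(root, cls, sprintf("%s_%d.png", cls, i)))
    }
  }
  ds <- scan_images(root)
  expect_equal(ds$classes, c("ant", "cat"))
  by_label <- split(ds$records$class_index, ds$records$label)
  expect_equal(unique(by_label$ant), 0L)
  expect_equal(unique(by_label$cat), 1L)
  # labels constant within folder, strictly increasing across sorted folders
  expect_true(all(diff(ds$records$class_index) >= 0))
})

test_that("an explicit file list fixes the order exactly and misses are reported", {
  root <- withr::local_tempdir()
  dir.create(file.path(root, "aardvark"))
  for (i in 1:2) {
    png::writePNG(matrix(0.3, 4, 4),
                  file.path(root, "aardvark", sprintf("aardvark_%02d.png", i)))
  }
  wanted <- c("aardvark/aardvark_02.png", "aardvark/aardvark_01.png")
  ds <- scan_images(root, file_names = wanted)
  expect_equal(ds$records$path, wanted)
  err <- expect_error(scan_images(root, file_names = c("aardvark/missing.png")),
                      class = "netrsa_input_error")
  expect_match(conditionMessage(err), "missing.png")
  expect_error(scan_images(withr::local_tempdir()), class = "netrsa_input_error")
})

test_that("load_image returns [0,1] HxWx3 with grayscale replication and alpha dropped", {
  root <- withr::local_tempdir()
  png::writePNG(matrix(1, 2, 2), file.path(root, "white.png"))        # grayscale white
  rgba <- array(runif(2 * 2 * 4), c(2, 2, 4))
  png::writePNG(rgba, file.path(root, "rgba.png"))
  img <- load_image(root, "white.png")
  expect_identical(dim(img), c(2L, 2L, 3L))
  expect_true(all(img == 1))
  expect_equal(img[, , 1], img[, , 2])   # replicated channels

  img4 <- load_image(root, "rgba.png")
  expect_identical(dim(img4), c(2L, 2L, 3L))

  # 8-bit 51 scales to 0.2
  png::writePNG(matrix(51 / 255, 1, 1), file.path(root, "gray.png"))
  expect_equal(load_image(root, "gray.png")[1, 1, 1], 0.2, tolerance = 1e-7)

  writeLines("not an image", file.path(root, "broken.png"))
  err <- expect_error(load_image(root, "broken.png"), class = "netrsa_decode_error")
  expect_match(conditionMessage(err), "broken.png")
})

test_that("apply_transforms resizes, crops and normalizes with the documented arithmetic", {
  img <- array(runif(512 * 384 * 3), c(512, 384, 3))
  out <- apply_transforms(img, transform_spec())
  expect_identical(dim(out), c(3L, 224L, 224L))

  # mean 0 / sd 1 leaves values unchanged by normalization
  small <- array(runif(8 * 8 * 3), c(8, 8, 3))
  ident <- transform_spec(resize = 8, crop = 8, mean = rep(0, 3), std = rep(1, 3))
  expect_equal(as.numeric(apply_transforms(small, ident)),
               as.numeric(aperm(small, c(3, 1, 2))))

  # channels_last carries identical values, permuted
  cf <- apply_transforms(small, ident, layout = "channels_first")
  cl <- apply_transforms(small, ident, layout = "channels_last")
  expect_identical(dim(cl), c(8L, 8L, 3L))
  expect_equal(aperm(cl, c(3, 1, 2)), cf)

  expect_error(transform_spec(resize = 100, crop = 224),
               class = "netrsa_parameter_error")
})

test_that("batch_iterator preserves order with a smaller final batch", {
  root <- make_image_root(withr::local_tempdir(), n_classes = 1, n_per_class = 5, size = 8)
  ds <- scan_images(root, transform = transform_spec(8, 8, rep(0, 3), rep(1, 3)))
  batches <- batch_iterator(ds, 2)
  expect_equal(vapply(batches, function(b) dim(b$data)[1], 0), c(2, 2, 1))
  expect_equal(unlist(lapply(batches, `[[`, "positions")), 0:4)
  single <- batch_iterator(ds, 99)
  expect_length(single, 1L)
  expect_equal(dim(single[[1]]$data)[1], 5L)
  expect_error(batch_iterator(ds, 0), class = "netrsa_range_error")
})

test_that("the order record pairs rows with image names and round-trips", {
  root <- make_image_root(withr::local_tempdir(), n_classes = 2, n_per_class = 2, size = 8)
  out <- withr::local_tempdir()
  ds <- scan_images(root)
  path <- write_order_record(ds, out)
  lines <- readLines(path)
  expect_equal(lines, ds$records$path)

  # explicit-list dataset writes the list verbatim (separate directory so the
  # original record file stays intact)
  rev_list <- rev(ds$records$path)
  ds_rev <- scan_images(root, file_names = rev_list)
  expect_equal(readLines(write_order_record(ds_rev, withr::local_tempdir())), rev_list)

  # involution: re-scanning with the record file as explicit list reproduces order
  ds_again <- scan_images(root, file_names = readLines(path))
  expect_equal(ds_again$records, ds$records)
})
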