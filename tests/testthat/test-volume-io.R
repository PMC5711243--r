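test_that("image_volume and binary_mask enforce their invariants", {
  expect_error(image_volume(matrix(0, 2, 2), c(1, 1, 1)), "3D")
  expect_error(image_volume(array(0, c(2, 2, 2)), c(1, -1, 1)), "positive")
  bad <- array(0, c(2, 2, 2)); bad[1] <- NA
  expect_error(image_volume(bad, c(1, 1, 1)), "finite")

  vol <- image_volume(array(1:8, c(2, 2, 2)), c(2, 2, 3), c(-1, 0, 1))
  m <- binary_mask(array(c(TRUE, rep(FALSE, 7)), c(2, 2, 2)),
                   geometry_from = vol)
  expect_equal(mask_volume_cm3(m), 1 * 2 * 2 * 3 / 1000)
  expect_error(binary_mask(array(TRUE, c(3, 2, 2)), geometry_from = vol),
               "shape")
})

test_that("voxel index / world coordinate mapping round-trips", {
  vol <- image_volume(array(0, c(5, 6, 7)), c(3.91, 3.91, 3.27),
                      c(-100, -50, 12))
  expect_equal(index_to_world(vol, c(1, 1, 1)), c(-100, -50, 12))
  expect_equal(index_to_world(vol, c(2, 1, 3)),
               c(-100 + 3.91, -50, 12 + 2 * 3.27))
  idx <- rbind(c(1, 2, 3), c(5, 6, 7), c(2.5, 3.5, 1))
  expect_equal(world_to_index(vol, index_to_world(vol, idx)), idx)
})

test_that("volumes round-trip through NIfTI and MetaImage with geometry", {
  set.seed(11)
  vol <- image_volume(array(rnorm(16 * 12 * 10, 5000, 800), c(16, 12, 10)),
                      spacing = c(3.91, 3.91, 3.27), origin = c(-31, -24, 0))
  for (ext in c(".nii.gz", ".mha", ".mhd")) {
    path <- tempfile(fileext = ext)
    write_volume(vol, path)
    back <- read_volume(path)
    expect_equal(back$data, vol$data, tolerance = 1e-12)
    expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
    expect_equal(back$origin, vol$origin, tolerance = 1e-4)
  }
})

test_that("masks round-trip bit-exactly and unreadable input errors cleanly", {
  set.seed(12)
  m <- binary_mask(array(stats::runif(8 * 8 * 8) > 0.5, c(8, 8, 8)),
                   spacing = c(2, 2, 2.5))
  for (ext in c(".nii.gz", ".mha")) {
    path <- tempfile(fileext = ext)
    write_volume(m, path)
    expect_identical(read_mask(path)$data, m$data)
  }
  expect_error(read_volume(tempfile(fileext = ".nii")), "does not exist")
  ## truncated MetaImage payload
  path <- tempfile(fileext = ".mha")
  write_volume(m, path)
  bytes <- readBin(path, "raw", file.info(path)$size)
  writeBin(bytes[1:(length(bytes) - 200)], path)
  expect_error(read_volume(path), "truncated")
  bad_ext <- tempfile(fileext = ".xyz")
  writeLines("not a volume", bad_ext)
  expect_error(read_volume(bad_ext), "format")
})

test_that("report CSVs carry a header, quote correctly and round-trip", {
  rows <- data.frame(lesion_id = 1:24, location = rep("RLL, upper", 24),
                     volume_cm3 = seq(0.1234567, 24, length.out = 24))
  path <- tempfile(fileext = ".csv")
  write_report(rows, path)
  expect_length(readLines(path), 25L)  # header + 24 records
  back <- read_report(path)
  expect_equal(back$volume_cm3, rows$volume_cm3, tolerance = 1e-9)
  expect_identical(back$location, rows$location)

  ## degenerate input: no records, header only
  write_report(rows[0, ], path)
  expect_length(readLines(path), 1L)
  ## list-of-records interface and key-set validation
  write_report(list(list(a = 1, b = "x"), list(a = 2, b = "y")), path)
  expect_equal(nrow(read_report(path)), 2L)
  expect_error(write_report(list(list(a = 1), list(b = 2)), path), "key set")
})

test_that("meshes export to OBJ and STL", {
  mesh <- mask_to_mesh(sphere_mask(6, spacing = 1))
  obj <- tempfile(fileext = ".obj")
  write_mesh(mesh, obj)
  lines <- readLines(obj)
  expect_equal(sum(startsWith(lines, "v ")), nrow(mesh$vertices))
  expect_equal(sum(startsWith(lines, "f ")), nrow(mesh$faces))
  stl <- tempfile(fileext = ".stl")
  write_mesh(mesh, stl)
  expect_equal(sum(grepl("^facet", readLines(stl))), nrow(mesh$faces))
})
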