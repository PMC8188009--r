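test_that("TIFF stacks round-trip through write_tif/read_tif", {
  dims <- c(10, 32, 32)
  vol <- voxel_volume(array(sample(0:255, prod(dims), TRUE), dims), spacing = 5)

  for (type in c("uint8", "uint16", "float32")) {
    path <- tempfile(fileext = ".tif")
    write_tif(vol, path, type = type)
    back <- read_tif(path)
    expect_identical(dim(back), as.integer(dims))
    expect_equal(as.vector(back), as.vector(vol))
    expect_equal(attr(back, "spacing"), 5)
    unlink(path)
  }

  # degenerate single-page stack
  one <- voxel_volume(array(runif(16), c(1, 4, 4)))
  path <- tempfile(fileext = ".tif")
  write_tif(one, path)
  expect_identical(dim(read_tif(path)), c(1L, 4L, 4L))
  unlink(path)

  # float with NaN (EF image convention)
  ef <- array(runif(64, -1, 1), c(4, 4, 4))
  ef[1, 1, 1] <- NaN
  path <- tempfile(fileext = ".tif")
  write_tif(voxel_volume(ef), path)
  expect_true(is.nan(read_tif(path)[1, 1, 1]))
  unlink(path)
})

test_that("read_tif rejects bad inputs", {
  expect_error(read_tif(tempfile()), "not found")
  bad <- tempfile(fileext = ".tif")
  writeBin(charToRaw("not a tiff at all"), bad)
  expect_error(read_tif(bad), "not a TIFF")
  mixed <- tempfile(fileext = ".tif")
  write_mixed_page_tiff(mixed)
  expect_error(read_tif(mixed), "differing dimensions")
  unlink(c(bad, mixed))
})

test_that("volume constructors enforce their invariants", {
  expect_error(voxel_volume(matrix(0, 2, 2)), "3D")
  expect_error(voxel_volume(array(0, c(2, 2, 2)), spacing = 0), "positive")
  expect_error(voxel_volume(array(0, c(2, 2, 2)), spacing = c(1, 1, 2)),
               "anisotropic")
  expect_silent(voxel_volume(array(0, c(2, 2, 2)), spacing = c(2, 2, 2)))
  expect_error(binary_volume(array(0.5, c(2, 2, 2))), "0 and 1")
})

test_that("median filter: identity, constants, and impulse removal", {
  vol <- voxel_volume(array(runif(5^3), c(5, 5, 5)))
  expect_equal(as.vector(median_filter3(vol, 0)), as.vector(vol))
  const <- voxel_volume(array(7, c(8, 8, 8)))
  expect_equal(as.vector(median_filter3(const, 3)), rep(7, 512))
  # single bright voxel in a zero field vanishes
  imp <- array(0, c(9, 9, 9)); imp[5, 5, 5] <- 100
  out <- median_filter3(voxel_volume(imp), 3)
  expect_equal(max(out), 0)
  expect_error(median_filter3(vol, -1), "non-negative")
})

test_that("median filter matches the brute-force ball median", {
  set.seed(42)
  vol <- array(runif(6^3), c(6, 6, 6))
  expect_equal(as.vector(median_filter3(voxel_volume(vol), 1)),
               as.vector(brute_median3(vol, 1)))
})

test_that("threshold uses strict inequality", {
  zeros <- voxel_volume(array(0, c(3, 3, 3)))
  expect_equal(sum(threshold_volume(zeros, 75)), 0)
  hund <- voxel_volume(array(100, c(3, 3, 3)))
  expect_equal(sum(threshold_volume(hund, 75)), 27)
  at_level <- voxel_volume(array(75, c(3, 3, 3)))
  expect_equal(sum(threshold_volume(at_level, 75)), 0)  # exactly at level: background
})

test_that("bone volume fraction counts correctly and respects masks", {
  full <- binary_volume(array(TRUE, c(4, 4, 4)))
  empty <- binary_volume(array(FALSE, c(4, 4, 4)))
  expect_equal(bone_volume_fraction(full), 1)
  expect_equal(bone_volume_fraction(empty), 0)
  half <- array(FALSE, c(4, 4, 4)); half[1:2, , ] <- TRUE
  expect_equal(bone_volume_fraction(binary_volume(half)), 0.5)
  mask <- array(FALSE, c(4, 4, 4)); mask[1, , ] <- TRUE
  expect_equal(bone_volume_fraction(binary_volume(half), binary_volume(mask)), 1)
  expect_error(bone_volume_fraction(full, empty), "empty")
  # invariant under axis permutation
  set.seed(1)
  a <- array(runif(4^3) < 0.4, c(4, 4, 4))
  expect_equal(bone_volume_fraction(binary_volume(a)),
               bone_volume_fraction(binary_volume(aperm(a, c(3, 1, 2)))))
})

test_that("distance transform is exact on random grids and analytic shapes", {
  # property: agreement with exhaustive search on random small grids
  set.seed(7)
  for (trial in 1:6) {
    d <- sample(4:10, 3, replace = TRUE)
    a <- array(runif(prod(d)) < runif(1, 0.3, 0.9), d)
    bin <- binary_volume(a)
    expect_equal(distance_transform(bin), brute_edt(a), tolerance = 1e-12)
  }
  # single foreground voxel: nearest background is adjacent
  one <- array(FALSE, c(5, 5, 5)); one[3, 3, 3] <- TRUE
  expect_equal(distance_transform(binary_volume(one))[3, 3, 3], 1)
  # all background
  expect_equal(max(distance_transform(binary_volume(array(FALSE, c(4, 4, 4))))), 0)
  # solid sphere: maximum distance at the centre approximately the radius
  sp <- make_sphere(8, 21)
  D <- distance_transform(sp)
  expect_equal(max(D), 8, tolerance = 0.15)
  expect_equal(which.max(D), which(array(seq_len(21^3), rep(21, 3)) ==
                                     (11 + 21 * 10 + 441 * 10)))
  # image border is background: a border foreground voxel has distance 1
  slab <- array(TRUE, c(3, 5, 5))
  expect_equal(distance_transform(binary_volume(slab))[1, 3, 3], 1)
})
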