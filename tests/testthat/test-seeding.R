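test_that("distance-ridge seeds are medial on reference shapes", {
  # ridge of a single voxel is that voxel
  one <- array(FALSE, c(7, 7, 7)); one[4, 4, 4] <- TRUE
  s <- distance_ridge_seeds(binary_volume(one))
  expect_identical(s$points, matrix(c(3L, 3L, 3L), 1,
                                    dimnames = list(NULL, c("z", "y", "x"))))
  # solid sphere: all seeds within 2 voxels of the centre
  sp <- make_sphere(10, 33)
  s <- distance_ridge_seeds(sp)
  expect_gt(nrow(s$points), 0)
  expect_true(all(sqrt(rowSums(sweep(s$points, 2, c(16, 16, 16))^2)) <= 2))
  # straight rod: all seeds within 1.5 voxels of the axis
  rod <- make_rod(4, "z", c(64, 33, 33))
  s <- distance_ridge_seeds(rod)
  expect_gt(nrow(s$points), 0)
  expect_true(all(sqrt((s$points[, 2] - 16)^2 + (s$points[, 3] - 16)^2) <= 1.5))
  expect_error(distance_ridge_seeds(binary_volume(array(FALSE, c(4, 4, 4)))),
               "empty")
})

test_that("ridge of a one-voxel-thin plate stays on the plate", {
  thin <- array(FALSE, c(9, 16, 16)); thin[5, , ] <- TRUE
  s <- distance_ridge_seeds(binary_volume(thin))
  expect_gt(nrow(s$points), 0)
  expect_true(all(s$points[, 1] == 4))
})

test_that("skeleton seeds preserve topology and stay medial", {
  # a one-voxel line is its own skeleton
  line <- array(FALSE, c(3, 3, 12)); line[2, 2, ] <- TRUE
  s <- skeleton_seeds(binary_volume(line))
  expect_equal(nrow(s$points), 12)
  expect_true(all(s$points[, 1] == 1 & s$points[, 2] == 1))
  # solid rod thins to a curve near the axis (short endpoint spurs at the
  # open grid-spanning ends are a normal thinning artefact, so the medial
  # check covers the interior)
  rod <- make_rod(4, "z", c(48, 33, 33))
  s <- skeleton_seeds(rod)
  expect_gt(nrow(s$points), 0)
  interior <- s$points[, 1] > 2 & s$points[, 1] < 45
  expect_true(all(sqrt((s$points[interior, 2] - 16)^2 +
                         (s$points[interior, 3] - 16)^2) <= 1.5))
  # two disjoint spheres keep two 26-connected components
  a <- make_sphere(5, 16)
  two <- array(FALSE, c(16, 16, 34))
  two[, , 1:16] <- as.logical(a)
  two[, , 19:34] <- as.logical(a)
  skel <- skeleton_seeds(binary_volume(two), return_volume = TRUE)
  expect_equal(count_components26(array(as.logical(skel), dim(skel))), 2)
  expect_error(skeleton_seeds(binary_volume(array(FALSE, c(3, 3, 3)))), "empty")
})

test_that("seeds always lie on foreground", {
  shapes <- list(make_sphere(8, 24), make_rod(5, "y", c(24, 48, 24)),
                 make_gyroid(16, 0.2, 32))
  for (sh in shapes) {
    for (s in list(distance_ridge_seeds(sh), skeleton_seeds(sh))) {
      expect_true(all(sh[s$points + 1]))
    }
  }
})

test_that("seed decimation keeps every n-th point in scan order and composes", {
  pts <- as.matrix(expand.grid(z = 0:4, y = 0:4, x = 0:3))
  s <- seed_set(pts, "skeleton")
  expect_identical(decimate_seeds(s, 1), s)
  expect_equal(nrow(decimate_seeds(s, 10)$points), 10)
  two_then_five <- decimate_seeds(decimate_seeds(s, 2), 5)
  expect_identical(two_then_five$points, decimate_seeds(s, 10)$points)
  expect_error(decimate_seeds(s, 0), "positive")
})

test_that("merging seed strategies is a de-duplicated union", {
  a <- seed_set(rbind(c(1, 1, 1), c(2, 2, 2)), "distance_ridge")
  b <- seed_set(rbind(c(2, 2, 2), c(3, 3, 3)), "skeleton")
  m <- merge_seed_strategies(a, b)
  expect_equal(m$strategy, "merged")
  expect_equal(nrow(m$points), 3)
  expect_identical(merge_seed_strategies(a, a)$points, a$points)
  empty <- seed_set(matrix(integer(), 0, 3), "skeleton")
  expect_identical(merge_seed_strategies(a, empty)$points, a$points)
  expect_lte(nrow(m$points), nrow(a$points) + nrow(b$points))
})
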