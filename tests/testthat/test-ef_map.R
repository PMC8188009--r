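test_that("assign_ef handles the degenerate and overlapping cases", {
  bin <- make_sphere(5, 16)
  # no ellipsoids: all NaN, zero filling
  r0 <- assign_ef(bin, list())
  expect_true(all(is.nan(r0$ef)))
  expect_equal(r0$filling_percentage, 0)
  # one ellipsoid covering all foreground: uniform EF, 100% filling
  cover <- ellipsoid(c(7.5, 7.5, 7.5), c(6, 6, 12))
  r1 <- assign_ef(bin, list(cover))
  expect_equal(r1$filling_percentage, 100)
  vals <- r1$ef[!is.nan(r1$ef)]
  expect_true(all(vals == ef_of_ellipsoid(cover)))
  # background voxels stay NaN
  expect_true(all(is.nan(r1$ef[!as.logical(bin)])))
  # concentric ellipsoids: overlap voxels take the larger one's EF
  small <- ellipsoid(c(7.5, 7.5, 7.5), c(2, 2, 4))
  big <- ellipsoid(c(7.5, 7.5, 7.5), c(4, 4, 5))
  r2 <- assign_ef(bin, list(small, big))
  centre_val <- r2$ef[8, 8, 8]
  expect_equal(centre_val, ef_of_ellipsoid(big))
})

test_that("spatial-index assignment equals the brute-force scan", {
  set.seed(21)
  for (trial in 1:10) {
    d <- sample(12:20, 3, replace = TRUE)
    a <- array(runif(prod(d)) < 0.7, d)
    bin <- binary_volume(a)
    ells <- lapply(seq_len(sample(3:8, 1)), function(i) random_ellipsoid(d))
    fast <- assign_ef(bin, ells)
    slow <- boneshape:::assign_ef_bruteforce(bin, ells)
    expect_identical(fast$claim, slow$claim)
    expect_identical(fast$ef, slow$ef)
  }
})

test_that("run_ef recovers the canonical shapes", {
  p1 <- fit_params(skeleton_points_per_ellipsoid = 1L)
  set.seed(2)
  sph <- run_ef(make_sphere(10, 33), p1)
  expect_gte(sph$filling_percentage, 75)  # algorithmic ceiling ~85%, see vignette
  expect_lt(abs(summary_stats(sph)$median_ef), 0.2)
  set.seed(2)
  rod <- run_ef(make_rod(6, "z", 64), p1)
  expect_gt(summary_stats(rod)$median_ef, 0.5)
  set.seed(2)
  pl <- run_ef(make_plate(8, "z", 64), p1)
  expect_lt(summary_stats(pl)$median_ef, -0.5)
  expect_error(run_ef(binary_volume(array(FALSE, c(4, 4, 4)))), "empty")
})

test_that("every non-NaN EF voxel lies in [-1, 1]", {
  set.seed(8)
  run <- run_ef(make_gyroid(16, 0.2, 32), fit_params())
  v <- run$ef[!is.nan(run$ef)]
  expect_gt(length(v), 0)
  expect_lte(max(v), 1)
  expect_gte(min(v), -1)
})

test_that("averaging runs: identities, NaN-awareness, and monotone filling", {
  set.seed(31)
  run <- run_ef(make_gyroid(16, 0.2, 32), fit_params())
  # n identical runs: all change records are zero
  res <- average_runs(list(run, run, run))
  expect_lte(max(res$convergence$median_change), 1e-12)
  expect_lte(max(res$convergence$max_change), 1e-12)  # running-mean roundoff only
  expect_equal(res$ef, run$ef)
  # a voxel covered only in run 2 takes run 2's value
  r1 <- run; r2 <- run
  i <- which(!is.nan(run$ef))[1]
  r1$ef[i] <- NaN
  res2 <- average_runs(list(r1, r2))
  expect_equal(res2$ef[i], r2$ef[i])
  # cumulative filling is non-decreasing
  set.seed(32)
  runs <- lapply(1:3, function(k) run_ef(make_gyroid(16, 0.2, 32), fit_params()))
  fills <- vapply(seq_along(runs), function(n)
    average_runs(runs[seq_len(n)])$filling_percentage, 0)
  expect_true(all(diff(fills) >= 0))
  # mismatched dimensions are rejected
  bad <- run; dim(bad$ef) <- NULL; bad$ef <- array(bad$ef, c(16, 32, 64))
  expect_error(average_runs(list(run, bad)), "mismatched")
})

test_that("summary statistics: order stats and binned mode", {
  u <- array(0.3, c(4, 4, 4))
  s <- summary_stats(u)
  expect_equal(s$min_ef, 0.3)
  expect_equal(s$max_ef, 0.3)
  expect_equal(s$median_ef, 0.3)
  expect_lte(abs(s$mode_ef - s$median_ef), 0.025 + 1e-9)  # within half a bin
  expect_equal(summary_stats(array(c(-0.5, 0, 0, 0.5), c(1, 2, 2)))$median_ef, 0)
  # 60% of voxels at 0.9 with bin width 0.05: mode in the right bin
  v <- array(c(rep(0.9, 60), runif(40, -1, 0.5)), c(10, 10, 1))
  m <- summary_stats(v, 0.05)$mode_ef
  expect_gte(m, 0.875); expect_lte(m, 0.925)
  expect_error(summary_stats(array(NaN, c(2, 2, 2))), "covered")
})

test_that("Flinn data: coordinates, isoline identity, and weighting", {
  bin <- make_sphere(6, 16)
  e1 <- ellipsoid(c(7.5, 7.5, 7.5), c(1.5, 2, 6.5))  # pokes outside e2 along x
  e2 <- ellipsoid(c(7.5, 7.5, 7.5), c(4, 4.5, 5))
  far <- ellipsoid(c(0.5, 0.5, 0.5), c(0.1, 0.1, 0.1))  # claims no foreground
  run <- assign_ef(bin, list(e1, e2, far))
  fd <- flinn_data(run)
  expect_true(all(fd$all$x > 0 & fd$all$x <= 1))
  expect_true(all(fd$all$y > 0 & fd$all$y <= 1))
  # y - x equals EF for every fitted ellipsoid
  expect_equal(fd$all$y - fd$all$x, run$table$ef, tolerance = 1e-12)
  # zero-claim ellipsoids are absent from the peak plot
  expect_equal(nrow(fd$peak), 2)
  expect_true(all(fd$peak$weight > 0))
  # an all-sphere run maps to (1, 1)
  sph_run <- assign_ef(bin, list(ellipsoid(c(7.5, 7.5, 7.5), c(4, 4, 4))))
  fd2 <- flinn_data(sph_run)
  expect_equal(unlist(fd2$peak[1, c("x", "y")]), c(x = 1, y = 1))
  # plotting runs headless
  tf <- tempfile(fileext = ".png")
  grDevices::png(tf); plot(fd, which = "peak"); grDevices::dev.off()
  expect_true(file.exists(tf)); unlink(tf)
})

test_that("secondary images are consistent with the EF image", {
  set.seed(41)
  run <- run_ef(make_gyroid(16, 0.2, 32), fit_params())
  sec <- secondary_images(run)
  cov <- !is.nan(run$ef)
  expect_equal(run$ef[cov], sec$ab[cov] - sec$bc[cov], tolerance = 1e-12)
  # volume image constant within one claimed region
  id1 <- run$table$id[which.max(run$table$n_claimed)]
  expect_equal(length(unique(sec$volume[run$claim == id1])), 1)
  # ID image indexes the sorted ellipsoid list
  ids <- sec$id[cov]
  expect_true(all(ids %in% run$table$id))
  expect_true(all(diff(run$table$volume) <= 1e-9))  # sorted by volume desc
})

test_that("median EF is robust to a 90-degree rotation of the volume", {
  gy <- make_gyroid(16, 0.2, 32)
  rot <- binary_volume(aperm(unclass(gy), c(2, 3, 1)))
  set.seed(6)
  m1 <- summary_stats(run_ef(gy, fit_params(skeleton_points_per_ellipsoid = 1L)))$median_ef
  set.seed(6)
  m2 <- summary_stats(run_ef(rot, fit_params(skeleton_points_per_ellipsoid = 1L)))$median_ef
  expect_lte(abs(m1 - m2), 0.05)
})

test_that("averaging the n largest containing ellipsoids reduces to the main rule", {
  bin <- make_sphere(5, 16)
  e1 <- ellipsoid(c(7.5, 7.5, 7.5), c(2, 3, 4))
  e2 <- ellipsoid(c(7.5, 7.5, 7.5), c(4, 4.5, 5))
  top1 <- assign_ef(bin, list(e1, e2), average_largest_n = 1L)
  top2 <- assign_ef(bin, list(e1, e2), average_largest_n = 2L)
  # overlap voxels take the mean of both EF values; n = 1 takes the larger
  expect_equal(top2$ef[8, 8, 8],
               mean(c(ef_of_ellipsoid(e1), ef_of_ellipsoid(e2))))
  expect_equal(top1$ef[8, 8, 8], ef_of_ellipsoid(e2))
  # voxels covered by the big ellipsoid alone agree between the two rules
  pts <- as.matrix(expand.grid(z = 0:15, y = 0:15, x = 0:15))
  in_small <- array(contains(e1, pts), c(16, 16, 16))
  only_big <- !is.nan(top1$ef) & !in_small
  expect_equal(top1$ef[only_big], top2$ef[only_big])
})
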