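test_that("ellipsoid constructor enforces its invariants", {
  expect_error(ellipsoid(c(0, 0, 0), c(3, 2, 1)), "sorted")
  expect_error(ellipsoid(c(0, 0, 0), c(0, 1, 2)), "positive")
  skew <- diag(3); skew[1, 2] <- 1e-6
  expect_error(ellipsoid(c(0, 0, 0), c(1, 2, 3), skew), "orthonormal")
  e <- ellipsoid(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ellipsoid_volume(e), 4 / 3 * pi * 6)
})

test_that("EF formula on the reference shapes", {
  ax <- diag(3)
  expect_equal(ef_of_ellipsoid(ellipsoid(c(0, 0, 0), c(5, 5, 5), ax)), 0)
  expect_equal(ef_of_ellipsoid(ellipsoid(c(0, 0, 0), c(1, 1, 10), ax)), 0.9)
  expect_equal(ef_of_ellipsoid(ellipsoid(c(0, 0, 0), c(1, 10, 10), ax)), -0.9)
  # intermediate shape on the EF = 0 isoline
  expect_equal(ef_of_ellipsoid(ellipsoid(c(0, 0, 0), c(2, 4, 8), ax)), 0)
})

test_that("containment equals the direct quadratic-form evaluation", {
  e <- ellipsoid(c(8, 8, 8), c(2, 3, 7))
  expect_true(contains(e, c(8, 8, 8)))
  expect_false(contains(e, c(8, 8, 8 + 7 + 1e-6)))  # just past the long axis
  set.seed(5)
  for (k in 1:4) {
    e <- random_ellipsoid(c(24, 24, 24))
    pts <- matrix(runif(750, 0, 24), ncol = 3)
    q <- sweep(pts, 2, e$centre) %*% e$axes
    oracle <- (q[, 1] / e$semi_axes[1])^2 + (q[, 2] / e$semi_axes[2])^2 +
      (q[, 3] / e$semi_axes[3])^2 <= 1
    expect_identical(contains(e, pts), oracle)
  }
})

test_that("surface sampling is on-surface, centred, and uniform by octant", {
  e <- ellipsoid(c(10, 10, 10), c(4, 4, 4))
  set.seed(3)
  p <- sample_surface_points(e, 1e4)
  r <- sqrt(rowSums(sweep(p, 2, e$centre)^2))
  expect_true(all(abs(r - 4) < 1e-9))            # surface membership
  expect_lt(sqrt(sum(colMeans(p) - e$centre)^2), 0.05 * 4)  # symmetry
  d <- sweep(p, 2, e$centre)
  oct <- 1 + (d[, 1] > 0) + 2 * (d[, 2] > 0) + 4 * (d[, 3] > 0)
  counts <- tabulate(oct, 8)
  expect_true(all(abs(counts - 1250) <= 4 * sqrt(1e4)))  # binomial bound
  # elongated ellipsoid: points still on the surface
  e2 <- ellipsoid(c(10, 10, 10), c(1, 2, 9))
  p2 <- sample_surface_points(e2, 500)
  q <- sweep(p2, 2, e2$centre) %*% e2$axes
  expect_true(all(abs(rowSums(sweep(q, 2, e2$semi_axes, "/")^2) - 1) < 1e-9))
  expect_error(sample_surface_points(e, 0), "at least 1")
})

test_that("contact detection distinguishes buried, oversized, and slab cases", {
  solid <- binary_volume(array(TRUE, c(32, 32, 32)))
  tiny <- ellipsoid(c(16, 16, 16), c(2, 2, 2))
  set.seed(1)
  expect_equal(detect_contacts(tiny, solid)$hits, 0)
  # sphere larger than the foreground sphere: everything is a contact
  sp <- make_sphere(8, 32)
  big <- ellipsoid(c(15.5, 15.5, 15.5), c(10, 10, 10))
  set.seed(1)
  ct <- detect_contacts(big, sp)
  expect_equal(ct$hits, 100)
  # slab: mean contact vector parallel to the normal within 15 degrees
  # (seeded slightly below mid-plane so the nearer face dominates the caps)
  pl <- make_plate(8, "z", 32)
  e <- ellipsoid(c(13, 16, 16), c(5, 5, 5))
  set.seed(2)
  ct <- detect_contacts(e, pl)
  expect_gt(ct$hits, 0)
  v <- ct$mean_contact_vector
  cosang <- abs(v[1]) / sqrt(sum(v^2))
  expect_gt(cosang, cos(15 * pi / 180))
})

test_that("growth stops at first collision at the right scale", {
  sp <- make_sphere(10, 33)
  seed <- ellipsoid(c(16, 16, 16), rep(1 / 2.3, 3))
  set.seed(4)
  g <- grow_until_contact(seed, sp, fit_params())
  expect_lt(abs(max(g$ellipsoid$semi_axes) - 10), 1 + 1 / 2.3)
  # increment larger than the structure: stops immediately
  set.seed(4)
  big_inc <- fit_params(sampling_increment = 30)
  seed2 <- ellipsoid(c(16, 16, 16), rep(30, 3))
  g2 <- grow_until_contact(seed2, sp, big_inc)
  expect_equal(g2$ellipsoid$semi_axes, rep(30, 3))
  # constrained growth in a slab leaves the thickness axis unchanged
  pl <- make_plate(4, "z", 64)
  e <- ellipsoid(c(31.5, 32, 32), c(1.5, 1.5, 1.5), diag(3))
  set.seed(4)
  g3 <- grow_until_contact(e, pl, fit_params(), constraint = "in_plane")
  expect_equal(g3$ellipsoid$semi_axes[1], 1.5)
  expect_gt(g3$ellipsoid$semi_axes[2], 1.5)
})

test_that("fit_params validates and production preset follows the published note", {
  p <- fit_params()
  expect_equal(p$n_vectors, 100L)
  expect_equal(p$sampling_increment, 1 / 2.3)
  expect_equal(p$skeleton_points_per_ellipsoid, 10L)
  expect_equal(p$contact_sensitivity, 1L)
  expect_equal(p$max_iterations, 50L)
  expect_equal(p$max_drift, sqrt(3))
  expect_equal(p$repetitions, 1L)
  expect_true(p$seed_distance_ridge)
  expect_false(p$seed_topology)
  pp <- production_params()
  expect_equal(pp$skeleton_points_per_ellipsoid, 1L)
  expect_equal(pp$repetitions, 6L)
  expect_error(fit_params(n_vectors = 2), "n_vectors")
})
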