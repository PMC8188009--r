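#' Ellipsoids
#'
#' An `ellipsoid` is the unit of local shape measurement: a centre in the
#' continuous voxel frame, sorted semi-axis lengths `a <= b <= c`, and the
#' three paired orthonormal axis directions (columns of `axes`, components
#' ordered `(z, y, x)`).
#'
#' @param centre numeric length 3, `(z, y, x)`
#' @param semi_axes numeric length 3, sorted `a <= b <= c`, all positive
#' @param axes 3x3 matrix, column j the unit direction of semi-axis j;
#'   must be orthonormal to within 1e-9
#' @return an object of class `ellipsoid`
#' @examples
#' e <- ellipsoid(c(8, 8, 8), c(2, 4, 8), diag(3))
#' ef_of_ellipsoid(e)  # 2/4 - 4/8 = 0: on the EF = 0 isoline
#' @export
ellipsoid <- function(centre, semi_axes, axes = diag(3)) {
  stopifnot(length(centre) == 3, length(semi_axes) == 3)
  if (any(semi_axes <= 0)) stop("semi-axis lengths must be positive")
  if (is.unsorted(semi_axes)) stop("semi-axes must be sorted a <= b <= c")
  axes <- as.matrix(axes)
  if (max(abs(crossprod(axes) - diag(3))) > 1e-9)
    stop("`axes` must be orthonormal (tolerance 1e-9)")
  structure(list(centre = as.numeric(centre), semi_axes = as.numeric(semi_axes),
                 axes = axes),
            class = "ellipsoid")
}

#' @export
print.ellipsoid <- function(x, ...) {
  cat(sprintf("<ellipsoid> centre (%.2f, %.2f, %.2f), semi-axes a=%.2f b=%.2f c=%.2f, EF=%.3f\n",
              x$centre[1], x$centre[2], x$centre[3],
              x$semi_axes[1], x$semi_axes[2], x$semi_axes[3],
              ef_of_ellipsoid(x)))
  invisible(x)
}

#' Ellipsoid volume
#' @param e an [ellipsoid()]
#' @return \eqn{(4/3)\pi abc}
#' @export
ellipsoid_volume <- function(e) 4 / 3 * pi * prod(e$semi_axes)

#' Ellipsoid factor of an ellipsoid
#'
#' The difference of sorted semi-axis ratios, `EF = a/b - b/c`, confined to
#' `[-1, 1]`: -1 is very plate-like (a << b = c), +1 very rod-like
#' (a = b << c), and 0 spheres as well as intermediate shapes with
#' a/b = b/c.
#'
#' @param e an [ellipsoid()]
#' @return EF in `[-1, 1]`
#' @export
ef_of_ellipsoid <- function(e) {
  s <- e$semi_axes
  s[1] / s[2] - s[2] / s[3]
}

#' Point-in-ellipsoid test
#'
#' A point is inside when, expressed in the ellipsoid's axis frame, the
#' quadratic form \eqn{\sum_i (q_i / r_i)^2} is at most 1.
#'
#' @param e an [ellipsoid()]
#' @param points numeric vector of length 3 or an n x 3 matrix of `(z, y, x)`
#'   coordinates
#' @return logical vector
#' @export
contains <- function(e, points) {
  p <- if (is.matrix(points)) points else matrix(points, ncol = 3)
  q <- sweep(p, 2, e$centre) %*% e$axes     # coordinates in the axis frame
  rowSums(sweep(q, 2, e$semi_axes, "/")^2) <= 1
}

#' Uniform sample of ellipsoid surface points
#'
#' Directions drawn uniformly on the unit sphere are mapped to the
#' ellipsoid and rejection-corrected by the surface-area Jacobian of the
#' map, so the returned points are uniform with respect to surface area
#' (the plain mapping is visibly non-uniform on elongated ellipsoids).
#' Uses R's RNG.
#'
#' @param e an [ellipsoid()]
#' @param n number of points
#' @return an n x 3 matrix of surface points
#' @export
sample_surface_points <- function(e, n) {
  if (n < 1) stop("`n` must be at least 1")
  if (any(e$semi_axes <= 0)) stop("degenerate ellipsoid")
  r <- e$semi_axes
  pr <- c(r[2] * r[3], r[1] * r[3], r[1] * r[2])
  gmax <- max(pr)
  out <- matrix(NA_real_, 0, 3)
  while (nrow(out) < n) {
    m <- max(16L, ceiling((n - nrow(out)) * 1.8))
    u <- matrix(rnorm(3 * m), m, 3)
    u <- u / sqrt(rowSums(u^2))
    g <- sqrt((pr[1] * u[, 1])^2 + (pr[2] * u[, 2])^2 + (pr[3] * u[, 3])^2)
    u <- u[runif(m) * gmax <= g, , drop = FALSE]
    out <- rbind(out, u)
  }
  u <- out[seq_len(n), , drop = FALSE]
  sweep(t(e$axes %*% (t(u) * r)), 2, e$centre, "+")
}

#' Fitting parameters
#'
#' Tuning parameters of the stochastic ellipsoid fit, named after the
#' published parameter list. Defaults are the documented quick-look values;
#' for production runs on full datasets set
#' `skeleton_points_per_ellipsoid = 1` and `repetitions = 6`
#' (see [production_params()]).
#'
#' @param n_vectors number of surface sampling directions used to search
#'   for boundary contacts (default 100)
#' @param sampling_increment growth step in voxel units (default 1/2.3)
#' @param skeleton_points_per_ellipsoid seed decimation granularity
#'   (default 10; see [decimate_seeds()])
#' @param contact_sensitivity number of sampled surface points on
#'   background required to register a collision (default 1)
#' @param max_iterations refinement attempts without volume gain before the
#'   fit stops (default 50); total attempts are also capped at 10x this
#' @param max_drift maximum centre displacement from the seed in voxels
#'   (default the unit voxel 3D diagonal, `sqrt(3)`)
#' @param repetitions number of runs to average EF over (default 1)
#' @param seed_distance_ridge,seed_topology which seeding strategies to use
#'   (defaults: ridge yes, skeleton no)
#' @param contract_factor multiplier applied to all semi-axes after each
#'   collision during growth (default 0.95)
#' @param rotation_max upper bound of the random refinement rotation angle
#'   in radians (default 0.1)
#' @param ridge_threshold see [distance_ridge_seeds()]
#' @param average_largest_n per-voxel EF averages the n largest containing
#'   ellipsoids (default 1: just the largest)
#' @param mode_bin_width histogram bin width used for the EF mode statistic
#'   (default 0.05)
#' @return a list of class `fit_params`
#' @export
fit_params <- function(n_vectors = 100L,
                       sampling_increment = 1 / 2.3,
                       skeleton_points_per_ellipsoid = 10L,
                       contact_sensitivity = 1L,
                       max_iterations = 50L,
                       max_drift = sqrt(3),
                       repetitions = 1L,
                       seed_distance_ridge = TRUE,
                       seed_topology = FALSE,
                       contract_factor = 0.95,
                       rotation_max = 0.1,
                       ridge_threshold = 0.5,
                       average_largest_n = 1L,
                       mode_bin_width = 0.05) {
  p <- list(n_vectors = as.integer(n_vectors),
            sampling_increment = sampling_increment,
            skeleton_points_per_ellipsoid = as.integer(skeleton_points_per_ellipsoid),
            contact_sensitivity = as.integer(contact_sensitivity),
            max_iterations = as.integer(max_iterations),
            max_drift = max_drift,
            repetitions = as.integer(repetitions),
            seed_distance_ridge = isTRUE(seed_distance_ridge),
            seed_topology = isTRUE(seed_topology),
            contract_factor = contract_factor,
            rotation_max = rotation_max,
            ridge_threshold = ridge_threshold,
            average_largest_n = as.integer(average_largest_n),
            mode_bin_width = mode_bin_width)
  stopifnot(p$n_vectors >= 4, p$sampling_increment > 0,
            p$contact_sensitivity >= 1, p$max_iterations >= 1,
            p$max_drift >= 0, p$repetitions >= 1,
            p$skeleton_points_per_ellipsoid >= 1,
            p$contract_factor > 0, p$contract_factor < 1,
            p$average_largest_n >= 1)
  class(p) <- "fit_params"
  p
}

#' @rdname fit_params
#' @export
production_params <- function(...) {
  fit_params(skeleton_points_per_ellipsoid = 1L, repetitions = 6L, ...)
}

#' Detect boundary contacts of an ellipsoid
#'
#' Samples `n_vectors` surface points; a point hits the boundary when the
#' voxel containing it (by rounding) is background, with everything outside
#' the grid counting as background. Used by the growth loop: a collision is
#' registered once at least `contact_sensitivity` points hit.
#'
#' @param e an [ellipsoid()]
#' @param bin a [binary_volume()]
#' @param params a [fit_params()]
#' @return a list with `points` (contact points, m x 3), `hits`, and
#'   `mean_contact_vector` (mean of contact point minus centre; NA when no
#'   contacts)
#' @export
detect_contacts <- function(e, bin, params = fit_params()) {
  p <- sample_surface_points(e, params$n_vectors)
  d <- dim(bin)
  iz <- round(p[, 1]); iy <- round(p[, 2]); ix <- round(p[, 3])
  inside <- iz >= 0 & iz < d[1] & iy >= 0 & iy < d[2] & ix >= 0 & ix < d[3]
  bg <- !inside
  if (any(inside)) {
    lin <- iz[inside] + d[1] * (iy[inside] + d[2] * ix[inside]) + 1
    bg[inside] <- !as.logical(bin)[lin]
  }
  pts <- p[bg, , drop = FALSE]
  mcv <- if (nrow(pts)) colMeans(sweep(pts, 2, e$centre)) else rep(NA_real_, 3)
  list(points = pts, hits = nrow(pts), mean_contact_vector = mcv)
}

#' Grow an ellipsoid until it contacts the boundary
#'
#' Enlarges the free semi-axes by `sampling_increment` per step — all three
#' when `constraint = "all"` (spherical growth), or only the two axes in
#' the plane orthogonal to the first semi-axis when
#' `constraint = "in_plane"` — and stops at the first registered collision.
#' The returned ellipsoid is the collided state (one step past the last
#' contact-free one); callers contract it slightly before continuing.
#'
#' @inheritParams detect_contacts
#' @param constraint `"all"` or `"in_plane"`
#' @return a list with the collided `ellipsoid` and the collision's
#'   `mean_contact_vector`
#' @export
grow_until_contact <- function(e, bin, params = fit_params(),
                               constraint = c("all", "in_plane")) {
  constraint <- match.arg(constraint)
  free <- if (constraint == "all") c(TRUE, TRUE, TRUE) else c(FALSE, TRUE, TRUE)
  rmax <- 2 * sum(dim(bin))
  repeat {
    ct <- detect_contacts(e, bin, params)
    if (ct$hits >= params$contact_sensitivity)
      return(list(ellipsoid = e, mean_contact_vector = ct$mean_contact_vector))
    r <- e$semi_axes + free * params$sampling_increment
    e <- unsorted_ellipsoid(e$centre, r, e$axes)
    if (max(r) > rmax) stop("ellipsoid grew beyond the grid without contact")
  }
}

# internal: ellipsoid whose working axes are not sorted (growth keeps axis 1
# as the first-contact axis); invariants except sortedness still checked
unsorted_ellipsoid <- function(centre, semi_axes, axes) {
  ord <- order(semi_axes)
  e <- ellipsoid(centre, semi_axes[ord], axes[, ord, drop = FALSE])
  # restore working order
  e$semi_axes <- as.numeric(semi_axes)
  e$axes <- axes
  e
}

#' Fit a locally maximal ellipsoid from a seed point
#'
#' The full stochastic fit: a small sphere at the seed grows uniformly to
#' first contact; the mean contact vector becomes the first semi-axis and
#' the ellipsoid, slightly contracted, then grows in the orthogonal plane
#' to the next contact; finally a hill-climbing phase of small random
#' rotations and translations coupled with single-increment in-plane growth
#' tries to enlarge the ellipsoid, stopping after `max_iterations`
#' consecutive failures or 10x that many total attempts. The centre never
#' drifts more than `max_drift` from the seed. The result is discarded
#' (`NULL`) when the seed's initial sphere cannot fit even after one
#' shrink, or when more than half of a fresh surface sample falls outside
#' the image bounds.
#'
#' @param seed integer `(z, y, x)` voxel coordinate (0-based) on foreground
#' @inheritParams detect_contacts
#' @return an [ellipsoid()] (with sorted axes) or `NULL` when invalid
#' @export
fit_maximal_ellipsoid <- function(seed, bin, params = fit_params()) {
  seed <- as.numeric(seed)
  d <- dim(bin)
  iz <- round(seed) + 1
  if (any(round(seed) < 0) || any(round(seed) >= d) ||
      !bin[iz[1], iz[2], iz[3]])
    stop("seed must lie on image foreground")
  fits <- .fit_ellipsoids_cpp(matrix(seed, 1, 3), as.logical(bin),
                              as.integer(d), unclass(params))
  fits_to_ellipsoids(fits)[[1]]
}

# internal: convert the C++ fit matrix into a list of ellipsoid objects
# (NULL entries for invalid fits)
fits_to_ellipsoids <- function(fits) {
  lapply(seq_len(nrow(fits)), function(i) {
    if (fits[i, 16] == 0) return(NULL)
    axes <- matrix(fits[i, 7:15], 3, 3)
    # re-orthonormalize against accumulated rotation roundoff
    qr_d <- qr(axes)
    axes_o <- qr.Q(qr_d) %*% diag(sign(diag(qr.R(qr_d))))
    ellipsoid(fits[i, 1:3], fits[i, 4:6], axes_o)
  })
}
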