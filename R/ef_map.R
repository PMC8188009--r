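# Per-voxel EF assignment and run averaging. One "run" = seeding, fitting
# one ellipsoid per seed, and assigning every foreground voxel the EF of the
# largest valid ellipsoid that contains it (NaN when uncovered). EF is
# stochastic, so results are typically averaged over several runs; the
# median and maximum per-voxel change of the running mean between runs n-1
# and n are reported as convergence diagnostics.

#' Assign EF values to voxels from a set of fitted ellipsoids
#'
#' Every foreground voxel receives the EF of the largest-volume ellipsoid
#' containing its centre (ties broken by lower ellipsoid ID), or NaN when
#' no ellipsoid contains it; background is NaN. Uses per-ellipsoid bounding
#' boxes as a spatial index; the result equals the brute-force
#' all-ellipsoids scan. With `average_largest_n > 1` a voxel's EF is
#' instead the mean EF of the n largest ellipsoids containing it.
#'
#' @param bin a [binary_volume()]
#' @param ellipsoids list of [ellipsoid()] objects (invalid/`NULL` entries
#'   are dropped)
#' @param average_largest_n average the EF of this many largest containing
#'   ellipsoids per voxel (default 1)
#' @return an `ef_run`: list with `ef` (3D array with NaN), `claim`
#'   (integer array of claiming ellipsoid IDs, 0 = none), `ellipsoids`
#'   (the valid list sorted by decreasing volume), `table` (one row per
#'   ellipsoid: centre, semi-axes, volume, EF, voxels claimed), and
#'   `filling_percentage`
#' @export
assign_ef <- function(bin, ellipsoids, average_largest_n = 1L) {
  ellipsoids <- Filter(Negate(is.null), ellipsoids)
  d <- dim(bin)
  n_fg <- sum(bin)
  if (!length(ellipsoids)) {
    ef <- array(NaN, d)
    return(structure(list(ef = ef, claim = array(0L, d), ellipsoids = list(),
                          table = ellipsoid_table(list()),
                          filling_percentage = 0, n_foreground = n_fg,
                          spacing = vol_spacing(bin)),
                     class = "ef_run"))
  }
  vols <- vapply(ellipsoids, function(e) prod(e$semi_axes), 0)
  ord <- order(-vols)  # stable: ties keep original (lower ID) order
  ellipsoids <- ellipsoids[ord]
  mat <- t(vapply(ellipsoids, function(e)
    c(e$centre, e$semi_axes, as.vector(e$axes)), numeric(15)))
  efs <- vapply(ellipsoids, ef_of_ellipsoid, 0)
  if (average_largest_n == 1L) {
    claim <- array(.assign_claims_cpp(as.logical(bin), as.integer(d), mat), d)
    ef <- array(NaN, d)
    ef[claim > 0] <- efs[claim[claim > 0]]
  } else {
    acc <- assign_topn(bin, mat, efs, average_largest_n)
    ef <- acc$ef
    claim <- acc$claim
  }
  covered <- sum(claim > 0)
  tab <- ellipsoid_table(ellipsoids)
  tab$ef <- efs
  tab$n_claimed <- tabulate(claim[claim > 0], nbins = nrow(tab))
  structure(list(ef = ef, claim = claim, ellipsoids = ellipsoids, table = tab,
                 filling_percentage = 100 * covered / max(n_fg, 1),
                 n_foreground = n_fg, spacing = vol_spacing(bin)),
            class = "ef_run")
}

ellipsoid_table <- function(ellipsoids) {
  if (!length(ellipsoids))
    return(data.frame(id = integer(), z = numeric(), y = numeric(),
                      x = numeric(), a = numeric(), b = numeric(),
                      c = numeric(), volume = numeric(), ef = numeric(),
                      n_claimed = integer()))
  ctr <- t(vapply(ellipsoids, `[[`, numeric(3), "centre"))
  ax <- t(vapply(ellipsoids, `[[`, numeric(3), "semi_axes"))
  data.frame(id = seq_along(ellipsoids), z = ctr[, 1], y = ctr[, 2],
             x = ctr[, 3], a = ax[, 1], b = ax[, 2], c = ax[, 3],
             volume = 4 / 3 * pi * ax[, 1] * ax[, 2] * ax[, 3],
             ef = NA_real_, n_claimed = 0L)
}

# mean EF of the top-n largest containing ellipsoids, per voxel (R path;
# used when average_largest_n > 1)
assign_topn <- function(bin, mat, efs, n_top) {
  d <- dim(bin)
  cnt <- array(0L, d)
  ssum <- array(0, d)
  claim <- array(0L, d)
  fg <- as.logical(bin)
  for (id in seq_len(nrow(mat))) {
    ctr <- mat[id, 1:3]; r <- mat[id, 4:6]; A <- matrix(mat[id, 7:15], 3, 3)
    h <- sqrt(as.vector(A^2 %*% r^2))  # world-axis extents of the ellipsoid
    lo <- pmax(0, ceiling(ctr - h)); hi <- pmin(d - 1, floor(ctr + h))
    if (any(lo > hi)) next
    zz <- lo[1]:hi[1]; yy <- lo[2]:hi[2]; xx <- lo[3]:hi[3]
    g <- expand.grid(z = zz, y = yy, x = xx)
    q <- (as.matrix(g) - matrix(ctr, nrow(g), 3, byrow = TRUE)) %*% A
    ins <- rowSums(sweep(q, 2, r, "/")^2) <= 1
    lin <- g$z + d[1] * (g$y + d[2] * g$x) + 1
    sel <- lin[ins & fg[lin] & cnt[lin] < n_top]
    if (!length(sel)) next
    cnt[sel] <- cnt[sel] + 1L
    ssum[sel] <- ssum[sel] + efs[id]
    claim[sel][claim[sel] == 0L] <- id
  }
  ef <- array(NaN, d)
  ef[cnt > 0] <- ssum[cnt > 0] / cnt[cnt > 0]
  list(ef = ef, claim = claim)
}

# brute-force oracle: all-pairs containment scan, no spatial index (test use)
assign_ef_bruteforce <- function(bin, ellipsoids) {
  ellipsoids <- Filter(Negate(is.null), ellipsoids)
  d <- dim(bin)
  vols <- vapply(ellipsoids, function(e) prod(e$semi_axes), 0)
  ord <- order(-vols)
  ellipsoids <- ellipsoids[ord]
  claim <- array(0L, d)
  fg_idx <- which(as.logical(bin))
  if (length(ellipsoids) && length(fg_idx)) {
    nz <- d[1]; ny <- d[2]
    pts <- cbind((fg_idx - 1) %% nz, ((fg_idx - 1) %/% nz) %% ny,
                 (fg_idx - 1) %/% (nz * ny))
    for (id in rev(seq_along(ellipsoids))) { # ascending volume: larger overwrite
      ins <- contains(ellipsoids[[id]], pts)
      claim[fg_idx[ins]] <- id
    }
    # ties: equal-volume ellipsoids must resolve to the lower ID
    for (id in seq_along(ellipsoids)[-1]) {
      if (vols[ord[id]] == vols[ord[id - 1]]) {
        ins <- contains(ellipsoids[[id - 1]], pts)
        sel <- fg_idx[ins][claim[fg_idx[ins]] == id]
        claim[sel] <- id - 1L
      }
    }
  }
  ef <- array(NaN, d)
  efs <- vapply(ellipsoids, ef_of_ellipsoid, 0)
  ef[claim > 0] <- efs[claim[claim > 0]]
  list(ef = ef, claim = claim)
}

#' One EF run: seed, fit, assign
#'
#' Computes seed points with the strategies enabled in `params`, decimates
#' them, fits one locally maximal ellipsoid per seed, drops invalid fits,
#' and assigns per-voxel EF. Randomness comes from R's RNG; call
#' `set.seed()` first for reproducible runs.
#'
#' @param bin a [binary_volume()] with non-empty foreground
#' @param params a [fit_params()]
#' @return an `ef_run` (see [assign_ef()]), with the seed set attached as
#'   `$seeds` and the attempted seed count as `$n_seeds`
#' @export
run_ef <- function(bin, params = fit_params()) {
  if (!any(bin)) stop("foreground is empty")
  seeds <- NULL
  if (params$seed_distance_ridge)
    seeds <- distance_ridge_seeds(bin, params$ridge_threshold)
  if (params$seed_topology) {
    sk <- skeleton_seeds(bin)
    seeds <- if (is.null(seeds)) sk else merge_seed_strategies(seeds, sk)
  }
  if (is.null(seeds))
    stop("no seeding strategy enabled")
  seeds <- decimate_seeds(seeds, params$skeleton_points_per_ellipsoid)
  fits <- .fit_ellipsoids_cpp(seeds$points + 0.0, as.logical(bin),
                              as.integer(dim(bin)), unclass(params))
  ells <- fits_to_ellipsoids(fits)
  run <- assign_ef(bin, ells, params$average_largest_n)
  run$seeds <- seeds
  run$n_seeds <- nrow(seeds$points)
  run
}

#' @export
print.ef_run <- function(x, ...) {
  cat(sprintf("<ef_run> %d ellipsoids, filling %.1f%%\n",
              length(x$ellipsoids), x$filling_percentage))
  invisible(x)
}

#' Average EF over several runs
#'
#' Per-voxel EF is the NaN-aware mean over the runs in which the voxel is
#' covered; the cumulative filling percentage counts voxels covered in at
#' least one run (non-decreasing in the number of runs). For every n >= 2
#' the median and maximum of the absolute change of the running mean from
#' n-1 to n runs are recorded, taken over the voxels covered in every run
#' so far — the stable core where a change is measurable at every stage
#' (voxels covered in only a few runs would otherwise dominate the maximum
#' with coverage noise rather than convergence behaviour). The published
#' convergence recommendation is that six runs typically bring the median
#' and maximum change below 0.15 and 0.4 respectively.
#'
#' @param runs list of `ef_run` objects on the same volume
#' @return an `ef_result`: list with `ef` (per-voxel mean), `n_runs`,
#'   `filling_percentage` (cumulative), `convergence` (data frame with
#'   columns `run`, `median_change`, `max_change`, `filling_percentage`),
#'   `n_ellipsoids` (total valid across runs), and `spacing`
#' @export
average_runs <- function(runs) {
  if (!length(runs)) stop("need at least one run")
  d <- dim(runs[[1]]$ef)
  for (r in runs) if (!identical(dim(r$ef), d))
    stop("runs have mismatched dimensions")
  total_fg <- runs[[1]]$n_foreground
  ssum <- array(0, d); cnt <- array(0L, d); ever <- array(FALSE, d)
  prev_mean <- NULL
  conv <- data.frame(run = integer(), median_change = numeric(),
                     max_change = numeric(), filling_percentage = numeric())
  for (n in seq_along(runs)) {
    x <- runs[[n]]$ef
    cov <- !is.nan(x)
    ssum[cov] <- ssum[cov] + x[cov]
    cnt[cov] <- cnt[cov] + 1L
    ever <- ever | cov
    cur_mean <- array(NaN, d)
    cur_mean[cnt > 0] <- ssum[cnt > 0] / cnt[cnt > 0]
    fill_n <- 100 * sum(ever) / max(total_fg, 1)
    if (n >= 2) {
      core <- cnt == n  # covered in every run so far
      delta <- abs(cur_mean[core] - prev_mean[core])
      conv <- rbind(conv, data.frame(run = n,
                                     median_change = stats::median(delta),
                                     max_change = if (length(delta)) max(delta) else NA_real_,
                                     filling_percentage = fill_n))
    }
    prev_mean <- cur_mean
  }
  structure(list(ef = prev_mean, n_runs = length(runs),
                 filling_percentage = 100 * sum(ever) / max(total_fg, 1),
                 convergence = conv,
                 n_ellipsoids = sum(vapply(runs, function(r)
                   length(r$ellipsoids), 0L)),
                 spacing = runs[[1]]$spacing),
            class = "ef_result")
}

#' @export
print.ef_result <- function(x, ...) {
  cat(sprintf("<ef_result> %d run(s), filling %.1f%%, %d ellipsoids\n",
              x$n_runs, x$filling_percentage, x$n_ellipsoids))
  if (nrow(x$convergence))
    cat(sprintf("  final median/max EF change: %.3f / %.3f\n",
                x$convergence$median_change[nrow(x$convergence)],
                x$convergence$max_change[nrow(x$convergence)]))
  invisible(x)
}

#' Descriptive statistics of an EF distribution
#'
#' Minimum, maximum, median and mode over covered (non-NaN) voxels. The
#' mode is the centre of the most populated histogram bin of the stated
#' width over `[-1, 1]` (lowest bin wins ties).
#'
#' @param x an `ef_result`, `ef_run`, or 3D EF array
#' @param mode_bin_width histogram bin width for the mode (default 0.05)
#' @return named list: `min_ef`, `max_ef`, `median_ef`, `mode_ef`,
#'   `n_covered`
#' @export
summary_stats <- function(x, mode_bin_width = 0.05) {
  grid <- if (is.list(x)) x$ef else x
  v <- grid[!is.nan(grid) & !is.na(grid)]
  if (!length(v)) stop("no covered voxels")
  nbins <- ceiling(2 / mode_bin_width)
  bin_idx <- pmin(pmax(floor((v + 1) / mode_bin_width) + 1, 1L), nbins)
  counts <- tabulate(bin_idx, nbins = nbins)
  mode_ef <- -1 + (which.max(counts) - 0.5) * mode_bin_width
  list(min_ef = min(v), max_ef = max(v), median_ef = stats::median(v),
       mode_ef = mode_ef, n_covered = length(v))
}

#' Flinn diagram data
#'
#' Semi-axis ratio coordinates `(x = b/c, y = a/b)` for the fitted
#' ellipsoids. The "peak" data has one point per voxel-claiming (locally
#' maximal) ellipsoid, weighted by the number of voxels it claims; the
#' plain data has all fitted ellipsoids unweighted. EF is constant along
#' the diagonals `y - x = EF` of the plot.
#'
#' @param run an `ef_run`
#' @return list of class `flinn_data` with data frames `peak`
#'   (`x`, `y`, `weight`, `id`) and `all` (`x`, `y`, `id`)
#' @export
flinn_data <- function(run) {
  tab <- run$table
  if (!nrow(tab)) stop("run contains no ellipsoids")
  xs <- tab$b / tab$c
  ys <- tab$a / tab$b
  peak <- data.frame(x = xs, y = ys, weight = tab$n_claimed, id = tab$id)
  peak <- peak[peak$weight > 0, , drop = FALSE]
  structure(list(peak = peak, all = data.frame(x = xs, y = ys, id = tab$id)),
            class = "flinn_data")
}

#' Plot a Flinn (peak) diagram
#'
#' @param x a [flinn_data()] object
#' @param which `"peak"` (weighted, default) or `"all"`
#' @param ... passed to [graphics::plot()]
#' @return invisibly, the plotted data frame
#' @export
plot.flinn_data <- function(x, which = c("peak", "all"), ...) {
  which <- match.arg(which)
  df <- x[[if (which == "peak") "peak" else "all"]]
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "b/c", ylab = "a/b",
                 main = if (which == "peak") "Flinn peak plot" else "Flinn plot",
                 ...)
  for (ef in seq(-0.8, 0.8, by = 0.2))
    graphics::abline(a = ef, b = 1, col = "grey70", lty = 2)
  cex <- if (which == "peak" && nrow(df))
    0.4 + 1.6 * sqrt(df$weight / max(df$weight)) else 0.7
  graphics::points(df$x, df$y, pch = 19,
                   col = grDevices::adjustcolor("black", 0.6), cex = cex)
  invisible(df)
}

#' Secondary images of an EF run
#'
#' For every covered voxel, the claiming (largest containing) ellipsoid's
#' semi-axes, semi-axis ratios, volume and ID, written to aligned grids
#' (NaN where uncovered). Consistent with the EF image:
#' `ef = a/b image - b/c image` wherever covered.
#'
#' @param run an `ef_run`
#' @return named list of 3D arrays: `a`, `b`, `c`, `ab`, `bc`, `volume`,
#'   `id`
#' @export
secondary_images <- function(run) {
  tab <- run$table
  claim <- run$claim
  lut <- function(v) {
    out <- array(NaN, dim(claim))
    out[claim > 0] <- v[claim[claim > 0]]
    out
  }
  list(a = lut(tab$a), b = lut(tab$b), c = lut(tab$c),
       ab = lut(tab$a / tab$b), bc = lut(tab$b / tab$c),
       volume = lut(tab$volume), id = lut(tab$id))
}

#' Full EF pipeline: repeated runs plus averaging
#'
#' @param bin a [binary_volume()]
#' @param params a [fit_params()]; `params$repetitions` runs are executed
#' @param keep_runs keep the individual `ef_run` objects in the result
#' @return an `ef_result` (see [average_runs()]); with `keep_runs = TRUE`
#'   the runs are attached as `$runs`
#' @export
ef_pipeline <- function(bin, params = fit_params(), keep_runs = FALSE) {
  runs <- lapply(seq_len(params$repetitions), function(i) run_ef(bin, params))
  res <- average_runs(runs)
  if (keep_runs) res$runs <- runs
  res$last_run <- runs[[length(runs)]]
  res
}
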