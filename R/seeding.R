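# Seed points for ellipsoid growth. Two strategies: the distance ridge
# (morphological closing minus opening of the distance transform picks out
# the medial locus of local distance maxima; efficient, favours thick
# regions) and a topology-preserving 3D thinning skeleton (slower, but
# reaches thin features). Both can be decimated and merged.

#' Seed sets
#'
#' A `seed_set` holds voxel coordinates (0-based, `(z, y, x)`) where
#' ellipsoid growth starts, plus the strategy that produced them. All
#' points lie on image foreground and rows are unique, in lexicographic
#' `(z, y, x)` order.
#'
#' @param points integer matrix (n x 3) of 0-based `(z, y, x)` coordinates
#' @param strategy one of `"distance_ridge"`, `"skeleton"`, `"merged"`
#' @return a `seed_set`
#' @export
seed_set <- function(points, strategy) {
  points <- matrix(as.integer(points), ncol = 3,
                   dimnames = list(NULL, c("z", "y", "x")))
  points <- points[order(points[, 1], points[, 2], points[, 3]), , drop = FALSE]
  points <- unique(points)
  structure(list(points = points, strategy = strategy), class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("<seed_set> %d points, strategy: %s\n", nrow(x$points), x$strategy))
  invisible(x)
}

which_coords <- function(mask, dims) {
  idx <- which(mask) - 1L
  nz <- dims[1]; ny <- dims[2]
  cbind(z = idx %% nz, y = (idx %/% nz) %% ny, x = idx %/% (nz * ny))
}

#' Distance-ridge seed points
#'
#' Computes the Euclidean distance transform D of the foreground and forms
#' the ridge image `R = close(D) - open(D)` with a flat 3x3x3 structuring
#' element; foreground voxels with `R > ridge_threshold` that are also
#' local (plateau) maxima of D in their 26-neighbourhood — the medial locus
#' where D peaks — become seeds. The default threshold of 0.5 voxels is the
#' smallest scale that suppresses flat-region noise; the local-maximum
#' condition discards spurious ridge responses on the staircase surface of
#' voxelized round structures, which would otherwise seed sub-voxel
#' ellipsoids on the boundary.
#'
#' @param bin a [binary_volume()] with non-empty foreground
#' @param ridge_threshold ridge strength cutoff in voxel units
#' @return a [seed_set()] with strategy `"distance_ridge"`
#' @export
distance_ridge_seeds <- function(bin, ridge_threshold = 0.5) {
  if (!any(bin)) stop("foreground is empty")
  d <- dim(bin)
  D <- .edt_cpp(as.logical(bin), as.integer(d))
  dil <- .gray_morph3_cpp(D, as.integer(d), 1L)
  ero <- .gray_morph3_cpp(D, as.integer(d), 0L)
  closed <- .gray_morph3_cpp(dil, as.integer(d), 0L)
  opened <- .gray_morph3_cpp(ero, as.integer(d), 1L)
  ridge <- closed - opened
  # Medial refinement: keep voxels that are near-maximal in their
  # 26-neighbourhood (no neighbour exceeds D by more than half a voxel, so
  # the band where D varies slowly along a ridge survives) and that are
  # either clear of the boundary layer (D > 1.5) or exact plateau maxima
  # (which keeps 1-voxel-thin structures). Staircase responses on voxelized
  # curved surfaces sit in the boundary layer next to strictly larger D and
  # fail both conditions.
  near_max <- D >= dil - 0.5
  plateau <- D >= dil - 1e-9
  mask <- as.logical(bin) & ridge > ridge_threshold & near_max &
    (D > 1.5 | plateau)
  seed_set(which_coords(array(mask, d), d), "distance_ridge")
}

#' Topology-preserving skeleton seed points
#'
#' Thins the foreground to a skeleton by sequential deletion of simple
#' points (points whose removal provably preserves 26-connectivity of the
#' foreground and 6-connectivity of the background), processing border
#' voxels in order of increasing distance-transform value so the skeleton
#' stays medial; curve endpoints are retained. The skeleton has the same
#' number of connected components as the input.
#'
#' @inheritParams distance_ridge_seeds
#' @param return_volume if `TRUE`, return the skeleton as a
#'   [binary_volume()] instead of a seed set (the "seed image" output)
#' @return a [seed_set()] with strategy `"skeleton"`
#' @export
skeleton_seeds <- function(bin, return_volume = FALSE) {
  if (!any(bin)) stop("foreground is empty")
  d <- dim(bin)
  edt <- .edt_cpp(as.logical(bin), as.integer(d))
  skel <- .skeletonize_cpp(as.logical(bin), as.integer(d), edt)
  if (return_volume) return(binary_volume(array(skel, d), vol_spacing(bin)))
  seed_set(which_coords(array(skel, d), d), "skeleton")
}

#' Decimate a seed set
#'
#' Keeps every n-th point in the reproducible lexicographic `(z, y, x)`
#' scan order. `n` is the "skeleton points per ellipsoid" granularity
#' parameter: 1 keeps all seeds (the recommended production setting), the
#' quick-look default of 10 keeps a tenth.
#'
#' @param seeds a [seed_set()]
#' @param skeleton_points_per_ellipsoid positive integer n
#' @return the decimated [seed_set()]
#' @export
decimate_seeds <- function(seeds, skeleton_points_per_ellipsoid) {
  n <- skeleton_points_per_ellipsoid
  if (length(n) != 1 || n < 1 || n != round(n))
    stop("`skeleton_points_per_ellipsoid` must be a positive integer")
  if (n == 1) return(seeds)
  keep <- seq(1L, nrow(seeds$points), by = as.integer(n))
  seed_set(seeds$points[keep, , drop = FALSE], seeds$strategy)
}

#' Merge two seed strategies
#'
#' De-duplicated union of two seed sets over the same volume; using both
#' the distance ridge and the skeleton lets ellipsoids seed densely in
#' thick regions while still reaching thin features.
#'
#' @param a,b [seed_set()] objects from the same volume
#' @return a [seed_set()] with strategy `"merged"`
#' @export
merge_seed_strategies <- function(a, b) {
  seed_set(rbind(a$points, b$points), "merged")
}
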