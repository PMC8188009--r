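# Synthetic binary phantoms with known local shape, standing in for micro-CT
# scans: reference shapes for SMI (sphere, cylinder, slab), a gyroid as a
# connected hyperbolic-surface texture resembling trabecular bone, and a
# labelled rod/plate lattice as ground truth for EF sign recovery. Inclusion
# tests use voxel centres (no partial volume), matching the binary input
# assumption of the ellipsoid fitting.

coord_grids <- function(dims) {
  list(z = array(rep(seq_len(dims[1]) - 1, times = dims[2] * dims[3]), dims),
       y = array(rep(rep(seq_len(dims[2]) - 1, each = dims[1]), times = dims[3]), dims),
       x = array(rep(seq_len(dims[3]) - 1, each = dims[1] * dims[2]), dims))
}

grid_centre <- function(dims) (dims - 1) / 2

#' Solid sphere phantom
#'
#' Foreground where the voxel centre lies within `radius` of the grid
#' centre. A sphere is the SMI = 4 reference shape and carries EF near 0.
#'
#' @param radius sphere radius in voxels
#' @param dims grid dimensions (nz, ny, nx)
#' @param spacing voxel spacing
#' @return a [binary_volume()]
#' @export
make_sphere <- function(radius, dims, spacing = 1) {
  dims <- check_dims(dims)
  if (radius <= 0) stop("`radius` must be positive")
  if (2 * radius + 4 > min(dims)) stop("sphere does not fit the grid")
  g <- coord_grids(dims)
  ctr <- grid_centre(dims)
  fg <- (g$z - ctr[1])^2 + (g$y - ctr[2])^2 + (g$x - ctr[3])^2 <= radius^2
  binary_volume(fg, spacing)
}

#' Grid-spanning circular rod phantom
#'
#' A circular cylinder of the given radius spanning the full grid along one
#' axis; the grid-spanning ends approximate an infinite cylinder
#' (SMI = 3 reference shape, EF near +1).
#'
#' @param radius rod radius in voxels
#' @param axis `"z"`, `"y"` or `"x"` — the rod's long axis
#' @inheritParams make_sphere
#' @return a [binary_volume()]
#' @export
make_rod <- function(radius, axis = c("z", "y", "x"), dims, spacing = 1) {
  axis <- match.arg(axis)
  dims <- check_dims(dims)
  if (radius <= 0) stop("`radius` must be positive")
  cross <- setdiff(c("z", "y", "x"), axis)
  cd <- dims[match(cross, c("z", "y", "x"))]
  if (2 * radius + 4 > min(cd)) stop("rod does not fit the grid cross-section")
  g <- coord_grids(dims)
  ctr <- grid_centre(dims)
  names(ctr) <- c("z", "y", "x")
  fg <- (g[[cross[1]]] - ctr[cross[1]])^2 + (g[[cross[2]]] - ctr[cross[2]])^2 <= radius^2
  binary_volume(fg, spacing)
}

#' Grid-spanning plate (slab) phantom
#'
#' A slab of given thickness spanning the grid in both transverse axes,
#' centred along the normal: the "infinite plate" reference shape
#' (EF near -1).
#'
#' @param thickness slab thickness in voxels (number of foreground slices)
#' @param normal `"z"`, `"y"` or `"x"` — the slab normal
#' @inheritParams make_sphere
#' @return a [binary_volume()]
#' @export
make_plate <- function(thickness, normal = c("z", "y", "x"), dims, spacing = 1) {
  normal <- match.arg(normal)
  dims <- check_dims(dims)
  if (thickness <= 0) stop("`thickness` must be positive")
  n_along <- dims[match(normal, c("z", "y", "x"))]
  if (thickness != n_along && thickness + 4 > n_along)
    stop("plate does not fit the grid")
  g <- coord_grids(dims)
  ctr <- grid_centre(dims)
  names(ctr) <- c("z", "y", "x")
  fg <- abs(g[[normal]] - ctr[normal]) <= thickness / 2 - 0.5 + 1e-9
  binary_volume(fg, spacing)
}

#' Axis-aligned solid ellipsoid phantom
#'
#' @param semi_axes numeric length 3: semi-axis lengths along (z, y, x)
#' @inheritParams make_sphere
#' @return a [binary_volume()]
#' @export
make_ellipsoid_phantom <- function(semi_axes, dims, spacing = 1) {
  dims <- check_dims(dims)
  if (length(semi_axes) != 3 || any(semi_axes <= 0))
    stop("`semi_axes` must be 3 positive lengths")
  if (any(2 * semi_axes + 4 > dims)) stop("ellipsoid does not fit the grid")
  g <- coord_grids(dims)
  ctr <- grid_centre(dims)
  fg <- ((g$z - ctr[1]) / semi_axes[1])^2 + ((g$y - ctr[2]) / semi_axes[2])^2 +
    ((g$x - ctr[3]) / semi_axes[3])^2 <= 1
  binary_volume(fg, spacing)
}

#' Gyroid lattice phantom
#'
#' Foreground where
#' \eqn{\sin x' \cos y' + \sin y' \cos z' + \sin z' \cos x' > level}
#' with coordinates scaled by \eqn{2\pi/period}. The gyroid is a connected
#' structure bounded by a hyperbolic (saddle-shaped) surface — the surface
#' type that dominates trabecular bone and that makes SMI's dilation
#' argument break down — so it serves as the package's trabecular-like test
#' texture. The volume fraction decreases monotonically with `level`
#' (0.5 at level 0).
#'
#' @param period lattice period in voxels (>= 8)
#' @param level iso-level of the implicit function, in `[-3, 3]`
#' @inheritParams make_sphere
#' @return a [binary_volume()]
#' @export
make_gyroid <- function(period, level, dims, spacing = 1) {
  dims <- check_dims(dims)
  if (period < 8) stop("`period` must be at least 8 voxels")
  g <- coord_grids(dims)
  s <- 2 * pi / period
  f <- sin(g$x * s) * cos(g$y * s) + sin(g$y * s) * cos(g$z * s) +
    sin(g$z * s) * cos(g$x * s)
  binary_volume(f > level, spacing)
}

#' Disjoint rod/plate lattice with ground-truth labels
#'
#' A union of grid-spanning axis-aligned rods and plates placed in disjoint
#' z-slots (so every foreground voxel has an unambiguous rod or plate
#' label), used as ground truth for EF sign recovery. Plates are normal to
#' z; rods run along x or y. Placement within slots is randomized from
#' `seed`; the generator is deterministic given `(spec, seed)`.
#'
#' @param dims grid dimensions (nz, ny, nx)
#' @param n_rods,n_plates member counts
#' @param rod_radius,plate_thickness member sizes in voxels
#' @param seed integer RNG seed for the placement (restores the caller's
#'   RNG state on exit)
#' @param spacing voxel spacing
#' @return a list with `volume` (a [binary_volume()]) and `labels` (an
#'   integer array: 0 background, 1 rod, 2 plate, 3 junction — junctions
#'   cannot occur in this disjoint construction but the coding is reserved)
#' @export
make_rod_plate_lattice <- function(dims, n_rods = 3, n_plates = 2,
                                   rod_radius = 3, plate_thickness = 4,
                                   seed = 1, spacing = 1) {
  dims <- check_dims(dims)
  n_members <- n_rods + n_plates
  if (n_members < 1) stop("need at least one rod or plate")
  slot_h <- floor(dims[1] / n_members)
  if (slot_h < max(2 * rod_radius + 3, plate_thickness + 3))
    stop("lattice members do not fit the grid: too many members for nz")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  kinds <- rep(c(1L, 2L), c(n_rods, n_plates))
  if (length(kinds) > 1) kinds <- sample(kinds)
  g <- coord_grids(dims)
  labels <- array(0L, dims)
  for (i in seq_len(n_members)) {
    z0 <- (i - 1) * slot_h          # slot covers z in [z0, z0 + slot_h - 1]
    if (kinds[i] == 1L) {           # rod along x or y, centred in the slot
      zc <- z0 + slot_h / 2 - 0.5
      along_x <- runif(1) < 0.5
      if (along_x) {
        yc <- runif(1, rod_radius + 1, dims[2] - rod_radius - 2)
        m <- (g$z - zc)^2 + (g$y - yc)^2 <= rod_radius^2
      } else {
        xc <- runif(1, rod_radius + 1, dims[3] - rod_radius - 2)
        m <- (g$z - zc)^2 + (g$x - xc)^2 <= rod_radius^2
      }
    } else {                        # plate normal to z, full xy extent
      zs <- z0 + sample.int(slot_h - plate_thickness - 1, 1)  # first slice
      m <- g$z >= zs & g$z <= zs + plate_thickness - 1
    }
    labels[m] <- ifelse(labels[m] > 0L & labels[m] != kinds[i], 3L, kinds[i])
  }
  list(volume = binary_volume(labels > 0L, spacing), labels = labels)
}

check_dims <- function(dims) {
  if (length(dims) == 1L) dims <- rep(dims, 3)
  if (length(dims) != 3L || any(dims < 1) || any(dims != round(dims)))
    stop("`dims` must be 3 positive integers (nz, ny, nx)")
  as.integer(dims)
}
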