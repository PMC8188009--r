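# Structure model index from a triangulated bone surface. SMI estimates
# global rod- versus plate-likeness from the relative change of surface
# area under a small parallel offset (dilation): SMI = 6 V S'/S^2, which is
# 4 for a sphere, 3 for an infinite cylinder and 0 for an infinite plate
# (dilating a plane leaves its area unchanged). Saddle-shaped (hyperbolic)
# surface patches shrink under dilation and contribute negatively; the
# per-triangle split of the area change gives the convex part SMI+ and the
# concave part SMI-.

#' Triangulate the bone surface
#'
#' Extracts the iso-surface at level 0.5 of the (optionally block-resampled)
#' binary grid by marching tetrahedra, then applies one pass of Laplacian
#' smoothing with the given relaxation factor. Resampling by block
#' averaging (factor 2 and smoothing 0.5 are the conventional settings)
#' turns the binary grid into a graded field whose interpolated iso-surface
#' is considerably smoother than the raw voxel surface. Triangles lying in
#' a bounding-box plane of the image (the artificial caps closing
#' grid-spanning structures) are flagged so they can be excluded from
#' open-shape area measurements.
#'
#' @param bin a [binary_volume()] with non-empty foreground
#' @param resampling integer block-averaging factor (>= 1; 1 = none)
#' @param smoothing Laplacian relaxation factor in `[0, 1]` (0 = none)
#' @return a `surface_mesh`: list with `vertices` (n x 3, `(z, y, x)` voxel
#'   coordinates), `triangles` (m x 3 vertex indices, outward winding),
#'   `boundary` (logical per triangle: lies on the image bounding box), and
#'   `spacing`
#' @export
make_mesh <- function(bin, resampling = 2L, smoothing = 0.5) {
  if (!any(bin)) stop("foreground is empty")
  if (resampling < 1 || resampling != round(resampling))
    stop("`resampling` must be a positive integer")
  k <- as.integer(resampling)
  d <- dim(bin)
  field <- array(as.numeric(bin), d)
  if (k > 1L) {
    dk <- (d %/% k) * k
    if (any(dk < k)) stop("volume too small for this resampling factor")
    f <- field[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3]), drop = FALSE]
    dr <- dk %/% k
    # block average: collapse each k^3 cell to its mean occupancy
    f <- array(f, c(k, dr[1], k, dr[2], k, dr[3]))
    field <- apply(f, c(2, 4, 6), mean)
  }
  # nudge values sitting exactly on the iso-level off it, so no zero-area
  # triangles are generated
  field[abs(field - 0.5) < 1e-9] <- 0.5 - 1e-6
  mt <- .march_tets_cpp(as.numeric(field), as.integer(dim(field)), 0.5)
  V <- mt$vertices
  Tm <- mt$triangles
  if (!nrow(V)) stop("empty mesh")
  if (k > 1L) V <- V * k + (k - 1) / 2  # back to original voxel coordinates
  # flag cap triangles before smoothing: any vertex on a bounding plane (at
  # -0.5 or n - 0.5 along some axis). Using "any" rather than "all" also
  # removes the band of tilted junction triangles where the surface proper
  # meets its artificial caps, which otherwise leaks end-cap area change
  # into open-shape measurements.
  tol <- 0.3
  on_plane <- matrix(FALSE, nrow(V), 6)
  for (ax in 1:3) {
    on_plane[, 2 * ax - 1] <- abs(V[, ax] + 0.5) < tol
    on_plane[, 2 * ax] <- abs(V[, ax] - (d[ax] - 0.5)) < tol
  }
  on_any <- rowSums(on_plane) > 0
  boundary <- on_any[Tm[, 1]] | on_any[Tm[, 2]] | on_any[Tm[, 3]]
  # bounding-plane vertices are pinned during smoothing so the junction to
  # the caps is not rounded into the retained surface
  if (smoothing > 0)
    V <- .smooth_mesh_cpp(V, Tm, smoothing, 1L, on_any)
  structure(list(vertices = V, triangles = Tm, boundary = boundary,
                 spacing = vol_spacing(bin)),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles (%d on image boundary)\n",
              nrow(x$vertices), nrow(x$triangles), sum(x$boundary)))
  invisible(x)
}

triangle_areas <- function(V, Tm) {
  e1 <- V[Tm[, 2], , drop = FALSE] - V[Tm[, 1], , drop = FALSE]
  e2 <- V[Tm[, 3], , drop = FALSE] - V[Tm[, 1], , drop = FALSE]
  cx <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  list(areas = 0.5 * sqrt(rowSums(cx^2)), normals = cx)  # normals unnormalized
}

#' Mesh surface area and enclosed volume
#'
#' Area sums triangle areas (optionally excluding image-boundary caps);
#' volume is the signed tetrahedron sum over the full closed mesh.
#'
#' @param mesh a [make_mesh()] result
#' @param exclude_boundary drop bounding-box triangles from the area
#' @return area / volume in voxel units (multiply by `spacing^2` /
#'   `spacing^3` for physical units)
#' @export
mesh_area <- function(mesh, exclude_boundary = FALSE) {
  keep <- if (exclude_boundary) !mesh$boundary else rep(TRUE, nrow(mesh$triangles))
  sum(triangle_areas(mesh$vertices, mesh$triangles[keep, , drop = FALSE])$areas)
}

#' @rdname mesh_area
#' @export
mesh_volume <- function(mesh) {
  V <- mesh$vertices; Tm <- mesh$triangles
  v0 <- V[Tm[, 1], , drop = FALSE]
  v1 <- V[Tm[, 2], , drop = FALSE]
  v2 <- V[Tm[, 3], , drop = FALSE]
  cx <- cbind(v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2],
              v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3],
              v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])
  sum(rowSums(v0 * cx)) / 6
}

#' Structure model index of a surface mesh
#'
#' Displaces every vertex by `dr` along its outward normal and measures the
#' area response: `SMI = 6 V S' / S^2` with `S' = (S(dr) - S)/dr`.
#' Reference values: sphere 4, infinite cylinder 3, infinite plate 0;
#' trabecular bone mixes these with saddle-shaped regions whose area
#' shrinks under dilation. The per-triangle area changes split SMI exactly
#' into a convex part `SMI+ >= 0` and a concave part `SMI- <= 0`
#' (`SMI = SMI+ + SMI-`).
#'
#' With `exclude_boundary = TRUE` (default) triangles on the image bounding
#' box are excluded from S and S', and vertex normals are computed from the
#' retained triangles only, so grid-spanning phantoms approximate their
#' infinite counterparts without end-cap artefacts; the enclosed volume V
#' always comes from the full closed mesh.
#'
#' @param mesh a [make_mesh()] result
#' @param dr dilation step in voxel units (default 1/100 voxel: small
#'   enough for a good derivative, large enough to avoid cancellation)
#' @param exclude_boundary exclude bounding-box cap triangles
#' @return an `smi_result`: list with `smi`, `smi_plus`, `smi_minus`,
#'   `surface_area`, `volume`, `area_derivative`, `dr`
#' @export
structure_model_index <- function(mesh, dr = 0.01, exclude_boundary = TRUE) {
  if (dr <= 0) stop("`dr` must be positive")
  V <- mesh$vertices; Tm <- mesh$triangles
  keep <- if (exclude_boundary) !mesh$boundary else rep(TRUE, nrow(Tm))
  Tk <- Tm[keep, , drop = FALSE]
  if (!nrow(Tk)) stop("no retained triangles (everything on the boundary)")
  ta <- triangle_areas(V, Tk)
  # area-weighted vertex normals accumulated from retained faces
  N <- matrix(0, nrow(V), 3)
  for (j in 1:3)
    for (cc in 1:3)
      N[, cc] <- N[, cc] + unname(tapply2(ta$normals[, cc], Tk[, j], nrow(V)))
  len <- sqrt(rowSums(N^2))
  nz <- len > 1e-12
  N[nz, ] <- N[nz, ] / len[nz]
  if (any(!is.finite(N))) stop("non-finite vertex normals")
  Vd <- V + dr * N
  ta2 <- triangle_areas(Vd, Tk)
  dA <- ta2$areas - ta$areas
  S <- sum(ta$areas)
  vol <- mesh_volume(mesh)
  sprime <- sum(dA) / dr
  smi_plus <- 6 * vol * sum(pmax(dA, 0)) / (dr * S^2)
  smi_minus <- 6 * vol * sum(pmin(dA, 0)) / (dr * S^2)
  structure(list(smi = smi_plus + smi_minus, smi_plus = smi_plus,
                 smi_minus = smi_minus, surface_area = S, volume = vol,
                 area_derivative = sprime, dr = dr),
            class = "smi_result")
}

# fast scatter-add: sum `vals` into `n` bins indexed by `idx`
tapply2 <- function(vals, idx, n) {
  out <- numeric(n)
  acc <- rowsum(vals, idx)
  out[as.integer(rownames(acc))] <- acc[, 1]
  out
}

#' @export
print.smi_result <- function(x, ...) {
  cat(sprintf("<smi_result> SMI %.3f (SMI+ %.3f, SMI- %.3f); S %.1f, V %.1f\n",
              x$smi, x$smi_plus, x$smi_minus, x$surface_area, x$volume))
  invisible(x)
}
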