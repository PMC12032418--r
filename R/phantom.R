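#' Nested acoustic topology
#'
#' An ordered set of closed surfaces with containment relations and a medium
#' per region. Region `0` is the unbounded exterior; surface `i` encloses
#' region `i`. `parents[i]` gives the region immediately outside surface
#' `i` (`0` for a top-level surface). Child surfaces must lie strictly
#' inside their parent and sibling interiors must be disjoint.
#'
#' @param surfaces list of `surface_mesh` objects.
#' @param media list of [acoustic_medium()]: `media[[1]]` is the exterior
#'   medium, `media[[i + 1]]` the medium of region `i` (inside surface `i`).
#' @param parents integer vector, parent region per surface (default: a
#'   simple nesting chain `0, 1, 2, ...`).
#' @param check verify containment/disjointness by point sampling.
#' @return Object of class `nested_topology`.
#' @export
nested_topology <- function(surfaces, media, parents = NULL, check = TRUE) {
  ns <- length(surfaces)
  stopifnot(ns >= 1, all(vapply(surfaces, inherits, TRUE, "surface_mesh")))
  stopifnot(length(media) == ns + 1L,
            all(vapply(media, inherits, TRUE, "acoustic_medium")))
  if (is.null(parents)) parents <- seq_len(ns) - 1L
  parents <- as.integer(parents)
  stopifnot(length(parents) == ns, all(parents >= 0L), all(parents < ns + 1L),
            all(parents < seq_len(ns)))   # parents listed before children
  topo <- structure(list(surfaces = surfaces, media = media,
                         parents = parents),
                    class = "nested_topology")
  if (check) {
    for (i in seq_len(ns)) {
      p <- parents[i]
      if (p > 0L) {
        inside <- points_inside(surfaces[[p]], surfaces[[i]]$vertices)
        if (!all(inside))
          stop(sprintf("surface %d ('%s') is not strictly inside its parent %d",
                       i, surfaces[[i]]$label, p))
      }
      for (j in seq_len(i - 1L)) {
        if (parents[j] == parents[i]) {
          if (any(points_inside(surfaces[[j]], surfaces[[i]]$vertices)) ||
              any(points_inside(surfaces[[i]], surfaces[[j]]$vertices)))
            stop(sprintf("sibling surfaces %d and %d overlap", j, i))
        }
      }
    }
  }
  topo
}

#' @export
print.nested_topology <- function(x, ...) {
  cat(sprintf("<nested_topology> %d surfaces, exterior medium '%s'\n",
              length(x$surfaces), x$media[[1]]$name))
  for (i in seq_along(x$surfaces))
    cat(sprintf("  [%d] '%s' (%d tris) in region %d, interior medium '%s'\n",
                i, x$surfaces[[i]]$label, nrow(x$surfaces[[i]]$triangles),
                x$parents[i], x$media[[i + 1]]$name))
  invisible(x)
}

innermost_index <- function(topo, region = NULL) {
  if (!is.null(region)) {
    labels <- vapply(topo$surfaces, `[[`, "", "label")
    idx <- match(region, labels)
    if (is.na(idx)) stop("no surface labelled '", region, "'")
    return(idx)
  }
  # deepest surface in the containment chain (ties: last listed)
  depth <- integer(length(topo$surfaces))
  for (i in seq_along(depth))
    depth[i] <- if (topo$parents[i] == 0L) 1L else depth[topo$parents[i]] + 1L
  which.max(depth + seq_along(depth) * 1e-3)
}

#' Icosphere subdivision level for a wavelength target
#'
#' Number of subdivisions such that the mean edge length of an icosphere of
#' radius `radius` is at most `wavelength / elements_per_wavelength`. The
#' wavelength is taken in the adjacent medium with the smaller sound speed
#' (the shorter wavelength controls the density of both sides of the
#' interface). A geometric-fidelity floor (`min_subdivisions`, default 2)
#' keeps the faceted sphere within ~1.5% of the true volume even when the
#' wavelength rule alone would permit a cruder mesh.
#'
#' @param radius sphere radius, m.
#' @param wavelength acoustic wavelength, m.
#' @param elements_per_wavelength target edge density (e.g. 4--5).
#' @param min_subdivisions geometric floor.
#' @return Integer subdivision level.
#' @export
subdivisions_for_wavelength <- function(radius, wavelength,
                                        elements_per_wavelength,
                                        min_subdivisions = 2L) {
  stopifnot(radius > 0, wavelength > 0, elements_per_wavelength > 0)
  edge0 <- 4 * radius / sqrt(2 * (5 + sqrt(5)))   # icosahedron edge, unit fit
  h_target <- wavelength / elements_per_wavelength
  n <- ceiling(log2(edge0 / h_target))
  max(min_subdivisions, 0L, n)
}

#' Two-sphere abdominal phantom
#'
#' The validation configuration: two concentric spheres at anatomical scale
#' (defaults: outer radius 0.25 m standing in for the abdomen, inner radius
#' 0.15 m for the uterus) in an air exterior. Mesh density follows the
#' elements-per-wavelength rule at the build frequency, using for each
#' interface the adjacent medium with the smaller sound speed (air outside
#' the abdomen; tissue around the uterus).
#'
#' @param outer_radius,inner_radius sphere radii, m
#'   (`0 < inner < outer`).
#' @param elements_per_wavelength target mesh density (default 5).
#' @param f build frequency, Hz.
#' @param media named list with `exterior`, `shell`, `core`
#'   [acoustic_medium()] entries; defaults to air / abdominal tissue /
#'   amniotic fluid from [tissue_library()].
#' @param center common centre.
#' @param min_subdivisions geometric-fidelity floor passed to
#'   [subdivisions_for_wavelength()].
#' @return A `nested_topology` with attribute `radii = c(outer, inner)`.
#' @export
nested_sphere_phantom <- function(outer_radius = 0.25, inner_radius = 0.15,
                                  elements_per_wavelength = 5, f = 1000,
                                  media = NULL, center = c(0, 0, 0),
                                  min_subdivisions = 2L) {
  stopifnot(inner_radius > 0, inner_radius < outer_radius, f > 0)
  if (is.null(media)) {
    lib <- tissue_library()
    media <- list(exterior = lib$air, shell = lib$abdominal_tissue,
                  core = lib$amniotic_fluid)
  }
  stopifnot(all(c("exterior", "shell", "core") %in% names(media)))
  lam_outer <- min(media$exterior$c0, media$shell$c0) / f
  lam_inner <- min(media$shell$c0, media$core$c0) / f
  n_out <- subdivisions_for_wavelength(outer_radius, lam_outer,
                                       elements_per_wavelength,
                                       min_subdivisions)
  n_in <- subdivisions_for_wavelength(inner_radius, lam_inner,
                                      elements_per_wavelength,
                                      min_subdivisions)
  outer <- icosphere(outer_radius, n_out, center, label = "abdomen")
  inner <- icosphere(inner_radius, n_in, center, label = "uterus")
  topo <- nested_topology(list(outer, inner),
                          list(media$exterior, media$shell, media$core),
                          check = FALSE)
  attr(topo, "radii") <- c(outer_radius, inner_radius)
  attr(topo, "center") <- center
  attr(topo, "elements_per_wavelength") <- elements_per_wavelength
  attr(topo, "build_frequency") <- f
  topo
}

#' Elements-per-wavelength audit
#'
#' Checks each interface of a topology at frequency `f`: the achieved
#' elements-per-wavelength is `lambda / mean_edge_length`, with the
#' wavelength from the adjacent medium with the smaller sound speed.
#'
#' @param topo a `nested_topology`.
#' @param f frequency, Hz.
#' @return Data frame with one row per surface: `label`, `mean_edge_m`,
#'   `wavelength_m`, `elements_per_wavelength`.
#' @export
mesh_wavelength_audit <- function(topo, f) {
  stopifnot(inherits(topo, "nested_topology"), f > 0)
  rows <- lapply(seq_along(topo$surfaces), function(i) {
    outer_med <- topo$media[[topo$parents[i] + 1L]]
    inner_med <- topo$media[[i + 1L]]
    lam <- min(outer_med$c0, inner_med$c0) / f
    h <- mean_edge_length(topo$surfaces[[i]])
    data.frame(label = topo$surfaces[[i]]$label, mean_edge_m = h,
               wavelength_m = lam, elements_per_wavelength = lam / h)
  })
  do.call(rbind, rows)
}

#' Point-in-mesh test (winding number by solid angles)
#'
#' @param mesh a watertight `surface_mesh`.
#' @param points n x 3 matrix.
#' @return Logical vector: point strictly inside the surface.
#' @export
points_inside <- function(mesh, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  sa <- solid_angles_cpp(points, mesh$vertices,
                         mesh$triangles - 1L)
  abs(sa$total) > 2 * pi            # winding ~ 4*pi inside, ~0 outside
}

#' Interior Cartesian evaluation grid with near-surface exclusion
#'
#' Builds an axis-aligned Cartesian grid of points strictly inside a
#' watertight surface and discards points too close to the surface: a point
#' is kept only when the largest solid angle subtended at it by any single
#' triangle of the mesh is at most `solid_angle_threshold` (boundary-element
#' field evaluation degrades near a surface, element by element; the default
#' 0.5 steradian matches the near-surface exclusion used for the exposure
#' metrics).
#'
#' @param mesh a watertight `surface_mesh`.
#' @param spacing grid spacing, m.
#' @param solid_angle_threshold steradians (default 0.5).
#' @return Object of class `evaluation_grid`: list with `points` (n x 3),
#'   `spacing`, `excluded_count` (interior points that failed the
#'   solid-angle rule).
#' @export
interior_grid <- function(mesh, spacing, solid_angle_threshold = 0.5) {
  stopifnot(spacing > 0)
  validate_mesh(mesh)
  v <- mesh$vertices
  lo <- apply(v, 2, min); hi <- apply(v, 2, max)
  if (any(lo + spacing / 2 > hi))
    stop("grid spacing too large for this surface; reduce 'spacing' below ",
         format(min(hi - lo) / 2))
  ax <- lapply(1:3, function(d) seq(lo[d] + spacing / 2, hi[d],
                                    by = spacing))
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]],
                               KEEP.OUT.ATTRS = FALSE))
  colnames(pts) <- NULL
  sa <- solid_angles_cpp(pts, mesh$vertices, mesh$triangles - 1L)
  inside <- abs(sa$total) > 2 * pi
  near <- sa$max_triangle > solid_angle_threshold
  keep <- inside & !near
  if (!any(keep))
    stop("no interior grid points survive the solid-angle exclusion; ",
         "use a smaller spacing than ", format(spacing))
  structure(list(points = pts[keep, , drop = FALSE], spacing = spacing,
                 excluded_count = sum(inside & near),
                 solid_angle_threshold = solid_angle_threshold),
            class = "evaluation_grid")
}

#' @export
print.evaluation_grid <- function(x, ...) {
  cat(sprintf("<evaluation_grid> %d points, spacing %.4g m, %d near-surface points excluded (> %.2g sr)\n",
              nrow(x$points), x$spacing, x$excluded_count,
              x$solid_angle_threshold))
  invisible(x)
}
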