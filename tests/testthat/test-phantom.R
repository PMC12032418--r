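test_that("the nested-sphere phantom is contained, labelled and meshed to the wavelength rule", {
  topo <- nested_sphere_phantom(0.25, 0.15, 5, f = 1000)
  expect_s3_class(topo, "nested_topology")
  expect_equal(attr(topo, "radii"), c(0.25, 0.15))
  inner <- topo$surfaces[[2]]; outer <- topo$surfaces[[1]]
  expect_true(all(points_inside(outer, inner$vertices)))
  expect_false(any(points_inside(inner, outer$vertices)))
  # wavelength basis: mean edge <= lambda_min / 4 on each surface (the
  # 4-to-5 elements-per-wavelength sufficiency band)
  aud <- mesh_wavelength_audit(topo, 1000)
  expect_true(all(aud$mean_edge_m <= aud$wavelength_m / 4))
  expect_true(all(aud$elements_per_wavelength >= 4))
  # default media roles
  expect_equal(topo$media[[1]]$name, "Air")
  expect_equal(topo$media[[2]]$name, "Abdominal tissue")
  expect_equal(topo$media[[3]]$name, "Amniotic fluid")
  expect_error(nested_sphere_phantom(0.15, 0.25), "inner_radius")
})

test_that("subdivision selection refines with frequency and respects the geometric floor", {
  subs <- vapply(c(100, 1000, 2000, 4000), function(f) {
    topo <- nested_sphere_phantom(f = f)
    log2(nrow(topo$surfaces[[1]]$triangles) / 20) / 2
  }, 0)
  expect_true(all(diff(subs) >= 0))
  expect_true(all(subs >= 2))          # fidelity floor
  expect_equal(subdivisions_for_wavelength(0.25, 343 / 2000, 5), 3)
  expect_equal(subdivisions_for_wavelength(0.25, 343 / 100, 5,
                                           min_subdivisions = 0L), 0)
})

test_that("interior grids match a brute-force point/triangle filter and are monotone in the threshold", {
  mesh <- icosphere(1, 1)
  grid <- interior_grid(mesh, 0.35, 0.5)
  # brute-force oracle: explicit loop over points and triangles
  lo <- apply(mesh$vertices, 2, min)
  hi <- apply(mesh$vertices, 2, max)
  ax <- lapply(1:3, function(d) seq(lo[d] + 0.175, hi[d], by = 0.35))
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  one <- function(p) {
    tot <- 0; mx <- 0
    for (t in seq_len(nrow(mesh$triangles))) {
      a <- mesh$vertices[mesh$triangles[t, 1], ] - p
      b <- mesh$vertices[mesh$triangles[t, 2], ] - p
      cc <- mesh$vertices[mesh$triangles[t, 3], ] - p
      la <- sqrt(sum(a^2)); lb <- sqrt(sum(b^2)); lc <- sqrt(sum(cc^2))
      num <- sum(a * c(b[2] * cc[3] - b[3] * cc[2],
                       b[3] * cc[1] - b[1] * cc[3],
                       b[1] * cc[2] - b[2] * cc[1]))
      den <- la * lb * lc + sum(a * b) * lc + sum(a * cc) * lb +
        sum(b * cc) * la
      om <- 2 * atan2(num, den)
      tot <- tot + om
      mx <- max(mx, abs(om))
    }
    c(tot, mx)
  }
  sa <- t(apply(pts, 1, one))
  keep <- abs(sa[, 1]) > 2 * pi & sa[, 2] <= 0.5
  expect_equal(nrow(grid$points), sum(keep))
  expect_equal(grid$points, pts[keep, , drop = FALSE],
               ignore_attr = TRUE)
  # threshold monotonicity
  counts <- vapply(c(0.3, 0.5, 1.0), function(th)
    nrow(interior_grid(mesh, 0.2, th)$points), 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("near-surface exclusion keeps the centre and drops points hugging a facet", {
  mesh <- icosphere(1, 3)
  centre <- matrix(0, 1, 3)
  sa <- fetalsound:::solid_angles_cpp(centre, mesh$vertices,
                                      mesh$triangles - 1L)
  expect_lt(sa$max_triangle, 0.5)      # every facet far from the centre
  # a point epsilon away from a facet subtends ~ 2 pi there
  tri <- mesh$triangles[1, ]
  fc <- colMeans(mesh$vertices[tri, ])
  close_pt <- matrix(fc * (1 - 1e-6), 1, 3)
  sa2 <- fetalsound:::solid_angles_cpp(close_pt, mesh$vertices,
                                       mesh$triangles - 1L)
  expect_gt(sa2$max_triangle, 2)
  # grids: an empty result or oversized spacing gives a diagnostic
  expect_error(interior_grid(mesh, 5), "spacing")
})

test_that("sibling surfaces must be disjoint and children contained", {
  lib <- tissue_library()
  outer <- icosphere(0.25, 2, label = "abdomen")
  a <- icosphere(0.05, 1, center = c(0.1, 0, 0), label = "uterus")
  b <- icosphere(0.05, 1, center = c(-0.1, 0, 0), label = "spine")
  topo <- nested_topology(list(outer, a, b),
                          list(lib$air, lib$abdominal_tissue,
                               lib$amniotic_fluid, lib$spine_bone),
                          parents = c(0L, 1L, 1L))
  expect_s3_class(topo, "nested_topology")
  overlap <- icosphere(0.05, 1, center = c(0.08, 0, 0), label = "bad")
  expect_error(nested_topology(list(outer, a, overlap),
                               list(lib$air, lib$abdominal_tissue,
                                    lib$amniotic_fluid, lib$spine_bone),
                               parents = c(0L, 1L, 1L)),
               "overlap")
  outside <- icosphere(0.05, 1, center = c(0.5, 0, 0), label = "out")
  expect_error(nested_topology(list(outer, outside),
                               list(lib$air, lib$abdominal_tissue,
                                    lib$amniotic_fluid),
                               parents = c(0L, 1L)),
               "inside")
})
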