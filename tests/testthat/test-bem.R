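# small meshes throughout: the solver is dense and these checks are about
# correctness, not resolution

test_that("a zero-contrast interface is acoustically transparent", {
  topo <- nested_topology(list(icosphere(0.25, 2, label = "s")),
                          list(lossless_air, lossless_air), check = FALSE)
  f <- 250
  prob <- transmission_problem(topo, f)
  sol <- solve_transmission(assemble(prob, audit = "none"),
                            method = "direct")
  k0 <- Re(wavenumber(lossless_air, f))
  v <- topo$surfaces[[1]]$vertices
  pex <- exp(1i * k0 * v[, 1])
  expect_lt(max(Mod(sol$phi[[1]] - pex)) / max(Mod(pex)), 0.04)
  nrm <- v / sqrt(rowSums(v^2))
  wex <- 1i * k0 * nrm[, 1] * pex / lossless_air$rho
  expect_lt(max(Mod(sol$w[[1]] - wex)) / max(Mod(wex)), 0.06)
  pts <- rbind(c(0.05, 0.02, -0.03), c(0, 0, 0), c(0.1, 0.05, 0.08),
               c(0.4, 0, 0))
  p <- evaluate_field(sol, pts, exclusion = Inf)
  expect_lt(max(Mod(p - exp(1i * k0 * pts[, 1]))), 0.01)
})

test_that("the exterior representation reproduces a radiating point source and is null inside", {
  mesh <- icosphere(0.25, 3, label = "s")
  k <- Re(wavenumber(lossless_air, 400)) + 0i
  x0 <- c(0.05, 0, 0)
  G <- function(x) {
    r <- sqrt(rowSums(sweep(x, 2, x0)^2))
    exp(1i * k * r) / (4 * pi * r)
  }
  v <- mesh$vertices
  phi <- G(v)
  # dG/dn at the vertices (radial normal on the sphere)
  rel <- sweep(v, 2, x0)
  rr <- sqrt(rowSums(rel^2))
  dGdr <- exp(1i * k * rr) * (1i * k * rr - 1) / (4 * pi * rr^2)
  nrm <- v / sqrt(rowSums(v^2))
  psi <- dGdr * rowSums(rel * nrm) / rr
  out_pts <- rbind(c(0.4, 0, 0), c(0, -0.5, 0.1), c(0.3, 0.3, 0.3))
  in_pts <- rbind(c(-0.1, 0.05, 0), c(0, 0.12, -0.08))
  pot_out <- fetalsound:::eval_potentials_cpp(out_pts, v,
                                              mesh$triangles - 1L,
                                              phi, psi, k)
  u_out <- pot_out$dl - pot_out$sl
  expect_lt(max(Mod(u_out - G(out_pts))) / max(Mod(G(out_pts))), 0.01)
  pot_in <- fetalsound:::eval_potentials_cpp(in_pts, v,
                                             mesh$triangles - 1L,
                                             phi, psi, k)
  u_in <- pot_in$dl - pot_in$sl
  expect_lt(max(Mod(u_in)) / max(Mod(G(out_pts))), 0.02)
})

test_that("assembly is deterministic and insensitive to triangle relabelling", {
  mesh <- icosphere(0.2, 1, label = "s")
  k <- 5 + 0.1i
  a1 <- fetalsound:::assemble_block_cpp(mesh$vertices, mesh$triangles - 1L,
                                        mesh$vertices, mesh$triangles - 1L,
                                        k, TRUE, 4L, 5L, 1.0)
  a2 <- fetalsound:::assemble_block_cpp(mesh$vertices, mesh$triangles - 1L,
                                        mesh$vertices, mesh$triangles - 1L,
                                        k, TRUE, 4L, 5L, 1.0)
  expect_identical(a1, a2)
  perm <- rev(seq_len(nrow(mesh$triangles)))
  a3 <- fetalsound:::assemble_block_cpp(mesh$vertices,
                                        mesh$triangles[perm, ] - 1L,
                                        mesh$vertices,
                                        mesh$triangles[perm, ] - 1L,
                                        k, TRUE, 4L, 5L, 1.0)
  expect_equal(a3$S, a1$S, tolerance = 1e-12)
  expect_equal(a3$N, a1$N, tolerance = 1e-12)
})

test_that("GMRES agrees with a dense direct solve", {
  topo <- nested_sphere_phantom(f = 100)   # floor meshes, 648 unknowns
  prob <- transmission_problem(topo, 100)
  sys <- assemble(prob, audit = "none")
  g <- solve_transmission(sys, tol = 1e-8, max_iter = 2000)
  d <- solve_transmission(sys, method = "direct")
  expect_lte(g$residual, 1e-8)
  expect_lt(g$iterations, 2000)
  for (i in 1:2) {
    expect_lt(max(Mod(g$phi[[i]] - d$phi[[i]])) / max(Mod(d$phi[[i]])),
              1e-4)
    expect_lt(max(Mod(g$w[[i]] - d$w[[i]])) / max(Mod(d$w[[i]])), 1e-4)
  }
})

test_that("the nested solver matches the analytical layered-sphere solution at 500 Hz", {
  f <- 500
  topo <- nested_sphere_phantom(f = f)
  grid <- interior_grid(topo$surfaces[[2]], 0.03)
  model <- layered_sphere_from_topology(topo)
  p_a <- pressure_field(solve_modal(model, f), grid$points)
  sol <- solve_transmission(assemble(transmission_problem(topo, f),
                                     audit = "none"))
  expect_lte(sol$residual, 1e-4)
  expect_lt(sol$iterations, 2000)
  p_b <- evaluate_field(sol, grid$points, exclusion = Inf)
  expect_lt(abs(impact_spl(p_b) - impact_spl(p_a)), 0.5)
  expect_lt(max(Mod(p_b - p_a)) / max(Mod(p_a)), 0.075)
})

test_that("pressure error against the oracle decreases under mesh refinement", {
  f <- 500
  pts <- rbind(c(0, 0, 0), c(0.05, 0.02, -0.03), c(0.08, -0.06, 0.04))
  lib <- tissue_library()
  media <- list(exterior = lib$air, shell = lib$abdominal_tissue,
                core = lib$amniotic_fluid)
  model <- layered_sphere(c(0.25, 0.15),
                          list(media$exterior, media$shell, media$core))
  p_a <- pressure_field(solve_modal(model, f), pts)
  subs <- list(c(1L, 1L), c(2L, 2L), c(3L, 2L))
  errs <- vapply(subs, function(s) {
    topo <- nested_topology(
      list(icosphere(0.25, s[1], label = "abdomen"),
           icosphere(0.15, s[2], label = "uterus")),
      list(media$exterior, media$shell, media$core), check = FALSE)
    attr(topo, "radii") <- c(0.25, 0.15)
    sol <- solve_transmission(assemble(transmission_problem(topo, f),
                                       audit = "none"), method = "direct")
    p_b <- evaluate_field(sol, pts, exclusion = Inf)
    max(Mod(p_b - p_a)) / max(Mod(p_a))
  }, 0)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[2], 0.075)   # the wavelength-rule density meets 7.5%
})

test_that("swapping the incidence direction leaves the centred-sphere response unchanged", {
  f <- 300
  topo <- nested_sphere_phantom(f = f)
  half <- as.matrix(expand.grid(c(0.02, 0.06, 0.1), c(0, 0.05),
                                c(-0.04, 0.03)))
  pts <- rbind(half, half %*% diag(c(-1, 1, 1)))   # mirror-symmetric set
  rms <- vapply(list(c(1, 0, 0), c(-1, 0, 0)), function(d) {
    sol <- solve_transmission(assemble(transmission_problem(topo, f,
                                                            direction = d),
                                       audit = "none"), method = "direct")
    impact_spl(evaluate_field(sol, pts, exclusion = Inf))
  }, 0)
  expect_equal(rms[1], rms[2], tolerance = 1e-6)
})

test_that("repeated runs are bit-identical and near-surface points are flagged", {
  f <- 150
  topo <- nested_sphere_phantom(f = f)
  prob <- transmission_problem(topo, f)
  r1 <- run_frequency(prob, matrix(c(0, 0, 0), 1), audit = "none")
  r2 <- run_frequency(prob, matrix(c(0, 0, 0), 1), audit = "none")
  expect_identical(r1$solution$phi, r2$solution$phi)
  expect_identical(r1$pressures, r2$pressures)
  near_pt <- matrix(c(0.1499, 0, 0), 1)
  expect_warning(p <- evaluate_field(r1$solution, near_pt),
                 "near-surface")
  expect_true(attr(p, "near_surface")[1])
})

test_that("the assembly audit flags meshes coarser than the wavelength rule", {
  topo <- nested_sphere_phantom(f = 100)    # floor meshes
  prob <- transmission_problem(topo, 5000)  # far above the build frequency
  expect_warning(assemble(prob, audit = "warn"), "elements per wavelength")
  expect_error(assemble(prob, audit = "error"), "elements per wavelength")
})
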