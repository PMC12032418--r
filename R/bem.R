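## Dense boundary-element solver for the multi-domain Helmholtz
## transmission problem on nested triangulated surfaces.
##
## Formulation: one blocked PMCHWT system over all interfaces. Unknowns per
## surface are the pressure trace phi and the scaled normal derivative
## w = (1/rho) dp/dn (continuous across interfaces by pressure / normal-
## velocity continuity). For every region m and every ordered pair (i, j)
## of surfaces bounding m, with orientation sign eps = +1 when the surface
## is m's outer boundary and -1 when it is a child, the blocks are
##   Dirichlet row:  eps_i eps_j [ -D_k    rho_m S_k ]
##   Neumann row:    eps_i eps_j [ -N_k/rho_m    D'_k ]
## with the wavenumber k of region m, and the incident plane wave projected
## on the rows of surfaces bounding the exterior. Adding interior and
## exterior Calderon identities cancels the jump terms, so no identity
## blocks appear.

#' Helmholtz transmission problem on a nested topology
#'
#' @param topology a `nested_topology`.
#' @param frequency Hz (> 0).
#' @param direction incident plane-wave direction (unit amplitude).
#' @param amplitude incident amplitude, Pa.
#' @return Object of class `transmission_problem`.
#' @export
transmission_problem <- function(topology, frequency,
                                 direction = c(1, 0, 0), amplitude = 1) {
  stopifnot(inherits(topology, "nested_topology"), frequency > 0)
  d <- as.numeric(direction)
  stopifnot(length(d) == 3, sum(d^2) > 0)
  k <- vapply(topology$media, function(m) wavenumber(m, frequency),
              complex(1))
  if (any(!is.finite(k)) || any(k == 0)) stop("non-finite or zero wavenumber")
  structure(list(topology = topology, frequency = frequency,
                 direction = d / sqrt(sum(d^2)), amplitude = amplitude,
                 k = k),
            class = "transmission_problem")
}

#' @export
print.transmission_problem <- function(x, ...) {
  cat(sprintf("<transmission_problem> f = %g Hz, %d surfaces\n",
              x$frequency, length(x$topology$surfaces)))
  invisible(x)
}

# surfaces bounding region m with orientation signs
region_boundary <- function(topo, m) {
  ns <- length(topo$surfaces)
  js <- integer(0); eps <- numeric(0)
  if (m >= 1L) { js <- m; eps <- 1 }
  kids <- which(topo$parents == m)
  list(surfaces = c(js, kids), eps = c(eps, rep(-1, length(kids))))
}

# Galerkin projection of the incident plane wave (and its scaled normal
# derivative) on the P1 space of a surface
project_incident <- function(mesh, k0, rho0, direction, amplitude,
                             neumann = FALSE) {
  rule <- list(l = rbind(c(0.108103018168070, 0.445948490915965, 0.445948490915965),
                         c(0.445948490915965, 0.108103018168070, 0.445948490915965),
                         c(0.445948490915965, 0.445948490915965, 0.108103018168070),
                         c(0.816847572980459, 0.091576213509771, 0.091576213509771),
                         c(0.091576213509771, 0.816847572980459, 0.091576213509771),
                         c(0.091576213509771, 0.091576213509771, 0.816847572980459)),
               w = c(rep(0.223381589678011, 3), rep(0.109951743655322, 3)))
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 1], , drop = FALSE]; b <- v[tr[, 2], , drop = FALSE]
  c_ <- v[tr[, 3], , drop = FALSE]
  nrm <- cross3(b - a, c_ - a)
  area2 <- sqrt(rowSums(nrm^2))
  nunit <- nrm / area2
  area <- area2 / 2
  out <- complex(nrow(v))
  for (q in seq_along(rule$w)) {
    x <- rule$l[q, 1] * a + rule$l[q, 2] * b + rule$l[q, 3] * c_
    ph <- amplitude * exp(1i * k0 * as.numeric(x %*% direction))
    if (neumann)
      ph <- ph * 1i * k0 * as.numeric(nunit %*% direction) / rho0
    wq <- rule$w[q] * area * ph
    for (loc in 1:3) {
      contrib <- wq * rule$l[q, loc]
      idx <- tr[, loc]
      acc <- tapply(contrib, idx, sum)
      out[as.integer(names(acc))] <- out[as.integer(names(acc))] +
        as.complex(acc)
    }
  }
  out
}

#' Assemble the blocked PMCHWT system
#'
#' Dense Galerkin assembly with continuous piecewise-linear elements.
#' Regular panel pairs use a symmetric triangle rule of degree
#' `quad_degree`; singular and near pairs use an inner Duffy-type
#' subdivision of the trial panel about the closest point to each test
#' quadrature point (the radial Jacobian cancels the kernel singularity).
#' The hypersingular operator is integrated by parts (Maue identity), so
#' only weakly singular kernels are ever evaluated.
#'
#' @param problem a [transmission_problem()].
#' @param quad_degree regular quadrature degree (default 4).
#' @param duffy_points 1D Gauss points per Duffy direction (default 5).
#' @param audit `"warn"`, `"error"` or `"none"`: action when a surface is
#'   coarser than 4 elements per wavelength at this frequency.
#' @return Object of class `transmission_system`: dense complex matrix `A`,
#'   right-hand side `rhs`, DOF `layout`, and the `problem`.
#' @export
assemble <- function(problem, quad_degree = 4, duffy_points = 5,
                     audit = c("warn", "error", "none")) {
  audit <- match.arg(audit)
  stopifnot(inherits(problem, "transmission_problem"))
  topo <- problem$topology
  if (audit != "none") {
    aud <- mesh_wavelength_audit(topo, problem$frequency)
    bad <- aud$elements_per_wavelength < 4
    if (any(bad)) {
      msg <- sprintf("mesh coarser than 4 elements per wavelength at %g Hz: %s",
                     problem$frequency,
                     paste(sprintf("%s (%.2f)", aud$label[bad],
                                   aud$elements_per_wavelength[bad]),
                           collapse = ", "))
      if (audit == "error") stop(msg) else warning(msg)
    }
  }
  ns <- length(topo$surfaces)
  nv <- vapply(topo$surfaces, function(s) nrow(s$vertices), 0L)
  # layout: per surface, phi block then w block
  off_phi <- integer(ns); off_w <- integer(ns)
  pos <- 0L
  for (i in seq_len(ns)) {
    off_phi[i] <- pos; off_w[i] <- pos + nv[i]
    pos <- pos + 2L * nv[i]
  }
  ntot <- pos
  A <- matrix(0 + 0i, ntot, ntot)
  rho <- vapply(topo$media, `[[`, 0, "rho")

  for (m in 0:ns) {
    bd <- region_boundary(topo, m)
    if (!length(bd$surfaces)) next
    km <- problem$k[m + 1L]
    rhom <- rho[m + 1L]
    for (ii in seq_along(bd$surfaces)) {
      for (jj in seq_along(bd$surfaces)) {
        i <- bd$surfaces[ii]; j <- bd$surfaces[jj]
        sgn <- bd$eps[ii] * bd$eps[jj]
        si <- topo$surfaces[[i]]; sj <- topo$surfaces[[j]]
        ops <- assemble_block_cpp(si$vertices, si$triangles - 1L,
                                  sj$vertices, sj$triangles - 1L,
                                  km, i == j,
                                  quad_degree, duffy_points, 1.0)
        rphi <- off_phi[i] + seq_len(nv[i]); rw <- off_w[i] + seq_len(nv[i])
        cphi <- off_phi[j] + seq_len(nv[j]); cw <- off_w[j] + seq_len(nv[j])
        A[rphi, cphi] <- A[rphi, cphi] - sgn * ops$D
        A[rphi, cw] <- A[rphi, cw] + sgn * rhom * ops$S
        A[rw, cphi] <- A[rw, cphi] - sgn / rhom * ops$N
        A[rw, cw] <- A[rw, cw] + sgn * ops$Dp
      }
    }
  }

  rhs <- complex(ntot)
  bd0 <- region_boundary(topo, 0L)
  for (i in bd0$surfaces) {
    mesh <- topo$surfaces[[i]]
    rhs[off_phi[i] + seq_len(nv[i])] <-
      project_incident(mesh, problem$k[1L], rho[1L], problem$direction,
                       problem$amplitude, neumann = FALSE)
    rhs[off_w[i] + seq_len(nv[i])] <-
      project_incident(mesh, problem$k[1L], rho[1L], problem$direction,
                       problem$amplitude, neumann = TRUE)
  }
  structure(list(A = A, rhs = rhs, n = ntot, nv = nv,
                 off_phi = off_phi, off_w = off_w, problem = problem),
            class = "transmission_system")
}

#' @export
print.transmission_system <- function(x, ...) {
  cat(sprintf("<transmission_system> %d unknowns (%d surfaces) at %g Hz\n",
              x$n, length(x$nv), x$problem$frequency))
  invisible(x)
}

# complex GMRES without restart (Arnoldi + Givens rotations)
gmres_complex <- function(A, b, tol = 1e-4, max_iter = 2000) {
  n <- length(b)
  max_iter <- min(max_iter, n)
  bnorm <- sqrt(sum(Mod(b)^2))
  if (bnorm == 0) return(list(x = complex(n), iterations = 0L,
                              residual = 0, history = numeric(0)))
  V <- matrix(0 + 0i, n, max_iter + 1L)
  H <- matrix(0 + 0i, max_iter + 1L, max_iter)
  cs <- complex(max_iter); sn <- complex(max_iter)
  g <- complex(max_iter + 1L)
  V[, 1L] <- b / bnorm
  g[1L] <- bnorm
  history <- numeric(0)
  k <- 0L
  for (j in seq_len(max_iter)) {
    w <- A %*% V[, j]
    for (i in seq_len(j)) {           # modified Gram-Schmidt
      H[i, j] <- sum(Conj(V[, i]) * w)
      w <- w - H[i, j] * V[, i]
    }
    H[j + 1L, j] <- sqrt(sum(Mod(w)^2))
    if (Mod(H[j + 1L, j]) > 0) V[, j + 1L] <- w / H[j + 1L, j]
    for (i in seq_len(j - 1L)) {      # apply previous rotations
      t <- cs[i] * H[i, j] + sn[i] * H[i + 1L, j]
      H[i + 1L, j] <- -Conj(sn[i]) * H[i, j] + Conj(cs[i]) * H[i + 1L, j]
      H[i, j] <- t
    }
    denom <- sqrt(Mod(H[j, j])^2 + Mod(H[j + 1L, j])^2)
    cs[j] <- Conj(H[j, j]) / denom
    sn[j] <- Conj(H[j + 1L, j]) / denom
    H[j, j] <- cs[j] * H[j, j] + sn[j] * H[j + 1L, j]
    H[j + 1L, j] <- 0
    g[j + 1L] <- -Conj(sn[j]) * g[j]
    g[j] <- cs[j] * g[j]
    res <- Mod(g[j + 1L]) / bnorm
    history <- c(history, res)
    k <- j
    if (res <= tol) break
  }
  y <- complex(k)                     # upper-triangular back substitution
  for (i in k:1) {
    s <- g[i]
    if (i < k) s <- s - sum(H[i, (i + 1L):k] * y[(i + 1L):k])
    y[i] <- s / H[i, i]
  }
  x <- V[, seq_len(k), drop = FALSE] %*% y
  list(x = as.complex(x), iterations = k, residual = history[k],
       history = history)
}

#' Solve an assembled transmission system
#'
#' GMRES without restart on the diagonally equilibrated system (symmetric
#' row/column scaling; the pressure and normal-derivative blocks have very
#' different physical scales). `method = "direct"` uses a dense LU solve
#' instead, mainly for cross-checks.
#'
#' @param system a `transmission_system` from [assemble()].
#' @param tol relative residual tolerance (default 1e-4).
#' @param max_iter maximum GMRES iterations (default 2000).
#' @param method `"gmres"` or `"direct"`.
#' @return Object of class `transmission_solution`: trace vectors per
#'   surface (`phi`, `w`), iteration count, achieved residual.
#' @export
solve_transmission <- function(system, tol = 1e-4, max_iter = 2000,
                               method = c("gmres", "direct")) {
  method <- match.arg(method)
  stopifnot(inherits(system, "transmission_system"))
  A <- system$A; b <- system$rhs
  dr <- 1 / sqrt(pmax(rowSums(Mod(A)), 1e-300))
  dc <- 1 / sqrt(pmax(colSums(Mod(A)), 1e-300))
  As <- A * (dr %o% dc)
  bs <- b * dr
  if (method == "direct") {
    x <- solve(As, bs) * dc
    it <- NA_integer_
    res <- sqrt(sum(Mod(A %*% x - b)^2)) / sqrt(sum(Mod(b)^2))
  } else {
    g <- gmres_complex(As, bs, tol = tol, max_iter = max_iter)
    if (g$residual > tol)
      stop(sprintf("GMRES did not reach tol %.1e in %d iterations (residual %.3e); history tail: %s",
                   tol, g$iterations, g$residual,
                   paste(signif(utils::tail(g$history, 5), 3),
                         collapse = " ")))
    x <- g$x * dc
    it <- g$iterations
    res <- g$residual
  }
  topo <- system$problem$topology
  ns <- length(topo$surfaces)
  phi <- vector("list", ns); w <- vector("list", ns)
  for (i in seq_len(ns)) {
    phi[[i]] <- x[system$off_phi[i] + seq_len(system$nv[i])]
    w[[i]] <- x[system$off_w[i] + seq_len(system$nv[i])]
  }
  structure(list(phi = phi, w = w, iterations = it, residual = res,
                 problem = system$problem),
            class = "transmission_solution")
}

#' @export
print.transmission_solution <- function(x, ...) {
  cat(sprintf("<transmission_solution> f = %g Hz, %s, residual %.3e\n",
              x$problem$frequency,
              if (is.na(x$iterations)) "direct solve" else
                sprintf("%d GMRES iterations", x$iterations),
              x$residual))
  invisible(x)
}

# deepest containing surface per point (0 = exterior)
assign_regions <- function(topo, points) {
  ns <- length(topo$surfaces)
  depth <- integer(ns)
  for (i in seq_len(ns))
    depth[i] <- if (topo$parents[i] == 0L) 1L else depth[topo$parents[i]] + 1L
  region <- integer(nrow(points))
  best <- integer(nrow(points))
  for (i in seq_len(ns)) {
    ins <- points_inside(topo$surfaces[[i]], points)
    upd <- ins & depth[i] > best
    region[upd] <- i
    best[upd] <- depth[i]
  }
  region
}

#' Evaluate the transmitted / scattered field
#'
#' Applies the representation formula of the region containing each point,
#' with that region's wavenumber: exterior points receive incident plus
#' scattered field, interior points the transmitted total field. Points
#' violating the near-surface rule (any boundary triangle of their region
#' subtending more than `exclusion` steradians) are flagged via the
#' `"near_surface"` attribute and a warning, since the boundary-element
#' representation overestimates fields close to a surface.
#'
#' @param solution a `transmission_solution`.
#' @param points n x 3 matrix, metres.
#' @param exclusion solid-angle threshold, steradians (default 0.5);
#'   `Inf` disables the check.
#' @return Complex pressures (Pa) with attribute `near_surface`.
#' @export
evaluate_field <- function(solution, points, exclusion = 0.5) {
  stopifnot(inherits(solution, "transmission_solution"))
  points <- matrix(as.numeric(points), ncol = 3)
  prob <- solution$problem
  topo <- prob$topology
  rho <- vapply(topo$media, `[[`, 0, "rho")
  region <- assign_regions(topo, points)
  p <- complex(nrow(points))
  near <- logical(nrow(points))
  for (m in sort(unique(region))) {
    idx <- which(region == m)
    bd <- region_boundary(topo, m)
    km <- prob$k[m + 1L]
    acc <- complex(length(idx))
    for (jj in seq_along(bd$surfaces)) {
      j <- bd$surfaces[jj]
      mesh <- topo$surfaces[[j]]
      if (is.finite(exclusion)) {
        sa <- solid_angles_cpp(points[idx, , drop = FALSE], mesh$vertices,
                               mesh$triangles - 1L)
        near[idx] <- near[idx] | sa$max_triangle > exclusion
      }
      pot <- eval_potentials_cpp(points[idx, , drop = FALSE], mesh$vertices,
                                 mesh$triangles - 1L,
                                 solution$phi[[j]], solution$w[[j]], km)
      acc <- acc - bd$eps[jj] * (pot$dl - rho[m + 1L] * pot$sl)
    }
    if (m == 0L) {
      rel <- points[idx, , drop = FALSE]
      acc <- acc + prob$amplitude *
        exp(1i * prob$k[1L] * as.numeric(rel %*% prob$direction))
    }
    p[idx] <- acc
  }
  if (any(near))
    warning(sprintf("%d evaluation point(s) inside the %.2g-sr near-surface zone; values there are unreliable",
                    sum(near), exclusion))
  attr(p, "near_surface") <- near
  p
}

#' Assemble, solve and evaluate one frequency
#'
#' Orchestrates one sweep step: PMCHWT assembly, GMRES solve and field
#' evaluation on the supplied points. Deterministic given its inputs.
#'
#' @param problem a [transmission_problem()].
#' @param points evaluation points (n x 3) or an `evaluation_grid`.
#' @param tol,max_iter solver controls.
#' @param ... passed to [assemble()].
#' @return List with `solution` (traces and diagnostics) and `pressures`.
#' @export
run_frequency <- function(problem, points, tol = 1e-4, max_iter = 2000,
                          ...) {
  pts <- if (inherits(points, "evaluation_grid")) points$points else
    matrix(as.numeric(points), ncol = 3)
  sol <- solve_transmission(assemble(problem, ...), tol = tol,
                            max_iter = max_iter)
  list(solution = sol, pressures = evaluate_field(sol, pts))
}
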