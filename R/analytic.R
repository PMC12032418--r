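## Analytical plane-wave transmission through concentric layered spheres,
## via spherical-harmonic series: the validation oracle for the BEM solver.

#' Spherical Bessel functions of complex argument
#'
#' `sph_bessel_j()` uses downward recurrence with rescaling (stable for all
#' orders, including far beyond the turning point); `sph_bessel_y()` uses
#' upward recurrence (stable for y). Both are vectorised over `z`.
#'
#' @param nmax maximum order.
#' @param z complex argument(s).
#' @return Complex matrix of dimension `(nmax + 1) x length(z)`; row `n + 1`
#'   holds order `n`.
#' @keywords internal
#' @export
sph_bessel_j <- function(nmax, z) {
  z <- as.complex(z)
  np <- length(z)
  J <- matrix(0 + 0i, nmax + 1L, np)
  small <- Mod(z) < 1e-8
  if (any(small)) J[1L, small] <- 1 + 0i   # j_0 -> 1, higher orders -> 0
  act <- which(!small)
  if (length(act)) {
    za <- z[act]
    M <- max(nmax, ceiling(max(Mod(za)))) + 25L
    fn1 <- rep(0 + 0i, length(za))       # f_{n+1}
    fn <- rep(1e-30 + 0i, length(za))    # f_n at n = M
    Ja <- matrix(0 + 0i, nmax + 1L, length(za))
    for (n in M:0) {
      if (n <= nmax) Ja[n + 1L, ] <- fn
      fm <- (2 * n + 1) / za * fn - fn1
      fn1 <- fn
      fn <- fm
      big <- Mod(fn) > 1e250
      if (any(big)) {
        fn[big] <- fn[big] * 1e-250
        fn1[big] <- fn1[big] * 1e-250
        Ja[, big] <- Ja[, big] * 1e-250
      }
    }
    # normalise with j_0 (or j_1 near a zero of j_0; they never vanish
    # together)
    j0 <- sin(za) / za
    j1 <- sin(za) / za^2 - cos(za) / za
    use1 <- Mod(j0) < 1e-2 & Mod(Ja[2L, ]) > 0
    scale <- ifelse(use1, j1 / Ja[2L, ], j0 / Ja[1L, ])
    Ja <- sweep(Ja, 2, scale, `*`)
    J[, act] <- Ja
  }
  J
}

#' @rdname sph_bessel_j
#' @export
sph_bessel_y <- function(nmax, z) {
  z <- as.complex(z)
  Y <- matrix(NA_complex_, nmax + 1L, length(z))
  y0 <- -cos(z) / z
  Y[1L, ] <- y0
  if (nmax >= 1L) {
    y1 <- -cos(z) / z^2 - sin(z) / z
    Y[2L, ] <- y1
    if (nmax >= 2L) for (n in 1:(nmax - 1L)) {
      Y[n + 2L, ] <- (2 * n + 1) / z * Y[n + 1L, ] - Y[n, ]
    }
  }
  Y
}

# derivative from the recurrence f'_n = f_{n-1} - (n+1)/z f_n, f'_0 = -f_1
sph_bessel_deriv <- function(Fm, z) {
  nmax <- nrow(Fm) - 1L
  stopifnot(nmax >= 1L)
  D <- Fm
  zrow <- matrix(z, nmax + 1L, length(z), byrow = TRUE)
  n <- 1:nmax
  D[n + 1L, ] <- Fm[n, , drop = FALSE] -
    sweep(Fm[n + 1L, , drop = FALSE] / zrow[n + 1L, , drop = FALSE],
          1, n + 1, `*`)
  D[1L, ] <- -Fm[2L, ]
  D
}

# Legendre polynomials P_0..P_nmax at mu, (nmax+1) x length(mu)
legendre_rows <- function(nmax, mu) {
  P <- matrix(0, nmax + 1L, length(mu))
  P[1L, ] <- 1
  if (nmax >= 1L) P[2L, ] <- mu
  if (nmax >= 2L) for (n in 1:(nmax - 1L))
    P[n + 2L, ] <- ((2 * n + 1) * mu * P[n + 1L, ] - n * P[n, ]) / (n + 1)
  P
}

#' Layered-sphere scattering model
#'
#' Concentric spheres with strictly decreasing radii embedded in an
#' unbounded exterior medium, excited by a unit-amplitude plane wave. The
#' model underlies the analytical solution used to validate the
#' boundary-element solver.
#'
#' @param radii strictly decreasing positive radii, m (outermost first).
#' @param media list of [acoustic_medium()]: exterior first, then one per
#'   layer, innermost last (`length(radii) + 1` entries).
#' @param direction plane-wave propagation direction (length-3, need not be
#'   normalised).
#' @param amplitude incident amplitude, Pa.
#' @param center common sphere centre.
#' @return Object of class `layered_sphere_model`.
#' @export
layered_sphere <- function(radii, media, direction = c(1, 0, 0),
                           amplitude = 1, center = c(0, 0, 0)) {
  radii <- as.numeric(radii)
  stopifnot(length(radii) >= 1, all(radii > 0), all(diff(radii) < 0))
  stopifnot(length(media) == length(radii) + 1L,
            all(vapply(media, inherits, TRUE, "acoustic_medium")))
  d <- as.numeric(direction)
  stopifnot(length(d) == 3, sum(d^2) > 0)
  structure(list(radii = radii, media = media, direction = d / sqrt(sum(d^2)),
                 amplitude = amplitude, center = as.numeric(center)),
            class = "layered_sphere_model")
}

#' @export
print.layered_sphere_model <- function(x, ...) {
  cat(sprintf("<layered_sphere_model> %d layers in '%s', radii %s m\n",
              length(x$radii), x$media[[1]]$name,
              paste(signif(x$radii, 4), collapse = " > ")))
  invisible(x)
}

#' Build a layered-sphere model from a concentric-sphere topology
#'
#' Requires a simple nesting chain of (faceted) spheres with a common
#' centre; uses the nominal radii recorded by [nested_sphere_phantom()]
#' when present, otherwise estimates centre and radii from the meshes.
#'
#' @param topo a `nested_topology`.
#' @param direction,amplitude incident plane wave.
#' @return A `layered_sphere_model`.
#' @export
layered_sphere_from_topology <- function(topo, direction = c(1, 0, 0),
                                         amplitude = 1) {
  stopifnot(inherits(topo, "nested_topology"))
  ns <- length(topo$surfaces)
  if (!all(topo$parents == seq_len(ns) - 1L))
    stop("analytic solver requires a simple nesting chain of spheres")
  radii <- attr(topo, "radii")
  center <- attr(topo, "center")
  if (is.null(radii)) {
    center <- volume_centroid(topo$surfaces[[1]])
    radii <- vapply(topo$surfaces, function(s) {
      r <- sqrt(rowSums(sweep(s$vertices, 2, center)^2))
      if (stats::sd(r) > 0.05 * mean(r))
        stop("surface '", s$label, "' is not a sphere about the common centre")
      mean(r)
    }, 0)
  }
  layered_sphere(radii, topo$media, direction = direction,
                 amplitude = amplitude, center = center)
}

#' Solve the modal transmission problem of a layered sphere
#'
#' Expands the incident plane wave in spherical harmonics and solves, order
#' by order, the 2L x 2L interface system enforcing continuity of pressure
#' and of normal velocity `(1/rho) dp/dr` at every interface. The
#' truncation order is `ceiling(max_j Re(k_j) * R_1) + 12` (a
#' Wiscombe-style margin) plus `extra_orders`.
#'
#' @param model a [layered_sphere()].
#' @param f frequency, Hz (> 0).
#' @param extra_orders added to the automatic truncation order.
#' @return Object of class `modal_solution`: per-region coefficient
#'   matrices, wavenumbers, truncation order and worst interface residual.
#' @export
solve_modal <- function(model, f, extra_orders = 0L) {
  stopifnot(inherits(model, "layered_sphere_model"), f > 0)
  R <- model$radii
  L <- length(R)
  k <- vapply(model$media, function(m) wavenumber(m, f), complex(1))
  rho <- vapply(model$media, `[[`, 0, "rho")
  N <- as.integer(ceiling(max(Re(k)) * R[1]) + 12L + extra_orders)

  # radial function tables at every (region, interface) pairing needed
  jt <- vector("list", L + 1L); yt <- jt; jdt <- jt; ydt <- jt
  for (g in seq_len(L + 1L)) {
    # region g-1 touches interfaces: g-1 (outer, if g>1) and g (inner, if g<=L)
    touch <- integer(0)
    if (g > 1L) touch <- c(touch, g - 1L)
    if (g <= L) touch <- c(touch, g)
    z <- k[g] * R[touch]
    Jm <- sph_bessel_j(N, z)
    Ym <- sph_bessel_y(N, z)
    jt[[g]] <- Jm; yt[[g]] <- Ym
    jdt[[g]] <- sph_bessel_deriv(Jm, z)
    ydt[[g]] <- sph_bessel_deriv(Ym, z)
    attr(jt[[g]], "touch") <- touch
  }
  radial <- function(g, iface, deriv = FALSE) {
    touch <- attr(jt[[g]], "touch")
    col <- match(iface, touch)
    if (deriv) list(j = jdt[[g]][, col], y = ydt[[g]][, col])
    else list(j = jt[[g]][, col], y = yt[[g]][, col])
  }

  n_seq <- 0:N
  inc <- model$amplitude * (2 * n_seq + 1) * (1i)^n_seq
  # unknown ordering: b_0, a_1, b_1, ..., a_{L-1}, b_{L-1}, a_L
  nun <- 2L * L
  coef_a <- matrix(0 + 0i, N + 1L, L + 1L)  # a per region (col g = region g-1)
  coef_b <- matrix(0 + 0i, N + 1L, L + 1L)
  coef_a[, 1L] <- inc
  max_resid <- 0
  col_of_a <- function(g) 2L * g            # region g in 1..L-1
  col_of_b <- function(g) if (g == 0L) 1L else 2L * g + 1L

  for (n in n_seq) {
    A <- matrix(0 + 0i, nun, nun)
    rhs <- rep(0 + 0i, nun)
    row <- 0L
    for (iface in seq_len(L)) {
      outer_g <- iface       # region index iface-1 stored at position iface
      inner_g <- iface + 1L
      ro <- radial(outer_g, iface); rdo <- radial(outer_g, iface, TRUE)
      ri <- radial(inner_g, iface); rdi <- radial(inner_g, iface, TRUE)
      ho <- ro$j[n + 1L] + 1i * ro$y[n + 1L]
      hdo <- rdo$j[n + 1L] + 1i * rdo$y[n + 1L]
      hi <- ri$j[n + 1L] + 1i * ri$y[n + 1L]
      hdi <- rdi$j[n + 1L] + 1i * rdi$y[n + 1L]
      vf_o <- k[outer_g] / rho[outer_g]
      vf_i <- k[inner_g] / rho[inner_g]
      # pressure row
      row <- row + 1L
      if (outer_g == 1L) {
        A[row, 1L] <- ho
        rhs[row] <- -inc[n + 1L] * ro$j[n + 1L]
      } else {
        A[row, col_of_a(outer_g - 1L)] <- ro$j[n + 1L]
        A[row, col_of_b(outer_g - 1L)] <- ho
      }
      if (inner_g == L + 1L) {
        A[row, nun] <- -ri$j[n + 1L]
      } else {
        A[row, col_of_a(inner_g - 1L)] <- -ri$j[n + 1L]
        A[row, col_of_b(inner_g - 1L)] <- -hi
      }
      # velocity row
      row <- row + 1L
      if (outer_g == 1L) {
        A[row, 1L] <- vf_o * hdo
        rhs[row] <- -inc[n + 1L] * vf_o * rdo$j[n + 1L]
      } else {
        A[row, col_of_a(outer_g - 1L)] <- vf_o * rdo$j[n + 1L]
        A[row, col_of_b(outer_g - 1L)] <- vf_o * hdo
      }
      if (inner_g == L + 1L) {
        A[row, nun] <- -vf_i * rdi$j[n + 1L]
      } else {
        A[row, col_of_a(inner_g - 1L)] <- -vf_i * rdi$j[n + 1L]
        A[row, col_of_b(inner_g - 1L)] <- -vf_i * hdi
      }
    }
    # column equilibration keeps the solve well-scaled when y_n is huge
    cs <- apply(abs(A), 2, max)
    cs[cs == 0] <- 1
    As <- sweep(A, 2, cs, `/`)
    sol <- tryCatch(solve(As, rhs) / cs, error = function(e)
      stop(sprintf("singular modal system at order %d, f = %g Hz", n, f)))
    resid <- max(abs(A %*% (sol) - rhs)) /
      max(abs(rhs), max(abs(A)) * max(abs(sol)), 1e-300)
    max_resid <- max(max_resid, resid)
    coef_b[n + 1L, 1L] <- sol[1L]
    if (L >= 2L) for (g in 1:(L - 1L)) {
      coef_a[n + 1L, g + 1L] <- sol[col_of_a(g)]
      coef_b[n + 1L, g + 1L] <- sol[col_of_b(g)]
    }
    coef_a[n + 1L, L + 1L] <- sol[nun]
  }
  structure(list(model = model, f = f, k = k, order = N,
                 a = coef_a, b = coef_b, max_residual = max_resid),
            class = "modal_solution")
}

#' @export
print.modal_solution <- function(x, ...) {
  cat(sprintf("<modal_solution> f = %g Hz, truncation order %d, interface residual %.2e\n",
              x$f, x$order, x$max_residual))
  invisible(x)
}

#' Evaluate the modal pressure field
#'
#' Complex total pressure at arbitrary points. Points are assigned to
#' layers by radius; a point exactly on an interface is evaluated from the
#' inner side. The exterior field is the exact incident plane wave plus the
#' scattered series.
#'
#' @param solution a `modal_solution` from [solve_modal()].
#' @param points n x 3 matrix, metres.
#' @return Complex pressures, Pa (length n).
#' @export
pressure_field <- function(solution, points) {
  stopifnot(inherits(solution, "modal_solution"))
  points <- matrix(as.numeric(points), ncol = 3)
  mod <- solution$model
  N <- solution$order
  L <- length(mod$radii)
  rel <- sweep(points, 2, mod$center)
  r <- sqrt(rowSums(rel^2))
  mu <- ifelse(r > 0, as.numeric(rel %*% mod$direction) / pmax(r, 1e-300), 1)
  # region 0 = exterior; point on interface -> inner side (<=)
  region <- rowSums(outer(r, mod$radii, `<=`))
  p <- complex(length(r))
  for (g in 0:L) {
    idx <- which(region == g)
    if (!length(idx)) next
    kg <- solution$k[g + 1L]
    z <- kg * r[idx]
    P <- legendre_rows(N, mu[idx])
    a <- solution$a[, g + 1L]
    b <- solution$b[, g + 1L]
    if (g == 0L) {
      H <- sph_bessel_j(N, z) + 1i * sph_bessel_y(N, z)
      ps <- colSums(H * P * b)
      pinc <- mod$amplitude * exp(1i * kg * (rel[idx, , drop = FALSE] %*%
                                               mod$direction))
      p[idx] <- as.complex(pinc) + ps
    } else {
      J <- sph_bessel_j(N, z)
      terms <- J * P * a
      if (g < L && any(b != 0)) {
        H <- sph_bessel_j(N, z) + 1i * sph_bessel_y(N, z)
        terms <- terms + H * P * b
      }
      p[idx] <- colSums(terms)
    }
  }
  p
}

#' Analytic frequency sweep of the inner-sphere exposure metrics
#'
#' Convenience wrapper: solves the modal problem at each frequency and
#' returns the spatial-RMS SPL, maximum SPL and centre pressure of the
#' innermost sphere, using a fixed interior evaluation grid.
#'
#' @param model a [layered_sphere()].
#' @param frequencies frequencies, Hz.
#' @param grid n x 3 matrix of evaluation points strictly inside the
#'   innermost sphere, or an `evaluation_grid`.
#' @return Data frame: `frequency_hz`, `spl_rms_db`, `spl_linf_db`,
#'   `centre_pressure_re`, `centre_pressure_im`.
#' @export
sweep_inner_sphere <- function(model, frequencies, grid) {
  pts <- if (inherits(grid, "evaluation_grid")) grid$points else
    matrix(as.numeric(grid), ncol = 3)
  rmax <- max(sqrt(rowSums(sweep(pts, 2, model$center)^2)))
  if (rmax >= min(model$radii))
    stop("evaluation grid extends outside the innermost sphere")
  centre <- matrix(model$center, 1)
  out <- data.frame(frequency_hz = frequencies, spl_rms_db = NA_real_,
                    spl_linf_db = NA_real_, centre_pressure_re = NA_real_,
                    centre_pressure_im = NA_real_)
  for (j in seq_along(frequencies)) {
    sol <- solve_modal(model, frequencies[j])
    p <- pressure_field(sol, rbind(pts, centre))
    n <- nrow(pts)
    out$spl_rms_db[j] <- impact_spl(p[seq_len(n)])
    out$spl_linf_db[j] <- linf_spl(p[seq_len(n)])
    out$centre_pressure_re[j] <- Re(p[n + 1L])
    out$centre_pressure_im[j] <- Im(p[n + 1L])
  }
  out
}
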