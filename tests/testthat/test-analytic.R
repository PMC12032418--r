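# independent spherical Bessel path through base R's fractional-order
# cylindrical functions: j_n(x) = sqrt(pi/2x) J_{n+1/2}(x)
ref_sph_j <- function(n, x) sqrt(pi / (2 * x)) * besselJ(x, n + 0.5)
ref_sph_y <- function(n, x) sqrt(pi / (2 * x)) * besselY(x, n + 0.5)

test_that("spherical Bessel recurrences agree with base R half-integer Bessel functions", {
  for (x in c(0.3, 2.7, 11.4, 91.6)) {
    J <- sph_bessel_j(12, x + 0i)
    Y <- sph_bessel_y(12, x + 0i)
    for (n in c(0, 1, 5, 12)) {
      expect_equal(Re(J[n + 1, 1]), ref_sph_j(n, x), tolerance = 1e-10)
      expect_equal(Re(Y[n + 1, 1]), ref_sph_y(n, x), tolerance = 1e-10)
    }
  }
  # far beyond the turning point the downward recurrence stays finite
  Jx <- sph_bessel_j(120, c(0.01 + 0i, 12 + 1.5i))
  expect_true(all(is.finite(Jx)))
  expect_equal(Re(Jx[3, 1]), 0.01^2 / 15, tolerance = 1e-4)  # j_2 ~ z^2/15
})

test_that("a contrast-free layered sphere is transparent to the incident wave", {
  mod <- layered_sphere(c(0.25, 0.15),
                        list(lossless_air, lossless_air, lossless_air))
  sol <- solve_modal(mod, 1000)
  expect_lt(max(Mod(sol$b[, 1])), 1e-12)
  pts <- rbind(c(0.05, 0.02, -0.03), c(0, 0, 0), c(0.3, 0.1, 0))
  p <- pressure_field(sol, pts)
  k0 <- wavenumber(lossless_air, 1000)
  expect_equal(p, exp(1i * k0 * pts[, 1]), tolerance = 1e-12)
})

test_that("interface conditions are satisfied to solver precision and fields are continuous", {
  lib <- tissue_library()
  mod <- layered_sphere(c(0.25, 0.15),
                        list(lib$air, lib$abdominal_tissue,
                             lib$amniotic_fluid))
  sol <- solve_modal(mod, 1500)
  expect_lt(sol$max_residual, 1e-8)
  eps <- 1e-7
  for (R in c(0.15, 0.25)) {
    p <- pressure_field(sol, rbind(c(R - eps, 0, 0), c(R + eps, 0, 0),
                                   c(0, -(R - eps), 0), c(0, -(R + eps), 0)))
    expect_lt(Mod(p[1] - p[2]) / Mod(p[1]), 1e-4)
    expect_lt(Mod(p[3] - p[4]) / Mod(p[3]), 1e-4)
  }
})

test_that("results are robust to raising the truncation order by 8", {
  lib <- tissue_library()
  mod <- layered_sphere(c(0.25, 0.15),
                        list(lib$air, lib$abdominal_tissue,
                             lib$uterine_tissue))
  pts <- rbind(c(0.05, 0.02, -0.03), c(0.12, -0.04, 0.01), c(0.2, 0, 0.1))
  for (f in c(40, 1000, 12000)) {
    p1 <- pressure_field(solve_modal(mod, f), pts)
    p2 <- pressure_field(solve_modal(mod, f, extra_orders = 8L), pts)
    expect_lt(max(Mod(p1 - p2)) / max(Mod(p1)), 1e-6)
  }
})

test_that("the field is axisymmetric about the incidence axis", {
  lib <- tissue_library()
  mod <- layered_sphere(c(0.25, 0.15),
                        list(lib$air, lib$abdominal_tissue,
                             lib$amniotic_fluid))
  sol <- solve_modal(mod, 3000)
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  ring <- cbind(0.05, 0.08 * cos(th), 0.08 * sin(th))
  p <- pressure_field(sol, ring)
  expect_lt(diff(range(Mod(p))), 1e-12)
  expect_lt(max(Mod(p - p[1])), 1e-12)
})

test_that("the long-wavelength limit transmits the incident amplitude", {
  lib <- tissue_library()
  mod <- layered_sphere(c(0.25, 0.15),
                        list(lib$air, lib$abdominal_tissue,
                             lib$amniotic_fluid))
  sol <- solve_modal(mod, 20)             # ka ~ 0.09
  pts <- rbind(c(0, 0, 0), c(0.05, 0.02, -0.03), c(0.1, 0, 0.05))
  expect_true(all(abs(Mod(pressure_field(sol, pts)) - 1) < 0.06))
})

test_that("the stiff-core limit reproduces an independently coded rigid-sphere series", {
  rigid_core <- acoustic_medium("rigid", 1500, 1e9, 0, 1)
  mod <- layered_sphere(0.25, list(lossless_air, rigid_core))
  f <- 500
  k <- Re(wavenumber(lossless_air, f))
  sol <- solve_modal(mod, f)
  pts <- rbind(c(0.3, 0, 0), c(-0.35, 0.1, 0), c(0, 0.4, 0.1))
  p <- pressure_field(sol, pts)
  # independent rigid-sphere series with base R Bessel functions
  N <- 30
  a <- 0.25
  jn_a <- ref_sph_j(0:(N + 1), k * a)
  yn_a <- ref_sph_y(0:(N + 1), k * a)
  deriv <- function(fn, x) {             # f'_n = f_{n-1} - (n+1)/x f_n
    n <- seq_len(length(fn) - 1)
    c(-fn[2], fn[n] - (n + 1) / x * fn[n + 1])
  }
  djn <- deriv(jn_a, k * a)
  dhn <- djn + 1i * deriv(yn_a, k * a)
  p_ref <- vapply(seq_len(nrow(pts)), function(i) {
    r <- sqrt(sum(pts[i, ]^2))
    mu <- pts[i, 1] / r
    Pn <- numeric(N + 1); Pn[1] <- 1; Pn[2] <- mu
    for (n in 1:(N - 1))
      Pn[n + 2] <- ((2 * n + 1) * mu * Pn[n + 1] - n * Pn[n]) / (n + 1)
    jr <- ref_sph_j(0:N, k * r)
    hr <- jr + 1i * ref_sph_y(0:N, k * r)
    nn <- 0:N
    sum((2 * nn + 1) * (1i)^nn *
          (jr - djn[nn + 1] / dhn[nn + 1] * hr) * Pn)
  }, complex(1))
  expect_lt(max(Mod(p - p_ref)) / max(Mod(p_ref)), 1e-4)
})

test_that("the order-0 transmission coefficient matches its closed form", {
  # single interface, order 0: with z = kR, j0 = sin z / z, h0 = -i e^{iz}/z,
  # the 2x2 interface solve gives a0/inc = (k1/rho1)(i/z1^2)/det
  lib <- list(ext = lossless_air, int = lossless_tissue)
  R <- 0.25; f <- 700
  k1 <- Re(wavenumber(lib$ext, f)); k2 <- Re(wavenumber(lib$int, f))
  z1 <- k1 * R; z2 <- k2 * R
  j0 <- function(z) sin(z) / z
  dj0 <- function(z) cos(z) / z - sin(z) / z^2
  h0 <- function(z) -1i * exp(1i * z) / z
  dh0 <- function(z) 1i * h0(z) - h0(z) / z   # d/dz[-i e^{iz}/z]
  det <- (k1 / lib$ext$rho) * j0(z2) * dh0(z1) -
    (k2 / lib$int$rho) * h0(z1) * dj0(z2)
  T_closed <- (k1 / lib$ext$rho) * (1i / z1^2) / det
  mod <- layered_sphere(R, list(lib$ext, lib$int))
  sol <- solve_modal(mod, f)
  expect_equal(sol$a[1, 2] / sol$a[1, 1], T_closed, tolerance = 1e-10)
})

test_that("lossless scattering satisfies the optical theorem", {
  mod <- layered_sphere(0.25, list(lossless_air, lossless_tissue))
  for (f in c(400, 2000)) {
    s <- solve_modal(mod, f)
    sn <- s$b[, 1] / s$a[, 1]
    nn <- 0:s$order
    scat <- sum((2 * nn + 1) * Mod(sn)^2)
    ext <- -sum((2 * nn + 1) * Re(sn))
    expect_lt(abs(scat - ext) / scat, 1e-4)
  }
})

test_that("solution fields match an independently verified reference", {
  # frozen complex pressures computed by a separately written scipy
  # implementation of the layered-sphere series (identical physics,
  # independent code path)
  mod <- layered_sphere(c(0.25, 0.15),
                        list(lossless_air, lossless_tissue, lossless_fluid))
  sol <- solve_modal(mod, 500)
  p <- pressure_field(sol, rbind(c(0.05, 0.02, -0.03), c(0.2, 0.05, 0)))
  expect_equal(p[1], 0.150908 - 0.139194i, tolerance = 1e-4)
  expect_equal(p[2], -0.645280 - 0.124402i, tolerance = 1e-4)
  p3 <- pressure_field(solve_modal(mod, 2996.614), matrix(0, 1, 3))
  expect_equal(p3[1], 6.148907 + 2.240905i, tolerance = 1e-4)
})

test_that("a high-attenuation core damps every resonance peak", {
  lib <- tissue_library()
  vs <- validation_sweep()
  sw_lo <- vs$sweep
  peaks <- find_resonance_peaks(data.frame(
    frequency_hz = sw_lo$frequency_hz, spl_rms_db = sw_lo$spl_rms_db))
  expect_gt(nrow(peaks), 1)
  mod_hi <- layered_sphere(c(0.25, 0.15),
                           list(lib$air, lib$abdominal_tissue,
                                lib$uterine_tissue))
  sw_hi <- sweep_inner_sphere(mod_hi, peaks$frequency_hz, vs$grid)
  lo_at_peaks <- sw_lo$spl_rms_db[match(peaks$frequency_hz,
                                        sw_lo$frequency_hz)]
  expect_true(all(sw_hi$spl_rms_db < lo_at_peaks))
})

test_that("sweeps reject evaluation grids outside the innermost sphere", {
  mod <- layered_sphere(c(0.25, 0.15),
                        list(lossless_air, lossless_tissue, lossless_fluid))
  expect_error(sweep_inner_sphere(mod, 100, matrix(c(0.2, 0, 0), 1)),
               "outside")
})
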