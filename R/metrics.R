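#' Twelfth-octave band grid
#'
#' Centre frequencies `ref * 2^(n/12)` for integer `n`, restricted to
#' `[fmin, fmax]` (inclusive). The default policy is a strict enumeration:
#' every band centre inside the range is kept and nothing else. `n_bands`
#' can force a chosen count by extending the grid symmetrically (half a
#' step at a time) beyond the range.
#'
#' @param fmin lower edge, Hz (default 20).
#' @param fmax upper edge, Hz (default 20000).
#' @param ref reference middle frequency, Hz (default 1000). Must satisfy
#'   `fmin < ref < fmax`; the grid always contains it exactly.
#' @param n_bands optional integer; extend the grid alternately below/above
#'   until this many centres are present.
#' @return An object of class `band_grid`: list with `frequencies` (Hz,
#'   ascending) and `ref`.
#' @examples
#' g <- twelfth_octave_grid()
#' length(g$frequencies)
#' 1000 %in% g$frequencies
#' @export
twelfth_octave_grid <- function(fmin = 20, fmax = 20000, ref = 1000,
                                n_bands = NULL) {
  if (!(fmin > 0 && fmin < ref && ref < fmax))
    stop("need 0 < fmin < ref < fmax")
  n_lo <- ceiling(12 * log2(fmin / ref) - 1e-9)
  n_hi <- floor(12 * log2(fmax / ref) + 1e-9)
  n <- seq.int(n_lo, n_hi)
  if (!is.null(n_bands)) {
    n_bands <- as.integer(n_bands)
    if (n_bands < length(n)) stop("'n_bands' smaller than the strict count")
    below <- TRUE
    while (length(n) < n_bands) {
      n <- if (below) c(n[1] - 1L, n) else c(n, n[length(n)] + 1L)
      below <- !below
    }
  }
  structure(list(frequencies = ref * 2^(n / 12), ref = ref),
            class = "band_grid")
}

#' @export
print.band_grid <- function(x, ...) {
  f <- x$frequencies
  cat(sprintf("<band_grid> %d twelfth-octave bands, %.4g Hz .. %.5g Hz (ref %g Hz)\n",
              length(f), min(f), max(f), x$ref))
  invisible(x)
}

#' Impact sound pressure level (spatial RMS)
#'
#' The spatial root-mean-square level of complex pressures sampled over a
#' region (the ISO 10052 impact-SPL construction),
#' \deqn{L_{RMS} = 20 \log_{10} \sqrt{\frac{1}{N}\sum_{i=1}^N |p_i|^2},}
#' in dB re `ref` (default 1 Pa, so 0 dB means "equal to a unit-amplitude
#' incident wave"). Invariant under per-point phase rotation and point
#' ordering.
#'
#' @param pressures complex (or numeric) pressures in Pa; at least one.
#' @param ref reference pressure, Pa.
#' @return Scalar dB value; `-Inf` when all pressures are zero.
#' @export
impact_spl <- function(pressures, ref = 1) {
  if (length(pressures) == 0L) stop("empty pressure sample")
  rms <- sqrt(mean(Mod(pressures)^2))
  if (rms == 0) return(-Inf)
  20 * log10(rms / ref)
}

#' Maximum (l-infinity) sound pressure level
#'
#' The level of the largest pressure magnitude across the sample points,
#' \eqn{L_{\infty} = 20 \log_{10} \max_i |p_i|} (dB re `ref`). A worst-case
#' exposure measure; always at least as large as [impact_spl()] on the same
#' sample.
#'
#' @inheritParams impact_spl
#' @return Scalar dB value; `-Inf` when all pressures are zero.
#' @export
linf_spl <- function(pressures, ref = 1) {
  if (length(pressures) == 0L) stop("empty pressure sample")
  m <- max(Mod(pressures))
  if (m == 0) return(-Inf)
  20 * log10(m / ref)
}

#' Frequency sweep of in-utero exposure metrics
#'
#' Runs the transmission model at every band centre of `grid` and collects,
#' for the innermost ("uterus") region: the spatial-RMS SPL, the maximum
#' SPL, and the complex pressure at the region barycentre.
#'
#' @param topology a `nested_topology` (see [nested_sphere_phantom()]), or a
#'   function `f -> nested_topology` used to remesh per band (the
#'   elements-per-wavelength rule makes the mesh frequency-dependent).
#' @param grid a [twelfth_octave_grid()] band grid.
#' @param solver `"analytic"` (concentric-sphere topologies only) or
#'   `"bem"`.
#' @param region label of the evaluated region; defaults to the innermost
#'   surface's label.
#' @param eval_grid optional `evaluation_grid` from [interior_grid()]; when
#'   omitted one is built from the evaluated region's surface with the
#'   default spacing (region diameter / 20) and the 0.5-steradian
#'   near-surface exclusion.
#' @param tol,max_iter GMRES controls for the BEM solver.
#' @param verbose print one diagnostic line per band.
#' @return An object of class `sweep_result`: data frame with columns
#'   `frequency_hz`, `spl_rms_db`, `spl_linf_db`, `barycentre_re_pa`,
#'   `barycentre_im_pa`, `n_points`, `solver_iterations`, `solver_residual`,
#'   `ok`, plus metadata attributes. Solver failure at a band is recorded
#'   (`ok = FALSE`, metrics `NA`) and the sweep continues.
#' @export
run_sweep <- function(topology, grid, solver = c("analytic", "bem"),
                      region = NULL, eval_grid = NULL,
                      tol = 1e-4, max_iter = 2000, verbose = FALSE) {
  solver <- match.arg(solver)
  stopifnot(inherits(grid, "band_grid"))
  topo_fun <- if (is.function(topology)) topology else function(f) topology
  topo0 <- topo_fun(grid$frequencies[1])
  stopifnot(inherits(topo0, "nested_topology"))
  idx <- innermost_index(topo0, region)
  region <- topo0$surfaces[[idx]]$label

  if (is.null(eval_grid)) {
    mesh <- topo0$surfaces[[idx]]
    spacing <- 2 * enclosing_radius(mesh) / 20
    eval_grid <- interior_grid(mesh, spacing)
  }
  pts <- eval_grid$points
  bary <- volume_centroid(topo0$surfaces[[idx]])

  fs <- grid$frequencies
  res <- data.frame(frequency_hz = fs, spl_rms_db = NA_real_,
                    spl_linf_db = NA_real_, barycentre_re_pa = NA_real_,
                    barycentre_im_pa = NA_real_, n_points = nrow(pts),
                    solver_iterations = NA_integer_,
                    solver_residual = NA_real_, ok = FALSE)
  errors <- character(0)
  for (j in seq_along(fs)) {
    f <- fs[j]
    step <- tryCatch({
      topo <- topo_fun(f)
      if (solver == "analytic") {
        model <- layered_sphere_from_topology(topo)
        sol <- solve_modal(model, f)
        p <- pressure_field(sol, rbind(pts, bary))
        list(p = p[seq_len(nrow(pts))], pb = p[nrow(pts) + 1L],
             iters = NA_integer_, resid = NA_real_)
      } else {
        prob <- transmission_problem(topo, f)
        sol <- solve_transmission(assemble(prob), tol = tol,
                                  max_iter = max_iter)
        p <- evaluate_field(sol, rbind(pts, bary))
        list(p = p[seq_len(nrow(pts))], pb = p[nrow(pts) + 1L],
             iters = sol$iterations, resid = sol$residual)
      }
    }, error = function(e) e)
    if (inherits(step, "error")) {
      errors <- c(errors, sprintf("%.6g Hz: %s", f, conditionMessage(step)))
      if (verbose) message(sprintf("band %.6g Hz FAILED: %s", f,
                                   conditionMessage(step)))
      next
    }
    res$spl_rms_db[j] <- impact_spl(step$p)
    res$spl_linf_db[j] <- linf_spl(step$p)
    res$barycentre_re_pa[j] <- Re(step$pb)
    res$barycentre_im_pa[j] <- Im(step$pb)
    res$solver_iterations[j] <- step$iters
    res$solver_residual[j] <- step$resid
    res$ok[j] <- TRUE
    if (verbose)
      message(sprintf("band %8.1f Hz: RMS %6.2f dB, max %6.2f dB%s", f,
                      res$spl_rms_db[j], res$spl_linf_db[j],
                      if (is.na(step$iters)) "" else
                        sprintf(", %d iters (resid %.2e)", step$iters,
                                step$resid)))
  }
  structure(res, class = c("sweep_result", "data.frame"),
            region = region, solver = solver, errors = errors,
            barycentre = bary, eval_grid_spacing = eval_grid$spacing)
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> region '%s', solver %s, %d bands (%d ok)\n",
              attr(x, "region"), attr(x, "solver"), nrow(x), sum(x$ok)))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("  ... %d more bands\n", nrow(x) - 10L))
  invisible(x)
}

#' Locate resonance peaks in a sweep
#'
#' A band is a resonance peak when its RMS SPL exceeds both neighbours and
#' stands at least `prominence` dB above the lower of the two surrounding
#' local minima.
#'
#' @param sweep a `sweep_result` (or any data frame with `frequency_hz` and
#'   `spl_rms_db`).
#' @param prominence minimum prominence in dB (default 1).
#' @return Data frame with `frequency_hz`, `spl_rms_db`, `prominence_db` of
#'   each peak, ascending in frequency.
#' @export
find_resonance_peaks <- function(sweep, prominence = 1) {
  f <- sweep$frequency_hz
  y <- sweep$spl_rms_db
  keep <- is.finite(y)
  f <- f[keep]; y <- y[keep]
  n <- length(y)
  if (n < 3) return(data.frame(frequency_hz = numeric(0),
                               spl_rms_db = numeric(0),
                               prominence_db = numeric(0)))
  out <- list()
  for (i in 2:(n - 1)) {
    if (y[i] > y[i - 1] && y[i] >= y[i + 1]) {
      left <- min(y[1:i]); right <- min(y[i:n])
      prom <- y[i] - max(left, right)
      if (prom >= prominence)
        out[[length(out) + 1L]] <- c(f[i], y[i], prom)
    }
  }
  if (!length(out)) return(data.frame(frequency_hz = numeric(0),
                                      spl_rms_db = numeric(0),
                                      prominence_db = numeric(0)))
  m <- do.call(rbind, out)
  data.frame(frequency_hz = m[, 1], spl_rms_db = m[, 2],
             prominence_db = m[, 3])
}

#' Write / read sweep results as CSV
#'
#' The CSV holds `frequency_hz, spl_rms_db, spl_linf_db, barycentre_re_pa,
#' barycentre_im_pa`; a YAML sidecar (`<path>.meta.yml`) records region,
#' solver and grid settings. Sweeps are deterministic, so no seed is
#' recorded.
#'
#' @param sweep a `sweep_result`.
#' @param path CSV output path.
#' @export
write_sweep_csv <- function(sweep, path) {
  cols <- c("frequency_hz", "spl_rms_db", "spl_linf_db",
            "barycentre_re_pa", "barycentre_im_pa")
  utils::write.csv(as.data.frame(sweep)[, cols], path, row.names = FALSE)
  meta <- list(region = attr(sweep, "region"), solver = attr(sweep, "solver"),
               n_bands = nrow(sweep),
               eval_grid_spacing_m = attr(sweep, "eval_grid_spacing"),
               deterministic = TRUE)
  yaml::write_yaml(meta, paste0(path, ".meta.yml"))
  invisible(path)
}

#' @rdname write_sweep_csv
#' @return `read_sweep_csv()` returns the data frame (with metadata
#'   attributes when the sidecar is present).
#' @export
read_sweep_csv <- function(path) {
  df <- utils::read.csv(path)
  side <- paste0(path, ".meta.yml")
  if (file.exists(side)) {
    meta <- yaml::read_yaml(side)
    attr(df, "region") <- meta$region
    attr(df, "solver") <- meta$solver
  }
  df
}
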