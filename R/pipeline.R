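## Configuration, canned validation experiment and file-level pipeline
## commands. Every command is deterministic given its configuration; there
## is no randomness anywhere in the pipeline.

default_run_config <- function() {
  list(
    phantom = list(type = "nested_spheres", outer_radius = 0.25,
                   inner_radius = 0.15, elements_per_wavelength = 5,
                   media = list(exterior = "air", shell = "abdominal_tissue",
                                core = "amniotic_fluid")),
    band_grid = list(fmin = 20, fmax = 20000, ref = 1000),
    solver = list(type = "analytic", tol = 1e-4, max_iter = 2000,
                  max_frequency = NULL),
    evaluation = list(spacing = NULL, solid_angle_threshold = 0.5),
    incident = list(direction = c(1, 0, 0), amplitude = 1),
    output_dir = "."
  )
}

#' Read / write a run configuration
#'
#' YAML configuration driving the pipeline commands: phantom specification
#' (type, radii, media names, elements per wavelength), band grid, solver
#' choice and tolerances, evaluation-grid spacing and solid-angle
#' threshold, incident wave and output directory. Missing keys fall back
#' to defaults; validation errors are reported exhaustively.
#'
#' @param path YAML file.
#' @param media_library named list of [acoustic_medium()] used to resolve
#'   media names (default [tissue_library()]).
#' @return Object of class `run_config`.
#' @export
read_run_config <- function(path, media_library = tissue_library()) {
  raw <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_run_config(), raw)
  validate_run_config(cfg, media_library)
}

#' @rdname read_run_config
#' @param config a `run_config` (or plain list in the same shape).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

validate_run_config <- function(cfg, media_library = tissue_library()) {
  cfg <- utils::modifyList(default_run_config(), unclass(cfg))
  errs <- character(0)
  ph <- cfg$phantom
  if (!identical(ph$type, "nested_spheres"))
    errs <- c(errs, sprintf("unknown phantom type '%s'", ph$type))
  if (!is.numeric(ph$outer_radius) || !is.numeric(ph$inner_radius) ||
      !(ph$inner_radius > 0) || !(ph$inner_radius < ph$outer_radius))
    errs <- c(errs, "phantom radii must satisfy 0 < inner < outer")
  for (role in c("exterior", "shell", "core"))
    if (!ph$media[[role]] %in% names(media_library))
      errs <- c(errs, sprintf("unknown medium '%s' for %s",
                              ph$media[[role]], role))
  if (!cfg$solver$type %in% c("analytic", "bem"))
    errs <- c(errs, sprintf("unknown solver '%s'", cfg$solver$type))
  bg <- cfg$band_grid
  if (!(bg$fmin > 0 && bg$fmin < bg$ref && bg$ref < bg$fmax))
    errs <- c(errs, "band grid must satisfy 0 < fmin < ref < fmax")
  if (length(errs))
    stop("invalid run configuration:\n  - ", paste(errs, collapse = "\n  - "))
  structure(cfg, class = "run_config")
}

config_media <- function(cfg, media_library) {
  lapply(cfg$phantom$media, function(nm) media_library[[nm]])
}

config_phantom_fun <- function(cfg, media_library) {
  med <- config_media(cfg, media_library)
  function(f) nested_sphere_phantom(cfg$phantom$outer_radius,
                                    cfg$phantom$inner_radius,
                                    cfg$phantom$elements_per_wavelength,
                                    f, media = med)
}

#' Run a frequency sweep from a configuration
#'
#' Builds the phantom, runs [run_sweep()] with the configured solver over
#' the configured band grid (capped at `solver$max_frequency` when set) and
#' writes `sweep.csv` plus its metadata sidecar into the output directory.
#'
#' @param config a `run_config` from [read_run_config()].
#' @param media_library named list of media for name resolution.
#' @param verbose per-band log lines.
#' @return The `sweep_result`, invisibly.
#' @export
pipeline_sweep <- function(config, media_library = tissue_library(),
                           verbose = FALSE) {
  config <- validate_run_config(config, media_library)
  grid <- twelfth_octave_grid(config$band_grid$fmin, config$band_grid$fmax,
                              config$band_grid$ref)
  fcap <- config$solver$max_frequency
  if (!is.null(fcap))
    grid$frequencies <- grid$frequencies[grid$frequencies <= fcap]
  phantom_fun <- config_phantom_fun(config, media_library)
  eval_grid <- config_eval_grid(config, phantom_fun)
  sweep <- run_sweep(phantom_fun, grid, solver = config$solver$type,
                     eval_grid = eval_grid, tol = config$solver$tol,
                     max_iter = config$solver$max_iter, verbose = verbose)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  write_sweep_csv(sweep, file.path(config$output_dir, "sweep.csv"))
  invisible(sweep)
}

# fixed evaluation grid: built once from the phantom at the lowest density
# (the coarsest surface gives the widest near-surface exclusion, so every
# retained point is valid for all bands)
config_eval_grid <- function(config, phantom_fun) {
  topo <- phantom_fun(config$band_grid$fmin)
  idx <- innermost_index(topo)
  mesh <- topo$surfaces[[idx]]
  spacing <- config$evaluation$spacing
  if (is.null(spacing)) spacing <- 2 * enclosing_radius(mesh) / 20
  interior_grid(mesh, spacing, config$evaluation$solid_angle_threshold)
}

#' Validate the BEM against the layered-sphere solution
#'
#' The canned validation experiment: concentric spheres (defaults 0.25 m /
#' 0.15 m; air exterior, abdominal-tissue shell, amniotic-fluid core),
#' remeshed per band at the requested elements-per-wavelength density, BEM
#' solution per twelfth-octave band up to `fmax`, compared with the
#' analytical series solution on a common interior evaluation grid.
#'
#' A band is a "resonance band" when the analytical RMS-SPL curve has a
#' local maximum there (see [find_resonance_peaks()]); agreement at
#' resonances is not expected to meet the bound. The report states, per
#' band: RMS SPL of both solvers, their difference, the field-scale
#' relative error of pressure magnitudes (max over grid points, normalised
#' by the largest analytic magnitude in the band), GMRES iterations.
#'
#' @param outer_radius,inner_radius sphere radii, m.
#' @param media list with `exterior`, `shell`, `core` media.
#' @param elements_per_wavelength mesh density (default 5).
#' @param fmax highest band, Hz (default 2000: dense desk-scale BEM).
#' @param bands optional subset of band centres to run (Hz); default all
#'   twelfth-octave centres up to `fmax`.
#' @param spl_tol_db pass bound for non-resonance SPL difference (0.5 dB).
#' @param rel_tol pass bound for the relative pressure error (0.075).
#' @param tol,max_iter GMRES controls.
#' @param verbose per-band progress lines.
#' @return Object of class `sphere_validation`: per-band data frame plus
#'   summary fields (`max_abs_dspl_db`, `max_rel_error`, `pass_spl`,
#'   `pass_rel`).
#' @export
validate_spheres <- function(outer_radius = 0.25, inner_radius = 0.15,
                             media = NULL, elements_per_wavelength = 5,
                             fmax = 2000, bands = NULL, spl_tol_db = 0.5,
                             rel_tol = 0.075, tol = 1e-4, max_iter = 2000,
                             verbose = FALSE) {
  if (is.null(media)) {
    lib <- tissue_library()
    media <- list(exterior = lib$air, shell = lib$abdominal_tissue,
                  core = lib$amniotic_fluid)
  }
  grid <- twelfth_octave_grid()
  fs <- grid$frequencies[grid$frequencies <= fmax]
  if (!is.null(bands)) fs <- fs[fs %in% bands | sapply(fs, function(f)
    any(abs(bands - f) / f < 1e-9))]
  phantom_fun <- function(f) nested_sphere_phantom(outer_radius,
                                                   inner_radius,
                                                   elements_per_wavelength,
                                                   f, media = media)
  # common evaluation grid from the coarsest inner mesh used in the sweep
  topo0 <- phantom_fun(min(fs))
  egrid <- interior_grid(topo0$surfaces[[2]],
                         2 * inner_radius / 20)
  pts <- egrid$points
  model <- layered_sphere_from_topology(topo0)

  # resonance bands from the analytic curve over the full audio range
  ana_full <- sweep_inner_sphere(model, grid$frequencies, pts)
  peaks <- find_resonance_peaks(data.frame(
    frequency_hz = ana_full$frequency_hz, spl_rms_db = ana_full$spl_rms_db))
  is_resonance <- fs %in% peaks$frequency_hz

  rows <- vector("list", length(fs))
  for (j in seq_along(fs)) {
    f <- fs[j]
    sol_a <- solve_modal(model, f)
    p_a <- pressure_field(sol_a, pts)
    topo <- phantom_fun(f)
    prob <- transmission_problem(topo, f)
    sys <- assemble(prob, audit = "none")
    sol_b <- solve_transmission(sys, tol = tol, max_iter = max_iter)
    p_b <- evaluate_field(sol_b, pts, exclusion = Inf)
    spl_a <- impact_spl(p_a); spl_b <- impact_spl(p_b)
    rel <- max(Mod(p_b - p_a)) / max(Mod(p_a))
    rows[[j]] <- data.frame(
      frequency_hz = f, unknowns = sys$n,
      spl_rms_analytic_db = spl_a, spl_rms_bem_db = spl_b,
      dspl_db = spl_b - spl_a, rel_error = rel,
      resonance = is_resonance[j], iterations = sol_b$iterations,
      residual = sol_b$residual)
    if (verbose)
      message(sprintf("%8.1f Hz: dSPL %+6.3f dB, rel err %5.2f%%, %d dof, %d iters",
                      f, spl_b - spl_a, 100 * rel, sys$n,
                      sol_b$iterations))
  }
  report <- do.call(rbind, rows)
  keep <- !report$resonance
  structure(list(
    bands = report,
    max_abs_dspl_db = max(abs(report$dspl_db[keep])),
    max_rel_error = max(report$rel_error[keep]),
    pass_spl = max(abs(report$dspl_db[keep])) <= spl_tol_db,
    pass_rel = max(report$rel_error[keep]) <= rel_tol,
    spl_tol_db = spl_tol_db, rel_tol = rel_tol,
    elements_per_wavelength = elements_per_wavelength,
    n_points = nrow(pts)),
    class = "sphere_validation")
}

#' @export
print.sphere_validation <- function(x, ...) {
  cat(sprintf("<sphere_validation> %d bands, %d grid points, %g elements/wavelength\n",
              nrow(x$bands), x$n_points, x$elements_per_wavelength))
  cat(sprintf("  max |dSPL| (non-resonance) : %.3f dB (bound %.2f dB) %s\n",
              x$max_abs_dspl_db, x$spl_tol_db,
              if (x$pass_spl) "PASS" else "FAIL"))
  cat(sprintf("  max relative |p| error     : %.2f%% (bound %.1f%%) %s\n",
              100 * x$max_rel_error, 100 * x$rel_tol,
              if (x$pass_rel) "PASS" else "FAIL"))
  invisible(x)
}

#' @rdname validate_spheres
#' @param config a `run_config`; radii, density, media and solver
#'   tolerances are taken from it and the report is written to
#'   `validation.csv` in the output directory.
#' @param media_library named list of media for name resolution.
#' @export
pipeline_validate_spheres <- function(config,
                                      media_library = tissue_library(),
                                      verbose = FALSE) {
  config <- validate_run_config(config, media_library)
  fcap <- config$solver$max_frequency
  rep <- validate_spheres(
    outer_radius = config$phantom$outer_radius,
    inner_radius = config$phantom$inner_radius,
    media = config_media(config, media_library),
    elements_per_wavelength = config$phantom$elements_per_wavelength,
    fmax = if (is.null(fcap)) 2000 else fcap,
    tol = config$solver$tol, max_iter = config$solver$max_iter,
    verbose = verbose)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(rep$bands,
                   file.path(config$output_dir, "validation.csv"),
                   row.names = FALSE)
  invisible(rep)
}

#' Field map on a plane through the uterus barycentre
#'
#' Regular 2D grid of SPL values on an axis-aligned plane (default: the
#' transverse x-y plane through the barycentre of the innermost region),
#' written as CSV with coordinates; points inside the near-surface
#' exclusion zone of any interface are marked.
#'
#' @param config a `run_config`.
#' @param f frequency, Hz.
#' @param axis plane normal: `"x"`, `"y"` or `"z"` (default `"z"`, a
#'   transverse plane).
#' @param offset plane offset along the normal; default: through the
#'   innermost region's barycentre.
#' @param spacing in-plane grid spacing, m (default: outer diameter / 40).
#' @param media_library named list of media.
#' @return Data frame `x, y, z, pressure_re, pressure_im, spl_db,
#'   near_surface` (also written to `map_<f>Hz.csv`).
#' @export
pipeline_map <- function(config, f, axis = "z", offset = NULL,
                         spacing = NULL, media_library = tissue_library()) {
  config <- validate_run_config(config, media_library)
  phantom_fun <- config_phantom_fun(config, media_library)
  topo <- phantom_fun(f)
  idx <- innermost_index(topo)
  bary <- volume_centroid(topo$surfaces[[idx]])
  ax <- match(axis, c("x", "y", "z"))
  if (is.na(ax)) stop("axis must be 'x', 'y' or 'z'")
  if (is.null(offset)) offset <- bary[ax]
  R <- config$phantom$outer_radius
  if (is.null(spacing)) spacing <- 2 * R / 40
  u <- seq(-1.2 * R, 1.2 * R, by = spacing)
  pts <- switch(axis,
    x = cbind(offset, rep(u, each = length(u)), u),
    y = cbind(rep(u, each = length(u)), offset, u),
    z = cbind(rep(u, each = length(u)), u, offset))
  centre <- attr(topo, "center")
  if (!is.null(centre)) pts <- sweep(pts, 2, centre, `+`)
  if (config$solver$type == "analytic") {
    model <- layered_sphere_from_topology(
      topo, direction = config$incident$direction,
      amplitude = config$incident$amplitude)
    p <- pressure_field(solve_modal(model, f), pts)
    near <- rep(FALSE, nrow(pts))
    for (s in topo$surfaces) {
      sa <- solid_angles_cpp(pts, s$vertices, s$triangles - 1L)
      near <- near | sa$max_triangle > config$evaluation$solid_angle_threshold
    }
  } else {
    prob <- transmission_problem(topo, f,
                                 direction = config$incident$direction,
                                 amplitude = config$incident$amplitude)
    sol <- solve_transmission(assemble(prob), tol = config$solver$tol,
                              max_iter = config$solver$max_iter)
    p <- suppressWarnings(
      evaluate_field(sol, pts,
                     exclusion = config$evaluation$solid_angle_threshold))
    near <- attr(p, "near_surface")
  }
  out <- data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                    pressure_re = Re(p), pressure_im = Im(p),
                    spl_db = ifelse(Mod(p) > 0, 20 * log10(Mod(p)), -Inf),
                    near_surface = near)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(out, file.path(config$output_dir,
                                  sprintf("map_%gHz.csv", f)),
                   row.names = FALSE)
  invisible(out)
}

#' Auralize a sweep's barycentre response
#'
#' Reads a sweep CSV (as written by [pipeline_sweep()] /
#' [write_sweep_csv()]), designs the FIR filter from the barycentre
#' pressure response and convolves the input WAV.
#'
#' @param response_csv sweep CSV path.
#' @param wav_in,wav_out audio paths.
#' @param fs,delay_samples,mse_tol,max_order FIR design controls (see
#'   [build_fir()]).
#' @param resample allow resampling of mismatched input.
#' @return The `fir_filter`, invisibly.
#' @export
pipeline_auralize <- function(response_csv, wav_in, wav_out, fs = 44100,
                              delay_samples = 200, mse_tol = 1e-4,
                              max_order = 8192, resample = FALSE) {
  sweep <- read_sweep_csv(response_csv)
  fir <- build_fir(barycentre_response(sweep), fs = fs,
                   delay_samples = delay_samples, mse_tol = mse_tol,
                   max_order = max_order)
  convolve_audio(fir, wav_in, wav_out, resample = resample)
  invisible(fir)
}
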