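#' Acoustic material model
#'
#' A homogeneous acoustic medium characterised by its equilibrium speed of
#' sound, density and a power-law attenuation of compressional waves,
#' \deqn{\alpha(f) = \alpha_{ref} (f / 1\,\mathrm{MHz})^{b},}
#' where \eqn{\alpha_{ref}} is the attenuation coefficient at the 1 MHz
#' reference frequency (Np/m) and \eqn{b \in \{1, 2\}} the power-law
#' exponent. Soft tissue and bone follow a linear law (\eqn{b = 1}); water
#' and amniotic fluid follow a frequency-squared law (\eqn{b = 2}).
#'
#' @param name medium label.
#' @param c0 equilibrium speed of sound, m/s. Must be positive.
#' @param rho density, kg/m^3. Must be positive.
#' @param alpha_ref attenuation coefficient at 1 MHz, Np/m. Non-negative.
#' @param power_b attenuation power-law exponent, 1 (linear) or 2 (squared).
#' @return An object of class `acoustic_medium`.
#' @examples
#' tissue <- acoustic_medium("Abdominal tissue", 1489, 950, 0.1, 1)
#' attenuation(tissue, 1e6)   # 0.1 Np/m at the reference frequency
#' wavenumber(tissue, 1000)   # complex wavenumber at 1 kHz
#' @export
acoustic_medium <- function(name, c0, rho, alpha_ref = 0, power_b = 1) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(c0) || length(c0) != 1L || c0 <= 0)
    stop("'c0' must be a positive speed of sound in m/s")
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0)
    stop("'rho' must be a positive density in kg/m^3")
  if (!is.numeric(alpha_ref) || length(alpha_ref) != 1L || alpha_ref < 0)
    stop("'alpha_ref' must be a non-negative attenuation in Np/m at 1 MHz")
  if (!power_b %in% c(1, 2))
    stop("'power_b' must be 1 (linear law) or 2 (frequency-squared law)")
  structure(list(name = name, c0 = c0, rho = rho,
                 alpha_ref = alpha_ref, power_b = power_b),
            class = "acoustic_medium")
}

#' @export
print.acoustic_medium <- function(x, ...) {
  cat(sprintf("<acoustic_medium> %s: c0 = %g m/s, rho = %g kg/m^3, alpha(1 MHz) = %g Np/m (law f^%d)\n",
              x$name, x$c0, x$rho, x$alpha_ref, x$power_b))
  invisible(x)
}

#' Viscoelastic loss-tangent material specification
#'
#' Describes a medium through its equilibrium speed of sound and the loss
#' tangent \eqn{\tan\delta} of its complex modulus. In an infinite
#' viscoelastic solid carrying no shear waves, the longitudinal sound speed
#' is \eqn{c_L = c_0 \sqrt{1 + i \tan\delta} = c_0 e^{i\delta/2} /
#' \sqrt{\cos\delta}}, which yields a frequency-linear attenuation
#' coefficient (see [loss_tangent_attenuation()]).
#'
#' @param c0 equilibrium speed of sound, m/s.
#' @param tan_delta loss tangent, dimensionless, in `[0, 1)`.
#' @param rho density, kg/m^3.
#' @return An object of class `viscoelastic_spec`.
#' @export
viscoelastic_medium <- function(c0, tan_delta, rho = 1000) {
  if (!is.numeric(c0) || length(c0) != 1L || c0 <= 0)
    stop("'c0' must be a positive speed of sound in m/s")
  if (!is.numeric(tan_delta) || length(tan_delta) != 1L ||
      tan_delta < 0 || tan_delta >= 1)
    stop("'tan_delta' must lie in [0, 1)")
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0)
    stop("'rho' must be a positive density in kg/m^3")
  structure(list(c0 = c0, tan_delta = tan_delta, rho = rho),
            class = "viscoelastic_spec")
}

#' @export
print.viscoelastic_spec <- function(x, ...) {
  cat(sprintf("<viscoelastic_spec> c0 = %g m/s, tan(delta) = %g, rho = %g kg/m^3\n",
              x$c0, x$tan_delta, x$rho))
  invisible(x)
}

#' Attenuation coefficient from a loss tangent
#'
#' Converts a loss-tangent viscoelastic specification into an attenuation
#' coefficient at frequency `f`:
#' \deqn{\alpha(f) = \frac{2 \pi \sqrt{\cos\delta}}{c_0}
#'       \sin\!\frac{\delta}{2} \; f, \qquad \delta = \arctan(\tan\delta).}
#' The result is exactly linear in frequency and vanishes in the lossless
#' limit \eqn{\tan\delta = 0}.
#'
#' @param spec a [viscoelastic_medium()] specification.
#' @param f frequency in Hz, non-negative (vectorised).
#' @return Attenuation in Np/m, same length as `f`.
#' @export
loss_tangent_attenuation <- function(spec, f) {
  stopifnot(inherits(spec, "viscoelastic_spec"))
  if (any(f < 0)) stop("frequency must be non-negative")
  delta <- atan(spec$tan_delta)
  2 * pi * sqrt(cos(delta)) / spec$c0 * sin(delta / 2) * f
}

#' Power-law attenuation coefficient
#'
#' @param medium an [acoustic_medium()].
#' @param f frequency in Hz, non-negative (vectorised).
#' @return Attenuation in Np/m: `alpha_ref * (f / 1e6)^power_b`.
#' @export
attenuation <- function(medium, f) {
  stopifnot(inherits(medium, "acoustic_medium"))
  if (any(f < 0)) stop("frequency must be non-negative")
  medium$alpha_ref * (f / 1e6)^medium$power_b
}

#' Complex wavenumber of a medium at an audio frequency
#'
#' With the time convention \eqn{e^{-i\omega t}}, a forward plane wave is
#' \eqn{e^{ikx}} and physical dissipation requires \eqn{\mathrm{Im}\,k > 0}
#' in a lossy medium so that the wave decays along propagation. The returned
#' wavenumber is \eqn{k = 2\pi f / c_0 + i\,\alpha(f)}.
#'
#' For a [viscoelastic_medium()] the exact complex sound speed
#' \eqn{c_L = c_0 e^{i\delta/2}/\sqrt{\cos\delta}} is used, giving
#' \eqn{k = (\omega \sqrt{\cos\delta} / c_0)(\cos\frac{\delta}{2} +
#' i \sin\frac{\delta}{2})}; for small \eqn{\delta} this agrees with
#' \eqn{(\omega/c_0)(1 + i\delta/2)} to second order.
#'
#' @param medium an [acoustic_medium()] or [viscoelastic_medium()].
#' @param f frequency in Hz, strictly positive (vectorised).
#' @return Complex wavenumber(s) in 1/m.
#' @export
wavenumber <- function(medium, f) UseMethod("wavenumber")

#' @export
wavenumber.acoustic_medium <- function(medium, f) {
  if (any(f <= 0)) stop("frequency must be strictly positive")
  complex(real = 2 * pi * f / medium$c0, imaginary = attenuation(medium, f))
}

#' @export
wavenumber.viscoelastic_spec <- function(medium, f) {
  if (any(f <= 0)) stop("frequency must be strictly positive")
  delta <- atan(medium$tan_delta)
  omega <- 2 * pi * f
  omega * sqrt(cos(delta)) / medium$c0 *
    complex(real = cos(delta / 2), imaginary = sin(delta / 2))
}

#' Acoustic wavelength in a medium
#'
#' @param medium an [acoustic_medium()].
#' @param f frequency in Hz.
#' @return Wavelength `c0 / f` in metres.
#' @export
wavelength <- function(medium, f) {
  stopifnot(inherits(medium, "acoustic_medium"))
  if (any(f <= 0)) stop("frequency must be strictly positive")
  medium$c0 / f
}

#' Reference library of anatomical acoustic properties
#'
#' Returns the acoustic constants used for the anatomical groups of the
#' abdominal model: abdominal (generic soft) tissue, spine bone, uterine
#' tissue (muscle, the high-attenuation bound for the uterine content) and
#' amniotic fluid (water-like, the low-attenuation bound), plus the air
#' exterior (c0 = 343 m/s, rho = 1.2 kg/m^3, lossless; standard values, the
#' exterior path lengths make air absorption negligible at audio
#' frequencies). Attenuation coefficients are referenced to 1 MHz.
#'
#' @return Named list of [acoustic_medium()] objects with keys
#'   `air`, `abdominal_tissue`, `spine_bone`, `uterine_tissue`,
#'   `amniotic_fluid`.
#' @export
tissue_library <- function() {
  list(
    air             = acoustic_medium("Air", 343, 1.2, 0, 1),
    abdominal_tissue = acoustic_medium("Abdominal tissue", 1489, 950, 0.1, 1),
    spine_bone      = acoustic_medium("Spine bone", 4020, 2700, 0.2, 1),
    uterine_tissue  = acoustic_medium("Uterine tissue", 1500, 1000, 585.3, 1),
    amniotic_fluid  = acoustic_medium("Amniotic fluid", 1500, 1000, 15e-3, 2)
  )
}

#' Read / write material tables
#'
#' Material tables are stored as YAML: a named map of entries with keys
#' `name`, `c0`, `rho`, `alpha_ref_1MHz`, `power_b`.
#'
#' @param path file path.
#' @return `read_media_config()` returns a named list of
#'   [acoustic_medium()] objects.
#' @export
read_media_config <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, function(m) {
    need <- c("name", "c0", "rho", "alpha_ref_1MHz", "power_b")
    if (!all(need %in% names(m)))
      stop("media config entry missing keys: ",
           paste(setdiff(need, names(m)), collapse = ", "))
    acoustic_medium(m$name, m$c0, m$rho, m$alpha_ref_1MHz, m$power_b)
  })
  names(out) <- names(raw)
  out
}

#' @rdname read_media_config
#' @param media named list of [acoustic_medium()] objects.
#' @export
write_media_config <- function(media, path) {
  stopifnot(all(vapply(media, inherits, TRUE, "acoustic_medium")))
  raw <- lapply(media, function(m)
    list(name = m$name, c0 = m$c0, rho = m$rho,
         alpha_ref_1MHz = m$alpha_ref, power_b = m$power_b))
  yaml::write_yaml(raw, path)
  invisible(path)
}
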