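## FIR auralization: turn a complex in-utero frequency response into a
## causal filter and convolve audio with it.

#' Complex frequency response
#'
#' @param frequencies Hz, strictly increasing.
#' @param values complex transfer values (Pa out per Pa in).
#' @return Object of class `frequency_response`.
#' @export
frequency_response <- function(frequencies, values) {
  frequencies <- as.numeric(frequencies)
  values <- as.complex(values)
  stopifnot(length(frequencies) == length(values), length(frequencies) >= 2)
  if (any(diff(frequencies) <= 0))
    stop("frequencies must be strictly increasing")
  if (any(!is.finite(frequencies)) || any(!is.finite(values)))
    stop("non-finite frequency response")
  structure(list(frequencies = frequencies, values = values),
            class = "frequency_response")
}

#' @export
print.frequency_response <- function(x, ...) {
  cat(sprintf("<frequency_response> %d points, %.4g Hz .. %.5g Hz\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies)))
  invisible(x)
}

#' Barycentre frequency response of a sweep
#'
#' @param sweep a `sweep_result` (or data frame with `frequency_hz`,
#'   `barycentre_re_pa`, `barycentre_im_pa`).
#' @return A [frequency_response()].
#' @export
barycentre_response <- function(sweep) {
  ok <- is.finite(sweep$barycentre_re_pa) & is.finite(sweep$barycentre_im_pa)
  frequency_response(sweep$frequency_hz[ok],
                     complex(real = sweep$barycentre_re_pa[ok],
                             imaginary = sweep$barycentre_im_pa[ok]))
}

unwrap_phase <- function(phase) {
  d <- diff(phase)
  phase - c(0, cumsum(2 * pi * round(d / (2 * pi))))
}

#' Extend a response to the full design band
#'
#' The sweep covers the audio band but the FIR design grid spans
#' `[0, fs/2]`. Below the lowest sweep frequency the magnitude is held
#' constant (the predicted transfer extends flat into infrasound, down to
#' 0 Hz) with phase through the origin; above the highest frequency the
#' magnitude rolls off to zero at the Nyquist frequency with the phase
#' continued linearly at the last group-delay slope. In-band values are
#' untouched.
#'
#' @param resp a [frequency_response()].
#' @param fs sampling rate, Hz.
#' @return A [frequency_response()] spanning `[0, fs/2]`.
#' @export
extend_response <- function(resp, fs = 44100) {
  stopifnot(inherits(resp, "frequency_response"))
  f <- resp$frequencies
  if (max(f) >= fs / 2 && min(f) <= 0) return(resp)
  mag <- Mod(resp$values)
  ph <- unwrap_phase(Arg(resp$values))
  n <- length(f)
  if (min(f) > 0) {
    f <- c(0, f); mag <- c(mag[1], mag); ph <- c(0, ph)
    n <- n + 1L
  }
  if (max(f) < fs / 2) {
    slope <- (ph[n] - ph[n - 1]) / (f[n] - f[n - 1])
    f <- c(f, fs / 2)
    mag <- c(mag, 0)
    ph <- c(ph, ph[n] + slope * (fs / 2 - f[n]))
  }
  frequency_response(f, complex(modulus = mag, argument = ph))
}

#' Least-squares FIR synthesis from a complex frequency response
#'
#' Design pipeline: spline-interpolate the magnitude and the unwrapped
#' phase onto a uniform grid of `n_interp` points over `[0, fs/2]`;
#' multiply by the linear phase `exp(-i 2 pi f delay / fs)` (a constant
#' `delay_samples` latency linearises the phase and makes the filter
#' causal); extend Hermitian-symmetrically to the full circle and fit a
#' real FIR of increasing order by least squares on that grid (with a full
#' uniform DFT grid the least-squares optimum is the truncated inverse
#' DFT), doubling the order until the relative magnitude-spectrum MSE
#' drops below `mse_tol` or the order cap is reached.
#'
#' @param resp a [frequency_response()]; extended with
#'   [extend_response()] if it does not already span `[0, fs/2]`.
#' @param fs sampling rate, Hz (default 44100).
#' @param n_interp interpolation points over `[0, fs/2]` (default 16385).
#' @param delay_samples constant delay, samples (default 200).
#' @param mse_tol relative design MSE target (default 1e-4).
#' @param max_order order cap, taps (default 8192).
#' @return Object of class `fir_filter`: `h` (impulse response, index 1 =
#'   time 0), `fs`, `order`, `delay_samples`, `mse`.
#' @export
build_fir <- function(resp, fs = 44100, n_interp = 16385,
                      delay_samples = 200, mse_tol = 1e-4,
                      max_order = 8192) {
  stopifnot(inherits(resp, "frequency_response"), n_interp >= 16,
            delay_samples >= 0)
  resp <- extend_response(resp, fs)
  fgrid <- seq(0, fs / 2, length.out = n_interp)
  mag <- stats::spline(resp$frequencies, Mod(resp$values), xout = fgrid,
                       method = "natural")$y
  mag <- pmax(mag, 0)
  ph <- stats::spline(resp$frequencies, unwrap_phase(Arg(resp$values)),
                      xout = fgrid, method = "natural")$y
  target <- complex(modulus = mag, argument = ph) *
    exp(-2i * pi * fgrid * delay_samples / fs)
  M <- 2L * (n_interp - 1L)
  Hfull <- complex(M)
  Hfull[1:n_interp] <- target
  Hfull[1] <- Re(target[1])
  Hfull[n_interp] <- Re(target[n_interp])
  Hfull[(n_interp + 1L):M] <- Conj(Hfull[seq(n_interp - 1L, 2L)])
  h_full <- Re(stats::fft(Hfull, inverse = TRUE)) / M
  tnorm <- mean(Mod(target)^2)
  if (tnorm == 0) stop("zero frequency response")
  order <- 256L
  repeat {
    order <- min(order, max_order)
    h <- h_full[seq_len(order)]
    Hfit <- stats::fft(c(h, rep(0, M - order)))[1:n_interp]
    mse <- mean(Mod(Hfit - target)^2) / tnorm
    if (mse <= mse_tol || order >= max_order) break
    order <- order * 2L
  }
  if (mse > mse_tol)
    stop(sprintf("FIR design MSE %.3e above tolerance %.1e at the %d-tap order cap",
                 mse, mse_tol, max_order))
  structure(list(h = h, fs = fs, order = order,
                 delay_samples = delay_samples, mse = mse,
                 n_interp = n_interp),
            class = "fir_filter")
}

#' @export
print.fir_filter <- function(x, ...) {
  cat(sprintf("<fir_filter> %d taps at %g Hz, design delay %g samples, MSE %.3e\n",
              x$order, x$fs, x$delay_samples, x$mse))
  invisible(x)
}

#' Discrete frequency response of an FIR filter
#'
#' @param fir a `fir_filter`.
#' @param n_points one-sided grid size over `[0, fs/2]`.
#' @return Data frame `frequency_hz`, `response` (complex).
#' @export
fir_response <- function(fir, n_points = fir$n_interp) {
  M <- 2L * (n_points - 1L)
  H <- stats::fft(c(fir$h, rep(0, M - length(fir$h))))[1:n_points]
  data.frame(frequency_hz = seq(0, fir$fs / 2, length.out = n_points),
             response = H)
}

#' Mean group delay of an FIR filter over a band
#'
#' Group delay from the derivative of the unwrapped phase of the discrete
#' frequency response, averaged over `[f_lo, f_hi]`, in samples.
#'
#' @param fir a `fir_filter`.
#' @param f_lo,f_hi band edges, Hz (defaults 100 and 10000).
#' @return Mean group delay in samples.
#' @export
group_delay <- function(fir, f_lo = 100, f_hi = 10000) {
  fr <- fir_response(fir)
  ph <- unwrap_phase(Arg(fr$response))
  f <- fr$frequency_hz
  gd <- -diff(ph) / diff(f) * fir$fs / (2 * pi)
  fm <- (f[-1] + f[-length(f)]) / 2
  mean(gd[fm >= f_lo & fm <= f_hi])
}

#' Apply an FIR filter to samples
#'
#' Linear (full) convolution via FFT; output length is
#' `n + length(h) - 1`.
#'
#' @param fir a `fir_filter`.
#' @param x numeric vector or n x channels matrix.
#' @return Filtered samples (same shape convention, longer by
#'   `length(h) - 1`).
#' @export
apply_fir <- function(fir, x) {
  h <- fir$h
  one <- function(v) {
    nout <- length(v) + length(h) - 1L
    nfft <- 2^ceiling(log2(nout))
    Re(stats::fft(stats::fft(c(v, rep(0, nfft - length(v)))) *
                  stats::fft(c(h, rep(0, nfft - length(h)))),
                  inverse = TRUE))[seq_len(nout)] / nfft
  }
  if (is.matrix(x)) apply(x, 2, one) else one(x)
}

#' Convolve a WAV file with an FIR filter
#'
#' Stereo inputs are filtered per channel with the same filter. The output
#' is peak-normalised to `peak_dbfs` (default -1 dBFS) and the applied
#' gain is recorded in the returned metadata (and a YAML sidecar).
#'
#' @param fir a `fir_filter`.
#' @param wav_in,wav_out input/output WAV paths.
#' @param resample allow linear-interpolation resampling when the input
#'   rate differs from the filter rate (default FALSE: mismatch is an
#'   error).
#' @param peak_dbfs output peak level, dBFS.
#' @return Invisibly, a list with `gain`, `peak_in`, `n_samples_out`,
#'   `rate`.
#' @export
convolve_audio <- function(fir, wav_in, wav_out, resample = FALSE,
                           peak_dbfs = -1) {
  w <- read_wav(wav_in)
  x <- w$samples
  if (w$rate != fir$fs) {
    if (!resample)
      stop(sprintf("sample-rate mismatch: WAV %g Hz vs filter %g Hz (set resample = TRUE to convert)",
                   w$rate, fir$fs))
    n_out <- round(nrow(x) * fir$fs / w$rate)
    t_in <- seq(0, (nrow(x) - 1)) / w$rate
    t_out <- seq(0, n_out - 1) / fir$fs
    x <- apply(x, 2, function(ch) stats::approx(t_in, ch, xout = t_out,
                                                rule = 2)$y)
  }
  y <- apply_fir(fir, x)
  if (!is.matrix(y)) y <- matrix(y, ncol = 1)
  peak <- max(abs(y))
  gain <- if (peak > 0) 10^(peak_dbfs / 20) / peak else 1
  write_wav(y * gain, fir$fs, wav_out, bits = w$bits)
  meta <- list(gain = gain, peak_in = peak, n_samples_out = nrow(y),
               rate = fir$fs, filter_order = fir$order)
  yaml::write_yaml(meta, paste0(wav_out, ".meta.yml"))
  invisible(meta)
}

#' Save / load an FIR filter as text
#'
#' Two whitespace-separated columns (sample index from 0, coefficient)
#' plus a YAML metadata sidecar (`<path>.meta.yml`).
#'
#' @param fir a `fir_filter`.
#' @param path output path.
#' @export
write_fir <- function(fir, path) {
  utils::write.table(data.frame(sample = seq_along(fir$h) - 1L,
                                coefficient = fir$h),
                     path, row.names = FALSE, col.names = TRUE,
                     quote = FALSE)
  yaml::write_yaml(list(fs = fir$fs, order = fir$order,
                        delay_samples = fir$delay_samples, mse = fir$mse,
                        n_interp = fir$n_interp),
                   paste0(path, ".meta.yml"))
  invisible(path)
}

#' @rdname write_fir
#' @export
read_fir <- function(path) {
  tab <- utils::read.table(path, header = TRUE)
  meta <- yaml::read_yaml(paste0(path, ".meta.yml"))
  structure(list(h = tab$coefficient, fs = meta$fs, order = meta$order,
                 delay_samples = meta$delay_samples, mse = meta$mse,
                 n_interp = meta$n_interp),
            class = "fir_filter")
}

## ---- minimal RIFF/WAVE I/O (16-bit PCM and 32-bit float) ------------------

#' Read / write WAV audio
#'
#' Minimal RIFF/WAVE support: 16-bit integer PCM and 32-bit IEEE float,
#' mono or multi-channel. Samples are exchanged as doubles in `[-1, 1]`.
#'
#' @param path WAV file path.
#' @return `read_wav()`: list with `samples` (n x channels matrix),
#'   `rate`, `bits`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- rawToChar(readBin(con, "raw", 4))
  if (riff != "RIFF") stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")
  if (rawToChar(readBin(con, "raw", 4)) != "WAVE")
    stop("not a WAVE file: ", path)
  fmt <- NULL; dat <- NULL
  repeat {
    idraw <- readBin(con, "raw", 4)
    if (length(idraw) < 4) break
    id <- rawToChar(idraw)
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    body <- readBin(con, "raw", sz + sz %% 2)
    if (id == "fmt ") fmt <- body[seq_len(sz)]
    else if (id == "data") dat <- body[seq_len(sz)]
    if (!is.null(fmt) && !is.null(dat)) break
  }
  if (is.null(fmt) || is.null(dat)) stop("missing fmt/data chunk in ", path)
  fmt_tag <- readBin(fmt[1:2], "integer", 1, 2, endian = "little",
                     signed = FALSE)
  channels <- readBin(fmt[3:4], "integer", 1, 2, endian = "little")
  rate <- readBin(fmt[5:8], "integer", 1, 4, endian = "little")
  bits <- readBin(fmt[15:16], "integer", 1, 2, endian = "little")
  if (fmt_tag == 1L && bits == 16L) {
    v <- readBin(dat, "integer", length(dat) / 2, 2, endian = "little") /
      32768
  } else if (fmt_tag == 3L && bits == 32L) {
    v <- readBin(dat, "numeric", length(dat) / 4, 4, endian = "little")
  } else {
    stop(sprintf("unsupported WAV encoding (format %d, %d bits)", fmt_tag,
                 bits))
  }
  list(samples = matrix(v, ncol = channels, byrow = TRUE), rate = rate,
       bits = bits)
}

#' @rdname read_wav
#' @param samples numeric vector or n x channels matrix in `[-1, 1]`.
#' @param rate sampling rate, Hz.
#' @param bits 16 (integer PCM) or 32 (IEEE float).
#' @export
write_wav <- function(samples, rate, path, bits = 16) {
  if (!is.matrix(samples)) samples <- matrix(samples, ncol = 1)
  channels <- ncol(samples)
  inter <- as.numeric(t(samples))          # interleave channels
  if (bits == 16) {
    pcm <- writeBin(as.integer(pmax(pmin(round(inter * 32767), 32767),
                                    -32768)),
                    raw(), size = 2, endian = "little")
    fmt_tag <- 1L
  } else if (bits == 32) {
    pcm <- writeBin(inter, raw(), size = 4, endian = "little")
    fmt_tag <- 3L
  } else stop("bits must be 16 or 32")
  block <- channels * bits / 8
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + length(pcm)), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, size = 4, endian = "little")
  writeBin(as.integer(fmt_tag), con, size = 2, endian = "little")
  writeBin(as.integer(channels), con, size = 2, endian = "little")
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * block), con, size = 4, endian = "little")
  writeBin(as.integer(block), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(length(pcm)), con, size = 4, endian = "little")
  writeBin(pcm, con)
  invisible(path)
}
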